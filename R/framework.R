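# Plug-in pipeline engine: discovery, wiring validation, sequential
# offline/online processing into the typed DataTable, and export.
#
# Processing is strictly sequential — determinism over throughput: rerun
# on the same inputs gives a bit-identical table, and an online run over a
# growing directory equals the offline run on the final file set.

#' Discover plug-ins in a directory
#'
#' Sources every `.R` file in the directory in an isolated environment and
#' registers each [PluginDescriptor-class] it defines. Malformed files are
#' skipped with a logged diagnostic, never fatally; duplicate plug-in
#' names are an error.
#'
#' @param directory path containing plug-in `.R` files.
#' @param registry an existing registry (named list) to extend, e.g.
#'   [builtinPlugins()].
#' @return named list of [PluginDescriptor-class] objects.
#' @export
discoverPlugins <- function(directory, registry = list()) {
  if (!dir.exists(directory)) stop("plug-in directory does not exist")
  for (f in sort(list.files(directory, pattern = "\\.[rR]$",
                            full.names = TRUE))) {
    env <- new.env(parent = getNamespace("saxspipe"))
    found <- tryCatch({
      sys.source(f, envir = env)
      objs <- Filter(function(o) is(o, "PluginDescriptor"),
                     mget(ls(env), envir = env))
      for (o in objs) validObject(o)
      objs
    }, error = function(e) {
      logMsg("warning", "skipping malformed plug-in '%s': %s",
             basename(f), conditionMessage(e))
      NULL
    })
    for (o in found) {
      if (o@name %in% names(registry))
        stop(sprintf("duplicate plug-in name '%s' (in %s)",
                     o@name, basename(f)))
      registry[[o@name]] <- o
    }
  }
  registry
}

# Topological order of the graph's nodes; NULL if cyclic.
.topoOrder <- function(graph) {
  nodes <- names(graph@nodes)
  deps <- lapply(graph@nodes, function(nd) {
    refs <- sub("\\.[^.]*$", "", unname(nd$inputs))
    intersect(refs, nodes)
  })
  order <- character()
  remaining <- nodes
  repeat {
    ready <- remaining[vapply(remaining, function(n)
      all(deps[[n]] %in% order), logical(1))]
    if (!length(ready)) break
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) NULL else order
}

#' Validate a pipeline graph against a registry
#'
#' Type-checks all wiring before any data flows: every node must name a
#' registered plug-in, every input port must be wired to an existing,
#' type-compatible upstream output (or to the reserved `source.path` of
#' type text), and the graph must be acyclic. Each problem is reported
#' with the offending node and port.
#'
#' @param graph a [PipelineGraph-class].
#' @param registry named list of [PluginDescriptor-class].
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validateGraph <- function(graph, registry) {
  errors <- character()
  nodes <- graph@nodes
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    pl <- registry[[nd$plugin]]
    if (is.null(pl)) {
      errors <- c(errors, sprintf("node '%s': unknown plug-in '%s'",
                                  nm, nd$plugin))
      next
    }
    wired <- names(nd$inputs)
    for (port in names(pl@inputs)) {
      if (!port %in% wired) {
        errors <- c(errors, sprintf("node '%s': dangling input '%s'",
                                    nm, port))
        next
      }
      ref <- nd$inputs[[port]]
      if (identical(ref, "source.path")) {
        srcType <- "text"
      } else {
        upNode <- sub("\\.[^.]*$", "", ref)
        upPort <- sub("^.*\\.", "", ref)
        up <- nodes[[upNode]]
        if (is.null(up)) {
          errors <- c(errors, sprintf(
            "node '%s' input '%s': reference to unknown node '%s'",
            nm, port, upNode))
          next
        }
        upPlugin <- registry[[up$plugin]]
        if (is.null(upPlugin) || !upPort %in% names(upPlugin@outputs)) {
          errors <- c(errors, sprintf(
            "node '%s' input '%s': upstream '%s' has no output '%s'",
            nm, port, upNode, upPort))
          next
        }
        srcType <- upPlugin@outputs[[upPort]]
      }
      wantType <- pl@inputs[[port]]
      if (!identical(srcType, wantType))
        errors <- c(errors, sprintf(
          "node '%s' input '%s' (%s) wired to '%s' of type %s",
          nm, port, wantType, nd$inputs[[port]], srcType))
    }
  }
  if (is.null(.topoOrder(graph)))
    errors <- c(errors, "graph contains a cycle")
  list(ok = length(errors) == 0, errors = errors)
}

# Declared output columns (namespaced node.output) of a graph.
graphColumns <- function(graph, registry) {
  types <- character()
  for (nm in names(graph@nodes)) {
    pl <- registry[[graph@nodes[[nm]]$plugin]]
    outs <- pl@outputs
    if (length(outs))
      types[paste0(nm, ".", names(outs))] <- unname(outs)
  }
  c(types, errors = "text")
}

# TRUE if the node consumes the per-dataset source directly.
.isReader <- function(node) any(node$inputs == "source.path")

#' Process one data set through a validated graph
#'
#' Executes the plug-ins in topological order and returns the union of
#' their outputs as one row (cells named `node.output`). A plug-in failure
#' yields NaN/empty cells for its outputs plus an entry in the `errors`
#' column, and downstream nodes that depended on it fail the same way —
#' the row is still produced. A reader failure (a node consuming
#' `source.path`) skips the data set: `NULL` is returned and logged.
#'
#' @param graph a validated [PipelineGraph-class].
#' @param item list describing the data set, with `$path`.
#' @param registry plug-in registry.
#' @return named list (one table row), or `NULL` if the reader failed.
#' @export
processDataset <- function(graph, item, registry) {
  order <- .topoOrder(graph)
  if (is.null(order)) stop("cannot process a cyclic graph")
  values <- list(`source.path` = item$path)
  row <- list()
  failures <- character()
  for (nm in order) {
    nd <- graph@nodes[[nm]]
    pl <- registry[[nd$plugin]]
    inputs <- lapply(nd$inputs, function(ref) values[[ref]])
    names(inputs) <- names(nd$inputs)
    upFailed <- any(vapply(nd$inputs, function(ref) {
      ref != "source.path" && is.null(values[[ref]])
    }, logical(1)))
    params <- nd$params
    out <- if (upFailed) NULL else tryCatch(
      pl@fun(inputs, params),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("%s: %s", nm, conditionMessage(e)))
        NULL
      })
    if (is.null(out)) {
      if (.isReader(nd)) {
        logMsg("warning", "reader '%s' failed on '%s': data set skipped",
               nm, item$path)
        return(NULL)
      }
      if (upFailed)
        failures <- c(failures, sprintf("%s: upstream failure", nm))
      for (port in names(pl@outputs)) {
        row[[paste0(nm, ".", port)]] <-
          if (pl@outputs[[port]] == "scalar") NaN else NULL
      }
      next
    }
    for (port in names(pl@outputs)) {
      v <- out[[port]]
      values[[paste0(nm, ".", port)]] <- v
      # the table stores images as path references, never pixels
      row[[paste0(nm, ".", port)]] <-
        if (pl@outputs[[port]] == "image-ref" && is(v, "Frame"))
          v@sourcePath else v
    }
  }
  row$errors <- paste(failures, collapse = "; ")
  row
}

#' Run a pipeline offline over a file list
#'
#' Sequentially processes each file through the graph and accumulates one
#' row per successfully read data set, in input order. Deterministic given
#' the inputs.
#'
#' @param graph a [PipelineGraph-class].
#' @param files character vector of data files.
#' @param registry plug-in registry (default [builtinPlugins()]).
#' @return A [DataTable-class].
#' @export
runOffline <- function(graph, files, registry = builtinPlugins()) {
  v <- validateGraph(graph, registry)
  if (!v$ok) stop(paste(c("invalid graph:", v$errors), collapse = "\n  "))
  table <- dataTable(graphColumns(graph, registry))
  for (f in files) {
    row <- processDataset(graph, list(path = f), registry)
    if (!is.null(row)) table <- appendRow(table, row)
  }
  table
}

#' Run a pipeline online on a growing directory
#'
#' Polls the directory and processes files matching `pattern` exactly
#' once, in name-sorted order within each arrival batch. A file becomes
#' eligible only when its size is unchanged across two consecutive polls
#' (completeness heuristic for partially written frames). An unreadable
#' eligible file is logged, retried on the next poll, then marked failed.
#' The run stops after the queue has drained and `idlePolls` consecutive
#' polls saw nothing new; `onPoll` (called once per poll, mainly a test
#' and instrumentation hook — e.g. to drop files into the directory from
#' the same process) can return `FALSE` to announce that no further files
#' will arrive.
#'
#' @param graph a [PipelineGraph-class].
#' @param directory watched directory.
#' @param pattern regular expression for eligible file names.
#' @param poll poll interval, seconds.
#' @param registry plug-in registry.
#' @param idlePolls consecutive quiet polls before stopping.
#' @param maxPolls hard safety cap on poll iterations.
#' @param onPoll optional `function(i)`; return `FALSE` once the source is
#'   exhausted.
#' @return A [DataTable-class] equal to [runOffline()] on the final file
#'   set.
#' @export
runOnline <- function(graph, directory, pattern = "\\.(tif|tiff|edf)$",
                      poll = 0.05, registry = builtinPlugins(),
                      idlePolls = 3, maxPolls = 10000, onPoll = NULL) {
  if (!dir.exists(directory)) stop("watched directory does not exist")
  v <- validateGraph(graph, registry)
  if (!v$ok) stop(paste(c("invalid graph:", v$errors), collapse = "\n  "))
  table <- dataTable(graphColumns(graph, registry))
  prevSize <- numeric()
  processed <- character()
  failed <- character()
  attempts <- new.env(parent = emptyenv())
  draining <- is.null(onPoll)
  idle <- 0L
  for (i in seq_len(maxPolls)) {
    if (!draining) {
      more <- onPoll(i)
      if (!isTRUE(more)) draining <- TRUE
    }
    files <- sort(list.files(directory, pattern = pattern))
    sizes <- file.size(file.path(directory, files))
    names(sizes) <- files
    stable <- files[files %in% names(prevSize) &
                      sizes[files] == prevSize[files]]
    todo <- setdiff(stable, c(processed, failed))
    for (f in todo) {      # name-sorted within the arrival batch
      row <- tryCatch(
        processDataset(graph, list(path = file.path(directory, f)),
                       registry),
        error = function(e) NULL)
      if (is.null(row)) {
        n <- (attempts[[f]] %||% 0L) + 1L
        attempts[[f]] <- n
        if (n >= 2L) {
          logMsg("warning", "file '%s' failed twice: marked failed", f)
          failed <- c(failed, f)
        } else {
          logMsg("info", "file '%s' unreadable; will retry", f)
        }
      } else {
        table <- appendRow(table, row)
        processed <- c(processed, f)
      }
    }
    pendingNew <- length(setdiff(files, c(processed, failed,
                                          names(prevSize)))) > 0
    pendingRetry <- length(setdiff(stable, c(processed, failed))) > 0
    unstable <- length(setdiff(files, c(processed, failed, stable))) > 0
    prevSize <- sizes
    if (draining && !pendingNew && !pendingRetry && !unstable) {
      idle <- idle + 1L
      if (idle >= idlePolls) break
    } else idle <- 0L
    if (poll > 0) Sys.sleep(poll)
  }
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a DataTable through an export plug-in or writer
#'
#' Delegates to [writeTable()] (`format = "table"`) or, for per-frame map
#' export, to [writeMapGrid()] via [boneMap()] column conventions.
#'
#' @param table a [DataTable-class].
#' @param path output path.
#' @param format `"table"` for the spreadsheet-style text export.
#' @return written path(s), invisibly.
#' @export
exportTable <- function(table, path, format = c("table")) {
  format <- match.arg(format)
  writeTable(table, path)
}
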