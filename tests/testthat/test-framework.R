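# Plug-in discovery, graph validation, offline/online processing, export.

writeTestFrames <- function(dir, n, seed = 1, nr = 16, nc = 16) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n)
  for (k in seq_len(n)) {
    set.seed(seed + k)
    files[k] <- file.path(dir, sprintf("f_%03d.tif", k))
    writeFrameTIFF(matrix(rpois(nr * nc, 60 + k), nr, nc), files[k])
  }
  files
}

roiGraph <- function() pipelineGraph(list(
  read = list(plugin = "reader", params = list(),
              inputs = c(path = "source.path")),
  roi = list(plugin = "roi_stats",
             params = list(x = 2, y = 2, width = 8, height = 8),
             inputs = c(frame = "read.frame"))))

test_that("plug-in discovery registers well-formed files and skips broken ones", {
  dir <- tempfile(); dir.create(dir)
  # the ROI-statistics example: four scalar outputs
  writeLines('
plugin <- scatterPlugin(
  "my_roi",
  function(inputs, params)
    roiStats(inputs$frame, params$x, params$y, params$w, params$h)[
      c("min", "max", "average", "sum")],
  inputs = c(frame = "image-ref"),
  outputs = c(min = "scalar", max = "scalar", average = "scalar",
              sum = "scalar"),
  parameters = list(list(name = "x", type = "scalar", default = 0)))
', file.path(dir, "roi.R"))
  writeLines('plugin <- scatterPlugin("broken", function(i, p) NULL,
    outputs = c(a = "nonsense-type"))', file.path(dir, "bad.R"))
  writeLines('this is not R at all (', file.path(dir, "ugly.R"))
  expect_message(reg <- discoverPlugins(dir), "skipping malformed")
  expect_named(reg, "my_roi")
  expect_length(reg$my_roi@outputs, 4)
  # empty folder -> empty registry
  empty <- tempfile(); dir.create(empty)
  expect_length(discoverPlugins(empty), 0)
  # duplicate names are fatal
  writeLines('plugin <- scatterPlugin("my_roi", function(i, p) list())',
             file.path(dir, "dup.R"))
  expect_error(suppressMessages(discoverPlugins(dir)), "duplicate")
})

test_that("graph validation names every wiring problem before data flows", {
  reg <- builtinPlugins()
  expect_true(validateGraph(roiGraph(), reg)$ok)
  # curve wired into an image input
  geom <- smallTransGeom(16, 16)
  bad <- pipelineGraph(list(
    read = list(plugin = "reader", params = list(),
                inputs = c(path = "source.path")),
    prof = list(plugin = "radial_profile",
                params = list(geometry = geom, qBreaks = c(1, 2, 3)),
                inputs = c(frame = "read.frame")),
    roi = list(plugin = "roi_stats", params = list(x = 0, y = 0,
                                                   width = 4, height = 4),
               inputs = c(frame = "prof.curve"))))
  v <- validateGraph(bad, reg)
  expect_false(v$ok)
  expect_match(v$errors, "roi.*frame.*prof\\.curve.*curve", all = FALSE)
  # self-loop
  loop <- pipelineGraph(list(
    roi = list(plugin = "roi_stats", params = list(),
               inputs = c(frame = "roi.min"))))
  vl <- validateGraph(loop, reg)
  expect_match(vl$errors, "cycle", all = FALSE)
  # dangling input and unknown plug-in
  dang <- pipelineGraph(list(
    roi = list(plugin = "roi_stats", params = list(),
               inputs = character())))
  expect_match(validateGraph(dang, reg)$errors, "dangling", all = FALSE)
  unk <- pipelineGraph(list(x = list(plugin = "nope", params = list(),
                                     inputs = character())))
  expect_match(validateGraph(unk, reg)$errors, "unknown plug-in",
               all = FALSE)
})

test_that("one frame through reader -> roi_stats yields the Fig.-3 row", {
  dir <- tempfile()
  files <- writeTestFrames(dir, 1, seed = 7)
  row <- processDataset(roiGraph(), list(path = files[1]), builtinPlugins())
  expect_named(row, c("read.frame", "roi.min", "roi.max", "roi.average",
                      "roi.sum", "errors"), ignore.order = TRUE)
  fr <- readFrame(files[1])
  st <- roiStats(fr, 2, 2, 8, 8)
  expect_equal(row$roi.min, st$min)
  expect_equal(row$roi.sum, st$sum)
  expect_identical(row$read.frame, files[1])   # image stored as reference
  expect_identical(row$errors, "")
})

test_that("a mid-chain failure yields NaN cells without touching neighbours", {
  dir <- tempfile()
  files <- writeTestFrames(dir, 3, seed = 17)
  # roi placed outside the detector for 16x16 frames -> plug-in failure
  reg <- builtinPlugins()
  reg$fragile <- scatterPlugin(
    "fragile",
    function(inputs, params) {
      if (grepl("f_002", inputs$frame@sourcePath)) stop("injected fault")
      list(value = sum(frameData(inputs$frame)))
    },
    inputs = c(frame = "image-ref"), outputs = c(value = "scalar"))
  g <- pipelineGraph(list(
    read = list(plugin = "reader", params = list(),
                inputs = c(path = "source.path")),
    frag = list(plugin = "fragile", params = list(),
                inputs = c(frame = "read.frame")),
    roi = list(plugin = "roi_stats",
               params = list(x = 0, y = 0, width = 6, height = 6),
               inputs = c(frame = "read.frame"))))
  tab <- runOffline(g, files, reg)
  expect_equal(nrow(tab), 3L)
  df <- as.data.frame(tab)
  expect_true(is.nan(df$frag.value[2]))
  expect_false(any(is.nan(df$frag.value[c(1, 3)])))
  expect_false(any(is.nan(df$roi.average)))    # sibling unaffected
  expect_match(df$errors[2], "frag: injected fault")
})

test_that("offline runs are ordered, deterministic, and skip unreadable files", {
  dir <- tempfile()
  files <- writeTestFrames(dir, 5, seed = 27)
  writeLines("garbage", file.path(dir, "f_000.tif"))  # truncated impostor
  all <- c(file.path(dir, "f_000.tif"), files)
  tab1 <- suppressMessages(runOffline(roiGraph(), all))
  tab2 <- suppressMessages(runOffline(roiGraph(), all))
  expect_equal(nrow(tab1), 5L)                    # impostor skipped
  expect_identical(as.data.frame(tab1), as.data.frame(tab2))
  expect_identical(as.data.frame(tab1)$read.frame, files)
})

test_that("online processing equals offline on the same dropped files", {
  src <- tempfile(); dir.create(src)
  watch <- tempfile(); dir.create(watch)
  files <- writeTestFrames(src, 12, seed = 37)
  # drop files into the watched directory between polls, a few at a time
  dropped <- 0L
  onPoll <- function(i) {
    take <- min(dropped + 3L, length(files))
    if (dropped < take) {
      for (k in (dropped + 1L):take)
        file.copy(files[k], file.path(watch, basename(files[k])))
      dropped <<- take
    }
    dropped < length(files)
  }
  online <- runOnline(roiGraph(), watch, pattern = "\\.tif$", poll = 0,
                      onPoll = onPoll)
  offline <- runOffline(roiGraph(),
                        file.path(watch, sort(basename(files))))
  expect_equal(nrow(online), 12L)
  dfOn <- as.data.frame(online); dfOff <- as.data.frame(offline)
  dfOn$read.frame <- basename(dfOn$read.frame)
  dfOff$read.frame <- basename(dfOff$read.frame)
  expect_identical(dfOn, dfOff)
})

test_that("overwritten files process once and an empty watch exits cleanly", {
  watch <- tempfile(); dir.create(watch)
  src <- tempfile()
  files <- writeTestFrames(src, 2, seed = 47)
  state <- 0L
  onPoll <- function(i) {
    state <<- state + 1L
    if (state == 1L)
      file.copy(files[1], file.path(watch, "a.tif"))
    if (state == 4L)   # overwrite after the first version completed
      file.copy(files[2], file.path(watch, "a.tif"), overwrite = TRUE)
    state < 6L
  }
  tab <- runOnline(roiGraph(), watch, pattern = "\\.tif$", poll = 0,
                   onPoll = onPoll, idlePolls = 2)
  expect_equal(nrow(tab), 1L)   # first complete version only
  fr <- readFrame(files[1])
  expect_equal(as.data.frame(tab)$roi.min,
               roiStats(fr, 2, 2, 8, 8)$min)
  # empty directory + stop: empty table, clean exit
  empty <- tempfile(); dir.create(empty)
  tabe <- runOnline(roiGraph(), empty, poll = 0, idlePolls = 1,
                    onPoll = function(i) FALSE)
  expect_equal(nrow(tabe), 0L)
})

test_that("a full config drives geometry, pipeline, and export", {
  dir <- tempfile()
  files <- writeTestFrames(dir, 3, seed = 57)
  cfgPath <- tempfile(fileext = ".yaml")
  writeLines('
geometry:
  wavelength_nm: 0.1
  distance_mm: 800
  beam_center_px: [7.5, 7.5]
  pixel_size_mm: [1.0, 1.0]
  mode: transmission
pipeline:
  read:
    plugin: reader
    inputs: {path: source.path}
  prof:
    plugin: radial_profile
    params:
      qBreaks: [0.2, 0.4, 0.6, 0.8]
    inputs: {frame: read.frame}
  roi:
    plugin: roi_stats
    params: {x: 0, y: 0, width: 8, height: 8}
    inputs: {frame: read.frame}
', cfgPath)
  pl <- readPipelineConfig(cfgPath)
  expect_s4_class(pl$geometry, "ExperimentGeometry")
  v <- validateGraph(pl$graph, builtinPlugins())
  expect_true(v$ok)
  tab <- runOffline(pl$graph, files)
  expect_equal(nrow(tab), 3L)
  out <- file.path(tempfile(), "table.tsv")
  dir.create(dirname(out))
  exportTable(tab, out)
  back <- utils::read.delim(out)
  expect_equal(nrow(back), 3)
  expect_true(all(file.exists(file.path(dirname(out), back$prof.curve))))
})
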