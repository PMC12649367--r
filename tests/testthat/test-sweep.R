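fake_result <- function(tab) {
  structure(list(table = tab,
                 config = list(axes = list(frequency = unique(tab$frequency),
                                           source_pressure =
                                             unique(tab$source_pressure)),
                               mode = "frequency", scale = "reduced")),
            class = "sweep_result")
}

synthetic_table <- function() {
  expand.grid(frequency = c(0.5e6, 1e6), source_pressure = c(5e5, 1e6, 2e6),
              KEEP.OUT.ATTRS = FALSE) |>
    transform(region = "temporal", skull_thickness = 4, roc = 65,
              mode = "frequency", linear = TRUE, runtime_s = 1,
              error = NA_character_,
              stl_db = ifelse(frequency > 0.6e6, 12, 8),
              max_pressure_ratio = 3, focal_depth_mm = 50 -
                frequency / 1e6, focus_zone_mm = 30 - 10 * frequency / 1e6,
              focus_zone_mm2 = 100)
}

test_that("sweep configuration is validated", {
  sc <- region_preset("temporal", 4, 65)
  expect_error(sweep_config(sc, list()), "nonempty")
  expect_error(sweep_config(sc, list(frequency = numeric(0))), "nonempty")
  expect_error(sweep_config(sc, list(voltage = 1)), "unknown axis")
  cfg <- sweep_config(sc, list(frequency = c(0.5e6, 1e6)), scale = "reduced")
  expect_s3_class(cfg, "sweep_config")
})

test_that("a reduced sweep runs, resumes from disk, and tags failures", {
  sc <- region_preset("temporal", 3.5, 65, source_frequency = 0.5e6)
  outdir <- tempfile("sweep")
  cfg <- sweep_config(sc, list(frequency = 0.5e6), mode = "frequency",
                      scale = "reduced", outdir = outdir)
  res <- run_sweep(cfg)
  expect_equal(nrow(res$table), 1)
  expect_true(is.na(res$table$error[1]))
  expect_true(res$table$stl_db[1] > -40 && res$table$stl_db[1] < 40)
  # one row file plus one JSON manifest per case
  expect_length(list.files(outdir, pattern = "\\.csv$"), 1)
  expect_length(list.files(outdir, pattern = "\\.json$"), 1)
  # resumability: the cached case is reused, not recomputed
  t0 <- Sys.time()
  res2 <- run_sweep(cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
  expect_equal(res2$table$stl_db, res$table$stl_db)
  # invalid case is recorded in-row, not dropped
  cfg_bad <- sweep_config(sc, list(skull_thickness = c(4, -1)),
                          mode = "frequency", scale = "reduced")
  res_bad <- run_sweep(cfg_bad)
  expect_equal(nrow(res_bad$table), 2)
  expect_equal(sum(!is.na(res_bad$table$error)), 1)
})

test_that("linear-mode STL is flagged invariant to source pressure", {
  tab <- synthetic_table()
  rep <- pressure_insensitivity_check(fake_result(tab))
  expect_true(all(rep$pass))
  expect_true(all(rep$stl_spread_db < 0.1))
  # a time-explicit spread is reported but not asserted
  tab2 <- tab
  tab2$mode <- "time_explicit"
  tab2$stl_db <- tab2$stl_db + seq(0, 0.5, length.out = nrow(tab2))
  rep2 <- pressure_insensitivity_check(fake_result(tab2))
  expect_true(all(is.na(rep2$pass)))
  expect_true(all(rep2$stl_spread_db > 0))
})

test_that("trend checks read the expected directions off the table", {
  tc <- trend_checks(fake_result(synthetic_table()))
  expect_true(tc$pass[tc$claim == "stl increases with frequency"])
  expect_true(tc$pass[tc$claim == "focal depth decreases with frequency"])
  expect_true(tc$pass[tc$claim == "focus zone decreases with frequency"])
  expect_true(is.na(tc$pass[tc$claim == "stl increases with skull thickness"]))
})

test_that("the report round-trips the table and writes trend files and plots", {
  res <- fake_result(synthetic_table())
  outdir <- tempfile("report")
  paths <- sweep_report(res, outdir)
  csv <- file.path(outdir, "sweep_results.csv")
  expect_true(file.exists(csv))
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  num <- vapply(res$table, is.numeric, TRUE)
  expect_equal(back[num], res$table[num], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(outdir, "trend_summary.csv")))
  expect_gt(sum(grepl("\\.png$", list.files(outdir))), 0)
  expect_error(sweep_report(fake_result(synthetic_table()[0, ]), outdir),
               "empty")
})
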