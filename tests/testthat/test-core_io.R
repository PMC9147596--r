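test_that("trace construction enforces its invariants", {
  expect_error(trace(numeric(0)), "non-empty")
  expect_error(trace(c(1, NA)), "finite")
  expect_error(trace(1:3, dt = 0), "positive")
  tr <- trace(1:5, dt = 0.1, t0 = 2)
  expect_equal(trace_times(tr), c(2.0, 2.1, 2.2, 2.3, 2.4))
})

test_that("density normalisation divides by capacitance and tracks units", {
  tr <- trace(c(-300, -150), dt = 0.1, units = "pA")
  nd <- density_normalise(tr, 150)
  expect_equal(nd$samples, c(-2, -1))
  expect_equal(nd$units, "pA/pF")
  expect_equal(density_normalise(tr, 1)$samples, tr$samples)
  expect_error(density_normalise(nd, 150), "twice")
  expect_error(density_normalise(tr, NULL), "capacitance")
  vt <- trace(c(1, 2), units = "mV")
  expect_error(density_normalise(vt, 10), "current trace")
})

test_that("sweep families validate keys, dt and capacitance", {
  s1 <- trace(rnorm(10), dt = 0.1, units = "pA")
  s2 <- trace(rnorm(10), dt = 0.1, units = "pA")
  fam <- sweep_family(list(`-40` = s1, `-30` = s2), "IV_ACTIVATION",
                      capacitance = 150)
  expect_equal(sweep_keys(fam), c(-40, -30))
  expect_error(sweep_family(list(s1, s2), "IV_ACTIVATION"), "unique")
  expect_error(
    sweep_family(list(`-40` = s1, `-30` = trace(1:10, dt = 0.2, units = "pA")),
                 "IV_ACTIVATION"),
    "same dt")
  expect_error(sweep_family(list(`-40` = s1), "IV_ACTIVATION",
                            capacitance = -5), "positive")
})

test_that("sweep-table write/read round trip is bit-exact", {
  set.seed(11)
  sweeps <- list(`-40` = trace(rnorm(50) * 1e3, dt = 0.1, units = "pA"),
                 `-30` = trace(rnorm(50) / 7, dt = 0.1, units = "pA"))
  fam <- sweep_family(sweeps, "IV_ACTIVATION", capacitance = 150,
                      meta = list(step_start_ms = 1))
  path <- tempfile(fileext = ".csv")
  write_sweep_table(fam, path)
  back <- read_sweep_table(path)
  expect_identical(back$sweeps[["-40"]]$samples, sweeps[["-40"]]$samples)
  expect_identical(back$sweeps[["-30"]]$samples, sweeps[["-30"]]$samples)
  expect_equal(back$capacitance, 150)
  expect_equal(back$protocol, "IV_ACTIVATION")
  expect_equal(back$meta$step_start_ms, 1)
  expect_equal(back$sweeps[[1]]$dt, 0.1)
  unlink(c(path, sub("\\.csv$", ".meta.json", path)))
})

test_that("sidecar omits capacitance when the family has none", {
  fam <- sweep_family(list(`-20` = trace(1:10, dt = 0.1, units = "pA/pF")),
                      "LATE_STEP")
  path <- tempfile(fileext = ".csv")
  write_sweep_table(fam, path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".meta.json", path))
  expect_false("capacitance_pF" %in% names(meta))
  expect_null(read_sweep_table(path)$capacitance)
  unlink(c(path, sub("\\.csv$", ".meta.json", path)))
})

test_that("malformed sweep tables are rejected with informative errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("t,-40", "0,1", "0.1,2"), path)
  expect_error(read_sweep_table(path), "time_ms")
  writeLines(c("time_ms,-40", "0,1", "0.1,2", "0.3,3"), path)
  expect_error(read_sweep_table(path), "uniform")
  writeLines(c("time_ms,notakey", "0,1", "0.1,2"), path)
  expect_error(read_sweep_table(path), "notakey")
  unlink(path)
})

test_that("configuration rejects unknown keys and reads YAML overrides", {
  expect_error(ephys_config(no_such_key = 1), "unknown")
  cfg <- ephys_config(apnoea_factor = 6)
  expect_equal(cfg$apnoea_factor, 6)
  expect_equal(cfg$default_dt_ms, 0.1)
  path <- tempfile(fileext = ".yaml")
  writeLines("late_window_ms: 0", path)
  expect_equal(read_config(path)$late_window_ms, 0)
  unlink(path)
})

test_that("ECG annotations validate ordering and merge noise intervals", {
  fid <- data.frame(complex_id = 1:2, qrs_on_ms = c(0, 130),
                    r_peak_ms = c(4, 134), qrs_end_ms = c(11, 141),
                    qt_end_ms = c(52, 182))
  ann <- ecg_annotation(fid, data.frame(start_ms = c(10, 30, 100),
                                        end_ms = c(40, 60, 120)))
  expect_equal(nrow(ann$noise), 2)
  expect_equal(ann$noise$end_ms[1], 60)
  bad <- fid; bad$r_peak_ms[1] <- -1
  expect_error(ecg_annotation(bad), "qrs_on < r_peak")
})
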