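# Reduced-duration specs (T = 200-2000 instead of the production 20,000)
# keep the suite fast; the full-scale settings are exercised by the
# acceptance tests.
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(forcing = 8.75, size = 20, duration = 200, shift = 1,
         env_seed = 1, reservoir_seed = 2, tuning_seed = 3),
    list(...))
  do.call(run_spec, args)
}

test_that("run specs enforce their invariants", {
  expect_error(run_spec(forcing = 8.75, size = 10, duration = 100.005),
               "multiple")
  expect_error(run_spec(forcing = 8.75, size = 10, duration = 100,
                        shift = 8), "10 forecast horizons")
  expect_error(run_spec(forcing = 8.75, size = 10, split_fraction = 1),
               "split_fraction")
})

test_that("a replicate is exactly reproducible from its spec", {
  a <- run_replicate(tiny_spec())
  b <- run_replicate(tiny_spec())
  expect_identical(a$r2_train, b$r2_train)
  expect_identical(a$r2_test, b$r2_test)
  expect_identical(a$metadata$seeds, list(env = 1L, reservoir = 2L,
                                          tuning = 3L))
})

test_that("tuning seed is isolated from environment and reservoir", {
  # with a single-point alpha grid the tuning stream is never consumed, so
  # runs differing only in tuning_seed must be bit-identical end to end
  a <- run_replicate(tiny_spec(tuning_seed = 3, alpha_grid = 1e-4))
  b <- run_replicate(tiny_spec(tuning_seed = 999, alpha_grid = 1e-4))
  expect_identical(a$r2_train, b$r2_train)
  expect_identical(a$r2_test, b$r2_test)
})

test_that("pipeline errors name the failing stage", {
  expect_error(run_replicate(tiny_spec(connectivity = 1e-9)),
               "\\[stage: reservoir\\]")
})

test_that("derived seeds are deterministic, distinct, and 32-bit safe", {
  s1 <- derive_seed(42, 1, 1)
  expect_identical(s1, derive_seed(42, 1, 1))
  grid <- expand.grid(r = 1:50, stream = 1:3)
  seeds <- mapply(function(r, k) derive_seed(42, r, k), grid$r, grid$stream)
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("replicate summaries order and summarise test R-squared", {
  one <- run_replicates(tiny_spec(), n = 1, base_seed = 5)
  expect_equal(one$minimum, one$median)
  expect_equal(one$median, one$maximum)

  four <- run_replicates(tiny_spec(), n = 4, base_seed = 5)
  expect_identical(four$n_replicates, 4L)
  expect_lte(four$minimum, four$median)
  expect_lte(four$median, four$maximum)
  srt <- sort(four$r2_test_pct)
  expect_equal(four$median, mean(srt[2:3]))  # even count: mean of middle two
  expect_equal(four$minimum, srt[1])
})

test_that("forecast quality degrades with the horizon (paired run)", {
  spec <- run_spec(forcing = 8.75, size = 25, duration = 2000, shift = 1,
                   env_seed = 1, reservoir_seed = 2, tuning_seed = 3)
  prof <- run_shift_profile(spec, c(0.25, 0.5, 1, 2))
  r2 <- vapply(prof, function(s) 100 * s$r2_test, numeric(1))
  expect_true(all(diff(r2) < 2))   # non-increasing up to 2-point noise
  expect_gt(r2[1], r2[4])
})

test_that("larger reservoirs predict better (median over replicates)", {
  med <- vapply(c(10, 25, 50), function(sz) {
    run_replicates(run_spec(forcing = 8.75, size = sz, duration = 2000,
                            shift = 0.5), n = 3, base_seed = 99)$median
  }, numeric(1))
  expect_true(all(diff(med) > -2))  # non-decreasing up to 2-point noise
  expect_gt(med[3], med[1])
})

test_that("sweeps cover the grid and recover the predictability trend", {
  sw <- run_sweep(forcings = c(8.5, 11), shifts = c(0.5, 1), sizes = 25,
                  duration = 2000, base_seed = 7, lyapunov_horizon = 500)
  expect_identical(nrow(sw), 4L)
  expect_identical(sort(names(sw))[1:3], c("dbl", "forcing", "r2_test_pct"))
  # weaker chaos (larger dbl) is more predictable at both horizons
  expect_gt(sw$dbl[sw$forcing == 8.5][1], sw$dbl[sw$forcing == 11][1])
  for (sh in c(0.5, 1)) {
    expect_gt(sw$r2_test_pct[sw$forcing == 8.5 & sw$shift == sh],
              sw$r2_test_pct[sw$forcing == 11 & sw$shift == sh])
  }
})

test_that("results round-trip through CSV with a provenance sidecar", {
  sw <- run_sweep(forcings = 8.75, shifts = 1, sizes = 15, duration = 200,
                  base_seed = 3, lyapunov_horizon = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(sw, path)
  expect_identical(
    readLines(path, n = 1),
    "forcing,dbl,shift,size,replicate,r2_train_pct,r2_test_pct")
  back <- read_results(path)
  expect_equal(back$r2_test_pct, signif(sw$r2_test_pct, 6))
  expect_equal(back$dbl, signif(sw$dbl, 6))

  # sidecar holds everything needed to regenerate the CSV exactly
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  replay <- do.call(run_sweep, sidecar$settings)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_results(replay, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("replicate summaries write in the compact summary format", {
  rs <- run_replicates(tiny_spec(), n = 2, base_seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(rs, path)
  expect_identical(readLines(path, n = 1), "size,n,min,median,max")
  back <- read_results(path)
  expect_equal(back$median, signif(rs$median, 6))
})

test_that("an empty sweep writes a header-only file", {
  empty <- structure(
    data.frame(forcing = numeric(0), dbl = numeric(0), shift = numeric(0),
               size = integer(0), replicate = integer(0),
               r2_train_pct = numeric(0), r2_test_pct = numeric(0)),
    class = c("sweep_result", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(empty, path)
  expect_identical(length(readLines(path)), 1L)
})

test_that("doubling-time targets map back to forcing values", {
  f <- forcing_for_doubling_time(1.0, range = c(8, 12), horizon = 300,
                                 seed = 2)
  expect_gt(f, 8.2)
  expect_lt(f, 9.5)
  est <- estimate_max_lyapunov(lorenz96_params(5, f), horizon = 300,
                               seed = 2)
  expect_equal(est$dbl, 1.0, tolerance = 0.05)
})
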