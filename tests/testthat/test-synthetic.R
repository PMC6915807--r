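# small config used across tests: reduced raster, modest groups
small_config <- function(...) {
  generator_config(dims = c(64L, 128L), groups = c(model = 15L, nonmodel = 12L),
                   ...)
}

test_that("generator config validates probabilities and sizes", {
  expect_error(generator_config(groups = c(a = 0L, b = 5L)), ">= 1")
  expect_error(generator_config(regions = list(r = list(
    center = c(0.5, 0.5), half = c(0.1, 0.1), p = c(model = 1.2, nonmodel = 0)))),
    "\\[0, 1\\]")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  # custom group names inherit default parameters
  cfg <- generator_config(groups = c(g1 = 5L, g2 = 5L))
  expect_named(cfg$sizes, c("g1", "g2"))
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 42)
  c2 <- generate_cohort(cfg, seed = 42)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  c3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(c1$subjects[[1]]$measured, c3$subjects[[1]]$measured))
})

test_that("planted region frequencies match the configured probabilities", {
  # pA = 0.6 vs pB = 0.2, no background concerns, one region
  cfg <- generator_config(
    dims = c(64L, 128L), groups = c(A = 200L, B = 200L),
    regions = list(target = list(center = c(0.5, 0.5), half = c(0.15, 0.08),
                                 p = c(A = 0.6, B = 0.2))),
    base_rate = 0)
  co <- generate_cohort(cfg, seed = 7)
  masks <- cohort_masks(co)
  g <- cohort_groups(co)
  # concern frequency at the region centre pixel (always covered when drawn)
  ctr <- round(c(0.5, 0.5) * cfg$dims)
  fA <- mean(vapply(masks[g == "A"], function(m) m[ctr[2], ctr[1]], integer(1)))
  fB <- mean(vapply(masks[g == "B"], function(m) m[ctr[2], ctr[1]], integer(1)))
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(fA - 0.6), 3 * se(0.6, 200))
  expect_lt(abs(fB - 0.2), 3 * se(0.2, 200))
  expect_lt(abs((fA - fB) - 0.4),
            3 * sqrt(se(0.6, 200)^2 + se(0.2, 200)^2))
})

test_that("zero-bias, zero-noise cohorts have exactly zero discrepancy", {
  zero_bias <- stats::setNames(rep(0, 7), measured_body_parts)
  cfg <- small_config(bias = list(model = zero_bias, nonmodel = zero_bias),
                      noise_sd = 0)
  co <- generate_cohort(cfg, seed = 11)
  dd <- cohort_discrepancies(co, cfg$calibration)
  expect_equal(max(abs(dd$discrepancy_cm)), 0, tolerance = 1e-9)
  expect_equal(co$meta$n_clipped, 0L)
})

test_that("group-mean discrepancy recovers the configured bias within 3 SE", {
  bias_m <- c(shoulders = -2, bust = -3, biceps = 1, waist = -4, hips = 0.5,
              thighs = -5, calves = -1.5)
  bias_n <- c(shoulders = -0.5, bust = -6, biceps = -4, waist = -8,
              hips = -5, thighs = -6, calves = -7)
  cfg <- generator_config(dims = c(32L, 64L),
                          groups = c(model = 40L, nonmodel = 40L),
                          bias = list(model = bias_m, nonmodel = bias_n),
                          noise_sd = 3)
  co <- generate_cohort(cfg, seed = 13)
  dd <- cohort_discrepancies(co, cfg$calibration)
  for (g in c("model", "nonmodel")) {
    bias <- if (g == "model") bias_m else bias_n
    for (p in measured_body_parts) {
      d <- dd$discrepancy_cm[dd$group == g & dd$part == p]
      se <- stats::sd(d) / sqrt(length(d))
      expect_lt(abs(mean(d) - bias[[p]]), 3 * se + 0.2)
    }
  }
})

test_that("null_cohort demands identical group parameters", {
  cfg <- small_config()
  expect_error(null_cohort(cfg, seed = 1), "unequal")
  sym <- symmetrize_config(cfg)
  co <- null_cohort(sym, seed = 1)
  expect_s3_class(co, "cohort")
  # symmetric: same region probabilities for both groups
  for (r in sym$regions) expect_equal(r$p[["model"]], r$p[["nonmodel"]])
  # null-cohort mean discrepancy difference between groups ~ 0 within 3 SE
  dd <- cohort_discrepancies(co, sym$calibration)
  d <- dd$discrepancy_cm[dd$part == "waist"]
  g <- dd$group[dd$part == "waist"]
  dm <- mean(d[g == "model"]) - mean(d[g == "nonmodel"])
  se <- sqrt(stats::var(d[g == "model"]) / sum(g == "model") +
             stats::var(d[g == "nonmodel"]) / sum(g == "nonmodel"))
  expect_lt(abs(dm), 3 * se)
})

test_that("single-subject groups run through the pipeline degenerately", {
  cfg <- generator_config(dims = c(32L, 64L), groups = c(a = 1L, b = 1L))
  cfg <- symmetrize_config(cfg)
  co <- null_cohort(cfg, seed = 2)
  fit <- body_map_test(co, B = 50, seed = 1, fwhm_px = 4)
  expect_s3_class(fit, "body_map_test")
  expect_true(all(fit$surviving == 0))
})

test_that("bias beyond the calibration range aborts with advice", {
  huge <- stats::setNames(rep(-200, 7), measured_body_parts)
  cfg <- small_config(bias = list(model = huge, nonmodel = huge))
  expect_error(generate_cohort(cfg, seed = 1), "extend the calibration")
})

test_that("clipping is counted, never silent", {
  # moderate negative bias on one part -> some clips, recorded in meta
  b <- stats::setNames(rep(0, 7), measured_body_parts)
  b["thighs"] <- -21   # m0 = 22.5 at m05 = 45: mean sits just above the floor
  cfg <- generator_config(dims = c(32L, 64L), groups = c(model = 60L, nonmodel = 2L),
                          bias = list(model = b, nonmodel = b), noise_sd = 4)
  co <- generate_cohort(cfg, seed = 3)
  expect_gt(co$meta$n_clipped, 0)
  expect_equal(co$meta$n_clipped, sum(unlist(co$meta$clipped_by_part)))
})
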