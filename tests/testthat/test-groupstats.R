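# Construct a sample with exactly the requested mean and SD (affine
# transform of a fixed base vector), so summary-statistic formulas can be
# cross-checked against stats::t.test on raw data.
raw_with <- function(mean, sd, n) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

test_that("welch_t matches t.test on reconstructed raw samples", {
  cases <- list(c(56.9, 8.4, 38, 57.5, 4.4, 65),
                c(10, 2, 12, 11.5, 3, 20),
                c(0, 1, 5, 0.3, 1.4, 9))
  for (cs in cases) {
    a <- raw_with(cs[1], cs[2], cs[3]); b <- raw_with(cs[4], cs[5], cs[6])
    ref <- stats::t.test(a, b)
    got <- welch_t(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    # pooled variant matches var.equal = TRUE
    refp <- stats::t.test(a, b, var.equal = TRUE)
    gotp <- welch_t(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6], pooled = TRUE)
    expect_equal(gotp$statistic, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(gotp$df, unname(refp$parameter))
  }
  # sign flips under group swap; df bounded by n1 + n2 - 2
  g <- welch_t(5, 1, 10, 6, 2, 15)
  gs <- welch_t(6, 2, 15, 5, 1, 10)
  expect_equal(g$statistic, -gs$statistic)
  expect_lte(g$df, 10 + 15 - 2)
  expect_equal(welch_t(5, 1, 10, 5, 2, 15)$statistic, 0)
  expect_error(welch_t(5, 0, 10, 5, 0, 15), "undefined")
})

test_that("welch_t reproduces the printed cohort comparisons", {
  # weight row (nonmodel vs model): printed t = -0.4
  wt <- welch_t(56.9, 8.4, 38, 57.5, 4.4, 65)
  expect_equal(round(wt$statistic, 1), -0.4)
  # usability enjoyment: printed df subscript 70
  en <- welch_t(5.9, 2.34, 65, 7.4, 2.43, 36)
  expect_equal(round(en$df), 70)
})

test_that("chi_square matches the demographic tables and independence", {
  race <- cbind(model = c(44, 5, 3, 1, 12), nonmodel = c(21, 7, 3, 2, 5))
  r <- chi_square(race)
  expect_equal(round(r$statistic, 1), 4.9)
  expect_equal(r$df, 4)
  edu <- cbind(model = c(2, 12, 6, 32, 9, 4), nonmodel = c(7, 25, 3, 3, 0, 0))
  e <- chi_square(edu)
  expect_equal(round(e$statistic, 1), 41.1)
  expect_equal(e$df, 5)
  # proportional rows -> exactly 0; permutation invariance
  prop <- cbind(c(10, 20, 40), c(5, 10, 20))
  expect_equal(chi_square(prop)$statistic, 0)
  expect_equal(chi_square(race[c(3, 1, 5, 2, 4), 2:1])$statistic,
               r$statistic)
  expect_error(chi_square(cbind(c(0, 0), c(0, 3))), "all-zero")
  expect_error(chi_square(cbind(c(1.5, 2), c(1, 3))), "integer")
})

test_that("tally counts each subject once per label with half-up percents", {
  mk <- function(id, group, affect_sets) {
    subject_record(id, group, concerns = lapply(affect_sets, function(a)
      concern_entry(square_poly(1, 1, 4, 4), affects = a,
                    concern_types = "bloated")))
  }
  subs <- c(
    # subject endorsing "frustrated" in two separate concerns: counts once
    list(mk("m1", "M", list("frustrated", c("frustrated", "sad")))),
    lapply(2:8, function(i) mk(paste0("m", i), "M", list("sad"))),
    list(mk("n1", "N", list("frustrated")), mk("n2", "N", list()))
  )
  tl <- tally(subs, "affects")
  expect_equal(tl$M_n[tl$label == "frustrated"], 1L)
  expect_equal(tl$M_n[tl$label == "sad"], 8L)
  expect_equal(tl$N_n[tl$label == "frustrated"], 1L)
  expect_equal(tl$N_pct[tl$label == "frustrated"], 50.0)
  # 1/8 = 12.5% rounds half-up to 12.5; 19/65 = 29.2
  expect_equal(tl$M_pct[tl$label == "frustrated"], 12.5)
  expect_equal(round(100 * 19 / 65, 1), 29.2)
  # concern types tallied the same way
  tc <- tally(subs, "concern_types")
  expect_equal(tc$M_n[tc$label == "bloated"], 8L)
  expect_error(tally(subs, "height"), "arg")
})

test_that("bh_adjust is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  a <- bh_adjust(p)
  expect_equal(a, stats::p.adjust(p, "BH"))
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= -1e-15))   # order preserving
  # re-adjusting an already-flat adjusted vector changes nothing
  flat <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_adjust(flat), flat)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mancova_wilks matches a direct E/H computation and manova()", {
  # fixed 12-subject, 2-response, 1-covariate toy dataset
  Y <- cbind(y1 = c(4.1, 5.2, 3.9, 6.1, 5.5, 4.8, 7.2, 8.1, 6.9, 7.7, 8.4, 7.1),
             y2 = c(10.2, 11.1, 9.8, 12.0, 11.4, 10.6, 9.1, 8.5, 9.9, 8.8, 8.2, 9.4))
  g <- factor(rep(c("a", "b"), each = 6))
  cov1 <- c(1.2, 2.1, 0.8, 2.9, 2.4, 1.7, 3.1, 3.8, 2.6, 3.3, 4.0, 2.8)
  fit <- mancova_wilks(Y, g, cov1)

  # independent oracle: explicit projection algebra
  X  <- cbind(1, cov1, as.numeric(g == "b"))
  X0 <- cbind(1, cov1)
  Pm <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  E  <- t(Y) %*% (diag(12) - Pm(X)) %*% Y
  H  <- t(Y) %*% (Pm(X) - Pm(X0)) %*% Y
  lam <- det(E) / det(E + H)
  expect_equal(fit$lambda, lam, tolerance = 1e-9)

  # and against stats::manova (sequential SS: group last == adjusted)
  mv <- summary(stats::manova(Y ~ cov1 + g), test = "Wilks")
  expect_equal(fit$lambda, mv$stats["g", "Wilks"], tolerance = 1e-8)
  expect_equal(fit$F, mv$stats["g", "approx F"], tolerance = 1e-8)
  expect_equal(unname(fit$df), unname(mv$stats["g", c("num Df", "den Df")]),
               tolerance = 1e-8)

  # post hoc ANCOVA equals per-response lm comparison
  for (j in 1:2) {
    full <- stats::lm(Y[, j] ~ cov1 + g)
    an <- stats::anova(full)
    expect_equal(fit$posthoc$F[j], an["g", "F value"], tolerance = 1e-8)
  }
  expect_true(all(fit$posthoc$partial_eta2 >= 0 &
                  fit$posthoc$partial_eta2 <= 1))
  expect_equal(fit$posthoc$cohen_f,
               sqrt(fit$posthoc$partial_eta2 / (1 - fit$posthoc$partial_eta2)))

  # dropping a constant covariate leaves lambda unchanged
  fit2 <- mancova_wilks(Y, g, cbind(cov1, const = rep(2, 12)))
  expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-12)

  # group effect exactly zero after adjustment (H = 0) -> lambda = 1, F = 0
  u <- (diag(12) - Pm(X0)) %*% as.numeric(g == "b")
  Yn <- Y - u %*% (t(u) %*% Y) / sum(u^2)
  fitn <- mancova_wilks(Yn, g, cov1)
  expect_equal(fitn$lambda, 1, tolerance = 1e-9)
  expect_equal(fitn$F, 0, tolerance = 1e-7)

  # lambda in (0, 1]
  expect_gt(fit$lambda, 0); expect_lte(fit$lambda, 1)

  # rank deficiency names the collinear column
  expect_error(mancova_wilks(Y, g, cbind(cov1, dup = cov1)),
               "collinear")
})
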