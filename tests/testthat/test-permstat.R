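test_that("two_proportion_z evaluates the pooled-variance formula", {
  # degenerate pixels: nobody (or everybody) concerned -> 0
  expect_equal(two_proportion_z(0, 65, 0, 38), 0)
  expect_equal(two_proportion_z(65, 65, 38, 38), 0)
  # equal proportions -> 0
  expect_equal(two_proportion_z(10, 20, 5, 10), 0)
  # worked value, cross-checked against prop.test's chi-square (z^2 = X^2)
  z <- two_proportion_z(30, 65, 10, 38)
  expect_equal(round(z, 3), 1.993)
  x2 <- suppressWarnings(
    stats::prop.test(c(30, 10), c(65, 38), correct = FALSE)$statistic)
  expect_equal(z^2, unname(x2), tolerance = 1e-12)
  # vectorized, antisymmetric
  expect_equal(two_proportion_z(c(30, 10), 65, c(10, 30), 38),
               -two_proportion_z(c(10, 30), 38, c(30, 10), 65))
  expect_error(two_proportion_z(-1, 10, 2, 10), "0 <= x <= n")
  expect_error(two_proportion_z(11, 10, 2, 10), "0 <= x <= n")
})

test_that("z_map agrees with the scalar statistic pixel by pixel", {
  dims <- c(2, 2)
  # 3 vs 3 subjects with hand-laid masks on a 2x2 raster
  A <- list(mask_from_pixels(dims, rbind(c(1, 1), c(2, 2))),
            mask_from_pixels(dims, rbind(c(1, 1))),
            mask_from_pixels(dims, rbind(c(1, 1), c(1, 2))))
  B <- list(mask_from_pixels(dims, rbind(c(2, 1))),
            mask_from_pixels(dims, NULL),
            mask_from_pixels(dims, rbind(c(2, 1), c(1, 2))))
  zm <- z_map(A, B)
  xA <- Reduce(`+`, A); xB <- Reduce(`+`, B)
  for (j in 1:2) for (i in 1:2)
    expect_equal(zm[j, i], two_proportion_z(xA[j, i], 3, xB[j, i], 3))
  # identical group composition -> all-zero map
  expect_true(all(z_map(A, A) == 0))
  # swapping groups negates the map
  expect_equal(z_map(B, A), -zm)
  expect_error(z_map(list(), A), "non-empty")
})

test_that("smoothed z_map uses effective counts n * smoothed proportion", {
  dims <- c(8, 8)
  set.seed(21)
  A <- lapply(1:4, function(i) rasterize_outline(random_polygon(dims), dims))
  B <- lapply(1:5, function(i) rasterize_outline(random_polygon(dims), dims))
  zm <- z_map(A, B, fwhm_px = 4)
  pA <- smooth_map(proportional_map(A), 4)$grid
  pB <- smooth_map(proportional_map(B), 4)$grid
  expect_equal(zm, matrix(two_proportion_z(4 * pA, 4, 5 * pB, 5), 8, 8),
               tolerance = 1e-9)
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  dims <- c(3, 3)
  set.seed(31)
  masks <- lapply(1:6, function(i) {
    m <- matrix(rbinom(9, 1, 0.5), 3, 3)
    m
  })
  labels <- rep(c("g1", "g2"), each = 3)
  fit <- permutation_pmap(masks, labels, B = 5000, seed = 99)
  p_exact <- exact_perm_p(masks, labels)
  # B = 5000 draws: within 3 Monte-Carlo SDs of the exact 20-relabeling p
  for (j in seq_len(9)) {
    pe <- p_exact[j]
    mc_sd <- sqrt(pe * (1 - pe) / 5000)
    expect_lt(abs(fit$p_uncorrected[j] - pe), 3 * mc_sd + 1e-9)
  }
})

test_that("permutation engine is seeded, bounded and label-symmetric", {
  dims <- c(4, 4)
  set.seed(8)
  masks <- lapply(1:10, function(i)
    matrix(rbinom(16, 1, 0.4), 4, 4))
  labels <- rep(c("x", "y"), each = 5)
  f1 <- permutation_pmap(masks, labels, B = 300, seed = 7)
  f2 <- permutation_pmap(masks, labels, B = 300, seed = 7)
  expect_identical(f1$p_uncorrected, f2$p_uncorrected)
  expect_identical(f1$null_max_extent, f2$null_max_extent)
  # different seed -> (almost surely) different permutation draws
  f3 <- permutation_pmap(masks, labels, B = 300, seed = 8)
  expect_false(identical(f1$null_max_extent, f3$null_max_extent))
  # p floor and ceiling
  expect_true(all(f1$p_uncorrected >= 1 / 301))
  expect_true(all(f1$p_uncorrected <= 1))
  # label swap: same two-sided p, negated z
  fs <- permutation_pmap(masks, rep(c("y", "x"), each = 5), B = 300, seed = 7)
  expect_equal(fs$z, -f1$z)
  expect_equal(fs$p_uncorrected, f1$p_uncorrected)
  # pixels where every subject agrees have p = 1
  allsame <- c(masks, list(matrix(0L, 4, 4)))
  fa <- permutation_pmap(lapply(1:6, function(i) matrix(1L, 4, 4)),
                         rep(c("x", "y"), each = 3), B = 100, seed = 1)
  expect_true(all(fa$p_uncorrected == 1))
  expect_error(permutation_pmap(masks, rep("x", 10), B = 10), "two distinct")
  expect_error(permutation_pmap(masks, labels, B = 0), "positive integer")
})

test_that("cluster correction labels 8-connected components and applies the max-extent null", {
  # no pixel below alpha -> zero clusters
  masks <- lapply(1:6, function(i) matrix(0L, 4, 4))
  masks[[1]][1, 1] <- 1L; masks[[4]][1, 1] <- 1L  # balanced -> weak z
  fit <- body_map_test(masks, rep(c("a", "b"), each = 3), B = 200, seed = 3,
                       fwhm_px = NULL)
  expect_equal(nrow(fit$cluster_table), 0)
  expect_true(all(fit$surviving == 0))

  # 8-connectivity: diagonal pixels form one cluster
  m <- matrix(0L, 5, 5); m[cbind(c(2, 3), c(2, 3))] <- 1L
  lab <- bodymapr:::.cc_label8(m)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 2L)
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[5, 5] <- 1L; m2[1, 5] <- 1L
  expect_equal(max(bodymapr:::.cc_label8(m2)), 3L)

  # provenance checks
  expect_error(cluster_correct(fit, alpha = 0.01), "differs")
  broken <- fit; broken$null_max_extent <- NULL
  expect_error(cluster_correct(broken), "provenance")

  # a single supra-threshold pixel cannot survive when the null max extent
  # is >= 2 in at least alpha of permutations
  fake <- fit
  fake$obs_supra <- matrix(0L, 4, 4); fake$obs_supra[2, 2] <- 1L
  fake$p_uncorrected[] <- 1; fake$p_uncorrected[2, 2] <- 1 / 201
  fake$null_max_extent <- rep(c(2, 0), c(50, 150))  # 95% quantile = 2
  cc <- cluster_correct(fake)
  expect_equal(nrow(cc$cluster_table), 1)
  expect_equal(cc$cluster_table$extent, 1L)
  expect_false(cc$cluster_table$surviving)
  expect_true(all(cc$surviving == 0))
  # with a null that almost never reaches 2, the same pixel survives
  fake$null_max_extent <- rep(c(2, 0), c(2, 198))
  cc2 <- cluster_correct(fake)
  expect_true(cc2$cluster_table$surviving)
  expect_equal(sum(cc2$surviving), 1)
})

test_that("surviving clusters recover a strong planted effect", {
  # planted difference: every group-a subject marks a block; both groups
  # also carry balanced random background concerns
  dims <- c(24, 24)
  blk <- square_poly(6, 6, 18, 18)
  set.seed(77)
  bg <- function() rasterize_outline(random_polygon(dims, nv = 5), dims)
  masks <- c(lapply(1:12, function(i)
               pmin(rasterize_outline(blk, dims) + bg(), 1L)),
             lapply(1:12, function(i) bg()))
  fit <- body_map_test(masks, rep(c("a", "b"), each = 12), B = 400,
                       seed = 5, fwhm_px = 4)
  expect_gt(sum(fit$surviving), 0)
  planted <- rasterize_outline(blk, dims)
  inter <- sum(fit$surviving & planted)
  uni <- sum(fit$surviving | planted)
  expect_gt(inter / uni, 0.3)
  # all surviving pixels belong to labeled clusters
  expect_true(all(fit$clusters[fit$surviving == 1] > 0))
})

test_that("body_map_test methods print and plot", {
  masks <- lapply(1:8, function(i) matrix(rbinom(16, 1, 0.5), 4, 4))
  fit <- body_map_test(masks, rep(c("a", "b"), 4), B = 100, seed = 2,
                       fwhm_px = NULL)
  expect_output(print(fit), "body_map_test")
  expect_output(summary(fit), "z range")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); plot(fit, which = "p"); grDevices::dev.off()
  expect_true(file.exists(tf))
})
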