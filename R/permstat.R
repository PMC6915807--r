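#' Two-proportion z statistic (pooled variance)
#'
#' z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2)) with p1 = x1/n1,
#' p2 = x2/n2 and pbar = (x1 + x2)/(n1 + n2). Degenerate pixels where the
#' pooled proportion is 0 or 1 (all subjects agree) return z = 0. Counts
#' may be fractional (effective counts n * smoothed proportion).
#'
#' @param x1,x2 successes per group (vectors allowed; 0 <= x <= n).
#' @param n1,n2 group sizes (>= 1).
#' @return numeric vector of z values.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (any(n1 < 1) || any(n2 < 1)) stop_f("group sizes must be >= 1")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2))
    stop_f("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  denom <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- ifelse(denom > 0, (p1 - p2) / denom, 0)
  ifelse(is.finite(z), z, 0)
}

# Stack masks into an n x P matrix (rows = subjects, P = H*W pixels,
# column-major pixel order), optionally Gaussian-smoothed per subject.
mask_matrix <- function(masks, fwhm_px = NULL) {
  d <- dim(masks[[1]])
  if (!is.null(fwhm_px)) {
    k <- gaussian_kernel1d(fwhm_to_sigma(fwhm_px))
    masks <- lapply(masks, function(m) convolve_reflect(m, k))
  }
  out <- matrix(0, nrow = length(masks), ncol = prod(d))
  for (i in seq_along(masks)) {
    if (!identical(dim(masks[[i]]), d)) stop_f("mask dimension mismatch")
    out[i, ] <- as.vector(masks[[i]])
  }
  out
}

#' Pixel-wise two-proportion z map between two groups
#'
#' With smoothing, each subject's binary mask is Gaussian-smoothed first
#' (equivalently, the group proportion maps are smoothed — the operations
#' commute by linearity) and the z statistic uses effective counts
#' x = n * smoothed proportion.
#'
#' @param groupA,groupB non-empty lists of H x W 0/1 masks (same dims).
#' @param fwhm_px smoothing kernel FWHM in pixels, or NULL for none.
#' @return H x W matrix of z values (groupA minus groupB).
#' @export
z_map <- function(groupA, groupB, fwhm_px = NULL) {
  if (!length(groupA) || !length(groupB)) stop_f("both groups must be non-empty")
  d <- dim(groupA[[1]])
  if (!identical(d, dim(groupB[[1]]))) stop_f("mask dimension mismatch")
  MA <- mask_matrix(groupA, fwhm_px); MB <- mask_matrix(groupB, fwhm_px)
  z <- two_proportion_z(colSums(MA), length(groupA),
                        colSums(MB), length(groupB))
  matrix(z, nrow = d[1], ncol = d[2])
}

#' Pixel-wise permutation p-values for a two-group body map
#'
#' Builds the observed z map, then the null distribution by randomly
#' relabeling subjects B times (group sizes preserved, sampled uniformly
#' with replacement from the relabeling space). The two-sided p-value per
#' pixel is the add-one estimator (1 + #\{b : |z_b| >= |z_obs|\})/(B + 1).
#' Identical thresholding at `alpha` is applied to every permuted map and
#' the null distribution of the maximum 8-connected supra-threshold
#' cluster extent is recorded for [cluster_correct()].
#'
#' @param masks list of per-subject H x W 0/1 masks.
#' @param labels group label per subject (exactly two distinct values; the
#'   z sign is first level minus second level of `factor(labels)`).
#' @param B number of permutations (>= 1).
#' @param seed RNG seed, recorded in the result.
#' @param fwhm_px Gaussian smoothing FWHM in pixels, or NULL.
#' @param alpha cluster-forming (and final) significance level.
#' @return an object of class `body_map_test` with elements `z`,
#'   `p_uncorrected` (H x W matrices), `null_max_extent` (length B),
#'   `B`, `seed`, `alpha`, `fwhm_px`, `groups`, `n`; cluster fields are
#'   filled by [cluster_correct()].
#' @export
permutation_pmap <- function(masks, labels, B = 5000L, seed = 1L,
                             fwhm_px = NULL, alpha = 0.05) {
  if (!is_count(B) || B < 1) stop_f("B must be a positive integer")
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop_f("need exactly two distinct group labels, got %d", nlevels(f))
  if (length(masks) != length(f))
    stop_f("labels length (%d) != number of masks (%d)", length(f),
           length(masks))
  d <- dim(masks[[1]]); H <- d[1]; W <- d[2]; P <- H * W
  n <- length(masks); nA <- sum(f == levels(f)[1]); nB <- n - nA
  if ((B + 1) * as.double(P) * 8 > 4e9)
    stop_f("permutation store would exceed 4 GB; reduce B or the raster")

  M <- mask_matrix(masks, fwhm_px)
  tot <- colSums(M)
  pbar <- tot / n
  denom <- sqrt(pbar * (1 - pbar) * (1 / nA + 1 / nB))
  zfun <- function(xA) {
    z <- ((xA / nA) - (tot - xA) / nB) / denom
    z[!is.finite(z)] <- 0
    z
  }
  z_obs <- zfun(colSums(M[f == levels(f)[1], , drop = FALSE]))

  absZ <- matrix(0, nrow = B + 1L, ncol = P)
  absZ[1L, ] <- abs(z_obs)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, nA)
      absZ[b + 1L, ] <- abs(zfun(colSums(M[idx, , drop = FALSE])))
    }
  })
  st <- .perm_pixel_stats(absZ, H, W, alpha)

  structure(list(
    z = matrix(z_obs, H, W),
    p_uncorrected = matrix(st$p_obs, H, W),
    obs_supra = matrix(st$obs_supra, H, W),
    null_max_extent = st$null_max_extent,
    clusters = NULL, surviving = NULL, cluster_table = NULL,
    extent_threshold = NA_real_,
    B = as.integer(B), seed = as.integer(seed), alpha = alpha,
    fwhm_px = fwhm_px, groups = levels(f),
    n = stats::setNames(c(nA, nB), levels(f)), dims = c(W, H)),
    class = "body_map_test")
}

#' Cluster-extent correction of a permutation body map
#'
#' Clusters are 8-connected components of the supra-threshold set
#' \{p_uncorrected < alpha\}. A cluster survives iff its pixel extent is at
#' least the (1 - alpha) quantile (order statistic) of the null
#' distribution of the maximum cluster extent, obtained by applying the
#' identical per-pixel thresholding to every permuted map. Per-cluster
#' family-wise p-values (1 + #\{b : max extent_b >= extent\})/(B + 1) are
#' also reported.
#'
#' @param result a `body_map_test` from [permutation_pmap()].
#' @param alpha significance level; must equal the level the permutation
#'   null was thresholded at (the stored provenance).
#' @return `result` with `clusters` (integer label matrix), `surviving`
#'   (0/1 matrix), `cluster_table` and `extent_threshold` filled.
#' @export
cluster_correct <- function(result, alpha = result$alpha) {
  if (!inherits(result, "body_map_test"))
    stop_f("result must come from permutation_pmap()")
  if (is.null(result$null_max_extent) || is.null(result$obs_supra) ||
      is.null(result$B) || is.null(result$seed))
    stop_f("result lacks permutation provenance (B/seed/null extents)")
  if (!isTRUE(all.equal(alpha, result$alpha)))
    stop_f(paste0("alpha (%.4g) differs from the level the permutation null",
                  " was built at (%.4g); re-run permutation_pmap"),
           alpha, result$alpha)
  lab <- .cc_label8(result$obs_supra)
  extents <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer()
  crit <- if (length(result$null_max_extent))
    stats::quantile(result$null_max_extent, 1 - alpha, type = 1, names = FALSE)
  else Inf
  keep <- which(extents >= crit)
  surv <- matrix(as.integer(lab %in% keep & lab > 0),
                 nrow = nrow(lab), ncol = ncol(lab))
  B <- result$B
  ctab <- if (length(extents)) data.frame(
    cluster = seq_along(extents),
    extent = extents,
    p_fwe = (1 + vapply(extents, function(e)
      sum(result$null_max_extent >= e), numeric(1))) / (B + 1),
    surviving = seq_along(extents) %in% keep)
  else data.frame(cluster = integer(), extent = integer(),
                  p_fwe = numeric(), surviving = logical())
  result$clusters <- lab
  result$surviving <- surv
  result$cluster_table <- ctab
  result$extent_threshold <- crit
  result
}

#' Fit a cluster-corrected statistical body map
#'
#' The one-call interface: computes the (optionally smoothed) pixel-wise
#' two-proportion z map between the two groups, permutation p-values
#' (B relabelings) and cluster-extent-corrected significance, returning a
#' classed result with print/summary/plot methods.
#'
#' @param x a `cohort` (masks and labels derived from it), or a list of
#'   per-subject 0/1 masks.
#' @param labels group label per subject (ignored for cohorts).
#' @param B number of permutations.
#' @param seed RNG seed.
#' @param fwhm_px Gaussian smoothing FWHM in pixels (NULL to disable).
#' @param alpha significance level (cluster-forming and cluster-level).
#' @param ... passed between methods.
#' @return an object of class `body_map_test`; see [permutation_pmap()]
#'   and [cluster_correct()] for the fields.
#' @export
body_map_test <- function(x, ...) UseMethod("body_map_test")

#' @rdname body_map_test
#' @export
body_map_test.cohort <- function(x, B = 5000L, seed = 1L, fwhm_px = 6,
                                 alpha = 0.05, ...) {
  body_map_test(cohort_masks(x), labels = cohort_groups(x), B = B,
                seed = seed, fwhm_px = fwhm_px, alpha = alpha, ...)
}

#' @rdname body_map_test
#' @export
body_map_test.default <- function(x, labels, B = 5000L, seed = 1L,
                                  fwhm_px = 6, alpha = 0.05, ...) {
  fit <- permutation_pmap(x, labels, B = B, seed = seed, fwhm_px = fwhm_px,
                          alpha = alpha)
  cluster_correct(fit)
}

#' @export
print.body_map_test <- function(x, ...) {
  cat(sprintf("<body_map_test> %s (n=%d) vs %s (n=%d), %dx%d px\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2],
              x$dims[1], x$dims[2]))
  cat(sprintf("  B = %d permutations (seed %d), alpha = %g, fwhm = %s px\n",
              x$B, x$seed, x$alpha,
              if (is.null(x$fwhm_px)) "none" else format(x$fwhm_px)))
  if (!is.null(x$cluster_table)) {
    ns <- sum(x$cluster_table$surviving)
    cat(sprintf("  %d supra-threshold cluster(s), %d surviving (extent >= %s)\n",
                nrow(x$cluster_table), ns, format(x$extent_threshold)))
  } else cat("  clusters: not yet corrected (run cluster_correct)\n")
  invisible(x)
}

#' @export
summary.body_map_test <- function(object, ...) {
  print(object)
  cat(sprintf("  z range [%.2f, %.2f]; min p = %.4g (floor 1/(B+1) = %.4g)\n",
              min(object$z), max(object$z), min(object$p_uncorrected),
              1 / (object$B + 1)))
  if (!is.null(object$cluster_table) && nrow(object$cluster_table)) {
    cat("  clusters:\n")
    print(object$cluster_table, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.body_map_test <- function(x, which = c("z", "p"), ...) {
  which <- match.arg(which)
  H <- x$dims[2]; W <- x$dims[1]
  m <- if (which == "z") x$z else -log10(x$p_uncorrected)
  z <- t(m[H:1, , drop = FALSE])
  if (which == "z") {
    lim <- max(abs(m), 1e-12)
    graphics::image(seq_len(W) - 0.5, seq_len(H) - 0.5, z,
                    zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(101, "Blue-Red 2"),
                    xlab = "x", ylab = "y", asp = 1,
                    main = sprintf("z map (%s - %s)", x$groups[1], x$groups[2]),
                    useRaster = TRUE, ...)
  } else {
    graphics::image(seq_len(W) - 0.5, seq_len(H) - 0.5, z,
                    col = grDevices::hcl.colors(101, "YlOrRd", rev = TRUE),
                    xlab = "x", ylab = "y", asp = 1,
                    main = "-log10 permutation p", useRaster = TRUE, ...)
  }
  if (!is.null(x$surviving) && any(x$surviving > 0))
    graphics::contour(seq_len(W) - 0.5, seq_len(H) - 0.5,
                      t(x$surviving[H:1, , drop = FALSE]), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lwd = 2)
  invisible(x)
}
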