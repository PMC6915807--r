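# Shared fixtures and independent oracles, built in code.

# Brute-force even-odd point-in-polygon (crossing-number ray cast toward
# +x). Deliberately a different algorithm from the scanline fill it checks.
pip_evenodd <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi <= py && py < yj) || (yj <= py && py < yi)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

brute_mask <- function(poly, dims) {
  W <- dims[1]; H <- dims[2]
  m <- matrix(0L, nrow = H, ncol = W)
  for (j in seq_len(H)) for (i in seq_len(W))
    m[j, i] <- as.integer(pip_evenodd(i - 0.5, j - 0.5, poly))
  m
}

# Random simple-ish polygon with non-lattice vertices (star-shaped around a
# centre, so vertices are ordered but edges can still be irregular).
random_polygon <- function(dims, nv = 7) {
  cx <- runif(1, 0.3, 0.7) * dims[1]
  cy <- runif(1, 0.3, 0.7) * dims[2]
  th <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, 0.05, 0.28) * min(dims)
  cbind(pmin(pmax(cx + r * cos(th), 0), dims[1]),
        pmin(pmax(cy + r * sin(th), 0), dims[2]))
}

square_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Mask whose set pixels are given as a two-column (row, col) index matrix.
mask_from_pixels <- function(dims, rc) {
  m <- matrix(0L, nrow = dims[2], ncol = dims[1])
  if (length(rc)) m[rc] <- 1L
  m
}

toy_calibration <- function() {
  calibration_table(data.frame(
    part = c("bicep", "waist", "thighs", "shoulders", "bust", "hips",
             "calves"),
    m0  = c(20, 50, 30, 25, 60, 70, 25),
    m05 = c(28, 70, 45, 33, 85, 95, 38),
    m1  = c(40, 95, 62, 45, 115, 130, 55)))
}

# A minimal 2-subject cohort exercising every optional block.
tiny_cohort <- function() {
  dims <- c(40L, 60L)
  ce <- concern_entry(square_poly(5, 5, 15, 15),
                      concern_types = c("bloated", "too large"),
                      affects = c("frustrated", "looks ok/fine"),
                      intensity = 55)
  calib <- default_calibration()
  sliders <- sapply(avatar_body_parts, function(p) 0.5)
  meas <- sapply(measured_body_parts, function(p)
    calib[measured_to_slider_test()[p], "m05"])
  s1 <- subject_record("a1", "A", concerns = list(ce),
                       avatar = avatar_settings(sliders),
                       measured = body_measurements(meas),
                       demographics = list(age_years = 25, height_cm = 170,
                                           weight_kg = 60,
                                           bmi = 60 / 1.7^2))
  s2 <- subject_record("b1", "B")
  cohort(list(s1, s2), raster_dims = dims)
}

# mirror of the internal measured-site -> slider-region map
measured_to_slider_test <- function() {
  c(shoulders = "shoulders", bust = "bust", biceps = "bicep",
    waist = "waist", hips = "hips", thighs = "thighs", calves = "calves")
}

# Exact two-sided permutation p-values over all group-A index subsets for
# small cohorts (enumeration oracle for the sampled permutation engine).
exact_perm_p <- function(masks, labels, fwhm_px = NULL) {
  f <- factor(labels)
  nA <- sum(f == levels(f)[1])
  n <- length(masks)
  d <- dim(masks[[1]])
  get_z <- function(idxA) {
    zm <- z_map(masks[idxA], masks[setdiff(seq_len(n), idxA)],
                fwhm_px = fwhm_px)
    abs(as.vector(zm))
  }
  combos <- utils::combn(n, nA)
  zs <- apply(combos, 2, get_z)            # P x ncombos
  z_obs <- get_z(which(f == levels(f)[1]))
  p <- vapply(seq_along(z_obs), function(j)
    mean(zs[j, ] >= z_obs[j] - 1e-12), numeric(1))
  matrix(p, d[1], d[2])
}

# 1-decimal half-up rounding as used for printed percentages
round_half_up_test <- function(x) floor(x * 10 + 0.5) / 10
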