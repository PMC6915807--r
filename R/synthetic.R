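# Table-derived defaults for the synthetic world: per-part actual size
# means/SDs (cm) and group perception bias (perceived - actual, cm).
.default_sizes <- list(
  model = list(
    mean = c(shoulders = 35.18, bust = 80.58, biceps = 22.37, waist = 64.68,
             hips = 89.03, thighs = 44.58, calves = 32.51),
    sd   = c(shoulders = 2.17, bust = 3.99, biceps = 2.30, waist = 4.94,
             hips = 4.65, thighs = 3.02, calves = 2.75)),
  nonmodel = list(
    mean = c(shoulders = 32.11, bust = 85.76, biceps = 28.61, waist = 74.11,
             hips = 96.11, thighs = 46.53, calves = 42.08),
    sd   = c(shoulders = 2.22, bust = 6.01, biceps = 6.18, waist = 6.45,
             hips = 7.09, thighs = 7.09, calves = 6.09)))

.default_bias <- list(
  model    = c(shoulders = -3.83, bust = -3.23, biceps = 0.01, waist = -4.30,
               hips = 0.58, thighs = -12.95, calves = -2.86),
  nonmodel = c(shoulders = -0.59, bust = -6.54, biceps = -4.34, waist = -11.91,
               hips = -5.04, thighs = -12.05, calves = -10.53))

.default_demographics <- list(
  model = list(height = c(175.9, 5.1), weight = c(57.5, 4.4),
               age = c(23.4, 5.5),
               race = c(Caucasian = 44, Asian = 5, Black = 3,
                        `Hispanic/Latino` = 1, `Mixed race` = 12),
               education = c(`Graduate school` = 2, `University graduate` = 12,
                             `Some university` = 6, `High school` = 32,
                             `Some high school` = 9, `Less than high school` = 4)),
  nonmodel = list(height = c(162.5, 6.3), weight = c(56.9, 8.4),
                  age = c(25.4, 5.2),
                  race = c(Caucasian = 21, Asian = 7, Black = 3,
                           `Hispanic/Latino` = 2, `Mixed race` = 5),
                  education = c(`Graduate school` = 7, `University graduate` = 25,
                                `Some university` = 3, `High school` = 3,
                                `Some high school` = 0, `Less than high school` = 0)))

# Affect sampling weights: pooled endorsement counts across both groups.
.default_affect_weights <- c(
  "frustrated" = 26, "anxious/tense/worried/nervous" = 21, "ashamed" = 19,
  "hopeless" = 9, "sad" = 10, "disgusted" = 8, "defective" = 6,
  "depressed" = 7, "fearful" = 3, "angry" = 3, "overwhelmed" = 1,
  "lonely" = 1, "numb/unreal/dead" = 1, "embarrassed" = 1, "other" = 23,
  "looks ok/fine" = 31, "hopeful" = 11, "satisfied/content" = 6)

#' Default avatar calibration table (synthetic)
#'
#' A stand-in for the in-engine ruler measurements of the scanned
#' volunteer, which are not published: baseline (slider 0.5) sizes are
#' plausible adult-female part sizes, and the slider endpoints span 50% to
#' 150% of baseline so that every realistic perceived size is
#' representable.
#'
#' @return a [calibration_table()] over the 13 avatar parts.
#' @export
default_calibration <- function() {
  m05 <- c(neck = 33, shoulders = 33, torso = 90, bust = 85, bicep = 28,
           forearm = 24, hands = 19, hips = 95, waist = 70, buttocks = 98,
           thighs = 45, calves = 38, feet = 24)
  calibration_table(data.frame(part = names(m05), m0 = 0.5 * m05,
                               m05 = m05, m1 = 1.5 * m05))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the pilot study's world: two groups of 65 and 38
#' women; spatially structured concern probabilities (a thighs/buttocks
#' region far more frequent in models, an abdomen region more frequent in
#' nonmodels) over a background rate of unstructured concerns; per-part
#' actual sizes and group perception biases matching the printed group
#' summaries; slider settings derived by inverting the calibration.
#'
#' @param dims raster `c(width, height)` in pixels.
#' @param groups named integer vector of group sizes (>= 1 each).
#' @param regions named list; each region has `center` and `half`
#'   (fractions of the raster), and `p`, the per-group probability that a
#'   subject draws a concern there.
#' @param base_rate expected number of additional unstructured concerns
#'   per subject (Poisson mean).
#' @param intensity_mean,intensity_sd intensity rating distribution
#'   (normal, clipped to \[0, 100\]).
#' @param sizes per-group list with named `mean` and `sd` vectors (cm)
#'   over the seven measured parts.
#' @param bias per-group named vector: mean perceived-minus-actual (cm).
#' @param noise_sd SD of perception noise (cm) on top of the bias.
#' @param calibration a [calibration_table()].
#' @param affect_weights named sampling weights over affect labels.
#' @param demographics per-group list of height/weight/age (mean, sd) and
#'   race/education category weights.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(dims = c(400L, 800L),
                             groups = c(model = 65L, nonmodel = 38L),
                             regions = NULL,
                             base_rate = 0.5,
                             intensity_mean = 30, intensity_sd = 30,
                             sizes = NULL, bias = NULL, noise_sd = 3,
                             calibration = default_calibration(),
                             affect_weights = .default_affect_weights,
                             demographics = NULL) {
  dims <- check_dims(dims)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_f("groups must be a named vector of sizes")
  if (any(groups < 1)) stop_f("group sizes must be >= 1")
  gnames <- names(groups)
  if (is.null(regions)) {
    # default layout: thighs/buttocks frequent in group 1 ("model"-like),
    # abdomen frequent in group 2; further groups reuse the group-1 rate
    byg <- function(p12) stats::setNames(
      p12[pmin(seq_along(gnames), 2L)], gnames)
    regions <- list(
      thighs_buttocks = list(center = c(0.5, 0.62), half = c(0.18, 0.10),
                             p = byg(c(0.74, 0.25))),
      abdomen = list(center = c(0.5, 0.42), half = c(0.14, 0.06),
                     p = byg(c(0.20, 0.45))))
  }
  for (rn in names(regions)) {
    r <- regions[[rn]]
    if (length(r$p) == 1L && is.null(names(r$p)))
      regions[[rn]]$p <- r$p <- stats::setNames(rep(r$p, length(gnames)),
                                                gnames)
    if (any(r$p < 0 | r$p > 1))
      stop_f("region %s: probabilities must lie in [0, 1]", rn)
    if (!all(gnames %in% names(r$p)))
      stop_f("region %s: p must be named by group (%s)", rn,
             paste(gnames, collapse = ", "))
    if (any(r$center < 0 | r$center > 1) || any(r$half <= 0 | r$half > 0.5))
      stop_f("region %s: center/half must be raster fractions", rn)
  }
  if (base_rate < 0) stop_f("base_rate must be >= 0")
  if (noise_sd < 0) stop_f("noise_sd must be >= 0")
  pick <- function(user, default) {
    if (!is.null(user)) {
      if (!all(gnames %in% names(user)))
        stop_f("per-group parameters must be named by group (%s)",
               paste(gnames, collapse = ", "))
      return(user[gnames])
    }
    # name-matched when possible, else positional, else the first default
    out <- lapply(seq_along(gnames), function(i)
      default[[gnames[i]]] %||% default[[min(i, length(default))]])
    stats::setNames(out, gnames)
  }
  structure(list(dims = dims, groups = groups, regions = regions,
                 base_rate = base_rate, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 sizes = pick(sizes, .default_sizes),
                 bias = pick(bias, .default_bias),
                 noise_sd = noise_sd, calibration = calibration,
                 affect_weights = affect_weights,
                 demographics = pick(demographics, .default_demographics)),
            class = "generator_config")
}

# Ellipse approximated by an nv-vertex polygon, vertices clamped in-bounds.
sample_ellipse_polygon <- function(center, axes, rotation, dims, nv = 24L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  x0 <- axes[1] * cos(th); y0 <- axes[2] * sin(th)
  x <- center[1] + x0 * cos(rotation) - y0 * sin(rotation)
  y <- center[2] + x0 * sin(rotation) + y0 * cos(rotation)
  cbind(pmin(pmax(x, 0), dims[1]), pmin(pmax(y, 0), dims[2]))
}

#' Binary mask of a configured planted region
#'
#' The nominal region footprint (ellipse with the configured half-axes),
#' used as ground truth in effect-recovery checks.
#'
#' @param config a [generator_config()].
#' @param name region name.
#' @return H x W 0/1 matrix.
#' @export
region_mask <- function(config, name) {
  r <- config$regions[[name]]
  if (is.null(r)) stop_f("unknown region: %s", name)
  d <- config$dims
  poly <- sample_ellipse_polygon(r$center * d, r$half * d, 0, d)
  rasterize_outline(poly, d)
}

sample_concern <- function(config, center, axes) {
  d <- config$dims
  poly <- sample_ellipse_polygon(center, axes, stats::runif(1, 0, pi), d)
  ntype <- 1L + min(stats::rpois(1, 1), 3L)
  naff <- 1L + min(stats::rpois(1, 0.7), 2L)
  concern_entry(
    polygon = poly,
    concern_types = sample(concern_type_vocabulary, ntype),
    affects = sample(names(config$affect_weights), naff,
                     prob = config$affect_weights),
    intensity = min(100, max(0, stats::rnorm(1, config$intensity_mean,
                                             config$intensity_sd))))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per subject: each configured region contributes a concern with its
#' group's probability (an ellipse jittered around the region centre and
#' guaranteed to cover it), plus a Poisson number of unstructured
#' background concerns; actual sizes are drawn per part from the group's
#' normal distribution; perceived size = actual + group bias + noise, and
#' the avatar slider is the calibration inverse of the perceived size.
#' Perceived values outside the calibration range are clipped to it; the
#' clip count is recorded in `meta$n_clipped` (never silent). If every
#' draw for some part falls outside the range the generator stops and
#' advises extending the calibration. Deterministic given (config, seed).
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return a validated `cohort`; `meta` records the seed and clipping.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$dims
  calib <- config$calibration
  gnames <- names(config$groups)
  with_seed(seed, {
    subjects <- list()
    n_clipped <- 0L; n_out <- integer(length(measured_body_parts))
    n_draw <- 0L
    names(n_out) <- measured_body_parts
    sid <- 0L
    for (g in gnames) {
      for (i in seq_len(config$groups[[g]])) {
        sid <- sid + 1L
        concerns <- list()
        for (r in config$regions) {
          if (stats::runif(1) >= r$p[[g]]) next
          ctr <- r$center * d + stats::runif(2, -0.15, 0.15) * r$half * d
          axes <- r$half * d * stats::runif(2, 0.85, 1.1)
          concerns[[length(concerns) + 1L]] <- sample_concern(config, ctr, axes)
        }
        for (k in seq_len(stats::rpois(1, config$base_rate))) {
          ctr <- stats::runif(2, 0.15, 0.85) * d
          axes <- stats::runif(2, 0.03, 0.08) * min(d)
          concerns[[length(concerns) + 1L]] <- sample_concern(config, ctr, axes)
        }
        sz <- config$sizes[[g]]
        true_cm <- stats::rnorm(length(measured_body_parts),
                                sz$mean[measured_body_parts],
                                sz$sd[measured_body_parts])
        true_cm <- pmax(true_cm, 0.2 * sz$mean[measured_body_parts])
        names(true_cm) <- measured_body_parts
        perceived <- true_cm + config$bias[[g]][measured_body_parts] +
          stats::rnorm(length(true_cm), 0, config$noise_sd)
        sliders <- numeric(0)
        for (p in measured_body_parts) {
          sp <- measured_to_slider[[p]]
          cr <- calib_row(calib, sp)
          n_draw <- n_draw + 1L
          if (perceived[[p]] < cr$m0 || perceived[[p]] > cr$m1) {
            n_out[[p]] <- n_out[[p]] + 1L
            n_clipped <- n_clipped + 1L
            perceived[[p]] <- min(max(perceived[[p]], cr$m0), cr$m1)
          }
          sliders[[sp]] <- cm_to_slider(calib, sp, perceived[[p]])
        }
        for (sp in setdiff(avatar_body_parts, unname(measured_to_slider)))
          sliders[[sp]] <- stats::runif(1, 0.3, 0.7)
        dem <- config$demographics[[g]]
        height <- stats::rnorm(1, dem$height[1], dem$height[2])
        weight <- stats::rnorm(1, dem$weight[1], dem$weight[2])
        subjects[[sid]] <- subject_record(
          id = sprintf("S%03d", sid), group = g, concerns = concerns,
          avatar = avatar_settings(sliders),
          measured = body_measurements(true_cm),
          demographics = list(
            age_years = max(18, stats::rnorm(1, dem$age[1], dem$age[2])),
            height_cm = height, weight_kg = weight,
            bmi = weight / (height / 100)^2,
            race_ethnicity = if (sum(dem$race) > 0)
              sample(names(dem$race), 1, prob = dem$race) else NA,
            education = if (sum(dem$education) > 0)
              sample(names(dem$education), 1, prob = dem$education) else NA),
          usability = list(
            ease = min(10, max(1, stats::rnorm(1, 8.4, 2.1))),
            enjoyment = min(10, max(1, stats::rnorm(1, 6.5, 2.4))),
            identification = min(10, max(0, stats::rnorm(1, 5.2, 2.5))),
            resemblance_pct = min(100, max(0, stats::rnorm(1, 74, 18)))))
      }
    }
    fully_out <- names(n_out)[n_out >= sum(config$groups)]
    if (length(fully_out))
      stop_f(paste0("perception bias pushes every subject outside the ",
                    "calibration range for: %s; extend the calibration ",
                    "(m0/m1) for these parts"),
             paste(fully_out, collapse = ", "))
    cohort(subjects, raster_dims = d,
           meta = list(generator = "bodymapr synthetic", seed = as.integer(seed),
                       n_clipped = n_clipped, n_slider_draws = n_draw,
                       clipped_by_part = as.list(n_out)))
  })
}

#' Generate a null cohort (identical generative model in both groups)
#'
#' For type-I-error studies: verifies that every per-group parameter
#' (region probabilities, size distributions, perception bias) is
#' identical across groups, then delegates to [generate_cohort()]. Group
#' labels are thus arbitrary by construction.
#'
#' @param config a symmetric [generator_config()] (see [symmetrize_config()]).
#' @param seed RNG seed.
#' @return a validated `cohort`.
#' @export
null_cohort <- function(config, seed = 1L) {
  gnames <- names(config$groups)
  for (rn in names(config$regions)) {
    p <- config$regions[[rn]]$p[gnames]
    if (length(unique(unlist(p))) > 1L)
      stop_f("null_cohort: region %s has unequal group probabilities", rn)
  }
  ref <- gnames[1]
  for (g in gnames[-1]) {
    if (!isTRUE(all.equal(config$sizes[[g]], config$sizes[[ref]])) ||
        !isTRUE(all.equal(config$bias[[g]], config$bias[[ref]])))
      stop_f("null_cohort: groups %s and %s have unequal size/bias parameters",
             ref, g)
  }
  generate_cohort(config, seed)
}

#' Make a generator config symmetric across groups
#'
#' Copies the first group's region probabilities, size distributions,
#' perception bias and demographics to every group, yielding a valid input
#' for [null_cohort()].
#'
#' @param config a [generator_config()].
#' @return a symmetric `generator_config`.
#' @export
symmetrize_config <- function(config) {
  gnames <- names(config$groups)
  ref <- gnames[1]
  for (rn in names(config$regions))
    config$regions[[rn]]$p[gnames] <- config$regions[[rn]]$p[[ref]]
  for (g in gnames[-1]) {
    config$sizes[[g]] <- config$sizes[[ref]]
    config$bias[[g]] <- config$bias[[ref]]
    config$demographics[[g]] <- config$demographics[[ref]]
  }
  config
}
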