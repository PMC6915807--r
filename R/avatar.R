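#' Avatar calibration table
#'
#' Per body part, the physical measurement (cm, in-engine ruler) of the
#' avatar at slider positions 0, 0.5 and 1. The 0.5 position is the
#' scanned volunteer's baseline body; slider-to-cm conversion is piecewise
#' linear between the three anchors.
#'
#' @param parts data.frame with columns `part`, `m0`, `m05`, `m1`, or a
#'   path handled by [read_calibration()].
#' @return an object of class `calibration_table`.
#' @export
calibration_table <- function(parts) {
  df <- as.data.frame(parts)
  need <- c("part", "m0", "m05", "m1")
  if (!all(need %in% names(df)))
    stop_f("calibration needs columns: %s", paste(need, collapse = ", "))
  df$part <- as.character(df$part)
  if (anyDuplicated(df$part)) stop_f("duplicated calibration part")
  for (col in c("m0", "m05", "m1")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0))
      stop_f("calibration %s must be positive", col)
  }
  if (any(df$m0 >= df$m1))
    stop_f("calibration requires m0 < m1 for every part")
  rownames(df) <- df$part
  structure(df, class = c("calibration_table", "data.frame"))
}

#' @rdname calibration_table
#' @param path CSV file with columns part, m0, m05, m1.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_f("calibration file not found: %s", path)
  calibration_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname calibration_table
#' @param x a `calibration_table`.
#' @export
write_calibration <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x))[c("part", "m0", "m05", "m1")],
                   path, row.names = FALSE)
  invisible(path)
}

calib_row <- function(calib, part) {
  if (!part %in% rownames(calib))
    stop_f("unknown calibration part: %s (have: %s)", part,
           paste(rownames(calib), collapse = ", "))
  calib[part, , drop = FALSE]
}

#' Convert a slider setting to centimeters
#'
#' Separate linear interpolations below and above the 0.5 baseline:
#' s in \[0, 0.5\] maps linearly m0 -> m05 and s in \[0.5, 1\] maps
#' m05 -> m1 (continuous at 0.5). Equivalently, with scale factors
#' r0 = m0/m05 and r1 = m1/m05, s <= 0.5 gives
#' m05 * (r0 + (1 - r0) * s/0.5).
#'
#' @param calib a [calibration_table()].
#' @param part body part name present in `calib`.
#' @param s slider value(s) in \[0, 1\].
#' @return measurement(s) in cm.
#' @export
slider_to_cm <- function(calib, part, s) {
  if (any(s < 0 | s > 1)) stop_f("slider value out of [0, 1]")
  cr <- calib_row(calib, part)
  ifelse(s <= 0.5,
         cr$m0 + (cr$m05 - cr$m0) * (s / 0.5),
         cr$m05 + (cr$m1 - cr$m05) * ((s - 0.5) / 0.5))
}

#' Invert the slider calibration: centimeters to slider value
#'
#' Exact inverse of [slider_to_cm()] on each linear segment;
#' `slider_to_cm(calib, part, cm_to_slider(calib, part, x)) == x` to 1e-9
#' for any representable x.
#'
#' @param calib a [calibration_table()].
#' @param part body part name present in `calib`.
#' @param cm measurement(s) in cm, within \[m0, m1\] for that part.
#' @return slider value(s) in \[0, 1\].
#' @export
cm_to_slider <- function(calib, part, cm) {
  cr <- calib_row(calib, part)
  if (!(cr$m0 <= cr$m05 && cr$m05 <= cr$m1))
    stop_f("%s: non-monotone calibration (m0 <= m05 <= m1 fails), no inverse",
           part)
  if (any(cm < cr$m0 | cm > cr$m1))
    stop_f("%s: %s cm outside representable range [%.4g, %.4g]",
           part, paste(format(cm[cm < cr$m0 | cm > cr$m1]), collapse = ", "),
           cr$m0, cr$m1)
  ifelse(cm <= cr$m05,
         0.5 * (cm - cr$m0) / (cr$m05 - cr$m0),
         0.5 + 0.5 * (cm - cr$m05) / (cr$m1 - cr$m05))
}

#' Perceived-versus-actual body size discrepancy profile
#'
#' Converts a subject's avatar sliders to perceived centimeters via the
#' calibration table and subtracts the tape-measured actual size for each
#' of the seven measured parts: negative discrepancy = underestimation.
#' Also reports the scaled body average: the mean over parts of
#' measurement / reference, where the reference defaults to the
#' calibration baseline (m05) of each part.
#'
#' @param avatar an [avatar_settings()] with sliders for all seven parts
#'   that have tape-measure counterparts.
#' @param calib a [calibration_table()] keyed by avatar part names.
#' @param actual a [body_measurements()] with the seven measured parts.
#' @param reference optional [body_measurements()] used as the scaling
#'   reference; defaults to the calibration m05 baseline.
#' @return an object of class `discrepancy_profile`: data.frame `parts`
#'   (part, slider, perceived_cm, actual_cm, discrepancy_cm) plus
#'   `scaled_perceived`, `scaled_actual`, `scaled_difference`.
#' @export
discrepancy_profile <- function(avatar, calib, actual, reference = NULL) {
  if (!inherits(avatar, "avatar_settings")) stop_f("avatar must be avatar_settings")
  if (!inherits(actual, "body_measurements"))
    stop_f("actual must be body_measurements")
  missing_sl <- setdiff(unname(measured_to_slider), names(avatar$sliders))
  missing_ms <- setdiff(measured_body_parts, names(actual$sizes_cm))
  if (length(missing_sl) || length(missing_ms))
    stop_f("missing parts - sliders: [%s]; measurements: [%s]",
           paste(missing_sl, collapse = ", "),
           paste(missing_ms, collapse = ", "))
  parts <- measured_body_parts
  slider_parts <- unname(measured_to_slider[parts])
  s <- avatar$sliders[slider_parts]
  perceived <- vapply(seq_along(parts), function(i)
    slider_to_cm(calib, slider_parts[i], s[i]), numeric(1))
  act <- actual$sizes_cm[parts]
  ref <- if (is.null(reference)) {
    vapply(slider_parts, function(p) calib_row(calib, p)$m05, numeric(1))
  } else {
    if (!inherits(reference, "body_measurements"))
      stop_f("reference must be body_measurements")
    if (length(setdiff(parts, names(reference$sizes_cm))))
      stop_f("reference lacks some measured parts")
    reference$sizes_cm[parts]
  }
  if (any(ref <= 0)) stop_f("reference measurements must be positive")
  df <- data.frame(part = parts, slider = unname(s),
                   perceived_cm = unname(perceived),
                   actual_cm = unname(act),
                   discrepancy_cm = unname(perceived - act))
  structure(list(parts = df,
                 scaled_perceived = mean(perceived / ref),
                 scaled_actual = mean(act / ref),
                 scaled_difference = mean(perceived / ref) - mean(act / ref)),
            class = "discrepancy_profile")
}

#' @export
print.discrepancy_profile <- function(x, ...) {
  cat("<discrepancy_profile> perceived - actual (cm):\n")
  print(x$parts, row.names = FALSE, digits = 4)
  cat(sprintf("scaled body average: perceived %.3f, actual %.3f, diff %.3f\n",
              x$scaled_perceived, x$scaled_actual, x$scaled_difference))
  invisible(x)
}

#' Per-subject discrepancy profiles for a cohort
#'
#' @param x a `cohort` whose subjects carry avatar sliders and tape
#'   measurements (subjects missing either block are skipped).
#' @param calib a [calibration_table()].
#' @param reference optional scaling reference, see [discrepancy_profile()].
#' @return data.frame with one row per subject x part (id, group, part,
#'   perceived_cm, actual_cm, discrepancy_cm) plus per-subject scaled
#'   averages as attribute "scaled" (id, group, perceived, actual, diff).
#' @export
cohort_discrepancies <- function(x, calib, reference = NULL) {
  rows <- list(); scal <- list()
  for (s in x$subjects) {
    if (is.null(s$avatar) || is.null(s$measured)) next
    dp <- discrepancy_profile(s$avatar, calib, s$measured, reference)
    rows[[length(rows) + 1L]] <-
      cbind(id = s$id, group = s$group, dp$parts)
    scal[[length(scal) + 1L]] <-
      data.frame(id = s$id, group = s$group,
                 perceived = dp$scaled_perceived,
                 actual = dp$scaled_actual,
                 difference = dp$scaled_difference)
  }
  if (!length(rows)) stop_f("no subject has both avatar and measurements")
  out <- do.call(rbind, rows)
  attr(out, "scaled") <- do.call(rbind, scal)
  out
}
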