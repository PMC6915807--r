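#' Build one outlined body concern
#'
#' A concern is a closed polygon drawn on the manikin raster, annotated with
#' the kinds of concern, the emotions it evokes, and an intensity rating on
#' a 0-100 slider. Coordinates are 0-based pixel units, origin at the
#' top-left corner, x rightward, y downward; the polygon is implicitly
#' closed (last vertex joins the first).
#'
#' @param polygon two-column matrix (or list of length-2 vectors) of (x, y)
#'   vertices; at least 3 vertices.
#' @param concern_types character vector of concern-type labels (free text
#'   allowed alongside [concern_type_vocabulary]).
#' @param affects character vector of affect labels, or a data.frame with
#'   columns `label` and `valence`; labels from [affect_vocabulary] take
#'   their fixed valence class, free text is "unclassified" unless flagged.
#' @param intensity magnitude rating in \[0, 100\].
#' @param negative_free_text free-text affect labels explicitly flagged as
#'   negative.
#' @return an object of class `concern_entry`.
#' @export
concern_entry <- function(polygon, concern_types = character(),
                          affects = character(), intensity = 0,
                          negative_free_text = character()) {
  if (is.list(polygon) && !is.data.frame(polygon))
    polygon <- do.call(rbind, lapply(polygon, as.numeric))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L)
    stop_f("polygon must have two columns (x, y)")
  if (nrow(polygon) < 3L)
    stop_f("degenerate polygon: %d vertices (need >= 3)", nrow(polygon))
  if (!all(is.finite(polygon)))
    stop_f("polygon vertices must be finite")
  storage.mode(polygon) <- "double"
  dimnames(polygon) <- list(NULL, c("x", "y"))

  if (is.data.frame(affects)) {
    if (!all(c("label", "valence") %in% names(affects)))
      stop_f("affect data.frame needs columns 'label' and 'valence'")
    bad <- setdiff(unique(affects$valence), valence_classes)
    if (length(bad))
      stop_f("unknown valence class: %s", paste(bad, collapse = ", "))
    aff <- data.frame(label = as.character(affects$label),
                      valence = as.character(affects$valence),
                      stringsAsFactors = FALSE)
  } else {
    aff <- data.frame(label = as.character(affects),
                      valence = affect_valence(as.character(affects),
                                               negative_free_text),
                      stringsAsFactors = FALSE)
  }
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity) || intensity < 0 || intensity > 100)
    stop_f("intensity must be a single value in [0, 100], got %s",
           format(intensity))

  structure(list(polygon = polygon,
                 concern_types = as.character(concern_types),
                 affects = aff,
                 intensity = as.numeric(intensity)),
            class = "concern_entry")
}

#' Avatar slider settings
#'
#' @param sliders named numeric vector, names drawn from the 13 adjustable
#'   regions ([avatar_body_parts]), values in \[0, 1\] (0.5 is the scanned
#'   volunteer's baseline body).
#' @return an object of class `avatar_settings`.
#' @export
avatar_settings <- function(sliders) {
  sliders <- unlist(sliders)
  if (is.null(names(sliders)) || any(!nzchar(names(sliders))))
    stop_f("sliders must be a named vector")
  bad <- setdiff(names(sliders), avatar_body_parts)
  if (length(bad))
    stop_f("unknown avatar body part(s): %s", paste(bad, collapse = ", "))
  out <- vapply(sliders, as.numeric, numeric(1))
  oob <- names(out)[!is.finite(out) | out < 0 | out > 1]
  if (length(oob))
    stop_f("slider value out of [0, 1] for: %s", paste(oob, collapse = ", "))
  structure(list(sliders = out), class = "avatar_settings")
}

#' Tape-measured body sizes
#'
#' @param sizes_cm named numeric vector (cm) over a subset of the seven
#'   measured sites ([measured_body_parts]); all values must be positive.
#' @return an object of class `body_measurements`.
#' @export
body_measurements <- function(sizes_cm) {
  sizes_cm <- unlist(sizes_cm)
  if (is.null(names(sizes_cm)))
    stop_f("sizes_cm must be a named vector")
  bad <- setdiff(names(sizes_cm), measured_body_parts)
  if (length(bad))
    stop_f("unknown measured body part(s): %s", paste(bad, collapse = ", "))
  out <- vapply(sizes_cm, as.numeric, numeric(1))
  nonpos <- names(out)[!is.finite(out) | out <= 0]
  if (length(nonpos))
    stop_f("non-positive measurement for: %s", paste(nonpos, collapse = ", "))
  structure(list(sizes_cm = out), class = "body_measurements")
}

#' One study participant
#'
#' @param id subject identifier (non-empty string).
#' @param group group label (non-empty string), e.g. "model"/"nonmodel".
#' @param concerns list of [concern_entry()] objects (possibly empty).
#' @param avatar optional [avatar_settings()].
#' @param measured optional [body_measurements()].
#' @param demographics optional named list (age_years, height_cm, weight_kg,
#'   bmi, race_ethnicity, education). If bmi is present together with
#'   height and weight it must equal weight/(height/100)^2 within 0.1.
#' @param usability optional named list of the four usability items.
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(id, group, concerns = list(), avatar = NULL,
                           measured = NULL, demographics = list(),
                           usability = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_f("subject id must be a non-empty string")
  if (!is.character(group) || length(group) != 1L || !nzchar(group))
    stop_f("subject %s: group label must be a non-empty string", id)
  if (!is.list(concerns) ||
      !all(vapply(concerns, inherits, logical(1), "concern_entry")))
    stop_f("subject %s: concerns must be a list of concern_entry", id)
  if (!is.null(avatar) && !inherits(avatar, "avatar_settings"))
    stop_f("subject %s: avatar must be avatar_settings or NULL", id)
  if (!is.null(measured) && !inherits(measured, "body_measurements"))
    stop_f("subject %s: measured must be body_measurements or NULL", id)
  d <- demographics
  if (!is.null(d$bmi) && !is.null(d$height_cm) && !is.null(d$weight_kg)) {
    expect <- d$weight_kg / (d$height_cm / 100)^2
    if (abs(d$bmi - expect) > 0.1)
      stop_f("subject %s: bmi %.2f inconsistent with height/weight (%.2f)",
             id, d$bmi, expect)
  }
  structure(list(id = id, group = group, concerns = concerns,
                 avatar = avatar, measured = measured,
                 demographics = demographics, usability = usability),
            class = "subject_record")
}

#' Assemble a cohort
#'
#' The canonical container for one study: subjects plus the shared manikin
#' raster geometry and label vocabularies. All concern polygons must fit the
#' raster (`0 <= x <= width`, `0 <= y <= height`).
#'
#' @param subjects list of [subject_record()] objects (at least one).
#' @param raster_dims `c(width, height)` of the manikin raster in pixels.
#' @param vocabulary list with elements `concern_types` and `affects`
#'   (defaults to the package vocabularies).
#' @param meta optional free-form provenance list (e.g. generator config).
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, raster_dims = c(400L, 800L),
                   vocabulary = list(concern_types = concern_type_vocabulary,
                                     affects = names(affect_vocabulary)),
                   meta = NULL) {
  raster_dims <- check_dims(raster_dims)
  obj <- structure(list(subjects = subjects, raster_dims = raster_dims,
                        vocabulary = vocabulary, meta = meta),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort against the data-model invariants
#'
#' Checks every invariant of the data model and reports all violations at
#' once, each naming the offending subject and field.
#'
#' @param x a `cohort` object (or a bare list with the same fields).
#' @return invisibly `TRUE`; stops with an itemized message on violation.
#' @export
validate_cohort <- function(x) {
  problems <- character()
  add <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  if (!is.list(x$subjects) || length(x$subjects) < 1L)
    add("cohort: needs at least one subject")
  dims <- tryCatch(check_dims(x$raster_dims), error = function(e) {
    add("cohort: %s", conditionMessage(e)); NULL
  })
  for (s in x$subjects) {
    if (!inherits(s, "subject_record")) {
      add("cohort: subject entries must be subject_record objects")
      next
    }
    if (!nzchar(s$group)) add("subject %s: empty group label", s$id)
    for (k in seq_along(s$concerns)) {
      ce <- s$concerns[[k]]
      poly <- ce$polygon
      if (nrow(poly) < 3L)
        add("subject %s concern %d: degenerate polygon", s$id, k)
      if (!is.null(dims)) {
        oob <- poly[, 1] < 0 | poly[, 1] > dims[1] |
               poly[, 2] < 0 | poly[, 2] > dims[2]
        if (any(oob))
          add("subject %s concern %d: %d vertex(es) outside raster bounds",
              s$id, k, sum(oob))
      }
      if (ce$intensity < 0 || ce$intensity > 100)
        add("subject %s concern %d: intensity %s out of [0, 100]",
            s$id, k, format(ce$intensity))
      badval <- setdiff(unique(ce$affects$valence), valence_classes)
      if (length(badval))
        add("subject %s concern %d: invalid valence %s", s$id, k,
            paste(badval, collapse = ", "))
    }
    if (!is.null(s$avatar)) {
      v <- s$avatar$sliders
      if (any(v < 0 | v > 1))
        add("subject %s: slider out of [0, 1]", s$id)
    }
    if (!is.null(s$measured) && any(s$measured$sizes_cm <= 0))
      add("subject %s: non-positive body measurement", s$id)
  }
  if (length(problems))
    stop(paste(c("cohort validation failed:",
                 paste0("  - ", problems)), collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}

#' Group labels of a cohort
#' @param x a `cohort`.
#' @return character vector, one label per subject.
#' @export
cohort_groups <- function(x) {
  vapply(x$subjects, function(s) s$group, character(1))
}

#' @export
print.cohort <- function(x, ...) {
  g <- table(cohort_groups(x))
  nc <- sum(vapply(x$subjects, function(s) length(s$concerns), integer(1)))
  cat(sprintf("<cohort> %d subjects (%s); raster %dx%d px; %d concerns\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(g), g), collapse = ", "),
              x$raster_dims[1], x$raster_dims[2], nc))
  invisible(x)
}

# ---- JSON (de)serialization -------------------------------------------------

subject_to_list <- function(s) {
  out <- list(id = s$id, group = s$group)
  out$concerns <- lapply(s$concerns, function(ce) {
    list(polygon = unname(lapply(seq_len(nrow(ce$polygon)),
                                 function(i) as.numeric(ce$polygon[i, ]))),
         concern_types = as.list(ce$concern_types),
         affects = unname(Map(function(l, v) list(label = l, valence = v),
                              ce$affects$label, ce$affects$valence)),
         intensity = ce$intensity)
  })
  if (!is.null(s$avatar)) out$avatar <- as.list(s$avatar$sliders)
  if (!is.null(s$measured)) out$measured <- as.list(s$measured$sizes_cm)
  if (length(s$demographics)) out$demographics <- s$demographics
  if (!is.null(s$usability)) out$usability <- s$usability
  out
}

subject_from_list <- function(l) {
  concerns <- lapply(l$concerns, function(c) {
    aff <- if (length(c$affects)) {
      data.frame(label = vapply(c$affects, function(a) a$label, character(1)),
                 valence = vapply(c$affects, function(a) a$valence, character(1)),
                 stringsAsFactors = FALSE)
    } else character()
    concern_entry(polygon = c$polygon,
                  concern_types = unlist(c$concern_types) %||% character(),
                  affects = aff, intensity = c$intensity)
  })
  subject_record(
    id = l$id, group = l$group, concerns = concerns,
    avatar = if (!is.null(l$avatar)) avatar_settings(l$avatar),
    measured = if (!is.null(l$measured)) body_measurements(l$measured),
    demographics = if (!is.null(l$demographics))
      lapply(l$demographics, function(v) if (is.list(v)) unlist(v) else v)
      else list(),
    usability = if (!is.null(l$usability))
      lapply(l$usability, function(v) if (is.list(v)) unlist(v) else v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to a JSON file
#'
#' One cohort per file; numbers are written at full precision so that
#' `read_cohort(write_cohort(x))` is the identity on the data model.
#'
#' @param x a validated `cohort`.
#' @param path destination file path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  doc <- list(format = "bodymapr-cohort", version = 1L,
              raster_dims = as.integer(x$raster_dims),
              vocabulary = x$vocabulary,
              subjects = lapply(x$subjects, subject_to_list))
  if (!is.null(x$meta)) doc$meta <- x$meta
  txt <- tryCatch(
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     null = "null"),
    error = function(e) stop_f("cohort serialization failed: %s",
                               conditionMessage(e)))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_f("cannot write cohort file: %s", path)
  invisible(path)
}

#' Read a cohort from a JSON file
#'
#' @param path path to a file written by [write_cohort()] (or conforming to
#'   the same schema).
#' @return a validated `cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_f("cohort file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_f("cannot parse cohort JSON %s: %s", path,
                           conditionMessage(e)))
  if (is.null(doc$subjects) || is.null(doc$raster_dims))
    stop_f("%s: not a cohort file (missing 'subjects'/'raster_dims')", path)
  subjects <- lapply(doc$subjects, subject_from_list)
  cohort(subjects,
         raster_dims = unlist(doc$raster_dims),
         vocabulary = lapply(doc$vocabulary, unlist) %||%
           list(concern_types = concern_type_vocabulary,
                affects = names(affect_vocabulary)),
         meta = doc$meta)
}
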