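#' Controlled vocabularies for the 2-D concern assessment
#'
#' The affect vocabulary carries a fixed two-way valence grouping
#' (negative vs neutral/positive); free-text affects are "unclassified"
#' unless explicitly flagged negative, and unclassified labels are
#' excluded from valence tallies.
#'
#' @format `affect_vocabulary` is a named character vector mapping affect
#'   label to valence class; `concern_type_vocabulary` is a character vector
#'   of concern-type labels; `avatar_body_parts` the 13 independently
#'   adjustable avatar regions; `measured_body_parts` the seven
#'   tape-measured sites.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
affect_vocabulary <- c(
  "frustrated"                    = "negative",
  "anxious/tense/worried/nervous" = "negative",
  "ashamed"                       = "negative",
  "hopeless"                      = "negative",
  "sad"                           = "negative",
  "disgusted"                     = "negative",
  "defective"                     = "negative",
  "depressed"                     = "negative",
  "fearful"                       = "negative",
  "angry"                         = "negative",
  "overwhelmed"                   = "negative",
  "lonely"                        = "negative",
  "numb/unreal/dead"              = "negative",
  "embarrassed"                   = "negative",
  "other"                         = "negative",
  "looks ok/fine"                 = "neutral_positive",
  "hopeful"                       = "neutral_positive",
  "satisfied/content"             = "neutral_positive"
)

#' @rdname vocabularies
#' @export
concern_type_vocabulary <- c(
  "acne", "bloated", "bulgy", "too large", "too thin", "too fat",
  "protrudes", "too round", "too much cellulite", "too much muscularity",
  "flawed", "other"
)

#' @rdname vocabularies
#' @export
avatar_body_parts <- c(
  "neck", "shoulders", "torso", "bust", "bicep", "forearm", "hands",
  "hips", "waist", "buttocks", "thighs", "calves", "feet"
)

#' @rdname vocabularies
#' @export
measured_body_parts <- c(
  "shoulders", "bust", "biceps", "waist", "hips", "thighs", "calves"
)

# tape-measure site -> avatar slider region (one-to-one for the 7 sites)
measured_to_slider <- c(
  shoulders = "shoulders", bust = "bust", biceps = "bicep",
  waist = "waist", hips = "hips", thighs = "thighs", calves = "calves"
)

valence_classes <- c("negative", "neutral_positive", "unclassified")

#' Resolve affect labels to valence classes
#'
#' Known labels take their fixed class from [affect_vocabulary]; unknown
#' (free-text) labels are "unclassified" unless listed in
#' `negative_free_text`.
#'
#' @param labels character vector of affect labels.
#' @param negative_free_text free-text labels explicitly flagged negative.
#' @return character vector of valence classes, same length as `labels`.
#' @export
affect_valence <- function(labels, negative_free_text = character()) {
  out <- unname(affect_vocabulary[labels])
  out[is.na(out)] <- "unclassified"
  out[labels %in% negative_free_text] <- "negative"
  out
}
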