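#' Rasterize a concern outline to a binary mask
#'
#' Fills the polygon interior on the manikin raster using the even-odd rule
#' applied to pixel centers: pixel (i, j) (0-based column i, row j) is set
#' iff its center (i + 0.5, j + 0.5) lies inside the closed polygon.
#' Centers falling exactly on the outline are included. Implemented as a
#' scanline sweep, so orientation and self-intersection (bow-tie) polygons
#' behave exactly as the even-odd rule dictates.
#'
#' @param polygon two-column (x, y) vertex matrix, implicitly closed;
#'   at least 3 vertices, all within the raster bounds.
#' @param dims `c(width, height)` of the raster.
#' @return an integer H x W matrix of 0/1 (class `concern_mask`), rows = y.
#' @export
rasterize_outline <- function(polygon, dims) {
  dims <- check_dims(dims)
  if (is.list(polygon) && !is.data.frame(polygon))
    polygon <- do.call(rbind, lapply(polygon, as.numeric))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop_f("degenerate polygon: %d vertices (need >= 3)", nrow(polygon))
  W <- dims[1]; H <- dims[2]
  px <- polygon[, 1]; py <- polygon[, 2]
  if (any(px < 0 | px > W | py < 0 | py > H))
    stop_f("polygon vertex outside raster bounds %dx%d", W, H)

  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])  # edge endpoints
  mask <- matrix(0L, nrow = H, ncol = W)
  ymin <- max(0L, floor(min(py))); ymax <- min(H - 1L, ceiling(max(py)))
  for (j in (if (ymin <= ymax) ymin:ymax else integer())) {
    yc <- j + 0.5
    # half-open edge rule: edge contributes iff yc in [min(y), max(y))
    hit <- (py <= yc & yc < ny) | (ny <= yc & yc < py)
    if (!any(hit)) next
    t <- (yc - py[hit]) / (ny[hit] - py[hit])
    xs <- sort(px[hit] + t * (nx[hit] - px[hit]))
    # even-odd: pair crossings; centers in [xs[2k-1], xs[2k]] are inside
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- ceiling(xs[k] - 0.5); hi <- floor(xs[k + 1L] - 0.5)
      lo <- max(lo, 0L); hi <- min(hi, W - 1L)
      if (lo <= hi) mask[j + 1L, (lo:hi) + 1L] <- 1L
    }
  }
  structure(mask, class = c("concern_mask", class(mask)))
}

#' Union of a subject's concern masks
#'
#' Collapses all of one subject's concern outlines into a single binary
#' mask by pixel-wise logical OR, so a subject contributes at most 1 to any
#' pixel of the group proportion map no matter how many overlapping
#' concerns they drew. An empty entry list yields the all-zero mask.
#'
#' @param entries list of [concern_entry()] objects (or bare polygon
#'   matrices); may be empty.
#' @param dims `c(width, height)` of the raster.
#' @return an integer H x W 0/1 matrix (class `concern_mask`).
#' @export
subject_concern_mask <- function(entries, dims) {
  dims <- check_dims(dims)
  acc <- matrix(0L, nrow = dims[2], ncol = dims[1])
  for (e in entries) {
    poly <- if (inherits(e, "concern_entry")) e$polygon else e
    m <- rasterize_outline(poly, dims)
    if (!identical(dim(m), dim(acc)))
      stop_f("mask dimension mismatch")
    acc <- acc | m
  }
  m <- matrix(as.integer(acc), nrow = dims[2], ncol = dims[1])
  structure(m, class = c("concern_mask", class(m)))
}

#' Per-subject concern masks for a whole cohort
#'
#' @param x a `cohort`.
#' @return named list of H x W 0/1 matrices, one per subject.
#' @export
cohort_masks <- function(x) {
  validate_cohort(x)
  out <- lapply(x$subjects, function(s)
    subject_concern_mask(s$concerns, x$raster_dims))
  names(out) <- vapply(x$subjects, function(s) s$id, character(1))
  out
}

#' Export a binary mask as plain-text PGM (P2)
#'
#' Portable grayscale text format (0 = background, 255 = concern); readable
#' by any image tool and by [read_mask_pgm()].
#'
#' @param mask H x W 0/1 matrix.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_mask_pgm <- function(mask, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "255"), con)
  apply(mask, 1L, function(r)
    writeLines(paste(ifelse(r > 0, 255L, 0L), collapse = " "), con))
  invisible(path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop_f("%s: not a plain PGM (P2) file", path)
  w <- as.integer(txt[2]); h <- as.integer(txt[3])
  vals <- as.integer(txt[-(1:4)])
  m <- matrix(as.integer(vals > 127L), nrow = h, ncol = w, byrow = TRUE)
  structure(m, class = c("concern_mask", class(m)))
}
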