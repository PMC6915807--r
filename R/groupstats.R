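#' Welch two-sample t test from summary statistics
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' degrees of freedom (the default; set `pooled = TRUE` for the classical
#' equal-variance test with df = n1 + n2 - 2).
#'
#' @param mean1,sd1,n1 first group: mean, SD, size (n >= 2).
#' @param mean2,sd2,n2 second group.
#' @param pooled use the pooled-variance (Student) form.
#' @return list with `statistic`, `df`, `p.value` (two-sided).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop_f("both group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop_f("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stop_f("t undefined: zero variance in both groups with equal means")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' Sigma (O - E)^2 / E with expected counts from the row/column margins
#' and df = (r - 1)(c - 1); no continuity correction (matching the usual
#' reporting for r x c demographic tables).
#'
#' @param table r x c matrix of non-negative integer counts.
#' @return list with `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != floor(m)))
    stop_f("counts must be non-negative integers")
  if (sum(m) <= 0) stop_f("empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_f("all-zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Per-group frequency tally of concern annotations
#'
#' Counts, for each label, the number of subjects in each group endorsing
#' it (a subject counts once per label no matter how many concerns repeat
#' it), with percentages of the group size rounded half-up to 1 decimal.
#'
#' @param subjects list of [subject_record()] objects, or a `cohort`.
#' @param field `"affects"` or `"concern_types"`.
#' @return data.frame: `label`, then per group `<group>_n` and
#'   `<group>_pct` columns; group sizes in attribute "group_n".
#' @export
tally <- function(subjects, field = c("affects", "concern_types")) {
  field <- match.arg(field)
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  groups <- vapply(subjects, function(s) s$group, character(1))
  glev <- sort(unique(groups))
  per_subject <- lapply(subjects, function(s) {
    labs <- unlist(lapply(s$concerns, function(ce)
      if (field == "affects") ce$affects$label else ce$concern_types))
    unique(labs)
  })
  labels <- sort(unique(unlist(per_subject)))
  out <- data.frame(label = labels, stringsAsFactors = FALSE)
  for (g in glev) {
    n_g <- sum(groups == g)
    cnt <- vapply(labels, function(l)
      sum(vapply(per_subject[groups == g], function(x) l %in% x,
                 logical(1))), integer(1))
    out[[paste0(g, "_n")]] <- unname(cnt)
    out[[paste0(g, "_pct")]] <- round_half_up(100 * cnt / n_g, 1)
  }
  attr(out, "group_n") <- stats::setNames(
    vapply(glev, function(g) sum(groups == g), integer(1)), glev)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_f("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' One-way MANCOVA via Wilks' lambda, with post hoc ANCOVA
#'
#' Tests a two-level group effect on multivariate responses after
#' adjusting for covariates (group fitted after covariates, i.e. the
#' hypothesis cross-product H compares the full model \[1, covariates,
#' group\] against the reduced \[1, covariates\]). Wilks' lambda =
#' det(E)/det(E + H); F by Rao's approximation. Post hoc per-response
#' ANCOVA F tests (same adjustment) with partial eta^2, Cohen f, and
#' Benjamini-Hochberg-adjusted p-values are returned when requested.
#'
#' @param responses n x p numeric matrix (or data.frame) of outcomes.
#' @param group length-n factor (or vector) with exactly 2 levels.
#' @param covariates optional n x q numeric matrix/data.frame.
#' @param posthoc also run per-response ANCOVA.
#' @return list with `lambda`, `F`, `df` = c(df1, df2), `p.value`, `E`,
#'   `H`, and (if requested) `posthoc` data.frame.
#' @export
mancova_wilks <- function(responses, group, covariates = NULL,
                          posthoc = TRUE) {
  Y <- as.matrix(responses); storage.mode(Y) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  g <- factor(group)
  if (nlevels(g) != 2L) stop_f("group must have exactly 2 levels")
  if (length(g) != n) stop_f("group length != number of rows")
  Xr <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates); storage.mode(C) <- "double"
    if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
    # constant covariates carry no information; drop them (lambda unchanged)
    keep <- apply(C, 2, function(x) stats::sd(x) > 0)
    Xr <- cbind(Xr, C[, keep, drop = FALSE])
  }
  Xf <- cbind(Xr, group = as.numeric(g == levels(g)[2]))
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf)) {
    drop <- colnames(Xf)[qrf$pivot[(qrf$rank + 1):ncol(Xf)]]
    stop_f("rank-deficient design; collinear column(s): %s",
           paste(drop, collapse = ", "))
  }
  if (n <= ncol(Xf) + p)
    stop_f("too few subjects (n = %d) for p = %d responses and %d design columns",
           n, p, ncol(Xf))
  resid_of <- function(X) {
    Q <- qr.Q(qr(X))
    Y - Q %*% (t(Q) %*% Y)
  }
  Rf <- resid_of(Xf); Rr <- resid_of(Xr)
  E <- crossprod(Rf)
  H <- crossprod(Rr) - E
  lambda <- det(E) / det(E + H)
  df_e <- n - ncol(Xf)      # error df of the full model
  q_h <- 1                  # group has 1 df
  # Rao's F approximation (exact for q_h = 1)
  tt <- if (p^2 + q_h^2 - 5 > 0) sqrt((p^2 * q_h^2 - 4) / (p^2 + q_h^2 - 5)) else 1
  w <- df_e + q_h - (p + q_h + 1) / 2
  df1 <- p * q_h
  df2 <- w * tt - (p * q_h - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  out <- list(lambda = lambda, F = Fstat, df = c(df1 = df1, df2 = df2),
              p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
              E = E, H = H, n = n, groups = levels(g))
  if (posthoc) {
    ph <- lapply(seq_len(p), function(j) {
      rss_f <- sum(Rf[, j]^2); rss_r <- sum(Rr[, j]^2)
      Fj <- ((rss_r - rss_f) / q_h) / (rss_f / df_e)
      eta2 <- (rss_r - rss_f) / rss_r
      data.frame(response = colnames(Y)[j] %||% paste0("y", j),
                 F = Fj, df1 = q_h, df2 = df_e,
                 p.value = stats::pf(Fj, q_h, df_e, lower.tail = FALSE),
                 partial_eta2 = eta2,
                 cohen_f = sqrt(eta2 / (1 - eta2)))
    })
    ph <- do.call(rbind, ph)
    ph$p.adjusted <- bh_adjust(ph$p.value)
    out$posthoc <- ph
  }
  out
}

#' Group-wise summary statistics (mean, SD, n) for one variable
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame with group, mean, sd, n.
#' @export
group_summary <- function(values, groups) {
  g <- factor(groups)
  do.call(rbind, lapply(levels(g), function(l) {
    v <- values[g == l & !is.na(values)]
    data.frame(group = l, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
}
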