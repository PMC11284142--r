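# Reliability and comparison statistics: normality-gated summaries and
# paired tests, Pearson correlation with Fisher-z intervals, and two-way
# ANOVA intraclass correlation coefficients with reliability banding.

# Evaluate expr with a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normality-gated summary of one angle method
#'
#' The full row (n, missing, mean, median, sd, range) is always computed; a
#' display rule additionally marks which presentation is appropriate --
#' mean +/- SD when a Shapiro-Wilk test at alpha = 0.05 does not reject
#' normality, median with total range otherwise.
#'
#' @param values Numeric angle values in degrees (NAs counted as missing).
#' @param label Method label for the row.
#' @param alpha Normality significance level (default 0.05).
#' @return A one-row data frame with columns `method`, `n`, `missing`,
#'   `mean`, `median`, `sd`, `min`, `max`, `shapiro_p`, `display`
#'   (`"mean_sd"`, `"median_range"` or `"degenerate"` for constant input).
#' @export
summarize_angles <- function(values, label = "angle", alpha = 0.05) {
  miss <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) < 3L) {
    stop(sprintf("summary of '%s' needs >= 3 finite values, got %d",
                 label, length(v)), call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    sw <- NA_real_
    display <- "degenerate"
  } else {
    sw <- stats::shapiro.test(v)$p.value
    display <- if (sw >= alpha) "mean_sd" else "median_range"
  }
  data.frame(
    method = label, n = length(v), missing = miss,
    mean = mean(v), median = stats::median(v), sd = stats::sd(v),
    min = min(v), max = max(v), shapiro_p = sw, display = display,
    stringsAsFactors = FALSE
  )
}

#' Summary table over the four angle methods
#'
#' @param records A torsion-record data frame (columns `ptta`, `pmtpa`,
#'   `ima`, `ta`; e.g. `measure_cohort(...)$records`).
#' @param alpha Normality significance level passed to [summarize_angles()].
#' @return A four-row data frame (PTTA, PMTPA, IMA, TA), one
#'   [summarize_angles()] row per method.
#' @export
angle_summary_table <- function(records, alpha = 0.05) {
  cols <- c(PTTA = "ptta", PMTPA = "pmtpa", IMA = "ima", TA = "ta")
  missing_cols <- setdiff(unname(cols), names(records))
  if (length(missing_cols)) {
    stop(sprintf("records are missing method column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(cols), function(m) {
    summarize_angles(records[[cols[[m]]]], label = m, alpha = alpha)
  }))
  rownames(out) <- NULL
  out
}

#' Paired comparison of two matched angle series
#'
#' Tests the null of zero paired difference. By default the branch follows
#' the normality of the differences (Shapiro-Wilk at alpha = 0.05): paired
#' Student t when normality is not rejected, Wilcoxon signed-rank (zero
#' differences dropped, normal approximation) otherwise. The branch can be
#' forced with `test`.
#'
#' @param a,b Matched numeric vectors (same tibias, same order), length >= 3.
#' @param test `"auto"` (normality-gated), `"t"` or `"wilcoxon"`.
#' @param alpha Normality significance level for the gate.
#' @return A list of class `"paired_comparison"`: `test_name`
#'   (`"paired-t"`, `"wilcoxon-signed-rank"` or `"degenerate"`),
#'   `statistic`, `p_value`, `mean_difference` (a - b, degrees),
#'   `normality_p`, `n`.
#' @export
paired_compare <- function(a, b, test = c("auto", "t", "wilcoxon"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (length(a) != length(b)) stop("paired series must have equal length", call. = FALSE)
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("paired comparison needs >= 3 complete pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = NA_real_, mean_difference = 0,
                          normality_p = NA_real_, n = length(d)),
                     class = "paired_comparison"))
  }
  norm_p <- if (stats::sd(d) == 0) NA_real_ else stats::shapiro.test(d)$p.value
  branch <- switch(test,
    auto = if (!is.na(norm_p) && norm_p >= alpha) "t" else "wilcoxon",
    test)
  if (branch == "t") {
    ht <- stats::t.test(a, b, paired = TRUE)
    name <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    name <- "wilcoxon-signed-rank"
  }
  structure(list(test_name = name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, mean_difference = mean(d),
                 normality_p = norm_p, n = length(d)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s: mean difference %.3f deg, statistic %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$mean_difference, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' @param r Sample Pearson correlation.
#' @param n Sample size (>= 4).
#' @param conf Confidence level (default 0.95).
#' @return Length-2 numeric, lower and upper bound.
#' @examples
#' fisher_z_ci(0.95, 200)
#' @export
fisher_z_ci <- function(r, n, conf = 0.95) {
  stopifnot(n >= 4, abs(r) < 1)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pearson correlation with Fisher-z interval
#'
#' @param a,b Numeric vectors of equal length (n >= 4), e.g. two angle
#'   methods over a cohort.
#' @param conf Confidence level.
#' @return A list of class `"correlation_result"`: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
pearson_with_ci <- function(a, b, conf = 0.95) {
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4L) stop("correlation needs >= 4 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(a, b, method = "pearson", conf.level = conf)
  ci <- fisher_z_ci(unname(ht$estimate), n, conf)
  structure(list(r = unname(ht$estimate), ci_low = ci[1L], ci_high = ci[2L],
                 p_value = ht$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f [95%% CI %.4f, %.4f], p = %.4g (n = %d)\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Reliability band for an ICC estimate
#'
#' Cut-points: poor below 0.5, moderate from 0.5 to 0.75, good above 0.75
#' up to 0.9, excellent above 0.9.
#'
#' @param estimate ICC estimate(s).
#' @return Character vector of bands.
#' @export
icc_band <- function(estimate) {
  vapply(estimate, function(e) {
    if (is.na(e)) NA_character_
    else if (e < 0.5) "poor"
    else if (e <= 0.75) "moderate"
    else if (e <= 0.9) "good"
    else "excellent"
  }, character(1))
}

#' Single-measure intraclass correlation coefficient
#'
#' Computes the ICC from the two-way ANOVA mean squares of a complete
#' subjects x raters (or sessions) matrix. The default model is two-way
#' random effects with absolute agreement, ICC(A,1) -- the conservative
#' choice for method-feasibility claims because systematic rater offsets
#' count against agreement; the two-way mixed, consistency form ICC(C,1)
#' is also available. Confidence bounds use the standard F-distribution
#' construction (Satterthwaite degrees of freedom for the agreement form).
#'
#' @param ratings Numeric matrix, one row per subject (tibia), one column
#'   per rater or session; >= 5 rows, >= 2 columns, no missing cells.
#' @param model `"two-way-random-absolute"` (default) or
#'   `"two-way-mixed-consistency"`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `"icc_result"`: `estimate`, `ci_low`, `ci_high`,
#'   `model`, `band`, `n`, `k`.
#' @export
icc <- function(ratings,
                model = c("two-way-random-absolute", "two-way-mixed-consistency"),
                conf = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  if (!is.numeric(m)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(m)) stop("ratings contain missing cells; complete-case handling is the caller's job", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 5L || k < 2L) {
    stop(sprintf("ICC needs >= 5 subjects and >= 2 raters/sessions, got %d x %d", n, k),
         call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - conf

  if (model == "two-way-mixed-consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      est <- if (msr > 0) 1 else NA_real_
      ci <- c(est, est)
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    est <- if (denom > 0) (msr - mse) / denom else NA_real_
    if (mse <= 0 && msc <= 0) {
      est <- if (msr > 0) 1 else NA_real_
      ci <- c(est, est)
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      ci <- c(
        n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
        n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
      )
      if (!all(is.finite(ci))) ci <- c(est, est)
    }
  }
  ci <- pmin(pmax(ci, -1), 1)
  ci <- c(min(ci[1L], est), max(ci[2L], est))
  structure(list(estimate = est, ci_low = ci[1L], ci_high = ci[2L],
                 model = model, band = icc_band(est), n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f [95%% CI %.4f, %.4f], %s (%s; %d x %d)\n",
              x$estimate, x$ci_low, x$ci_high, x$band, x$model, x$n, x$k))
  invisible(x)
}

#' Intra- or inter-observer reliability study on a simulated cohort
#'
#' Mirrors the two-rater feasibility design: the intra-observer arm uses one
#' rater's two sessions on a subset of images (default 22), the
#' inter-observer arm uses two raters' first sessions on a larger subset
#' (default 44). The image subset is drawn deterministically from `seed`,
#' images are taken to be tibias, and both counts are exposed as
#' parameters. ICCs are reported per angle method.
#'
#' @param cohort A `"cohort_truth"` with the required raters/sessions.
#' @param design `"intra"` or `"inter"`.
#' @param n_images Number of tibias in the subset (default 22 intra,
#'   44 inter).
#' @param rater Rater used for the intra design (default 1).
#' @param model ICC model, see [icc()].
#' @param seed Seed for the deterministic subset draw.
#' @return A list of class `"reliability_study"`: one `"icc_result"` per
#'   method (`PTTA`, `PMTPA`, `IMA`, `TA`) plus `design` and `tibias`.
#' @export
reliability_study <- function(cohort, design = c("intra", "inter"),
                              n_images = NULL, rater = 1L,
                              model = "two-way-random-absolute", seed = 1L) {
  stopifnot(inherits(cohort, "cohort_truth"))
  design <- match.arg(design)
  if (design == "intra" && cohort$spec$sessions < 2L) {
    stop("intra-observer design needs >= 2 sessions in the cohort", call. = FALSE)
  }
  if (design == "inter" && cohort$spec$raters < 2L) {
    stop("inter-observer design needs >= 2 raters in the cohort", call. = FALSE)
  }
  if (is.null(n_images)) n_images <- if (design == "intra") 22L else 44L
  all_tibias <- paste(cohort$truth$subject_id, cohort$truth$side, sep = "/")
  if (n_images > length(all_tibias)) {
    stop(sprintf("subset of %d tibias requested but cohort has only %d",
                 n_images, length(all_tibias)), call. = FALSE)
  }
  tibias <- with_seed(seed, sort(sample(all_tibias, n_images)))

  reps <- if (design == "intra") {
    list(cohort_replicate(cohort, rater, 1L, tibias),
         cohort_replicate(cohort, rater, 2L, tibias))
  } else {
    list(cohort_replicate(cohort, 1L, 1L, tibias),
         cohort_replicate(cohort, 2L, 1L, tibias))
  }
  recs <- lapply(reps, function(sets) measure_cohort(sets)$records)
  for (rc in recs) {
    if (nrow(rc) != n_images) {
      stop("reliability subset could not be fully measured", call. = FALSE)
    }
  }
  methods <- c(PTTA = "ptta", PMTPA = "pmtpa", IMA = "ima", TA = "ta")
  out <- lapply(methods, function(col) {
    icc(cbind(recs[[1L]][[col]], recs[[2L]][[col]]), model = model)
  })
  out$design <- design
  out$tibias <- tibias
  class(out) <- "reliability_study"
  out
}

#' Reliability ICCs from a long torsion-record table
#'
#' Same designs as [reliability_study()], but computed from already-measured
#' torsion records (e.g. a records CSV carrying `rater` and `session`
#' columns) instead of a simulated cohort.
#'
#' @param records Torsion-record data frame with `subject_id`, `side`,
#'   `rater`, `session` and the four method columns.
#' @param design `"intra"` or `"inter"`.
#' @param n_images Tibias to subsample (default 22 intra / 44 inter; capped
#'   at the number available only by erroring, never silently).
#' @param rater Rater used for the intra design.
#' @param model ICC model, see [icc()].
#' @param seed Seed for the deterministic subset draw.
#' @return A `"reliability_study"` list, one `"icc_result"` per method.
#' @export
reliability_from_records <- function(records, design = c("intra", "inter"),
                                     n_images = NULL, rater = 1L,
                                     model = "two-way-random-absolute",
                                     seed = 1L) {
  design <- match.arg(design)
  need <- c("subject_id", "side", "rater", "session", "ptta", "pmtpa", "ima", "ta")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records are missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(n_images)) n_images <- if (design == "intra") 22L else 44L
  pick <- function(r, s) {
    sub <- records[records$rater == r & records$session == s, , drop = FALSE]
    sub[order(sub$subject_id, sub$side), , drop = FALSE]
  }
  reps <- if (design == "intra") list(pick(rater, 1L), pick(rater, 2L))
          else list(pick(1L, 1L), pick(2L, 1L))
  key <- function(df) paste(df$subject_id, df$side, sep = "/")
  common <- intersect(key(reps[[1L]]), key(reps[[2L]]))
  if (length(common) < n_images) {
    stop(sprintf("%s-observer design needs %d tibias present in both replicates, found %d",
                 design, n_images, length(common)), call. = FALSE)
  }
  tibias <- with_seed(seed, sort(sample(common, n_images)))
  reps <- lapply(reps, function(df) df[match(tibias, key(df)), , drop = FALSE])
  methods <- c(PTTA = "ptta", PMTPA = "pmtpa", IMA = "ima", TA = "ta")
  out <- lapply(methods, function(col) {
    icc(cbind(reps[[1L]][[col]], reps[[2L]][[col]]), model = model)
  })
  out$design <- design
  out$tibias <- tibias
  class(out) <- "reliability_study"
  out
}

#' @export
print.reliability_study <- function(x, ...) {
  cat(sprintf("<reliability_study> %s-observer, %d tibias\n",
              x$design, length(x$tibias)))
  for (m in c("PTTA", "PMTPA", "IMA", "TA")) {
    cat(sprintf("  %-5s ", m)); print(x[[m]])
  }
  invisible(x)
}
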