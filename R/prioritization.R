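#' Prioritization filter configuration
#'
#' Thresholds of the four-filter cascade. Defaults are the study settings:
#' minimum read depth 30, minimum distance to the nearest annotated feature
#' 5,000 bp, minimum 3 exons, and a Grubbs outlier test on the 8-tissue
#' expression profile at significance 0.05 (critical value 2.13 at n = 8).
#' All thresholds are inclusive (depth 30 passes, distance 5,000 passes,
#' 3 exons pass); the outlier test itself is a strict inequality on the
#' critical value.
#'
#' @param min_depth Minimum per-model read coverage (reads).
#' @param min_distance Minimum distance to the nearest annotated feature (bp).
#' @param min_exons Minimum exon count.
#' @param alpha Significance level of the tissue-restriction test.
#' @param n_tissues Expected number of tissues in the expression matrix.
#' @param log_expression Test tissue profiles on the `log1p` scale (default).
#'   The studentized-deviate calibration assumes approximately normal values;
#'   normalized expression is right-skewed on the raw scale, so the raw-scale
#'   test is badly oversized. See [tissue_restriction_filter()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 30, min_distance = 5000, min_exons = 3,
                          alpha = 0.05, n_tissues = 8, log_expression = TRUE) {
  stopifnot(min_depth > 0, min_distance > 0, min_exons >= 1,
            alpha > 0, alpha < 1, n_tissues >= 3,
            is.logical(log_expression))
  structure(list(min_depth = min_depth, min_distance = min_distance,
                 min_exons = min_exons, alpha = alpha, n_tissues = n_tissues,
                 log_expression = log_expression),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(paste0("<filter_config: depth >= %s reads, distance >= %s bp, ",
                     ">= %s exons, Grubbs alpha = %s (n = %s tissues)>\n"),
              x$min_depth, x$min_distance, x$min_exons, x$alpha, x$n_tissues))
  invisible(x)
}

#' Depth filter
#'
#' Keeps transcript models with read-coverage depth at or above the threshold.
#' @param models List of [transcript_model()] objects.
#' @param min_depth Minimum depth in reads (inclusive).
#' @return The surviving subset of `models`.
#' @export
depth_filter <- function(models, min_depth = 30) {
  stopifnot(min_depth > 0)
  keep <- vapply(models, function(m) m$depth >= min_depth, logical(1))
  models[keep]
}

#' Distance filter
#'
#' Keeps models at or beyond `min_distance` bases from the nearest annotated
#' feature; models on chromosomes with no annotation are infinitely distant
#' and always pass.
#' @param models List of [transcript_model()] objects.
#' @param ann An [annotation_set()].
#' @param min_distance Minimum distance in bp (inclusive).
#' @return The surviving subset of `models`.
#' @export
distance_filter <- function(models, ann, min_distance = 5000) {
  stopifnot(min_distance > 0)
  if (!length(models)) return(models)
  d <- nearest_feature_distance(models, ann)
  models[d >= min_distance]
}

#' Exon-count filter
#'
#' Keeps models with at least `min_exons` exons.
#' @param models List of [transcript_model()] objects.
#' @param min_exons Minimum exon count (inclusive).
#' @return The surviving subset of `models`.
#' @export
exon_filter <- function(models, min_exons = 3) {
  stopifnot(min_exons >= 1)
  keep <- vapply(models, function(m) n_exons(m) >= min_exons, logical(1))
  models[keep]
}

#' Extreme studentized deviate of an expression profile
#'
#' Standardizes each value against the profile mean and the sample standard
#' deviation (n - 1 denominator) and reports the extreme deviate. `max_z` is
#' the largest *signed* (upward) deviate — the statistic used to flag
#' tissue-restricted over-expression — while `max_abs_z` is the classical
#' two-sided Grubbs statistic max |Z|. Profiles with zero variance are not
#' testable and return `NA` statistics.
#'
#' @param values Numeric vector of per-tissue normalized expression values
#'   (length >= 3).
#' @return List with `max_z`, `max_abs_z` and `tissue` (index of the most
#'   upward-deviant value).
#' @examples
#' grubbs_statistic(c(0, 0, 0, 0, 0, 0, 0, 8))  # max_z = 7/sqrt(8) = 2.475
#' @export
grubbs_statistic <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("Grubbs statistic needs at least 3 values")
  if (anyNA(values)) stop("missing expression values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    return(list(max_z = NA_real_, max_abs_z = NA_real_, tissue = NA_integer_))
  z <- (values - mean(values)) / s
  i <- which.max(z)
  list(max_z = z[i], max_abs_z = max(abs(z)), tissue = i)
}

#' Grubbs/ESD critical value
#'
#' Two-sided single-outlier critical value
#' \deqn{G = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n-2+t^2}}}
#' where `t` is the upper `alpha/(2n)` quantile of the t distribution with
#' `n - 2` degrees of freedom. At `n = 8`, `alpha = 0.05` this is 2.13 (2 dp),
#' the threshold applied to the 8-tissue profiles. A one-sided variant
#' (`alpha/n` in the quantile) is available for reference.
#'
#' @param n Sample size (number of tissues), at least 3.
#' @param alpha Significance level in (0, 1).
#' @param type `"two.sided"` (default) or `"one.sided"`.
#' @return Critical value of the studentized extreme deviate.
#' @export
grubbs_critical <- function(n, alpha = 0.05, type = c("two.sided", "one.sided")) {
  type <- match.arg(type)
  if (n < 3) stop("Grubbs critical value requires n >= 3")
  stopifnot(alpha > 0, alpha < 1)
  p <- if (type == "two.sided") alpha / (2 * n) else alpha / n
  t <- stats::qt(1 - p, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Tissue-restriction filter
#'
#' Flags transcripts whose expression is concentrated in a single tissue:
#' the extreme studentized deviate of the profile exceeds the Grubbs critical
#' value at level `alpha`. By default only *upward* deviation counts (a
#' transcript "restricted by absence" in one tissue is not flagged), applied
#' at the two-sided critical value as in the source protocol; set
#' `direction = "two.sided"` to flag deviation in either direction, which is
#' the calibration under which the test has size `alpha`. Profiles with zero
#' variance are not testable and are excluded with a reason.
#'
#' @param expr Numeric matrix of normalized expression (transcripts x tissues,
#'   rownames = transcript ids), or a single numeric profile. Values must be
#'   non-negative.
#' @param alpha Significance level.
#' @param direction `"positive"` (default) or `"two.sided"`.
#' @param log_expression Apply the test to `log1p(values)` (default). The
#'   critical value calibrates a test that assumes roughly normal values;
#'   normalized expression is strongly right-skewed on the raw scale, where
#'   the test flags far more than `alpha` of null profiles. The log scale
#'   restores the calibration; the pseudocount of 1 accommodates zeros. The
#'   statistic of an idealized one-high-tissue profile is the same on either
#'   scale (the deviate is scale-invariant for a 7-equal-plus-1 pattern).
#' @return Data frame with one row per transcript: `transcript_id`, `max_z`,
#'   `tissue` (index of the flagged tissue), `tissue_name` (if the matrix has
#'   column names), `critical`, `restricted`, `reason` (`""`, or why the row
#'   was excluded).
#' @export
tissue_restriction_filter <- function(expr, alpha = 0.05,
                                      direction = c("positive", "two.sided"),
                                      log_expression = TRUE) {
  direction <- match.arg(direction)
  if (is.vector(expr)) expr <- matrix(expr, nrow = 1,
                                      dimnames = list("profile", NULL))
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  if (log_expression) {
    if (any(expr < 0, na.rm = TRUE))
      stop("negative expression values cannot be log-transformed")
    expr <- log1p(expr)
  }
  crit <- grubbs_critical(ncol(expr), alpha)
  out <- data.frame(transcript_id = rownames(expr),
                    max_z = NA_real_, tissue = NA_integer_,
                    tissue_name = NA_character_,
                    critical = crit, restricted = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    g <- grubbs_statistic(expr[i, ])
    if (is.na(g$max_z)) {
      out$reason[i] <- "zero variance: not testable"
      next
    }
    stat <- if (direction == "positive") g$max_z else g$max_abs_z
    out$max_z[i] <- stat
    out$tissue[i] <- g$tissue
    if (!is.null(colnames(expr))) out$tissue_name[i] <- colnames(expr)[g$tissue]
    out$restricted[i] <- stat > crit
  }
  out
}

#' Run the four-filter prioritization cascade
#'
#' Applies, in order, the depth, distance, exon-count and tissue-restriction
#' filters to a set of unannotated transcript models, recording per-stage
#' survivor counts and id sets. The four filters are independent per-transcript
#' predicates, so the final set does not depend on their order; the
#' conventional order is depth, distance, exons, tissue restriction.
#' Models with no row in the expression matrix cannot be tested and are
#' excluded at the final stage (with a logged reason).
#'
#' @param models List of [transcript_model()] objects.
#' @param ann An [annotation_set()].
#' @param expr Expression matrix (see [tissue_restriction_filter()]).
#' @param config A [filter_config()].
#' @return An object of class `cascade_report`: list with `stage_names`,
#'   `counts_after_stage`, `surviving_ids` (list of id vectors, one per stage,
#'   nested), `tissue_flags` (the tissue-restriction table for stage-3
#'   survivors) and `dropped` (id + reason for untestable/missing rows).
#' @export
run_cascade <- function(models, ann, expr, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  ids0 <- vapply(models, `[[`, character(1), "id")
  s1 <- depth_filter(models, config$min_depth)
  s2 <- distance_filter(s1, ann, config$min_distance)
  s3 <- exon_filter(s2, config$min_exons)
  ids3 <- vapply(s3, `[[`, character(1), "id")

  dropped <- data.frame(transcript_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  flags <- NULL
  ids4 <- character(0)
  if (length(ids3)) {
    present <- ids3 %in% rownames(expr)
    if (any(!present)) {
      dropped <- rbind(dropped, data.frame(
        transcript_id = ids3[!present],
        reason = "no expression row", stringsAsFactors = FALSE))
    }
    if (any(present)) {
      flags <- tissue_restriction_filter(
        expr[ids3[present], , drop = FALSE], config$alpha,
        log_expression = isTRUE(config$log_expression))
      not_testable <- flags$reason != ""
      if (any(not_testable)) {
        dropped <- rbind(dropped, data.frame(
          transcript_id = flags$transcript_id[not_testable],
          reason = flags$reason[not_testable], stringsAsFactors = FALSE))
      }
      ids4 <- flags$transcript_id[flags$restricted]
    }
  }
  s4 <- s3[ids3 %in% ids4]

  surviving <- list(
    input = ids0,
    depth = vapply(s1, `[[`, character(1), "id"),
    distance = vapply(s2, `[[`, character(1), "id"),
    exons = ids3,
    tissue_restriction = ids4)
  structure(list(
    stage_names = names(surviving),
    counts_after_stage = lengths(surviving),
    surviving_ids = surviving,
    surviving_models = s4,
    tissue_flags = flags,
    dropped = dropped,
    config = config), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Prioritization cascade\n")
  labels <- c(input = "input models",
              depth = sprintf("depth >= %s", x$config$min_depth),
              distance = sprintf("distance >= %s bp", x$config$min_distance),
              exons = sprintf(">= %s exons", x$config$min_exons),
              tissue_restriction = sprintf("tissue-restricted (alpha = %s)",
                                           x$config$alpha))
  for (s in x$stage_names)
    cat(sprintf("  %-32s %6d\n", labels[[s]], x$counts_after_stage[[s]]))
  if (nrow(x$dropped))
    cat(sprintf("  (%d model(s) untestable at the expression stage)\n",
                nrow(x$dropped)))
  invisible(x)
}

#' Cascade report as a data frame
#' @param x A `cascade_report`.
#' @param ... Unused.
#' @return Data frame with `stage`, `count`.
#' @method as.data.frame cascade_report
#' @export
as.data.frame.cascade_report <- function(x, ...) {
  data.frame(stage = x$stage_names,
             count = as.integer(x$counts_after_stage),
             row.names = NULL)
}
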