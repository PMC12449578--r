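#' Summarize longitudinal changes per subject and arm
#'
#' Computes per-subject absolute and percent change for every metric and
#' aggregates to arm-level mean +/- SD. Percent change is computed per
#' subject then averaged; the ratio of arm means (mean change over mean
#' baseline) is also reported for cross-checking against published tables,
#' where both conventions agree.
#'
#' @param subject_table data.frame with columns `subject`, `arm`, `metric`,
#'   `baseline`, `followup` (one row per subject x metric).
#' @return object of class `cohort_result`: list with `subjects` (per-subject
#'   changes) and `arms` (arm-level summaries).
#' @export
summarize_changes <- function(subject_table) {
  need <- c("subject", "arm", "metric", "baseline", "followup")
  if (!all(need %in% names(subject_table)))
    stop("subject_table needs columns: ", paste(need, collapse = ", "))
  tab <- subject_table[, need]
  miss <- !is.finite(tab$baseline) | !is.finite(tab$followup)
  if (any(miss)) {
    warning(sum(miss), " subject-metric rows missing a timepoint; excluded")
    tab <- tab[!miss, ]
  }
  if (nrow(tab) == 0) stop("no complete subject rows")
  tab$change <- tab$followup - tab$baseline
  tab$pct_change <- ifelse(tab$baseline > 0,
                           100 * tab$change / tab$baseline, NA_real_)

  agg <- function(x) c(mean = mean(x), sd = sd(x))
  arms <- do.call(rbind, lapply(
    split(tab, list(tab$arm, tab$metric), drop = TRUE),
    function(g) {
      data.frame(
        arm = g$arm[1], metric = g$metric[1], n = nrow(g),
        baseline_mean = mean(g$baseline), baseline_sd = sd(g$baseline),
        followup_mean = mean(g$followup), followup_sd = sd(g$followup),
        change_mean = mean(g$change), change_sd = sd(g$change),
        pct_change_mean = mean(g$pct_change), pct_change_sd = sd(g$pct_change),
        pct_change_ratio_of_means =
          100 * mean(g$change) / mean(g$baseline),
        stringsAsFactors = FALSE)
    }))
  rownames(arms) <- NULL
  structure(list(subjects = tab, arms = arms), class = "cohort_result")
}

#' Ratio-of-means percent change from arm-level summary statistics
#'
#' `100 * change_mean / baseline_mean` - the consistency check applicable to
#' published per-arm tables that report baseline, follow-up and change means.
#'
#' @param baseline_mean,change_mean arm-level means.
#' @return percent change.
#' @export
percent_change_ratio_of_means <- function(baseline_mean, change_mean) {
  if (any(baseline_mean <= 0)) stop("baseline mean must be > 0")
  100 * change_mean / baseline_mean
}

#' Arm-comparison statistics
#'
#' For each metric: one-way ANOVA of the change scores across arms, followed
#' by pairwise two-sample Student's t-tests between arms and paired t-tests
#' of follow-up vs baseline within each arm, with significance flagged at
#' p < .05 (no multiplicity correction).
#'
#' @param cohort a [summarize_changes()] result.
#' @param alpha significance threshold.
#' @param welch logical; use Welch's unequal-variance t-test between arms
#'   instead of the pooled-variance Student's test.
#' @return the `cohort_result` annotated with `anova`, `pairwise` and
#'   `within` data.frames.
#' @export
run_tests <- function(cohort, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(cohort, "cohort_result"))
  tab <- cohort$subjects
  anova_rows <- pair_rows <- within_rows <- list()
  for (met in unique(tab$metric)) {
    g <- tab[tab$metric == met, ]
    sizes <- table(g$arm)
    arms_ok <- names(sizes)[sizes >= 2]
    if (length(arms_ok) < length(sizes))
      warning("metric ", met, ": arms with < 2 subjects skipped from tests")
    g <- g[g$arm %in% arms_ok, ]
    if (length(arms_ok) >= 2) {
      fit <- aov(change ~ factor(arm), data = g)
      an <- anova(fit)
      anova_rows[[met]] <- data.frame(
        metric = met, F = an$`F value`[1], p = an$`Pr(>F)`[1],
        df_between = an$Df[1], df_within = an$Df[2],
        stringsAsFactors = FALSE)
      pairs <- utils::combn(sort(arms_ok), 2, simplify = FALSE)
      pair_rows[[met]] <- do.call(rbind, lapply(pairs, function(pr) {
        tt <- tryCatch(
          t.test(g$change[g$arm == pr[1]], g$change[g$arm == pr[2]],
                 var.equal = !welch),
          error = function(e) NULL)  # zero-variance data
        data.frame(metric = met, arm1 = pr[1], arm2 = pr[2],
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   p = if (is.null(tt)) NA_real_ else tt$p.value,
                   significant = if (is.null(tt)) NA else tt$p.value < alpha,
                   stringsAsFactors = FALSE)
      }))
    }
    within_rows[[met]] <- do.call(rbind, lapply(arms_ok, function(a) {
      ga <- g[g$arm == a, ]
      tt <- tryCatch(t.test(ga$followup, ga$baseline, paired = TRUE),
                     error = function(e) NULL)
      data.frame(metric = met, arm = a,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 significant = if (is.null(tt)) NA else tt$p.value < alpha,
                 stringsAsFactors = FALSE)
    }))
  }
  cohort$anova <- do.call(rbind, anova_rows)
  cohort$pairwise <- do.call(rbind, pair_rows)
  cohort$within <- do.call(rbind, within_rows)
  rownames(cohort$anova) <- rownames(cohort$pairwise) <-
    rownames(cohort$within) <- NULL
  cohort$alpha <- alpha
  cohort
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  print(x$arms, digits = 4)
  if (!is.null(x$anova)) {
    cat("\nANOVA across arms (change scores):\n")
    print(x$anova, digits = 4)
  }
  invisible(x)
}
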