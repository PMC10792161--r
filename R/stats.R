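#' Paired study-vs-fellow-eye t-test
#'
#' Two-sided paired Student's t-test on per-subject differences
#' `d = study - fellow`: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom, with a Shapiro-Wilk normality p-value on the
#' differences attached. Shapiro-Wilk is advisory — reported, never gating —
#' since the analysis applies the t-test throughout. Pairs with a missing
#' side are dropped and counted.
#'
#' @param study_values,fellow_values Equal-length numeric vectors, one entry
#'   per subject.
#' @param metric Optional metric name carried into the output.
#' @return An object of class `octa_paired_test`; use [tidy()] for a one-row
#'   tibble (estimates, t, df, p, shapiro p) or [glance()] for a model-level
#'   summary.
#' @export
paired_t_test <- function(study_values, fellow_values, metric = NA_character_) {
  if (length(study_values) != length(fellow_values)) {
    abort("`study_values` and `fellow_values` must have equal length.")
  }
  ok <- !is.na(study_values) & !is.na(fellow_values)
  n_dropped <- sum(!ok)
  s <- study_values[ok]; f <- fellow_values[ok]
  n <- length(s)
  if (n < 2) abort("Need at least 2 complete pairs.")
  d <- s - f
  if (sd(d) == 0) {
    abort("Zero-variance paired differences: the t statistic is undefined (all differences identical).")
  }
  tt <- t.test(s, f, paired = TRUE, alternative = "two.sided")
  sw <- if (n >= 3) shapiro.test(d)$p.value else NA_real_
  structure(
    list(metric = metric, n = n, n_dropped = n_dropped,
         study_mean = mean(s), study_sd = sd(s),
         fellow_mean = mean(f), fellow_sd = sd(f),
         mean_difference = mean(d), sd_difference = sd(d),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, shapiro_p = sw,
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2]),
    class = "octa_paired_test"
  )
}

#' @export
print.octa_paired_test <- function(x, ...) {
  cat(sprintf("<octa_paired_test> %s: n = %d pairs\n",
              ifelse(is.na(x$metric), "(unnamed metric)", x$metric), x$n))
  cat(sprintf("  study %.3f +/- %.3f vs fellow %.3f +/- %.3f\n",
              x$study_mean, x$study_sd, x$fellow_mean, x$fellow_sd))
  cat(sprintf("  t(%d) = %.3f, p = %.4g (Shapiro-Wilk p = %.3g)\n",
              x$df, x$t, x$p_value, x$shapiro_p))
  invisible(x)
}

#' @rdname paired_t_test
#' @param x An `octa_paired_test`.
#' @param ... Unused.
#' @export
tidy.octa_paired_test <- function(x, ...) {
  tibble(metric = x$metric, n = x$n,
         study_mean = x$study_mean, study_sd = x$study_sd,
         fellow_mean = x$fellow_mean, fellow_sd = x$fellow_sd,
         mean_difference = x$mean_difference,
         statistic = x$t, df = x$df, p_value = x$p_value,
         shapiro_p = x$shapiro_p,
         conf_low = x$conf_low, conf_high = x$conf_high)
}

#' @rdname paired_t_test
#' @export
glance.octa_paired_test <- function(x, ...) {
  tibble(n = x$n, n_dropped = x$n_dropped, statistic = x$t, df = x$df,
         p_value = x$p_value, shapiro_p = x$shapiro_p)
}

#' Analytic power of the two-sided paired t-test
#'
#' Exact noncentral-t formulation: with critical value
#' `tc = qt(1 - alpha/2, n - 1)` and noncentrality `ncp = d * sqrt(n)`,
#' `power = P(T' > tc) + P(T' < -tc)` where `T'` is noncentral t with
#' `n - 1` df. `d` is Cohen's d on the paired differences
#' (mean difference / SD of differences).
#'
#' @param n Number of pairs (>= 2); vectorized.
#' @param d Effect size on the paired differences.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`, same length as `n`.
#' @export
paired_t_power <- function(n, d, alpha = 0.05) {
  stopifnot(all(n >= 2), alpha > 0, alpha < 1)
  tc <- qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  (1 - pt(tc, n - 1, ncp)) + pt(-tc, n - 1, ncp)
}

#' Minimal sample size for a paired t-test
#'
#' Smallest number of pairs `n >= 2` whose analytic power
#' ([paired_t_power()]) reaches `target_power` for effect size `d` at
#' two-sided level `alpha`. Power is monotone increasing in `n`, so a linear
#' scan from 2 upward returns the exact minimum.
#'
#' @param effect_size Cohen's d on the paired differences (non-zero).
#' @param alpha Two-sided significance level in (0, 1).
#' @param target_power Required power in (0, 1).
#' @param n_max Give up beyond this `n` (power unreachable).
#' @return A one-row tibble: `effect_size`, `alpha`, `target_power`,
#'   `n_required`, `achieved_power`.
#' @export
#' @examples
#' required_sample_size(0.7, 0.05, 0.80)  # 19 pairs, power 0.823
required_sample_size <- function(effect_size, alpha = 0.05,
                                 target_power = 0.80, n_max = 1e6) {
  if (!is.numeric(effect_size) || effect_size == 0) {
    abort("`effect_size` must be a non-zero number.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must be in (0, 1).")
  }
  d <- abs(effect_size)
  n <- 2
  while (n <= n_max) {
    pw <- paired_t_power(n, d, alpha)
    if (pw >= target_power) {
      return(tibble(effect_size = effect_size, alpha = alpha,
                    target_power = target_power, n_required = n,
                    achieved_power = pw))
    }
    n <- n + 1
  }
  abort(sprintf("Target power %.2f unreachable with n <= %g.", target_power, n_max))
}

#' Paired study-vs-fellow summary table for a cohort
#'
#' Runs one paired t-test per metric over a per-eye cohort table (see
#' [write_cohort_table()] for the schema) and formats the standard report:
#' per-eye mean ± SD to 2 decimals and the two-sided p-value to 3 decimals,
#' one row per metric. Subjects missing either eye for a metric are dropped
#' from that metric's comparison; a metric absent for all subjects is
#' omitted with a warning.
#'
#' No multiple-testing correction is applied by default (each of the 8
#' metrics is tested at its nominal level); `adjust = "holm"` opts into a
#' Holm adjustment of the p-values.
#'
#' @param cohort A tibble with `subject_id`, `eye` and metric columns.
#' @param metrics Which metric columns to summarize (default: all canonical
#'   metrics present).
#' @param alpha Significance level used by the `significant` flag.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble of class `octa_cohort_summary`: `metric`, `label`, `n`,
#'   numeric means/SDs, `statistic`, `df`, `p_value`, `shapiro_p`,
#'   `significant`, and formatted columns `study_mean_sd`, `fellow_mean_sd`,
#'   `p_formatted`.
#' @export
summarize_cohort <- function(cohort, metrics = NULL, alpha = 0.05,
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  cohort <- as_tibble(cohort)
  if (!all(c("subject_id", "eye") %in% names(cohort))) {
    abort("`cohort` needs `subject_id` and `eye` columns.")
  }
  present <- intersect(metrics %||% cohort_metric_names(), names(cohort))
  if (is.null(metrics)) {
    extra <- setdiff(names(cohort), c("subject_id", "eye", present))
    present <- c(present, extra[vapply(cohort[extra], is.numeric, logical(1))])
  }
  if (length(present) == 0) abort("No metric columns found in `cohort`.")

  labels <- metric_labels()
  rows <- purrr::map(present, function(mname) {
    wide <- cohort |>
      dplyr::select("subject_id", "eye", value = dplyr::all_of(mname)) |>
      tidyr::pivot_wider(names_from = "eye", values_from = "value")
    if (!all(c("study", "fellow") %in% names(wide))) return(NULL)
    ok <- !is.na(wide$study) & !is.na(wide$fellow)
    if (sum(ok) < 2) return(NULL)
    tt <- paired_t_test(wide$study[ok], wide$fellow[ok], metric = mname)
    tidy(tt)
  })
  dropped <- present[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warn(paste0("Metrics without >= 2 complete pairs omitted: ",
                paste(dropped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("No metric had >= 2 complete pairs.")
  if (adjust == "holm") out$p_value <- p.adjust(out$p_value, method = "holm")
  out <- out |>
    dplyr::mutate(
      label = unname(ifelse(.data$metric %in% names(labels),
                            labels[.data$metric], .data$metric)),
      significant = .data$p_value <= alpha,
      study_mean_sd = sprintf("%.2f ± %.2f", .data$study_mean, .data$study_sd),
      fellow_mean_sd = sprintf("%.2f ± %.2f", .data$fellow_mean, .data$fellow_sd),
      p_formatted = sprintf("%.3f", .data$p_value)
    ) |>
    dplyr::select("metric", "label", "n", "study_mean", "study_sd",
                  "fellow_mean", "fellow_sd", "statistic", "df", "p_value",
                  "shapiro_p", "significant", "study_mean_sd",
                  "fellow_mean_sd", "p_formatted")
  class(out) <- c("octa_cohort_summary", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' @export
print.octa_cohort_summary <- function(x, ...) {
  cat(sprintf("Paired study-vs-fellow-eye comparison (n up to %d pairs, alpha = %g, %s adjustment)\n",
              max(x$n), attr(x, "alpha") %||% 0.05,
              attr(x, "adjust") %||% "none"))
  df <- data.frame(Metric = x$label, `Study eye` = x$study_mean_sd,
                   `Fellow eye` = x$fellow_mean_sd, `P value` = x$p_formatted,
                   check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
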