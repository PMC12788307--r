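#' Age-adjusted ANCOVA group comparison
#'
#' Fits value ~ group + age by least squares and tests the group term
#' with a partial (type-III equivalent; the model has only these two
#' terms) F-test on (1, n - 3) degrees of freedom. If the design is
#' singular with the covariate (constant age, or age perfectly
#' confounded with group), falls back to the group-only one-way model
#' with a warning.
#'
#' @param values numeric response vector
#' @param group factor or character with exactly two levels; "patient" is
#'   taken as the non-reference level when present
#' @param age numeric covariate
#' @return list: `f`, `p`, `direction` (sign of the patient-minus-control
#'   adjusted difference), `df` (c(1, residual df))
#' @export
ancova_group <- function(values, group, age) {
  stopifnot(length(values) == length(group), length(values) == length(age))
  if (!all(is.finite(age))) stop("ages must be finite")
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (min(table(group)) < 2) stop("need at least 2 subjects per group")
  if ("control" %in% levels(group))
    group <- stats::relevel(group, "control")
  full <- stats::lm(values ~ group + age)
  singular <- anyNA(stats::coef(full))
  if (singular || stats::sd(age) == 0) {
    warning("covariate is degenerate; falling back to group-only model")
    full <- stats::lm(values ~ group)
  }
  reduced <- stats::update(full, . ~ . - group)
  a <- stats::anova(reduced, full)
  rss_diff <- a$`Sum of Sq`[2]
  df_res <- a$Res.Df[2]
  rss_full <- a$RSS[2]
  gcoef <- grep("^group", names(stats::coef(full)), value = TRUE)[1]
  if (rss_full <= .Machine$double.eps * sum(values^2)) {
    warning("zero residual variance; degenerate fit")
    return(list(f = Inf, p = 0,
                direction = sign(stats::coef(full)[[gcoef]]),
                df = c(1, df_res)))
  }
  f <- (rss_diff / 1) / (rss_full / df_res)
  p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
  list(f = f, p = p, direction = sign(stats::coef(full)[[gcoef]]),
       df = c(1, df_res))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate procedure; input validation plus the
#' standard adjustment, returned in the original order.
#'
#' @param p numeric vector of raw p-values in [0, 1]
#' @return adjusted p-values (elementwise >= raw, capped at 1)
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' (mean(patients) - mean(controls)) / s_pooled, with the pooled SD
#' sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)). The patient-minus-control
#' sign convention means elevated patient values give d > 0.
#'
#' @param patient,control numeric vectors (>= 2 each)
#' @return scalar d
#' @export
cohens_d <- function(patient, control) {
  n1 <- length(patient); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  sp <- sqrt(((n1 - 1) * stats::var(patient) + (n2 - 1) * stats::var(control)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero; effect size undefined")
  (mean(patient) - mean(control)) / sp
}

#' Group comparison over a feature table
#'
#' Runs one age-adjusted ANCOVA per feature cell and adjusts p-values
#' with Benjamini-Hochberg FDR separately within each (task, band)
#' family across regions. For network AUC features (identified by a
#' `metric` column) each (task, band, metric) cell forms its own family,
#' i.e. the raw p is reported unadjusted unless `fdr_network = TRUE`.
#'
#' @param features data.frame with columns subject_id, group, age, task,
#'   band, a feature column (`region` or `metric`), and `value` (or `rp`
#'   / `auc_value`, auto-detected)
#' @param alpha significance level on the adjusted p (default 0.05)
#' @param fdr_network also FDR-adjust network families across metrics
#' @return data.frame with one row per (task, band, feature):
#'   f_stat, p_raw, p_fdr, cohens_d, medium_effect (|d| > 0.5),
#'   significant (p_fdr < alpha), n_patient, n_control
#' @export
run_group_comparison <- function(features, alpha = 0.05, fdr_network = FALSE) {
  value_col <- intersect(c("value", "rp", "auc_value"), names(features))[1]
  if (is.na(value_col)) stop("no value column (value/rp/auc_value) found")
  feature_col <- intersect(c("region", "metric"), names(features))[1]
  if (is.na(feature_col)) stop("no feature column (region/metric) found")
  is_network <- feature_col == "metric"
  need <- c("subject_id", "group", "age", "task", "band")
  stopifnot(all(need %in% names(features)))

  cells <- unique(features[, c("task", "band", feature_col)])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- features[features$task == cells$task[i] &
                      features$band == cells$band[i] &
                      features[[feature_col]] == cells[[feature_col]][i], ]
    if (!nrow(sub) || anyNA(sub[[value_col]])) {
      message(sprintf("skipping %s/%s/%s: missing values",
                      cells$task[i], cells$band[i], cells[[feature_col]][i]))
      next
    }
    pat <- sub[[value_col]][sub$group == "patient"]
    ctl <- sub[[value_col]][sub$group == "control"]
    an <- ancova_group(sub[[value_col]], sub$group, sub$age)
    d <- tryCatch(cohens_d(pat, ctl), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      task = cells$task[i], band = cells$band[i],
      feature = cells[[feature_col]][i],
      f_stat = an$f, p_raw = an$p, cohens_d = d,
      n_patient = length(pat), n_control = length(ctl),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  if (is_network && !fdr_network) {
    out$p_fdr <- out$p_raw    # family of size one per (task, band, metric)
  } else {
    fams <- unique(out[, c("task", "band")])
    for (i in seq_len(nrow(fams))) {
      idx <- out$task == fams$task[i] & out$band == fams$band[i]
      out$p_fdr[idx] <- bh_fdr(out$p_raw[idx])
    }
  }
  out$medium_effect <- !is.na(out$cohens_d) & abs(out$cohens_d) > 0.5
  out$significant <- out$p_fdr < alpha
  out[, c("task", "band", "feature", "f_stat", "p_raw", "p_fdr", "cohens_d",
          "medium_effect", "significant", "n_patient", "n_control")]
}

#' Text summary of significant group differences
#'
#' One line per flagged row using the conventional star notation:
#' `*` p_fdr < 0.05, `**` p_fdr < 0.01, `#` medium effect (|d| > 0.5).
#' The two criteria are reported independently, never merged.
#'
#' @param stats data.frame from [run_group_comparison()]
#' @return character vector of report lines (invisibly printed)
#' @export
format_stats_report <- function(stats) {
  flagged <- stats[stats$significant | stats$medium_effect, , drop = FALSE]
  if (!nrow(flagged)) return("no significant or medium-effect differences")
  lines <- vapply(seq_len(nrow(flagged)), function(i) {
    r <- flagged[i, ]
    marks <- paste0(if (r$p_fdr < 0.01) "**" else if (r$p_fdr < 0.05) "*" else "",
                    if (r$medium_effect) "#" else "")
    sprintf("%s / %s / %s: F = %.2f, p_raw = %.4f, p_fdr = %.4f, d = %.2f %s",
            r$task, r$band, r$feature, r$f_stat, r$p_raw, r$p_fdr,
            r$cohens_d, marks)
  }, "")
  lines
}
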