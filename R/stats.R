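## Group-comparison statistics: variance-gated pooled/Satterthwaite
## two-sample t-tests, empirical ROC with Youden-optimal cut-offs, and the
## normal-approximation sample-size formula for two means.

#' Two-sided F test for equality of variances from summary statistics
#'
#' `F` is the larger sample variance over the smaller, with numerator and
#' denominator degrees of freedom matched accordingly; the two-sided p-value
#' is twice the upper-tail F probability (capped at 1). This is the gate
#' used to choose between the pooled and Satterthwaite t-tests: unequal
#' variances (p <= `alpha`) select Satterthwaite. When both SDs are zero the
#' test is degenerate and returns an equal-variance verdict (F = 1, p = 1).
#'
#' @param s1,s2 Group standard deviations.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Gate level; default 0.05.
#' @return List with `F`, `df1`, `df2`, `p`, and `method` (the gated choice,
#'   `"pooled"` or `"satterthwaite"`).
#' @export
variance_equality_test <- function(s1, n1, s2, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    return(list(F = 1, df1 = n1 - 1, df2 = n2 - 1, p = 1, method = "pooled"))
  }
  if (s1^2 >= s2^2) {
    f <- if (s2 == 0) Inf else s1^2 / s2^2
    df1 <- n1 - 1; df2 <- n2 - 1
  } else {
    f <- s2^2 / s1^2
    df1 <- n2 - 1; df2 <- n1 - 1
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(F = f, df1 = df1, df2 = df2, p = p,
       method = if (p <= alpha) "satterthwaite" else "pooled")
}

t_from_summary_one <- function(m1, s1, n1, m2, s2, n2, method) {
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se == 0) n1 + n2 - 2 else
      (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = p)
}

#' Two-sample t-test from group summary statistics
#'
#' Pooled (equal-variance) or Satterthwaite (Welch, unequal-variance)
#' two-sample t-test computed directly from (mean, SD, n) per group. With
#' `method = "auto"` the variance-equality F gate at `alpha` chooses the
#' method, mirroring SAS-style reporting. P-values from both methods are
#' always returned alongside the gated one. Degenerate inputs (both SDs
#' zero) give t = 0, p = 1 when the means agree and p -> 0 otherwise.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param method `"auto"` (variance-gated), `"pooled"` or `"satterthwaite"`.
#' @param alpha Gate level for the F test.
#' @return Object of class `dect_test`: list with `t_statistic`, `df`,
#'   `method`, `p_two_sided`, `variance_test_p`, `significant`,
#'   `p_pooled`, `p_satterthwaite`.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                      method = c("auto", "pooled",
                                                 "satterthwaite"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  vt <- variance_equality_test(s1, n1, s2, n2, alpha = alpha)
  use <- if (method == "auto") vt$method else method
  res <- t_from_summary_one(m1, s1, n1, m2, s2, n2, use)
  both <- lapply(c(pooled = "pooled", satterthwaite = "satterthwaite"),
                 function(mm) t_from_summary_one(m1, s1, n1, m2, s2, n2, mm)$p)
  structure(list(t_statistic = res$t, df = res$df, method = use,
                 p_two_sided = res$p, variance_test_p = vt$p,
                 significant = res$p <= 0.05,
                 p_pooled = both$pooled,
                 p_satterthwaite = both$satterthwaite),
            class = "dect_test")
}

#' Two-sample t-test from raw samples
#'
#' Computes the per-group summaries (mean, sample SD, n) and delegates to
#' [two_sample_t_from_summary()]; the variance gate is applied by default.
#'
#' @param x,y Numeric samples, each with >= 2 values.
#' @inheritParams two_sample_t_from_summary
#' @return A `dect_test` object.
#' @export
two_sample_t <- function(x, y, method = "auto", alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("input error: each sample needs >= 2 values", call. = FALSE)
  two_sample_t_from_summary(mean(x), stats::sd(x), length(x),
                            mean(y), stats::sd(y), length(y),
                            method = method, alpha = alpha)
}

#' @export
print.dect_test <- function(x, ...) {
  cat(sprintf("two-sample t-test (%s): t = %.4g, df = %.4g, p = %.4g%s\n",
              x$method, x$t_statistic, x$df, x$p_two_sided,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Empirical ROC analysis with Youden-optimal cut-off
#'
#' The AUC is the rank (Mann-Whitney) statistic with midrank handling of
#' ties. The orientation is chosen so that AUC >= 0.5 and is reported as the
#' cut-off inequality direction: `">"` means the positive (malignant) call
#' is `value >= cutoff`, `"<"` means `value <= cutoff` (the decision rule is
#' inclusive of the boundary on the positive side). The cut-off is the
#' observed value maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity.
#'
#' @param values Numeric marker values.
#' @param labels Class labels, two classes.
#' @param positive Label of the positive class (default `"malignant"`);
#'   sensitivity is defined on this class, specificity on the other.
#' @return Object of class `dect_roc`: list with `auc`, `direction`,
#'   `cutoff`, `sensitivity`, `specificity`, `youden`, `n_positive`,
#'   `n_negative`.
#' @export
roc_analysis <- function(values, labels, positive = "malignant") {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  classes <- unique(labels)
  if (length(classes) != 2 || !positive %in% classes)
    stop("input error: need exactly two classes including the positive one",
         call. = FALSE)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)  # midranks
  auc_raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_raw >= 0.5) ">" else "<"
  auc <- max(auc_raw, 1 - auc_raw)
  cand <- sort(unique(values))
  best <- NULL
  for (cut in cand) {
    call_pos <- if (direction == ">") values >= cut else values <= cut
    sens <- sum(call_pos & pos) / n1
    spec <- sum(!call_pos & !pos) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && spec > best$specificity + 1e-12)) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  structure(c(list(auc = auc, direction = direction), best,
              list(n_positive = n1, n_negative = n0)),
            class = "dect_roc")
}

#' @export
print.dect_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, cut-off %s%.4g (sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$direction, x$cutoff,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Sample size for detecting a difference in two means
#'
#' Standard normal-approximation formula for a two-sided two-sample
#' comparison of means with common SD:
#' `n = ceiling(2 * sd^2 * (z_{1-alpha/2} + z_{power})^2 / delta^2)` per
#' group, floored at 2.
#'
#' @param delta Smallest difference in means worth detecting (> 0).
#' @param sd Common within-group standard deviation (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Required size per group (integer).
#' @export
sample_size_two_means <- function(delta, sd, alpha = 0.05, power = 0.80) {
  if (delta <= 0) stop("input error: delta must be positive", call. = FALSE)
  if (sd <= 0) stop("input error: sd must be positive", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  max(2L, as.integer(ceiling(2 * sd^2 * z^2 / delta^2)))
}

summarize_groups <- function(values, labels) {
  out <- lapply(split(values, labels), function(v)
    list(n = length(v), mean = mean(v), sd = stats::sd(v)))
  out
}

report_row <- function(feature, energy, values, labels, alpha = 0.05) {
  gs <- summarize_groups(values, labels)
  b <- gs[["benign"]]; m <- gs[["malignant"]]
  tt <- two_sample_t_from_summary(b$mean, b$sd, b$n, m$mean, m$sd, m$n,
                                  alpha = alpha)
  roc <- roc_analysis(values, labels, positive = "malignant")
  data.frame(
    feature = feature, energy_keV = energy,
    benign_n = b$n, benign_mean = b$mean, benign_sd = b$sd,
    malignant_n = m$n, malignant_mean = m$mean, malignant_sd = m$sd,
    method = tt$method, t = tt$t_statistic, df = tt$df, p = tt$p_two_sided,
    p_pooled = tt$p_pooled, p_satterthwaite = tt$p_satterthwaite,
    variance_p = tt$variance_test_p, significant = tt$significant,
    cutoff_direction = roc$direction, cutoff = roc$cutoff,
    sensitivity_pct = round(100 * roc$sensitivity, 1),
    specificity_pct = round(100 * roc$specificity, 1),
    auc = round(roc$auc, 3))
}

#' Benign-versus-malignant report over a cohort's feature tables
#'
#' For every texture feature x energy (and, when given, the spectral iodine
#' and normalized-slope columns), computes the per-class summary (n, mean,
#' SD), the variance-gated two-sample t-test and the ROC analysis, mirroring
#' a diagnostic-performance table: sensitivity/specificity in percent, AUC
#' to 3 decimals, raw two-sided P values with significance flagged at
#' p <= 0.05 and no multiplicity correction by default.
#'
#' @param features Wide feature table from [extract_features()].
#' @param spectral Optional spectral table from [spectral_summary()]; adds
#'   `iodine_content` and `normalized_slope` rows (energy `NA`).
#' @param alpha Gate level for the variance-equality F test.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()];
#'   `"none"` (the default) reports raw P values; the adjusted values are
#'   added as a `p_adjusted` column when another method is chosen.
#' @return `data.frame`, one row per feature x energy plus spectral rows.
#' @export
build_report <- function(features, spectral = NULL, alpha = 0.05,
                         p_adjust = "none") {
  labs <- unique(features$label)
  if (!all(c("benign", "malignant") %in% labs))
    stop("input error: report needs both a benign and a malignant group",
         call. = FALSE)
  if (min(table(features$label[!duplicated(features$nodule_id)])) < 2)
    stop("input error: need >= 2 nodules per class", call. = FALSE)
  keys <- intersect(dect_feature_names(), names(features))
  rows <- list()
  for (e in sort(unique(features$energy_keV))) {
    sub <- features[features$energy_keV == e, ]
    for (k in keys)
      rows[[length(rows) + 1L]] <- report_row(k, e, sub[[k]], sub$label, alpha)
  }
  if (!is.null(spectral)) {
    for (k in c("iodine_mg_per_ml", "normalized_slope")) {
      if (!k %in% names(spectral) || all(is.na(spectral[[k]]))) next
      nm <- if (k == "iodine_mg_per_ml") "iodine_content" else k
      rows[[length(rows) + 1L]] <-
        report_row(nm, NA_real_, spectral[[k]], spectral$label, alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out
}
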