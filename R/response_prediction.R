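#' @include AllClasses.R utils.R
NULL

#' HAM-D-6 reduction ratio
#'
#' `(baseline - endpoint) / baseline`; the fraction of baseline symptom
#' severity lost over the first two treatment weeks.
#'
#' @param baseline Baseline HAM-D-6 score (> 0).
#' @param endpoint Endpoint HAM-D-6 score (>= 0).
#' @return Fraction <= 1 (negative if symptoms worsened).
#' @export
reductionRatio <- function(baseline, endpoint) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  if (any(endpoint < 0)) stop("endpoint must be non-negative")
  (baseline - endpoint) / baseline
}

#' Responder classification by the >= 50% rule
#'
#' @param ratio Reduction ratio(s), each <= 1.
#' @return `"responder"` if `ratio >= 0.5` (boundary inclusive), else
#'   `"non_responder"`.
#' @export
classifyResponse <- function(ratio) {
  if (any(ratio > 1 + 1e-12, na.rm = TRUE)) stop("ratio must be <= 1")
  ifelse(ratio >= 0.5, "responder", "non_responder")
}

#' Cohort exclusion-cascade arithmetic
#'
#' Tracks enrollment through the exclusion steps (electroconvulsive therapy,
#' data-quality rejection, treatment switch) down to the analyzed sample.
#'
#' @param enrolledMdd,enrolledHc Enrollment counts.
#' @param excludedEct Patients excluded for electroconvulsive therapy.
#' @param excludedQualityMdd,excludedQualityHc Excluded for excessive head
#'   motion or poor image quality.
#' @param excludedSwitch Patients switched to another drug class.
#' @return A [CohortCounts-class]; errors on any negative remainder.
#' @examples
#' exclusionCascade(100, 30, excludedEct = 9, excludedQualityMdd = 9,
#'                  excludedQualityHc = 1, excludedSwitch = 17)
#' @export
exclusionCascade <- function(enrolledMdd, enrolledHc, excludedEct = 0,
                             excludedQualityMdd = 0, excludedQualityHc = 0,
                             excludedSwitch = 0) {
  remMdd <- enrolledMdd - excludedEct - excludedQualityMdd - excludedSwitch
  remHc <- enrolledHc - excludedQualityHc
  if (remMdd < 0 || remHc < 0) stop("exclusions exceed enrollment")
  new("CohortCounts", enrolledMdd = as.integer(enrolledMdd),
      enrolledHc = as.integer(enrolledHc), excludedEct = as.integer(excludedEct),
      excludedQualityMdd = as.integer(excludedQualityMdd),
      excludedQualityHc = as.integer(excludedQualityHc),
      excludedSwitch = as.integer(excludedSwitch),
      remainingMdd = as.integer(remMdd), remainingHc = as.integer(remHc),
      analyzedTotal = as.integer(remMdd + remHc))
}

#' Pearson correlation of coupling features with symptom improvement
#'
#' @param features Per-patient feature vector, or a matrix/data frame with
#'   one column per feature.
#' @param ratios Per-patient reduction ratios (same length; computed over
#'   patients only, since controls have no ratio).
#' @return Data frame: `feature`, `r`, `p` (two-sided, via the t transform).
#' @export
correlateFeatures <- function(features, ratios) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  keep <- complete.cases(features) & is.finite(ratios)
  features <- features[keep, , drop = FALSE]
  ratios <- ratios[keep]
  if (length(ratios) < 4) stop("need >= 4 paired observations")
  if (var(ratios) == 0) stop("zero variance in the reduction ratios")
  out <- lapply(colnames(features), function(nm) {
    x <- features[, nm]
    if (var(x) == 0) stop("zero variance in feature ", nm)
    ct <- cor.test(x, ratios, method = "pearson")
    data.frame(feature = nm, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

## ROC curve of a score against a binary positive-class indicator.
.rocCurve <- function(score, positive) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(score[positive] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[!positive] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- tpr - fpr
  best <- which.max(j)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
       sensitivity = tpr[best], specificity = 1 - fpr[best],
       threshold = thr[best])
}

#' Combine two coupling features and evaluate response discrimination
#'
#' Fits an ordinary least-squares linear combination of the two features
#' against the binary non-responder indicator (linear regression, taken
#' literally rather than logistic); the fitted score is the ROC input. AUC is
#' the trapezoidal area over all score thresholds; the operating point
#' maximizes Youden's J. Single-feature ROC curves (each feature fitted the
#' same way) are reported alongside for comparison. The AUC is in-sample: no
#' held-out validation is performed, and it should be read as such.
#'
#' @param feature1,feature2 Per-patient scalar features.
#' @param labels Group labels, `"responder"` / `"non_responder"` (the
#'   positive class being detected is non-response).
#' @param positive Positive class label (default `"non_responder"`).
#' @return List: `combined` ([RocResult-class]), `single` (list of two
#'   [RocResult-class]), `aucGain` = combined AUC minus the best single AUC.
#' @export
combineAndRoc <- function(feature1, feature2, labels,
                          positive = "non_responder") {
  keep <- is.finite(feature1) & is.finite(feature2) & !is.na(labels)
  feature1 <- feature1[keep]; feature2 <- feature2[keep]
  labels <- labels[keep]
  y <- as.integer(labels == positive)
  if (all(y == 1) || all(y == 0)) stop("one class is empty")
  if (var(feature1) == 0 && var(feature2) == 0) stop("constant score")
  fit <- lm(y ~ feature1 + feature2)
  score <- fitted(fit)
  comb <- .rocCurve(score, y == 1)
  singles <- lapply(list(feature1, feature2), function(f) {
    s <- fitted(lm(y ~ f))
    r <- .rocCurve(s, y == 1)
    new("RocResult", auc = r$auc, fpr = r$fpr, tpr = r$tpr,
        thresholds = r$thresholds, sensitivity = r$sensitivity,
        specificity = r$specificity, threshold = r$threshold,
        coefficients = NA_real_)
  })
  combined <- new("RocResult", auc = comb$auc, fpr = comb$fpr,
                  tpr = comb$tpr, thresholds = comb$thresholds,
                  sensitivity = comb$sensitivity,
                  specificity = comb$specificity, threshold = comb$threshold,
                  coefficients = coef(fit))
  list(combined = combined, single = singles,
       aucGain = comb$auc - max(vapply(singles, slot, numeric(1), "auc")))
}

#' Group-comparison demographics table
#'
#' Builds a Table-1-shaped summary from a cohort data frame: one-way ANOVA
#' across the three groups for continuous demographics, Pearson chi-square
#' (no continuity correction) for sex counts, and pooled two-sample t between
#' the two patient groups for clinical scores.
#'
#' @param subjects Data frame with columns `group`, `age`, `sex`,
#'   `education`, and optionally `hamd17Baseline`, `hamd6Baseline`.
#' @return Data frame: `variable`, `test`, `statistic`, `p`.
#' @export
demographicsTable <- function(subjects) {
  stopifnot(all(c("group", "age", "sex") %in% names(subjects)))
  groups <- split(subjects, subjects$group)
  if (length(groups) < 2) stop("need >= 2 groups")
  rows <- list()
  for (v in intersect(c("age", "education"), names(subjects))) {
    a <- summary(aov(subjects[[v]] ~ factor(subjects$group)))[[1]]
    rows[[v]] <- data.frame(variable = v, test = "anova",
                            statistic = a[["F value"]][1],
                            p = a[["Pr(>F)"]][1])
  }
  tab <- table(subjects$group, subjects$sex)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  rows$sex <- data.frame(variable = "sex", test = "chisq",
                         statistic = unname(cs$statistic), p = cs$p.value)
  pat <- subjects[subjects$group %in% c("responder", "non_responder"), ]
  for (v in intersect(c("hamd17Baseline", "hamd6Baseline"), names(subjects))) {
    if (all(is.na(pat[[v]]))) next
    tt <- stats::t.test(pat[[v]] ~ pat$group, var.equal = TRUE)
    rows[[v]] <- data.frame(variable = v, test = "t",
                            statistic = unname(tt$statistic), p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
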