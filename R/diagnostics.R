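# Rounding used for all printed percentages: half away from zero, 1 decimal,
# matching the table style of clinical reader studies (not round()'s
# round-half-even).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Build a 2x2 diagnostic contingency table
#'
#' Either give the four counts directly, or derive them from per-lesion
#' dichotomous verdicts against the pathology gold standard with
#' [table_from_verdicts()].
#'
#' @param tp,fp,fn,tn Non-negative integer counts: true/false positives,
#'   false/true negatives against pathology.
#' @return Object of class `"contingency_2x2"`.
#' @export
#' @examples
#' contingency_2x2(tp = 175, fp = 58, fn = 25, tn = 254)
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("tp, fp, fn, tn must be non-negative integers")
  }
  if (sum(counts) == 0) stop("contingency table must have at least one count")
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "contingency_2x2")
}

#' @rdname contingency_2x2
#' @param verdict Character vector of `"positive"`/`"negative"` calls.
#' @param truth Character vector of `"malignant"`/`"benign"` pathology labels
#'   (the gold standard), aligned with `verdict`.
#' @export
table_from_verdicts <- function(verdict, truth) {
  stopifnot(length(verdict) == length(truth))
  if (!all(verdict %in% c("positive", "negative"))) {
    stop("verdict values must be 'positive'/'negative'")
  }
  if (!all(truth %in% c("malignant", "benign"))) {
    stop("truth values must be 'malignant'/'benign'")
  }
  contingency_2x2(tp = sum(verdict == "positive" & truth == "malignant"),
                  fp = sum(verdict == "positive" & truth == "benign"),
                  fn = sum(verdict == "negative" & truth == "malignant"),
                  tn = sum(verdict == "negative" & truth == "benign"))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(pathology = c("malignant", "benign"),
                              verdict = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive and negative
#' predictive values tp/(tp+fp) and tn/(tn+fn), and accuracy
#' (tp+tn)/total, each carried as an exact ratio (numerator, denominator),
#' a proportion, and a percent string rounded half-away-from-zero to one
#' decimal. A metric whose denominator is zero is returned as `NA` and
#' flagged in `undefined`; the others are still computed.
#'
#' @param t A [contingency_2x2()].
#' @return A data.frame of class `"diagnostic_metrics"` with one row per
#'   metric and columns `metric`, `numerator`, `denominator`, `proportion`,
#'   `percent` (character, 1 decimal). Attribute `undefined` lists any
#'   metrics with a zero denominator.
#' @export
#' @examples
#' metrics_from_table(contingency_2x2(tp = 175, fp = 58, fn = 25, tn = 254))
metrics_from_table <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  total <- t$tp + t$fp + t$fn + t$tn
  num <- c(sensitivity = t$tp, specificity = t$tn, ppv = t$tp,
           npv = t$tn, accuracy = t$tp + t$tn)
  den <- c(sensitivity = t$tp + t$fn, specificity = t$tn + t$fp,
           ppv = t$tp + t$fp, npv = t$tn + t$fn, accuracy = total)
  prop <- ifelse(den > 0, num / den, NA_real_)
  pct <- ifelse(is.na(prop), NA_character_,
                sprintf("%.1f", round_half_away(100 * prop, 1L)))
  out <- data.frame(metric = names(num), numerator = unname(num),
                    denominator = unname(den), proportion = unname(prop),
                    percent = unname(pct), stringsAsFactors = FALSE)
  attr(out, "undefined") <- names(num)[den == 0]
  class(out) <- c("diagnostic_metrics", class(out))
  out
}

test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method), list(...)),
            class = "qp_test_result")
}

#' @export
print.qp_test_result <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %s, p = %s\n", x$method,
              format(x$statistic), format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' McNemar test on paired dichotomous calls
#'
#' Tests marginal homogeneity of two diagnostic modes read on the same
#' lesions, from the two discordant counts: `b` lesions called positive by
#' mode 1 only and `c` by mode 2 only. The exact version is the two-sided
#' binomial tail with success probability 1/2 over the `b + c` discordant
#' pairs; the asymptotic version is the continuity-corrected chi-square
#' statistic `(|b - c| - 1)^2 / (b + c)` on 1 df. `mode = "auto"` uses the
#' exact test when `b + c < 25`. With no discordant pairs the p-value is 1
#' and the statistic undefined.
#'
#' @param b,c Non-negative discordant counts.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return A test-result object with `statistic` (chi-square, or `NA` for
#'   the exact test), `p_value` and `method`.
#' @export
#' @examples
#' mcnemar_test(b = 15, c = 5)
mcnemar_test <- function(b, c, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (b < 0 || c < 0 || b != floor(b) || c != floor(c)) {
    stop("b and c must be non-negative integers")
  }
  n <- b + c
  if (n == 0) {
    return(test_result(NA_real_, 1, "mcnemar_exact", b = b, c = c))
  }
  if (mode == "auto") mode <- if (n < 25) "exact" else "asymptotic"
  if (mode == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    test_result(NA_real_, p, "mcnemar_exact", b = b, c = c)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    test_result(stat, p, "mcnemar_continuity_corrected", b = b, c = c)
  }
}

#' Cross-tabulate two raters' dichotomous calls
#'
#' @param v1,v2 Aligned character vectors of `"positive"`/`"negative"` calls
#'   on the same lesions.
#' @return Object of class `"paired_agreement"` with counts `pp`, `pn`,
#'   `np`, `nn` ((rater1, rater2) = (+,+), (+,-), (-,+), (-,-)).
#' @export
paired_agreement_table <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  ok <- c("positive", "negative")
  if (!all(v1 %in% ok) || !all(v2 %in% ok)) {
    stop("verdicts must be 'positive'/'negative'")
  }
  agreement_counts(pp = sum(v1 == "positive" & v2 == "positive"),
                   pn = sum(v1 == "positive" & v2 == "negative"),
                   np = sum(v1 == "negative" & v2 == "positive"),
                   nn = sum(v1 == "negative" & v2 == "negative"))
}

#' @rdname paired_agreement_table
#' @param pp,pn,np,nn Non-negative counts of the four verdict pairs.
#' @export
agreement_counts <- function(pp, pn, np, nn) {
  counts <- c(pp = pp, pn = pn, np = np, nn = nn)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("pp, pn, np, nn must be non-negative integers")
  }
  if (sum(counts) == 0) stop("agreement table must have at least one pair")
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "paired_agreement")
}

kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0.2) "poor"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "good"
  else "perfect"
}

#' Cohen's kappa for two raters' dichotomous calls
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement and p_e the marginal-product chance agreement.
#' The band follows the conventional cut-points: poor <= 0.2, fair
#' 0.21-0.4, moderate 0.41-0.6, good 0.61-0.8, perfect 0.81-1.
#'
#' @param t A `"paired_agreement"` table from [paired_agreement_table()] or
#'   [agreement_counts()].
#' @return Object of class `"agreement_result"`: `kappa` (exact),
#'   `kappa_rounded` (2 decimals), `p_o`, `p_e`, `band`. When p_e = 1
#'   (both raters constant) kappa is undefined and returned `NA` with band
#'   `NA`.
#' @export
#' @examples
#' cohen_kappa(agreement_counts(pp = 141, pn = 33, np = 55, nn = 283))
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "paired_agreement"))
  pp <- as.numeric(t$pp); pn <- as.numeric(t$pn)
  np <- as.numeric(t$np); nn <- as.numeric(t$nn)
  n <- pp + pn + np + nn
  p_o <- (pp + nn) / n
  p_e <- ((pp + pn) * (pp + np) + (np + nn) * (pn + nn)) / n^2
  if (p_e >= 1) {
    kappa <- NA_real_
    warning("chance agreement p_e = 1; kappa undefined")
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa,
                 kappa_rounded = round_half_away(kappa, 2L),
                 p_o = p_o, p_e = p_e, band = kappa_band(kappa), n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%s agreement), p_o = %.4f, p_e = %.4f, n = %.0f\n",
              x$kappa, x$band, x$p_o, x$p_e, x$n))
  invisible(x)
}

normalize_truth <- function(truth, positive = "malignant") {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  truth == positive
}

#' Empirical ROC curve over ordinal scores
#'
#' Builds the empirical ROC of an ordinal score (e.g. BI-RADS rank or the
#' number of malignant planes) against pathology, with one operating point
#' per achievable threshold "score >= v" for each distinct observed level v,
#' plus the (0,0) endpoint. The AUC is the trapezoidal area, which equals
#' the tie-corrected pairwise statistic (concordant pairs + half ties) /
#' (n_pos * n_neg). The standard error is the Hanley-McNeil formula.
#'
#' @param scores Numeric (or ordered-coercible) vector of scores, higher
#'   meaning more suspicious.
#' @param truth Pathology labels: `"malignant"`/`"benign"`, logical, or 0/1.
#' @param positive Label in `truth` counted as diseased when `truth` is
#'   character (default `"malignant"`).
#' @return Object of class `"roc_result"`: `points` (data.frame `fpr`,
#'   `tpr`, `threshold`; threshold `Inf` for the (0,0) endpoint), `auc`,
#'   `se_auc`, `n_pos`, `n_neg`, `youden_j`, `optimal_cutoff`, and
#'   `levels`, the sorted distinct score values.
#' @seealso [youden_optimal()], [hanley_mcneil_se()], [compare_auc_paired()]
#' @export
#' @examples
#' empirical_roc(c(3, 2, 2, 1, 2, 0), rep(c("malignant", "benign"), each = 3))
empirical_roc <- function(scores, truth, positive = "malignant") {
  stopifnot(length(scores) == length(truth))
  if (anyNA(scores) || anyNA(truth)) stop("scores and truth must not contain NA")
  pos <- normalize_truth(truth, positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to draw a ROC curve")
  }
  scores <- as.numeric(scores)
  lv <- sort(unique(scores))
  tpr <- vapply(lv, function(v) mean(scores[pos] >= v), numeric(1))
  fpr <- vapply(lv, function(v) mean(scores[!pos] >= v), numeric(1))
  # thresholds in decreasing order give points from (0,0) to (1,1)
  pts <- data.frame(fpr = c(0, rev(fpr)), tpr = c(0, rev(tpr)),
                    threshold = c(Inf, rev(lv)))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  roc <- structure(list(points = pts, auc = auc,
                        se_auc = hanley_mcneil_se(auc, n_pos, n_neg),
                        n_pos = n_pos, n_neg = n_neg, levels = lv,
                        youden_j = NA_real_, optimal_cutoff = NA_real_),
                   class = "roc_result")
  if (length(lv) >= 2) {
    opt <- youden_optimal(roc)
    roc$youden_j <- opt$j
    roc$optimal_cutoff <- opt$cutoff
  }
  roc
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (SE %.4f), %d positive / %d negative\n",
              x$auc, x$se_auc, x$n_pos, x$n_neg))
  if (!is.na(x$youden_j)) {
    cat(sprintf("  Youden J = %.4f at cutoff %.2f\n", x$youden_j,
                x$optimal_cutoff))
  }
  invisible(x)
}

#' @export
#' @rdname empirical_roc
#' @param x,y,... Plot method arguments (passed to [graphics::plot()]).
plot.roc_result <- function(x, y, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "b", pch = 16,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' SE^2 = (A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)) /
#' (n_pos * n_neg), with Q1 = A/(2-A) and Q2 = 2A^2/(1+A).
#'
#' @param auc Area under the curve, in `[0, 1]`.
#' @param n_pos,n_neg Numbers of diseased and non-diseased cases (>= 1).
#' @return Non-negative standard error.
#' @export
#' @examples
#' hanley_mcneil_se(0.84, n_pos = 200, n_neg = 312)
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (is.na(auc) || auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be >= 1")
  n_pos <- as.numeric(n_pos); n_neg <- as.numeric(n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' Compare two (possibly correlated) AUCs by the Hanley-McNeil z-test
#'
#' z = (auc1 - auc2) / sqrt(se1^2 + se2^2 - 2 r se1 se2), with a two-sided
#' normal p-value. `r` is the correlation induced by reading the two
#' modalities on the same lesions; `r = 0` reduces to the unpaired
#' comparison. Estimate `r` from the ratings with
#' [estimate_paired_auc_correlation()] when it is not known.
#'
#' @param auc1,auc2 The two AUCs.
#' @param se1,se2 Their standard errors (e.g. [hanley_mcneil_se()]).
#' @param r Correlation between the two AUC estimates, in `[-1, 1]`.
#' @return A test-result object with `statistic` (z), `p_value`, `method`,
#'   and the AUC difference `estimate`. A zero denominator gives an
#'   undefined z (`NA`) with p `NA`.
#' @export
#' @examples
#' compare_auc_paired(0.84, 0.76, 0.019, 0.022, r = 0.4)
compare_auc_paired <- function(auc1, auc2, se1, se2, r = 0) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be non-negative")
  if (is.na(r) || r < -1 || r > 1) stop("r must lie in [-1, 1]")
  denom2 <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (denom2 <= 0) {
    if (auc1 == auc2) {
      return(test_result(0, 1, "hanley_mcneil_z", estimate = 0, r = r))
    }
    warning("zero variance of the AUC difference; z undefined")
    return(test_result(NA_real_, NA_real_, "hanley_mcneil_z",
                       estimate = auc1 - auc2, r = r))
  }
  z <- (auc1 - auc2) / sqrt(denom2)
  test_result(z, 2 * stats::pnorm(-abs(z)), "hanley_mcneil_z",
              estimate = auc1 - auc2, r = r)
}

#' Estimate the paired-AUC correlation input from the ratings
#'
#' The correlated-AUC z-test needs the correlation between the two AUC
#' estimates, which the usual tabulations derive from the rating
#' correlation. This estimator averages the Spearman rank correlations of
#' the two score vectors computed separately within the diseased and
#' non-diseased classes, then clips the average to `[0, 1]` (a negative
#' rating correlation is treated as no correlation for variance purposes,
#' which is conservative). A class in which either score vector is constant
#' contributes no term and raises a warning.
#'
#' @param scores1,scores2 Aligned ordinal score vectors from the two
#'   modalities on the same lesions.
#' @inheritParams empirical_roc
#' @return Estimated correlation in `[0, 1]`. If both classes are
#'   degenerate, 0 is returned with a warning.
#' @export
estimate_paired_auc_correlation <- function(scores1, scores2, truth,
                                            positive = "malignant") {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(truth))
  pos <- normalize_truth(truth, positive)
  if (!any(pos) || !any(!pos)) stop("both classes must be present")
  one_class <- function(idx, label) {
    s1 <- scores1[idx]; s2 <- scores2[idx]
    if (length(unique(s1)) < 2 || length(unique(s2)) < 2) {
      warning("constant scores within the ", label,
              " class; its correlation term is dropped")
      return(NA_real_)
    }
    stats::cor(s1, s2, method = "spearman")
  }
  terms <- c(one_class(pos, "diseased"), one_class(!pos, "non-diseased"))
  if (all(is.na(terms))) {
    warning("both classes degenerate; returning r = 0")
    return(0)
  }
  min(max(mean(terms, na.rm = TRUE), 0), 1)
}

#' Youden-index optimal cutoff of an empirical ROC
#'
#' Maximizes J = sensitivity + specificity - 1 over the interior operating
#' points (thresholds lying strictly between two observed score levels).
#' The cutoff is reported as the midpoint of the two adjacent achievable
#' score values bracketing the maximizing threshold — on a 0-4
#' malignant-plane-count scale this yields half-integer cutoffs such as
#' 1.5 or 2.5. Ties in J are broken toward the cutoff with higher
#' sensitivity (the lower threshold).
#'
#' @param roc A `"roc_result"` from [empirical_roc()].
#' @return List with `cutoff` and `j`.
#' @export
#' @examples
#' r <- empirical_roc(c(4, 3, 3, 2, 1, 1, 0, 2),
#'                    rep(c("malignant", "benign"), each = 4))
#' youden_optimal(r)
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  lv <- roc$levels
  if (length(lv) < 2) {
    stop("no interior operating point: scores take a single value")
  }
  pts <- roc$points
  # interior thresholds: ">= lv[i]" for i >= 2 (cutoff between lv[i-1], lv[i])
  idx <- match(lv[-1], pts$threshold)
  j <- pts$tpr[idx] - pts$fpr[idx]
  # ties broken toward higher sensitivity, i.e. the lowest tied threshold
  best <- min(which(j == max(j)))
  list(cutoff = (lv[best] + lv[best + 1]) / 2, j = max(j))
}

#' Compare two independent proportions
#'
#' Two-sided chi-square test without continuity correction by default,
#' falling back to Fisher's exact conditional test when any expected cell
#' count is 5 or less.
#'
#' @param a,n1 Successes and trials in group 1.
#' @param b,n2 Successes and trials in group 2.
#' @return A test-result object with the two sample proportions in
#'   `estimate`.
#' @export
#' @examples
#' compare_proportions(44, 115, 27, 70)
compare_proportions <- function(a, n1, b, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (a < 0 || a > n1 || b < 0 || b > n2) {
    stop("successes must lie within their trial counts")
  }
  m <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  est <- c(a / n1, b / n2)
  if (any(expected <= 5)) {
    p <- stats::fisher.test(m)$p.value
    test_result(NA_real_, p, "fisher_exact", estimate = est)
  } else {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    test_result(unname(ht$statistic), ht$p.value, "chi_square",
                estimate = est)
  }
}
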