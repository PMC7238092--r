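#' Printed summary tables of the reference reader study
#'
#' The package ships the published contingency counts of the prospective
#' breast-ultrasound reader study its design follows (512 surgically
#' confirmed lesions, 200 malignant / 312 benign; a novice and an
#' experienced reader each reading without CAD and in combined-CAD mode
#' with the quadri-planes rule; stand-alone CAD under both fusion rules).
#' Lesion-level data were never released, so these aggregate tables are
#' the study's reproducible data surface.
#'
#' * `study_mode_counts()`: the 2x2 counts (tp, fn, fp, tn vs pathology)
#'   of all six diagnostic modes.
#' * `study_reader_agreement()`: paired verdict counts of the experienced
#'   reader (without CAD, rater 1) against the novice reader (rater 2) in
#'   each novice reading mode; `pp` = both positive, `pn` = experienced
#'   positive / novice negative, etc.
#' * `study_decision_changes()`: per reader, the counts of lesions whose
#'   category crossed the 4A/4B boundary under CAD adjustment, split by
#'   direction and correctness, with `n_changed` the reader's total.
#'
#' @return A data.frame (see above).
#' @name study_fixtures
NULL

study_fixture <- function(file) {
  path <- system.file("extdata", file, package = "quadriplanes",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname study_fixtures
#' @export
study_mode_counts <- function() study_fixture("study_mode_counts.csv")

#' @rdname study_fixtures
#' @export
study_reader_agreement <- function() {
  study_fixture("study_reader_agreement.csv")
}

#' @rdname study_fixtures
#' @export
study_decision_changes <- function() {
  study_fixture("study_decision_changes.csv")
}

#' Recompute the reference study's result tables from its printed counts
#'
#' Feeds the packaged fixtures back through the package's statistics: the
#' metric panel of all six modes from [metrics_from_table()], the reader
#' agreement kappas from [cohen_kappa()], and the decision-change
#' proportion comparisons from [compare_proportions()]. Two printed cells
#' are known not to round-trip and are reported at their computed values:
#' the experienced reader's without-CAD specificity computes 92.9 from
#' 290/312 where 93.0 was printed, and the without-CAD reader kappa
#' computes 0.5648 where 0.57 was printed.
#'
#' @param dir Optional directory; when given, the tables are also written
#'   there as CSV/JSON.
#' @return List with `metric_panel` (mode x metric percent table plus exact
#'   proportions), `agreement` (kappa per novice mode), and
#'   `decision_changes` (per-direction proportions and tests).
#' @export
#' @examples
#' rep <- reproduce_study()
#' rep$metric_panel
reproduce_study <- function(dir = NULL) {
  counts <- study_mode_counts()
  panel <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    m <- metrics_from_table(contingency_2x2(tp = counts$tp[i],
                                            fp = counts$fp[i],
                                            fn = counts$fn[i],
                                            tn = counts$tn[i]))
    data.frame(mode = counts$mode[i], metric = m$metric,
               proportion = m$proportion, percent = m$percent,
               stringsAsFactors = FALSE)
  }))

  agr <- study_reader_agreement()
  agreement <- do.call(rbind, lapply(seq_len(nrow(agr)), function(i) {
    k <- cohen_kappa(agreement_counts(pp = agr$pp[i], pn = agr$pn[i],
                                      np = agr$np[i], nn = agr$nn[i]))
    data.frame(novice_mode = agr$novice_mode[i], kappa = k$kappa,
               kappa_rounded = k$kappa_rounded, band = k$band,
               stringsAsFactors = FALSE)
  }))

  chg <- study_decision_changes()
  readers <- unique(chg$reader)
  stopifnot(length(readers) == 2)
  n1 <- chg$n_changed[chg$reader == readers[1]][1]
  n2 <- chg$n_changed[chg$reader == readers[2]][1]
  changes <- do.call(rbind, lapply(split(chg, chg$direction), function(d) {
    d <- d[match(readers, d$reader), ]
    do.call(rbind, lapply(c("correct", "incorrect"), function(kind) {
      a <- d[[kind]][1]; b <- d[[kind]][2]
      tst <- compare_proportions(a, n1, b, n2)
      data.frame(direction = d$direction[1], outcome = kind,
                 count1 = a, n1 = n1, prop1 = a / n1,
                 count2 = b, n2 = n2, prop2 = b / n2,
                 p_value = tst$p_value, method = tst$method,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(changes) <- NULL
  attr(changes, "readers") <- readers
  # overall rate of decision changes, out of all 512 lesions
  n_total <- sum(study_mode_counts()[1, c("tp", "fn", "fp", "tn")])
  overall <- compare_proportions(n1, n_total, n2, n_total)
  out <- list(metric_panel = panel, agreement = agreement,
              decision_changes = changes,
              overall_change_test = list(count1 = n1, count2 = n2,
                                         n = n_total,
                                         p_value = overall$p_value,
                                         method = overall$method),
              n_lesions = n_total)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(panel, file.path(dir, "metric_panel.csv"),
                     row.names = FALSE)
    utils::write.csv(agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(changes, file.path(dir, "decision_changes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(dir, "reproduction.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
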