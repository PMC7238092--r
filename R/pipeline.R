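reader_without_columns <- function(cohort) {
  grep("_without$", names(cohort), value = TRUE)
}

#' Read and validate a lesion-cohort CSV
#'
#' Schema: columns `lesion_id`, `pathology` (`malignant`/`benign`),
#' `plane_call_long`, `plane_call_trans` and optionally `plane_call_obl_a`,
#' `plane_call_obl_b` (values `M`/`B`), plus one `<reader>_without` BI-RADS
#' category column (values `3`, `4A`, `4B`, `4C`, `5`) per reader.
#' Validation is strict: unknown category or call labels, duplicate lesion
#' ids and missing headers are rejected with the offending row and field
#' named.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("lesion_id", "pathology", "plane_call_long",
                "plane_call_trans")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("cohort CSV has no data rows")
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  dup <- df$lesion_id[duplicated(df$lesion_id)]
  if (length(dup)) {
    stop("duplicate lesion_id: ", paste(unique(dup), collapse = ", "))
  }
  check_values <- function(col, allowed) {
    if (is.null(df[[col]])) return(invisible())
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad)) {
      stop(sprintf("invalid value '%s' in field '%s' at row %d",
                   df[[col]][bad[1]], col, bad[1]))
    }
  }
  check_values("pathology", c("malignant", "benign"))
  for (col in intersect(plane_columns(), names(df))) {
    check_values(col, c("M", "B"))
  }
  readers <- reader_without_columns(df)
  if (!length(readers)) {
    stop("cohort needs at least one '<reader>_without' category column")
  }
  for (col in readers) check_values(col, birads_levels())
  invisible(df)
}

#' @rdname read_cohort_csv
#' @param cohort A cohort data.frame (e.g. from [simulate_cohort()]).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

cohort_plane_matrix <- function(cohort, method) {
  cols <- if (method == "cross_planes") plane_columns()[1:2] else plane_columns()
  absent <- setdiff(cols, names(cohort))
  if (length(absent)) {
    stop("cohort lacks plane column(s) required by the ", method,
         " method: ", paste(absent, collapse = ", "))
  }
  as.matrix(cohort[cols])
}

#' Evaluate every diagnostic mode of a cohort against pathology
#'
#' Builds, with pathology as the gold standard: the stand-alone CAD
#' verdicts under the cross-planes (any of 2) and quadri-planes (2 of 4)
#' fusion rules; each reader's without-CAD dichotomized verdict; and each
#' reader's combined-CAD verdict (category adjusted by the quadri fusion,
#' then dichotomized). For every mode it tabulates the 2x2 counts, the
#' metric panel and the ordinal-score ROC (malignant-plane counts for CAD,
#' BI-RADS rank for readers). Paired comparisons (McNemar on sensitivity,
#' specificity and accuracy; Hanley-McNeil z on AUCs with the rating-based
#' correlation estimate), reader agreement kappas and the per-reader
#' decision-change audit complete the report.
#'
#' @param cohort A cohort data.frame as returned by [read_cohort_csv()] or
#'   [simulate_cohort()].
#' @param combined_cross Also evaluate combined reader+CAD modes under the
#'   cross-planes rule (off by default; combined reading is defined on the
#'   quadri rule).
#' @return Object of class `"study_report"`; see Details. Deterministic
#'   given the input.
#' @details The returned list has elements `n`, `n_malignant`, `n_benign`;
#'   `modes` (per mode: `verdict`, `scores`, `table`, `metrics`, `roc`);
#'   `mcnemar` (data.frame of paired-mode tests); `auc_comparisons`;
#'   `agreement` (pairwise reader-mode kappas); `decision_changes` (per
#'   reader, from [decision_change_audit()]).
#' @export
evaluate_modes <- function(cohort, combined_cross = FALSE) {
  validate_cohort(cohort)
  truth <- cohort$pathology
  if (!any(truth == "malignant") || !any(truth == "benign")) {
    stop("cohort must contain both malignant and benign lesions")
  }
  rule_cross <- fusion_rule("cross_planes")
  rule_quadri <- fusion_rule("quadri_planes")
  cross_m <- cohort_plane_matrix(cohort, "cross_planes")
  quadri_m <- cohort_plane_matrix(cohort, "quadri_planes")

  modes <- list()
  add_mode <- function(name, verdict, scores) {
    modes[[name]] <<- list(
      verdict = verdict, scores = scores,
      table = table_from_verdicts(verdict, truth),
      metrics = metrics_from_table(table_from_verdicts(verdict, truth)),
      roc = empirical_roc(scores, truth))
  }
  add_mode("cad_cross", cad_standalone_verdict(cross_m, rule_cross),
           count_malignant_planes(cross_m, rule_cross))
  add_mode("cad_quadri", cad_standalone_verdict(quadri_m, rule_quadri),
           count_malignant_planes(quadri_m, rule_quadri))

  readers <- sub("_without$", "", reader_without_columns(cohort))
  combined_cats <- list()
  for (r in readers) {
    cats <- cohort[[paste0(r, "_without")]]
    add_mode(paste0(r, "_without"), dichotomize_category(cats),
             birads_rank(cats))
    adj <- adjust_category(cats, quadri_m, rule_quadri)
    combined_cats[[r]] <- adj
    add_mode(paste0(r, "_combined"), dichotomize_category(adj),
             birads_rank(adj))
    if (combined_cross) {
      adj2 <- adjust_category(cats, cross_m, rule_cross)
      add_mode(paste0(r, "_combined_cross"), dichotomize_category(adj2),
               birads_rank(adj2))
    }
  }

  pairs <- list(c("cad_cross", "cad_quadri"))
  for (r in readers) {
    pairs <- c(pairs, list(c(paste0(r, "_without"), paste0(r, "_combined"))))
  }
  mcnemar <- do.call(rbind, lapply(pairs, function(p) {
    compare_modes_mcnemar(modes[[p[1]]]$verdict, modes[[p[2]]]$verdict,
                          truth, p[1], p[2])
  }))
  auc_cmp <- do.call(rbind, lapply(pairs, function(p) {
    r1 <- modes[[p[1]]]$roc; r2 <- modes[[p[2]]]$roc
    rr <- estimate_paired_auc_correlation(modes[[p[1]]]$scores,
                                          modes[[p[2]]]$scores, truth)
    tst <- compare_auc_paired(r1$auc, r2$auc, r1$se_auc, r2$se_auc, rr)
    data.frame(mode1 = p[1], mode2 = p[2], auc1 = r1$auc, auc2 = r2$auc,
               r = rr, z = tst$statistic, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  }))

  reader_modes <- grep("^cad_", names(modes), value = TRUE, invert = TRUE)
  agreement <- NULL
  if (length(reader_modes) > 1) {
    cmb <- utils::combn(reader_modes, 2)
    agreement <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      k <- cohen_kappa(paired_agreement_table(modes[[a]]$verdict,
                                              modes[[b]]$verdict))
      data.frame(mode1 = a, mode2 = b, kappa = k$kappa,
                 kappa_rounded = k$kappa_rounded, band = k$band,
                 stringsAsFactors = FALSE)
    }))
  }

  changes <- lapply(readers, function(r) {
    decision_change_audit(cohort[[paste0(r, "_without")]],
                          combined_cats[[r]], truth)
  })
  names(changes) <- readers

  structure(list(n = nrow(cohort),
                 n_malignant = sum(truth == "malignant"),
                 n_benign = sum(truth == "benign"),
                 modes = modes, mcnemar = mcnemar,
                 auc_comparisons = auc_cmp, agreement = agreement,
                 decision_changes = changes),
            class = "study_report")
}

# McNemar comparisons of two modes: sensitivity (paired on malignant
# lesions), specificity (benign lesions), accuracy (all lesions, paired on
# correct/incorrect). PPV and NPV have mode-dependent denominators and admit
# no per-lesion pairing, so no McNemar test is reported for them.
compare_modes_mcnemar <- function(v1, v2, truth, name1, name2) {
  rows <- lapply(c("sensitivity", "specificity", "accuracy"), function(met) {
    if (met == "sensitivity") {
      idx <- truth == "malignant"; hit <- "positive"
    } else if (met == "specificity") {
      idx <- truth == "benign"; hit <- "negative"
    } else {
      idx <- rep(TRUE, length(truth)); hit <- NULL
    }
    ok1 <- if (is.null(hit)) correct_verdict(v1, truth) else v1[idx] == hit
    ok2 <- if (is.null(hit)) correct_verdict(v2, truth) else v2[idx] == hit
    if (is.null(hit)) { ok1 <- ok1; ok2 <- ok2 } # accuracy: all lesions
    b <- sum(ok1 & !ok2); cc <- sum(!ok1 & ok2)
    tst <- mcnemar_test(b, cc)
    data.frame(mode1 = name1, mode2 = name2, metric = met, b = b, c = cc,
               p_value = tst$p_value, method = tst$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

correct_verdict <- function(v, truth) {
  (v == "positive") == (truth == "malignant")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d lesions (%d malignant, %d benign)\n",
              x$n, x$n_malignant, x$n_benign))
  panel <- metric_panel(x)
  print(panel, row.names = FALSE)
  invisible(x)
}

#' Metric panel of a study report
#'
#' One row per diagnostic mode with the five percent-formatted metrics and
#' the AUC, mirroring the layout of a reader-study results table.
#'
#' @param report A `"study_report"` from [evaluate_modes()].
#' @return data.frame with columns `mode`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percent strings) and `auc`.
#' @export
metric_panel <- function(report) {
  do.call(rbind, lapply(names(report$modes), function(nm) {
    m <- report$modes[[nm]]$metrics
    row <- as.data.frame(as.list(stats::setNames(m$percent, m$metric)),
                         stringsAsFactors = FALSE)
    cbind(data.frame(mode = nm, stringsAsFactors = FALSE), row,
          data.frame(auc = round(report$modes[[nm]]$roc$auc, 2)))
  }))
}

#' Audit management-decision changes between reading modes
#'
#' Counts lesions whose BI-RADS category crossed the 4A/4B management
#' boundary when the reader's category was adjusted by the CAD verdict.
#' An upgrade 4A -> 4B is correct iff the lesion is malignant; a downgrade
#' 4B -> 4A is correct iff it is benign. (One-level adjustment means these
#' are the only boundary-crossing changes.)
#'
#' @param without_cats,adjusted_cats Aligned BI-RADS category vectors for
#'   the without-CAD and combined-CAD reading modes.
#' @param pathology Aligned `"malignant"`/`"benign"` gold-standard labels.
#' @return List of class `"decision_audit"`: `upgraded_correct`,
#'   `upgraded_incorrect`, `downgraded_correct`, `downgraded_incorrect`,
#'   `total_changed` (their sum).
#' @export
decision_change_audit <- function(without_cats, adjusted_cats, pathology) {
  if (length(without_cats) != length(adjusted_cats) ||
      length(without_cats) != length(pathology)) {
    stop("inputs must have equal length")
  }
  birads_rank(without_cats); birads_rank(adjusted_cats)  # validate labels
  up <- without_cats == "4A" & adjusted_cats == "4B"
  down <- without_cats == "4B" & adjusted_cats == "4A"
  mal <- pathology == "malignant"
  out <- list(upgraded_correct = sum(up & mal),
              upgraded_incorrect = sum(up & !mal),
              downgraded_correct = sum(down & !mal),
              downgraded_incorrect = sum(down & mal))
  out$total_changed <- sum(unlist(out))
  structure(out, class = "decision_audit")
}

#' @export
print.decision_audit <- function(x, ...) {
  cat(sprintf(paste0("Decision changes across the 4A/4B boundary: %d\n",
                     "  4A->4B: %d correct (malignant), %d incorrect (benign)\n",
                     "  4B->4A: %d correct (benign), %d incorrect (malignant)\n"),
              x$total_changed, x$upgraded_correct, x$upgraded_incorrect,
              x$downgraded_correct, x$downgraded_incorrect))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits a versioned machine-readable JSON report plus human-readable CSV
#' tables (mode counts, metric panel, paired comparisons, agreement,
#' decision changes). Output is deterministic for a given report: no
#' timestamps enter the files.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- do.call(rbind, lapply(names(report$modes), function(nm) {
    t <- report$modes[[nm]]$table
    data.frame(mode = nm, tp = t$tp, fn = t$fn, fp = t$fp, tn = t$tn,
               stringsAsFactors = FALSE)
  }))
  panel <- metric_panel(report)
  paths <- c(file.path(dir, "mode_counts.csv"),
             file.path(dir, "metric_panel.csv"),
             file.path(dir, "mcnemar_comparisons.csv"),
             file.path(dir, "auc_comparisons.csv"),
             file.path(dir, "decision_changes.csv"),
             file.path(dir, "report.json"))
  utils::write.csv(counts, paths[1], row.names = FALSE)
  utils::write.csv(panel, paths[2], row.names = FALSE)
  utils::write.csv(report$mcnemar, paths[3], row.names = FALSE)
  utils::write.csv(report$auc_comparisons, paths[4], row.names = FALSE)
  changes <- do.call(rbind, lapply(names(report$decision_changes), function(r) {
    cbind(data.frame(reader = r, stringsAsFactors = FALSE),
          as.data.frame(unclass(report$decision_changes[[r]])))
  }))
  utils::write.csv(changes, paths[5], row.names = FALSE)
  json <- list(schema_version = "1.0",
               n = report$n, n_malignant = report$n_malignant,
               n_benign = report$n_benign,
               mode_counts = counts, metric_panel = panel,
               mcnemar = report$mcnemar,
               auc_comparisons = report$auc_comparisons,
               decision_changes = changes)
  if (!is.null(report$agreement)) {
    utils::write.csv(report$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(dir, "agreement.csv"))
    json$agreement <- report$agreement
  }
  jsonlite::write_json(json, paths[grepl("json$", paths)][1],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
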