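#' The BI-RADS category scale used throughout the package
#'
#' The five ordinal suspicion categories assessed in this design: 3
#' (probably benign, <2% malignancy likelihood), 4A (2-10%), 4B (10-50%),
#' 4C (50-95%) and 5 (>95%). Categories are carried as character labels;
#' [birads_rank()] maps them to integer ranks 0-4 for ordering arithmetic.
#'
#' @return Character vector of the five category labels in increasing order
#'   of suspicion.
#' @export
#' @examples
#' birads_levels()
birads_levels <- function() c("3", "4A", "4B", "4C", "5")

#' Convert between BI-RADS labels and integer ranks
#'
#' `birads_rank()` maps category labels to ranks 0-4 (3 -> 0, ..., 5 -> 4);
#' `birads_category()` is the inverse. The two are a bijection on the valid
#' scale; anything outside it is an error.
#'
#' @param cat Character vector of category labels among
#'   `c("3","4A","4B","4C","5")`.
#' @param rank Integer vector of ranks in 0..4.
#' @return Integer ranks, or character labels, respectively.
#' @export
#' @examples
#' birads_rank(c("3", "4B", "5"))
#' birads_category(0:4)
birads_rank <- function(cat) {
  cat <- as.character(cat)
  r <- match(cat, birads_levels()) - 1L
  if (anyNA(r)) {
    bad <- unique(cat[is.na(r)])
    stop("invalid BI-RADS category label(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(birads_levels(), collapse = ", "), ")")
  }
  r
}

#' @rdname birads_rank
#' @export
birads_category <- function(rank) {
  rank <- as.integer(rank)
  if (anyNA(rank) || any(rank < 0L | rank > 4L)) {
    stop("BI-RADS rank must be an integer in 0..4")
  }
  birads_levels()[rank + 1L]
}

#' Map a malignant-sign count to a BI-RADS category
#'
#' Lesions with no definitive malignant ultrasound sign (irregular shape,
#' antiparallel orientation, noncircumscribed margin, microcalcification,
#' acoustic halo, posterior shadowing, surrounding-tissue abnormality) are
#' assigned category 3; 1, 2 and 3 signs give 4A, 4B and 4C; four or more
#' signs give category 5. The mapping is monotone non-decreasing in the
#' count; counts of exactly 4 take category 5 by monotone closure of the
#' 0-3 / ">4" assignment.
#'
#' @param n_signs Non-negative integer vector of malignant-sign counts.
#' @return Character vector of BI-RADS category labels.
#' @export
#' @examples
#' signs_to_category(c(0, 1, 2, 3, 4, 7))
signs_to_category <- function(n_signs) {
  if (anyNA(n_signs) || any(n_signs < 0) || any(n_signs != floor(n_signs))) {
    stop("n_signs must be non-negative integers")
  }
  birads_category(pmin(as.integer(n_signs), 4L))
}

#' Dichotomize a BI-RADS category at the 4A/4B boundary
#'
#' Categories 4B, 4C and 5 are considered positive for cancer; 3 and 4A
#' negative. This is the operating threshold used for every 2x2 table in
#' the evaluation pipeline.
#'
#' @param cat Character vector of BI-RADS category labels.
#' @return Character vector in `c("positive", "negative")`.
#' @export
#' @examples
#' dichotomize_category(c("4A", "4B", "3"))
dichotomize_category <- function(cat) {
  ifelse(birads_rank(cat) >= 2L, "positive", "negative")
}

#' Construct a plane-fusion rule
#'
#' A fusion rule states how the dichotomous per-plane CAD calls of one
#' lesion combine into a single fused verdict: positive when at least
#' `k_positive` planes are called malignant. The cross-planes method reads
#' the two orthogonal planes (longitudinal, transverse) with k = 1 (any
#' malignant plane is positive); the quadri-planes method adds two oblique
#' planes at 45 degrees and defaults to k = 2 (any 2 of 4).
#'
#' @param method `"cross_planes"` or `"quadri_planes"`.
#' @param k_positive Integer threshold of malignant planes for a positive
#'   fused verdict; defaults to 1 (cross) or 2 (quadri). Must lie in
#'   1..n_planes.
#' @return An object of class `"fusion_rule"` with fields `method`,
#'   `n_planes`, `k_positive`.
#' @export
#' @examples
#' fusion_rule("quadri_planes")
#' fusion_rule("cross_planes")
fusion_rule <- function(method = c("quadri_planes", "cross_planes"),
                        k_positive = NULL) {
  method <- match.arg(method)
  n_planes <- if (method == "cross_planes") 2L else 4L
  if (is.null(k_positive)) {
    k_positive <- if (method == "cross_planes") 1L else 2L
  }
  k_positive <- as.integer(k_positive)
  if (length(k_positive) != 1L || is.na(k_positive) ||
      k_positive < 1L || k_positive > n_planes) {
    stop("k_positive must be a single integer in 1..", n_planes)
  }
  structure(list(method = method, n_planes = n_planes,
                 k_positive = k_positive),
            class = "fusion_rule")
}

#' @export
print.fusion_rule <- function(x, ...) {
  cat(sprintf("<fusion_rule> %s: positive if >= %d of %d planes malignant\n",
              x$method, x$k_positive, x$n_planes))
  invisible(x)
}

# Normalize plane calls to "M"/"B"; accepts the long verdict labels too.
# `calls` may be a character vector (one lesion) or matrix (lesions x planes).
normalize_plane_calls <- function(calls) {
  was_vector <- is.null(dim(calls))
  m <- as.matrix(calls)
  if (was_vector) m <- matrix(m, nrow = 1L)
  v <- c("M" = "M", "B" = "B",
         "possibly_malignant" = "M", "possibly_benign" = "B",
         "malignant" = "M", "benign" = "B")
  out <- v[as.character(m)]
  if (anyNA(out)) {
    bad <- unique(as.character(m)[is.na(out)])
    stop("invalid plane call value(s): ", paste(bad, collapse = ", "),
         " (expected M/B or possibly_malignant/possibly_benign)")
  }
  matrix(out, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}

count_malignant_planes <- function(calls, rule) {
  m <- normalize_plane_calls(calls)
  if (ncol(m) != rule$n_planes) {
    stop("plane call set has ", ncol(m), " planes but the ", rule$method,
         " rule expects ", rule$n_planes)
  }
  as.integer(rowSums(m == "M"))
}

#' Fused stand-alone CAD verdict for one or more lesions
#'
#' Applies a k-of-n fusion rule to the per-plane calls: the fused verdict is
#' positive when at least `rule$k_positive` planes are called malignant.
#' Plane order is irrelevant; only the count matters.
#'
#' @param calls Character vector of plane calls (`"M"`/`"B"`, or the long
#'   labels `"possibly_malignant"`/`"possibly_benign"`) for a single lesion,
#'   or a matrix with one row per lesion and one column per plane.
#' @param rule A [fusion_rule()]. The number of columns of `calls` must
#'   match the rule's plane count.
#' @return Character vector in `c("positive", "negative")`, one per lesion.
#' @export
#' @examples
#' cad_standalone_verdict(c("M", "B"), fusion_rule("cross_planes"))
#' cad_standalone_verdict(c("M", "B", "B", "B"), fusion_rule("quadri_planes"))
cad_standalone_verdict <- function(calls, rule = fusion_rule()) {
  stopifnot(inherits(rule, "fusion_rule"))
  k <- count_malignant_planes(calls, rule)
  ifelse(k >= rule$k_positive, "positive", "negative")
}

#' Adjust a reader's BI-RADS category by the fused CAD verdict
#'
#' The combined reading mode adjusts the reader's category by one level
#' according to the fused CAD outcome: if the fusion rule fires positive
#' (>= k malignant planes) the category is increased one level (3 -> 4A,
#' 4A -> 4B, 4B -> 4C, 4C -> 5); if every plane is called benign it is
#' decreased one level (5 -> 4C, ..., 4A -> 3). Under the quadri rule a
#' lesion with exactly one malignant plane satisfies neither branch and the
#' category is unchanged. The scale saturates: category 5 is never upgraded
#' past 5 and category 3 never downgraded past 3, so the output rank always
#' lies within one level of the input.
#'
#' @inheritParams cad_standalone_verdict
#' @param cat Character vector of reader BI-RADS categories, recycled
#'   against the rows of `calls` if scalar.
#' @return Character vector of adjusted BI-RADS categories.
#' @export
#' @examples
#' adjust_category("4A", c("M", "M", "B", "B"), fusion_rule("quadri_planes"))
#' adjust_category("4C", c("B", "B", "B", "B"), fusion_rule("quadri_planes"))
adjust_category <- function(cat, calls, rule = fusion_rule()) {
  stopifnot(inherits(rule, "fusion_rule"))
  n_mal <- count_malignant_planes(calls, rule)
  r <- birads_rank(cat)
  if (length(r) == 1L) r <- rep(r, length(n_mal))
  if (length(r) != length(n_mal)) {
    stop("length of cat (", length(r), ") does not match number of lesions (",
         length(n_mal), ")")
  }
  shift <- integer(length(r))
  shift[n_mal >= rule$k_positive] <- 1L
  shift[n_mal == 0L] <- -1L
  birads_category(pmin(pmax(r + shift, 0L), 4L))
}

#' Dichotomous verdict of the combined reader+CAD reading mode
#'
#' The combined-mode verdict is the one-level category adjustment
#' ([adjust_category()]) followed by dichotomization at the 4A/4B boundary
#' ([dichotomize_category()]).
#'
#' @inheritParams adjust_category
#' @return Character vector in `c("positive", "negative")`.
#' @export
#' @examples
#' combined_mode_verdict("4A", c("M", "M", "B", "B"), fusion_rule("quadri_planes"))
combined_mode_verdict <- function(cat, calls, rule = fusion_rule()) {
  dichotomize_category(adjust_category(cat, calls, rule))
}
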