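#' Calibrate per-plane call rates to fused k-of-4 targets
#'
#' Under class-conditional independence of the planes, a per-plane positive
#' probability p gives a fused k-of-n positive rate equal to the binomial
#' tail `sum_{j>=k} C(n,j) p^j (1-p)^{n-j}`, which is continuous and
#' strictly increasing in p from 0 to 1. This inverts the tail by monotone
#' bisection, separately for the malignant arm (target fused sensitivity)
#' and the benign arm (target fused false-positive rate `1 - target_spec`),
#' to residual below 1e-9.
#'
#' @param target_sens,target_spec Fused sensitivity and specificity targets,
#'   both strictly inside (0, 1).
#' @param k Fusion threshold, in `1..n_planes`.
#' @param n_planes Number of planes (default 4).
#' @param rho Exchangeable latent inter-plane correlation under which the
#'   targets should hold; 0 (the default) gives the pure binomial-tail
#'   inversion, positive values invert [fused_positive_rate()] under the
#'   shared-latent-factor model used by [simulate_cohort()].
#' @return List with `plane_sens` and `plane_fpr`, the per-plane
#'   class-conditional positive probabilities.
#' @export
#' @examples
#' calibrate_to_fused_targets(0.875, 0.814, k = 2)
calibrate_to_fused_targets <- function(target_sens, target_spec, k = 2,
                                       n_planes = 4, rho = 0) {
  if (target_sens <= 0 || target_sens >= 1 || target_spec <= 0 ||
      target_spec >= 1) {
    stop("targets must lie strictly inside (0, 1)")
  }
  if (k < 1 || k > n_planes) stop("k must lie in 1..n_planes")
  invert_tail <- function(target) {
    stats::uniroot(function(p) fused_positive_rate(p, k, n_planes, rho) -
                     target,
                   interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  out <- list(plane_sens = invert_tail(target_sens),
              plane_fpr = invert_tail(1 - target_spec))
  resid <- c(fused_positive_rate(out$plane_sens, k, n_planes, rho) -
               target_sens,
             fused_positive_rate(out$plane_fpr, k, n_planes, rho) -
               (1 - target_spec))
  if (any(abs(resid) >= 1e-9)) stop("bisection failed to reach tolerance")
  out
}

# P(X >= k), X ~ Binomial(n, p)
binomial_tail <- function(p, k, n) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Fused k-of-n positive rate under exchangeable latent correlation
#'
#' Probability that at least `k` of `n` planes are called positive when
#' each call arises by thresholding an equicorrelated standard-normal
#' latent vector with per-plane marginal positive probability `p` and
#' pairwise latent correlation `rho`. At `rho = 0` this is the binomial
#' tail `sum_{j>=k} C(n,j) p^j (1-p)^{n-j}`; for `rho > 0` the planes are
#' conditionally independent given the shared factor and the tail is
#' integrated over it.
#'
#' @param p Per-plane marginal positive probability.
#' @param k Fusion threshold.
#' @param n Number of planes.
#' @param rho Latent correlation in `[0, 1)`.
#' @return The fused positive probability.
#' @export
#' @examples
#' fused_positive_rate(0.65, k = 2, n = 4)           # binomial tail
#' fused_positive_rate(0.65, k = 2, n = 4, rho = 0.3)
fused_positive_rate <- function(p, k, n = 4, rho = 0) {
  stopifnot(p >= 0, p <= 1, rho >= 0, rho < 1)
  if (rho == 0 || p == 0 || p == 1) return(binomial_tail(p, k, n))
  thr <- stats::qnorm(1 - p)
  f <- function(w) {
    pw <- stats::pnorm((sqrt(rho) * w - thr) / sqrt(1 - rho))
    stats::pbinom(k - 1, n, pw, lower.tail = FALSE) * stats::dnorm(w)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
}

#' Reader profile for the ordinal-probit rating model
#'
#' A simulated reader observes each lesion's latent severity plus
#' reader-specific Gaussian noise and reports the BI-RADS category by
#' comparing the noisy value against four strictly increasing thresholds
#' (the 3/4A, 4A/4B, 4B/4C and 4C/5 boundaries). Smaller `noise_sd`
#' corresponds to a more experienced reader.
#'
#' @param name Reader label, used as the column prefix in simulated cohorts.
#' @param noise_sd Non-negative standard deviation of the reader's private
#'   noise, in latent-severity units.
#' @param thresholds Numeric vector of 4 strictly increasing category
#'   boundaries on the reader's observed scale.
#' @return Object of class `"reader_profile"`.
#' @export
reader_profile <- function(name, noise_sd, thresholds) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing values")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(name = name, noise_sd = noise_sd,
                 thresholds = as.numeric(thresholds)),
            class = "reader_profile")
}

#' @rdname reader_profile
#' @description `calibrate_reader_profile()` derives the profile whose
#'   dichotomized (4A/4B boundary) operating point matches a target
#'   sensitivity/specificity pair, given the cohort's latent severity
#'   shift: the observed score is N(0, 1 + noise_sd^2) for benign and
#'   N(severity_shift, 1 + noise_sd^2) for malignant lesions, so the
#'   boundary and noise follow in closed form. The remaining three
#'   boundaries are placed at fixed offsets (-1, +0.9, +1.8 observed-scale
#'   standard deviations) around the 4A/4B boundary; they do not affect
#'   dichotomized performance.
#' @param target_sens,target_spec Without-CAD dichotomized operating point
#'   the reader should attain.
#' @param severity_shift Latent severity mean shift of malignant lesions.
#' @export
#' @examples
#' calibrate_reader_profile("experienced", 0.76, 0.93, severity_shift = 2.4)
calibrate_reader_profile <- function(name, target_sens, target_spec,
                                     severity_shift = 2.4) {
  s <- severity_shift / (stats::qnorm(target_spec) + stats::qnorm(target_sens))
  if (is.na(s) || s < 1) {
    stop("operating point unattainable: it would require negative reader ",
         "noise at this severity shift")
  }
  t_4b <- s * stats::qnorm(target_spec)
  reader_profile(name, noise_sd = sqrt(s^2 - 1),
                 thresholds = t_4b + s * c(-1, 0, 0.9, 1.8))
}

default_reader_profiles <- function(severity_shift = 2.4) {
  list(calibrate_reader_profile("novice", 0.600, 0.849, severity_shift),
       calibrate_reader_profile("experienced", 0.760, 0.930, severity_shift))
}

#' Configuration of the synthetic lesion-cohort generator
#'
#' Defaults emulate the reference reader-study conditions: 512 lesions with
#' 39.1% malignancy prevalence; per-plane CAD call rates calibrated so that
#' the 2-of-4 fused verdict attains sensitivity 87.5% and specificity 81.4%
#' under the configured inter-plane correlation (see
#' [fused_positive_rate()]); exchangeable inter-plane latent correlation
#' 0.3 (no published estimate exists for this quantity — the default is a
#' placeholder at a plausible magnitude); and two ordinal-probit readers
#' whose without-CAD operating points match the study's novice (60.0%/84.9%)
#' and experienced (76.0%/93.0%) readers.
#'
#' @param n_lesions Number of lesions (>= 1).
#' @param prevalence Probability a lesion is malignant.
#' @param plane_sens Per-plane P(call = M | malignant); default calibrated
#'   by [calibrate_to_fused_targets()].
#' @param plane_fpr Per-plane P(call = M | benign); default calibrated.
#' @param plane_rho Exchangeable latent correlation across a lesion's 4
#'   planes, in `[0, 1)`.
#' @param severity_shift Mean latent severity of malignant lesions (benign
#'   lesions have mean 0, unit variance).
#' @param cad_reader_dependence In `[0, 1]`: fraction of the planes' shared
#'   latent factor drawn from the lesion severity, coupling CAD calls to
#'   reader scores. 0 makes CAD independent of the readers given pathology.
#' @param reader_profiles List of [reader_profile()] objects.
#' @param seed Optional integer seed stored with the config and used by
#'   [simulate_cohort()] unless overridden.
#' @return Object of class `"simulation_config"`.
#' @export
#' @examples
#' simulation_config(n_lesions = 100, seed = 1)
simulation_config <- function(n_lesions = 512, prevalence = 0.391,
                              plane_sens = NULL, plane_fpr = NULL,
                              plane_rho = 0.3, severity_shift = 2.4,
                              cad_reader_dependence = 0.5,
                              reader_profiles = NULL, seed = NULL) {
  if (plane_rho < 0 || plane_rho >= 1) stop("plane_rho must lie in [0, 1)")
  if (is.null(plane_sens) || is.null(plane_fpr)) {
    # calibrated under the config's own correlation so the fused 2-of-4
    # operating point holds at any plane_rho, not only under independence
    cal <- calibrate_to_fused_targets(0.875, 0.814, k = 2, rho = plane_rho)
    if (is.null(plane_sens)) plane_sens <- cal$plane_sens
    if (is.null(plane_fpr)) plane_fpr <- cal$plane_fpr
  }
  if (is.null(reader_profiles)) {
    reader_profiles <- default_reader_profiles(severity_shift)
  }
  if (n_lesions < 1 || n_lesions != floor(n_lesions)) {
    stop("n_lesions must be a positive integer")
  }
  probs <- c(prevalence = prevalence, plane_sens = plane_sens,
             plane_fpr = plane_fpr)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cad_reader_dependence < 0 || cad_reader_dependence > 1) {
    stop("cad_reader_dependence must lie in [0, 1]")
  }
  if (!length(reader_profiles) ||
      !all(vapply(reader_profiles, inherits, logical(1), "reader_profile"))) {
    stop("reader_profiles must be a non-empty list of reader_profile objects")
  }
  nms <- vapply(reader_profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("reader names must be unique")
  structure(list(n_lesions = as.integer(n_lesions), prevalence = prevalence,
                 plane_sens = plane_sens, plane_fpr = plane_fpr,
                 plane_rho = plane_rho, severity_shift = severity_shift,
                 cad_reader_dependence = cad_reader_dependence,
                 reader_profiles = reader_profiles, seed = seed),
            class = "simulation_config")
}

#' Read or write a simulation configuration as YAML
#'
#' @param path File path of the YAML configuration.
#' @return `read_simulation_config()` returns a `"simulation_config"`;
#'   `write_simulation_config()` invisibly returns `path`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- NULL
  if (!is.null(raw$reader_profiles)) {
    profiles <- lapply(raw$reader_profiles, function(p) {
      reader_profile(p$name, p$noise_sd, unlist(p$thresholds))
    })
  }
  simulation_config(
    n_lesions = raw$n_lesions %||% 512,
    prevalence = raw$prevalence %||% 0.391,
    plane_sens = raw$plane_sens, plane_fpr = raw$plane_fpr,
    plane_rho = raw$plane_rho %||% 0.3,
    severity_shift = raw$severity_shift %||% 2.4,
    cad_reader_dependence = raw$cad_reader_dependence %||% 0.5,
    reader_profiles = profiles, seed = raw$seed)
}

#' @rdname read_simulation_config
#' @param config A `"simulation_config"`.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  out$reader_profiles <- lapply(config$reader_profiles, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plane_columns <- function() {
  c("plane_call_long", "plane_call_trans", "plane_call_obl_a",
    "plane_call_obl_b")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards; no global side effects escape.
with_local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a synthetic lesion cohort
#'
#' Each lesion draws a pathology label (Bernoulli at the configured
#' prevalence) and a standard-normal within-class severity; malignant
#' lesions' severity is shifted by `severity_shift`. The four per-plane CAD
#' calls are exchangeably correlated binaries obtained by thresholding an
#' equicorrelated latent Gaussian vector at the class-conditional quantile,
#' so the marginal positive rate is exactly `plane_sens` (malignant) or
#' `plane_fpr` (benign) at any correlation. The planes' shared latent
#' factor mixes the lesion severity (weight `cad_reader_dependence`) with
#' an independent component, inducing the positive CAD-reader dependence
#' real reading data show. Reader without-CAD BI-RADS categories come from
#' thresholding severity plus reader noise (ordinal probit).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; overrides `config$seed`. The generator runs in
#'   a private RNG stream and leaves the caller's RNG state untouched.
#' @return A data.frame of class `"synthetic_cohort"` with columns
#'   `lesion_id`, `pathology`, the four `plane_call_*` columns (`"M"`/
#'   `"B"`), and one `<reader>_without` BI-RADS category column per
#'   configured reader.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_lesions = 50), seed = 7)
#' head(cohort)
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  with_local_rng(seed, {
    n <- config$n_lesions
    malignant <- stats::rbinom(n, 1, config$prevalence) == 1
    severity_core <- stats::rnorm(n)                  # within-class, N(0,1)
    severity <- severity_core + config$severity_shift * malignant

    # planes: Z_ij = sqrt(rho) W_i + sqrt(1-rho) e_ij with W standard
    # normal; W mixes the severity core with an independent factor so the
    # class-conditional marginals stay exact
    tau <- config$cad_reader_dependence
    w <- sqrt(tau) * severity_core + sqrt(1 - tau) * stats::rnorm(n)
    rho <- config$plane_rho
    z <- sqrt(rho) * w + sqrt(1 - rho) *
      matrix(stats::rnorm(n * 4), nrow = n)
    p_call <- ifelse(malignant, config$plane_sens, config$plane_fpr)
    calls <- ifelse(z > stats::qnorm(1 - p_call), "M", "B")
    colnames(calls) <- plane_columns()

    out <- data.frame(lesion_id = sprintf("L%05d", seq_len(n)),
                      pathology = ifelse(malignant, "malignant", "benign"),
                      calls, stringsAsFactors = FALSE)
    for (rp in config$reader_profiles) {
      x <- severity + rp$noise_sd * stats::rnorm(n)
      rank <- findInterval(x, rp$thresholds)          # 0..4
      out[[paste0(rp$name, "_without")]] <- birads_category(rank)
    }
    class(out) <- c("synthetic_cohort", "data.frame")
    out
  })
}

#' Recover per-plane call rates from a cohort
#'
#' Class-conditional empirical per-plane positive rates, pooled across the
#' four exchangeable planes. Used as a parameter-recovery check against the
#' generating configuration.
#'
#' @param cohort A cohort data.frame with `pathology` and the four
#'   `plane_call_*` columns.
#' @return List with `plane_sens_hat`, `plane_fpr_hat` (pooled), and
#'   `per_plane`, a 2 x 4 matrix of class-by-plane rates.
#' @export
recover_plane_parameters <- function(cohort) {
  cols <- plane_columns()
  if (!all(cols %in% names(cohort))) stop("cohort lacks plane call columns")
  mal <- cohort$pathology == "malignant"
  if (!any(mal) || all(mal)) stop("both pathology classes must be present")
  m <- as.matrix(cohort[cols]) == "M"
  per_plane <- rbind(malignant = colMeans(m[mal, , drop = FALSE]),
                     benign = colMeans(m[!mal, , drop = FALSE]))
  list(plane_sens_hat = mean(m[mal, ]), plane_fpr_hat = mean(m[!mal, ]),
       per_plane = per_plane)
}
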