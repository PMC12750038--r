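# Affinity-ranking assessment: Kendall tau per supertarget, the
# submission-count-weighted combination kappa_N across supertargets, the
# resampling estimate of the experimental-noise ceiling on achievable tau,
# physicochemical descriptor baselines, and the Stage 1 vs Stage 2
# comparison.
#
# Measured affinities are IC50 values (nM).  For the ceiling they are
# mapped to free energies via dG ~ RT ln IC50 with RT chosen so that a
# 3-fold IC50 error corresponds to 0.66 kcal/mol.

#' Construct an affinity dataset
#'
#' @param supertarget supertarget id
#' @param measurements named numeric vector of IC50 values (nM, > 0),
#'   names are target ids
#' @param stage 1 (before structures released) or 2 (after)
#' @return affinity_dataset
#' @export
affinity_dataset <- function(supertarget, measurements, stage = 1) {
  .assert(length(measurements) >= 2, "need >=2 measurements")
  .assert(all(measurements > 0), "IC50 values must be positive")
  .assert(!is.null(names(measurements)), "measurements must be named by target")
  .assert(stage %in% c(1, 2), "stage must be 1 or 2")
  structure(list(supertarget = supertarget, measurements = measurements,
                 stage = stage), class = "affinity_dataset")
}

#' Construct an affinity prediction
#'
#' @param group_id integer group id
#' @param supertarget supertarget id
#' @param kind `"absolute_kd"` (dissociation constants), `"relative"`
#'   (ratio of each Kd to a reference ligand's), or `"rank"` (1 =
#'   strongest binder)
#' @param values named numeric vector, names are target ids
#' @param reference for `"relative"`: the reference target id (must be
#'   among the names)
#' @return affinity_prediction
#' @export
affinity_prediction <- function(group_id, supertarget, kind, values,
                                reference = NULL) {
  kind <- match.arg(kind, c("absolute_kd", "relative", "rank"))
  .assert(!is.null(names(values)), "values must be named by target")
  if (kind == "rank") .assert(all(values > 0), "ranks must be positive")
  if (kind == "relative") {
    .assert(!is.null(reference) && reference %in% names(values),
            "relative prediction needs its reference target present")
    .assert(all(values > 0), "relative affinities must be positive ratios")
  }
  structure(list(group_id = as.integer(group_id), supertarget = supertarget,
                 kind = kind, values = values, reference = reference),
            class = "affinity_prediction")
}

#' IC50 to binding free energy
#'
#' dG = RT ln(IC50) in the dataset's native unit; RT defaults to 0.6
#' kcal/mol so that a factor-of-3 IC50 ratio maps to 0.66 kcal/mol.
#'
#' @param ic50 positive IC50 value(s)
#' @param rt RT in kcal/mol
#' @return free energy in kcal/mol (relative scale)
#' @export
ic50_to_dg <- function(ic50, rt = 0.6) {
  .assert(all(ic50 > 0), "IC50 must be positive")
  rt * log(ic50)
}

#' Normalize any prediction kind to a ranking
#'
#' Returns per-target ranks with 1 = strongest binder, so that a perfect
#' prediction yields tau = +1 against the experimental IC50 ordering.
#' Absolute and relative affinities rank ascending (smaller dissociation
#' constant = stronger); rank submissions pass through (ties averaged).
#'
#' @param pred affinity_prediction
#' @return named numeric vector of ranks
#' @export
normalize_to_ranking <- function(pred) {
  v <- pred$values
  r <- switch(pred$kind,
    absolute_kd = rank(v, ties.method = "average"),
    relative = rank(v, ties.method = "average"),
    rank = rank(v, ties.method = "average"))
  stats::setNames(as.numeric(r), names(v))
}

#' Tie-corrected Kendall tau
#'
#' tau-b between two equal-length vectors.
#'
#' @param x,y numeric vectors, length >= 2
#' @return tau in -1..1
#' @export
kendall_tau <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 2,
          "need two equal-length vectors of length >= 2")
  .assert(length(unique(x)) > 1 && length(unique(y)) > 1,
          "undefined-tau: constant input vector")
  stats::cor(x, y, method = "kendall")
}

#' Tau between a prediction and an affinity dataset
#'
#' Computed on the intersection of targets present in both, after
#' normalizing the prediction to a ranking.
#'
#' @param dataset affinity_dataset
#' @param pred affinity_prediction
#' @param blacklist target ids removed before scoring (previously
#'   disclosed values)
#' @return list(tau, n)
#' @export
affinity_tau <- function(dataset, pred, blacklist = character(0)) {
  ranks <- normalize_to_ranking(pred)
  common <- setdiff(intersect(names(ranks), names(dataset$measurements)),
                    blacklist)
  .assert(length(common) >= 2, "fewer than 2 targets in common")
  list(tau = kendall_tau(ranks[common], dataset$measurements[common]),
       n = length(common))
}

#' N-weighted Kendall tau
#'
#' kappa_N = sum(n_i tau_i) / sum(n_i): each supertarget's tau weighted by
#' the number of affinities the group submitted for it.
#'
#' @param taus per-supertarget tau values
#' @param ns matching submission counts (>= 1)
#' @return weighted tau
#' @export
n_weighted_tau <- function(taus, ns) {
  .assert(length(taus) >= 1 && length(taus) == length(ns), "need matched tau/n")
  .assert(all(ns >= 1), "weights must be >= 1")
  sum(ns * taus) / sum(ns)
}

#' Experimental-noise ceiling on Kendall tau
#'
#' Resamples the dataset `n_resamples` times, adding i.i.d. Gaussian noise
#' of standard deviation `sigma` (kcal/mol) to each free energy of the
#' comparison copy only, and computes tau of each resample against the
#' unperturbed values.  The mean over replicates estimates the best tau
#' even a perfect predictor could achieve against data with that level of
#' experimental error.
#'
#' @param dg numeric vector of free energies (kcal/mol), length >= 3
#' @param sigma assumed experimental noise, kcal/mol
#' @param n_resamples number of replicates (default 1000)
#' @param seed RNG seed (results are a pure function of inputs + seed)
#' @return object of class `ceiling_estimate`:
#'   list(mean_tau, sd_tau, sigma, n_resamples, seed)
#' @export
ceiling_tau <- function(dg, sigma, n_resamples = 1000, seed = 1) {
  .assert(length(dg) >= 3, "need >= 3 values")
  .assert(sigma >= 0, "sigma must be >= 0")
  .assert(n_resamples >= 1, "need >= 1 resample")
  taus <- withr_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      kendall_tau(dg + stats::rnorm(length(dg), 0, sigma), dg)
    }, numeric(1))
  })
  structure(list(mean_tau = mean(taus), sd_tau = stats::sd(taus),
                 sigma = sigma, n_resamples = n_resamples, seed = seed),
            class = "ceiling_estimate")
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.ceiling_estimate <- function(x, ...) {
  cat(sprintf(
    "<ceiling_estimate> mean tau %.3f (SD %.3f) at sigma %.2f kcal/mol, %d resamples\n",
    x$mean_tau, x$sd_tau, x$sigma, x$n_resamples))
  invisible(x)
}

#' Descriptor-based affinity baseline
#'
#' Ranks compounds by a physicochemical descriptor (e.g. molecular weight
#' or cLogP) with a stated direction, mirroring the naive baselines used
#' to contextualize submitted predictions.
#'
#' @param descriptors named numeric vector (target id -> descriptor)
#' @param direction `"higher_binds_tighter"` or `"lower_binds_tighter"`
#' @param supertarget supertarget id for the resulting prediction
#' @param group_id pseudo group id (default 0)
#' @return affinity_prediction of kind `"rank"`
#' @export
descriptor_baseline <- function(descriptors,
                                direction = c("higher_binds_tighter",
                                              "lower_binds_tighter"),
                                supertarget = "baseline", group_id = 0) {
  direction <- match.arg(direction)
  .assert(!is.null(names(descriptors)) && !anyNA(descriptors),
          "descriptor missing for some target")
  r <- if (direction == "higher_binds_tighter") {
    rank(-descriptors, ties.method = "average")
  } else rank(descriptors, ties.method = "average")
  affinity_prediction(group_id, supertarget, "rank",
                      stats::setNames(as.numeric(r), names(descriptors)))
}

#' Stage 1 vs Stage 2 comparison
#'
#' Summarizes the per-group tau distributions of the two stages (group
#' sets may differ; no pairing is assumed) and their difference in means.
#'
#' @param stage1 named numeric vector of per-group tau (Stage 1)
#' @param stage2 named numeric vector of per-group tau (Stage 2)
#' @return list(stage1, stage2, shift, paired_shift, n1, n2)
#' @export
stage_comparison <- function(stage1, stage2) {
  summ <- function(x) c(n = length(x), mean = mean(x),
                        median = stats::median(x), sd = stats::sd(x))
  common <- intersect(names(stage1), names(stage2))
  list(stage1 = summ(stage1), stage2 = summ(stage2),
       shift = mean(stage2) - mean(stage1),
       paired_shift = if (length(common))
         mean(stage2[common] - stage1[common]) else NA_real_,
       n1 = length(stage1), n2 = length(stage2))
}
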