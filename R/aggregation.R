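# Group-level statistics and rankings from per-target pose scores:
# skip-penalized means, success rates, best-of-models analysis, target
# difficulty, cross-supertarget consistency and LScore reliability.
#
# Scores arrive as the data.frame produced by score_cohort().  An entry is
# a "skip" when the group submitted nothing scorable for the target; a
# target is "undefined" when the reference itself cannot be scored (e.g.
# zero reference contacts) — by default such targets are removed from both
# numerator and target list, because the defect is the reference's, not
# the predictor's (set `undefined_as_skip = TRUE` to count them as skips).

#' Skip-penalized mean
#'
#' Mean over the full target list with missing targets contributing zero.
#'
#' @param scores named numeric vector (names are target ids; values in 0..1)
#' @param targets full target list
#' @return mean in 0..1
#' @export
skip_penalized_mean <- function(scores, targets) {
  .assert(length(targets) > 0, "empty target list")
  .assert(all(names(scores) %in% targets), "score for target not in list")
  filled <- stats::setNames(numeric(length(targets)), targets)
  filled[names(scores)] <- scores
  mean(filled)
}

#' Skip-penalized pose success rate
#'
#' Fraction of targets whose pose RMSD is at or below the cutoff; skipped
#' targets count as failures; the boundary value counts as a success.
#'
#' @param rmsds named numeric vector of RMSDs (Angstrom)
#' @param targets full target list
#' @param cutoff success cutoff (default 2.5 Angstrom)
#' @return fraction in 0..1
#' @export
success_rate <- function(rmsds, targets, cutoff = 2.5) {
  .assert(length(targets) > 0, "empty target list")
  .assert(all(names(rmsds) %in% targets), "rmsd for target not in list")
  sum(rmsds <= cutoff, na.rm = TRUE) / length(targets)
}

#' Best-of-models selection
#'
#' From the (up to five) models one group submitted for one target, the
#' row with the highest LDDT-PLI; ties break to the lowest model number.
#' A group that submitted only Model 1 keeps Model 1 as its best.
#'
#' @param rows data.frame of scored rows (columns lddt_pli, model_num)
#' @return the winning row, or NULL if no model was scored
#' @export
best_of_models <- function(rows) {
  rows <- rows[!is.na(rows$lddt_pli), , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  rows <- rows[order(-rows$lddt_pli, rows$model_num), , drop = FALSE]
  rows[1, , drop = FALSE]
}

# Reduce a cohort score table to one best-of-models row per (group, target).
best_model_table <- function(score_df) {
  split_key <- interaction(score_df$group_id, score_df$target_id, drop = TRUE)
  out <- lapply(split(score_df, split_key), best_of_models)
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(score_df[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Targets undefined for every group (reference defect), to be dropped.
undefined_targets <- function(score_df) {
  has_undef <- grepl("undefined-score", score_df$flags)
  by_target <- tapply(has_undef & !score_df$skipped, score_df$target_id, any)
  scored_ok <- tapply(!is.na(score_df$lddt_pli), score_df$target_id, any)
  names(by_target)[by_target & !scored_ok]
}

#' Group summaries
#'
#' One row per group: number of scored targets, skip-penalized mean
#' LDDT-PLI and success rate for Model 1, mean best-of-models LDDT-PLI
#' (also skip-penalized), and the LScore reliability tau where LScores
#' were given.
#'
#' @param score_df data.frame from [score_cohort()]
#' @param targets full target list (defaults to targets present)
#' @param success_cutoff RMSD success cutoff, Angstrom
#' @param undefined_as_skip count reference-undefined targets as skips
#'   instead of excluding them
#' @return data.frame of class `group_summary`
#' @export
group_summaries <- function(score_df, targets = NULL, success_cutoff = 2.5,
                            undefined_as_skip = FALSE) {
  targets <- targets %||% sort(unique(score_df$target_id))
  if (!undefined_as_skip) {
    targets <- setdiff(targets, undefined_targets(score_df))
    score_df <- score_df[score_df$target_id %in% targets, , drop = FALSE]
  }
  best <- best_model_table(score_df)
  m1 <- score_df[score_df$model_num == 1 & !is.na(score_df$lddt_pli), ,
                 drop = FALSE]
  groups <- sort(unique(score_df$group_id))
  rows <- lapply(groups, function(g) {
    gm1 <- m1[m1$group_id == g, , drop = FALSE]
    gbest <- best[best$group_id == g, , drop = FALSE]
    s_pli <- stats::setNames(gm1$lddt_pli, gm1$target_id)
    s_rmsd <- stats::setNames(gm1$rmsd, gm1$target_id)
    b_pli <- stats::setNames(gbest$lddt_pli, gbest$target_id)
    all_g <- score_df[score_df$group_id == g & !is.na(score_df$lddt_pli) &
                        !is.na(score_df$lscore), , drop = FALSE]
    tau <- if (nrow(all_g) >= 2 && length(unique(all_g$lscore)) > 1) {
      lscore_reliability(all_g$lscore, all_g$lddt_pli)
    } else NA_real_
    data.frame(
      group_id = g,
      n_submitted = length(unique(gm1$target_id)),
      skip_penalized_mean_lddt_pli = skip_penalized_mean(s_pli, targets),
      skip_penalized_success_rate = success_rate(s_rmsd, targets,
                                                 success_cutoff),
      best_model_mean_lddt_pli = skip_penalized_mean(b_pli, targets),
      lscore_tau = tau)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", class(out))
  out
}

#' Rank groups by a summary metric
#'
#' Descending by the chosen key; ties break to the lower group id.
#'
#' @param summaries data.frame from [group_summaries()]
#' @param key one of `skip_penalized_mean_lddt_pli`,
#'   `skip_penalized_success_rate`, `best_model_mean_lddt_pli`
#' @return the summaries reordered, with a `rank` column prepended
#' @export
rank_groups <- function(summaries, key = "skip_penalized_mean_lddt_pli") {
  valid <- c("skip_penalized_mean_lddt_pli", "skip_penalized_success_rate",
             "best_model_mean_lddt_pli")
  .assert(key %in% valid,
          paste("unknown ranking key; use one of:", paste(valid, collapse = ", ")))
  out <- summaries[order(-summaries[[key]], summaries$group_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Per-target difficulty statistics
#'
#' For each target: the mean across groups of each group's best (over
#' models) LDDT-PLI, the maximum Model 1 LDDT-PLI across groups, and the
#' maximum over all models of all groups.  Skips are excluded from the
#' mean (no skip penalty): difficulty describes the targets, not the
#' groups.
#'
#' @param score_df data.frame from [score_cohort()]
#' @return data.frame: target_id, n_groups, mean_best_lddt_pli,
#'   max_model1_lddt_pli, max_any_model_lddt_pli
#' @export
target_difficulty <- function(score_df) {
  best <- best_model_table(score_df)
  targets <- sort(unique(score_df$target_id[!is.na(score_df$lddt_pli)]))
  rows <- lapply(targets, function(t) {
    bt <- best[best$target_id == t, , drop = FALSE]
    st <- score_df[score_df$target_id == t & !is.na(score_df$lddt_pli), ,
                   drop = FALSE]
    m1 <- st$lddt_pli[st$model_num == 1]
    data.frame(target_id = t, n_groups = nrow(bt),
               mean_best_lddt_pli = mean(bt$lddt_pli),
               max_model1_lddt_pli = if (length(m1)) max(m1) else NA_real_,
               max_any_model_lddt_pli = max(st$lddt_pli))
  })
  do.call(rbind, rows)
}

#' LScore reliability
#'
#' Tie-corrected Kendall tau between a group's self-reported reliability
#' scores and the achieved LDDT-PLI over all its models, with no skip
#' penalty.  A constant LScore vector carries no ranking information and
#' raises an error (such submissions are excluded from the reliability
#' analysis).
#'
#' @param lscores numeric vector in 0..1
#' @param lddt_plis matching accuracy values
#' @return Kendall tau in -1..1
#' @export
lscore_reliability <- function(lscores, lddt_plis) {
  keep <- !is.na(lscores) & !is.na(lddt_plis)
  lscores <- lscores[keep]; lddt_plis <- lddt_plis[keep]
  .assert(length(lscores) >= 2, "need >=2 scored entries with LScores")
  .assert(length(unique(lscores)) > 1,
          "undefined-tau: constant LScore vector")
  kendall_tau(lscores, lddt_plis)
}

#' Cross-supertarget consistency
#'
#' Squared Pearson correlation of per-group non-penalized mean LDDT-PLI
#' between two supertargets, over groups meeting a minimum submission
#' count on each.  Reported for context, never used for ranking.
#'
#' @param score_df data.frame from [score_cohort()]
#' @param supertarget_map named character vector: target id -> supertarget
#' @param min_submissions minimum scored targets per group per supertarget
#' @return data.frame of pairwise r-squared values
#' @export
supertarget_consistency <- function(score_df, supertarget_map,
                                    min_submissions = 1) {
  score_df$supertarget <- supertarget_map[score_df$target_id]
  m1 <- score_df[score_df$model_num == 1 & !is.na(score_df$lddt_pli), ,
                 drop = FALSE]
  agg <- stats::aggregate(lddt_pli ~ group_id + supertarget, m1, mean)
  cnt <- stats::aggregate(lddt_pli ~ group_id + supertarget, m1, length)
  names(cnt)[3] <- "n"
  agg <- merge(agg, cnt)
  sts <- sort(unique(agg$supertarget))
  out <- NULL
  for (i in seq_along(sts)) for (j in seq_along(sts)) {
    if (i >= j) next
    a <- agg[agg$supertarget == sts[i] & agg$n >= min_submissions, ]
    b <- agg[agg$supertarget == sts[j] & agg$n >= min_submissions, ]
    common <- intersect(a$group_id, b$group_id)
    if (length(common) < 3) next
    r <- stats::cor(a$lddt_pli[match(common, a$group_id)],
                    b$lddt_pli[match(common, b$group_id)])
    out <- rbind(out, data.frame(supertarget_a = sts[i],
                                 supertarget_b = sts[j],
                                 n_groups = length(common), r_squared = r^2))
  }
  out
}
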