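# Challenge composition bookkeeping.  The shipped CSV records, per
# supertarget (one protein system grouping many individual targets), how
# many pose and affinity targets the challenge posed, how many pose
# targets were later excluded (structures that turned out to be public
# before the deadline), and how many affinity values were found to have
# been previously disclosed and were therefore removed before assessment.

#' Challenge composition table
#'
#' @param path CSV path; defaults to the table shipped with the package
#' @return data.frame, one row per supertarget
#' @export
challenge_composition <- function(path = system.file(
  "extdata", "challenge_composition.csv", package = "ligassess")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Disclosed-target blacklist
#'
#' Affinity targets whose experimental values were found in the public
#' record (patents/publications) during assessment; removed from the
#' affinity statistics before scoring.
#'
#' @param path CSV path; defaults to the shipped blacklist
#' @return data.frame with columns target_id, supertarget
#' @export
disclosed_targets <- function(path = system.file(
  "extdata", "disclosed_targets.csv", package = "ligassess")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Challenge target counts
#'
#' Arithmetic over the composition table: assessed pose targets (posed
#' minus excluded), Stage 1 affinity targets, pose targets for a chosen
#' supertarget, and affinity targets remaining after the disclosed-target
#' removals.
#'
#' @param composition data.frame from [challenge_composition()]
#' @param disclosed data.frame from [disclosed_targets()]
#' @return list(pose_targets, affinity_stage1, pose_by_supertarget,
#'   affinity_after_exclusions)
#' @export
challenge_counts <- function(composition = challenge_composition(),
                             disclosed = disclosed_targets()) {
  pose_posed <- composition$n_pose_with_affinity +
    composition$n_pose_structure_only
  pose_assessed <- pose_posed - composition$n_pose_excluded
  .assert(sum(composition$n_disclosed) == nrow(disclosed),
          "composition/disclosed tables disagree")
  list(
    pose_targets = sum(pose_assessed),
    affinity_stage1 = sum(composition$n_affinity_stage1),
    pose_by_supertarget = stats::setNames(pose_assessed,
                                          composition$protein),
    affinity_after_exclusions = sum(composition$n_affinity_stage1) -
      nrow(disclosed)
  )
}
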