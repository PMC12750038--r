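# Structural accuracy metrics for one predicted protein-ligand complex
# against a crystallographic reference:
#
#   BiSyRMSD  — binding-site superposed, symmetry-corrected ligand RMSD
#   LDDT-PLI  — local distance difference test over ligand-protein contacts,
#               with a penalty for predicted contacts absent in the crystal
#   BB-RMSD   — Calpha RMSD of binding-site residues under the site
#               superposition
#   LDDT-LP   — LDDT over binding-site ("ligand pocket") atom pairs
#
# Copies, alternate conformations, ligand symmetry (graph automorphisms)
# and chain bijections are all searched, and the best score is reported:
# LDDT-PLI from the best-LDDT-PLI pairing, RMSD (and with it BB-RMSD and
# LDDT-LP) from the best-RMSD pairing.

#' Default pose-scoring configuration
#'
#' @param site_cutoff binding-site residue cutoff, Angstrom
#' @param inclusion_radius ligand-protein contact radius, Angstrom
#' @param thresholds LDDT distance-difference thresholds, Angstrom
#' @param automorphism_cap maximum number of ligand automorphisms enumerated
#' @param include_nonpolymer include non-polymer groups (metals, glycans) as
#'   contact-environment atoms
#' @param chain_mapping try chain bijections of equal sequence and keep the
#'   best LDDT-PLI (covers homodimer symmetry)
#' @param success_cutoff RMSD defining a successful pose, Angstrom
#' @return named list of parameters
#' @export
scoring_config <- function(site_cutoff = 4.0, inclusion_radius = 4.0,
                           thresholds = c(0.5, 1, 2, 4),
                           automorphism_cap = 10000,
                           include_nonpolymer = TRUE, chain_mapping = TRUE,
                           success_cutoff = 2.5) {
  list(site_cutoff = site_cutoff, inclusion_radius = inclusion_radius,
       thresholds = sort(thresholds), automorphism_cap = automorphism_cap,
       include_nonpolymer = include_nonpolymer, chain_mapping = chain_mapping,
       success_cutoff = success_cutoff)
}

# ---------------------------------------------------------------------------
# Binding site
# ---------------------------------------------------------------------------

#' Find the binding site of a ligand instance
#'
#' A residue belongs to the site iff any of its heavy atoms lies within
#' `cutoff` of any heavy atom of the instance.  Calpha coordinates are
#' drawn from polymer residues only; at least three are required for the
#' site superposition to be defined.
#'
#' @param ref reference_complex
#' @param instance one of `ref$ligand_instances`
#' @param cutoff Angstrom (default 4)
#' @return list(residues, ca_keys, ca, atoms) where `ca` is an n x 3 matrix
#'   of reference Calpha coordinates named by residue key and `atoms` the
#'   site's heavy-atom table
#' @export
find_binding_site <- function(ref, instance, cutoff = 4.0) {
  a <- ref$protein$atoms
  key <- paste(a$chain, a$resi, a$resn, sep = ":")
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]), instance$xyz)
  dmin <- apply(d, 1, min)
  in_site <- tapply(dmin, key, min) <= cutoff
  site_keys <- names(in_site)[in_site]
  .assert(length(site_keys) > 0, "superposition-undefined: empty binding site")
  atoms <- a[key %in% site_keys, , drop = FALSE]
  akey <- paste(atoms$chain, atoms$resi, atoms$resn, sep = ":")
  ca_rows <- atoms$polymer & atoms$atom == "CA"
  .assert(sum(ca_rows) >= 3,
          "superposition-undefined: fewer than 3 site residues with Calpha")
  ca <- as.matrix(atoms[ca_rows, c("x", "y", "z")])
  rownames(ca) <- akey[ca_rows]
  list(residues = site_keys, ca_keys = akey[ca_rows], ca = ca, atoms = atoms)
}

# ---------------------------------------------------------------------------
# Kabsch superposition
# ---------------------------------------------------------------------------

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mov_pts` onto `ref_pts`
#' (correspondence by list position), constrained to a proper rotation
#' (determinant +1).  Degenerate (rank-deficient, e.g. collinear) point
#' sets are flagged; the SVD solution with sign correction is still
#' returned.
#'
#' @param ref_pts n x 3 matrix of target points
#' @param mov_pts n x 3 matrix of moving points
#' @return list(R, t, rmsd, degenerate, transform) where
#'   `transform(x)` maps an m x 3 matrix into the reference frame
#' @export
kabsch_superpose <- function(ref_pts, mov_pts) {
  ref_pts <- as.matrix(ref_pts); mov_pts <- as.matrix(mov_pts)
  .assert(nrow(ref_pts) == nrow(mov_pts) && nrow(ref_pts) >= 3,
          "need matched point lists of length >= 3")
  cr <- colMeans(ref_pts); cm <- colMeans(mov_pts)
  P <- sweep(mov_pts, 2, cm); Q <- sweep(ref_pts, 2, cr)
  H <- crossprod(P, Q)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 || (sv$d[3] / max(sv$d[1], 1e-12)) < 1e-8
  transform <- function(x) {
    sweep(sweep(as.matrix(x), 2, cm) %*% t(R), 2, cr, "+")
  }
  list(R = R, t = as.numeric(cr - R %*% cm),
       rmsd = rmsd_points(transform(mov_pts), ref_pts),
       degenerate = degenerate, transform = transform)
}

# ---------------------------------------------------------------------------
# Graph isomorphisms / automorphisms (deterministic backtracking)
# ---------------------------------------------------------------------------

# Enumerate element-preserving, adjacency-preserving mappings from graph 1
# onto graph 2 in lexicographic order of the image vector.  With both
# arguments equal this enumerates the automorphism group, identity first.
enumerate_mappings <- function(el1, adj1, el2, adj2, cap = 10000,
                               first_only = FALSE) {
  n <- length(el1)
  if (length(el2) != n || !identical(sort(el1), sort(el2))) return(list())
  deg1 <- rowSums(adj1); deg2 <- rowSums(adj2)
  out <- list()
  truncated <- FALSE
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(i) {
    if (truncated || (first_only && length(out) >= 1)) return()
    if (i > n) { out[[length(out) + 1]] <<- perm; return() }
    for (cand in seq_len(n)) {
      if (used[cand] || el2[cand] != el1[i] || deg2[cand] != deg1[i]) next
      ok <- TRUE
      if (i > 1) {
        prev <- seq_len(i - 1)
        if (any(adj1[i, prev] != adj2[cand, perm[prev]])) ok <- FALSE
      }
      if (!ok) next
      perm[i] <<- cand; used[cand] <<- TRUE
      recurse(i + 1)
      used[cand] <<- FALSE
      if (length(out) >= cap) { truncated <<- TRUE; return() }
    }
  }
  recurse(1)
  if (truncated) {
    warning(sprintf("mapping enumeration truncated at cap = %d", cap))
  }
  out
}

ligand_adjacency <- function(lig) {
  n <- n_atoms(lig)
  adj <- matrix(0L, n, n)
  if (nrow(lig$bonds) > 0) {
    adj[lig$bonds[, 1:2, drop = FALSE]] <- 1L
    adj[lig$bonds[, c(2, 1), drop = FALSE]] <- 1L
  }
  adj
}

#' Enumerate ligand automorphisms
#'
#' All atom permutations preserving element labels and bond adjacency, in
#' lexicographic order (identity first), truncated at `cap` with a warning.
#'
#' @param lig ligand
#' @param cap maximum number of permutations returned
#' @return list of integer permutation vectors
#' @export
ligand_automorphisms <- function(lig, cap = 10000) {
  adj <- ligand_adjacency(lig)
  enumerate_mappings(lig$elements, adj, lig$elements, adj, cap = cap)
}

# One element/adjacency-preserving mapping from `from` onto `to`
# (indices: map[i] is the `to`-atom corresponding to `from`-atom i),
# or NULL if the ligands are not isomorphic.
ligand_base_mapping <- function(from, to) {
  m <- enumerate_mappings(from$elements, ligand_adjacency(from),
                          to$elements, ligand_adjacency(to),
                          first_only = TRUE)
  if (length(m) == 0) NULL else m[[1]]
}

# ---------------------------------------------------------------------------
# Matching predicted atoms to reference atoms
# ---------------------------------------------------------------------------

# Lookup table pred (chain resi atom) -> row, with an optional chain map
# (named vector: reference chain -> predicted chain).
pred_atom_lookup <- function(pred_prot) {
  a <- pred_prot$atoms
  idx <- seq_len(nrow(a))
  names(idx) <- paste(a$chain, a$resi, a$atom, sep = ":")
  idx
}

map_chain <- function(chain, chain_map) {
  if (is.null(chain_map)) return(chain)
  mapped <- chain_map[chain]
  ifelse(is.na(mapped), chain, mapped)
}

# Rows in pred_prot matching reference atoms given by chain/resi/atom
# vectors; NA where absent.
match_pred_rows <- function(lookup, chain, resi, atom, chain_map = NULL) {
  key <- paste(map_chain(chain, chain_map), resi, atom, sep = ":")
  out <- lookup[key]
  unname(out)
}

# Candidate chain bijections reference -> predicted: identity plus all
# bijections among chains sharing the same residue sequence signature.
enumerate_chain_maps <- function(ref_prot, pred_prot, cap = 24) {
  sig <- function(prot, ch) {
    a <- prot$atoms[prot$atoms$chain == ch & prot$atoms$polymer, ]
    a <- a[!duplicated(a$resi), ]
    paste(a$resi, a$resn, collapse = ";")
  }
  rch <- sort(unique(ref_prot$atoms$chain))
  pch <- sort(unique(pred_prot$atoms$chain))
  maps <- list(NULL)                        # identity (match chains verbatim)
  if (length(rch) <= 1) return(maps)
  rsig <- vapply(rch, function(c) sig(ref_prot, c), character(1))
  psig <- vapply(pch, function(c) sig(pred_prot, c), character(1))
  classes <- unique(rsig)
  per_class <- lapply(classes, function(cl) {
    r <- rch[rsig == cl]; p <- pch[psig == cl]
    if (length(r) != length(p) || length(r) == 0) return(NULL)
    perms <- all_permutations(length(p))
    lapply(perms, function(pm) stats::setNames(p[pm], r))
  })
  if (any(vapply(per_class, is.null, logical(1)))) return(maps)
  combos <- Reduce(function(acc, cls) {
    out <- list()
    for (a in acc) for (b in cls) out[[length(out) + 1]] <- c(a, b)
    out
  }, per_class, accumulate = FALSE, init = list(stats::setNames(character(0), character(0))))
  for (cm in combos) {
    if (length(maps) - 1 >= cap) break
    maps[[length(maps) + 1]] <- cm
  }
  maps
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# LDDT core
# ---------------------------------------------------------------------------

#' LDDT fraction over a labelled distance set
#'
#' For every reference pair and every threshold, a check passes when the
#' model reproduces the reference distance within the threshold.  Pairs
#' without a model counterpart (NA model distance) fail all checks.  Each
#' penalty pair (a model-only contact) adds one failed check per threshold
#' to the denominator.
#'
#' @param d_ref reference distances (length n >= 1)
#' @param d_model model distances, NA where no counterpart exists
#' @param thresholds ascending thresholds, Angstrom
#' @param penalty_pairs number of model-only contacts penalized
#' @return fraction in 0..1
#' @export
lddt_core <- function(d_ref, d_model, thresholds = c(0.5, 1, 2, 4),
                      penalty_pairs = 0) {
  .assert(length(d_ref) >= 1, "undefined-score: zero reference pairs")
  .assert(length(d_model) == length(d_ref), "distance sets differ in length")
  .assert(!is.unsorted(thresholds), "thresholds must be ascending")
  dev <- abs(d_model - d_ref)
  hits <- vapply(thresholds, function(t) sum(dev <= t, na.rm = TRUE), numeric(1))
  sum(hits) / (length(thresholds) * (length(d_ref) + penalty_pairs))
}

# ---------------------------------------------------------------------------
# Metric internals (shared by score_target)
# ---------------------------------------------------------------------------

# Contact environment: reference protein heavy atoms eligible as LDDT-PLI
# partners.
contact_environment <- function(ref, include_nonpolymer = TRUE) {
  a <- ref$protein$atoms
  if (!include_nonpolymer) a <- a[a$polymer, , drop = FALSE]
  a
}

# Symmetry-corrected ligand RMSD for one (instance, pose) pairing given a
# site superposition into the reference frame.
.sym_rmsd <- function(instance, pose_xyz_ref_frame, base_map, automorphisms) {
  best <- Inf; best_aut <- 1L
  for (k in seq_along(automorphisms)) {
    a <- automorphisms[[k]]
    r <- rmsd_points(instance$xyz, pose_xyz_ref_frame[base_map[a], , drop = FALSE])
    if (r < best - 1e-15) { best <- r; best_aut <- k }
  }
  list(rmsd = best, automorphism = best_aut)
}

# Site superposition of the predicted protein onto the reference site.
# Returns NULL (with reason) when undefined.
.site_superpose <- function(site, pred_prot, lookup, chain_map) {
  parts <- strsplit(site$ca_keys, ":", fixed = TRUE)
  ch <- vapply(parts, `[`, character(1), 1)
  ri <- vapply(parts, `[`, character(1), 2)
  rows <- match_pred_rows(lookup, ch, ri, "CA", chain_map)
  ok <- !is.na(rows)
  if (sum(ok) < 3) return(NULL)
  partial <- mean(ok) < 0.5
  fit <- kabsch_superpose(site$ca[ok, , drop = FALSE],
                          as.matrix(pred_prot$atoms[rows[ok], c("x", "y", "z")]))
  fit$partial <- partial
  fit
}

#' Binding-site superposed, symmetry-corrected ligand RMSD
#'
#' @param ref reference_complex
#' @param instance reference ligand instance scored against
#' @param pred predicted_entry (protein required)
#' @param pose predicted ligand pose (graph-isomorphic to `instance`)
#' @param config see [scoring_config()]
#' @param chain_map optional named vector mapping reference chains to
#'   predicted chains
#' @return list(rmsd, automorphism, transform, partial_site)
#' @export
bisy_rmsd <- function(ref, instance, pred, pose, config = scoring_config(),
                      chain_map = NULL) {
  .assert(!protein_is_absent(pred$protein), "predicted protein absent")
  base_map <- ligand_base_mapping(instance, pose)
  .assert(!is.null(base_map), "pose not isomorphic to reference ligand")
  site <- find_binding_site(ref, instance, cutoff = config$site_cutoff)
  lookup <- pred_atom_lookup(pred$protein)
  fit <- .site_superpose(site, pred$protein, lookup, chain_map)
  .assert(!is.null(fit), "superposition-undefined: too few matching Calpha")
  auts <- ligand_automorphisms(instance, cap = config$automorphism_cap)
  pose_ref <- fit$transform(pose$xyz)
  sr <- .sym_rmsd(instance, pose_ref, base_map, auts)
  list(rmsd = sr$rmsd, automorphism = sr$automorphism, transform = fit,
       partial_site = isTRUE(fit$partial))
}

#' LDDT-PLI for one (instance, pose) pairing
#'
#' Reference contacts are (ligand heavy atom, protein heavy atom) pairs
#' within the inclusion radius in the crystal.  Model-only contacts
#' (within the radius in the model but not in the crystal) are penalized.
#' The score is maximized over ligand automorphisms.  Superposition-free.
#'
#' @inheritParams bisy_rmsd
#' @return list(score, automorphism, n_contacts, penalty_pairs)
#' @export
lddt_pli <- function(ref, instance, pred, pose, config = scoring_config(),
                     chain_map = NULL) {
  .assert(!protein_is_absent(pred$protein), "predicted protein absent")
  base_map <- ligand_base_mapping(instance, pose)
  .assert(!is.null(base_map), "pose not isomorphic to reference ligand")
  env <- contact_environment(ref, config$include_nonpolymer)
  D_ref <- cross_dist(instance$xyz, as.matrix(env[, c("x", "y", "z")]))
  contact <- D_ref <= config$inclusion_radius
  .assert(any(contact), "undefined-score: ligand has zero reference contacts")
  lookup <- pred_atom_lookup(pred$protein)
  rows <- match_pred_rows(lookup, env$chain, env$resi, env$atom, chain_map)
  pxyz <- matrix(NA_real_, nrow(env), 3)
  ok <- !is.na(rows)
  pxyz[ok, ] <- as.matrix(pred$protein$atoms[rows[ok], c("x", "y", "z")])
  D_mod_all <- cross_dist(pose$xyz, pxyz)       # rows: pose atoms; NA cols ok
  D_mod_all[, !ok] <- NA_real_
  auts <- ligand_automorphisms(instance, cap = config$automorphism_cap)
  ij <- which(contact, arr.ind = TRUE)
  best <- -1; best_aut <- 1L; best_pen <- NA_integer_
  for (k in seq_along(auts)) {
    map_a <- base_map[auts[[k]]]                # reference atom i -> pose atom
    D_mod <- D_mod_all[map_a, , drop = FALSE]
    d_model <- D_mod[ij]
    penalty <- sum(D_mod <= config$inclusion_radius & !contact, na.rm = TRUE)
    s <- lddt_core(D_ref[ij], d_model, config$thresholds, penalty)
    if (s > best + 1e-15) { best <- s; best_aut <- k; best_pen <- penalty }
  }
  list(score = best, automorphism = best_aut,
       n_contacts = nrow(ij),
       penalty_pairs = best_pen)
}

#' Binding-site accuracy: BB-RMSD and LDDT-LP
#'
#' BB-RMSD is the Calpha RMSD of site residues under the site
#' superposition used for the best-RMSD pairing.  LDDT-LP runs the LDDT
#' core over all heavy-atom pairs of the site drawn from distinct
#' residues (superposition-free, no penalty pairs).
#'
#' @param ref reference_complex
#' @param instance the instance whose site is evaluated
#' @param pred predicted_entry
#' @param config see [scoring_config()]
#' @param chain_map optional chain mapping
#' @return list(bb_rmsd, lddt_lp)
#' @export
site_metrics <- function(ref, instance, pred, config = scoring_config(),
                         chain_map = NULL) {
  site <- find_binding_site(ref, instance, cutoff = config$site_cutoff)
  lookup <- pred_atom_lookup(pred$protein)
  fit <- .site_superpose(site, pred$protein, lookup, chain_map)
  .assert(!is.null(fit), "superposition-undefined: too few matching Calpha")
  sa <- site$atoms
  rows <- match_pred_rows(lookup, sa$chain, sa$resi, sa$atom, chain_map)
  pxyz <- matrix(NA_real_, nrow(sa), 3)
  ok <- !is.na(rows)
  pxyz[ok, ] <- as.matrix(pred$protein$atoms[rows[ok], c("x", "y", "z")])
  rxyz <- as.matrix(sa[, c("x", "y", "z")])
  res_id <- paste(sa$chain, sa$resi, sep = ":")
  pair <- which(upper.tri(matrix(TRUE, nrow(sa), nrow(sa))), arr.ind = TRUE)
  pair <- pair[res_id[pair[, 1]] != res_id[pair[, 2]], , drop = FALSE]
  .assert(nrow(pair) > 0, "undefined-score: no inter-residue site pairs")
  d_ref <- sqrt(rowSums((rxyz[pair[, 1], , drop = FALSE] -
                           rxyz[pair[, 2], , drop = FALSE])^2))
  d_mod <- sqrt(rowSums((pxyz[pair[, 1], , drop = FALSE] -
                           pxyz[pair[, 2], , drop = FALSE])^2))
  list(bb_rmsd = fit$rmsd,
       lddt_lp = lddt_core(d_ref, d_mod, config$thresholds, 0))
}

# ---------------------------------------------------------------------------
# score_target
# ---------------------------------------------------------------------------

#' Score one predicted entry against a reference complex
#'
#' Evaluates all (reference instance x predicted pose) pairings and all
#' candidate chain bijections.  The reported LDDT-PLI comes from the
#' best-LDDT-PLI pairing; RMSD from the best-RMSD pairing; BB-RMSD and
#' LDDT-LP from the best-RMSD pairing's superposition.  The chain
#' bijection is chosen by best LDDT-PLI and used throughout.
#'
#' @param ref reference_complex
#' @param pred predicted_entry (not skipped, protein present)
#' @param config see [scoring_config()]
#' @param which `"drug"` scores against the drug-like instances,
#'   `"incidental"` against the incidental ligands (reported separately,
#'   never mixed into drug-like aggregates)
#' @return object of class `pose_score`, or NULL for unscorable entries
#' @export
score_target <- function(ref, pred, config = scoring_config(),
                         which = c("drug", "incidental")) {
  which <- match.arg(which)
  if (!entry_scorable(pred)) return(NULL)
  instances <- if (which == "drug") ref$ligand_instances else ref$incidental_ligands
  .assert(length(instances) >= 1, "no reference instances to score against")
  poses <- pred$ligand_poses
  for (p in poses) {
    .assert(!is.null(ligand_base_mapping(instances[[1]], p)),
            sprintf("pose %s not isomorphic to reference ligand", p$instance_id))
  }
  chain_maps <- if (isTRUE(config$chain_mapping)) {
    enumerate_chain_maps(ref$protein, pred$protein)
  } else list(NULL)

  best <- NULL
  for (cm in chain_maps) {
    res <- .score_pairings(ref, instances, pred, poses, config, cm)
    if (is.null(best) || res$lddt_pli > best$lddt_pli + 1e-15) {
      best <- res
      best$chain_map <- cm
    }
  }
  structure(c(list(target_id = ref$target_id, group_id = pred$group_id,
                   model_num = pred$model_num, lscore = pred$lscore,
                   incidental = which == "incidental"),
              best),
            class = "pose_score")
}

# All pairings for a fixed chain map.
.score_pairings <- function(ref, instances, pred, poses, config, chain_map) {
  best_pli <- -Inf; best_rmsd <- Inf
  pli_ref <- pli_pose <- rmsd_ref <- rmsd_pose <- NA_character_
  aut_used <- NA_integer_
  rmsd_pair <- NULL
  flags <- character(0)
  for (r in seq_along(instances)) {
    for (p in seq_along(poses)) {
      pli <- tryCatch(
        lddt_pli(ref, instances[[r]], pred, poses[[p]], config, chain_map),
        error = function(e) NULL)
      if (!is.null(pli) && pli$score > best_pli + 1e-15) {
        best_pli <- pli$score
        pli_ref <- instances[[r]]$instance_id
        pli_pose <- poses[[p]]$instance_id
        aut_used <- pli$automorphism
      }
      rr <- tryCatch(
        bisy_rmsd(ref, instances[[r]], pred, poses[[p]], config, chain_map),
        error = function(e) { flags <<- union(flags, conditionMessage(e)); NULL })
      if (!is.null(rr) && rr$rmsd < best_rmsd - 1e-15) {
        best_rmsd <- rr$rmsd
        rmsd_ref <- instances[[r]]$instance_id
        rmsd_pose <- poses[[p]]$instance_id
        rmsd_pair <- list(r = r, p = p)
        if (rr$partial_site) flags <- union(flags, "partial_site")
      }
    }
  }
  bb <- lp <- NA_real_
  if (!is.null(rmsd_pair)) {
    sm <- tryCatch(
      site_metrics(ref, instances[[rmsd_pair$r]], pred, config, chain_map),
      error = function(e) NULL)
    if (!is.null(sm)) { bb <- sm$bb_rmsd; lp <- sm$lddt_lp }
  }
  list(rmsd = if (is.finite(best_rmsd)) best_rmsd else NA_real_,
       lddt_pli = if (is.finite(best_pli)) best_pli else NA_real_,
       bb_rmsd = bb, lddt_lp = lp,
       matched_reference = rmsd_ref, matched_pose = rmsd_pose,
       matched_reference_pli = pli_ref, matched_pose_pli = pli_pose,
       automorphism_used = aut_used, flags = flags)
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf(
    "<pose_score %s G%d model %d> RMSD %.3f A  LDDT-PLI %.3f  BB-RMSD %.3f A  LDDT-LP %.3f\n",
    x$target_id, x$group_id, x$model_num, x$rmsd, x$lddt_pli, x$bb_rmsd,
    x$lddt_lp))
  invisible(x)
}

#' Score a cohort of entries
#'
#' Applies [score_target()] to every entry; skipped/invalid/failed entries
#' produce rows with NA metrics and a flag, never abort the run.
#'
#' @param refs named list of reference_complex (names = target ids)
#' @param entries list of predicted_entry
#' @param config see [scoring_config()]
#' @return data.frame, one row per entry: target_id, group_id, model_num,
#'   rmsd, lddt_pli, bb_rmsd, lddt_lp, lscore, skipped, flags
#' @export
score_cohort <- function(refs, entries, config = scoring_config()) {
  rows <- lapply(entries, function(e) {
    base <- data.frame(target_id = e$target_id, group_id = e$group_id,
                       model_num = e$model_num, rmsd = NA_real_,
                       lddt_pli = NA_real_, bb_rmsd = NA_real_,
                       lddt_lp = NA_real_, lscore = e$lscore,
                       skipped = TRUE, flags = paste(e$flags, collapse = ";"),
                       stringsAsFactors = FALSE)
    if (!entry_scorable(e)) return(base)
    ref <- refs[[e$target_id]]
    if (is.null(ref)) { base$flags <- "unknown_target"; return(base) }
    ps <- tryCatch(score_target(ref, e, config), error = function(err) {
      base$flags <<- conditionMessage(err); NULL
    })
    if (is.null(ps)) return(base)
    base$rmsd <- ps$rmsd; base$lddt_pli <- ps$lddt_pli
    base$bb_rmsd <- ps$bb_rmsd; base$lddt_lp <- ps$lddt_lp
    base$skipped <- FALSE
    base$flags <- paste(ps$flags, collapse = ";")
    base
  })
  out <- do.call(rbind, rows)
  out[order(out$group_id, out$target_id, out$model_num), , drop = FALSE]
}
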