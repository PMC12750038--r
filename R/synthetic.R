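# Synthetic-data generators: miniature reference complexes, perturbed
# predictions, multi-group submission cohorts and affinity datasets with
# known ground truth, so that every pipeline stage has a closed testing
# loop.  Everything is a pure function of (spec, seed).
#
# Miniature proteins are procedural: idealized residues (N, CA, C, O plus
# a pseudo side-chain atom CB) arranged around the ligand so that at
# least three residues fall inside the 4-Angstrom binding site.  Ligand
# templates are hard-coded connectivity tables with 3D coordinates: a
# benzene-like symmetric ring, an asymmetric branched chain, and a
# two-ring biphenyl-like "drug-like" hybrid with one rotatable bond.

#' Built-in ligand templates
#'
#' @param name `"ring6"` (symmetric 6-ring, 12 automorphisms),
#'   `"branched"` (asymmetric chain, identity only), or `"hybrid"`
#'   (two-ring biphenyl-like scaffold with a rotatable bridge bond)
#' @return ligand with attribute `"smiles"`
#' @export
ligand_template <- function(name = c("ring6", "branched", "hybrid")) {
  name <- match.arg(name)
  hexagon <- function(center, start_angle = 0) {
    ang <- start_angle + seq(0, 300, by = 60) * pi / 180
    cbind(center[1] + 1.4 * cos(ang), center[2] + 1.4 * sin(ang), center[3])
  }
  ring_bonds <- function(off) {
    cbind(off + 1:6, off + c(2:6, 1), rep(c(1L, 2L), 3))
  }
  lig <- switch(name,
    ring6 = {
      l <- ligand(rep("C", 6), hexagon(c(0, 0, 0)), ring_bonds(0), "ring6")
      attr(l, "smiles") <- "c1ccccc1"
      l
    },
    branched = {
      xyz <- rbind(c(-1.52, 0, 0), c(0, 0, 0), c(0.55, 1.25, 0.45),
                   c(0.75, -1.28, -0.2), c(2.15, -1.2, -0.35))
      bonds <- rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1), c(4, 5, 1))
      l <- ligand(c("C", "C", "N", "C", "O"), xyz, bonds, "branched")
      attr(l, "smiles") <- "CC(N)CO"
      l
    },
    hybrid = {
      xyz <- rbind(hexagon(c(0, 0, 0)), hexagon(c(4.3, 0, 0), pi))
      bonds <- rbind(ring_bonds(0), ring_bonds(6), c(1, 7, 1))
      l <- ligand(rep("C", 12), xyz, bonds, "hybrid")
      attr(l, "smiles") <- "c1ccc(cc1)-c1ccccc1"
      l
    })
  lig
}

# Build one idealized residue whose pseudo side-chain atom CB sits at
# `cb`, with the backbone extending outward along unit vector `u`.
.make_residue <- function(chain, resi, resn, cb, u) {
  v0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- v0 - sum(v0 * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  ca <- cb + 1.53 * u
  data.frame(chain = chain, resi = resi, resn = resn, polymer = TRUE,
             atom = c("N", "CA", "C", "O", "CB"),
             element = c("N", "C", "C", "O", "C"),
             x = c(ca[1] + 1.45 * v[1], ca[1], ca[1] - 1.52 * v[1] + 0.3 * w[1],
                   ca[1] - 1.52 * v[1] + 1.45 * w[1], cb[1]),
             y = c(ca[2] + 1.45 * v[2], ca[2], ca[2] - 1.52 * v[2] + 0.3 * w[2],
                   ca[2] - 1.52 * v[2] + 1.45 * w[2], cb[2]),
             z = c(ca[3] + 1.45 * v[3], ca[3], ca[3] - 1.52 * v[3] + 0.3 * w[3],
                   ca[3] - 1.52 * v[3] + 1.45 * w[3], cb[3]),
             stringsAsFactors = FALSE)
}

# Pocket residues enclosing a ligand: CB placed 3.2-3.9 A from a randomly
# chosen ligand heavy atom, pointing outward from the ligand centroid.
.build_pocket <- function(lig, n_res, chain, resi_start) {
  centroid <- colMeans(lig$xyz)
  rows <- list()
  for (i in seq_len(n_res)) {
    a <- lig$xyz[sample.int(nrow(lig$xyz), 1), ]
    u <- a - centroid + stats::rnorm(3, 0, 0.6)
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-6) random_unit_vector() else u / nu
    cb <- a + stats::runif(1, 3.2, 3.9) * u
    rows[[i]] <- .make_residue(chain, resi_start + i - 1,
                               sample(STANDARD_AA, 1), cb, u)
  }
  do.call(rbind, rows)
}

#' Generate a miniature reference complex
#'
#' @param seed RNG seed (NULL continues the current stream)
#' @param template ligand template name, see [ligand_template()]
#' @param pocket_size residues built around each ligand instance (>= 4)
#' @param n_copies fully occupied ligand copies (separate sites)
#' @param alt_conf add a second, rotated conformation in the same site
#' @param incidental add a chloride-like incidental ion 4.0 A from the
#'   drug-like ligand
#' @param n_far_residues residues far from any ligand (outside every site)
#' @param target_id target identifier
#' @return reference_complex
#' @export
make_complex <- function(seed = NULL, template = "hybrid", pocket_size = 8,
                         n_copies = 1, alt_conf = FALSE, incidental = FALSE,
                         n_far_residues = 4, target_id = "T1") {
  .assert(pocket_size >= 4, "pocket_size must be >= 4")
  gen <- function() {
    base <- ligand_template(template)
    smiles <- attr(base, "smiles")
    instances <- list()
    pockets <- list()
    resi <- 1L
    for (k in seq_len(n_copies)) {
      inst <- base
      shift <- c(12 * (k - 1), 0, 0)
      R <- rotation_about_axis(random_unit_vector(), stats::runif(1, 0, 2 * pi))
      ctr <- colMeans(inst$xyz)
      inst$xyz <- sweep(sweep(inst$xyz, 2, ctr) %*% t(R), 2, ctr + shift, "+")
      inst$instance_id <- paste0("inst", k)
      instances[[k]] <- inst
      pockets[[k]] <- .build_pocket(inst, pocket_size, "A", resi)
      resi <- resi + pocket_size
    }
    if (alt_conf) {
      alt <- instances[[1]]
      ctr <- colMeans(alt$xyz)
      R <- rotation_about_axis(c(0, 0, 1), 25 * pi / 180)
      alt$xyz <- sweep(sweep(alt$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
      alt$instance_id <- "alt2"
      instances[[length(instances) + 1]] <- alt
    }
    far <- lapply(seq_len(n_far_residues), function(i) {
      u <- random_unit_vector()
      .make_residue("A", resi + i - 1, sample(STANDARD_AA, 1),
                    colMeans(instances[[1]]$xyz) + (22 + 3 * i) * u, u)
    })
    atoms <- do.call(rbind, c(pockets, far))
    inc <- list()
    if (incidental) {
      a1 <- instances[[1]]$xyz[1, ]
      dir_out <- a1 - colMeans(instances[[1]]$xyz)
      dir_out <- dir_out / sqrt(sum(dir_out^2))
      inc <- list(ligand("Cl", matrix(a1 + 4.0 * dir_out, 1, 3),
                         matrix(integer(0), 0, 3), "ion1"))
    }
    ref <- reference_complex(target_id, protein_structure(atoms), instances,
                             incidental_ligands = inc)
    attr(ref, "smiles") <- smiles
    # contract: every instance's 4-A site supports a superposition
    for (inst in instances) invisible(find_binding_site(ref, inst))
    ref
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Perturb a reference into a predicted entry
#'
#' Controlled degradations with known consequences: `translate` moves the
#' ligand rigidly by exactly `magnitude` (RMSD equals `magnitude` when the
#' protein is untouched); `rotate` spins it about its centroid by
#' `magnitude` degrees; `torsion` rotates the smaller side of a rotatable
#' (bridge) bond by `magnitude` degrees (templates without one get a
#' small coordinate jitter of sd `0.05 * magnitude`); `symmetry_flip`
#' applies a non-identity graph automorphism (BiSyRMSD stays 0);
#' `rebind_site` drops the ligand on a decoy surface patch far from the
#' pocket (LDDT-PLI 0 expected).
#'
#' @param ref reference_complex
#' @param mode perturbation mode
#' @param magnitude Angstrom (translate) or degrees (rotate/torsion)
#' @param seed RNG seed (NULL continues the current stream)
#' @param protein_sigma optional Gaussian jitter (A) applied to protein
#'   atoms (default 0: protein copied verbatim)
#' @param group_id,model_num identifiers for the resulting entry
#' @param instance which reference instance to start from
#' @return predicted_entry
#' @export
perturb_pose <- function(ref, mode = c("translate", "rotate", "torsion",
                                       "symmetry_flip", "rebind_site"),
                         magnitude = 1, seed = NULL, protein_sigma = 0,
                         group_id = 1, model_num = 1, instance = 1) {
  mode <- match.arg(mode)
  .assert(magnitude >= 0, "magnitude must be >= 0")
  gen <- function() {
    pose <- ref$ligand_instances[[instance]]
    pose$instance_id <- "pose1"
    if (mode == "translate") {
      pose$xyz <- sweep(pose$xyz, 2, magnitude * random_unit_vector(), "+")
    } else if (mode == "rotate") {
      ctr <- colMeans(pose$xyz)
      R <- rotation_about_axis(random_unit_vector(), magnitude * pi / 180)
      pose$xyz <- sweep(sweep(pose$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
    } else if (mode == "torsion") {
      rb <- .rotatable_bond(pose)
      if (is.null(rb)) {
        pose$xyz <- pose$xyz + matrix(stats::rnorm(length(pose$xyz), 0,
                                                   0.05 * magnitude),
                                      ncol = 3)
      } else {
        axis <- pose$xyz[rb$j, ] - pose$xyz[rb$i, ]
        R <- rotation_about_axis(axis, magnitude * pi / 180)
        side <- rb$side
        pivot <- pose$xyz[rb$i, ]
        pose$xyz[side, ] <- sweep(sweep(pose$xyz[side, , drop = FALSE], 2,
                                        pivot) %*% t(R), 2, pivot, "+")
      }
    } else if (mode == "symmetry_flip") {
      auts <- ligand_automorphisms(pose)
      if (length(auts) > 1) pose$xyz <- pose$xyz[auts[[2]], , drop = FALSE]
    } else if (mode == "rebind_site") {
      prot_ctr <- colMeans(protein_coords(ref$protein))
      u <- random_unit_vector()
      pose$xyz <- sweep(pose$xyz, 2,
                        prot_ctr + 30 * u - colMeans(pose$xyz), "+")
    }
    prot <- ref$protein
    if (protein_sigma > 0) {
      prot$atoms[, c("x", "y", "z")] <- prot$atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(prot$atoms), 0, protein_sigma), ncol = 3)
    }
    predicted_entry(group_id, ref$target_id, model_num, protein = prot,
                    ligand_poses = list(pose))
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# A bridge bond splitting the ligand into two sides of >= 2 atoms each;
# returns NULL if none (e.g. a single ring).
.rotatable_bond <- function(lig) {
  adj <- ligand_adjacency(lig)
  n <- n_atoms(lig)
  for (b in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds[b, 1]; j <- lig$bonds[b, 2]
    adj2 <- adj; adj2[i, j] <- adj2[j, i] <- 0L
    comp <- .component_of(adj2, j)
    if (i %in% comp) next                       # bond is in a ring
    if (length(comp) >= 2 && n - length(comp) >= 2) {
      return(list(i = i, j = j, side = comp))
    }
  }
  NULL
}

.component_of <- function(adj, start) {
  seen <- logical(nrow(adj)); queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] == 1 & !seen)
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  which(seen)
}

#' Cohort specification
#'
#' @param n_targets number of targets
#' @param group_profiles data.frame with one row per group: columns
#'   sigma_pose (A), skip_prob, lscore_rho (LScore fidelity in 0..1)
#' @param ligand_templates template names cycled over targets
#' @param multi_copy_fraction fraction of targets with two ligand copies
#' @param alt_conf_fraction fraction with an alternate conformation
#' @param incidental_fraction fraction with an incidental ion
#' @param n_models models per group per target
#' @param pocket_size residues per pocket
#' @param seed RNG seed
#' @return cohort_spec
#' @export
cohort_spec <- function(n_targets = 10,
                        group_profiles = data.frame(
                          sigma_pose = c(0.3, 1.5, 4.0),
                          skip_prob = c(0, 0.1, 0.3),
                          lscore_rho = c(0.9, 0.7, 0.5)),
                        ligand_templates = c("ring6", "branched", "hybrid"),
                        multi_copy_fraction = 0.15,
                        alt_conf_fraction = 0.15,
                        incidental_fraction = 0.15,
                        n_models = 5, pocket_size = 8, seed = 1) {
  .assert(all(group_profiles$skip_prob >= 0 & group_profiles$skip_prob <= 1),
          "skip probabilities must be in [0,1]")
  .assert(all(group_profiles$sigma_pose >= 0), "sigma_pose must be >= 0")
  .assert(all(group_profiles$lscore_rho >= 0 & group_profiles$lscore_rho <= 1),
          "lscore_rho must be in [0,1]")
  .assert(length(ligand_templates) >= 1, "need >=1 ligand template")
  structure(list(n_targets = n_targets, group_profiles = group_profiles,
                 ligand_templates = ligand_templates,
                 multi_copy_fraction = multi_copy_fraction,
                 alt_conf_fraction = alt_conf_fraction,
                 incidental_fraction = incidental_fraction,
                 n_models = n_models, pocket_size = pocket_size, seed = seed),
            class = "cohort_spec")
}

#' Simulate a full submission cohort
#'
#' For every target a miniature reference complex is generated; for every
#' (group, target) the group either skips (with its profile probability)
#' or submits Models 1..n with translation+rotation noise growing with
#' the model number (Model 1 lowest-noise on average).  LScores are the
#' model's true LDDT-PLI plus Gaussian noise of sd `(1 - rho) * 0.3`,
#' clamped to 0..1.
#'
#' @param spec cohort_spec
#' @param config scoring config used for the LScore ground truth
#' @return list(refs, entries, spec): named reference list and
#'   predicted_entry list
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = scoring_config()) {
  withr_seed(spec$seed, {
    targets <- sprintf("T%03d", seq_len(spec$n_targets))
    refs <- list()
    for (t in seq_len(spec$n_targets)) {
      template <- spec$ligand_templates[((t - 1) %% length(spec$ligand_templates)) + 1]
      u <- stats::runif(3)
      refs[[targets[t]]] <- make_complex(
        seed = NULL, template = template, pocket_size = spec$pocket_size,
        n_copies = if (u[1] < spec$multi_copy_fraction) 2 else 1,
        alt_conf = u[1] >= spec$multi_copy_fraction &&
          u[2] < spec$alt_conf_fraction,
        incidental = u[3] < spec$incidental_fraction,
        target_id = targets[t])
    }
    entries <- list()
    for (g in seq_len(nrow(spec$group_profiles))) {
      prof <- spec$group_profiles[g, ]
      for (t in targets) {
        if (stats::runif(1) < prof$skip_prob) {
          entries[[length(entries) + 1]] <-
            predicted_entry(g, t, 1, skipped = TRUE)
          next
        }
        for (m in seq_len(spec$n_models)) {
          sigma_m <- prof$sigma_pose * (1 + 0.3 * (m - 1))
          ent <- perturb_pose(refs[[t]], "translate",
                              magnitude = abs(stats::rnorm(1, 0, sigma_m)),
                              group_id = g, model_num = m)
          ang <- abs(stats::rnorm(1, 0, 8 * sigma_m))
          ctr <- colMeans(ent$ligand_poses[[1]]$xyz)
          R <- rotation_about_axis(random_unit_vector(), min(ang, 180) * pi / 180)
          ent$ligand_poses[[1]]$xyz <-
            sweep(sweep(ent$ligand_poses[[1]]$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
          truth <- tryCatch(
            score_target(refs[[t]], ent, config)$lddt_pli,
            error = function(e) 0)
          ent$lscore <- min(max(truth + stats::rnorm(1, 0,
                                                     (1 - prof$lscore_rho) * 0.3),
                                0), 1)
          entries[[length(entries) + 1]] <- ent
        }
      }
    }
    list(refs = refs, entries = entries, spec = spec)
  })
}

#' Affinity simulation specification
#'
#' @param n number of targets (>= 3)
#' @param dg_span free-energy range width, kcal/mol
#' @param sigma_exp experimental noise sd, kcal/mol
#' @param group_sigmas per-group prediction noise sds, kcal/mol
#' @param rt RT (kcal/mol) for the IC50 mapping
#' @param supertarget supertarget id
#' @param seed RNG seed
#' @return affinity_sim_spec
#' @export
affinity_sim_spec <- function(n = 50, dg_span = 5.4, sigma_exp = 0.66,
                              group_sigmas = c(0.3, 1.0, 3.0), rt = 0.6,
                              supertarget = "SIM", seed = 1) {
  .assert(n >= 3, "need n >= 3")
  .assert(dg_span >= 0 && sigma_exp >= 0 && all(group_sigmas >= 0),
          "spans and sigmas must be >= 0")
  structure(list(n = n, dg_span = dg_span, sigma_exp = sigma_exp,
                 group_sigmas = group_sigmas, rt = rt,
                 supertarget = supertarget, seed = seed),
            class = "affinity_sim_spec")
}

#' Simulate an affinity dataset with group predictions
#'
#' True free energies are uniform over the span; the experimental values
#' add Gaussian noise of sd `sigma_exp`; group g predicts the truth plus
#' Gaussian noise of its own sd.  IC50s are emitted as exp(dG / RT).
#'
#' @param spec affinity_sim_spec
#' @return list(dataset, dg_true, dg_experimental, predictions, spec)
#' @export
simulate_affinity <- function(spec = affinity_sim_spec()) {
  withr_seed(spec$seed, {
    ids <- sprintf("A%03d", seq_len(spec$n))
    dg_true <- stats::runif(spec$n, 0, spec$dg_span)
    dg_exp <- dg_true + stats::rnorm(spec$n, 0, spec$sigma_exp)
    ic50 <- stats::setNames(exp(dg_exp / spec$rt), ids)
    dataset <- affinity_dataset(spec$supertarget, ic50, stage = 1)
    preds <- lapply(seq_along(spec$group_sigmas), function(g) {
      dg_g <- dg_true + stats::rnorm(spec$n, 0, spec$group_sigmas[g])
      affinity_prediction(g, spec$supertarget, "absolute_kd",
                          stats::setNames(exp(dg_g / spec$rt), ids))
    })
    list(dataset = dataset, dg_true = stats::setNames(dg_true, ids),
         dg_experimental = stats::setNames(dg_exp, ids),
         predictions = preds, spec = spec)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the same PDB/molfile/CSV/JSON layout that [read_submission_dir()]
#' and [read_reference_dir()] consume, making the generator the format
#' contract test.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  refs_dir <- file.path(dir, "refs"); subs_dir <- file.path(dir, "subs")
  for (t in names(cohort$refs)) {
    td <- file.path(refs_dir, t)
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    ref <- cohort$refs[[t]]
    write_pdb(ref$protein, file.path(td, "protein.pdb"))
    lig_files <- character(0)
    for (k in seq_along(ref$ligand_instances)) {
      f <- sprintf("ligand_%d.mol", k)
      write_molfile(ref$ligand_instances[[k]], file.path(td, f))
      lig_files <- c(lig_files, f)
    }
    inc_files <- character(0)
    for (k in seq_along(ref$incidental_ligands)) {
      f <- sprintf("incidental_%d.mol", k)
      write_molfile(ref$incidental_ligands[[k]], file.path(td, f))
      inc_files <- c(inc_files, f)
    }
    jsonlite::write_json(
      list(target_id = t, smiles = attr(ref, "smiles"),
           ligands = lig_files, incidental = inc_files),
      file.path(td, "meta.json"), auto_unbox = TRUE)
  }
  groups <- sort(unique(vapply(cohort$entries, `[[`, integer(1), "group_id")))
  ls_rows <- list()
  for (e in cohort$entries) {
    if (e$skipped) next
    td <- file.path(subs_dir, paste0("G", e$group_id), e$target_id)
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    write_pdb(e$protein, file.path(td, sprintf("model%d.pdb", e$model_num)))
    write_molfile(e$ligand_poses[[1]],
                  file.path(td, sprintf("model%d.mol", e$model_num)))
    if (!is.na(e$lscore)) {
      ls_rows[[length(ls_rows) + 1]] <-
        data.frame(group = e$group_id, target = e$target_id,
                   model = e$model_num, lscore = e$lscore)
    }
  }
  if (length(ls_rows)) {
    ls <- do.call(rbind, ls_rows)
    for (g in groups) {
      gl <- ls[ls$group == g, c("target", "model", "lscore")]
      if (nrow(gl)) {
        utils::write.csv(gl, file.path(subs_dir, paste0("G", g), "lscores.csv"),
                         row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(
    list(groups = groups, targets = names(cohort$refs),
         n_models = cohort$spec$n_models),
    file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Read back a reference directory written by [write_cohort()]
#'
#' @param refs_dir the `refs/` directory
#' @return named list of reference_complex
#' @export
read_reference_dir <- function(refs_dir) {
  targets <- list.dirs(refs_dir, recursive = FALSE)
  refs <- list()
  for (td in targets) {
    meta <- jsonlite::read_json(file.path(td, "meta.json"))
    ref <- read_reference(
      file.path(td, "protein.pdb"),
      file.path(td, unlist(meta$ligands)),
      smiles = meta$smiles, target_id = meta$target_id,
      incidental_paths = if (length(meta$incidental))
        file.path(td, unlist(meta$incidental)) else character(0))
    refs[[meta$target_id]] <- ref
  }
  refs
}
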