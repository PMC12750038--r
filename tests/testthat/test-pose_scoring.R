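cfg <- scoring_config()

test_that("binding-site membership respects the 4-A cutoff exactly", {
  lig <- ligand_template("branched")
  ref <- toy_complex_around(lig)
  # toy residues have CB at 3.5 A from the nearest ligand atom: all in site
  site <- find_binding_site(ref, lig)
  expect_length(site$residues, 5)
  # residue 1 was built along +x with its CB exactly 3.5 A from the
  # nearest ligand atom; shifting it along +x moves that distance 1:1
  a <- ref$protein$atoms
  r1 <- a$resi == 1
  d1 <- min(cross_dist(as.matrix(a[r1, c("x", "y", "z")]), lig$xyz))
  expect_equal(d1, 3.5, tolerance = 1e-9)
  ref41 <- ref
  ref41$protein$atoms[r1, "x"] <- a[r1, "x"] + (4.1 - d1)
  expect_false("A:1:ALA" %in% find_binding_site(ref41, lig)$residues)
  ref39 <- ref
  ref39$protein$atoms[r1, "x"] <- a[r1, "x"] + (3.9 - d1)
  expect_true("A:1:ALA" %in% find_binding_site(ref39, lig)$residues)
  # ligand far from the protein: superposition undefined
  far <- lig; far$xyz <- far$xyz + 50
  ref_far <- reference_complex("far", ref$protein, list(far))
  expect_error(find_binding_site(ref_far, far), "superposition-undefined")
  # brute-force membership scan agrees on a generated pocket
  gref <- make_complex(seed = 31, template = "hybrid")
  ginst <- gref$ligand_instances[[1]]
  gsite <- find_binding_site(gref, ginst)
  pa <- gref$protein$atoms
  keys <- unique(paste(pa$chain, pa$resi, pa$resn, sep = ":"))
  manual <- keys[vapply(keys, function(k) {
    rows <- paste(pa$chain, pa$resi, pa$resn, sep = ":") == k
    min(cross_dist(as.matrix(pa[rows, c("x", "y", "z")]), ginst$xyz)) <= 4
  }, logical(1))]
  expect_setequal(gsite$residues, manual)
})

test_that("Kabsch superposition recovers exact rigid motions and matches a numerical optimizer", {
  set.seed(12)
  ref_pts <- matrix(rnorm(60, sd = 4), ncol = 3)
  # exact recovery of a known rotation + translation
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  mov <- sweep(ref_pts %*% t(R), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(ref_pts, mov)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  # identity
  expect_lt(kabsch_superpose(ref_pts, ref_pts)$rmsd, 1e-12)
  # noisy case: agreement with a direct numerical minimizer over 6 dof
  mov2 <- ref_pts + matrix(rnorm(60, sd = 0.1), ncol = 3)
  fit2 <- kabsch_superpose(ref_pts, mov2)
  obj <- function(p) {
    ax <- p[1:3]; th <- sqrt(sum(ax^2))
    Rn <- if (th < 1e-12) diag(3) else {
      u <- ax / th
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                  byrow = TRUE)
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    sqrt(mean(rowSums((sweep(mov2 %*% t(Rn), 2, p[4:6], "+") - ref_pts)^2)))
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_lt(abs(fit2$rmsd - opt$value), 1e-5)
  expect_lte(fit2$rmsd, opt$value + 1e-8)     # Kabsch is the true minimum
  # collinear points are flagged degenerate
  line <- cbind(1:5, 0, 0)
  expect_true(kabsch_superpose(line, line)$degenerate)
})

test_that("automorphism enumeration matches brute force and respects the cap", {
  set.seed(3)
  expect_length(ligand_automorphisms(ligand_template("ring6")), 12)
  expect_length(ligand_automorphisms(ligand_template("branched")), 1)
  # identity always first
  auts <- ligand_automorphisms(ligand_template("hybrid"))
  expect_equal(auts[[1]], 1:12)
  # brute force over all element-preserving permutations agrees
  for (i in 1:12) {
    lig <- random_ligand(n_atoms = 7)
    expect_equal(length(ligand_automorphisms(lig)),
                 length(brute_isomorphisms(lig, lig)))
  }
  # para-like symmetric case: 4-ring with two equivalent substituents
  para <- ligand(c("C", "C", "C", "C", "O", "O"),
                 rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                       c(2, 0, 0), c(-2, 0, 0)),
                 rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 1),
                       c(1, 5, 1), c(3, 6, 1)))
  expect_equal(length(ligand_automorphisms(para)),
               length(brute_isomorphisms(para, para)))
  # cap truncates with a warning
  expect_warning(a <- ligand_automorphisms(ligand_template("ring6"), cap = 5),
                 "truncated")
  expect_length(a, 5)
})

test_that("lddt_core reproduces hand-enumerated indicator tables", {
  th <- c(0.5, 1, 2, 4)
  # deviations {0.3, 1.5, 5.0}: 4 + 2 + 0 = 6 hits of 4*(3+1) checks
  expect_equal(lddt_core(c(10, 10, 10), c(10.3, 11.5, 15), th, 1), 6 / 16)
  expect_equal(lddt_core(c(3, 4), c(3, 4), th, 0), 1)
  expect_equal(lddt_core(c(3, 4), c(13, 24), th, 0), 0)
  # missing model counterparts fail all checks
  expect_equal(lddt_core(c(3, 4), c(3, NA), th, 0), 0.5)
  # penalty monotonicity
  s <- vapply(0:4, function(p) lddt_core(c(3, 4), c(3.1, 4.2), th, p),
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(lddt_core(numeric(0), numeric(0), th, 0), "zero reference")
})

test_that("metric identities hold: identity, symmetry flip, exact translation", {
  for (tmpl in c("ring6", "branched", "hybrid")) {
    ref <- make_complex(seed = 40 + match(tmpl, c("ring6", "branched", "hybrid")),
                        template = tmpl)
    ps <- score_target(ref, identity_prediction(ref))
    expect_lt(ps$rmsd, 1e-9)
    expect_equal(ps$lddt_pli, 1)
    expect_lt(ps$bb_rmsd, 1e-9)
    expect_equal(ps$lddt_lp, 1)
    # symmetry flip scores 0 RMSD
    flip <- perturb_pose(ref, "symmetry_flip", seed = 1)
    expect_lt(score_target(ref, flip)$rmsd, 1e-9)
    # rigid ligand translation with fixed protein: rmsd = d exactly
    for (d in c(0.5, 1, 2, 4)) {
      tr <- perturb_pose(ref, "translate", d, seed = 7)
      expect_equal(score_target(ref, tr)$rmsd, d, tolerance = 1e-9)
    }
  }
})

test_that("LDDT-PLI is 1 for identity, 0 in solvent, automorphism-closed and penalty-aware", {
  ref <- make_complex(seed = 44, template = "ring6")
  inst <- ref$ligand_instances[[1]]
  pred <- identity_prediction(ref)
  expect_equal(lddt_pli(ref, inst, pred, pred$ligand_poses[[1]])$score, 1)
  # displaced far into solvent: every contact lost
  solv <- pred$ligand_poses[[1]]; solv$xyz <- solv$xyz + 30
  expect_equal(lddt_pli(ref, inst, pred, solv)$score, 0)
  # automorphism closure: flipped pose scores like the unflipped one
  auts <- ligand_automorphisms(inst)
  flip <- pred$ligand_poses[[1]]
  flip$xyz <- flip$xyz[auts[[2]], , drop = FALSE]
  expect_equal(lddt_pli(ref, inst, pred, flip)$score, 1)
})

test_that("monotone degradation: LDDT-PLI non-increasing with translation distance", {
  ref <- make_complex(seed = 46, template = "hybrid")
  plis <- vapply(c(0.5, 1, 2, 4), function(d) {
    score_target(ref, perturb_pose(ref, "translate", d, seed = 5))$lddt_pli
  }, numeric(1))
  expect_true(all(diff(plis) <= 1e-12))
})

test_that("all four metrics are invariant under rigid motions of either complex", {
  set.seed(9)
  ref <- make_complex(seed = 47, template = "hybrid", alt_conf = TRUE)
  pred <- perturb_pose(ref, "translate", 1.2, seed = 3)
  base <- score_target(ref, pred)
  rigid <- function() {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    t <- runif(3, -15, 15)
    function(xyz) sweep(as.matrix(xyz) %*% t(R), 2, -t)
  }
  # move the whole predicted complex
  mv <- rigid()
  pred2 <- pred
  pred2$protein$atoms[, c("x", "y", "z")] <- mv(protein_coords(pred$protein))
  pred2$ligand_poses[[1]]$xyz <- mv(pred$ligand_poses[[1]]$xyz)
  s2 <- score_target(ref, pred2)
  # move the whole reference complex
  mv2 <- rigid()
  ref3 <- ref
  ref3$protein$atoms[, c("x", "y", "z")] <- mv2(protein_coords(ref$protein))
  ref3$ligand_instances <- lapply(ref$ligand_instances, function(l) {
    l$xyz <- mv2(l$xyz); l
  })
  s3 <- score_target(ref3, pred)
  for (m in c("rmsd", "lddt_pli", "bb_rmsd", "lddt_lp")) {
    expect_equal(s2[[m]], base[[m]], tolerance = 1e-6)
    expect_equal(s3[[m]], base[[m]], tolerance = 1e-6)
  }
})

test_that("symmetry-corrected RMSD and both LDDT metrics match brute-force oracles", {
  set.seed(2024)
  for (i in 1:25) {
    lig <- random_ligand(n_atoms = 7)
    ref <- toy_complex_around(lig)
    pose <- shuffle_ligand(lig)
    pose$xyz <- pose$xyz + matrix(rnorm(length(pose$xyz), sd = runif(1, 0, 2)),
                                  ncol = 3)
    pred <- predicted_entry(1, ref$target_id, 1, protein = ref$protein,
                            ligand_poses = list(pose))
    rr <- bisy_rmsd(ref, lig, pred, pose)
    expect_equal(rr$rmsd, brute_sym_rmsd(lig, pose), tolerance = 1e-9)
    # bisy_rmsd <= identity-mapping RMSD always
    pl <- lddt_pli(ref, lig, pred, pose)
    expect_equal(pl$score, brute_lddt_pli(ref, lig, pred, pose),
                 tolerance = 1e-12)
    sm <- site_metrics(ref, lig, pred)
    expect_equal(sm$lddt_lp, brute_lddt_lp(ref, lig, pred), tolerance = 1e-12)
  }
})

test_that("best-score selection over copies, alternate conformations and pairings", {
  # two fully occupied copies: prediction matching copy 2 scores as that pair
  ref <- make_complex(seed = 50, template = "branched", n_copies = 2)
  pose_b <- ref$ligand_instances[[2]]
  pred <- predicted_entry(7, ref$target_id, 1, protein = ref$protein,
                          ligand_poses = list(pose_b))
  ps <- score_target(ref, pred)
  expect_lt(ps$rmsd, 1e-9)
  expect_equal(ps$lddt_pli, 1)
  expect_equal(ps$matched_reference, "inst2")
  # alternate conformations: matching conformation 2 is exact
  ref2 <- make_complex(seed = 51, template = "hybrid", alt_conf = TRUE)
  pred2 <- identity_prediction(ref2, pose = ref2$ligand_instances[[2]])
  ps2 <- score_target(ref2, pred2)
  expect_lt(ps2$rmsd, 1e-9)
  expect_equal(ps2$lddt_pli, 1)
  # 2x2 pairing grid equals the brute-force evaluation of all 4 pairings
  set.seed(61)
  pose1 <- perturb_pose(ref, "translate", 1.0, seed = 62)$ligand_poses[[1]]
  pose2 <- perturb_pose(ref, "translate", 2.5, seed = 63,
                        instance = 2)$ligand_poses[[1]]
  pose2$instance_id <- "pose2"
  both <- predicted_entry(7, ref$target_id, 1, protein = ref$protein,
                          ligand_poses = list(pose1, pose2))
  psb <- score_target(ref, both)
  grid_rmsd <- grid_pli <- matrix(NA_real_, 2, 2)
  for (r in 1:2) for (p in 1:2) {
    grid_rmsd[r, p] <- bisy_rmsd(ref, ref$ligand_instances[[r]], both,
                                 both$ligand_poses[[p]])$rmsd
    grid_pli[r, p] <- lddt_pli(ref, ref$ligand_instances[[r]], both,
                               both$ligand_poses[[p]])$score
  }
  expect_equal(psb$rmsd, min(grid_rmsd), tolerance = 1e-12)
  expect_equal(psb$lddt_pli, max(grid_pli), tolerance = 1e-12)
})

test_that("site metrics absorb pure translations of the predicted protein", {
  ref <- make_complex(seed = 55, template = "branched")
  pred <- identity_prediction(ref)
  pred$protein$atoms[, "x"] <- pred$protein$atoms[, "x"] + 1  # +1 A along x
  pred$ligand_poses[[1]]$xyz[, 1] <- pred$ligand_poses[[1]]$xyz[, 1] + 1
  sm <- site_metrics(ref, ref$ligand_instances[[1]], pred)
  expect_lt(sm$bb_rmsd, 1e-9)
  expect_equal(sm$lddt_lp, 1)
  ps <- score_target(ref, pred)
  expect_lt(ps$rmsd, 1e-9)
})

test_that("homodimer chain mapping finds the symmetric assignment", {
  # duplicate the pocket as chain B, 180-degree rotated about the ligand
  ref <- make_complex(seed = 66, template = "branched")
  a <- ref$protein$atoms
  b <- a
  ctr <- colMeans(ref$ligand_instances[[1]]$xyz)
  R <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  b[, c("x", "y", "z")] <- sweep(sweep(as.matrix(a[, c("x", "y", "z")]), 2,
                                       ctr) %*% t(R), 2, ctr, "+")
  b$chain <- "B"
  dimer <- reference_complex("DIM", protein_structure(rbind(a, b)),
                             ref$ligand_instances)
  # predicted protein swaps the chain labels
  swapped <- dimer$protein
  swapped$atoms$chain <- ifelse(swapped$atoms$chain == "A", "B", "A")
  pred <- predicted_entry(1, "DIM", 1, protein = swapped,
                          ligand_poses = list(dimer$ligand_instances[[1]]))
  with_map <- score_target(dimer, pred, scoring_config(chain_mapping = TRUE))
  without <- score_target(dimer, pred, scoring_config(chain_mapping = FALSE))
  expect_equal(with_map$lddt_pli, 1)
  expect_gte(with_map$lddt_pli, without$lddt_pli)
})
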