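test_that("PDB and molfile round-trips preserve coordinates to format precision", {
  set.seed(101)
  ref <- make_complex(seed = 5, template = "branched", incidental = TRUE)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ref$protein, pdb)
  back <- read_pdb(pdb)
  key <- function(p) paste(p$atoms$chain, p$atoms$resi, p$atoms$atom)
  m <- match(key(ref$protein), key(back))
  expect_false(anyNA(m))
  expect_lt(max(abs(as.matrix(ref$protein$atoms[, c("x", "y", "z")]) -
                      as.matrix(back$atoms[m, c("x", "y", "z")]))), 1e-3)
  expect_equal(back$atoms$polymer[m], ref$protein$atoms$polymer)

  mol <- withr::local_tempfile(fileext = ".mol")
  lig <- ref$ligand_instances[[1]]
  write_molfile(lig, mol)
  lig2 <- read_molfile(mol)
  expect_equal(lig2$elements, lig$elements)
  expect_lt(max(abs(lig2$xyz - lig$xyz)), 1e-3)
  expect_equal(lig2$bonds[, 1:2], lig$bonds[, 1:2])
})

test_that("altloc resolution keeps the highest occupancy, ties by letter", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.30  0.00           C",
    "ATOM      4  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  O   ALA A   1       0.000   1.000   0.000  1.00  0.00           O",
    "ATOM      7  H   ALA A   1       0.000   2.000   0.000  1.00  0.00           H",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  p <- read_pdb(f)
  expect_equal(p$atoms$x[p$atoms$atom == "CA"], 1.0)   # occupancy 0.7 wins
  expect_equal(p$atoms$x[p$atoms$atom == "CB"], 2.0)   # tie -> altloc A
  expect_false("H" %in% p$atoms$element)               # hydrogens dropped
})

test_that("SMILES graph checks accept relabelings and reject different molecules", {
  set.seed(77)
  expect_true(ligand_matches_smiles(ligand_template("ring6"), "C1=CC=CC=C1"))
  expect_true(ligand_matches_smiles(ligand_template("hybrid"),
                                    "c1ccc(-c2ccccc2)cc1"))
  # any atom permutation of the same molecule is accepted
  cases <- list(c("ring6", "c1ccccc1"), c("branched", "CC(N)CO"),
                c("hybrid", "c1ccc(cc1)-c1ccccc1"))
  for (cs in cases) {
    for (i in 1:5) {
      shuf <- shuffle_ligand(ligand_template(cs[1]))
      expect_true(ligand_matches_smiles(shuf, cs[2]))
    }
  }
  # a molecule with a different element multiset is rejected
  expect_false(ligand_matches_smiles(ligand_template("ring6"), "c1ccncc1"))
  expect_false(ligand_matches_smiles(ligand_template("branched"), "CC(O)CO"))
  # same multiset, different connectivity is rejected too
  expect_false(ligand_matches_smiles(ligand_template("branched"), "CCC(N)O"))
  # bracket atoms and explicit hydrogens are tolerated
  expect_true(ligand_matches_smiles(ligand_template("branched"),
                                    "C[C@@H](N)C[OH]"))
  # parse errors surface
  expect_error(parse_smiles("C1CC"), "ring")
})

test_that("read_reference enforces the molfile-vs-SMILES validity check", {
  d <- withr::local_tempdir()
  ref <- make_complex(seed = 9, template = "ring6")
  write_pdb(ref$protein, file.path(d, "p.pdb"))
  write_molfile(ref$ligand_instances[[1]], file.path(d, "l.mol"))
  ok <- read_reference(file.path(d, "p.pdb"), file.path(d, "l.mol"),
                       smiles = "c1ccccc1")
  expect_s3_class(ok, "reference_complex")
  expect_length(ok$ligand_instances, 1)
  expect_error(
    read_reference(file.path(d, "p.pdb"), file.path(d, "l.mol"),
                   smiles = "CC(N)CO"),
    "does not match")
})

test_that("incidental detection follows the 4.5-A heavy-atom rule and is rigid-invariant", {
  ref <- make_complex(seed = 4, template = "branched")
  inst <- ref$ligand_instances[[1]]
  mk_ion <- function(d) {
    a <- inst$xyz[1, ]
    u <- a - colMeans(inst$xyz); u <- u / sqrt(sum(u^2))
    ligand("Cl", matrix(a + d * u, 1, 3), matrix(integer(0), 0, 3), "ion")
  }
  res <- detect_incidental(ref, list(mk_ion(4.4), mk_ion(4.6), mk_ion(0)))
  expect_equal(res$is_incidental, c(TRUE, FALSE, TRUE))

  set.seed(8)
  R <- diag(3); tr <- c(0, 0, 0)
  ang <- runif(1, 0, 2 * pi); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  tr <- runif(3, -30, 30)
  move <- function(xyz) sweep(as.matrix(xyz) %*% t(R), 2, -tr)
  ref2 <- ref
  ref2$protein$atoms[, c("x", "y", "z")] <- move(protein_coords(ref$protein))
  ref2$ligand_instances <- lapply(ref$ligand_instances, function(l) {
    l$xyz <- move(l$xyz); l
  })
  cands2 <- lapply(list(mk_ion(4.4), mk_ion(4.6), mk_ion(0)), function(l) {
    l$xyz <- move(l$xyz); l
  })
  expect_equal(detect_incidental(ref2, cands2)$is_incidental,
               c(TRUE, FALSE, TRUE))
})

test_that("read_submission_dir materializes skips and flags bad entries", {
  d <- withr::local_tempdir()
  spec <- cohort_spec(n_targets = 3, n_models = 1, seed = 21,
                      group_profiles = data.frame(sigma_pose = c(0.5, 0.5),
                                                  skip_prob = c(0, 0),
                                                  lscore_rho = c(1, 1)))
  cmd_simulate(d, spec)
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  # remove one target dir entirely for group 2
  unlink(file.path(d, "subs", "G2", "T002"), recursive = TRUE)
  ents <- suppressMessages(read_submission_dir(file.path(d, "subs"), man))
  expect_length(ents, 6)                      # 2 groups x 3 targets
  expect_equal(sum(vapply(ents, `[[`, logical(1), "skipped")), 1)

  # corrupt one molfile: flagged invalid, treated as skip
  victim <- file.path(d, "subs", "G1", "T001", "model1.mol")
  writeLines("garbage", victim)
  ents2 <- suppressMessages(read_submission_dir(file.path(d, "subs"), man))
  inv <- Filter(function(e) "invalid" %in% e$flags, ents2)
  expect_length(inv, 1)
  expect_true(inv[[1]]$skipped)

  # out-of-range lscore flagged, value dropped
  e <- predicted_entry(1, "T1", 1, protein = NULL, ligand_poses = list(),
                       lscore = 1.2, skipped = FALSE)
  expect_true("lscore_out_of_range" %in% e$flags)
  expect_true(is.na(e$lscore))

  # empty directory: one skip per (group, target)
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "G1")); dir.create(file.path(empty, "G2"))
  man5 <- list(groups = 1:2, targets = paste0("T", 1:5))
  ents3 <- read_submission_dir(empty, man5)
  expect_length(ents3, 10)
  expect_true(all(vapply(ents3, `[[`, logical(1), "skipped")))
})

test_that("zero-coordinate protein templates are treated as absent", {
  ref <- make_complex(seed = 2, template = "ring6")
  p <- ref$protein
  p$atoms[, c("x", "y", "z")] <- 0
  expect_true(protein_is_absent(p))
  expect_false(protein_is_absent(ref$protein))
  ent <- predicted_entry(1, ref$target_id, 1, protein = p,
                         ligand_poses = list(ref$ligand_instances[[1]]))
  expect_false(entry_scorable(ent))
})
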