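# Parsing, validation and in-memory representation of proteins, ligands,
# reference complexes and submission sets.
#
# Containers are light S3 objects:
#   protein_structure : data.frame of heavy atoms
#                       (chain, resi, resn, polymer, atom, element, x, y, z)
#   ligand            : list(elements, xyz, bonds, instance_id), heavy atoms only
#   reference_complex : crystal protein + >=1 drug-like ligand instance
#   predicted_entry   : one group's Model k for one target (or an explicit skip)
#
# No pre-installed R package in the target environment reads PDB or MDL
# molfiles, so minimal fixed-width readers/writers for the two formats the
# challenge used are implemented here.  Only the fields the assessment needs
# are interpreted.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a protein structure
#'
#' @param atoms data.frame with columns chain, resi, resn, polymer, atom,
#'   element, x, y, z (one row per heavy atom)
#' @return an object of class `protein_structure`
#' @export
protein_structure <- function(atoms) {
  need <- c("chain", "resi", "resn", "polymer", "atom", "element", "x", "y", "z")
  .assert(all(need %in% names(atoms)), "missing protein atom columns")
  .assert(all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)),
          "non-finite protein coordinates")
  atoms <- atoms[, need]
  # standard residues carry at most one CA after altloc resolution
  ca <- atoms[atoms$polymer & atoms$atom == "CA" & atoms$resn %in% STANDARD_AA, ]
  if (nrow(ca) > 0) {
    .assert(!anyDuplicated(paste(ca$chain, ca$resi, ca$resn)),
            "duplicate CA within a residue")
  }
  structure(list(atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<protein_structure> %d heavy atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resi))),
              paste(sort(unique(a$chain)), collapse = ",")))
  invisible(x)
}

residue_keys <- function(prot) {
  a <- prot$atoms
  unique(paste(a$chain, a$resi, a$resn, sep = ":"))
}

protein_coords <- function(prot) as.matrix(prot$atoms[, c("x", "y", "z")])

#' Is a predicted protein effectively absent?
#'
#' Challenge templates are distributed with zeroed coordinate fields; a
#' protein whose coordinates are all zero is treated as not predicted.
#' @param prot protein_structure or NULL
#' @return logical
#' @export
protein_is_absent <- function(prot) {
  is.null(prot) || nrow(prot$atoms) == 0 || all(protein_coords(prot) == 0)
}

#' Construct a ligand
#'
#' Hydrogens are stripped (all metrics are heavy-atom metrics); bonds are
#' reindexed accordingly.  The heavy-atom connectivity graph must be
#' connected and non-empty.
#'
#' @param elements character vector of element symbols
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param bonds m x 3 integer matrix: from, to, order (1-based indices)
#' @param instance_id identifier for this ligand instance
#' @return an object of class `ligand`
#' @export
ligand <- function(elements, xyz, bonds, instance_id = "lig1") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  .assert(length(elements) == nrow(xyz), "elements/coords length mismatch")
  heavy <- elements != "H"
  .assert(any(heavy), "ligand has no heavy atom")
  if (!all(heavy)) {
    keep <- which(heavy)
    remap <- integer(length(elements)); remap[keep] <- seq_along(keep)
    bk <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, , drop = FALSE]
    bonds <- cbind(remap[bk[, 1]], remap[bk[, 2]], bk[, 3])
    elements <- elements[keep]; xyz <- xyz[keep, , drop = FALSE]
  }
  .assert(all(is.finite(xyz)), "non-finite ligand coordinates")
  n <- length(elements)
  if (nrow(bonds) > 0) {
    .assert(all(bonds[, 1:2] >= 1) && all(bonds[, 1:2] <= n),
            "bond index out of range")
  }
  lig <- structure(list(elements = elements, xyz = xyz, bonds = bonds,
                        instance_id = instance_id), class = "ligand")
  g <- ligand_graph(lig)
  .assert(n == 1 || igraph::is_connected(g), "ligand graph not connected")
  lig
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand %s> %d heavy atoms (%s), %d bonds\n", x$instance_id,
              length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(lig) length(lig$elements)

# igraph view of a ligand's heavy-atom connectivity (bond orders dropped).
ligand_graph <- function(lig) {
  g <- igraph::make_empty_graph(n = n_atoms(lig), directed = FALSE)
  if (nrow(lig$bonds) > 0) {
    g <- igraph::add_edges(g, t(lig$bonds[, 1:2, drop = FALSE]))
  }
  igraph::set_vertex_attr(g, "element", value = lig$elements)
}

# Element-colored VF2 isomorphism on connectivity only (bond orders and
# aromaticity flags deliberately ignored, tolerating kekulization
# differences between predictors' files).
graphs_isomorphic <- function(g1, g2) {
  e1 <- igraph::vertex_attr(g1, "element")
  e2 <- igraph::vertex_attr(g2, "element")
  if (length(e1) != length(e2)) return(FALSE)
  if (!identical(sort(e1), sort(e2))) return(FALSE)
  lev <- sort(unique(c(e1, e2)))
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = match(e1, lev),
                     vertex.color2 = match(e2, lev))
}

ligands_isomorphic <- function(a, b) {
  graphs_isomorphic(ligand_graph(a), ligand_graph(b))
}

# ---------------------------------------------------------------------------
# PDB
# ---------------------------------------------------------------------------

#' Read a PDB file
#'
#' Minimal fixed-width reader for ATOM/HETATM records.  Hydrogens are
#' dropped; alternate locations are resolved by highest occupancy (ties by
#' altloc letter order).  HETATM groups (metals, glycans, cosolutes) are
#' kept as non-polymer residues.
#'
#' @param path PDB file path
#' @return protein_structure
#' @export
read_pdb <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  .assert(length(lines) > 0, paste("no coordinates in", path))
  f <- function(a, b) trimws(substr(lines, a, b))
  elem <- f(77, 78)
  name <- f(13, 16)
  # element fallback: leading letters of the atom name, first char uppercase
  guess <- sub("^[0-9]*([A-Za-z]+).*$", "\\1", name)
  guess <- ifelse(nchar(guess) > 1,
                  paste0(substr(guess, 1, 1), tolower(substr(guess, 2, 2))),
                  guess)
  elem <- ifelse(elem == "", guess, paste0(substr(elem, 1, 1),
                                           tolower(substr(elem, 2, 2))))
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    atom = name,
    altloc = f(17, 17),
    resn = f(18, 20),
    chain = f(22, 22),
    resi = as.integer(f(23, 26)),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occ = occ, element = elem,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  # altloc: highest occupancy wins, ties by altloc letter order
  key <- paste(atoms$chain, atoms$resi, atoms$resn, atoms$atom)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms$polymer <- atoms$record == "ATOM"
  out <- atoms[order(atoms$chain, atoms$resi,
                     match(atoms$atom, c("N", "CA", "C", "O"))),
               c("chain", "resi", "resn", "polymer", "atom", "element",
                 "x", "y", "z")]
  rownames(out) <- NULL
  protein_structure(out)
}

#' Write a protein to PDB format
#'
#' @param prot protein_structure
#' @param path output file
#' @export
write_pdb <- function(prot, path) {
  a <- prot$atoms
  rec <- ifelse(a$polymer, "ATOM  ", "HETATM")
  name <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                 sprintf("%-4s", a$atom))
  lines <- sprintf(
    "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), name, a$resn, a$chain, a$resi,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# MDL molfile (V2000)
# ---------------------------------------------------------------------------

#' Read an MDL molfile (V2000)
#'
#' Hydrogens are dropped and bonds reindexed.
#' @param path molfile/SDF path (first molecule only)
#' @param instance_id id assigned to the ligand
#' @return ligand
#' @export
read_molfile <- function(path, instance_id = NULL) {
  .assert(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  .assert(length(lines) >= 4, paste("truncated molfile:", path))
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  .assert(!is.na(na) && !is.na(nb) && length(lines) >= 4 + na + nb,
          paste("malformed molfile counts line:", path))
  at <- lines[5:(4 + na)]
  xyz <- cbind(as.numeric(substr(at, 1, 10)),
               as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  elements <- trimws(substr(at, 32, 34))
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
          as.integer(substr(bl, 7, 9)))
  } else matrix(integer(0), 0, 3)
  .assert(all(is.finite(xyz)), paste("bad coordinates in", path))
  ligand(elements, xyz, bonds,
         instance_id = instance_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a ligand as an MDL molfile (V2000)
#'
#' @param lig ligand
#' @param path output file
#' @param title molfile title line
#' @export
write_molfile <- function(lig, path, title = lig$instance_id) {
  n <- n_atoms(lig); m <- nrow(lig$bonds)
  head <- c(title, "  ligassess", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                lig$xyz[, 1], lig$xyz[, 2], lig$xyz[, 3], lig$elements)
  bl <- if (m > 0) sprintf("%3d%3d%3d  0", lig$bonds[, 1], lig$bonds[, 2],
                           pmax(1L, lig$bonds[, 3])) else character(0)
  writeLines(c(head, at, bl, "M  END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SMILES (identity graphs only)
# ---------------------------------------------------------------------------

#' Parse a SMILES string to a heavy-atom graph
#'
#' Minimal parser used only to verify that a submitted molfile has the
#' connectivity the challenge announced for the target.  Supports the
#' organic subset, bracket atoms, branches, ring closures (including %nn)
#' and bond symbols; stereo marks, charges and explicit hydrogens are
#' ignored.  Bond orders are not retained (identity is element +
#' connectivity).
#'
#' @param smiles SMILES string
#' @return list(elements, bonds) where bonds is an m x 2 index matrix
#' @export
parse_smiles <- function(smiles) {
  .assert(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
          "empty SMILES")
  chars <- strsplit(smiles, "")[[1]]
  elements <- character(0)
  bonds <- matrix(integer(0), 0, 2)
  stack <- integer(0)
  prev <- NA_integer_
  ring <- list()
  i <- 1
  two_letter <- c("Cl", "Br")
  add_atom <- function(el) {
    elements <<- c(elements, el)
    idx <- length(elements)
    if (!is.na(prev)) bonds <<- rbind(bonds, c(prev, idx))
    prev <<- idx
    idx
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    pair <- if (i < length(chars)) paste0(ch, chars[i + 1]) else ""
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      .assert(length(stack) > 0, "unbalanced parenthesis in SMILES")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) { i <- i + 1
    } else if (ch == ".") { prev <- NA_integer_; i <- i + 1
    } else if (ch == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      .assert(j <= length(chars), "unterminated bracket atom in SMILES")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      body <- sub("^[0-9]+", "", body)             # isotope
      el <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
      .assert(length(el) == 1, paste("bad bracket atom:", body))
      el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
      # [nH] etc: aromatic one-letter symbols come out capitalized correctly;
      # trailing lowercase 'h' from e.g. [NH2] must not be kept
      if (nchar(el) == 2 && substr(el, 2, 2) == "h") el <- substr(el, 1, 1)
      if (el == "H") {                              # explicit hydrogen: skip
        prev_keep <- prev
        i <- j + 1
        # swallow a ring-closure digit on the H if any (unusual); none expected
        prev <- prev_keep
        next
      }
      add_atom(el)
      i <- j + 1
    } else if (pair %in% two_letter) { add_atom(pair); i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch); i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch)); i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { lab <- paste(chars[(i + 1):(i + 2)], collapse = ""); i <- i + 3 }
      else { lab <- ch; i <- i + 1 }
      .assert(!is.na(prev), "ring closure before any atom in SMILES")
      if (!is.null(ring[[lab]])) {
        bonds <- rbind(bonds, c(ring[[lab]], prev))
        ring[[lab]] <- NULL
      } else ring[[lab]] <- prev
    } else {
      stop(sprintf("unsupported SMILES token '%s' in '%s'", ch, smiles),
           call. = FALSE)
    }
  }
  .assert(length(ring) == 0, "unclosed ring bond in SMILES")
  .assert(length(elements) > 0, "SMILES encodes no heavy atom")
  list(elements = elements, bonds = bonds)
}

smiles_graph <- function(smiles) {
  s <- parse_smiles(smiles)
  g <- igraph::make_empty_graph(n = length(s$elements), directed = FALSE)
  if (nrow(s$bonds) > 0) g <- igraph::add_edges(g, t(s$bonds))
  igraph::set_vertex_attr(g, "element", value = s$elements)
}

#' Check a ligand against a SMILES identity
#'
#' Element + connectivity isomorphism (bond orders ignored); mirrors the
#' challenge's technical-validity check that a submitted molfile matches
#' the announced SMILES.
#' @param lig ligand
#' @param smiles SMILES string
#' @return logical
#' @export
ligand_matches_smiles <- function(lig, smiles) {
  graphs_isomorphic(ligand_graph(lig), smiles_graph(smiles))
}

# ---------------------------------------------------------------------------
# Reference complexes
# ---------------------------------------------------------------------------

#' Construct a reference complex
#'
#' @param target_id target identifier
#' @param protein protein_structure (crystal)
#' @param ligand_instances list of ligand (copies and/or alternate
#'   conformations; all must be mutually graph-isomorphic)
#' @param incidental_ligands list of ligand (crystallization additives)
#' @param covalent_note optional free-text covalent-attachment metadata
#'   (carried, never used in scoring)
#' @return reference_complex
#' @export
reference_complex <- function(target_id, protein, ligand_instances,
                              incidental_ligands = list(),
                              covalent_note = NULL) {
  .assert(inherits(protein, "protein_structure"), "protein must be a protein_structure")
  .assert(length(ligand_instances) >= 1, "need >=1 ligand instance")
  if (length(ligand_instances) > 1) {
    for (k in 2:length(ligand_instances)) {
      .assert(ligands_isomorphic(ligand_instances[[1]], ligand_instances[[k]]),
              "ligand instances are not mutually isomorphic")
    }
  }
  structure(list(target_id = target_id, protein = protein,
                 ligand_instances = ligand_instances,
                 incidental_ligands = incidental_ligands,
                 covalent_note = covalent_note),
            class = "reference_complex")
}

#' @export
print.reference_complex <- function(x, ...) {
  cat(sprintf("<reference_complex %s> %d ligand instance(s), %d incidental\n",
              x$target_id, length(x$ligand_instances),
              length(x$incidental_ligands)))
  invisible(x)
}

#' Read a reference complex from files
#'
#' @param protein_path crystal protein PDB
#' @param ligand_paths molfile path(s) for the drug-like ligand instance(s)
#' @param smiles announced ligand SMILES; if given, every instance must
#'   match it (element + connectivity) or an error is raised
#' @param target_id target identifier
#' @param incidental_paths molfile paths for incidental ligands
#' @return reference_complex
#' @export
read_reference <- function(protein_path, ligand_paths, smiles = NULL,
                           target_id = "target", incidental_paths = character()) {
  prot <- read_pdb(protein_path)
  ligs <- lapply(seq_along(ligand_paths), function(k)
    read_molfile(ligand_paths[[k]], instance_id = paste0("inst", k)))
  if (!is.null(smiles)) {
    for (lg in ligs) {
      .assert(ligand_matches_smiles(lg, smiles),
              sprintf("ligand %s does not match target SMILES '%s'",
                      lg$instance_id, smiles))
    }
  }
  inc <- lapply(seq_along(incidental_paths), function(k)
    read_molfile(incidental_paths[[k]], instance_id = paste0("incidental", k)))
  reference_complex(target_id, prot, ligs, incidental_ligands = inc)
}

#' Partition candidate ligands into incidental / non-incidental
#'
#' A candidate is incidental iff any of its heavy atoms lies within
#' `cutoff` of any heavy atom of any drug-like ligand instance.
#'
#' @param ref reference_complex
#' @param candidates list of ligand
#' @param cutoff distance cutoff in Angstrom (default 4.5)
#' @return list(incidental, other, is_incidental)
#' @export
detect_incidental <- function(ref, candidates, cutoff = 4.5) {
  .assert(length(ref$ligand_instances) >= 1, "reference has no drug-like ligand")
  flag <- vapply(candidates, function(cand) {
    any(vapply(ref$ligand_instances,
               function(inst) min_cross_dist(cand$xyz, inst$xyz) <= cutoff,
               logical(1)))
  }, logical(1))
  list(incidental = candidates[flag], other = candidates[!flag],
       is_incidental = flag)
}

# ---------------------------------------------------------------------------
# Predicted entries and submission directories
# ---------------------------------------------------------------------------

#' Construct a predicted entry
#'
#' @param group_id integer group id
#' @param target_id target id
#' @param model_num model number 1..5
#' @param protein predicted protein_structure or NULL
#' @param ligand_poses list of ligand poses
#' @param lscore optional self-reported reliability in 0..1
#' @param skipped explicit skip flag
#' @param flags character vector of diagnostics (e.g. "invalid", "no_protein")
#' @return predicted_entry
#' @export
predicted_entry <- function(group_id, target_id, model_num,
                            protein = NULL, ligand_poses = list(),
                            lscore = NA_real_, skipped = FALSE,
                            flags = character(0)) {
  .assert(model_num %in% 1:5, "model_num must be in 1..5")
  if (skipped) {
    .assert(is.null(protein) && length(ligand_poses) == 0,
            "skipped entry must carry no coordinates")
  }
  if (!is.na(lscore) && (lscore < 0 || lscore > 1)) {
    flags <- union(flags, "lscore_out_of_range")
    lscore <- NA_real_
  }
  structure(list(group_id = as.integer(group_id), target_id = target_id,
                 model_num = as.integer(model_num), protein = protein,
                 ligand_poses = ligand_poses, lscore = lscore,
                 skipped = skipped, flags = flags),
            class = "predicted_entry")
}

#' Is an entry scorable?
#'
#' Scorable means: not skipped, not flagged invalid, has >=1 pose and a
#' non-absent predicted protein (all four metrics need the protein).
#' @param entry predicted_entry
#' @return logical
#' @export
entry_scorable <- function(entry) {
  !entry$skipped && !("invalid" %in% entry$flags) &&
    length(entry$ligand_poses) > 0 && !protein_is_absent(entry$protein)
}

#' Read a submission directory
#'
#' Expected layout (the synthetic-data writer emits the same):
#' `root/G<group>/<target>/model<k>.pdb` + `model<k>.mol`, with an optional
#' per-group `lscores.csv` (columns target, model, lscore).  Every
#' (group, target) combination listed in the manifest with no parseable
#' model is materialized as one skipped entry; malformed files yield
#' entries flagged `"invalid"` (treated as skips downstream) with a
#' diagnostic message attached.
#'
#' @param root submission root directory
#' @param manifest list(groups = integer vector, targets = character vector)
#' @return list of predicted_entry
#' @export
read_submission_dir <- function(root, manifest) {
  .assert(dir.exists(root), paste("no such directory:", root))
  .assert(length(manifest$groups) > 0 && length(manifest$targets) > 0,
          "manifest must list groups and targets")
  entries <- list()
  for (g in manifest$groups) {
    gdir <- file.path(root, paste0("G", g))
    ls_path <- file.path(gdir, "lscores.csv")
    lsc <- if (file.exists(ls_path)) {
      utils::read.csv(ls_path, stringsAsFactors = FALSE)
    } else NULL
    for (t in manifest$targets) {
      tdir <- file.path(gdir, t)
      model_files <- if (dir.exists(tdir)) {
        sort(list.files(tdir, pattern = "^model[1-5]\\.mol$"))
      } else character(0)
      if (length(model_files) == 0) {
        entries[[length(entries) + 1]] <-
          predicted_entry(g, t, 1, skipped = TRUE)
        next
      }
      for (mf in model_files) {
        m <- as.integer(sub("^model([1-5])\\.mol$", "\\1", mf))
        ls_val <- NA_real_
        if (!is.null(lsc)) {
          hit <- lsc$target == t & lsc$model == m
          if (any(hit)) ls_val <- lsc$lscore[which(hit)[1]]
        }
        ent <- tryCatch({
          pose <- read_molfile(file.path(tdir, mf),
                               instance_id = paste0("pose", m))
          ppath <- file.path(tdir, sub("\\.mol$", ".pdb", mf))
          prot <- if (file.exists(ppath)) read_pdb(ppath) else NULL
          flags <- character(0)
          if (protein_is_absent(prot)) flags <- "no_protein"
          predicted_entry(g, t, m, protein = prot, ligand_poses = list(pose),
                          lscore = ls_val, flags = flags)
        }, error = function(e) {
          message(sprintf("invalid entry G%s/%s/%s: %s", g, t, mf,
                          conditionMessage(e)))
          predicted_entry(g, t, m, lscore = ls_val, skipped = TRUE,
                          flags = "invalid")
        })
        entries[[length(entries) + 1]] <- ent
      }
    }
  }
  entries
}
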