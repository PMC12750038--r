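# Template-similarity scoring: how well a target protein-ligand complex is
# represented by a template complex.  Ligand overlap is a SuCOS-style
# score (0.5 x Gaussian-volume shape overlap + 0.5 x pharmacophore-feature
# overlap); pocket coverage is the fraction of the target's 6-Angstrom
# binding-pocket residues mapped into the template's pocket by a supplied
# residue alignment.  The combined score is their product.  Template
# search and target-template superposition are inputs, not computed here.

#' Pocket residues of a complex
#'
#' Residues with any heavy atom within `cutoff` of any heavy atom of any
#' drug-like ligand instance.  The 6-Angstrom default is deliberately
#' looser than the 4-Angstrom accuracy-assessment site, because target and
#' template need not share side chains.
#'
#' @param complex reference_complex
#' @param cutoff Angstrom (default 6)
#' @return character vector of residue keys ("chain:resi:resn")
#' @export
pocket_residues <- function(complex, cutoff = 6.0) {
  .assert(length(complex$ligand_instances) >= 1, "complex has no ligand")
  a <- complex$protein$atoms
  key <- paste(a$chain, a$resi, a$resn, sep = ":")
  lig_xyz <- do.call(rbind, lapply(complex$ligand_instances, `[[`, "xyz"))
  dmin <- apply(cross_dist(as.matrix(a[, c("x", "y", "z")]), lig_xyz), 1, min)
  in_pocket <- tapply(dmin, key, min) <= cutoff
  out <- names(in_pocket)[in_pocket]
  .assert(length(out) > 0, "empty pocket")
  out
}

#' Construct a pocket alignment
#'
#' A residue-level target-template correspondence (e.g. from a structure
#' aligner), injective both ways.
#'
#' @param target_keys residue keys in the target
#' @param template_keys matching residue keys in the template
#' @param source free-text provenance
#' @return pocket_alignment
#' @export
pocket_alignment <- function(target_keys, template_keys, source = "supplied") {
  .assert(length(target_keys) == length(template_keys),
          "alignment columns differ in length")
  .assert(!anyDuplicated(target_keys) && !anyDuplicated(template_keys),
          "alignment must be injective both ways")
  structure(list(target_keys = target_keys, template_keys = template_keys,
                 source = source), class = "pocket_alignment")
}

#' Pocket coverage
#'
#' Number of target-pocket residues mapped by the alignment onto
#' template-pocket residues, normalized by the target pocket size.
#'
#' @param target_pocket residue keys of the target pocket
#' @param template_pocket residue keys of the template pocket
#' @param aln pocket_alignment
#' @return fraction in 0..1
#' @export
pocket_coverage <- function(target_pocket, template_pocket, aln) {
  .assert(length(target_pocket) > 0, "empty target pocket")
  mapped <- aln$template_keys[match(target_pocket, aln$target_keys)]
  mean(!is.na(mapped) & mapped %in% template_pocket)
}

# Gaussian-volume overlap of two atom sets with a single fixed radius.
# Grant-Pickup style spherical Gaussians: rho_i(r) = p exp(-a |r - ri|^2)
# with a chosen so the Gaussian integral matches the hard-sphere volume.
gaussian_overlap <- function(xyz_a, xyz_b, radius) {
  p <- 2.7
  a <- pi * (3 * p / (4 * pi * radius^3))^(2 / 3)
  d2 <- cross_dist(xyz_a, xyz_b)^2
  sum(p * p * (pi / (2 * a))^(3 / 2) * exp(-(a / 2) * d2))
}

gaussian_tanimoto <- function(xyz_a, xyz_b, radius) {
  vab <- gaussian_overlap(xyz_a, xyz_b, radius)
  vaa <- gaussian_overlap(xyz_a, xyz_a, radius)
  vbb <- gaussian_overlap(xyz_b, xyz_b, radius)
  min(max(vab / (vaa + vbb - vab), 0), 1)
}

# Pharmacophore feature centers per family, derived from the heavy-atom
# graph (no hydrogens are stored, so N/O are treated as both donor-like
# and acceptor-like).  Returns a named list of coordinate matrices.
ligand_features <- function(lig, families = c("donor_acceptor", "aromatic",
                                              "hydrophobe")) {
  adj <- ligand_adjacency(lig)
  feats <- list()
  if ("donor_acceptor" %in% families) {
    idx <- which(lig$elements %in% c("N", "O"))
    if (length(idx)) feats$donor_acceptor <- lig$xyz[idx, , drop = FALSE]
  }
  if ("aromatic" %in% families) {
    g <- ligand_graph(lig)
    rings <- ring_centers(lig, g)
    if (!is.null(rings)) feats$aromatic <- rings
  }
  if ("hydrophobe" %in% families) {
    is_c <- lig$elements == "C"
    polar_nbr <- vapply(seq_along(lig$elements), function(i) {
      any(lig$elements[which(adj[i, ] == 1)] %in% c("N", "O", "S", "P"))
    }, logical(1))
    idx <- which(is_c & !polar_nbr)
    if (length(idx)) feats$hydrophobe <- lig$xyz[idx, , drop = FALSE]
  }
  feats
}

# Centers of 5- and 6-membered rings (aromatic-ring proxies on a
# heavy-atom graph without aromaticity flags).
ring_centers <- function(lig, g) {
  n <- n_atoms(lig)
  if (n < 5 || igraph::ecount(g) < 5) return(NULL)
  # minimum cycle basis via girth-style search: use igraph's fundamental
  # cycles from a spanning tree
  centers <- NULL
  seen <- character(0)
  adj <- ligand_adjacency(lig)
  for (len in c(5L, 6L)) {
    # enumerate simple cycles of given length by DFS from each vertex
    for (start in seq_len(n)) {
      stack <- list(start)
      path <- function(pth) {
        last <- pth[length(pth)]
        if (length(pth) == len) {
          if (adj[last, start] == 1) {
            key <- paste(sort(pth), collapse = "-")
            if (!(key %in% seen)) {
              seen <<- c(seen, key)
              centers <<- rbind(centers,
                                colMeans(lig$xyz[pth, , drop = FALSE]))
            }
          }
          return()
        }
        for (nb in which(adj[last, ] == 1)) {
          if (nb > start && !(nb %in% pth)) path(c(pth, nb))
        }
      }
      path(start)
    }
  }
  centers
}

#' SuCOS-style overlap score between two positioned molecules
#'
#' 0.5 x shape term + 0.5 x feature term.  The shape term is the
#' Gaussian-volume Tanimoto over heavy atoms with a single fixed radius;
#' the feature term is the same Tanimoto computed per pharmacophore
#' family (donor/acceptor N and O, aromatic ring centers, hydrophobic
#' carbons) and averaged over the families present in either molecule
#' (a family present in only one contributes zero; if neither molecule
#' has any feature the feature term equals the shape term).  Both
#' molecules must already be in a common frame.
#'
#' @param query ligand (positioned)
#' @param ref ligand (positioned)
#' @param radius Gaussian atom radius, Angstrom (default 1.7)
#' @param weights c(shape, feature) mixing weights (default 0.5/0.5)
#' @param families feature families used
#' @return score in 0..1
#' @export
sucos <- function(query, ref, radius = 1.7, weights = c(0.5, 0.5),
                  families = c("donor_acceptor", "aromatic", "hydrophobe")) {
  .assert(n_atoms(query) > 0 && n_atoms(ref) > 0, "empty molecule")
  shape <- gaussian_tanimoto(query$xyz, ref$xyz, radius)
  fq <- ligand_features(query, families)
  fr <- ligand_features(ref, families)
  fams <- union(names(fq), names(fr))
  feature <- if (length(fams) == 0) shape else {
    mean(vapply(fams, function(f) {
      if (is.null(fq[[f]]) || is.null(fr[[f]])) return(0)
      gaussian_tanimoto(fq[[f]], fr[[f]], radius)
    }, numeric(1)))
  }
  min(max(weights[1] * shape + weights[2] * feature, 0), 1)
}

#' Combined target-template similarity
#'
#' Places the template ligand into the target frame by Kabsch
#' superposition of the aligned pocket Calpha atoms (unless a precomputed
#' rigid transform is supplied), then reports SuCOS x pocket coverage.
#' With multiple target ligand instances the best instance is used.
#'
#' @param target reference_complex
#' @param template reference_complex
#' @param aln pocket_alignment (target residue keys -> template keys)
#' @param transform optional function mapping template-frame coordinates
#'   into the target frame (overrides the alignment-based superposition)
#' @param pocket_cutoff pocket definition cutoff, Angstrom
#' @return list of class `similarity_record`:
#'   sucos, pocket_coverage, combined, template_id
#' @export
combined_similarity <- function(target, template, aln, transform = NULL,
                                pocket_cutoff = 6.0) {
  tp <- pocket_residues(target, pocket_cutoff)
  mp <- pocket_residues(template, pocket_cutoff)
  cov <- pocket_coverage(tp, mp, aln)
  if (is.null(transform)) {
    ca_by_key <- function(prot) {
      a <- prot$atoms[prot$atoms$atom == "CA", , drop = FALSE]
      m <- as.matrix(a[, c("x", "y", "z")])
      rownames(m) <- paste(a$chain, a$resi, a$resn, sep = ":")
      m
    }
    tca <- ca_by_key(target$protein)
    mca <- ca_by_key(template$protein)
    ok <- aln$target_keys %in% rownames(tca) &
      aln$template_keys %in% rownames(mca)
    .assert(sum(ok) >= 3, "need >=3 aligned Calpha pairs for superposition")
    fit <- kabsch_superpose(tca[aln$target_keys[ok], , drop = FALSE],
                            mca[aln$template_keys[ok], , drop = FALSE])
    transform <- fit$transform
  }
  best <- 0
  for (tl in template$ligand_instances) {
    moved <- tl
    moved$xyz <- transform(tl$xyz)
    for (inst in target$ligand_instances) {
      best <- max(best, sucos(moved, inst))
    }
  }
  structure(list(sucos = best, pocket_coverage = cov,
                 combined = best * cov,
                 template_id = template$target_id),
            class = "similarity_record")
}

#' Best similarity across a template list
#'
#' @param target reference_complex
#' @param templates list of reference_complex
#' @param alns list of pocket_alignment, parallel to `templates`
#' @param ... passed to [combined_similarity()]
#' @return the similarity_record with the highest combined score; with no
#'   templates, a record with all scores 0 (a target with nothing similar
#'   in the library scores 0)
#' @export
best_similarity <- function(target, templates, alns, ...) {
  if (length(templates) == 0) {
    return(structure(list(sucos = 0, pocket_coverage = 0, combined = 0,
                          template_id = NA_character_),
                     class = "similarity_record"))
  }
  recs <- Map(function(tm, al) combined_similarity(target, tm, al, ...),
              templates, alns)
  recs[[which.max(vapply(recs, `[[`, numeric(1), "combined"))]]
}

#' @export
print.similarity_record <- function(x, ...) {
  cat(sprintf("<similarity_record %s> SuCOS %.3f x coverage %.3f = %.3f\n",
              x$template_id %||% "none", x$sucos, x$pocket_coverage,
              x$combined))
  invisible(x)
}
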