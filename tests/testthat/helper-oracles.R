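# Independent oracles and tiny fixtures used across the suite.  These are
# deliberately slow, brute-force implementations that share no code with
# the package internals they check.

# --- permutations ----------------------------------------------------------

all_perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# All element-preserving bijections from atoms of `el_a` onto `el_b`:
# cartesian product of within-class permutations.
element_preserving_perms <- function(el_a, el_b) {
  if (!identical(sort(el_a), sort(el_b))) return(list())
  classes <- unique(el_a)
  per_class <- lapply(classes, function(cl) {
    tgt <- which(el_b == cl)
    all_perms_of(tgt)
  })
  src <- lapply(classes, function(cl) which(el_a == cl))
  combos <- Reduce(function(acc, k) {
    out <- list()
    for (a in acc) for (p in per_class[[k]]) {
      perm <- a
      perm[src[[k]]] <- p
      out[[length(out) + 1]] <- perm
    }
    out
  }, seq_along(classes), init = list(integer(length(el_a))))
  combos
}

adj_of <- function(lig) {
  n <- length(lig$elements)
  adj <- matrix(0L, n, n)
  if (nrow(lig$bonds) > 0) {
    for (b in seq_len(nrow(lig$bonds))) {
      adj[lig$bonds[b, 1], lig$bonds[b, 2]] <- 1L
      adj[lig$bonds[b, 2], lig$bonds[b, 1]] <- 1L
    }
  }
  adj
}

# Valid isomorphisms a -> b by exhaustive filtering.
brute_isomorphisms <- function(a, b) {
  A <- adj_of(a); B <- adj_of(b)
  Filter(function(p) all(B[p, p] == A),
         element_preserving_perms(a$elements, b$elements))
}

# Brute-force symmetry-corrected RMSD between a reference instance and a
# pose already expressed in the reference frame.
brute_sym_rmsd <- function(instance, pose) {
  perms <- brute_isomorphisms(instance, pose)
  stopifnot(length(perms) > 0)
  min(vapply(perms, function(p) {
    sqrt(mean(rowSums((instance$xyz - pose$xyz[p, , drop = FALSE])^2)))
  }, numeric(1)))
}

# Brute-force LDDT-PLI by explicit loops: contacts, thresholds, penalty,
# max over all valid instance->pose isomorphisms.
brute_lddt_pli <- function(ref, instance, pred, pose, radius = 4,
                           thresholds = c(0.5, 1, 2, 4)) {
  env <- ref$protein$atoms
  ref_d <- matrix(NA_real_, nrow(instance$xyz), nrow(env))
  for (i in seq_len(nrow(instance$xyz))) for (j in seq_len(nrow(env))) {
    ref_d[i, j] <- sqrt(sum((instance$xyz[i, ] -
                               c(env$x[j], env$y[j], env$z[j]))^2))
  }
  pa <- pred$protein$atoms
  pkey <- paste(pa$chain, pa$resi, pa$atom)
  ekey <- paste(env$chain, env$resi, env$atom)
  prow <- match(ekey, pkey)
  best <- -Inf
  for (p in brute_isomorphisms(instance, pose)) {
    mod_d <- matrix(NA_real_, nrow(instance$xyz), nrow(env))
    for (i in seq_len(nrow(instance$xyz))) for (j in seq_len(nrow(env))) {
      if (is.na(prow[j])) next
      mod_d[i, j] <- sqrt(sum((pose$xyz[p[i], ] -
                                 c(pa$x[prow[j]], pa$y[prow[j]],
                                   pa$z[prow[j]]))^2))
    }
    hits <- 0; n_contacts <- 0; penalty <- 0
    for (i in seq_len(nrow(ref_d))) for (j in seq_len(ncol(ref_d))) {
      if (ref_d[i, j] <= radius) {
        n_contacts <- n_contacts + 1
        for (t in thresholds) {
          if (!is.na(mod_d[i, j]) && abs(mod_d[i, j] - ref_d[i, j]) <= t) {
            hits <- hits + 1
          }
        }
      } else if (!is.na(mod_d[i, j]) && mod_d[i, j] <= radius) {
        penalty <- penalty + 1
      }
    }
    if (n_contacts == 0) next
    s <- hits / (length(thresholds) * (n_contacts + penalty))
    best <- max(best, s)
  }
  best
}

# Brute-force LDDT-LP from raw coordinates: recompute the 4-A site, all
# inter-residue heavy-atom pairs, indicator counts.
brute_lddt_lp <- function(ref, instance, pred, cutoff = 4,
                          thresholds = c(0.5, 1, 2, 4)) {
  a <- ref$protein$atoms
  rkey <- paste(a$chain, a$resi, a$resn, sep = ":")
  in_site <- rep(FALSE, nrow(a))
  for (j in seq_len(nrow(a))) {
    dmin <- min(sqrt(rowSums(sweep(instance$xyz, 2,
                                   c(a$x[j], a$y[j], a$z[j]))^2)))
    if (dmin <= cutoff) in_site[rkey == rkey[j]] <- TRUE
  }
  sa <- a[in_site, , drop = FALSE]
  pa <- pred$protein$atoms
  prow <- match(paste(sa$chain, sa$resi, sa$atom),
                paste(pa$chain, pa$resi, pa$atom))
  hits <- 0; npair <- 0
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sa))) {
    if (j <= i) next
    if (sa$chain[i] == sa$chain[j] && sa$resi[i] == sa$resi[j]) next
    npair <- npair + 1
    dr <- sqrt(sum((c(sa$x[i], sa$y[i], sa$z[i]) -
                      c(sa$x[j], sa$y[j], sa$z[j]))^2))
    if (is.na(prow[i]) || is.na(prow[j])) next
    dm <- sqrt(sum((c(pa$x[prow[i]], pa$y[prow[i]], pa$z[prow[i]]) -
                      c(pa$x[prow[j]], pa$y[prow[j]], pa$z[prow[j]]))^2))
    for (t in thresholds) if (abs(dm - dr) <= t) hits <- hits + 1
  }
  hits / (length(thresholds) * npair)
}

# O(n^2) tie-corrected Kendall tau-b.
brute_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Closed-form expected tau when Gaussian noise of sd sigma is added to one
# copy of the data: pair (i,j) inverts with probability
# Phi(-|d_i - d_j| / (sigma * sqrt(2))).
analytic_ceiling_tau <- function(dg, sigma) {
  n <- length(dg)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + (1 - 2 * pnorm(-abs(dg[i] - dg[j]) / (sigma * sqrt(2))))
  }
  2 * s / (n * (n - 1))
}

# --- fixtures --------------------------------------------------------------

# A random connected ligand with <= n_atoms heavy atoms: random tree plus
# (sometimes) one ring-closing edge, elements from a small palette.
random_ligand <- function(n_atoms = 8, ring_prob = 0.3) {
  n <- sample(4:n_atoms, 1)
  elements <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- NULL
  for (i in 2:n) bonds <- rbind(bonds, c(sample(i - 1, 1), i, 1L))
  if (runif(1) < ring_prob && n >= 4) {
    free <- which(rowSums(adj_of(list(elements = elements,
                                      bonds = bonds))) < 3)
    if (length(free) >= 2) {
      pick <- sample(free, 2)
      if (!any(bonds[, 1] == min(pick) & bonds[, 2] == max(pick))) {
        bonds <- rbind(bonds, c(min(pick), max(pick), 1L))
      }
    }
  }
  ligand(elements, matrix(rnorm(3 * n, sd = 2), ncol = 3), bonds,
         instance_id = "rand")
}

# Relabel a ligand's atoms by a random permutation (graph-isomorphic copy).
shuffle_ligand <- function(lig) {
  n <- length(lig$elements)
  q <- sample(n)                     # new index of old atom i is q[i]
  bonds <- lig$bonds
  bonds[, 1] <- q[bonds[, 1]]; bonds[, 2] <- q[bonds[, 2]]
  xyz <- lig$xyz; xyz[q, ] <- lig$xyz
  el <- character(n); el[q] <- lig$elements
  ligand(el, xyz, bonds, instance_id = "shuffled")
}

# Deterministic miniature complex built around an arbitrary ligand via
# exported constructors only (independent of make_complex internals).
toy_complex_around <- function(lig, target_id = "TOY") {
  ctr <- colMeans(lig$xyz)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  rows <- NULL
  for (r in seq_len(nrow(dirs))) {
    u <- dirs[r, ]
    # CB 3.5 A out from the ligand atom most aligned with u
    proj <- as.numeric(sweep(lig$xyz, 2, ctr) %*% u)
    anchor <- lig$xyz[which.max(proj), ]
    cb <- anchor + 3.5 * u
    ca <- cb + 1.5 * u
    v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    rows <- rbind(rows,
      data.frame(chain = "A", resi = r, resn = "ALA", polymer = TRUE,
                 atom = c("N", "CA", "C", "O", "CB"),
                 element = c("N", "C", "C", "O", "C"),
                 x = c(ca[1] + 1.45 * v[1], ca[1], ca[1] - 1.5 * v[1],
                       ca[1] - 2.6 * v[1], cb[1]),
                 y = c(ca[2] + 1.45 * v[2], ca[2], ca[2] - 1.5 * v[2],
                       ca[2] - 2.6 * v[2], cb[2]),
                 z = c(ca[3] + 1.45 * v[3], ca[3], ca[3] - 1.5 * v[3],
                       ca[3] - 2.6 * v[3], cb[3])))
  }
  reference_complex(target_id, protein_structure(rows), list(lig))
}

# Identity prediction for a reference (protein copied verbatim).
identity_prediction <- function(ref, pose = ref$ligand_instances[[1]],
                                group_id = 1, model_num = 1) {
  pose$instance_id <- "pose1"
  predicted_entry(group_id, ref$target_id, model_num, protein = ref$protein,
                  ligand_poses = list(pose))
}
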