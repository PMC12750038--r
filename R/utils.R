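# Internal geometry and small-molecule helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Pairwise Euclidean distances between rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

min_cross_dist <- function(a, b) min(cross_dist(a, b))

rmsd_points <- function(a, b) {
  .assert(nrow(a) == nrow(b), "point sets differ in size")
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Apply rigid transform (rotation R, translation t) to an n x 3 matrix of rows.
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(R), 2, -t)
}

random_rigid_transform <- function() {
  R <- rotation_about_axis(random_unit_vector(), stats::runif(1, 0, 2 * pi))
  list(R = R, t = stats::runif(3, -20, 20))
}

# Standard atomic masses (u) for elements that occur in drug-like ligands.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Zn = 65.38, Br = 79.904, I = 126.904
)

#' Molecular weight from an element vector
#'
#' Sums standard atomic masses.  Used by the molecular-weight affinity
#' baseline; hydrogens may be passed explicitly (parsed ligands are
#' heavy-atom only, so supply `n_hydrogens` when a full formula weight
#' is wanted).
#'
#' @param elements character vector of element symbols
#' @param n_hydrogens implicit hydrogen count to add
#' @return molecular weight in g/mol
#' @export
molecular_weight <- function(elements, n_hydrogens = 0) {
  unknown <- setdiff(unique(elements), names(ATOMIC_MASS))
  .assert(length(unknown) == 0,
          paste("no mass for element(s):", paste(unknown, collapse = ", ")))
  sum(ATOMIC_MASS[elements]) + n_hydrogens * ATOMIC_MASS[["H"]]
}
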