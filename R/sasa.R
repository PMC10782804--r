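# Shrake-Rupley solvent-accessible surface area and per-residue buried
# surface area (BSA).
#
# Sphere test points are generated on a Fibonacci spiral and expressed in a
# molecule-fixed frame (principal axes of the atom cloud, with a
# rotation-equivariant sign convention), so SASA/BSA values are exactly
# invariant under rigid-body motion of the input coordinates.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80)

fibonacci_sphere <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5)) + phase
  cbind(r * cos(phi), r * sin(phi), z)
}

# Molecule-fixed orthonormal frame: principal axes of the coordinates,
# signs fixed against the atom farthest from the centroid (equivariant
# under proper rotations), right-handedness enforced.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 2L) return(diag(3))
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors
  far <- X[which.max(rowSums(X^2)), ]
  for (k in 1:2) {
    s <- sum(ev[, k] * far)
    if (abs(s) < 1e-9) s <- sum(ev[, k] * X[which.max(abs(X %*% ev[, k])), ])
    if (s < 0) ev[, k] <- -ev[, k]
  }
  ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
               ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
               ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  ev
}

# Per-atom SASA (Angstrom^2) for one coordinate set. `frame` fixes the
# sphere-point orientation; contexts compared in a difference (BSA) must
# share it so discretization error cancels. `phase` gives each atom its
# own azimuthal offset of the spiral (keyed by a stable atom id), which
# decorrelates quadrature error between atoms of a residue.
sasa_atoms <- function(xyz, elements, n_points = 100L, probe = 1.4,
                       frame = canonical_frame(xyz),
                       phase = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  radii <- VDW_RADII[elements]
  radii[is.na(radii)] <- 1.70
  R <- radii + probe
  golden <- pi * (3 - sqrt(5))
  pts_for <- function(ph) fibonacci_sphere(n_points, ph * golden) %*%
    t(frame)
  # neighbour lists under the largest possible contact distance
  sq <- rowSums(xyz^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R)^2
    nb <- which(D2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    P <- pts_for(phase[i]) * R[i] + matrix(xyz[i, ], n_points, 3,
                                           byrow = TRUE)
    NB <- xyz[nb, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(NB^2), "+") - 2 * P %*% t(NB)
    buried <- rowSums(d2 < matrix(R[nb]^2, n_points, length(nb),
                                  byrow = TRUE)) > 0
    out[i] <- 4 * pi * R[i]^2 * sum(!buried) / n_points
  }
  out
}

# Per-residue SASA for a context given by an atom subset of the complex.
residue_sasa <- function(complex, atom_sel, n_points = 100L, probe = 1.4,
                         frame = NULL) {
  a <- complex$atoms[atom_sel, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (is.null(frame)) frame <- canonical_frame(xyz)
  s <- sasa_atoms(xyz, a$element, n_points = n_points, probe = probe,
                  frame = frame, phase = which(atom_sel))
  rowsum(s, a$ridx)
}

#' Buried surface area of one residue upon complex formation
#'
#' BSA(res) = SASA of the residue with its own chain alone minus its SASA
#' with both chains present (Shrake-Rupley, probe 1.4 Angstrom), clipped at
#' zero.
#'
#' @param complex A \code{ppi_complex}.
#' @param residue Residue key \code{"chain:number:icode"} or row index into
#'   \code{complex$residues}.
#' @param n_points Sphere test points per atom (accuracy/speed trade-off).
#' @param probe Solvent probe radius, Angstrom.
#' @return BSA in Angstrom^2.
#' @seealso [compute_bsa_all()] for all residues at once.
#' @export
compute_bsa <- function(complex, residue, n_points = 100L, probe = 1.4) {
  if (is.character(residue)) {
    residue <- match(residue, complex$residues$key)
    if (is.na(residue)) stop("residue key not found")
  }
  compute_bsa_all(complex, n_points = n_points,
                  probe = probe)[[complex$residues$key[residue]]]
}

#' Buried surface area for every residue of a complex
#'
#' @inheritParams compute_bsa
#' @return Named numeric vector keyed by residue key.
#' @export
compute_bsa_all <- function(complex, n_points = 100L, probe = 1.4) {
  n <- nrow(complex$residues)
  # one molecule-fixed frame for every context, so the chain-alone and
  # complex SASA share sphere points and their difference is noise-free
  frame <- canonical_frame(as.matrix(complex$atoms[, c("x", "y", "z")]))
  both <- residue_sasa(complex, rep(TRUE, nrow(complex$atoms)),
                       n_points, probe, frame = frame)
  iso <- numeric(n)
  for (ch in complex$chains) {
    sel <- complex$atoms$chain == ch
    s <- residue_sasa(complex, sel, n_points, probe, frame = frame)
    iso[as.integer(rownames(s))] <- s
  }
  all_s <- numeric(n)
  all_s[as.integer(rownames(both))] <- both
  out <- pmax(iso - all_s, 0)
  names(out) <- complex$residues$key
  out
}
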