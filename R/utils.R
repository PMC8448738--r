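# Internal geometry and vocabulary helpers.

# Controlled vocabulary for subunit roles and region labels. The paper-style
# nomenclature (core cylinders A/A'/B/C/C' with trimer layers 1-4; rods
# R1-R3, Rb, Rs1, Rs2, Rt and their primed partners) lives in prose in the
# literature, not in coordinate files, so it is validated here as free text
# against these sets.
.pbs_roles <- c("ApcA", "ApcB", "ApcC", "ApcD", "ApcE", "ApcF",
                "CpcA", "CpcB", "CpcC", "CpcG", "other")
.alpha_roles_apc <- c("ApcA", "ApcD", "ApcE")
.beta_roles_apc  <- c("ApcB", "ApcF")
.pbs_cylinders <- c("A", "A'", "B", "C", "C'", "none")
.pbs_compartments <- c("core", "rod", "none")
.rod_names <- c("R1", "R1'", "R2", "R2'", "R3", "R3'",
                "Rb", "Rb'", "Rs1", "Rs1'", "Rs2", "Rs2'", "Rt", "Rt'", "none")

# Bilin chemical-component codes: phycocyanobilin, phycoerythrobilin,
# phycourobilin, phycoviolobilin, plus the packaged toy code used by the
# synthetic fixture generator.
.bilin_codes <- c("CYC", "PEB", "PUB", "PVB", "TBL")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
          "TRP", "TYR", "VAL")

.aromatic_res <- c("PHE", "TYR", "TRP", "HIS")

# Side-chain ring atom names for the aromatic residues (heavy atoms).
.aromatic_ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# Cationic-group heavy atoms.
.cation_atoms <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),  # guanidinium
  LYS = c("NZ"))                      # terminal amine

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero at a given number of digits
#'
#' Matches the convention used when comparing computed distances against
#' values printed at fixed precision (e.g. "5 A"), where 4.5 reports as 5.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Minimum Euclidean distance between two point sets (n x 3, m x 3 matrices).
.min_cross_dist <- function(a, b) {
  sqrt(max(0, min(.cross_dist2(a, b))))
}

# Squared cross-distance matrix, vectorised.
.cross_dist2 <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Index pair attaining the minimum cross distance (first in row-major order).
.argmin_cross <- function(a, b) {
  d2 <- .cross_dist2(a, b)
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(i = unname(ij[1]), j = unname(ij[2]), dist = sqrt(d2[ij[1], ij[2]]))
}

# Check a 3x3 rotation matrix: orthonormal, det +1.
.rotation_residual <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) return(Inf)
  max(max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
}

.check_rotation <- function(R, tol = 1e-6) {
  res <- .rotation_residual(R)
  if (!is.finite(res) || res > tol) {
    stop(sprintf("invalid placement: rotation is not a proper orthonormal matrix (residual %.3g > %.3g)",
                 res, tol), call. = FALSE)
  }
  invisible(TRUE)
}

# Rotation matrix mapping unit vector +z onto unit vector u.
.rotation_z_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antiparallel: flip about x
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Deterministic rotation matrix from three Euler-like angles.
.rotation_xyz <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Random proper rotation (uniform via QR of Gaussian matrix).
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# Centroid and unit normal of a near-planar ring: normal is the
# smallest-variance principal axis of the atom scatter.
.ring_plane <- function(xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) < 3) stop("degenerate plane: fewer than 3 ring atoms", call. = FALSE)
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9) stop("degenerate plane: collinear ring atoms", call. = FALSE)
  list(centroid = ctr, normal = sv$v[, 3])
}

# Angle between two undirected axes, folded to [0, 90] degrees.
.axis_angle_deg <- function(n1, n2) {
  c_ <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  c_ <- min(1, max(-1, c_))
  acos(c_) * 180 / pi
}

# xyz matrix from an atom data.frame.
.axyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

.fmt_id <- function(chain, resno) sprintf("%s/%s", chain, resno)
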