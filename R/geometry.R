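# Small vector-geometry kernel shared by the metric, rotamer and synthetic
# modules. All coordinates are Cartesian Angstrom; angles are degrees.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector")
  a / n
}

#' Torsion angle of four points
#'
#' Signed dihedral p1-p2-p3-p4 mapped to [0, 360) degrees, with 0 the cis
#' (eclipsed) and 180 the trans arrangement.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors, Angstrom.
#' @return Angle in degrees in [0, 360).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("collinear points: dihedral undefined")
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  ang %% 360
}

# NeRF placement: position atom D given A-B-C, the C-D bond length,
# the B-C-D bond angle (deg) and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  d2 <- length * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  frame <- cbind(bc, m, n)
  as.numeric(c + frame %*% d2)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of two matched coordinate sets by the
#' SVD-based Kabsch algorithm, with reflection correction so the returned
#' rotation is proper (det = +1).
#'
#' @param coords_ref N x 3 reference coordinates (Angstrom).
#' @param coords_mov N x 3 moving coordinates, matched row-by-row.
#' @return List with `rotation` (3 x 3, applied on the right of the centred
#'   moving set), `translation` (length 3), and `rmsd` (Angstrom). The fitted
#'   coordinates are `coords_mov %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  n <- nrow(coords_ref)
  if (n < 3 || nrow(coords_mov) != n)
    stop("need at least 3 matched points")
  cr <- colMeans(coords_ref)
  cm <- colMeans(coords_mov)
  xr <- sweep(coords_ref, 2, cr)
  xm <- sweep(coords_mov, 2, cm)
  if (svd(xr)$d[2] < 1e-9 || svd(xm)$d[2] < 1e-9)
    stop("degenerate (collinear) point set")
  h <- t(xm) %*% xr
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- xm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}
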