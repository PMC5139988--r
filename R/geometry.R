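# Internal 3D geometry primitives shared by the fixture builder and the
# dihedral Monte Carlo mover.

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

# Natural-extension placement: position a new atom bonded to c such that
# |new - c| = bond, angle(b, c, new) = ang (deg) and torsion(a, b, c, new) =
# tors (deg).
.placeAtom <- function(a, b, c, bond, ang, tors) {
    ang <- ang * pi / 180
    tors <- tors * pi / 180
    bc <- c - b
    bc <- bc / .vnorm(bc)
    ab <- b - a
    n <- .vcross(ab, bc)
    nn <- .vnorm(n)
    if (nn < 1e-10) stop("collinear reference atoms in placement")
    n <- n / nn
    m <- .vcross(n, bc)
    d2 <- c(-bond * cos(ang), bond * cos(tors) * sin(ang),
            bond * sin(tors) * sin(ang))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion about the p2-p3 axis, in degrees in (-180, 180].
#' The backbone phi angle of residue i is the torsion C(i-1)-N-CA-C; psi is
#' N-CA-C-N(i+1).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' computeDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180
#' @export
computeDihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1
    b2 <- p3 - p2
    b3 <- p4 - p3
    n1 <- .vcross(b1, b2)
    n2 <- .vcross(b2, b3)
    if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10)
        stop("collinear points: dihedral undefined")
    m1 <- .vcross(n1, b2 / .vnorm(b2))
    x <- sum(n1 * n2)
    y <- sum(m1 * n2)
    ang <- -atan2(y, x) * 180 / pi  # IUPAC sign convention
    if (ang <= -180) ang <- ang + 360
    ang
}

# Rodrigues rotation of coordinate rows `xyz` (n x 3) by `deg` degrees about
# the axis through `origin` with direction `axis`.
.rotateAbout <- function(xyz, origin, axis, deg) {
    th <- deg * pi / 180
    k <- axis / .vnorm(axis)
    x <- sweep(xyz, 2L, origin)
    kx <- cbind(k[2] * x[, 3] - k[3] * x[, 2],
                k[3] * x[, 1] - k[1] * x[, 3],
                k[1] * x[, 2] - k[2] * x[, 1])
    kdot <- as.numeric(x %*% k)
    rot <- x * cos(th) + kx * sin(th) +
        outer(kdot * (1 - cos(th)), k)
    sweep(rot, 2L, origin, `+`)
}
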