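# All-atom scattering intensity calculators: the exact orientationally
# averaged Debye sum (O(n^2), the reference), the golden-vector method
# (quasi-uniform directional quadrature, near-linear in atoms per
# direction), the pair-distance distribution P(r), and Gaussian beam
# smearing.

.frameCoords <- function(frame) {
    if (is(frame, "Structure")) return(coords(frame))
    if (is(frame, "Ensemble")) return(getFrame(frame, 1L))
    as.matrix(frame)
}

#' Quasi-uniform unit directions from the golden-ratio spiral
#'
#' Deterministic spherical grid: \code{z_k = 1 - (2k - 1)/m} and azimuth
#' \code{phi_k = 2 pi k / g} with \code{g = (1 + sqrt(5))/2}, k = 1..m.
#'
#' @param m number of directions (>= 1).
#' @return m x 3 matrix of unit vectors.
#' @examples
#' colMeans(goldenDirections(1000))  # near zero: quasi-uniform
#' @export
goldenDirections <- function(m) {
    m <- as.integer(m)
    if (is.na(m) || m < 1L) stop("m must be a positive integer")
    k <- seq_len(m)
    z <- 1 - (2 * k - 1) / m
    az <- 2 * pi * k / ((1 + sqrt(5)) / 2)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(az), r * sin(az), z)
}

#' Intensity by the golden-vector method
#'
#' Exact all-atom expression \code{I(Q) = (1/M) sum_m |sum_j f_j exp(i Q
#' u_m . r_j)|^2} with the directions u_m taken from the golden-ratio
#' spiral. Converges to the Debye sum as M grows; I(0) equals
#' \code{(sum f)^2} exactly.
#'
#' @param frame coordinate matrix (n x 3, Angstrom) or a [Structure-class].
#' @param amplitudes per-atom amplitudes (see [assignAmplitudes()]).
#' @param q Q grid in 1/Angstrom.
#' @param mDirections number of directions M (default 1000).
#' @return a [ScatteringCurve-class].
#' @seealso [intensityDebye()]
#' @export
intensityGolden <- function(frame, amplitudes, q, mDirections = 1000L) {
    xyz <- .frameCoords(frame)
    if (length(amplitudes) != nrow(xyz))
        stop("amplitude/coordinate length mismatch")
    dirs <- goldenDirections(mDirections)
    scatteringCurve(q, .cppGolden(xyz, as.numeric(amplitudes),
                                  as.numeric(q), dirs))
}

#' Intensity by the Debye equation
#'
#' Exact orientationally averaged intensity \code{I(Q) = sum_jk f_j f_k
#' sinc(Q r_jk)}. Cost grows with the square of the atom count; this is the
#' reference calculator against which faster methods are validated.
#'
#' @inheritParams intensityGolden
#' @return a [ScatteringCurve-class].
#' @seealso [intensityGolden()], [intensitySphereDebye()]
#' @export
intensityDebye <- function(frame, amplitudes, q) {
    xyz <- .frameCoords(frame)
    if (length(amplitudes) != nrow(xyz))
        stop("amplitude/coordinate length mismatch")
    scatteringCurve(q, .cppDebye(xyz, as.numeric(amplitudes), as.numeric(q)))
}

#' Pair-distance distribution function P(r)
#'
#' Weighted histogram of all interatomic distances (weight \code{2 f_j f_k}
#' per unordered pair), normalized per unit r so that
#' \code{sum(P) * binWidth = (sum f)^2 - sum(f^2)}. The support ends at the
#' maximum particle dimension D_max.
#'
#' @inheritParams intensityGolden
#' @param binWidth histogram bin width in Angstrom.
#' @return list with \code{r} (bin centres), \code{p} (P(r) per Angstrom),
#'   \code{binWidth} and \code{dmax}.
#' @export
prDistribution <- function(frame, amplitudes, binWidth = 1) {
    if (binWidth <= 0) stop("binWidth must be positive")
    xyz <- .frameCoords(frame)
    f <- as.numeric(amplitudes)
    if (length(f) != nrow(xyz)) stop("amplitude/coordinate length mismatch")
    if (nrow(xyz) < 2L)
        return(list(r = binWidth / 2, p = 0, binWidth = binWidth, dmax = 0))
    d <- as.vector(dist(xyz))
    fo <- outer(f, f)
    w <- 2 * fo[lower.tri(fo)]  # same pair order as dist()
    nb <- ceiling(max(d) / binWidth)
    bin <- pmin(nb, floor(d / binWidth) + 1L)
    p <- numeric(nb)
    sums <- tapply(w, bin, sum)
    p[as.integer(names(sums))] <- sums
    list(r = (seq_len(nb) - 0.5) * binWidth, p = p / binWidth,
         binWidth = binWidth, dmax = max(d))
}

#' Gaussian instrumental smearing
#'
#' Convolves the curve with a Q-dependent Gaussian kernel of width
#' \code{sigma(Q)^2 = sigmaGeo^2 + (Q dLambda/lambda)^2 / (8 ln 2)},
#' modelling beam divergence and wavelength spread of a (neutron)
#' instrument. Evaluated by trapezoidal quadrature on the curve's own grid
#' with per-point kernel normalization; zero parameters return the input
#' unchanged. A warning is issued when the kernel extends beyond the grid
#' (edge-truncated normalization).
#'
#' @param curve a [ScatteringCurve-class].
#' @param wavelengthSpread fractional FWHM wavelength spread (dLambda/lambda).
#' @param sigmaGeo geometric divergence term, 1/Angstrom.
#' @return a [ScatteringCurve-class].
#' @export
smearGaussian <- function(curve, wavelengthSpread = 0, sigmaGeo = 0) {
    if (wavelengthSpread < 0 || sigmaGeo < 0)
        stop("smearing parameters must be >= 0")
    q <- qValues(curve)
    i <- intensities(curve)
    if (wavelengthSpread == 0 && sigmaGeo == 0) return(curve)
    if (length(q) < 3L) stop("smearing needs at least 3 grid points")
    sig <- sqrt(sigmaGeo^2 + (q * wavelengthSpread)^2 / (8 * log(2)))
    # trapezoid weights of the grid
    n <- length(q)
    dq <- diff(q)
    wtrap <- c(dq[1] / 2, (dq[-1] + dq[-(n - 1)]) / 2, dq[n - 1] / 2)
    out <- numeric(n)
    truncated <- FALSE
    for (k in seq_len(n)) {
        if (sig[k] < 1e-12) { out[k] <- i[k]; next }
        if (q[k] - 3 * sig[k] < q[1] || q[k] + 3 * sig[k] > q[n])
            truncated <- TRUE
        kern <- exp(-0.5 * ((q - q[k]) / sig[k])^2) * wtrap
        out[k] <- sum(kern * i) / sum(kern)
    }
    if (truncated)
        warning("smearing kernel wider than grid margin; edge-truncated normalization")
    scatteringCurve(q, out, curve@sigma)
}
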