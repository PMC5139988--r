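# ASCII scattering-curve IO and curve utilities.

#' Read a scattering curve from a text file
#'
#' Reads whitespace-delimited columns Q, I(Q) and (optionally) the error of
#' I(Q); lines starting with '#' are skipped. Q is stored internally in
#' inverse Angstrom; data tabulated in inverse nanometre are converted with
#' \code{units = "nm"} (divide by 10).
#'
#' @param path file path.
#' @param units unit of the Q column in the file: \code{"A"} (1/Angstrom,
#'   default) or \code{"nm"} (1/nm).
#' @return a [ScatteringCurve-class].
#' @export
readCurve <- function(path, units = c("A", "nm")) {
    units <- match.arg(units)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("curve format error: no data rows in ", path)
    fields <- strsplit(lines, "[ \t]+")
    ncol <- unique(lengths(fields))
    if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
        stop("curve format error: expected 2 or 3 numeric columns")
    m <- suppressWarnings(
        matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE))
    if (anyNA(m)) stop("curve format error: non-numeric field")
    q <- m[, 1]
    if (units == "nm") q <- q / 10
    if (any(diff(q) <= 0))
        stop("curve ordering error: Q must be strictly increasing")
    sigma <- if (ncol == 3L) m[, 3] else numeric()
    if (length(sigma) && any(sigma < 0))
        stop("curve value error: negative sigma")
    if (length(sigma) && any(sigma == 0)) {
        # zero errors are treated as 'essentially exact' with a tiny floor
        sigma <- pmax(sigma, 1e-6 * max(abs(m[, 2]), 1e-300))
    }
    scatteringCurve(q, m[, 2], sigma)
}

#' Write a scattering curve to a text file
#'
#' Three columns (Q, I, sigma) when the curve carries uncertainties,
#' otherwise two, preceded by a '#' header line.
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file path.
#' @param units Q units to write: \code{"A"} (1/Angstrom) or \code{"nm"}.
#' @return invisibly, the path.
#' @export
writeCurve <- function(curve, path, units = c("A", "nm")) {
    units <- match.arg(units)
    q <- qValues(curve)
    if (units == "nm") q <- q * 10
    sig <- uncertainties(curve)
    if (is.null(sig)) {
        header <- sprintf("# Q(1/%s) I(Q)", if (units == "A") "Ang" else "nm")
        body <- sprintf("%.8g %.8g", q, intensities(curve))
    } else {
        header <- sprintf("# Q(1/%s) I(Q) err", if (units == "A") "Ang" else "nm")
        body <- sprintf("%.8g %.8g %.8g", q, intensities(curve), sig)
    }
    writeLines(c(header, body), path)
    invisible(path)
}

#' Interpolate a curve onto a new Q grid
#'
#' Linear interpolation of intensity (and sigma, when present) onto
#' \code{targetQ}; exact at shared nodes. Extrapolation is refused.
#'
#' @param curve a [ScatteringCurve-class].
#' @param targetQ strictly increasing grid within the source Q range.
#' @return a [ScatteringCurve-class] on \code{targetQ}.
#' @export
interpolateCurve <- function(curve, targetQ) {
    q <- qValues(curve)
    if (min(targetQ) < min(q) || max(targetQ) > max(q))
        stop(sprintf(
            "range error: target Q [%g, %g] outside source [%g, %g] (no extrapolation)",
            min(targetQ), max(targetQ), min(q), max(q)))
    i <- approx(q, intensities(curve), xout = targetQ)$y
    sig <- uncertainties(curve)
    sig_out <- if (is.null(sig)) numeric() else
        approx(q, sig, xout = targetQ)$y
    scatteringCurve(targetQ, i, sig_out)
}

#' Kratky transform of a curve
#'
#' Returns the curve \code{(Q, Q^2 I(Q))}, the standard diagnostic of compact
#' versus extended conformations (flat rise for random coils, bell-shaped
#' peak for globular particles).
#'
#' @param curve a [ScatteringCurve-class].
#' @return a [ScatteringCurve-class] holding Q^2 I(Q) (uncertainties, when
#'   present, are scaled by Q^2 as well).
#' @export
kratkyTransform <- function(curve) {
    q <- qValues(curve)
    sig <- uncertainties(curve)
    scatteringCurve(q, q^2 * intensities(curve),
                    if (is.null(sig)) numeric() else {
                        s <- q^2 * sig
                        # keep sigma positive at Q = 0
                        pmax(s, 1e-12 * max(s, 1e-300))
                    })
}

#' Add a linear buffer background
#'
#' Residual incoherent scattering (mostly from protons) leaves an
#' approximately linear background after buffer subtraction; this applies
#' \code{I'(Q) = I(Q) + a + b Q}.
#'
#' @param curve a [ScatteringCurve-class].
#' @param a constant term.
#' @param b slope in intensity units per 1/Angstrom.
#' @return a [ScatteringCurve-class].
#' @export
addBackground <- function(curve, a = 0, b = 0) {
    scatteringCurve(qValues(curve),
                    intensities(curve) + a + b * qValues(curve),
                    curve@sigma)
}
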