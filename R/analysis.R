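# Curve comparison and ensemble filtering: Guinier analysis, the three
# chi-square variants, the crystallography-style R factor, best-fit
# selection and volumetric occupancy envelopes.

#' Guinier fit
#'
#' Weighted least squares of ln I against Q^2 over the low-Q region,
#' iterated until every included point satisfies \code{Q Rg <= qrgMax}
#' (default 1.3, the conventional globular-protein bound). Returns
#' \code{I(0) = exp(intercept)} and \code{Rg = sqrt(-3 slope)}.
#'
#' @param curve a [ScatteringCurve-class] (positive intensities in the
#'   fitted region).
#' @param qrgMax upper bound on Q Rg for included points.
#' @return list with \code{i0}, \code{rg} (Angstrom), \code{nPoints} and
#'   \code{qmax} actually used.
#' @export
guinierFit <- function(curve, qrgMax = 1.3) {
    q <- qValues(curve)
    i <- intensities(curve)
    sig <- uncertainties(curve)
    use <- rep(TRUE, length(q))
    for (iter in 1:50) {
        sel <- use & i > 0 & q > 0
        if (sum(sel) < 3L)
            stop("Guinier fit error: fewer than 3 usable low-Q points")
        x <- q[sel]^2
        y <- log(i[sel])
        w <- if (is.null(sig)) rep(1, sum(sel)) else (i[sel] / sig[sel])^2
        fit <- lm(y ~ x, weights = w)
        slope <- coef(fit)[[2]]
        if (slope >= 0)
            stop("Guinier fit error: no Guinier region (ln I not decreasing)")
        rg <- sqrt(-3 * slope)
        keep <- q * rg <= qrgMax
        if (identical(keep, use)) break
        use <- keep
    }
    list(i0 = exp(coef(fit)[[1]]), rg = rg, nPoints = sum(sel),
         qmax = max(q[sel]))
}

# common grid + scale factor for the comparison metrics: model interpolated
# onto the experimental grid (preserving experimental sigma), scaled by
# c = I(0)_expt / I(0)_model
.alignCurves <- function(model, expt, i0Expt, autoScale = FALSE) {
    qe <- qValues(expt)
    qm <- qValues(model)
    sel <- qe >= min(qm) & qe <= max(qm)
    if (!any(sel)) stop("range error: model and experimental Q do not overlap")
    im <- approx(qm, intensities(model), xout = qe[sel])$y
    ie <- intensities(expt)[sel]
    sig <- uncertainties(expt)
    if (!is.null(sig)) sig <- sig[sel]
    cc <- if (autoScale) {
        w <- if (is.null(sig)) rep(1, length(im)) else 1 / sig^2
        sum(w * im * ie) / sum(w * im^2)  # least-squares scale
    } else {
        i0m <- intensities(model)[which.min(qm)]
        if (!is.null(i0Expt)) i0Expt / i0m else 1
    }
    list(ie = ie, im = cc * im, sig = sig, scale = cc, n = length(im))
}

#' Chi-square comparison of a model curve with experiment
#'
#' The model is interpolated onto the experimental grid and scaled by
#' \code{c = I(0)_expt / I(0)_model}. Variants: \code{chi2 = sum[(I_e - c
#' I_m)/sigma]^2}; \code{chi2_reduced = chi2/(N - 1)} (one fitted scale);
#' \code{chi2_pearson = sum (I_e - c I_m)^2 / (c I_m)} (no sigma needed).
#'
#' @param model model [ScatteringCurve-class].
#' @param expt experimental-style [ScatteringCurve-class]; must carry sigma
#'   for the chi2 variants.
#' @param i0Expt experimental I(0) (from Guinier or P(r) analysis) used for
#'   scaling; NULL with \code{autoScale = TRUE} uses least squares instead.
#' @param variant "chi2_reduced" (default), "chi2" or "chi2_pearson".
#' @param autoScale least-squares scale instead of the I(0) ratio.
#' @return the metric value (non-negative scalar).
#' @seealso [rFactor()], [fitEnsemble()]
#' @export
chiSquare <- function(model, expt, i0Expt = NULL,
                      variant = c("chi2_reduced", "chi2", "chi2_pearson"),
                      autoScale = FALSE) {
    variant <- match.arg(variant)
    al <- .alignCurves(model, expt, i0Expt, autoScale)
    if (variant == "chi2_pearson") {
        return(sum((al$ie - al$im)^2 / al$im))
    }
    if (is.null(al$sig))
        stop("value error: experimental sigma required for ", variant)
    chi2 <- sum(((al$ie - al$im) / al$sig)^2)
    if (variant == "chi2") chi2 else chi2 / (al$n - 1)
}

#' R factor between model and experimental curves
#'
#' Crystallography-style normalized absolute deviation, in percent:
#' \code{R = 100 sum |I_e - c I_m| / sum |I_e|}, with c the I(0) scale.
#' Typical best-fit values for SAXS/SANS analyses fall between 2 and 8
#' percent.
#'
#' @inheritParams chiSquare
#' @return R factor in percent.
#' @export
rFactor <- function(model, expt, i0Expt = NULL, autoScale = FALSE) {
    al <- .alignCurves(model, expt, i0Expt, autoScale)
    denom <- sum(abs(al$ie))
    if (denom == 0) stop("value error: experimental curve sums to zero")
    100 * sum(abs(al$ie - al$im)) / denom
}

#' Fit every ensemble frame against an experimental curve
#'
#' Computes each frame's Debye-equation curve directly on the experimental Q
#' grid, then all comparison metrics and the frame Rg. This is the per-frame
#' record table that [filterModels()] consumes.
#'
#' @param ens an [Ensemble-class] (or [MCResult-class]).
#' @param expt experimental-style [ScatteringCurve-class] with sigma.
#' @param i0Expt experimental I(0) used for scaling.
#' @param amplitudes per-atom amplitudes; default neutron amplitudes of the
#'   topology.
#' @return data.frame with columns \code{frame}, \code{chi2},
#'   \code{chi2_reduced}, \code{chi2_pearson}, \code{r_factor},
#'   \code{scale_c}, \code{rg}.
#' @export
fitEnsemble <- function(ens, expt, i0Expt,
                        amplitudes = assignAmplitudes(
                            if (is(ens, "MCResult")) ens@ensemble@topology
                            else ens@topology)) {
    if (is(ens, "MCResult")) ens <- ens@ensemble
    qe <- qValues(expt)
    ie <- intensities(expt)
    sig <- uncertainties(expt)
    if (is.null(sig)) stop("value error: experimental sigma required")
    nf <- nFrames(ens)
    out <- data.frame(frame = seq_len(nf), chi2 = NA_real_,
                      chi2_reduced = NA_real_, chi2_pearson = NA_real_,
                      r_factor = NA_real_, scale_c = NA_real_, rg = NA_real_)
    f <- as.numeric(amplitudes)
    i0m <- sum(f)^2
    w <- rep(1, nAtoms(ens))
    for (k in seq_len(nf)) {
        fr <- getFrame(ens, k)
        im <- .cppDebye(fr, f, qe)
        cc <- i0Expt / i0m
        res <- ie - cc * im
        chi2 <- sum((res / sig)^2)
        out$chi2[k] <- chi2
        out$chi2_reduced[k] <- chi2 / (length(qe) - 1)
        out$chi2_pearson[k] <- sum(res^2 / (cc * im))
        out$r_factor[k] <- 100 * sum(abs(res)) / sum(abs(ie))
        out$scale_c[k] <- cc
        out$rg[k] <- .rgWeighted(fr, w)
    }
    out
}

#' Select best-fit frames
#'
#' Criteria: a metric threshold (\code{metric < threshold}), a best-N rank,
#' and/or an Rg window combined with the metric (e.g. frames within 10
#' percent of an experimental Rg). Returns sorted frame indices; an empty
#' selection is returned with a warning, not an error.
#'
#' @param fits data.frame from [fitEnsemble()] (needs the metric column and,
#'   for Rg windows, \code{rg}).
#' @param metric column name to filter on (default "chi2_reduced").
#' @param threshold keep frames with metric strictly below this value.
#' @param bestN keep the N lowest-metric frames.
#' @param rgWindow optional \code{c(low, high)} Rg window in Angstrom.
#' @return integer vector of frame indices, sorted.
#' @export
filterModels <- function(fits, metric = "chi2_reduced", threshold = Inf,
                         bestN = NULL, rgWindow = NULL) {
    if (!nrow(fits)) stop("empty fit table")
    if (!metric %in% names(fits)) stop("unknown metric column: ", metric)
    keep <- fits[[metric]] < threshold
    if (!is.null(rgWindow))
        keep <- keep & fits$rg >= rgWindow[1] & fits$rg <= rgWindow[2]
    idx <- fits$frame[keep]
    if (!is.null(bestN)) {
        ord <- order(fits[[metric]][keep])
        idx <- idx[head(ord, bestN)]
    }
    idx <- sort(idx)
    if (!length(idx)) warning("no frames pass the filter criterion")
    idx
}

#' Accumulate a volumetric occupancy map over selected frames
#'
#' Counts (frame, atom) events on a cubic voxel grid spanning the selected
#' frames' bounding box plus a one-voxel margin. The scalar field written to
#' cube files is the occupancy counts/n_frames.
#'
#' @param ens an [Ensemble-class].
#' @param frames integer indices of the frames to accumulate (default all).
#' @param spacing voxel edge in Angstrom.
#' @return a [DensityGrid-class].
#' @seealso [writeCube()]
#' @export
densityMap <- function(ens, frames = seq_len(nFrames(ens)), spacing = 2.0) {
    if (spacing <= 0) stop("spacing must be positive")
    if (!length(frames)) stop("value error: no frames selected")
    if (any(frames < 1L | frames > nFrames(ens)))
        stop("frame index out of range")
    sel <- ens@frames[frames]
    lo <- Reduce(pmin, lapply(sel, function(f) apply(f, 2L, min)))
    hi <- Reduce(pmax, lapply(sel, function(f) apply(f, 2L, max)))
    origin <- lo - spacing  # one-voxel margin
    dims <- as.integer(ceiling((hi - origin) / spacing) + 1L)
    counts <- array(0L, dim = dims)
    for (f in sel) {
        ijk <- floor(sweep(sweep(f, 2L, origin), 2L, spacing, `/`)) + 1L
        lin <- ijk[, 1] + dims[1] * ((ijk[, 2] - 1L) +
                                         dims[2] * (ijk[, 3] - 1L))
        tab <- tabulate(lin, nbins = prod(dims))
        counts <- counts + array(tab, dim = dims)
    }
    new("DensityGrid", origin = as.numeric(origin), spacing = spacing,
        counts = counts, nFrames = length(frames))
}

#' Write a density grid as a Gaussian cube file
#'
#' Standard text cube format: two comment lines, atom count and origin,
#' three axis records, atom records, then the scalar field (occupancy =
#' counts/n_frames) in z-fastest order. Lengths are converted to Bohr
#' (1 Angstrom = 1.8897259886 Bohr) per the format convention.
#'
#' @param grid a [DensityGrid-class].
#' @param path output file path.
#' @param structure optional [Structure-class] whose atoms are written as
#'   the cube's atom records (else a single dummy atom at the origin).
#' @return invisibly, the path.
#' @export
writeCube <- function(grid, path, structure = NULL) {
    bohr <- 1.8897259886
    d <- dim(grid@counts)
    occ <- grid@counts / grid@nFrames
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("scatterfit ensemble occupancy map",
                 sprintf("counts over %d frames, occupancy scalar field",
                         grid@nFrames)), con)
    natoms <- if (is.null(structure)) 1L else nAtoms(structure)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natoms,
                       grid@origin[1] * bohr, grid@origin[2] * bohr,
                       grid@origin[3] * bohr), con)
    sp <- grid@spacing * bohr
    writeLines(c(sprintf("%5d %11.6f %11.6f %11.6f", d[1], sp, 0, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, sp, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, sp)), con)
    if (is.null(structure)) {
        writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0,
                           grid@origin[1] * bohr, grid@origin[2] * bohr,
                           grid@origin[3] * bohr), con)
    } else {
        z <- .elementLookup(.ELECTRONS, atoms(structure)$element,
                            "electron count")
        xyz <- coords(structure) * bohr
        writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", as.integer(z),
                           as.numeric(z), xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
    for (ix in seq_len(d[1]))
        for (iy in seq_len(d[2])) {
            vals <- occ[ix, iy, ]
            writeLines(paste(sprintf("%13.5e", vals), collapse = " "), con)
        }
    invisible(path)
}
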