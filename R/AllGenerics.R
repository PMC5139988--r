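#' @useDynLib scatterfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx dist lm coef rnorm runif setNames weighted.mean
#' @importFrom utils head tail
NULL

#' Accessors for scatterfit objects
#'
#' Small generic surface over the S4 containers: \code{atoms()} returns the
#' atom table, \code{coords()} the coordinates of a structure or of one
#' ensemble frame, \code{nAtoms()}/\code{nFrames()} the obvious counts,
#' \code{qValues()}, \code{intensities()} and \code{uncertainties()} the
#' columns of a scattering curve.
#'
#' @param x a scatterfit object.
#' @param frame frame index for ensembles.
#' @param value replacement coordinates.
#' @return the requested component.
#' @name accessors
#' @aliases atoms coords coords<- nAtoms nFrames getFrame qValues
#'   intensities uncertainties
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, frame) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("uncertainties", function(x) standardGeneric("uncertainties"))
#' @rdname accessors
#' @export
setGeneric("isClean", function(x) standardGeneric("isClean"))

#' @rdname accessors
setMethod("atoms", "Structure", function(x) x@atoms)
#' @rdname accessors
setMethod("coords", "Structure", function(x, ...) x@coords)
#' @rdname accessors
setMethod("coords<-", "Structure", function(x, value) {
    x@coords <- value
    validObject(x)
    x
})
#' @rdname accessors
setMethod("nAtoms", "Structure", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("nAtoms", "Ensemble", function(x) nAtoms(x@topology))
#' @rdname accessors
setMethod("nFrames", "Ensemble", function(x) length(x@frames))
#' @rdname accessors
setMethod("atoms", "Ensemble", function(x) atoms(x@topology))
#' @rdname accessors
setMethod("getFrame", "Ensemble", function(x, frame) {
    if (frame < 1L || frame > length(x@frames))
        stop("frame index out of range")
    x@frames[[frame]]
})
#' @rdname accessors
setMethod("coords", "Ensemble", function(x, frame = 1L, ...) getFrame(x, frame))
#' @rdname accessors
setMethod("qValues", "ScatteringCurve", function(x) x@q)
#' @rdname accessors
setMethod("intensities", "ScatteringCurve", function(x) x@i)
#' @rdname accessors
setMethod("uncertainties", "ScatteringCurve", function(x)
    if (length(x@sigma)) x@sigma else NULL)
#' @rdname accessors
setMethod("isClean", "ScanReport", function(x) x@clean)
#' @rdname accessors
setMethod("coords", "SphereModel", function(x, ...) x@centers)
#' @rdname accessors
setMethod("nAtoms", "SphereModel", function(x) nrow(x@centers))

#' Construct a scattering curve
#'
#' @param q strictly increasing non-negative grid (1/Angstrom).
#' @param i intensities.
#' @param sigma optional per-point uncertainties (positive).
#' @return a [ScatteringCurve-class].
#' @examples
#' scatteringCurve(c(0.01, 0.02), c(100, 99), c(1, 1))
#' @export
scatteringCurve <- function(q, i, sigma = numeric()) {
    new("ScatteringCurve", q = as.numeric(q), i = as.numeric(i),
        sigma = as.numeric(sigma))
}

#' Construct an ensemble from a topology and frames
#'
#' @param topology a [Structure-class].
#' @param frames list of n_atoms x 3 coordinate matrices; defaults to the
#'   topology's own coordinates as a single frame.
#' @return an [Ensemble-class].
#' @export
ensemble <- function(topology, frames = list(coords(topology))) {
    frames <- lapply(frames, function(f) {
        f <- as.matrix(f)
        dimnames(f) <- NULL
        f
    })
    new("Ensemble", topology = topology, frames = frames)
}

setMethod("show", "Structure", function(object) {
    a <- object@atoms
    cat("Structure:", nrow(a), "atoms,",
        length(unique(paste(a$chain, a$resid)[!a$is_het])), "residues,",
        length(unique(a$chain)), "chain(s)\n")
    if (nzchar(object@title)) cat("  title:", object@title, "\n")
    if (length(object@remarks))
        cat("  header remarks retained:", length(object@remarks), "lines\n")
})

setMethod("show", "Ensemble", function(object) {
    cat("Ensemble:", nFrames(object), "frames x", nAtoms(object), "atoms\n")
})

setMethod("show", "ScatteringCurve", function(object) {
    cat(sprintf("ScatteringCurve: %d points, Q in [%.4g, %.4g] 1/Ang%s\n",
        length(object@q), min(object@q), max(object@q),
        if (length(object@sigma)) ", with uncertainties" else ""))
})

setMethod("show", "SphereModel", function(object) {
    cat(sprintf("SphereModel: %d dry + %d hydration spheres, R = %.3f Ang (cube %.3f Ang)\n",
        sum(!object@isHydration), sum(object@isHydration),
        object@radius, object@cubeSide))
})

setMethod("show", "ScanReport", function(object) {
    cat("ScanReport:", if (object@clean) "clean" else "NOT clean", "\n")
    cat("  chain gaps:          ", nrow(object@chainGaps), "\n")
    cat("  residues w/ missing: ", nrow(object@missingAtoms), "\n")
    cat("  nonstandard residues:", nrow(object@nonstandardResidues), "\n")
    cat("  HET residue types:   ", length(object@hetInventory), "\n")
    cat("  disulphides:         ", nrow(object@disulphides), "\n")
    cat("  BIOMT operators:     ", object@biomtCount, "\n")
})

setMethod("show", "MCResult", function(object) {
    cat(sprintf("MCResult: %d accepted / %d trials (%.1f%%)\n",
        object@nAccepted, object@nTrials,
        100 * object@nAccepted / max(1L, object@nTrials)))
    if (length(object@rejectionCounts)) {
        cat("  rejections:",
            paste(names(object@rejectionCounts), object@rejectionCounts,
                  sep = "=", collapse = ", "), "\n")
    }
    if (length(object@perFrameRg))
        cat(sprintf("  Rg range: %.2f - %.2f Ang\n",
            min(object@perFrameRg), max(object@perFrameRg)))
})

setMethod("show", "DensityGrid", function(object) {
    d <- dim(object@counts)
    cat(sprintf("DensityGrid: %d x %d x %d voxels, spacing %.2f Ang, %d frames\n",
        d[1], d[2], d[3], object@spacing, object@nFrames))
})
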