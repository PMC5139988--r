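#' @import methods
NULL

#' Atomistic structure
#'
#' The universal coordinate container: an ordered table of named atoms with
#' chain/residue identity plus an \code{n x 3} coordinate matrix in Angstrom.
#' Atom order is stable and defines the layout of every trajectory frame
#' derived from the structure.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{chain}, \code{resid},
#'   \code{is_het}, \code{altloc} (one row per atom).
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot title character scalar.
#' @slot remarks character vector of header lines retained verbatim
#'   (REMARK 350 rows used for biological-unit expansion).
#'
#' @seealso [readPDB()], [buildPolypeptide()], [scanStructure()]
#' @export
setClass("Structure",
    representation(atoms = "data.frame", coords = "matrix",
                   title = "character", remarks = "character"),
    prototype(title = "", remarks = character()))

setValidity("Structure", function(object) {
    a <- object@atoms
    need <- c("serial", "name", "element", "resname", "chain", "resid",
              "is_het", "altloc")
    if (!all(need %in% names(a)))
        return(paste("atoms table must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(a) != nrow(object@coords))
        return("atoms table and coordinate matrix disagree in length")
    if (nrow(a) > 0L) {
        if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
        if (!all(is.finite(object@coords))) return("non-finite coordinates")
        if (any(!nzchar(a$element))) return("empty element symbol")
        key <- paste(a$chain, a$resid, a$name, a$altloc)
        if (anyDuplicated(key))
            return("duplicated (chain, resid, name, altloc) atom identity")
    }
    TRUE
})

#' Conformational ensemble
#'
#' An ordered collection of coordinate frames sharing one [Structure-class]
#' topology (the in-memory analogue of a DCD trajectory).
#'
#' @slot topology a [Structure-class].
#' @slot frames list of numeric \code{n_atoms x 3} matrices (Angstrom).
#'
#' @seealso [readDCD()], [runMonomerMC()]
#' @export
setClass("Ensemble",
    representation(topology = "Structure", frames = "list"))

setValidity("Ensemble", function(object) {
    n <- nAtoms(object@topology)
    if (length(object@frames) < 1L) return("ensemble needs at least one frame")
    ok <- vapply(object@frames, function(f)
        is.matrix(f) && nrow(f) == n && ncol(f) == 3L, logical(1))
    if (!all(ok)) return("every frame must be an n_atoms x 3 matrix")
    TRUE
})

#' Scattering curve
#'
#' A one-dimensional scattering profile: momentum-transfer grid Q (inverse
#' Angstrom, \code{Q = 4 pi sin(theta)/lambda}), intensity I(Q) in arbitrary
#' units, and optional per-point uncertainty.
#'
#' @slot q strictly increasing, non-negative numeric grid (1/Angstrom).
#' @slot i intensity at each Q.
#' @slot sigma per-point uncertainty (same units as \code{i}); length zero
#'   when the curve carries no error estimates.
#'
#' @seealso [readCurve()], [intensityDebye()], [chiSquare()]
#' @export
setClass("ScatteringCurve",
    representation(q = "numeric", i = "numeric", sigma = "numeric"),
    prototype(sigma = numeric()))

setValidity("ScatteringCurve", function(object) {
    if (length(object@q) == 0L) return("empty Q grid")
    if (length(object@i) != length(object@q))
        return("i and q differ in length")
    if (any(!is.finite(object@q)) || any(object@q < 0))
        return("Q grid must be finite and non-negative")
    if (any(diff(object@q) <= 0)) return("Q grid must be strictly increasing")
    if (length(object@sigma) &&
        (length(object@sigma) != length(object@q) || any(object@sigma <= 0)))
        return("sigma must match q in length and be positive")
    TRUE
})

#' Coarse-grained sphere model
#'
#' Cube-grid decomposition of an atomistic structure into equal spheres of
#' volume matching the grid cube (radius \code{cube_side * (3/(4 pi))^(1/3)}),
#' optionally extended by a hydration monolayer of water-filled surface cubes.
#'
#' @slot centers numeric \code{n x 3} matrix of sphere centres (Angstrom).
#' @slot radius common sphere radius (Angstrom).
#' @slot cubeSide edge of the decomposition cube (Angstrom).
#' @slot isHydration logical per sphere, TRUE for hydration-shell spheres.
#' @slot atomsPerSphere integer per sphere (0 for hydration spheres).
#' @slot anchor 3-vector, grid origin (coordinate minimum of the source
#'   frame).
#' @slot partialCubes integer matrix of lattice coordinates of cubes that
#'   hold at least one atom but fewer than the cutoff; such cubes are part
#'   of the particle, not bulk solvent, and are therefore not eligible to
#'   receive hydration water.
#'
#' @seealso [buildSphereModel()], [addHydration()], [intensitySphereDebye()]
#' @export
setClass("SphereModel",
    representation(centers = "matrix", radius = "numeric",
                   cubeSide = "numeric", isHydration = "logical",
                   atomsPerSphere = "integer", anchor = "numeric",
                   partialCubes = "matrix"),
    prototype(anchor = c(0, 0, 0),
              partialCubes = matrix(integer(), ncol = 3)))

setValidity("SphereModel", function(object) {
    n <- nrow(object@centers)
    if (n < 1L) return("empty sphere model")
    if (ncol(object@centers) != 3L) return("centers must be n x 3")
    if (length(object@isHydration) != n || length(object@atomsPerSphere) != n)
        return("per-sphere flags must match the number of centres")
    if (object@radius <= 0 || object@cubeSide <= 0)
        return("radius and cubeSide must be positive")
    if (abs(object@radius - object@cubeSide * (3 / (4 * pi))^(1 / 3)) > 1e-6)
        return("radius must equal cubeSide * (3/(4*pi))^(1/3)")
    TRUE
})

#' Volumetric occupancy grid
#'
#' Voxel counts of (frame, atom) events over a set of ensemble frames, the
#' basis of the density-envelope Gaussian cube output.
#'
#' @slot origin 3-vector, corner of the grid (Angstrom).
#' @slot spacing voxel edge (Angstrom).
#' @slot counts 3D integer-valued array of voxel counts.
#' @slot nFrames number of frames accumulated.
#'
#' @seealso [densityMap()], [writeCube()]
#' @export
setClass("DensityGrid",
    representation(origin = "numeric", spacing = "numeric",
                   counts = "array", nFrames = "integer"))

setValidity("DensityGrid", function(object) {
    if (length(object@origin) != 3L) return("origin must be a 3-vector")
    if (object@spacing <= 0) return("spacing must be positive")
    if (length(dim(object@counts)) != 3L) return("counts must be a 3D array")
    if (any(object@counts < 0)) return("negative voxel count")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    TRUE
})

#' Structure validation report
#'
#' Result of [scanStructure()]: chain gaps, missing heavy atoms against the
#' standard amino-acid templates, nonstandard residues, HET inventory,
#' disulphide bridges and the count of biological-unit symmetry operators
#' found in the header. \code{clean} is TRUE iff gaps, missing atoms and
#' nonstandard residues are all absent.
#'
#' @slot chainGaps data.frame: chain, resid_before, resid_after, reason.
#' @slot missingAtoms data.frame: chain, resid, resname, atoms (list column).
#' @slot nonstandardResidues data.frame: chain, resid, resname.
#' @slot hetInventory named integer vector, residue name -> count.
#' @slot disulphides data.frame: chain1, resid1, chain2, resid2, distance.
#' @slot biomtCount integer.
#' @slot clean logical.
#'
#' @export
setClass("ScanReport",
    representation(chainGaps = "data.frame", missingAtoms = "data.frame",
                   nonstandardResidues = "data.frame",
                   hetInventory = "integer", disulphides = "data.frame",
                   biomtCount = "integer", clean = "logical"))

setValidity("ScanReport", function(object) {
    want <- nrow(object@chainGaps) == 0L && nrow(object@missingAtoms) == 0L &&
        nrow(object@nonstandardResidues) == 0L
    if (!identical(object@clean, want))
        return("clean flag inconsistent with report contents")
    TRUE
})

#' Monte Carlo run result
#'
#' @slot ensemble accepted frames as an [Ensemble-class].
#' @slot nTrials total trial moves attempted.
#' @slot nAccepted accepted moves (= number of frames).
#' @slot rejectionCounts named integer vector of rejection reasons.
#' @slot perFrameRg radius of gyration of each accepted frame (Angstrom).
#'
#' @seealso [runMonomerMC()]
#' @export
setClass("MCResult",
    representation(ensemble = "Ensemble", nTrials = "integer",
                   nAccepted = "integer", rejectionCounts = "integer",
                   perFrameRg = "numeric"))

setValidity("MCResult", function(object) {
    if (object@nAccepted != length(object@ensemble@frames))
        return("nAccepted must equal the number of frames")
    if (object@nAccepted > object@nTrials)
        return("nAccepted cannot exceed nTrials")
    if (length(object@perFrameRg) != object@nAccepted)
        return("perFrameRg must have one value per frame")
    TRUE
})
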