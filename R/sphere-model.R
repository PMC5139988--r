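# Coarse-grained cube-sphere modelling: decompose an atomistic structure on
# a cube grid into equal-volume spheres (each representing about 4-5 atoms),
# optionally add a hydration monolayer of water-filled surface cubes, and
# compute the scattering curve by the Debye equation adapted to small
# spheres (valid while the sphere diameter stays below the structural
# resolution of the curve, about 1 nm).

# integer lattice coordinates of sphere centres relative to the grid anchor
.sphereLattice <- function(model) {
    floor(sweep(sweep(model@centers, 2L, model@anchor), 2L,
                model@cubeSide, `/`))
}

#' Build a coarse-grained sphere model
#'
#' Lays an axis-aligned cube grid (anchored at the coordinate minimum) over
#' the frame; every cube containing at least \code{atomCutoff} atoms becomes
#' one dry sphere at the cube centre. The common sphere radius
#' \code{cubeSide (3/(4 pi))^(1/3)} makes sphere volume equal cube volume.
#' The defaults (cube side 5.30 Angstrom, cutoff 4 atoms) give roughly one
#' sphere per 4-5 atoms for packed proteins.
#'
#' @param frame coordinate matrix (n x 3, Angstrom) or a [Structure-class].
#' @param cubeSide grid cube edge, Angstrom (default 5.30).
#' @param atomCutoff minimum atoms per occupied cube (default 4).
#' @return a [SphereModel-class] (dry spheres only).
#' @export
buildSphereModel <- function(frame, cubeSide = 5.30, atomCutoff = 4L) {
    if (cubeSide <= 0) stop("cubeSide must be positive")
    if (atomCutoff < 1L) stop("atomCutoff must be >= 1")
    xyz <- .frameCoords(frame)
    anchor <- apply(xyz, 2L, min)
    idx <- floor(sweep(sweep(xyz, 2L, anchor), 2L, cubeSide, `/`))
    key <- paste(idx[, 1], idx[, 2], idx[, 3])
    counts <- table(key)
    keep <- names(counts)[counts >= atomCutoff]
    if (!length(keep))
        stop("empty sphere model: no cube reaches the atom cutoff of ",
             atomCutoff)
    ijk <- do.call(rbind, lapply(strsplit(keep, " "), as.numeric))
    centers <- sweep((ijk + 0.5) * cubeSide, 2L, anchor, `+`)
    dimnames(centers) <- NULL
    partial <- setdiff(names(counts), keep)
    pmat <- if (length(partial))
        do.call(rbind, lapply(strsplit(partial, " "),
                              function(v) as.integer(as.numeric(v))))
    else matrix(integer(), ncol = 3)
    new("SphereModel", centers = centers,
        radius = cubeSide * (3 / (4 * pi))^(1 / 3), cubeSide = cubeSide,
        isHydration = rep(FALSE, nrow(centers)),
        atomsPerSphere = as.integer(counts[keep]),
        anchor = as.numeric(anchor), partialCubes = pmat)
}

#' Add a hydration monolayer to a sphere model
#'
#' Adds water-filled cubes on the dry surface until the deposited water mass
#' reaches \code{hydrationGperG} grams of water per gram of dry structure.
#' Candidate cubes are the empty grid cubes sharing a face with a dry cube;
#' each represents water at 1 g/cm^3 (mass \code{cubeSide^3 x 0.6022} Da,
#' about 5 waters for the default cube). Candidates are consumed in
#' decreasing order of dry-neighbour count, ties broken in deterministic
#' lattice order, so the shell grows inward-first and reproducibly.
#'
#' @param model a dry [SphereModel-class].
#' @param dryMassDa dry mass in Daltons (e.g. [molecularWeight()]).
#' @param hydrationGperG target hydration, g water per g dry mass
#'   (default 0.3, the canonical protein hydration-monolayer value).
#' @return a [SphereModel-class] with hydration spheres appended.
#' @export
addHydration <- function(model, dryMassDa, hydrationGperG = 0.3) {
    if (dryMassDa <= 0) stop("dryMassDa must be positive")
    if (hydrationGperG < 0) stop("hydrationGperG must be >= 0")
    if (hydrationGperG == 0) return(model)
    if (any(model@isHydration))
        stop("model already carries a hydration shell")
    side <- model@cubeSide
    lat <- .sphereLattice(model)
    occ <- new.env(hash = TRUE)
    keyOf <- function(v) paste(v[1], v[2], v[3])
    for (r in seq_len(nrow(lat))) assign(keyOf(lat[r, ]), TRUE, envir = occ)
    # partially occupied cubes belong to the particle, not the solvent:
    # they can neither receive water nor count as dry neighbours
    for (r in seq_len(nrow(model@partialCubes)))
        assign(keyOf(model@partialCubes[r, ]), TRUE, envir = occ)
    shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    cand <- new.env(hash = TRUE)
    for (r in seq_len(nrow(lat))) {
        for (s in seq_len(6L)) {
            v <- lat[r, ] + shifts[s, ]
            k <- keyOf(v)
            if (exists(k, envir = occ, inherits = FALSE)) next
            prev <- if (exists(k, envir = cand, inherits = FALSE))
                get(k, envir = cand) else c(v, 0)
            prev[4] <- prev[4] + 1
            assign(k, prev, envir = cand)
        }
    }
    cands <- do.call(rbind, as.list(mget(ls(envir = cand), envir = cand)))
    if (is.null(cands)) stop("no candidate hydration cubes found")
    # decreasing neighbour count, then deterministic lattice order
    ord <- order(-cands[, 4], cands[, 1], cands[, 2], cands[, 3])
    cands <- cands[ord, , drop = FALSE]
    massPerSphere <- side^3 * .WATER_DENSITY_DA_A3
    target <- hydrationGperG * dryMassDa
    nNeed <- ceiling(target / massPerSphere)
    if (nNeed > nrow(cands))
        stop(sprintf(
            "insufficient hydration candidates: %d cubes give %.2f g/g (target %.2f)",
            nrow(cands), nrow(cands) * massPerSphere / dryMassDa,
            hydrationGperG))
    take <- cands[seq_len(nNeed), 1:3, drop = FALSE]
    hyd_centers <- sweep((take + 0.5) * side, 2L, model@anchor, `+`)
    dimnames(hyd_centers) <- NULL
    new("SphereModel",
        centers = rbind(model@centers, hyd_centers),
        radius = model@radius, cubeSide = side,
        isHydration = c(model@isHydration, rep(TRUE, nNeed)),
        atomsPerSphere = c(model@atomsPerSphere, rep(0L, nNeed)))
}

#' Sphere-model scattering intensity
#'
#' Debye equation adapted to small equal spheres: \code{I(Q)/I(0) = g(Q)
#' [1/n + (2/n^2) sum_{j<k} sinc(Q r_jk)]} with the single-sphere form
#' factor \code{g(Q) = [3 (sin QR - QR cos QR)/(QR)^3]^2}. All spheres carry
#' unit weight (single-density model); the returned curve is normalized to
#' I(0) = 1. A warning is issued for Q beyond the small-sphere validity
#' bound \code{2 pi / (2 R)}.
#'
#' @param model a [SphereModel-class].
#' @param q Q grid, 1/Angstrom.
#' @param includeHydration include hydration-shell spheres (default TRUE
#'   when present).
#' @return a [ScatteringCurve-class], I(Q)/I(0).
#' @export
intensitySphereDebye <- function(model, q, includeHydration = TRUE) {
    keep <- if (includeHydration) rep(TRUE, nrow(model@centers)) else
        !model@isHydration
    centers <- model@centers[keep, , drop = FALSE]
    n <- nrow(centers)
    if (n < 1L) stop("empty sphere model")
    R <- model@radius
    if (any(q > 2 * pi / (2 * R)))
        warning(sprintf(
            "Q beyond small-sphere validity bound %.3f 1/Ang; curve unreliable there",
            2 * pi / (2 * R)))
    qR <- q * R
    g <- ifelse(qR < 1e-6, 1,
                (3 * (sin(qR) - qR * cos(qR)) / qR^3)^2)
    s <- .cppDebye(centers, rep(1, n), as.numeric(q)) / n^2
    scatteringCurve(q, g * s)
}

#' Radius of gyration of a sphere model
#'
#' Centre-based Rg with unit weight per sphere, optionally including the
#' hydration shell, plus the parallel-axis sphere term \code{(3/5) R^2}.
#'
#' @param model a [SphereModel-class].
#' @param includeHydration include hydration spheres (default TRUE).
#' @return Rg in Angstrom.
#' @export
sphereModelRg <- function(model, includeHydration = TRUE) {
    keep <- if (includeHydration) rep(TRUE, nrow(model@centers)) else
        !model@isHydration
    centers <- model@centers[keep, , drop = FALSE]
    rg2 <- .rgWeighted(centers, rep(1, nrow(centers)))^2
    sqrt(rg2 + 0.6 * model@radius^2)
}
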