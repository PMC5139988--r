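# Dihedral-angle Monte Carlo: Markov-chain sampling of backbone phi/psi
# torsions in user-declared flexible regions, with acceptance decided purely
# by geometry (steric overlap, optional Rg window, optional distance
# constraints). No energy model is involved: energetics are delegated to
# downstream force-field tools outside this package's scope.

#' Declare a flexible region
#'
#' @param chain chain identifier.
#' @param first,last inclusive residue-number range.
#' @param angles subset of \code{c("phi", "psi")} to sample.
#' @return a list of class \code{"FlexibleRegion"}.
#' @export
flexibleRegion <- function(chain, first, last, angles = c("phi", "psi")) {
    angles <- match.arg(angles, c("phi", "psi"), several.ok = TRUE)
    first <- as.integer(first); last <- as.integer(last)
    if (last < first) stop("empty residue range")
    structure(list(chain = as.character(chain), first = first, last = last,
                   angles = angles), class = "FlexibleRegion")
}

#' Monte Carlo run configuration
#'
#' @param nAcceptTarget number of accepted structures to collect.
#' @param maxTrials trial budget (default 200 x nAcceptTarget).
#' @param maxStepDeg maximum rotation per move, degrees in (0, 180]; steps
#'   are drawn uniformly from (-maxStepDeg, +maxStepDeg). Published
#'   workflows have used anything from 10 to 80 degrees; 30 is a reasonable
#'   middle ground for linker sampling.
#' @param overlapCutoff steric overlap distance cutoff in Angstrom
#'   (default 3.0, i.e. 0.3 nm).
#' @param overlapAtomNames optional character vector restricting the overlap
#'   check to named atoms (e.g. "CA"); default all heavy atoms.
#' @param rgBounds optional \code{c(low, high)} window (Angstrom) that
#'   accepted frames' radius of gyration must lie in.
#' @param distanceConstraints optional list of constraints, each
#'   \code{list(a = "chain:resid:name", b = "chain:resid:name", min =, max =)}
#'   in Angstrom.
#' @param seed integer RNG seed; the full acceptance sequence is a
#'   deterministic function of (structure, regions, config, seed).
#' @return a list of class \code{"MCConfig"}.
#' @export
mcConfig <- function(nAcceptTarget = 100L, maxTrials = 200L * nAcceptTarget,
                     maxStepDeg = 30, overlapCutoff = 3.0,
                     overlapAtomNames = NULL, rgBounds = NULL,
                     distanceConstraints = NULL, seed = 1L) {
    if (maxStepDeg <= 0 || maxStepDeg > 180)
        stop("maxStepDeg must be in (0, 180]")
    if (overlapCutoff <= 0) stop("overlapCutoff must be positive")
    if (!is.null(rgBounds)) {
        if (length(rgBounds) != 2L || rgBounds[1] >= rgBounds[2])
            stop("rgBounds must be c(low, high) with low < high")
    }
    structure(list(nAcceptTarget = as.integer(nAcceptTarget),
                   maxTrials = as.integer(maxTrials),
                   maxStepDeg = maxStepDeg, overlapCutoff = overlapCutoff,
                   overlapAtomNames = overlapAtomNames, rgBounds = rgBounds,
                   distanceConstraints = distanceConstraints,
                   seed = as.integer(seed)),
              class = "MCConfig")
}

.atomIndex <- function(a, chain, resid, name) {
    i <- which(a$chain == chain & a$resid == resid & a$name == name)
    if (length(i) != 1L)
        stop(sprintf("topology error: atom %s:%d:%s %s", chain, resid, name,
                     if (length(i)) "ambiguous" else "not found"))
    i
}

.parseAtomRef <- function(ref) {
    if (is.character(ref)) {
        p <- strsplit(ref, ":")[[1]]
        if (length(p) != 3L) stop("atom reference must be chain:resid:name")
        list(chain = p[1], resid = as.integer(p[2]), name = p[3])
    } else ref
}

# indices of atoms C-terminal to the rotation bond, and the axis endpoints
.dihedralMove <- function(a, chain, resid, angleType) {
    resn <- a$resname[a$chain == chain & a$resid == resid][1]
    if (is.na(resn))
        stop(sprintf("topology error: no residue %s:%d", chain, resid))
    if (angleType == "phi" && resn == "PRO")
        stop("topology error: phi rotation on proline refused (ring-constrained)")
    iN <- .atomIndex(a, chain, resid, "N")
    iCA <- .atomIndex(a, chain, resid, "CA")
    in_chain <- a$chain == chain
    if (angleType == "phi") {
        axis <- c(iN, iCA)
        moving <- which(in_chain &
            (a$resid > resid |
             (a$resid == resid &
              !(a$name %in% c("N", "CA") | (a$element %in% c("H", "D") &
                                            a$name %in% c("H", "HN", "H1",
                                                          "H2", "H3"))))))
    } else {
        iC <- .atomIndex(a, chain, resid, "C")
        axis <- c(iCA, iC)
        moving <- which(in_chain &
            (a$resid > resid |
             (a$resid == resid & a$name %in% c("O", "OXT"))))
    }
    list(axis = axis, moving = moving)
}

#' Rotate a backbone dihedral angle
#'
#' Applies a rigid rotation of \code{deltaDeg} degrees about the phi (N-CA)
#' or psi (CA-C) bond of one residue. The N-terminal side of the bond is
#' held fixed; all atoms of the same chain C-terminal to the bond move (for
#' phi, everything beyond CA except the amide group; for psi, the carbonyl
#' O and everything from the next residue's N onward). Bond lengths and
#' angles are untouched. Phi moves on proline are refused.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param structure the [Structure-class] giving atom identities and order
#'   (chains must run N to C).
#' @param chain,resid residue whose torsion is rotated.
#' @param angleType "phi" or "psi".
#' @param deltaDeg rotation in degrees.
#' @return the rotated coordinate matrix.
#' @export
rotateDihedral <- function(frame, structure, chain, resid,
                           angleType = c("phi", "psi"), deltaDeg) {
    angleType <- match.arg(angleType)
    mv <- .dihedralMove(atoms(structure), chain, as.integer(resid), angleType)
    p1 <- frame[mv$axis[1], ]
    p2 <- frame[mv$axis[2], ]
    frame[mv$moving, ] <- .rotateAbout(frame[mv$moving, , drop = FALSE],
                                       p1, p2 - p1, deltaDeg)
    frame
}

#' Steric overlap check
#'
#' TRUE when any pair of selected atoms lies closer than \code{cutoff},
#' excluding pairs within the same or sequence-adjacent residues of the same
#' chain (covalent neighbours). A cell-list spatial grid keeps the cost
#' near-linear in the number of atoms.
#'
#' @param frame n_atoms x 3 coordinate matrix (or NULL to use the
#'   structure's own coordinates).
#' @param structure the [Structure-class] giving residue identities.
#' @param cutoff overlap distance in Angstrom (default 3.0).
#' @param selection optional character vector of atom names to restrict the
#'   check to; default all heavy atoms.
#' @param countAll count every clashing pair (TRUE) or stop at the first
#'   (FALSE, cheaper for accept/reject loops).
#' @return \code{list(clash = logical, n_pairs = numeric)}.
#' @export
checkOverlap <- function(frame = NULL, structure, cutoff = 3.0,
                         selection = NULL, countAll = TRUE) {
    if (cutoff <= 0) stop("cutoff must be positive")
    if (is.null(frame)) frame <- coords(structure)
    a <- atoms(structure)
    sel <- a$element != "H" & a$element != "D"
    if (!is.null(selection)) sel <- sel & a$name %in% selection
    if (!any(sel)) stop("empty atom selection for overlap check")
    res <- .cppClash(frame, which(sel) - 1L, cutoff,
                     match(a$chain, unique(a$chain)), a$resid, countAll)
    list(clash = res$clash, n_pairs = res$n_pairs)
}

#' Radius of gyration
#'
#' \code{Rg = sqrt(sum w_j |r_j - rbar|^2 / sum w_j)} about the w-weighted
#' centroid. Weighting options: atomic mass (default), uniform, or neutron
#' coherent scattering length.
#'
#' @param frame n_atoms x 3 coordinate matrix, or a [Structure-class].
#' @param structure the [Structure-class] (needed for mass/scattering
#'   weights when \code{frame} is a matrix).
#' @param weighting "mass", "uniform" or "scattering".
#' @return Rg in Angstrom.
#' @examples
#' s <- buildPolypeptide(fixtureSpec(nResidues = 10))
#' radiusOfGyration(s)
#' @export
radiusOfGyration <- function(frame, structure = NULL,
                             weighting = c("mass", "uniform", "scattering")) {
    weighting <- match.arg(weighting)
    if (is(frame, "Structure")) {
        structure <- frame
        frame <- coords(frame)
    }
    n <- nrow(frame)
    if (n < 1L) stop("no atoms")
    w <- switch(weighting,
        uniform = rep(1, n),
        mass = .elementLookup(.MASSES, atoms(structure)$element, "mass"),
        scattering = .elementLookup(.NEUTRON_B, atoms(structure)$element,
                                    "scattering length"))
    .rgWeighted(frame, w)
}

.rgWeighted <- function(frame, w) {
    tw <- sum(w)
    if (abs(tw) < 1e-12) stop("total weight is zero")
    ctr <- colSums(frame * w) / tw
    d2 <- (frame[, 1] - ctr[1])^2 + (frame[, 2] - ctr[2])^2 +
        (frame[, 3] - ctr[3])^2
    sqrt(sum(w * d2) / tw)
}

#' Generate an ensemble by dihedral Monte Carlo
#'
#' Markov chain over backbone torsions: each trial picks a flexible residue
#' uniformly, then an angle type allowed for it, then a step drawn uniformly
#' from (-maxStepDeg, +maxStepDeg), and applies the rigid rotation. The
#' trial is accepted iff the frame passes the steric overlap check and any
#' configured Rg window and distance constraints; accepted frames are
#' appended to the ensemble and become the current state, rejected trials
#' revert. Acceptance is purely geometric (no Boltzmann criterion). The run
#' is fully reproducible from the seed.
#'
#' @param structure a clean [Structure-class] (see [scanStructure()]).
#' @param regions a [flexibleRegion()] or list of them.
#' @param config an [mcConfig()].
#' @param force skip the cleanliness pre-check (default FALSE).
#' @return an [MCResult-class].
#' @examples
#' sys <- makeTwoDomainSystem()
#' res <- runMonomerMC(sys$structure, sys$region,
#'                     mcConfig(nAcceptTarget = 25, seed = 7))
#' res
#' @export
runMonomerMC <- function(structure, regions, config = mcConfig(),
                         force = FALSE) {
    if (inherits(regions, "FlexibleRegion")) regions <- list(regions)
    if (!force && !isClean(scanStructure(structure)))
        stop("structure fails scanStructure(); fix it or call with force = TRUE")
    a <- atoms(structure)

    # move table: one row per (residue, angle); proline phi dropped
    moves <- list()
    for (rg in regions) {
        for (r in seq(rg$first, rg$last)) {
            rows <- which(a$chain == rg$chain & a$resid == r)
            if (!length(rows))
                stop(sprintf("topology error: region residue %s:%d absent",
                             rg$chain, r))
            resn <- a$resname[rows[1]]
            for (ang in rg$angles) {
                if (ang == "phi" && resn == "PRO") {
                    warning(sprintf(
                        "phi move on proline %s:%d dropped (ring-constrained)",
                        rg$chain, r))
                    next
                }
                mv <- .dihedralMove(a, rg$chain, r, ang)
                moves[[length(moves) + 1L]] <-
                    c(mv, list(chain = rg$chain, resid = r, angle = ang))
            }
        }
    }
    if (!length(moves)) stop("no sampleable torsions in the given regions")
    # group moves by residue for the residue-then-angle draw order
    res_key <- vapply(moves, function(m) paste(m$chain, m$resid), "")
    by_res <- split(seq_along(moves), res_key)
    by_res <- by_res[unique(res_key)]  # stable order
    n_res <- length(by_res)

    sel_heavy <- a$element != "H" & a$element != "D"
    if (!is.null(config$overlapAtomNames))
        sel_heavy <- sel_heavy & a$name %in% config$overlapAtomNames
    if (!any(sel_heavy)) stop("empty overlap atom selection")
    sel0 <- which(sel_heavy) - 1L
    chain_id <- match(a$chain, unique(a$chain))
    masses <- .elementLookup(.MASSES, a$element, "mass")

    dcs <- lapply(config$distanceConstraints, function(dc) {
        pa <- .parseAtomRef(dc$a); pb <- .parseAtomRef(dc$b)
        list(i = .atomIndex(a, pa$chain, pa$resid, pa$name),
             j = .atomIndex(a, pb$chain, pb$resid, pb$name),
             min = dc$min, max = dc$max)
    })

    cur <- coords(structure)
    # a state is only adopted once it satisfies every constraint, so a
    # window that excludes the starting structure can never be entered
    if (!is.null(config$rgBounds)) {
        rg0 <- .rgWeighted(cur, masses)
        if (rg0 < config$rgBounds[1] || rg0 > config$rgBounds[2])
            warning(sprintf(
                "starting structure Rg %.2f Ang lies outside rgBounds [%g, %g]; the chain cannot enter the window and the run will likely accept nothing",
                rg0, config$rgBounds[1], config$rgBounds[2]))
    }
    frames <- vector("list", config$nAcceptTarget)
    rgs <- numeric(config$nAcceptTarget)
    nacc <- 0L
    rej <- c(overlap = 0L, rg_bounds = 0L, distance = 0L)
    trial <- 0L

    .withSeed(config$seed, {
        while (nacc < config$nAcceptTarget && trial < config$maxTrials) {
            trial <- trial + 1L
            cand <- by_res[[sample.int(n_res, 1L)]]
            mvi <- cand[[sample.int(length(cand), 1L)]]
            delta <- runif(1L, -config$maxStepDeg, config$maxStepDeg)
            mv <- moves[[mvi]]
            new <- cur
            p1 <- new[mv$axis[1], ]
            p2 <- new[mv$axis[2], ]
            new[mv$moving, ] <- .rotateAbout(new[mv$moving, , drop = FALSE],
                                             p1, p2 - p1, delta)
            cl <- .cppClash(new, sel0, config$overlapCutoff, chain_id,
                            a$resid, FALSE)
            if (cl$clash) { rej["overlap"] <- rej["overlap"] + 1L; next }
            rg_now <- .rgWeighted(new, masses)
            if (!is.null(config$rgBounds) &&
                (rg_now < config$rgBounds[1] || rg_now > config$rgBounds[2])) {
                rej["rg_bounds"] <- rej["rg_bounds"] + 1L
                next
            }
            ok <- TRUE
            for (dc in dcs) {
                d <- sqrt(sum((new[dc$i, ] - new[dc$j, ])^2))
                if (d < dc$min || d > dc$max) { ok <- FALSE; break }
            }
            if (!ok) { rej["distance"] <- rej["distance"] + 1L; next }
            nacc <- nacc + 1L
            frames[[nacc]] <- new
            rgs[nacc] <- rg_now
            cur <- new
        }
    })

    if (nacc == 0L)
        stop("MC produced no accepted structures after ", trial,
             " trials; rejections: ",
             paste(names(rej), rej, sep = "=", collapse = ", "))
    if (nacc < config$nAcceptTarget)
        warning(sprintf("accepted %d of %d requested structures in %d trials",
                        nacc, config$nAcceptTarget, trial))
    new("MCResult",
        ensemble = ensemble(structure, frames[seq_len(nacc)]),
        nTrials = trial, nAccepted = nacc, rejectionCounts = rej,
        perFrameRg = rgs[seq_len(nacc)])
}
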