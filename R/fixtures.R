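# Synthetic-structure and synthetic-curve generators. These stand in for
# deposited PDB coordinates and experimental curves so that the whole
# workflow (scan -> MC -> calculate -> fit) runs and is testable offline.

# Side-chain internal-coordinate templates (heavy atoms only). Each entry:
# new atom, three reference atoms of the same residue, bond (Ang),
# angle(b-c-new) (deg), torsion(a-b-c-new) (deg). CB placement uses the
# L-amino-acid improper torsion(N, C, CA, CB) = +123 deg. Aromatic rings
# close exactly by construction (planar 120 deg chains); the proline ring is
# approximate, which is irrelevant downstream because phi moves on proline
# are refused and fixtures are scanned by atom name only.
.zrow <- function(name, a, b, c, bond, ang, tors) {
    list(name = name, a = a, b = b, c = c, bond = bond, ang = ang, tors = tors)
}
.CB <- .zrow("CB", "N", "C", "CA", 1.530, 110.5, 123.0)

.SIDECHAIN_ZMAT <- list(
    GLY = list(),
    ALA = list(.CB),
    SER = list(.CB, .zrow("OG",  "N", "CA", "CB", 1.417, 110.8, 180)),
    CYS = list(.CB, .zrow("SG",  "N", "CA", "CB", 1.808, 113.8, 180)),
    THR = list(.CB, .zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
               .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
    VAL = list(.CB, .zrow("CG1", "N", "CA", "CB", 1.527, 110.4, 180),
               .zrow("CG2", "N", "CA", "CB", 1.527, 110.4, 60)),
    LEU = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.530, 116.3, 180),
               .zrow("CD1", "CA", "CB", "CG", 1.521, 110.5, 180),
               .zrow("CD2", "CA", "CB", "CG", 1.521, 110.5, 60)),
    ILE = list(.CB, .zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
               .zrow("CG2", "N", "CA", "CB", 1.521, 110.4, -60),
               .zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
    MET = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
               .zrow("SD",  "CA", "CB", "CG", 1.803, 112.7, 180),
               .zrow("CE",  "CB", "CG", "SD", 1.791, 100.9, 180)),
    PRO = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.495, 104.5, 30),
               .zrow("CD",  "CA", "CB", "CG", 1.507, 105.5, -35)),
    PHE = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.502, 113.8, 180),
               .zrow("CD1", "CA", "CB", "CG", 1.390, 120.0, 90),
               .zrow("CD2", "CA", "CB", "CG", 1.390, 120.0, -90),
               .zrow("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
               .zrow("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
               .zrow("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0)),
    TYR = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.502, 113.8, 180),
               .zrow("CD1", "CA", "CB", "CG", 1.390, 120.0, 90),
               .zrow("CD2", "CA", "CB", "CG", 1.390, 120.0, -90),
               .zrow("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
               .zrow("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
               .zrow("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0),
               .zrow("OH",  "CD1", "CE1", "CZ", 1.376, 120.0, 180)),
    TRP = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.498, 113.6, 180),
               .zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
               .zrow("CD2", "CA", "CB", "CG", 1.433, 126.7, -90),
               .zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
               .zrow("CE2", "CG", "CD1", "NE1", 1.370, 108.9, 0),
               .zrow("CE3", "CB", "CG", "CD2", 1.400, 133.9, 180),
               .zrow("CZ2", "CD1", "NE1", "CE2", 1.394, 130.1, 180),
               .zrow("CZ3", "CG", "CD2", "CE3", 1.391, 118.6, 180),
               .zrow("CH2", "CD2", "CE3", "CZ3", 1.368, 121.1, 0)),
    ASP = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
               .zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, -20),
               .zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 160)),
    ASN = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
               .zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, -20),
               .zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 160)),
    GLU = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
               .zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
               .zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, -20),
               .zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 160)),
    GLN = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
               .zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
               .zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, -20),
               .zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 160)),
    LYS = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
               .zrow("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
               .zrow("CE",  "CB", "CG", "CD", 1.520, 111.3, 180),
               .zrow("NZ",  "CG", "CD", "CE", 1.489, 111.9, 180)),
    ARG = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
               .zrow("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
               .zrow("NE",  "CB", "CG", "CD", 1.461, 112.0, 180),
               .zrow("CZ",  "CG", "CD", "NE", 1.329, 124.2, 180),
               .zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
               .zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
    HIS = list(.CB, .zrow("CG",  "N", "CA", "CB", 1.492, 113.8, 180),
               .zrow("ND1", "CA", "CB", "CG", 1.380, 122.7, 90),
               .zrow("CD2", "CA", "CB", "CG", 1.354, 131.1, -90),
               .zrow("CE1", "CB", "CG", "ND1", 1.326, 109.0, 180),
               .zrow("NE2", "CG", "ND1", "CE1", 1.326, 111.7, 0))
)

# ideal backbone geometry (Engh-Huber-type values), Ang / deg
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, omega = 180)

# canonical torsions per conformation label
.CONF_TORSIONS <- list(extended = c(phi = -120, psi = 120),
                       helix = c(phi = -57, psi = -47))

#' Describe a synthetic fixture
#'
#' Bundles the knobs of the synthetic-structure/curve generators. The
#' defaults emulate a small single-chain protein test system: a 10-residue
#' polyalanine, extended conformation, 2 percent counting-statistics noise on
#' synthetic curves.
#'
#' @param nResidues number of residues (ignored if \code{sequence} given).
#' @param sequence one-letter amino-acid string; default poly-A.
#' @param conformation "extended" (phi = -120, psi = 120) or "helix"
#'   (phi = -57, psi = -47).
#' @param noiseFraction fractional sigma for synthetic noisy curves.
#' @param seed integer RNG seed for anything stochastic.
#' @return a list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(nResidues = 10L, sequence = NULL,
                        conformation = c("extended", "helix"),
                        noiseFraction = 0.02, seed = 1L) {
    conformation <- match.arg(conformation)
    if (!is.null(sequence)) {
        sequence <- toupper(sequence)
        nResidues <- nchar(sequence)
    } else {
        sequence <- strrep("A", nResidues)
    }
    if (nResidues < 1L) stop("need at least one residue")
    if (noiseFraction < 0) stop("noiseFraction must be >= 0")
    bad <- setdiff(strsplit(sequence, "")[[1]], names(.AA1_TO_3))
    if (length(bad))
        stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
    structure(list(nResidues = as.integer(nResidues), sequence = sequence,
                   conformation = conformation,
                   noiseFraction = noiseFraction, seed = as.integer(seed)),
              class = "FixtureSpec")
}

# run expr with a private, restored RNG stream
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Core chain builder: residue names plus per-residue phi/psi (deg).
.buildChain <- function(resnames, phi, psi, chain = "A") {
    n <- length(resnames)
    bb <- .BB
    name <- character(0); resname <- character(0); resid <- integer(0)
    xyz <- matrix(numeric(0), ncol = 3)
    push <- function(nm, rn, ri, p) {
        name <<- c(name, nm); resname <<- c(resname, rn)
        resid <<- c(resid, ri); xyz <<- rbind(xyz, p)
    }
    prev <- NULL  # list(N, CA, C) of previous residue
    for (i in seq_len(n)) {
        rn <- resnames[i]
        if (is.null(prev)) {
            N <- c(0, 0, 0)
            CA <- c(bb$n_ca, 0, 0)
            th <- bb$ang_n_ca_c * pi / 180
            C <- CA + bb$ca_c * c(-cos(th), sin(th), 0)
        } else {
            N <- .placeAtom(prev$N, prev$CA, prev$C, bb$c_n, bb$ang_ca_c_n,
                            psi[i - 1])
            CA <- .placeAtom(prev$CA, prev$C, N, bb$n_ca, bb$ang_c_n_ca,
                             bb$omega)
            C <- .placeAtom(prev$C, N, CA, bb$ca_c, bb$ang_n_ca_c, phi[i])
        }
        # carbonyl O anti to the next amide N: torsion(N, CA, C, O) = psi+180
        O <- .placeAtom(N, CA, C, bb$c_o, bb$ang_ca_c_o, psi[i] + 180)
        push("N", rn, i, N); push("CA", rn, i, CA)
        push("C", rn, i, C); push("O", rn, i, O)
        local_coords <- list(N = N, CA = CA, C = C, O = O)
        for (z in .SIDECHAIN_ZMAT[[rn]]) {
            p <- .placeAtom(local_coords[[z$a]], local_coords[[z$b]],
                            local_coords[[z$c]], z$bond, z$ang, z$tors)
            local_coords[[z$name]] <- p
            push(z$name, rn, i, p)
        }
        prev <- list(N = N, CA = CA, C = C)
    }
    atoms <- data.frame(serial = seq_along(name), name = name,
                        element = elementFromName(name), resname = resname,
                        chain = chain, resid = resid, is_het = FALSE,
                        altloc = "", stringsAsFactors = FALSE)
    dimnames(xyz) <- NULL
    new("Structure", atoms = atoms, coords = xyz, title = "synthetic chain")
}

#' Build an ideal-geometry polypeptide
#'
#' Constructs a single-chain, heavy-atom polypeptide with ideal backbone
#' geometry (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom, trans omega) and
#' uniform backbone torsions set by the conformation label. Side chains come
#' from internal-coordinate templates. The result passes [scanStructure()]
#' clean by construction.
#'
#' @param spec a [fixtureSpec()].
#' @param chain chain identifier (default "A").
#' @return a [Structure-class].
#' @examples
#' s <- buildPolypeptide(fixtureSpec(nResidues = 5))
#' nAtoms(s)
#' @export
buildPolypeptide <- function(spec = fixtureSpec(), chain = "A") {
    resnames <- unname(.AA1_TO_3[strsplit(spec$sequence, "")[[1]]])
    tor <- .CONF_TORSIONS[[spec$conformation]]
    n <- length(resnames)
    .buildChain(resnames, rep(tor["phi"], n), rep(tor["psi"], n), chain)
}

#' Build a two-domain test system with a flexible linker
#'
#' Two helical domains joined by a 5-residue extended linker; the linker is
#' returned as the flexible region for Monte Carlo sampling. This is the
#' standard end-to-end test topology (a minimal multi-domain protein with an
#' inter-domain linker).
#'
#' @param spec a [fixtureSpec()]; \code{nResidues} is the total length
#'   (>= 12), split as (n-5)/2 helix + 5 linker + remainder helix.
#' @return list with elements \code{structure} ([Structure-class]) and
#'   \code{region} ([flexibleRegion()]).
#' @examples
#' sys <- makeTwoDomainSystem(fixtureSpec(nResidues = 29))
#' sys$region
#' @export
makeTwoDomainSystem <- function(spec = fixtureSpec(nResidues = 29L)) {
    n <- spec$nResidues
    if (n < 12L) stop("two-domain system needs at least 12 residues")
    linker_len <- 5L
    d1 <- (n - linker_len) %/% 2L
    resnames <- unname(.AA1_TO_3[strsplit(spec$sequence, "")[[1]]])
    hel <- .CONF_TORSIONS$helix
    ext <- .CONF_TORSIONS$extended
    kind <- rep(c("h", "l", "h"), c(d1, linker_len, n - d1 - linker_len))
    phi <- ifelse(kind == "h", hel["phi"], ext["phi"])
    psi <- ifelse(kind == "h", hel["psi"], ext["psi"])
    # the torsion transition happens at the psi of the residue preceding the
    # linker; keeping it helical would pinch its carbonyl against the linker
    psi[d1] <- ext["psi"]
    s <- .buildChain(resnames, phi, psi, chain = "A")
    s@title <- "synthetic two-domain system"
    list(structure = s,
         region = flexibleRegion("A", d1 + 1L, d1 + linker_len,
                                 c("phi", "psi")))
}

#' Add synthetic counting noise to a curve
#'
#' Emulates an experimental three-column data file: multiplicative Gaussian
#' noise \code{I' = I (1 + eps)}, \code{eps ~ N(0, noiseFraction)}, and
#' per-point sigma equal to \code{noiseFraction * I}. With
#' \code{noiseFraction = 0} the intensities are returned unchanged and a tiny
#' positive sigma floor is applied so downstream chi-square code treats the
#' curve as essentially exact.
#'
#' @param trueCurve a [ScatteringCurve-class].
#' @param noiseFraction fractional noise level (>= 0).
#' @param seed integer seed; the generator is private and reproducible.
#' @return a [ScatteringCurve-class] with sigma.
#' @export
makeNoisyCurve <- function(trueCurve, noiseFraction = 0.02, seed = 1L) {
    if (noiseFraction < 0) stop("noiseFraction must be >= 0")
    i <- intensities(trueCurve)
    eps <- if (noiseFraction > 0)
        .withSeed(seed, rnorm(length(i), 0, noiseFraction)) else 0
    sig <- noiseFraction * abs(i)
    floorv <- 1e-6 * max(abs(i), 1e-300)
    sig <- pmax(sig, floorv)
    scatteringCurve(qValues(trueCurve), i * (1 + eps), sig)
}
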