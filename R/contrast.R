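# Contrast handling: per-atom scattering amplitudes for neutrons (coherent
# scattering lengths, H/D exchange of labile hydrogens, solvent D2O
# fraction) and X-rays (electron counts), plus scattering-length-density
# utilities for contrast-variation planning.

#' Describe the scattering contrast situation
#'
#' @param mode "neutron" or "xray".
#' @param d2oFraction solvent D2O volume fraction in [0, 1] (neutron mode).
#' @param exchangeFraction fraction of labile hydrogens that actually
#'   exchange with solvent deuterium (default 1).
#' @param solventSubtraction subtract the solvent-displaced volume term
#'   \code{rho_solvent * V_j} from each amplitude (default FALSE: the
#'   particle is treated at uniform contrast, as in single-density sphere
#'   modelling).
#' @return a list of class \code{"ContrastModel"}.
#' @export
contrastModel <- function(mode = c("neutron", "xray"), d2oFraction = 0,
                          exchangeFraction = 1, solventSubtraction = FALSE) {
    mode <- match.arg(mode)
    if (d2oFraction < 0 || d2oFraction > 1)
        stop("d2oFraction must be in [0, 1]")
    if (exchangeFraction < 0 || exchangeFraction > 1)
        stop("exchangeFraction must be in [0, 1]")
    structure(list(mode = mode, d2oFraction = d2oFraction,
                   exchangeFraction = exchangeFraction,
                   solventSubtraction = solventSubtraction),
              class = "ContrastModel")
}

# Labile (exchangeable) hydrogens are those bonded to N, O or S. With only
# names available, attachment is inferred from the PDB naming convention:
# hydrogens carry the name of their parent heavy atom with the leading
# element letter replaced ("H" / "HN" amide, "HG1" on OG1, "HZ3" on NZ...).
.isLabileH <- function(a) {
    isH <- a$element %in% c("H", "D")
    out <- logical(nrow(a))
    if (!any(isH)) return(out)
    key <- paste(a$chain, a$resid)
    heavies <- split(a$name[!isH], key[!isH])
    for (i in which(isH)) {
        nm <- toupper(gsub("^[0-9]+", "", a$name[i]))
        suffix <- sub("^H", "", nm)
        if (nm %in% c("H", "HN", "HT1", "HT2", "HT3") || suffix == "") {
            out[i] <- TRUE
            next
        }
        sibs <- heavies[[key[i]]]
        cands <- c(paste0(c("N", "O", "S"), suffix),
                   paste0(c("N", "O", "S"), sub("[0-9]$", "", suffix)))
        out[i] <- any(cands %in% sibs)
    }
    out
}

#' Per-atom scattering amplitudes
#'
#' Neutron mode assigns coherent scattering lengths (fm), replacing each
#' labile hydrogen's amplitude by
#' \code{b_H + d2oFraction * exchangeFraction * (b_D - b_H)}. X-ray mode
#' assigns electron counts (the constant-form-factor approximation, adequate
#' over the small-angle range Q below about 0.5 1/Angstrom). With
#' \code{solventSubtraction} the solvent term \code{rho_solvent * V_j} is
#' subtracted using tabulated displaced atomic volumes, with the solvent
#' density linear in the D2O fraction.
#'
#' @param structure a [Structure-class].
#' @param contrast a [contrastModel()].
#' @return numeric vector of per-atom amplitudes (fm for neutrons, electrons
#'   for X-rays).
#' @export
assignAmplitudes <- function(structure, contrast = contrastModel()) {
    a <- atoms(structure)
    if (contrast$mode == "neutron") {
        f <- .elementLookup(.NEUTRON_B, a$element, "neutron scattering length")
        lab <- .isLabileH(a) & a$element == "H"
        if (any(lab))
            f[lab] <- .NEUTRON_B[["H"]] +
                contrast$d2oFraction * contrast$exchangeFraction *
                (.NEUTRON_B[["D"]] - .NEUTRON_B[["H"]])
    } else {
        f <- .elementLookup(.ELECTRONS, a$element, "electron count")
    }
    if (contrast$solventSubtraction) {
        v <- .elementLookup(.VOLUMES, a$element, "displaced volume")
        f <- f - .solventDensity(contrast) * v
    }
    f
}

# solvent scattering length density in the units of the amplitudes
# (fm/Ang^3 for neutrons, electrons/Ang^3 for X-rays)
.solventDensity <- function(contrast) {
    if (contrast$mode == "neutron") {
        bH2O <- 2 * .NEUTRON_B[["H"]] + .NEUTRON_B[["O"]]
        bD2O <- 2 * .NEUTRON_B[["D"]] + .NEUTRON_B[["O"]]
        ((1 - contrast$d2oFraction) * bH2O +
             contrast$d2oFraction * bD2O) / .WATER_VOLUME
    } else {
        10 / .WATER_VOLUME  # 10 electrons per water molecule
    }
}

#' Scattering length density and contrast match point
#'
#' Computes the particle neutron scattering length density as a linear
#' function of the solvent D2O fraction f (exchangeable hydrogens
#' interpolate b_H to b_D with f), the solvent SLD line between pure H2O and
#' pure D2O (water volume 29.9 Ang^3), and the match point where the two
#' lines cross. SLD values are reported in 1e10 cm^-2, the conventional
#' unit.
#'
#' @param composition named numeric vector, element symbol -> atom count
#'   (include ALL hydrogens under "H"; exchangeable ones are counted again
#'   via \code{exchangeableH}).
#' @param exchangeableH number of labile hydrogens among the H count.
#' @param volume particle dry volume in Ang^3.
#' @return list with \code{particleSLD} and \code{solventSLD} (each
#'   \code{c(intercept, slope)} in 1e10 cm^-2 per unit D2O fraction),
#'   \code{matchPoint} (D2O fraction, NA if no crossing in [0, 1]) and
#'   \code{degenerate} (TRUE when particle and solvent lines coincide).
#' @examples
#' sldMatchpoint(c(H = 2, O = 1), exchangeableH = 2, volume = 29.9)
#' @export
sldMatchpoint <- function(composition, exchangeableH = 0, volume) {
    if (volume <= 0) stop("volume must be positive")
    els <- names(composition)
    b0 <- sum(.elementLookup(.NEUTRON_B, els, "neutron scattering length") *
                  composition)
    dbdf <- exchangeableH * (.NEUTRON_B[["D"]] - .NEUTRON_B[["H"]])
    # 1 fm/Ang^3 = 10 x 1e10 cm^-2
    particle <- 10 * c(b0, dbdf) / volume
    bH2O <- 2 * .NEUTRON_B[["H"]] + .NEUTRON_B[["O"]]
    bD2O <- 2 * .NEUTRON_B[["D"]] + .NEUTRON_B[["O"]]
    solvent <- 10 * c(bH2O, bD2O - bH2O) / .WATER_VOLUME
    dslope <- particle[2] - solvent[2]
    dint <- particle[1] - solvent[1]
    degenerate <- abs(dslope) < 1e-9 && abs(dint) < 1e-9
    mp <- if (degenerate) NA_real_
        else if (abs(dslope) < 1e-12) NA_real_
        else -dint / dslope
    if (!is.na(mp) && (mp < 0 || mp > 1)) mp <- NA_real_
    list(particleSLD = setNames(particle, c("intercept", "slope")),
         solventSLD = setNames(solvent, c("intercept", "slope")),
         matchPoint = mp, degenerate = degenerate)
}
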