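# Element and residue reference tables used across the calculators and the
# structure scanner. Values are standard: coherent neutron scattering lengths
# (Sears 1992, fm), atomic numbers/masses, and Fraser-type displaced atomic
# volumes (Ang^3) for optional solvent subtraction.

# coherent neutron scattering lengths b_c, fm
.NEUTRON_B <- c(
    H = -3.7406, D = 6.671, C = 6.6511, N = 9.37, O = 5.803,
    S = 2.847, P = 5.13, SE = 7.97, FE = 9.45, ZN = 5.68,
    MG = 5.375, CA = 4.70, MN = -3.73, CU = 7.718, `NA` = 3.63,
    K = 3.67, CL = 9.577, BR = 6.795, I = 5.28, F = 5.654
)

# atomic numbers (X-ray amplitudes at the constant-form-factor level)
.ELECTRONS <- c(
    H = 1, D = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34,
    FE = 26, ZN = 30, MG = 12, CA = 20, MN = 25, CU = 29, `NA` = 11,
    K = 19, CL = 17, BR = 35, I = 53, F = 9
)

# atomic masses, Da
.MASSES <- c(
    H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
    S = 32.06, P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
    MG = 24.305, CA = 40.078, MN = 54.938, CU = 63.546, `NA` = 22.99,
    K = 39.098, CL = 35.45, BR = 79.904, I = 126.904, F = 18.998
)

# displaced atomic volumes, Ang^3 (used only with solvent subtraction)
.VOLUMES <- c(
    H = 5.15, D = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86,
    P = 5.73, SE = 28.7, FE = 7.99, ZN = 9.85, MG = 17.1, CA = 31.9,
    MN = 9.2, CU = 8.8, `NA` = 49.0, K = 101.0, CL = 28.8, BR = 39.0,
    I = 55.0, F = 11.2
)

# volume of one water molecule, Ang^3 (solvent SLD denominator)
.WATER_VOLUME <- 29.9
# water at 1 g/cm^3 expressed in Da/Ang^3 (1 g/cm^3 * N_A / 1e24)
.WATER_DENSITY_DA_A3 <- 0.6022140857

# Heavy-atom templates for the 20 standard amino acids (PDB v3 atom names).
# Backbone N, CA, C, O implicit; OXT optional at the C-terminus.
.SIDECHAIN_ATOMS <- list(
    ALA = c("CB"),
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    ASP = c("CB", "CG", "OD1", "OD2"),
    CYS = c("CB", "SG"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    GLY = character(),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"),
    SER = c("CB", "OG"),
    THR = c("CB", "OG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c("CB", "CG1", "CG2")
)

.AA3 <- names(.SIDECHAIN_ATOMS)
.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.AA1_TO_3 <- setNames(names(.AA1), .AA1)

.TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR",
                          "SE", "CA")  # CA element only for HETATM context

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column of a PDB record is blank. Digits and spaces
#' are stripped; for protein (ATOM) records the first letter is the element
#' ("CA" is an alpha-carbon, not calcium); for HETATM records common
#' two-letter metal/halogen symbols are recognized first.
#'
#' @param name atom-name string(s).
#' @param is_het logical, HETATM context (default FALSE).
#' @return element symbol(s), upper case.
#' @export
elementFromName <- function(name, is_het = FALSE) {
    is_het <- rep_len(is_het, length(name))
    stripped <- toupper(gsub("[^A-Za-z]", "", name))
    el <- substr(stripped, 1L, 1L)
    two <- substr(stripped, 1L, 2L)
    hit <- is_het & two %in% .TWO_LETTER_ELEMENTS
    el[hit] <- two[hit]
    # deuterium named D... in neutron-ready files
    el[el == "D" & !hit] <- "D"
    el
}

.elementLookup <- function(table, elements, what) {
    miss <- setdiff(unique(elements), names(table))
    if (length(miss))
        stop("no ", what, " tabulated for element(s): ",
             paste(miss, collapse = ", "))
    unname(table[elements])
}

#' Molecular weight of a structure
#'
#' Sum of the atomic masses of all atoms (Da), used e.g. as the dry mass for
#' hydration-shell bookkeeping.
#'
#' @param structure a [Structure-class].
#' @return mass in Daltons.
#' @export
molecularWeight <- function(structure) {
    sum(.elementLookup(.MASSES, atoms(structure)$element, "mass"))
}
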