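# Simulation-readiness validation of starting structures, and expansion of
# header symmetry (REMARK 350 BIOMT) into biological units.

# peptide-bond based gap criterion: C(i)-N(i+1) beyond this is a break
.GAP_CN_MAX <- 2.5
# S-S distances below this are reported as disulphide bridges
.SS_MAX <- 2.3

#' Parse biological-unit symmetry operators
#'
#' Extracts the BIOMT rotation/translation operators from the REMARK 350
#' header rows retained by [readPDB()]. Rotations are checked for
#' orthonormality (tolerance 1e-3) with a warning when violated.
#'
#' @param x a [Structure-class] (its retained header) or a character vector
#'   of REMARK 350 lines.
#' @return list of operators, each \code{list(rotation = 3x3 matrix,
#'   translation = 3-vector, opId = integer)}.
#' @export
biomtOperators <- function(x) {
    lines <- if (is(x, "Structure")) x@remarks else as.character(x)
    lines <- lines[grepl("BIOMT[123]", lines)]
    if (!length(lines)) return(list())
    fields <- strsplit(trimws(lines), "[ \t]+")
    rowno <- as.integer(sub(".*BIOMT([123]).*", "\\1",
                            vapply(fields, `[`, "", 3L)))
    opid <- as.integer(vapply(fields, `[`, "", 4L))
    vals <- t(vapply(fields, function(f) as.numeric(f[5:8]), numeric(4)))
    ops <- list()
    for (id in sort(unique(opid))) {
        sel <- which(opid == id)
        if (length(sel) != 3L)
            stop("BIOMT parse error: operator ", id, " lacks three rows")
        sel <- sel[order(rowno[sel])]
        R <- vals[sel, 1:3, drop = FALSE]
        t <- vals[sel, 4]
        if (max(abs(crossprod(R) - diag(3))) > 1e-3)
            warning("BIOMT operator ", id,
                    ": rotation not orthonormal within 1e-3")
        ops[[length(ops) + 1L]] <- list(rotation = unname(R),
                                        translation = unname(t),
                                        opId = id)
    }
    ops
}

#' Apply symmetry operators to a structure
#'
#' Generates one copy of the structure per operator with \code{r' = R r + t}.
#' Copies receive fresh chain identifiers so the result remains a valid
#' single model (atom count = n_ops x original).
#'
#' @param structure a [Structure-class].
#' @param operators list of operators as returned by [biomtOperators()]; by
#'   default taken from the structure's own header.
#' @return a [Structure-class] holding all copies.
#' @export
applySymmetry <- function(structure, operators = biomtOperators(structure)) {
    if (!length(operators))
        stop("no symmetry operators supplied or found in header")
    for (op in operators)
        if (max(abs(crossprod(op$rotation) - diag(3))) > 1e-3)
            warning("operator ", op$opId,
                    ": rotation not orthonormal within 1e-3; applied anyway")
    a0 <- atoms(structure)
    x0 <- coords(structure)
    pool <- c(LETTERS, letters, as.character(0:9))
    old_chains <- unique(a0$chain)
    need <- length(operators) * length(old_chains)
    if (need > length(pool))
        stop("too many symmetry copies for single-character chain ids")
    at <- list(); xs <- list(); k <- 0L
    for (io in seq_along(operators)) {
        op <- operators[[io]]
        ai <- a0
        map <- setNames(pool[k + seq_along(old_chains)], old_chains)
        k <- k + length(old_chains)
        ai$chain <- unname(map[ai$chain])
        at[[io]] <- ai
        xs[[io]] <- sweep(x0 %*% t(op$rotation), 2L, op$translation, `+`)
    }
    at <- do.call(rbind, at)
    at$serial <- seq_len(nrow(at))
    rownames(at) <- NULL
    xyz <- do.call(rbind, xs)
    dimnames(xyz) <- NULL
    new("Structure", atoms = at, coords = xyz,
        title = paste(structure@title, "(symmetry expanded)"),
        remarks = structure@remarks)
}

#' Validate a structure for simulation readiness
#'
#' Reports chain gaps (residue-numbering jumps or peptide C-N distances above
#' 2.5 Angstrom), heavy atoms missing relative to the standard amino-acid
#' templates (OXT optional at the C-terminus; hydrogens are ignored),
#' residues outside the 20-residue template set, an inventory of HETATM
#' residues, disulphide bridges (SG-SG under 2.3 Angstrom) and the number of
#' biological-unit operators in the header. A report is always produced; the
#' structure is \code{clean} iff gaps, missing atoms and nonstandard
#' residues are all absent.
#'
#' @param structure a [Structure-class].
#' @return a [ScanReport-class].
#' @examples
#' scanStructure(buildPolypeptide(fixtureSpec(nResidues = 10)))
#' @export
scanStructure <- function(structure) {
    a <- atoms(structure)
    xyz <- coords(structure)
    heavy <- a$element != "H" & a$element != "D"

    het <- a[a$is_het, , drop = FALSE]
    het_res <- unique(het[c("chain", "resid", "resname")])
    hetInventory <- if (nrow(het_res))
        vapply(split(het_res, het_res$resname), nrow, integer(1)) else
        setNames(integer(0), character(0))

    prot <- a[!a$is_het, , drop = FALSE]
    prot_idx <- which(!a$is_het)
    gaps <- data.frame(chain = character(), resid_before = integer(),
                       resid_after = integer(), reason = character(),
                       stringsAsFactors = FALSE)
    miss_chain <- character(); miss_resid <- integer()
    miss_resname <- character(); miss_atoms <- list()
    nonstd <- data.frame(chain = character(), resid = integer(),
                         resname = character(), stringsAsFactors = FALSE)

    if (nrow(prot)) {
        key <- paste(prot$chain, prot$resid)
        first <- !duplicated(key)
        res <- prot[first, c("chain", "resid", "resname")]
        std <- res$resname %in% .AA3
        nonstd <- res[!std, , drop = FALSE]
        rownames(nonstd) <- NULL

        for (r in which(std)) {
            sel <- key == paste(res$chain[r], res$resid[r])
            have <- prot$name[sel & prot$element != "H" & prot$element != "D"]
            want <- c("N", "CA", "C", "O", .SIDECHAIN_ATOMS[[res$resname[r]]])
            lost <- setdiff(want, have)  # OXT never required
            if (length(lost)) {
                miss_chain <- c(miss_chain, res$chain[r])
                miss_resid <- c(miss_resid, res$resid[r])
                miss_resname <- c(miss_resname, res$resname[r])
                miss_atoms <- c(miss_atoms, list(lost))
            }
        }

        for (ch in unique(res$chain)) {
            rr <- res[res$chain == ch, , drop = FALSE]
            if (nrow(rr) < 2L) next
            for (j in seq_len(nrow(rr) - 1L)) {
                r1 <- rr$resid[j]; r2 <- rr$resid[j + 1L]
                reason <- NULL
                if (r2 - r1 != 1L) {
                    reason <- "residue numbering discontinuity"
                } else {
                    ci <- prot_idx[key == paste(ch, r1) & prot$name == "C"]
                    ni <- prot_idx[key == paste(ch, r2) & prot$name == "N"]
                    if (length(ci) == 1L && length(ni) == 1L) {
                        d <- sqrt(sum((xyz[ci, ] - xyz[ni, ])^2))
                        if (d > .GAP_CN_MAX)
                            reason <- sprintf(
                                "peptide C-N distance %.2f Ang > %.1f", d,
                                .GAP_CN_MAX)
                    }
                }
                if (!is.null(reason))
                    gaps <- rbind(gaps, data.frame(
                        chain = ch, resid_before = r1, resid_after = r2,
                        reason = reason, stringsAsFactors = FALSE))
            }
        }
    }

    sg <- which(a$name == "SG" & heavy)
    ss <- data.frame(chain1 = character(), resid1 = integer(),
                     chain2 = character(), resid2 = integer(),
                     distance = numeric(), stringsAsFactors = FALSE)
    if (length(sg) >= 2L) {
        for (u in seq_along(sg)[-length(sg)])
            for (v in seq((u + 1L), length(sg))) {
                i <- sg[u]; j <- sg[v]
                if (a$chain[i] == a$chain[j] && a$resid[i] == a$resid[j]) next
                d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
                if (d < .SS_MAX)
                    ss <- rbind(ss, data.frame(
                        chain1 = a$chain[i], resid1 = a$resid[i],
                        chain2 = a$chain[j], resid2 = a$resid[j],
                        distance = d, stringsAsFactors = FALSE))
            }
    }

    missing <- data.frame(chain = miss_chain, resid = miss_resid,
                          resname = miss_resname, stringsAsFactors = FALSE)
    missing$atoms <- miss_atoms

    new("ScanReport",
        chainGaps = gaps,
        missingAtoms = missing,
        nonstandardResidues = nonstd,
        hetInventory = hetInventory,
        disulphides = ss,
        biomtCount = length(biomtOperators(structure)),
        clean = nrow(gaps) == 0L && nrow(missing) == 0L &&
            nrow(nonstd) == 0L)
}

#' Serialize a scan report to JSON-ready list
#'
#' @param report a [ScanReport-class].
#' @return a plain list mirroring the report slots, suitable for
#'   \code{jsonlite::toJSON()}.
#' @export
reportAsList <- function(report) {
    list(clean = report@clean,
         chain_gaps = report@chainGaps,
         missing_atoms = if (nrow(report@missingAtoms))
             data.frame(report@missingAtoms[, 1:3],
                        atoms = vapply(report@missingAtoms$atoms,
                                       paste, "", collapse = ","))
         else report@missingAtoms[, 1:3],
         nonstandard_residues = report@nonstandardResidues,
         het_inventory = as.list(report@hetInventory),
         disulphides = report@disulphides,
         biomt_count = report@biomtCount)
}
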