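# Fixed-column PDB reading/writing. The parser keeps REMARK 350 header rows
# verbatim (for biological-unit expansion), resolves alternate locations by
# policy, and turns MODEL blocks into ensemble frames.

.parseAtomLine <- function(line, lineno) {
    num <- function(from, to, what) {
        v <- suppressWarnings(as.numeric(substr(line, from, to)))
        if (is.na(v))
            stop(sprintf("PDB format error at line %d: unparseable %s field",
                         lineno, what))
        v
    }
    el <- trimws(substr(line, 77, 78))
    list(record = substr(line, 1, 6),
         serial = suppressWarnings(as.integer(substr(line, 7, 11))),
         name = trimws(substr(line, 13, 16)),
         altloc = trimws(substr(line, 17, 17)),
         resname = trimws(substr(line, 18, 20)),
         chain = trimws(substr(line, 22, 22)),
         resid = as.integer(num(23, 26, "residue number")),
         x = num(31, 38, "x coordinate"),
         y = num(39, 46, "y coordinate"),
         z = num(47, 54, "z coordinate"),
         element = el)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records of the fixed-column PDB dialect. REMARK 350
#' header rows are retained verbatim on the returned object so that
#' [biomtOperators()] and [scanStructure()] can use them. MODEL blocks become
#' ensemble frames, the first model defining the topology.
#'
#' @param path file path.
#' @param altloc alternate-location policy: \code{"first"} keeps the
#'   first-seen conformer of each atom, \code{"all"} keeps every conformer.
#' @return a [Structure-class], or an [Ensemble-class] when the file holds
#'   more than one MODEL.
#' @seealso [writePDB()]
#' @export
readPDB <- function(path, altloc = c("first", "all")) {
    altloc <- match.arg(altloc)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    recs <- substr(lines, 1, 6)
    is_atom <- recs %in% c("ATOM  ", "HETATM")
    if (!any(is_atom))
        stop("PDB format error: no ATOM/HETATM records in ", path)
    remarks <- lines[startsWith(lines, "REMARK 350")]
    title_lines <- lines[startsWith(lines, "TITLE")]
    title <- if (length(title_lines))
        trimws(paste(trimws(substr(title_lines, 11, 80)), collapse = " "))
    else ""

    model_starts <- which(startsWith(lines, "MODEL"))
    n_models <- max(1L, length(model_starts))
    # model index of every line
    model_of <- if (length(model_starts))
        findInterval(seq_along(lines), model_starts) else
        rep(1L, length(lines))
    model_of[model_of == 0L] <- 1L

    idx1 <- which(is_atom & model_of == model_of[which(is_atom)[1]])
    parsed <- lapply(idx1, function(i) .parseAtomLine(lines[i], i))
    at <- data.frame(
        serial = vapply(parsed, function(p) p$serial, integer(1)),
        name = vapply(parsed, function(p) p$name, character(1)),
        element = vapply(parsed, function(p) p$element, character(1)),
        resname = vapply(parsed, function(p) p$resname, character(1)),
        chain = vapply(parsed, function(p) p$chain, character(1)),
        resid = vapply(parsed, function(p) p$resid, integer(1)),
        is_het = vapply(parsed, function(p) p$record == "HETATM", logical(1)),
        altloc = vapply(parsed, function(p) p$altloc, character(1)),
        stringsAsFactors = FALSE)
    xyz <- cbind(vapply(parsed, function(p) p$x, numeric(1)),
                 vapply(parsed, function(p) p$y, numeric(1)),
                 vapply(parsed, function(p) p$z, numeric(1)))
    blank <- !nzchar(at$element)
    if (any(blank))
        at$element[blank] <- elementFromName(at$name[blank], at$is_het[blank])
    keep <- seq_len(nrow(at))
    if (altloc == "first") {
        key <- paste(at$chain, at$resid, at$resname, at$name)
        keep <- which(!duplicated(key))
    }
    at <- at[keep, , drop = FALSE]
    rownames(at) <- NULL
    s <- new("Structure", atoms = at, coords = xyz[keep, , drop = FALSE],
             title = title, remarks = remarks)
    if (n_models <= 1L) return(s)

    frames <- vector("list", n_models)
    frames[[1]] <- coords(s)
    ref_n <- length(idx1)
    for (m in 2:n_models) {
        idx <- which(is_atom & model_of == model_of[model_starts[m]])
        if (length(idx) != ref_n)
            stop(sprintf(
                "PDB format error: MODEL %d has %d atoms, expected %d",
                m, length(idx), ref_n))
        pm <- lapply(idx, function(i) .parseAtomLine(lines[i], i))
        fx <- cbind(vapply(pm, function(p) p$x, numeric(1)),
                    vapply(pm, function(p) p$y, numeric(1)),
                    vapply(pm, function(p) p$z, numeric(1)))
        frames[[m]] <- fx[keep, , drop = FALSE]
    }
    ensemble(s, frames)
}

.formatAtomName <- function(name, element) {
    # names of atoms with one-letter elements are right-shifted one column
    ifelse(nchar(name) >= 4L | nchar(element) >= 2L,
           sprintf("%-4s", name), sprintf(" %-3s", name))
}

.pdbAtomLines <- function(s, xyz) {
    if (any(abs(xyz) >= 10000))
        stop("coordinate overflow: |x| must be < 10000 Angstrom for PDB output")
    a <- atoms(s)
    serial <- if (max(a$serial, na.rm = TRUE) > 99999 || anyNA(a$serial))
        seq_len(nrow(a)) else a$serial
    sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$is_het, "HETATM", "ATOM"), serial,
            .formatAtomName(a$name, a$element), a$altloc, a$resname,
            a$chain, a$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0,
            a$element)
}

#' Write a PDB coordinate file
#'
#' Writes fixed-column ATOM/HETATM records at standard PDB precision (3
#' decimals on coordinates). Ensembles are written as MODEL/ENDMDL blocks.
#' Retained REMARK 350 header rows are emitted verbatim, so a
#' read-write-read cycle preserves symmetry information.
#'
#' @param x a [Structure-class] or [Ensemble-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readPDB()]
#' @export
writePDB <- function(x, path) {
    if (is(x, "Structure")) {
        s <- x
        frames <- list(coords(x))
    } else if (is(x, "Ensemble")) {
        s <- x@topology
        frames <- x@frames
    } else stop("x must be a Structure or an Ensemble")
    out <- character()
    if (nzchar(s@title)) out <- c(out, sprintf("TITLE     %s", s@title))
    out <- c(out, s@remarks)
    multi <- length(frames) > 1L
    for (m in seq_along(frames)) {
        if (multi) out <- c(out, sprintf("MODEL     %4d", m))
        out <- c(out, .pdbAtomLines(s, frames[[m]]))
        if (multi) out <- c(out, "ENDMDL")
    }
    out <- c(out, "END")
    writeLines(out, path)
    invisible(path)
}
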