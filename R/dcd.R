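# Binary DCD trajectory IO following the CHARMM/NAMD convention: Fortran
# unformatted records (4-byte length markers), 'CORD' magic, 20-int control
# block, then per frame one single-precision record each for X, Y and Z.
# Files are written little-endian; the reader auto-detects endianness from
# the first record marker.

#' Write a DCD trajectory
#'
#' @param ens an [Ensemble-class] (or a [Structure-class], written as one
#'   frame).
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readDCD()]
#' @export
writeDCD <- function(ens, path) {
    if (is(ens, "Structure")) ens <- ensemble(ens)
    stopifnot(is(ens, "Ensemble"))
    nframes <- nFrames(ens)
    natom <- nAtoms(ens)
    con <- file(path, "wb")
    on.exit(close(con))
    wint <- function(x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")
    wfloat <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                   endian = "little")
    # header record: 'CORD' + 20 control ints (int 10 holds a float delta,
    # int 20 the CHARMM version stamp)
    wint(84L)
    writeBin(charToRaw("CORD"), con)
    wint(c(nframes, 1L, 1L, nframes, 0L, 0L, 0L, 0L, 0L))
    wfloat(1.0)                       # timestep placeholder
    wint(rep(0L, 9L))
    wint(24L)                         # CHARMM version
    wint(84L)
    # title record
    title <- sprintf("%-80s", "written by scatterfit")
    wint(4L + 80L)
    wint(1L)
    writeBin(charToRaw(substr(title, 1, 80)), con)
    wint(4L + 80L)
    # natom record
    wint(4L); wint(natom); wint(4L)
    for (f in ens@frames) {
        for (d in 1:3) {
            wint(4L * natom)
            wfloat(f[, d])
            wint(4L * natom)
        }
    }
    invisible(path)
}

#' Read a DCD trajectory
#'
#' Reads CHARMM/NAMD-convention binary trajectories. Endianness is detected
#' from the first record marker; the header frame count is cross-checked
#' against the file contents. A frame cut off mid-record raises a format
#' error reporting how many complete frames were recovered.
#'
#' @param path file path.
#' @param topology a [Structure-class] whose atom count must match the file
#'   header.
#' @return an [Ensemble-class] over \code{topology}.
#' @seealso [writeDCD()]
#' @export
readDCD <- function(path, topology) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    endian <- "little"
    rint <- function(n = 1L) readBin(con, "integer", n = n, size = 4L,
                                     endian = endian)
    m <- rint()
    if (length(m) == 0L) stop("DCD format error: empty file")
    if (m != 84L) {
        endian <- "big"
        seek(con, 0L)
        m <- rint()
        if (!identical(m, 84L))
            stop("DCD format error: unrecognized header record length")
    }
    magic <- rawToChar(readBin(con, "raw", 4L))
    if (magic != "CORD") stop("DCD format error: missing CORD magic")
    icntrl_a <- rint(9L)
    readBin(con, "numeric", 1L, size = 4L, endian = endian)  # delta
    rint(10L)
    if (rint() != 84L) stop("DCD format error: bad header record close")
    header_frames <- icntrl_a[1]
    # title record
    tlen <- rint()
    readBin(con, "raw", tlen)
    if (rint() != tlen) stop("DCD format error: bad title record close")
    # natom record
    if (rint() != 4L) stop("DCD format error: bad natom record open")
    natom <- rint()
    if (rint() != 4L) stop("DCD format error: bad natom record close")
    if (natom != nAtoms(topology))
        stop(sprintf(
            "DCD topology error: file has %d atoms, topology has %d",
            natom, nAtoms(topology)))
    frames <- list()
    repeat {
        open <- rint()
        if (length(open) == 0L) break  # clean end of file
        xyz <- matrix(NA_real_, natom, 3L)
        for (d in 1:3) {
            if (d > 1L) {
                open <- rint()
                if (length(open) == 0L)
                    stop(sprintf(
                        "DCD format error: truncated frame; %d complete frames recovered",
                        length(frames)))
            }
            if (open != 4L * natom)
                stop(sprintf(
                    "DCD format error after %d complete frames: bad record size",
                    length(frames)))
            v <- readBin(con, "numeric", natom, size = 4L, endian = endian)
            cl <- rint()
            if (length(v) < natom || length(cl) == 0L || cl != 4L * natom)
                stop(sprintf(
                    "DCD format error: truncated frame; %d complete frames recovered",
                    length(frames)))
            xyz[, d] <- v
        }
        frames[[length(frames) + 1L]] <- xyz
    }
    if (length(frames) == 0L)
        stop("DCD format error: no complete frames in file")
    if (header_frames > 0L && header_frames != length(frames))
        warning(sprintf("DCD header declares %d frames, file contains %d",
                        header_frames, length(frames)))
    ensemble(topology, frames)
}
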