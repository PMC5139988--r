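# Independent oracles, deliberately written against the naive definitions
# rather than the package's optimized paths.

# O(n^2) brute-force steric scan via dist(), excluding same/adjacent-residue
# pairs of the same chain (mirrors the documented exclusion rule).
bruteOverlap <- function(frame, structure, cutoff = 3.0) {
    a <- atoms(structure)
    keep <- a$element != "H" & a$element != "D"
    idx <- which(keep)
    d <- as.matrix(dist(frame[idx, , drop = FALSE]))
    excl <- outer(a$chain[idx], a$chain[idx], "==") &
        abs(outer(a$resid[idx], a$resid[idx], "-")) <= 1
    d[excl] <- Inf
    diag(d) <- Inf
    sum(d < cutoff) / 2
}

# pure-R Debye sum, double loop over pairs folded into dist()
debyeOracle <- function(xyz, f, q) {
    d <- as.matrix(dist(xyz))
    out <- numeric(length(q))
    for (k in seq_along(q)) {
        x <- q[k] * d
        s <- ifelse(x < 1e-12, 1, sin(x) / x)
        out[k] <- sum(outer(f, f) * s)
    }
    out
}

# maximum intra-residue interatomic distance drift between a frame and the
# reference coordinates. Pairs split by a sampled psi axis (carbonyl O/OXT
# against atoms other than CA/C in the flexible residues) are 1-4 pairs
# across the rotated bond and legitimately change; they are exempted.
maxIntraResidueDrift <- function(frame, ref, structure,
                                 flexResidues = integer()) {
    a <- atoms(structure)
    worst <- 0
    for (g in split(seq_len(nrow(a)), paste(a$chain, a$resid))) {
        if (length(g) < 2L) next
        dd <- abs(dist(frame[g, , drop = FALSE]) -
                      dist(ref[g, , drop = FALSE]))
        if (a$resid[g[1]] %in% flexResidues) {
            nm <- a$name[g]
            ox <- which(nm %in% c("O", "OXT"))
            if (length(ox)) {
                m <- matrix(FALSE, length(g), length(g))
                keepMate <- nm %in% c("CA", "C", "O", "OXT")
                m[ox, !keepMate] <- TRUE
                m[!keepMate, ox] <- TRUE
                dd[as.logical(as.vector(as.dist(m)))] <- 0
            }
        }
        worst <- max(worst, max(dd))
    }
    worst
}

# seeded random cloud with positive amplitudes, for calculator tests
randomConfiguration <- function(n, seed, sd = 8) {
    set.seed(seed)
    list(xyz = matrix(rnorm(3 * n, sd = sd), n, 3),
         f = runif(n, 0.5, 2))
}
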