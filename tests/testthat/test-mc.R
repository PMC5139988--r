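test_that("dihedral angles follow the standard sign convention", {
    # planar trans and cis arrangements
    expect_equal(computeDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                 c(1, -1, 0)), 180)
    expect_equal(computeDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                 c(1, 1, 0)), 0)
    # mirroring flips the sign
    set.seed(4)
    for (t in 1:6) {
        p <- matrix(rnorm(12), 4, 3)
        ang <- computeDihedral(p[1, ], p[2, ], p[3, ], p[4, ])
        pm <- p
        pm[, 3] <- -pm[, 3]
        expect_equal(computeDihedral(pm[1, ], pm[2, ], pm[3, ], pm[4, ]),
                     -ang, tolerance = 1e-9)
    }
    expect_error(computeDihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                 c(3, 1, 0)), "collinear")
})

test_that("dihedral sign matches an independent torsion implementation", {
    skip_if_not_installed("bio3d")
    set.seed(7)
    for (t in 1:8) {
        p <- matrix(rnorm(12, sd = 3), 4, 3)
        expect_equal(computeDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                     bio3d::torsion.xyz(as.vector(t(p))),
                     tolerance = 1e-6, ignore_attr = TRUE)
    }
})

test_that("dihedral rotations are rigid group operations", {
    sys <- makeTwoDomainSystem()
    s <- sys$structure
    x0 <- coords(s)
    r <- sys$region$first + 1L

    expect_lt(max(abs(rotateDihedral(x0, s, "A", r, "phi", 360) - x0)), 1e-9)
    x1 <- rotateDihedral(x0, s, "A", r, "psi", 30)
    expect_lt(max(abs(rotateDihedral(x1, s, "A", r, "psi", -30) - x0)), 1e-9)

    # rigid rotation: distances within the moved set and within the static
    # set are unchanged; the realized torsion change equals the request
    mv <- scatterfit:::.dihedralMove(atoms(s), "A", r, "phi")
    x2 <- rotateDihedral(x0, s, "A", r, "phi", 47)
    expect_lt(max(abs(dist(x2[mv$moving, ]) - dist(x0[mv$moving, ]))), 1e-9)
    stat <- setdiff(seq_len(nAtoms(s)), mv$moving)
    expect_lt(max(abs(dist(x2[stat, ]) - dist(x0[stat, ]))), 1e-9)
    a <- atoms(s)
    idx <- function(rr, n) which(a$resid == rr & a$name == n)
    phi <- function(x) computeDihedral(x[idx(r - 1, "C"), ], x[idx(r, "N"), ],
                                       x[idx(r, "CA"), ], x[idx(r, "C"), ])
    d <- (phi(x2) - phi(x0)) %% 360
    expect_equal(min(d, 360 - d), 47, tolerance = 1e-6)

    expect_error(rotateDihedral(x0, s, "A", 999, "phi", 5), "topology error")
})

test_that("phi moves on proline are refused", {
    s <- buildPolypeptide(fixtureSpec(sequence = "AAPAA"))
    expect_error(rotateDihedral(coords(s), s, "A", 3, "phi", 10),
                 "proline")
    expect_warning(
        runMonomerMC(s, flexibleRegion("A", 3, 3, "phi"),
                     mcConfig(nAcceptTarget = 2, maxTrials = 50, seed = 1)),
        "proline") |> expect_error("no sampleable")
})

test_that("overlap check honours cutoff and the covalent-neighbour exclusion", {
    s <- buildPolypeptide(fixtureSpec(nResidues = 6))
    x <- coords(s)
    a <- atoms(s)
    i1 <- which(a$resid == 1 & a$name == "CA")
    i5 <- which(a$resid == 5 & a$name == "CA")
    x[i5, ] <- x[i1, ] + c(2.9, 0, 0)
    expect_true(checkOverlap(x, s, cutoff = 3.0)$clash)
    expect_false(checkOverlap(x, s, cutoff = 2.5,
                              selection = c("CA"))$clash)
    # bonded N-CA pair in the same residue is excluded
    expect_false(checkOverlap(coords(s), s, cutoff = 2.0,
                              selection = c("N", "CA"))$clash)
    expect_error(checkOverlap(coords(s), s, selection = "NOPE"),
                 "empty atom selection")
})

test_that("gridded overlap check equals the brute-force oracle", {
    sys <- makeTwoDomainSystem()
    s <- sys$structure
    set.seed(12)
    for (t in 1:8) {
        x <- coords(s) + matrix(rnorm(nAtoms(s) * 3, sd = 1.2), ncol = 3)
        got <- checkOverlap(x, s, cutoff = 3.0, countAll = TRUE)
        want <- bruteOverlap(x, s, cutoff = 3.0)
        expect_equal(got$n_pairs, want)
        expect_identical(got$clash, want > 0)
    }
})

test_that("radius of gyration matches closed forms", {
    s2 <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
    fake <- buildPolypeptide(fixtureSpec(nResidues = 1))
    expect_equal(scatterfit:::.rgWeighted(s2, c(1, 1)), 1.0)
    cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    expect_equal(scatterfit:::.rgWeighted(cube, rep(1, 8)), sqrt(3),
                 tolerance = 1e-12)
    expect_equal(scatterfit:::.rgWeighted(matrix(5, 1, 3), 1), 0)
    expect_error(scatterfit:::.rgWeighted(s2, c(0, 0)), "zero")
    # weighting options run on a real structure
    expect_gt(radiusOfGyration(fake), 0)
    expect_gt(radiusOfGyration(coords(fake), fake, "scattering"), 0)
})

test_that("monomer MC produces valid, reproducible ensembles", {
    sys <- makeTwoDomainSystem()
    cfg <- mcConfig(nAcceptTarget = 150, seed = 7)
    res <- runMonomerMC(sys$structure, sys$region, cfg)
    expect_equal(res@nAccepted, 150L)
    expect_lte(res@nAccepted, res@nTrials)
    # every accepted frame passes an independent overlap scan
    for (k in seq(1, 150, by = 25))
        expect_equal(bruteOverlap(getFrame(res@ensemble, k), sys$structure,
                                  3.0), 0)
    # determinism
    res2 <- runMonomerMC(sys$structure, sys$region, cfg)
    expect_identical(res@ensemble@frames, res2@ensemble@frames)
    expect_identical(res@nTrials, res2@nTrials)
    # Rg window is enforced
    # window must contain the starting Rg (the chain cannot enter an
    # excluding window); it still binds against compact excursions
    resb <- runMonomerMC(sys$structure, sys$region,
                         mcConfig(nAcceptTarget = 60, seed = 8,
                                  rgBounds = c(12, 16.5)))
    expect_true(all(resb@perFrameRg >= 12 & resb@perFrameRg <= 16.5))
    expect_warning(
        runMonomerMC(sys$structure, sys$region,
                     mcConfig(nAcceptTarget = 2, maxTrials = 10, seed = 1,
                              rgBounds = c(5, 8))),
        "outside rgBounds") |> expect_error("no accepted")
})

test_that("vanishing step size gives near-total acceptance at the start", {
    sys <- makeTwoDomainSystem()
    res <- runMonomerMC(sys$structure, sys$region,
                        mcConfig(nAcceptTarget = 50, maxStepDeg = 1e-4,
                                 seed = 1))
    expect_equal(res@nAccepted, res@nTrials)
    expect_lt(max(abs(getFrame(res@ensemble, 50) - coords(sys$structure))),
              1e-3)
})

test_that("distance constraints and hopeless runs are reported", {
    sys <- makeTwoDomainSystem()
    n <- max(atoms(sys$structure)$resid)
    dc <- list(list(a = "A:1:CA", b = sprintf("A:%d:CA", n),
                    min = 0, max = 47))
    res <- runMonomerMC(sys$structure, sys$region,
                        mcConfig(nAcceptTarget = 40, seed = 5,
                                 distanceConstraints = dc))
    a <- atoms(sys$structure)
    i1 <- which(a$resid == 1 & a$name == "CA")
    i2 <- which(a$resid == n & a$name == "CA")
    for (k in seq_len(res@nAccepted)) {
        fr <- getFrame(res@ensemble, k)
        expect_lte(sqrt(sum((fr[i1, ] - fr[i2, ])^2)), 47)
    }
    err <- tryCatch(
        suppressWarnings(
            runMonomerMC(sys$structure, sys$region,
                         mcConfig(nAcceptTarget = 5, maxTrials = 40,
                                  seed = 1, rgBounds = c(1000, 2000)))),
        error = conditionMessage)
    expect_match(err, "no accepted structures")
    expect_match(err, "rg_bounds")
})

test_that("config invariants are validated", {
    expect_error(mcConfig(maxStepDeg = 0), "maxStepDeg")
    expect_error(mcConfig(maxStepDeg = 181), "maxStepDeg")
    expect_error(mcConfig(overlapCutoff = -1), "overlapCutoff")
    expect_error(mcConfig(rgBounds = c(5, 4)), "rgBounds")
    expect_error(flexibleRegion("A", 5, 4), "empty")
})
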