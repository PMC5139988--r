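test_that("amplitudes follow the standard tables and exchange rules", {
    s <- buildPolypeptide(fixtureSpec(nResidues = 2))
    f <- assignAmplitudes(s, contrastModel("neutron"))
    a <- atoms(s)
    expect_equal(unique(f[a$element == "C"]), 6.6511)
    expect_equal(unique(f[a$element == "N"]), 9.37)
    fx <- assignAmplitudes(s, contrastModel("xray"))
    expect_equal(unique(fx[a$element == "O"]), 8)
    expect_equal(unique(fx[a$element == "C"]), 6)
})

test_that("labile hydrogens take the deuterium amplitude in D2O", {
    # hand-built residue fragment with amide H, aliphatic HA and hydroxyl HG
    at <- data.frame(serial = 1:6,
                     name = c("N", "H", "CA", "HA", "OG", "HG"),
                     element = c("N", "H", "C", "H", "O", "H"),
                     resname = "SER", chain = "A", resid = 1L,
                     is_het = FALSE, altloc = "", stringsAsFactors = FALSE)
    s <- new("Structure", atoms = at, coords = matrix(rnorm(18), 6, 3))
    f0 <- assignAmplitudes(s, contrastModel("neutron", d2oFraction = 0))
    f1 <- assignAmplitudes(s, contrastModel("neutron", d2oFraction = 1))
    bH <- -3.7406; bD <- 6.671
    expect_equal(f0[c(2, 4, 6)], rep(bH, 3))      # all protons in H2O
    expect_equal(f1[2], bD)                        # amide H exchanges
    expect_equal(f1[6], bD)                        # hydroxyl H exchanges
    expect_equal(f1[4], bH)                        # carbon-bound H does not
    fhalf <- assignAmplitudes(s, contrastModel("neutron", d2oFraction = 0.5,
                                               exchangeFraction = 0.9))
    expect_equal(fhalf[2], bH + 0.5 * 0.9 * (bD - bH))
    bad <- s
    bad@atoms$element[5] <- "XX"
    expect_error(assignAmplitudes(bad), "XX")
})

test_that("golden directions are unit, deterministic and quasi-uniform", {
    expect_error(goldenDirections(0), "positive")
    d1 <- goldenDirections(1)
    expect_equal(sqrt(sum(d1^2)), 1)
    d <- goldenDirections(937)
    expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
    expect_lt(sqrt(sum(colMeans(goldenDirections(10000))^2)), 0.01)
})

test_that("golden-vector intensity converges to the Debye sum", {
    q <- seq(0.02, 0.5, length.out = 20)
    for (seed in 1:5) {
        cfg <- randomConfiguration(50, seed)
        ig <- intensities(intensityGolden(cfg$xyz, cfg$f, q, 1000))
        id <- intensities(intensityDebye(cfg$xyz, cfg$f, q))
        expect_lt(max(abs(ig - id) / id), 0.01)
    }
    # I(0) is exact
    cfg <- randomConfiguration(20, 9)
    expect_equal(intensities(intensityGolden(cfg$xyz, cfg$f, 0, 100)),
                 sum(cfg$f)^2)
})

test_that("Debye sum reproduces closed forms and the pure-R oracle", {
    q <- seq(0, 0.5, length.out = 11)
    expect_equal(intensities(intensityDebye(matrix(0, 1, 3), 2, q)),
                 rep(4, 11))
    # two atoms at d = 10: I = 2 + 2 sin(Qd)/(Qd); at Q = pi/10 exactly 2
    two <- rbind(c(0, 0, 0), c(10, 0, 0))
    expect_equal(intensities(intensityDebye(two, c(1, 1), pi / 10)), 2)
    qq <- seq(0.01, 0.5, length.out = 13)
    expect_equal(intensities(intensityDebye(two, c(1, 1), qq)),
                 2 + 2 * sin(qq * 10) / (qq * 10), tolerance = 1e-12)
    cfg <- randomConfiguration(30, 2)
    expect_equal(intensities(intensityDebye(cfg$xyz, cfg$f, qq)),
                 debyeOracle(cfg$xyz, cfg$f, qq), tolerance = 1e-9)
    expect_error(intensityDebye(two, 1, qq), "mismatch")
})

test_that("cube decomposition obeys the occupancy cutoff", {
    # 4 atoms in one cube -> one sphere at its centre
    x4 <- matrix(c(1, 1, 1, 2, 1, 1, 1, 2, 1, 1, 1, 2), 4, 3, byrow = TRUE)
    m <- buildSphereModel(x4, cubeSide = 5.30, atomCutoff = 4)
    expect_equal(nrow(m@centers), 1L)
    expect_equal(m@atomsPerSphere, 4L)
    expect_equal(m@centers[1, ], apply(x4, 2, min) + 5.30 / 2)
    expect_equal(m@radius, 5.30 * (3 / (4 * pi))^(1 / 3), tolerance = 1e-9)
    expect_equal(m@radius, 3.288, tolerance = 1e-3)
    # 3 atoms do not reach the cutoff
    expect_error(buildSphereModel(x4[1:3, ], atomCutoff = 4), "empty")
    # about n/4-5 spheres for a packed body
    set.seed(6)
    ball <- matrix(rnorm(3 * 900, sd = 8), ncol = 3)
    mb <- buildSphereModel(ball)
    expect_gt(sum(mb@atomsPerSphere), 0.5 * 900)
})

test_that("hydration bookkeeping deposits the requested water mass", {
    s <- buildPolypeptide(fixtureSpec(nResidues = 60,
                                      conformation = "helix"))
    m <- buildSphereModel(coords(s))
    massPerSphere <- 5.30^3 * 0.6022140857
    expect_equal(massPerSphere, 89.65, tolerance = 1e-3)

    hyd <- addHydration(m, dryMassDa = 10000, hydrationGperG = 0.3)
    n <- sum(hyd@isHydration)
    expect_gte(n * massPerSphere, 3000)
    expect_lt((n - 1) * massPerSphere, 3000)   # within one sphere of target
    expect_true(n %in% 33:34)

    expect_identical(addHydration(m, 10000, 0), m)
    # the shell lies outside: hydrated Rg strictly exceeds dry Rg
    hyd2 <- addHydration(m, molecularWeight(s), 0.3)
    expect_gt(sphereModelRg(hyd2), sphereModelRg(m, includeHydration = FALSE))
    # impossible targets report the achievable hydration
    expect_error(addHydration(m, 1e7, 0.3), "insufficient")
})

test_that("sphere-model intensity reduces to the analytic form factor", {
    R <- 5.30 * (3 / (4 * pi))^(1 / 3)
    one <- new("SphereModel", centers = matrix(0, 1, 3), radius = R,
               cubeSide = 5.30, isHydration = FALSE, atomsPerSphere = 1L)
    qr <- seq(0.01, 5, length.out = 80) / R
    ana <- (3 * (sin(qr * R) - qr * R * cos(qr * R)) / (qr * R)^3)^2
    got <- intensities(suppressWarnings(intensitySphereDebye(one, qr)))
    expect_lt(max(abs(got - ana)), 1e-10)

    # n coincident spheres behave like one
    five <- new("SphereModel", centers = matrix(0, 5, 3, byrow = TRUE),
                radius = R, cubeSide = 5.30, isHydration = rep(FALSE, 5),
                atomsPerSphere = rep(1L, 5))
    got5 <- intensities(suppressWarnings(intensitySphereDebye(five, qr)))
    expect_lt(max(abs(got5 - ana)), 1e-10)

    # two spheres track the 2-point Debye interference modulated by g(Q)
    two <- new("SphereModel",
               centers = rbind(c(0, 0, 0), c(10, 0, 0)), radius = R,
               cubeSide = 5.30, isHydration = rep(FALSE, 2),
               atomsPerSphere = rep(1L, 2))
    qs <- seq(0.01, 0.3, length.out = 15)
    want <- (3 * (sin(qs * R) - qs * R * cos(qs * R)) / (qs * R)^3)^2 *
        (2 + 2 * sin(qs * 10) / (qs * 10)) / 4
    expect_lt(max(abs(intensities(intensitySphereDebye(two, qs)) / want - 1)),
              0.001)
    expect_warning(intensitySphereDebye(one, 1.2), "validity")
})

test_that("dry sphere model reproduces the all-atom curve of a compact body", {
    set.seed(5)
    R <- 20
    N <- round(0.054 * 4 / 3 * pi * R^3)  # protein heavy-atom density
    u <- matrix(rnorm(3 * N), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    xyz <- u * (R * runif(N)^(1 / 3))
    q <- seq(0.01, 0.314, length.out = 30)  # 2 pi / (2 x 1 nm resolution)
    ia <- intensities(intensityDebye(xyz, rep(6, N), q))
    isph <- intensities(intensitySphereDebye(buildSphereModel(xyz), q))
    can <- scatteringCurve(q, ia / ia[1])
    csn <- scatteringCurve(q, isph / isph[1])
    expect_lt(rFactor(csn, can, i0Expt = 1), 5)
    rg <- scatterfit:::.rgWeighted(xyz, rep(1, N))
    gu <- q <= 1.3 / rg
    expect_lt(max(abs(intensities(csn)[gu] / intensities(can)[gu] - 1)), 0.05)
})

test_that("P(r) respects the counting identities", {
    two <- rbind(c(0, 0, 0), c(10, 0, 0))
    pr <- prDistribution(two, c(1, 1), binWidth = 1)
    expect_equal(sum(pr$p > 0), 1L)
    expect_equal(pr$r[pr$p > 0], 9.5)  # bin containing r = 10
    expect_equal(sum(pr$p) * pr$binWidth, 2)

    cfg <- randomConfiguration(40, 3)
    pr <- prDistribution(cfg$xyz, cfg$f, binWidth = 0.5)
    expect_equal(sum(pr$p) * pr$binWidth, sum(cfg$f)^2 - sum(cfg$f^2),
                 tolerance = 1e-9)
    expect_lte(max(pr$r[pr$p != 0]) - pr$binWidth / 2, pr$dmax)
    expect_equal(prDistribution(matrix(0, 1, 3), 1)$p, 0)
})

test_that("Gaussian smearing preserves constants and fills minima", {
    q <- seq(0.01, 0.6, length.out = 150)
    cst <- scatteringCurve(q, rep(3, 150))
    out <- suppressWarnings(smearGaussian(cst, 0.1, 0.005))
    expect_lt(max(abs(intensities(out) - 3)), 1e-12)
    expect_identical(smearGaussian(cst, 0, 0), cst)

    two <- intensityDebye(rbind(c(0, 0, 0), c(30, 0, 0)), c(1, 1), q)
    sm <- suppressWarnings(smearGaussian(two, 0.1, 0.005))
    i0 <- intensities(two)
    mins <- which(diff(sign(diff(i0))) > 0) + 1L
    expect_true(all(intensities(sm)[mins] > i0[mins]))
    expect_error(smearGaussian(cst, -0.1, 0), ">= 0")
})

test_that("background addition is linear in Q", {
    cv <- scatteringCurve(c(0.1, 0.2), c(1, 1))
    expect_identical(addBackground(cv, 0, 0)@i, cv@i)
    expect_equal(intensities(addBackground(cv, 2, 0)), c(3, 3))
    expect_equal(intensities(addBackground(cv, 0, 1)), c(1.1, 1.2))
})

test_that("SLD match point interpolates between H2O and D2O", {
    # water against water: degenerate everywhere
    w <- sldMatchpoint(c(H = 2, O = 1), exchangeableH = 2, volume = 29.9)
    expect_true(w$degenerate)
    # no exchangeable H: constant particle line, unique crossing
    p <- sldMatchpoint(c(C = 10, O = 2, N = 2), exchangeableH = 0,
                       volume = 300)
    expect_equal(p$particleSLD[["slope"]], 0)
    f <- p$matchPoint
    expect_equal(p$particleSLD[["intercept"]],
                 p$solventSLD[["intercept"]] + f * p$solventSLD[["slope"]],
                 tolerance = 1e-9)
    # scale invariance: doubling composition and volume leaves SLD unchanged
    p2 <- sldMatchpoint(c(C = 20, O = 4, N = 4), exchangeableH = 0,
                        volume = 600)
    expect_equal(p2$particleSLD, p$particleSLD)
    # solvent line endpoints match the known pure-water SLDs (1e10 cm^-2)
    expect_equal(p$solventSLD[["intercept"]], -0.561, tolerance = 1e-3)
    expect_equal(sum(p$solventSLD), 6.404, tolerance = 1e-3)
})

test_that("solvent subtraction lowers amplitudes by displaced volume", {
    s <- buildPolypeptide(fixtureSpec(nResidues = 2))
    f0 <- assignAmplitudes(s, contrastModel("xray"))
    f1 <- assignAmplitudes(s, contrastModel("xray", solventSubtraction = TRUE))
    expect_true(all(f1 < f0))
    a <- atoms(s)
    expect_equal(f0[a$element == "C"][1] - f1[a$element == "C"][1],
                 10 / 29.9 * 16.44, tolerance = 1e-9)
})
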