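test_that("Guinier fit recovers exact Gaussian parameters", {
    q <- seq(0.005, 0.3, 0.005)
    g <- scatteringCurve(q, 100 * exp(-q^2 * 25 / 3))
    fit <- guinierFit(g)
    expect_equal(fit$i0, 100, tolerance = 1e-9)
    expect_equal(fit$rg, 5, tolerance = 1e-9)
    # scale equivariance
    fit3 <- guinierFit(scatteringCurve(q, 3 * intensities(g)))
    expect_equal(fit3$i0, 300, tolerance = 1e-9)
    expect_equal(fit3$rg, 5, tolerance = 1e-9)
    # included range respects Q Rg <= 1.3
    expect_lte(fit$qmax * fit$rg, 1.3)
    # rising curves have no Guinier region
    expect_error(guinierFit(scatteringCurve(q, exp(q^2 * 8))), "no Guinier")
})

test_that("Guinier Rg of a Debye curve matches the coordinate Rg", {
    cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    q <- seq(0.005, 0.6, length.out = 120)
    cv <- intensityDebye(cube, rep(1, 8), q)
    # an 8-point body this small needs a conservative Q Rg bound for the
    # Guinier expansion to hold to 1%
    fit <- guinierFit(cv, qrgMax = 0.7)
    expect_equal(fit$rg, sqrt(3), tolerance = 0.01)
    expect_equal(fit$i0, 64, tolerance = 0.5)
})

test_that("chi-square variants behave as constructed", {
    q <- seq(0.01, 0.3, length.out = 21)
    model <- scatteringCurve(q, 50 * exp(-q^2 * 40))
    # exact proportionality gives 0 for every variant
    expt <- scatteringCurve(q, 3 * intensities(model),
                            sigma = rep(0.5, 21))
    i0e <- 3 * intensities(model)[1]
    for (v in c("chi2_reduced", "chi2", "chi2_pearson"))
        expect_equal(chiSquare(model, expt, i0Expt = i0e, variant = v), 0,
                     tolerance = 1e-18)
    expect_equal(rFactor(model, expt, i0Expt = i0e), 0, tolerance = 1e-9)
    # one sigma-scaled unit residual per point: chi2 = N
    sig <- 0.02 * intensities(model)
    expt1 <- scatteringCurve(q, intensities(model) + sig, sigma = sig)
    expect_equal(chiSquare(model, expt1, i0Expt = intensities(model)[1],
                           variant = "chi2"), 21, tolerance = 1e-9)
    expect_equal(chiSquare(model, expt1, i0Expt = intensities(model)[1]),
                 21 / 20, tolerance = 1e-9)
    # sigma is mandatory for the sigma-weighted variants
    nosig <- scatteringCurve(q, intensities(model))
    expect_error(chiSquare(model, nosig, i0Expt = 1), "sigma required")
    # non-overlapping grids
    far <- scatteringCurve(q + 10, intensities(model), sigma = sig)
    expect_error(chiSquare(model, far, i0Expt = 1), "range error")
})

test_that("chi2_reduced calibrates to 1 against matched noise", {
    q <- seq(0.01, 0.3, length.out = 40)
    s <- buildPolypeptide(fixtureSpec(nResidues = 8))
    truth <- intensityDebye(s, assignAmplitudes(s), q)
    v <- vapply(1:100, function(k)
        chiSquare(truth, makeNoisyCurve(truth, 0.02, seed = k),
                  i0Expt = intensities(truth)[1]), numeric(1))
    expect_gt(mean(v), 0.8)
    expect_lt(mean(v), 1.2)
})

test_that("metrics are invariant to common rescaling", {
    q <- seq(0.01, 0.3, length.out = 15)
    model <- scatteringCurve(q, 10 * exp(-q^2 * 30))
    set.seed(2)
    ie <- intensities(model) * (1 + rnorm(15, 0, 0.05))
    expt <- scatteringCurve(q, ie, sigma = 0.05 * ie)
    base_chi <- chiSquare(model, expt, i0Expt = ie[1])
    base_r <- rFactor(model, expt, i0Expt = ie[1])
    for (k in c(0.1, 7)) {
        scaled_model <- scatteringCurve(q, k * intensities(model))
        expect_equal(chiSquare(scaled_model, expt, i0Expt = ie[1]), base_chi,
                     tolerance = 1e-9)
        scaled_expt <- scatteringCurve(q, k * ie, sigma = k * 0.05 * ie)
        expect_equal(rFactor(model, scaled_expt, i0Expt = k * ie[1]), base_r,
                     tolerance = 1e-9)
    }
    # 5% uniform deviation with the scale pinned to 1 gives R = 5%
    dev <- scatteringCurve(q, 1.05 * intensities(model))
    expect_equal(rFactor(model, dev, i0Expt = intensities(model)[1]) /
                     (100 * 0.05 / 1.05), 1, tolerance = 1e-9)
})

test_that("filterModels supports thresholds, ranks and Rg windows", {
    fits <- data.frame(frame = 1:3, chi2_reduced = c(0.5, 1.9, 3.0),
                       rg = c(10, 20, 30))
    expect_equal(filterModels(fits, threshold = 2), c(1L, 2L))
    expect_equal(filterModels(fits, bestN = 1), 1L)
    expect_warning(sel <- filterModels(fits, threshold = 0.1),
                   "no frames")
    expect_length(sel, 0L)
    expect_equal(filterModels(fits, threshold = Inf), 1:3)
    expect_equal(filterModels(fits, threshold = 2, rgWindow = c(15, 25)), 2L)
    # monotone: smaller threshold selects a subset
    for (th in c(0.6, 2, 3.5))
        expect_true(all(filterModels(fits, threshold = th) %in%
                            filterModels(fits, threshold = th + 1)))
})

test_that("density maps conserve counts and write valid cube files", {
    s <- buildPolypeptide(fixtureSpec(nResidues = 4))
    one_atom <- new("Structure",
                    atoms = atoms(s)[1, , drop = FALSE],
                    coords = coords(s)[1, , drop = FALSE])
    ens1 <- ensemble(one_atom)
    g <- densityMap(ens1, spacing = 2)
    expect_equal(sum(g@counts), 1L)
    expect_equal(sum(g@counts > 0), 1L)
    expect_equal(max(g@counts) / g@nFrames, 1)

    # ten identical frames normalize back to occupancy 1
    ens10 <- ensemble(one_atom, replicate(10, coords(one_atom),
                                          simplify = FALSE))
    g10 <- densityMap(ens10, spacing = 2)
    expect_equal(sum(g10@counts > 0), 1L)
    expect_equal(max(g10@counts) / g10@nFrames, 1)

    set.seed(8)
    frames <- lapply(1:6, function(i)
        coords(s) + matrix(rnorm(nAtoms(s) * 3, sd = 3), ncol = 3))
    ens <- ensemble(s, frames)
    g6 <- densityMap(ens, frames = c(2, 4, 5), spacing = 1.5)
    expect_equal(sum(g6@counts), 3L * nAtoms(s))
    expect_error(densityMap(ens, frames = integer()), "no frames")

    p <- withr::local_tempfile(fileext = ".cube")
    writeCube(g6, p, s)
    lines <- readLines(p)
    hdr <- as.numeric(strsplit(trimws(lines[3]), "[ ]+")[[1]])
    expect_equal(hdr[1], nAtoms(s))
    dims <- vapply(4:6, function(i)
        as.numeric(strsplit(trimws(lines[i]), "[ ]+")[[1]][1]), numeric(1))
    expect_equal(dims, dim(g6@counts))
    # voxel sum in the file equals counts/n_frames
    nhead <- 6 + nAtoms(s)
    vox <- as.numeric(unlist(strsplit(trimws(lines[-seq_len(nhead)]), "[ ]+")))
    expect_equal(sum(vox) * 3, 3 * nAtoms(s), tolerance = 1e-6)
    # spacing recorded in Bohr
    expect_equal(as.numeric(strsplit(trimws(lines[4]), "[ ]+")[[1]][2]),
                 1.5 * 1.8897259886, tolerance = 1e-5)
})

test_that("metric-vs-Rg landscape bottoms out at the generating frame", {
    sys <- makeTwoDomainSystem()
    f <- assignAmplitudes(sys$structure, contrastModel("xray"))
    res <- runMonomerMC(sys$structure, sys$region,
                        mcConfig(nAcceptTarget = 400, seed = 31))
    q <- seq(0.02, 0.25, length.out = 15)
    k0 <- 200L
    truth <- getFrame(res@ensemble, k0)
    expt <- makeNoisyCurve(intensityDebye(truth, f, q), 0.02, seed = 5)
    fits <- fitEnsemble(res, expt, i0Expt = sum(f)^2, amplitudes = f)
    best <- fits[which.min(fits$chi2_reduced), ]
    rg0 <- res@perFrameRg[k0]
    expect_lt(abs(best$rg - rg0) / rg0, 0.05)
    expect_lt(best$chi2_reduced, 2)
})
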