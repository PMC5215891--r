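circleShape <- function(N = 200, r = 1, phase = 0, center = c(0, 0)) {
    th <- phase + 2 * pi * (seq_len(N) - 1) / N
    new("Shape", points = rbind(center[1] + r * cos(th),
                                center[2] + r * sin(th)))
}

ellipseShape <- function(N = 200, a = 2, b = 1) {
    th <- 2 * pi * (seq_len(N) - 1) / N
    new("Shape", points = rbind(a * cos(th), b * sin(th)))
}

test_that("one period is extracted from a multi-cycle trajectory", {
    pt <- analyticTrajectory("circle", T = 11, r = 2, f = 0.5)  # 3 cycles post-transient
    per <- extractPeriod(pt, transient = 5)
    expect_equal(attr(per, "period"), 2, tolerance = 1e-3)
    expect_equal(attr(per, "period"), 1 / cycleFrequency(pt),
                 tolerance = 1e-3)
    ## ends nearly closed: gap comparable to one sample step along the curve
    gap <- sqrt(sum((per[, 1] - per[, ncol(per)])^2))
    step <- sqrt(sum((per[, 2] - per[, 1])^2))
    expect_lt(gap, 3 * step)
    ## about a third of the post-transient samples
    expect_equal(ncol(per), sum(pt@times >= 5) / 3, tolerance = 0.05)
    expect_error(extractPeriod(analyticTrajectory("fixed_point", T = 11)))
})

test_that("closed-curve resampling stays on the curve and preserves arclength", {
    th <- 2 * pi * (0:99) / 100
    pts <- rbind(3 * cos(th), 3 * sin(th))
    shp <- resampleClosedCurve(pts, 257)
    rr <- sqrt(colSums(shapePoints(shp)^2))
    expect_lt(max(abs(rr - 3)) / 3, 1e-6)

    ## arclength of a smooth ellipse preserved within 0.1 % at N = 200
    pe <- rbind(2 * cos(th), 1 * sin(th))
    se <- shapePoints(resampleClosedCurve(pe, 200))
    arc <- function(m) { d <- cbind(m, m[, 1]) ; sum(sqrt(rowSums(diff(t(d))^2))) }
    expect_equal(arc(se), arc(pe), tolerance = 1e-3)
    expect_error(resampleClosedCurve(matrix(1, 2, 10), 50), "degenerate")
})

test_that("Procrustes of a shape with itself is the identity fit", {
    shp <- ellipseShape()
    fit <- procrustesFit(shp, shp)
    expect_equal(fit$pd, 0, tolerance = 1e-14)
    expect_equal(fit$b, 1, tolerance = 1e-12)
    expect_equal(fit$R, diag(2), tolerance = 1e-10)
    expect_equal(fit$rss, 0, tolerance = 1e-10)
})

test_that("similarity transforms are fully discounted", {
    set.seed(5)
    for (i in 1:20) {
        A <- new("Shape", points = matrix(rnorm(20), 2, 10))
        th <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        b <- runif(1, 0.2, 3)
        cc <- rnorm(2, sd = 5)
        B <- new("Shape", points = b * R %*% shapePoints(A) + cc)
        fit <- procrustesFit(A, B)
        expect_lt(fit$pd, 1e-10)
        expect_equal(fit$b, b, tolerance = 1e-8)
        ## det +1: reflections are never used
        expect_equal(det(fit$R), 1, tolerance = 1e-10)
    }
})

test_that("the closed form matches a brute-force rotation-grid oracle", {
    set.seed(6)
    for (i in 1:10) {
        A <- matrix(rnorm(20), 2, 10)
        B <- matrix(rnorm(20), 2, 10)
        fit <- procrustesFit(new("Shape", points = A), new("Shape", points = B))
        expect_equal(fit$pd, procrustesOracle(A, B), tolerance = 1e-4)
    }
})

test_that("the standardized dissimilarity agrees with vegan's symmetric fit", {
    skip_if_not_installed("vegan")
    set.seed(7)
    A <- matrix(rnorm(24), 2, 12); B <- matrix(rnorm(24), 2, 12)
    ## vegan permits reflections; our fit excludes them, so compare the
    ## better of the direct and mirrored fits
    fit <- procrustesFit(new("Shape", points = A), new("Shape", points = B))
    Bm <- B; Bm[2, ] <- -Bm[2, ]
    fitM <- procrustesFit(new("Shape", points = A), new("Shape", points = Bm))
    vg <- vegan::procrustes(t(A), t(B), symmetric = TRUE)
    expect_equal(min(fit$pd, fitM$pd), vg$ss, tolerance = 1e-10)
})

test_that("circle-vs-ellipse dissimilarity matches its closed form", {
    ## uniform-angle samples: pd = 1 - (a+b)^2 / (2 (a^2+b^2))
    fit <- procrustesFit(circleShape(), ellipseShape(a = 2, b = 1))
    expect_equal(fit$pd, 1 - 9 / 10, tolerance = 1e-10)
    fit2 <- procrustesFit(circleShape(), ellipseShape(a = 3, b = 1))
    expect_equal(fit2$pd, 1 - 16 / 20, tolerance = 1e-10)
    ## more eccentric -> more dissimilar
    expect_gt(fit2$pd, fit$pd)
})

test_that("phase alignment removes index offsets and traversal direction", {
    A <- ellipseShape(N = 120)
    shifted <- shapePoints(A)[, c(31:120, 1:30)]      # quarter-phase offset
    fit <- phaseAlignedPD(A, new("Shape", points = shifted))
    expect_lt(fit$pd, 1e-12)
    ## the ellipse's two-fold symmetry makes 30 and 90 equivalent minimisers
    expect_true(fit$phaseShift %in% c(30, 90))

    reversed <- shapePoints(A)[, c(1, 120:2)]
    fitR <- phaseAlignedPD(A, new("Shape", points = reversed))
    expect_lt(fitR$pd, 1e-12)
    expect_true(fitR$reversed)

    ## aligned pd never exceeds the unaligned pd; equals exhaustive search
    set.seed(8)
    B <- new("Shape", points = matrix(rnorm(40), 2, 20))
    A2 <- new("Shape", points = matrix(rnorm(40), 2, 20))
    al <- phaseAlignedPD(A2, B)
    expect_lte(al$pd, procrustesFit(A2, B)$pd + 1e-15)
    ref <- min(sapply(0:19, function(k) {
        idx <- ((0:19 + k) %% 20) + 1
        procrustesFit(A2, new("Shape", points = shapePoints(B)[, idx]))$pd
    }))
    expect_lte(al$pd, ref + 1e-15)
})

test_that("scale-only and shape-morphing families behave as expected", {
    ## uniformly shrunken cycles: pd ~ 0, fitted scale tracks the shrinkage
    A <- circleShape(r = 2)
    for (f in c(0.8, 0.5, 0.2)) {
        fit <- phaseAlignedPD(A, circleShape(r = 2 * f))
        expect_lt(fit$pd, 1e-10)
        expect_equal(fit$b, f, tolerance = 1e-8)
    }
    ## morphing circle -> ellipse: pd strictly increasing with distortion
    pds <- sapply(c(1, 1.5, 2, 3), function(a)
        phaseAlignedPD(A, ellipseShape(a = a, b = 1))$pd)
    expect_true(all(diff(pds) > 0))
})

test_that("curves normalise and average per the stated conventions", {
    crv <- new("PDCurve", mu = c(0, 1, 2, 3, 4), pd = c(0, 1, 2, 3, 4),
               scaling = c(1, 0.9, 0.8, 0.7, 0.6),
               translation = c(0, 0.1, 0.2, 0.3, 0.4),
               frequency = rep(0.5, 5), muStar = 4.2)
    avg <- normalizeAndAverage(list(crv), "pd", gridSize = 5)
    expect_equal(avg$grid, seq(0, 1, length.out = 5))
    expect_equal(avg$mean, seq(0, 1, length.out = 5), tolerance = 1e-9)
    expect_equal(avg$sd, rep(0, 5))

    dup <- normalizeAndAverage(list(crv, crv), "pd", gridSize = 5)
    expect_equal(dup$mean, avg$mean)
    expect_equal(dup$sd, rep(0, 5))

    ## scaling curves are not value-normalised
    sc <- normalizeAndAverage(list(crv), "scaling", gridSize = 5)
    expect_equal(sc$mean[1], 1, tolerance = 1e-9)
    expect_equal(sc$mean[5], 0.6, tolerance = 1e-9)

    ## two linear curves average to their hand-computed pointwise mean
    crv2 <- new("PDCurve", mu = c(0, 2, 4), pd = c(0, 4, 8),
                scaling = c(1, 1, 1), translation = c(0, 0, 0),
                frequency = rep(0.5, 3), muStar = 4.2)
    two <- normalizeAndAverage(list(crv, crv2), "pd", gridSize = 3)
    expect_equal(two$mean, c(0, 0.5, 1), tolerance = 1e-9)
    expect_error(normalizeAndAverage(list(), "pd"), "empty")
})

test_that("curve features are fixed-length and invariant to mu* rescaling", {
    crv <- new("PDCurve", mu = c(0, 1, 2, 3), pd = c(0, 0.2, 0.1, 0.4),
               scaling = rep(1, 4), translation = rep(0, 4),
               frequency = rep(0.5, 4), muStar = 3.1)
    f1 <- pdCurveFeatures(crv, gridSize = 12)
    expect_length(f1, 12)
    crvScaled <- new("PDCurve", mu = 2.5 * c(0, 1, 2, 3),
                     pd = c(0, 0.2, 0.1, 0.4), scaling = rep(1, 4),
                     translation = rep(0, 4), frequency = rep(0.5, 4),
                     muStar = 2.5 * 3.1)
    expect_equal(pdCurveFeatures(crvScaled, gridSize = 12), f1)
    flat <- new("PDCurve", mu = c(0, 1, 2), pd = c(0, 0, 0),
                scaling = rep(1, 3), translation = rep(0, 3),
                frequency = rep(0.5, 3), muStar = 2.5)
    expect_equal(pdCurveFeatures(flat, gridSize = 6), rep(0, 6))
})

test_that("the motif's deficit curve starts at zero and ends at collapse", {
    ctx <- motifContext()
    inj <- sampleInjury(syntheticSwellingDistribution(), ctx$cx, seed = 11)
    prof <- findMuStar(ctx$cx, ctx$params, inj, ctx$plane, ctx$Iext,
                       init = ctx$rest$state)
    crv <- pdCurve(ctx$cx, ctx$params, inj, prof, ctx$plane, ctx$shape,
                   ctx$Iext, init = ctx$rest$state)
    expect_equal(crv@mu[1], 0)
    expect_lt(crv@pd[1], 1e-3)
    expect_equal(abs(crv@scaling[1] - 1) < 0.01, TRUE)
    expect_lt(crv@translation[1], 0.05)
    expect_equal(max(crv@mu), max(prof@muSamples))
    expect_lte(max(crv@mu), muStar(prof))
    ok <- !is.na(crv@pd)
    expect_gt(sum(ok), 10)
    ## distortion grows toward collapse; the cycle shrinks
    expect_gt(max(crv@pd[ok]), 10 * max(crv@pd[1], 1e-6))
    expect_lt(min(crv@scaling[ok]), 0.2)
    .cache$motifCurve <- list(inj = inj, prof = prof, crv = crv)
})
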