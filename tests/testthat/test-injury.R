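test_that("histogram distributions normalise and validate", {
    d <- distributionFromHistogram(data.frame(v = c(1, 2), p = c(3, 1)))
    expect_equal(d$probabilities, c(0.75, 0.25))
    single <- distributionFromHistogram(data.frame(v = 2, p = 7))
    expect_equal(single$probabilities, 1)
    expect_error(distributionFromHistogram(data.frame(v = 1, p = -1)),
                 "nonnegative")
    expect_error(distributionFromHistogram(data.frame(v = 1, p = 0)),
                 "all-zero")
})

test_that("sampling matches the histogram mean (law of large numbers)", {
    d <- distributionFromHistogram(data.frame(v = c(0.5, 1, 2),
                                              p = c(0.2, 0.5, 0.3)))
    n <- 1e5
    set.seed(42)
    x <- sampleSwellings(d, n)
    mu <- sum(d$values * d$probabilities)
    se <- sqrt(sum(d$probabilities * (d$values - mu)^2) / n)
    expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("injury vectors are unit norm, protect the input pair, and are seeded", {
    cx <- oscillatorMotif()
    d <- syntheticSwellingDistribution()
    inj <- sampleInjury(d, cx, seed = 3)
    expect_equal(sqrt(sum(swellings(inj)^2)), 1, tolerance = 1e-12)
    expect_equal(unname(swellings(inj)[c("IN1", "IN2")]), c(0, 0))
    expect_identical(swellings(sampleInjury(d, cx, seed = 3)), swellings(inj))
    expect_false(identical(swellings(sampleInjury(d, cx, seed = 4)),
                           swellings(inj)))
})

test_that("normalisation follows the hand calculation through the weight hook", {
    ## degenerate distribution (all draws 1) with weights (3, 4) -> m = (0.6, 0.8)
    cx <- Connectome(matrix(0, 2, 2), matrix(c(0, 1, 1, 0), 2, 2),
                     rep("excitatory", 2), neuronNames = c("A", "B"))
    d1 <- distributionFromHistogram(data.frame(v = 1, p = 1))
    inj <- sampleInjury(d1, cx, protected = character(), seed = 1,
                        weight = c(A = 3, B = 4))
    expect_equal(unname(swellings(inj)), c(0.6, 0.8))
})

test_that("amplitude from a target mean swelling ratio satisfies its identity", {
    m <- c(A = 0.05, B = 0.05, C = 0.05)
    m <- m / sqrt(sum(m^2))
    inj <- new("InjuryVector", m = m, protected = character(),
               mu = NA_real_, seed = 1)
    expect_equal(muFromMeanSwelling(1, inj), 0)
    mu <- muFromMeanSwelling(1.5, inj)
    expect_equal(mean(1 + mu * swellings(inj)), 1.5)    # round trip

    inj2 <- new("InjuryVector", m = c(A = 0.6, B = 0.8),
                protected = character(), mu = NA_real_, seed = 1)
    ## <m> = 0.7 here; target 1.5 -> mu = 0.5 / 0.7
    expect_equal(muFromMeanSwelling(1.5, inj2), 0.5 / 0.7)
    expect_error(muFromMeanSwelling(0.9, inj2))
})

test_that("swelling factors are 1 at mu = 0 and scale linearly", {
    inj <- new("InjuryVector", m = c(A = 0.6, B = 0.8),
               protected = character(), mu = NA_real_, seed = 1)
    expect_equal(unname(injuryScale(inj, 0)), c(1, 1))
    m5 <- c(A = 0.5 / sqrt(1.25), B = 1 / sqrt(1.25))
    inj5 <- new("InjuryVector", m = m5, protected = character(),
                mu = NA_real_, seed = 1)
    expect_equal(unname(injuryScale(inj5, 2))[1], 1 + 2 * m5[["A"]])
    ## monotone: larger mu never increases effective coupling
    s1 <- 1 / injuryScale(inj5, 1); s2 <- 1 / injuryScale(inj5, 3)
    expect_true(all(s2 <= s1))
})

test_that("dividing coupling currents equals scaling C and Gc per neuron", {
    ## one Euler step computed through the injured update equals the step
    ## derived independently from area-scaled capacitance and leak
    p <- modelParams()
    Ns <- matrix(0, 3, 3); Ns[2, 1] <- 4; Ns[3, 2] <- 2; Ns[1, 3] <- 3
    Ng <- matrix(0, 3, 3); Ng[1, 2] <- Ng[2, 1] <- 2
    cx <- Connectome(Ng, Ns, c("excitatory", "inhibitory", "excitatory"))
    rest <- restingState(cx, p)
    st <- rest$state; st@V <- st@V + c(3, -2, 5)
    scale <- c(1.7, 1, 2.4)
    stepped <- eulerStep(st, buildConductances(cx, p@g), rest$params,
                         injuryScale = scale, polarity = polarity(cx))
    cur <- membraneCurrents(st, buildConductances(cx, p@g), rest$params,
                            polarity(cx))
    ## area-scaled form: C_i(1+mu m) dV = -Gc(1+mu m)(V-Ec) - (Igap+Isyn)
    vdotScaled <- (-p@Gc * scale * (st@V - p@Ecell) -
                   (cur$Igap + cur$Isyn)) / (p@C * scale)
    expect_equal(stepped@V, st@V + p@dt * vdotScaled)
})

test_that("injury ensembles round-trip through their CSV + JSON serialisation", {
    cx <- oscillatorMotif()
    d <- syntheticSwellingDistribution()
    injs <- lapply(1:3, function(k) sampleInjury(d, cx, seed = k))
    path <- file.path(withr::local_tempdir(), "ens.csv")
    writeInjuryEnsemble(injs, path, distributionId = "synthetic-lognormal")
    back <- readInjuryEnsemble(path)
    expect_length(back, 3)
    for (k in 1:3)
        expect_equal(swellings(back[[k]]), swellings(injs[[k]]),
                     tolerance = 1e-6)
    expect_equal(back[[2]]@protected, c("IN1", "IN2"))
})
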