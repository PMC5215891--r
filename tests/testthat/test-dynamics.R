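test_that("sigmoid activation has the right midpoint, limits and values", {
    expect_equal(sigmoidActivation(-20, 0.125, -20), 0.5)
    expect_equal(sigmoidActivation(1e6, 0.125, 0), 1)
    expect_equal(sigmoidActivation(-1e6, 0.125, 0), 0)
    ## 8 mV above threshold at beta = 0.125 -> 1/(1 + e^-1)
    expect_equal(sigmoidActivation(8, 0.125, 0), 1 / (1 + exp(-1)))
})

test_that("synaptic equilibrium solves ds/dt = 0 and Euler converges to it", {
    expect_equal(synapticEquilibrium(0), 0)
    expect_equal(synapticEquilibrium(1, 1, 5), 1 / 6)
    ## explicit Euler of the s-kinetics at clamped phi converges to s_eq
    phi <- 0.37; ar <- 1; ad <- 5; dt <- 1e-4
    s <- 0
    for (i in seq_len(1e5)) s <- s + dt * (ar * phi * (1 - s) - ad * s)
    expect_equal(s, synapticEquilibrium(phi, ar, ad), tolerance = 1e-6)
})

test_that("membrane currents match their definitions and a brute-force oracle", {
    p <- modelParams()
    ## all voltages equal -> zero gap current (ohmic symmetry)
    cx <- syntheticConnectome(4, density = 0.8, seed = 2)
    cond <- buildConductances(cx, p@g)
    st <- new("NetworkState", V = rep(-20, 4), s = rep(0.3, 4), t = 0)
    cur <- membraneCurrents(st, cond, p, polarity(cx))
    expect_equal(unname(cur$Igap), rep(0, 4))

    ## single excitatory synapse: Gs = 100 pS, s_j = 1, V_i = -35, E_j = 0
    Ns <- matrix(0, 2, 2); Ns[2, 1] <- 1
    c2 <- Connectome(matrix(0, 2, 2), Ns, rep("excitatory", 2))
    cd2 <- buildConductances(c2, 100)
    st2 <- new("NetworkState", V = c(0, -35), s = c(1, 0), t = 0)
    cur2 <- membraneCurrents(st2, cd2, p, polarity(c2))
    expect_equal(unname(cur2$Isyn[2]), 100 * (-35 - 0))

    ## random 6-neuron state vs double-loop oracle
    cx6 <- syntheticConnectome(6, density = 0.5, inhibitoryFraction = 0.5,
                               seed = 4)
    cond6 <- buildConductances(cx6, p@g)
    set.seed(11)
    st6 <- new("NetworkState", V = runif(6, -50, 10), s = runif(6), t = 0)
    cur6 <- membraneCurrents(st6, cond6, p, polarity(cx6))
    E <- ifelse(polarity(cx6) == "excitatory", p@Eexc, p@Einh)
    for (i in 1:6) {
        gap <- syn <- 0
        for (j in 1:6) {
            gap <- gap + cond6@Gg[i, j] * (st6@V[i] - st6@V[j])
            syn <- syn + cond6@Gs[i, j] * st6@s[j] * (st6@V[i] - E[j])
        }
        expect_equal(unname(cur6$Igap[i]), unname(gap))
        expect_equal(unname(cur6$Isyn[i]), unname(syn))
    }
})

test_that("Euler step holds equilibria and reaches closed-form fixed points", {
    p <- modelParams()
    ## unconnected neuron at the leak potential stays there
    c1 <- Connectome(matrix(0, 1, 1), matrix(0, 1, 1), "excitatory",
                     neuronNames = "A")
    rest <- restingState(c1, p)
    st <- rest$state
    cond <- buildConductances(c1, p@g)
    p1 <- rest$params
    for (i in 1:100) st <- eulerStep(st, cond, p1, polarity = polarity(c1))
    expect_equal(unname(st@V), p@Ecell, tolerance = 1e-10)

    ## constant input drives V to Ecell + I/Gc
    traj <- simulateNetwork(c1, p1, Iext = c(A = 500), T = 3,
                            init = rest$state)
    expect_equal(unname(traj@V[nrow(traj@V), 1]), p@Ecell + 500 / p@Gc,
                 tolerance = 1e-6)
})

test_that("single-neuron Euler matches the analytic exponential to O(dt)", {
    ## dV/dt = -(Gc/C)(V - Ecell) from V0: V(t) = Ecell + (V0-Ecell) e^(-t Gc/C)
    p <- modelParams()
    c1 <- Connectome(matrix(0, 1, 1), matrix(0, 1, 1), "excitatory",
                     neuronNames = "A")
    rest <- restingState(c1, p)
    V0 <- -20
    init <- new("NetworkState", V = c(A = V0), s = rest$state@s, t = 0)
    err <- sapply(c(1e-4, 5e-5), function(dt) {
        pp <- rest$params; pp@dt <- dt
        tr <- simulateNetwork(c1, pp, T = 1, init = init, stride = 1)
        exact <- p@Ecell + (V0 - p@Ecell) * exp(-tr@times * p@Gc / p@C)
        max(abs(tr@V[, 1] - exact))
    })
    expect_lt(err[1], 0.01)                      # small at dt = 1e-4
    expect_gt(err[1] / err[2], 1.6)              # ~halves with dt: first order
})

test_that("an overwhelmingly injured neuron decays to Ecell at rate Gc/C", {
    p <- modelParams()
    ## two coupled neurons; neuron B massively swollen -> isolated
    Ns <- matrix(0, 2, 2); Ns[2, 1] <- 5; Ns[1, 2] <- 5
    Ng <- matrix(0, 2, 2); Ng[1, 2] <- Ng[2, 1] <- 3
    cx <- Connectome(Ng, Ns, rep("excitatory", 2), neuronNames = c("A", "B"))
    rest <- restingState(cx, p)
    m <- c(A = 0, B = 1)
    inj <- new("InjuryVector", m = m, protected = "A", mu = 1e8, seed = 1)
    init <- rest$state
    init@V["B"] <- -20
    tr <- simulateNetwork(cx, rest$params, injury = inj, T = 0.5,
                          init = init, stride = 10)
    dV <- tr@V[, "B"] - p@Ecell
    keep <- dV > 1e-6
    fit <- stats::lm(log(dV[keep]) ~ tr@times[keep])
    expect_equal(unname(-coef(fit)[2]), p@Gc / p@C, tolerance = 0.01)
})

test_that("a zero-amplitude injury reproduces the healthy update bitwise", {
    ctx <- motifContext()
    inj0 <- setMu(sampleInjury(syntheticSwellingDistribution(), ctx$cx,
                               seed = 5), 0)
    a <- simulateNetwork(ctx$cx, ctx$params, injury = NULL, Iext = ctx$Iext,
                         T = 2, init = ctx$rest$state)
    b <- simulateNetwork(ctx$cx, ctx$params, injury = inj0, Iext = ctx$Iext,
                         T = 2, init = ctx$rest$state)
    expect_identical(a@V, b@V)
    expect_identical(a@finalState@s, b@finalState@s)
})

test_that("synaptic activity stays in [0, 1] along a stiff trajectory", {
    ctx <- motifContext()
    tr <- simulateNetwork(ctx$cx, ctx$params, Iext = ctx$Iext * 5, T = 5,
                          record = neuronNames(ctx$cx))
    expect_true(all(is.finite(tr@V)))
    s <- tr@finalState@s
    expect_true(all(s >= 0 & s <= 1))
})

test_that("with all potentials equal and no input, V = Ecell is invariant", {
    p <- modelParams(Eexc = -35, Einh = -35)
    cx <- syntheticConnectome(5, density = 0.6, inhibitoryFraction = 0.4,
                              seed = 6)
    rest <- restingState(cx, p)
    expect_equal(unname(rest$Vth), rep(-35, 5), tolerance = 1e-9)
    tr <- simulateNetwork(cx, rest$params, T = 1, init = rest$state)
    expect_equal(max(abs(tr@V + 35)), 0, tolerance = 1e-9)
})

test_that("resting state is a self-consistent fixed point", {
    p <- modelParams()
    ## unconnected network: Vth = Ecell everywhere
    cx0 <- Connectome(matrix(0, 3, 3), matrix(0, 3, 3), rep("excitatory", 3))
    expect_equal(unname(restingState(cx0, p)$Vth), rep(p@Ecell, 3))

    ## connected network: residual of the voltage equation is ~0 at rest
    cx <- syntheticConnectome(8, density = 0.4, inhibitoryFraction = 0.3,
                              seed = 12)
    rest <- restingState(cx, p)
    cond <- buildConductances(cx, p@g)
    cur <- membraneCurrents(rest$state, cond, rest$params, polarity(cx))
    vdot <- (-p@Gc * (rest$state@V - p@Ecell) - cur$Igap - cur$Isyn) / p@C
    expect_lt(max(abs(vdot)), 1e-6)

    ## a simulated run from rest stays at rest
    tr <- simulateNetwork(cx, rest$params, T = 2, init = rest$state)
    expect_lt(max(abs(sweep(tr@V, 2, rest$state@V[colnames(tr@V)]))), 1e-6)

    ## adding an excitatory synapse pulls the postsynaptic equilibrium up
    Ns <- matrix(0, 2, 2)
    base <- Connectome(matrix(0, 2, 2), Ns, rep("excitatory", 2))
    Ns2 <- Ns; Ns2[2, 1] <- 10
    more <- Connectome(matrix(0, 2, 2), Ns2, rep("excitatory", 2))
    expect_gt(restingState(more, p)$Vth[2], restingState(base, p)$Vth[2])
})
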