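#' @include AllClasses.R connectome.R
NULL

#' Model parameter constructor
#'
#' Returns a \linkS4class{ModelParams} with the standard defaults
#' (C = 1 pF, Gc = 10 pS, Ecell = -35 mV, g = 100 pS, Eexc = 0 mV,
#' Einh = -45 mV, beta = 0.125 / mV, ar = 1 / s, ad = 5 / s, dt = 1e-4 s);
#' any can be overridden by name.
#'
#' @param C membrane capacitance (pF).
#' @param Gc membrane leakage conductance (pS).
#' @param Ecell leakage potential (mV).
#' @param g per-connection conductivity (pS).
#' @param Eexc,Einh excitatory/inhibitory reversal potentials (mV).
#' @param beta sigmoid width (1/mV).
#' @param Vth per-neuron thresholds (mV); usually left unset and filled by
#'   \code{\link{restingState}}.
#' @param ar,ad synaptic rise/decay constants (1/s).
#' @param dt integration timestep (s).
#' @return a \linkS4class{ModelParams}.
#' @export
modelParams <- function(C = 1, Gc = 10, Ecell = -35, g = 100, Eexc = 0,
                        Einh = -45, beta = 0.125, Vth = numeric(0),
                        ar = 1, ad = 5, dt = 1e-4) {
    ## slots are assigned (not passed to new()) so the short slot name "C"
    ## cannot partially match new()'s Class argument
    p <- new("ModelParams")
    p@C <- C; p@Gc <- Gc; p@Ecell <- Ecell; p@g <- g
    p@Eexc <- Eexc; p@Einh <- Einh; p@beta <- beta; p@Vth <- Vth
    p@ar <- ar; p@ad <- ad; p@dt <- dt
    validObject(p)
    p
}

.erev <- function(params, polarity)
    ifelse(polarity == "excitatory", params@Eexc, params@Einh)

#' Sigmoidal synaptic activation
#'
#' \code{phi(v) = 1 / (1 + exp(-beta (v - vth)))}, the graded activation
#' of a synapse as a function of presynaptic voltage. Overflow-guarded.
#'
#' @param v membrane voltage (mV); vectorised.
#' @param beta sigmoid width (1/mV).
#' @param vth activation threshold (mV).
#' @return activation fraction in (0, 1).
#' @export
sigmoidActivation <- function(v, beta = 0.125, vth = 0) {
    x <- pmin(pmax(-beta * (v - vth), -50), 50)
    1 / (1 + exp(x))
}

#' Equilibrium synaptic activity at fixed activation
#'
#' Setting the synaptic kinetics \code{ds/dt = ar phi (1 - s) - ad s} to
#' zero gives \code{s_eq = ar phi / (ar phi + ad)}.
#'
#' @param phi activation fraction in [0, 1].
#' @param ar,ad rise and decay constants (1/s).
#' @return equilibrium activity in [0, 1).
#' @export
synapticEquilibrium <- function(phi, ar = 1, ad = 5) {
    stopifnot(all(phi >= 0 & phi <= 1))
    ar * phi / (ar * phi + ad)
}

#' Gap-junction and synaptic currents
#'
#' \code{Igap_i = sum_j Gg_ij (V_i - V_j)} (ohmic gap junctions) and
#' \code{Isyn_i = sum_j Gs_ij s_j (V_i - E_j)} with the reversal potential
#' \code{E_j} of the presynaptic (sender) neuron chosen by its polarity.
#' Currents are in pS * mV (arbitrary units).
#'
#' @param state a \linkS4class{NetworkState}.
#' @param cond a \linkS4class{ConductanceSet}.
#' @param params a \linkS4class{ModelParams}.
#' @param polarity per-neuron polarity labels.
#' @return list with per-neuron vectors \code{Igap} and \code{Isyn}.
#' @export
membraneCurrents <- function(state, cond, params, polarity) {
    V <- state@V; s <- state@s
    stopifnot(length(V) == nrow(cond@Gg), length(polarity) == length(V))
    E <- .erev(params, polarity)
    Igap <- V * rowSums(cond@Gg) - drop(cond@Gg %*% V)
    Isyn <- V * drop(cond@Gs %*% s) - drop(cond@Gs %*% (s * E))
    list(Igap = Igap, Isyn = Isyn)
}

#' One explicit Euler step of the (possibly injured) network equations
#'
#' Advances voltage by
#' \code{V <- V + (dt/C) (-Gc (V - Ecell) - (Igap + Isyn)/scale + Iext)}
#' and synaptic activity by the explicit Euler update of its first-order
#' kinetics, clipping \code{s} to [0, 1]. With \code{injuryScale = 1}
#' everywhere this is exactly the healthy update. Reference (R-level)
#' implementation used by tests; production runs use the compiled loop in
#' \code{\link{simulateNetwork}}.
#'
#' @param state a \linkS4class{NetworkState}.
#' @param cond a \linkS4class{ConductanceSet}.
#' @param params a \linkS4class{ModelParams} with \code{Vth} set.
#' @param injuryScale per-neuron swelling factor \code{1 + mu m_i}
#'   (>= 1); scalar 1 recycles.
#' @param Iext per-neuron external current (pS * mV); scalar 0 recycles.
#' @param polarity per-neuron polarity labels.
#' @return the advanced \linkS4class{NetworkState}.
#' @export
eulerStep <- function(state, cond, params, injuryScale = 1, Iext = 0,
                      polarity) {
    n <- length(state@V)
    if (!all(is.finite(state@V)))
        stop("non-finite voltage at neuron ",
             names(state@V)[which(!is.finite(state@V))[1]])
    cur <- membraneCurrents(state, cond, params, polarity)
    scale <- rep_len(injuryScale, n)
    Iext <- rep_len(Iext, n)
    vdot <- (-params@Gc * (state@V - params@Ecell) -
             (cur$Igap + cur$Isyn) / scale + Iext) / params@C
    phi <- sigmoidActivation(state@V, params@beta, params@Vth)
    sdot <- params@ar * phi * (1 - state@s) - params@ad * state@s
    V <- state@V + params@dt * vdot
    s <- pmin(pmax(state@s + params@dt * sdot, 0), 1)
    new("NetworkState", V = V, s = s, t = state@t + params@dt)
}

#' Zero-input resting state and self-consistent thresholds
#'
#' Solves the zero-input fixed point of the network equations by
#' alternating the synaptic-equilibrium map and the linear voltage
#' balance, under the self-consistency condition that each neuron's
#' activation threshold equals its own equilibrium voltage (so
#' \code{phi = 1/2} at rest and rest is exactly a fixed point). For an
#' unconnected network this gives \code{Vth = Ecell}.
#'
#' @param c a \linkS4class{Connectome}.
#' @param params a \linkS4class{ModelParams} (\code{Vth} ignored).
#' @param tol convergence tolerance on the voltage update (mV).
#' @param maxit maximum alternating iterations.
#' @return list with the resting \code{state} (\linkS4class{NetworkState}),
#'   the per-neuron \code{Vth}, and \code{params} with \code{Vth} filled in.
#' @export
restingState <- function(c, params = modelParams(), tol = 1e-10, maxit = 100) {
    cond <- buildConductances(c, params@g)
    n <- nNeurons(c)
    E <- .erev(params, c@polarity)
    V <- rep(params@Ecell, n)
    converged <- FALSE
    for (it in seq_len(maxit)) {
        ## with Vth tied to the equilibrium voltage, phi = 1/2 at rest
        sEq <- rep(synapticEquilibrium(0.5, params@ar, params@ad), n)
        A <- diag(params@Gc + rowSums(cond@Gg) + drop(cond@Gs %*% sEq), n) -
            cond@Gg
        b <- params@Gc * params@Ecell + drop(cond@Gs %*% (sEq * E))
        Vnew <- solve(A, b)
        done <- max(abs(Vnew - V)) < tol
        V <- Vnew
        if (done) { converged <- TRUE; break }
    }
    if (!converged)
        stop("resting state did not converge after ", maxit,
             " iterations; residual ", max(abs(solve(A, b) - V)))
    names(V) <- c@neuronNames
    sEq <- rep(synapticEquilibrium(0.5, params@ar, params@ad), n)
    names(sEq) <- c@neuronNames
    params@Vth <- unname(V)
    list(state = new("NetworkState", V = V, s = sEq, t = 0),
         Vth = V, params = params)
}

#' Integrate the network by forward Euler
#'
#' Runs the compiled explicit-Euler loop for duration \code{T} at the
#' timestep in \code{params}, recording decimated voltage snapshots of the
#' requested neuron subset. Deterministic given inputs and initial state.
#' If \code{injury} is supplied, the gap and synaptic currents of neuron
#' \code{i} are divided by \code{1 + mu m_i}; \code{injury = NULL} (or
#' \code{mu = 0}) is the healthy network.
#'
#' @param c a \linkS4class{Connectome}.
#' @param params a \linkS4class{ModelParams}; if \code{Vth} is unset it is
#'   computed via \code{\link{restingState}}.
#' @param injury an \linkS4class{InjuryVector} with \code{mu} set, or
#'   \code{NULL}.
#' @param Iext named numeric of constant external currents (pS * mV) for
#'   stimulated neurons, e.g. \code{c(PLML = 2e4, PLMR = 2e4)}; unnamed
#'   scalar recycles to all neurons.
#' @param T duration (s).
#' @param record neuron names to record; default the
#'   \code{"forward_motor"} group if present, else all neurons.
#' @param stride recording decimation factor (default 100, i.e. 1 ms
#'   sampling at the default dt).
#' @param init optional initial \linkS4class{NetworkState}; default the
#'   resting state.
#' @param vbound divergence guard: error if any |V| exceeds this (mV).
#' @return a \linkS4class{Trajectory} (with the full final state for
#'   continuation).
#' @export
simulateNetwork <- function(c, params = modelParams(), injury = NULL,
                            Iext = 0, T, record = NULL, stride = 100,
                            init = NULL, vbound = 1e4) {
    stopifnot(T > 0)
    n <- nNeurons(c)
    if (length(params@Vth) == 0 || is.null(init)) {
        rest <- restingState(c, params)
        if (length(params@Vth) == 0) params <- rest$params
        if (is.null(init)) init <- rest$state
    }
    stopifnot(length(params@Vth) == n)
    cond <- buildConductances(c, params@g)
    E <- .erev(params, c@polarity)
    iv <- rep(0, n); names(iv) <- c@neuronNames
    if (is.null(names(Iext))) iv[] <- Iext
    else {
        stopifnot(all(names(Iext) %in% c@neuronNames))
        iv[names(Iext)] <- Iext
    }
    scale <- rep(1, n)
    if (!is.null(injury)) {
        stopifnot(is(injury, "InjuryVector"), length(injury@mu) == 1)
        scale <- injuryScale(injury)[c@neuronNames]
    }
    if (is.null(record)) {
        record <- if (!is.null(c@groups[["forward_motor"]]))
            c@groups[["forward_motor"]] else c@neuronNames
    }
    stopifnot(all(record %in% c@neuronNames))
    recIdx <- match(record, c@neuronNames) - 1L
    nsteps <- as.integer(round(T / params@dt))
    out <- sim_euler_cpp(unname(init@V[c@neuronNames]),
        unname(init@s[c@neuronNames]), cond@Gg, cond@Gs, E,
        params@Vth, params@C, params@Gc, params@Ecell, params@beta,
        params@ar, params@ad, scale, unname(iv), params@dt, nsteps,
        as.integer(stride), recIdx, vbound, init@t)
    Vs <- out$V_samples
    colnames(Vs) <- record
    Vf <- drop(out$V_final); sf <- drop(out$s_final)
    names(Vf) <- names(sf) <- c@neuronNames
    new("Trajectory", times = drop(out$times), V = Vs, stride = stride,
        dt = params@dt,
        finalState = new("NetworkState", V = Vf, s = sf, t = out$t_final))
}

#' Write a trajectory as columnar CSV
#'
#' Columns: \code{time} plus one column per recorded neuron.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path) {
    df <- data.frame(time = traj@times, traj@V, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
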