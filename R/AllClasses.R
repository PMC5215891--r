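#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib wormFAS, .registration = TRUE
NULL

#' Connectome: neuron names, gap-junction and synapse count matrices
#'
#' Container for a wiring diagram over named neurons: a symmetric
#' gap-junction count matrix \code{Ng}, a directed chemical-synapse count
#' matrix \code{Ns}, a per-neuron excitatory/inhibitory polarity, optional
#' per-neuron class labels (e.g. motorneuron classes DB, VB, DD, VD), and
#' named neuron groups (e.g. \code{"input"}, \code{"forward_motor"}).
#'
#' Orientation convention: \code{Ns[i, j]} counts synapses from presynaptic
#' neuron \code{j} onto postsynaptic neuron \code{i}, so that the synaptic
#' current on neuron \code{i} sums over columns \code{j} with the sender's
#' reversal potential.
#'
#' @slot neuronNames character vector of neuron identifiers (ordered).
#' @slot Ng symmetric nonnegative integer matrix of gap-junction counts.
#' @slot Ns nonnegative integer matrix of synapse counts (post x pre).
#' @slot polarity named character vector, values \code{"excitatory"} or
#'   \code{"inhibitory"}, one per neuron; sets the sender reversal potential.
#' @slot classes named character vector of neuron class labels (may be
#'   \code{NA} for unclassified neurons).
#' @slot groups named list of character vectors, each a subset of
#'   \code{neuronNames}.
#' @export
setClass("Connectome",
    representation(
        neuronNames = "character",
        Ng = "matrix",
        Ns = "matrix",
        polarity = "character",
        classes = "character",
        groups = "list"
    )
)

setValidity("Connectome", function(object) {
    n <- length(object@neuronNames)
    msg <- character()
    if (anyDuplicated(object@neuronNames))
        msg <- c(msg, "duplicated neuron names")
    for (nm in c("Ng", "Ns")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(n, n)))
            msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
        else {
            if (any(m < 0)) msg <- c(msg, sprintf("%s has negative counts", nm))
            if (any(diag(m) != 0)) msg <- c(msg, sprintf("%s has nonzero diagonal", nm))
        }
    }
    if (all(dim(object@Ng) == c(n, n)) && !isTRUE(all.equal(object@Ng, t(object@Ng))))
        msg <- c(msg, "Ng must be symmetric")
    if (length(object@polarity) != n)
        msg <- c(msg, "polarity must be defined for every neuron")
    else if (!all(object@polarity %in% c("excitatory", "inhibitory")))
        msg <- c(msg, "polarity values must be 'excitatory' or 'inhibitory'")
    if (length(object@classes) != n)
        msg <- c(msg, "classes must have one entry per neuron")
    bad <- unlist(object@groups)[!unlist(object@groups) %in% object@neuronNames]
    if (length(bad))
        msg <- c(msg, paste("unknown neuron name in groups:", paste(unique(bad), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Gap and synaptic conductance matrices derived from a Connectome
#'
#' @slot Gg symmetric gap conductivity matrix (pS), \code{g * Ng}.
#' @slot Gs synaptic maximum-conductivity matrix (pS), \code{g * Ns}.
#' @slot g the per-connection conductivity used (pS).
#' @export
setClass("ConductanceSet",
    representation(Gg = "matrix", Gs = "matrix", g = "numeric"))

setValidity("ConductanceSet", function(object) {
    if (!isTRUE(all.equal(object@Gg, t(object@Gg)))) "Gg must be symmetric" else TRUE
})

#' Membrane/synapse model parameters
#'
#' Defaults are the standard order-of-magnitude assignments for the
#' single-compartment C. elegans network model: C = 1 pF, Gc = 10 pS,
#' Ecell = -35 mV, g = 100 pS, Eexc = 0 mV, Einh = -45 mV,
#' beta = 0.125 / mV, ar = 1 / s, ad = 5 / s, dt = 1e-4 s.
#' \code{Vth} is per-neuron and typically computed by
#' \code{\link{restingState}} so that the zero-input equilibrium is
#' self-consistent; it may be left empty until then.
#'
#' @slot C membrane capacitance (pF).
#' @slot Gc membrane leakage conductance (pS).
#' @slot Ecell leakage potential (mV).
#' @slot g per-connection conductivity (pS).
#' @slot Eexc,Einh synaptic reversal potentials (mV) for excitatory and
#'   inhibitory senders.
#' @slot beta sigmoid width (1/mV).
#' @slot Vth per-neuron activation threshold (mV); length 0 until set.
#' @slot ar,ad synaptic rise and decay constants (1/s).
#' @slot dt integration timestep (s).
#' @export
setClass("ModelParams",
    representation(C = "numeric", Gc = "numeric", Ecell = "numeric",
        g = "numeric", Eexc = "numeric", Einh = "numeric",
        beta = "numeric", Vth = "numeric", ar = "numeric", ad = "numeric",
        dt = "numeric"),
    prototype(C = 1, Gc = 10, Ecell = -35, g = 100, Eexc = 0, Einh = -45,
        beta = 0.125, Vth = numeric(0), ar = 1, ad = 5, dt = 1e-4))

setValidity("ModelParams", function(object) {
    pos <- c(C = object@C, Gc = object@Gc, g = object@g, beta = object@beta,
             ar = object@ar, ad = object@ad, dt = object@dt)
    if (any(pos <= 0))
        paste("parameters must be positive:",
              paste(names(pos)[pos <= 0], collapse = ", "))
    else TRUE
})

#' Instantaneous network state
#'
#' @slot V named per-neuron membrane voltage (mV).
#' @slot s named per-neuron synaptic activity in [0, 1].
#' @slot t simulation time (s).
#' @export
setClass("NetworkState",
    representation(V = "numeric", s = "numeric", t = "numeric"))

setValidity("NetworkState", function(object) {
    msg <- character()
    if (length(object@V) != length(object@s))
        msg <- c(msg, "V and s must have equal length")
    if (any(!is.finite(object@V)) || any(!is.finite(object@s)))
        msg <- c(msg, "state must be finite")
    if (length(object@s) && (min(object@s) < 0 || max(object@s) > 1))
        msg <- c(msg, "s must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Recorded voltage trajectory
#'
#' @slot times sampled instants (s), uniformly spaced at \code{dt * stride}.
#' @slot V matrix of voltage snapshots, rows = times, columns = recorded
#'   neurons (named).
#' @slot stride recording decimation factor relative to the integration step.
#' @slot dt integration timestep used (s).
#' @slot finalState the full \code{NetworkState} at the end of the run,
#'   enabling continuation.
#' @export
setClass("Trajectory",
    representation(times = "numeric", V = "matrix", stride = "numeric",
        dt = "numeric", finalState = "NetworkState"))

setValidity("Trajectory", function(object) {
    msg <- character()
    if (nrow(object@V) != length(object@times))
        msg <- c(msg, "V must have one row per time")
    if (length(object@times) > 1) {
        d <- diff(object@times)
        if (any(d <= 0)) msg <- c(msg, "times must be strictly increasing")
        else if (max(abs(d - d[1])) > 1e-9 * max(d))
            msg <- c(msg, "times must be uniformly spaced")
    }
    if (length(msg)) msg else TRUE
})

#' Per-neuron focal-swelling injury vector
#'
#' Swelling magnitudes \code{m} are L2-normalised (\code{||m|| = 1}) and
#' forced to zero on protected neurons (by default the stimulated PLM
#' pair, which is left uninjured). The global amplitude \code{mu} scales
#' the whole vector; \code{mu = 0} is the healthy network.
#'
#' @slot m named nonnegative per-neuron swelling, unit L2 norm.
#' @slot protected character vector of protected neuron names (m forced 0).
#' @slot mu global injury amplitude (>= 0).
#' @slot seed integer RNG seed used to draw the vector (NA if not drawn).
#' @export
setClass("InjuryVector",
    representation(m = "numeric", protected = "character", mu = "numeric",
        seed = "numeric"))

setValidity("InjuryVector", function(object) {
    msg <- character()
    if (any(object@m < 0)) msg <- c(msg, "swellings must be nonnegative")
    if (abs(sqrt(sum(object@m^2)) - 1) > 1e-8)
        msg <- c(msg, "m must have unit L2 norm")
    if (length(object@protected) &&
        any(object@m[object@protected] != 0, na.rm = TRUE))
        msg <- c(msg, "protected neurons must have m = 0")
    if (length(object@mu) && !is.na(object@mu) && object@mu < 0)
        msg <- c(msg, "mu must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Two-mode response plane from motorneuron voltage snapshots
#'
#' Holds the first two left singular vectors of the (neurons x time)
#' snapshot matrix, the full singular spectrum, and the recorded neuron
#' subset in order.
#'
#' @slot modes matrix (neurons x 2) of orthonormal modes.
#' @slot singularValues full nonincreasing singular spectrum.
#' @slot subset neuron names, in the row order of \code{modes}.
#' @export
setClass("NeuralPlane",
    representation(modes = "matrix", singularValues = "numeric",
        subset = "character"))

setValidity("NeuralPlane", function(object) {
    msg <- character()
    if (ncol(object@modes) != 2) msg <- c(msg, "modes must have 2 columns")
    else {
        if (abs(sum(object@modes[, 1]^2) - 1) > 1e-8 ||
            abs(sum(object@modes[, 2]^2) - 1) > 1e-8)
            msg <- c(msg, "modes must be unit norm")
        if (abs(sum(object@modes[, 1] * object@modes[, 2])) > 1e-8)
            msg <- c(msg, "modes must be orthogonal")
    }
    if (is.unsorted(rev(object@singularValues)))
        msg <- c(msg, "singular values must be nonincreasing")
    if (nrow(object@modes) != length(object@subset))
        msg <- c(msg, "one mode row per subset neuron")
    if (length(msg)) msg else TRUE
})

#' Trajectory projected onto the two-mode plane
#'
#' @slot times sampled instants (s).
#' @slot xy matrix (times x 2) of projections onto mode 1 and mode 2.
#' @export
setClass("PlaneTrajectory",
    representation(times = "numeric", xy = "matrix"))

setValidity("PlaneTrajectory", function(object) {
    if (nrow(object@xy) != length(object@times)) "xy must have one row per time"
    else if (ncol(object@xy) != 2) "xy must have 2 columns"
    else TRUE
})

#' One resampled closed-cycle period as a 2 x N shape matrix
#'
#' @slot points 2 x N coordinate matrix of one limit-cycle period,
#'   uniformly resampled in phase (the curve is closed by construction;
#'   the first point is not duplicated at the end).
#' @export
setClass("Shape", representation(points = "matrix"))

setValidity("Shape", function(object) {
    if (nrow(object@points) != 2) "points must be 2 x N" else TRUE
})

#' Injury amplitude profile: collapse amplitude and sampled attractors
#'
#' @slot muStar critical amplitude at which the limit cycle collapses to
#'   a stable fixed point.
#' @slot muSamples ordered amplitudes (5 in (0, 0.9 muStar), 10 in
#'   (0.9 muStar, muStar)).
#' @slot results list of per-sample attractor classifications (as returned
#'   by \code{\link{classifyAttractor}}).
#' @slot endpoint 2-vector, the plane location of the collapsed fixed point.
#' @slot bracket numeric length-2, the final periodic/fixed bisection bracket.
#' @export
setClass("MuProfile",
    representation(muStar = "numeric", muSamples = "numeric",
        results = "list", endpoint = "numeric", bracket = "numeric"))

#' Procrustes deficit curve for one injury
#'
#' @slot mu sampled injury amplitudes (increasing; first entry 0).
#' @slot pd phase-aligned Procrustes distance to the healthy cycle.
#' @slot scaling optimal scale factor applied to the healthy cycle.
#' @slot translation displacement of the injured cycle centroid from the
#'   healthy cycle centroid.
#' @slot frequency cycle frequency (Hz) at each sample (NA where fixed).
#' @slot muStar collapse amplitude terminating the curve.
#' @export
setClass("PDCurve",
    representation(mu = "numeric", pd = "numeric", scaling = "numeric",
        translation = "numeric", frequency = "numeric", muStar = "numeric"))

setValidity("PDCurve", function(object) {
    lens <- c(length(object@pd), length(object@scaling),
              length(object@translation), length(object@frequency))
    if (any(lens != length(object@mu))) "curve components must have equal length"
    else if (is.unsorted(object@mu, strictly = TRUE)) "mu must be strictly increasing"
    else TRUE
})

#' Paralysis endpoints split into upper/lower outcome classes
#'
#' @slot endpoints K x 2 plane coordinates of collapse fixed points.
#' @slot principalAxis unit 2-vector, leading principal mode of the cloud.
#' @slot projections K projections onto the principal axis.
#' @slot labels factor with levels \code{upper}, \code{lower}.
#' @slot threshold the projection split value (default -0.01; projections
#'   >= threshold are "upper").
#' @slot centered logical; was the cloud mean-centred before the SVD.
#' @export
setClass("EndpointSet",
    representation(endpoints = "matrix", principalAxis = "numeric",
        projections = "numeric", labels = "factor", threshold = "numeric",
        centered = "logical"))

setValidity("EndpointSet", function(object) {
    msg <- character()
    if (ncol(object@endpoints) != 2) msg <- c(msg, "endpoints must be K x 2")
    if (abs(sum(object@principalAxis^2) - 1) > 1e-8)
        msg <- c(msg, "principalAxis must be unit norm")
    k <- nrow(object@endpoints)
    if (length(object@projections) != k || length(object@labels) != k)
        msg <- c(msg, "projections and labels must match endpoint count")
    want <- ifelse(object@projections >= object@threshold, "upper", "lower")
    if (k && !all(as.character(object@labels) == want))
        msg <- c(msg, "labels inconsistent with projections/threshold")
    if (length(msg)) msg else TRUE
})

#' Fitted CART classification tree
#'
#' Nodes are stored as a data.frame: \code{id}, \code{isLeaf},
#' \code{feature} (column name, NA at leaves), \code{threshold} (go left
#' if value < threshold), \code{left}, \code{right} (child ids),
#' \code{pred} (majority class), \code{n} (training samples),
#' \code{decrease} (total Gini impurity decrease of the split).
#'
#' @slot nodes data.frame of tree nodes, row 1 is the root.
#' @slot minLeaf minimum leaf size enforced at fitting.
#' @slot features character vector of feature (column) names.
#' @slot classes factor levels of the response.
#' @export
setClass("TreeModel",
    representation(nodes = "data.frame", minLeaf = "numeric",
        features = "character", classes = "character"))

setValidity("TreeModel", function(object) {
    leaf <- object@nodes[object@nodes$isLeaf, ]
    ## a root-only tree on fewer than minLeaf samples is legal (no split
    ## was admissible); every leaf produced by a split obeys minLeaf
    floorN <- min(object@minLeaf, object@nodes$n[1])
    if (nrow(leaf) && any(leaf$n < floorN))
        "every leaf must hold at least minLeaf training samples" else TRUE
})
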