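#' @include AllClasses.R
NULL

.readCountTable <- function(path, neuronUniverse = NULL) {
    ## Two dialects: edge list with header (pre, post, count), or a dense
    ## matrix whose first column holds row (postsynaptic) neuron names and
    ## whose remaining column headers are the presynaptic neuron names.
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("pre", "post", "count") %in% names(tab))) {
        if (any(tab$count < 0)) stop("negative counts in ", path)
        nms <- neuronUniverse
        if (is.null(nms)) nms <- sort(unique(c(tab$pre, tab$post)))
        unknown <- setdiff(c(tab$pre, tab$post), nms)
        if (length(unknown))
            stop("unknown neuron name(s) in ", path, ": ",
                 paste(unknown, collapse = ", "))
        m <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
        ## orientation: m[post, pre]
        for (k in seq_len(nrow(tab)))
            m[tab$post[k], tab$pre[k]] <- m[tab$post[k], tab$pre[k]] + tab$count[k]
        m
    } else {
        rn <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- rn
        if (any(m < 0)) stop("negative counts in ", path)
        if (!identical(rownames(m), colnames(m)))
            m <- m[, rownames(m), drop = FALSE]
        m
    }
}

.symmetrizeGap <- function(Ng) {
    if (!isTRUE(all.equal(Ng, t(Ng)))) {
        warning("gap-junction counts are asymmetric; symmetrizing by ",
                "summing reciprocal entries and halving")
        Ng <- (Ng + t(Ng)) / 2
    }
    Ng
}

.defaultGroups <- function(nms, classes, groups = list()) {
    fwd <- c("DB", "VB", "DD", "VD")
    if (is.null(groups[["forward_motor"]]) && any(classes %in% fwd, na.rm = TRUE))
        groups[["forward_motor"]] <- nms[classes %in% fwd]
    if (is.null(groups[["input"]]) && all(c("PLML", "PLMR") %in% nms))
        groups[["input"]] <- c("PLML", "PLMR")
    groups
}

#' Construct a Connectome from matrices
#'
#' Low-level constructor; most users will call \code{\link{loadConnectome}}
#' or \code{\link{syntheticConnectome}}. The gap matrix is symmetrized
#' (with a warning) if the input is asymmetric.
#'
#' @param Ng,Ns square count matrices over the same neuron ordering
#'   (\code{Ns[i, j]} = synapses from presynaptic \code{j} onto
#'   postsynaptic \code{i}).
#' @param polarity named or unnamed character vector,
#'   \code{"excitatory"}/\code{"inhibitory"} per neuron.
#' @param classes optional per-neuron class labels (e.g. "DB", "VB").
#' @param groups named list of neuron-name subsets.
#' @param neuronNames neuron identifiers; defaults to the row names of
#'   \code{Ng}.
#' @return a validated \linkS4class{Connectome}.
#' @export
Connectome <- function(Ng, Ns, polarity, classes = NULL, groups = list(),
                       neuronNames = rownames(Ng)) {
    if (is.null(neuronNames))
        neuronNames <- paste0("N", formatC(seq_len(nrow(Ng)), width = 3, flag = "0"))
    dimnames(Ng) <- dimnames(Ns) <- list(neuronNames, neuronNames)
    Ng <- .symmetrizeGap(Ng)
    if (is.null(classes)) classes <- rep(NA_character_, length(neuronNames))
    classes <- stats::setNames(as.character(classes), names(classes))
    if (is.null(names(polarity))) names(polarity) <- neuronNames
    if (is.null(names(classes))) names(classes) <- neuronNames
    groups <- .defaultGroups(neuronNames, classes, groups)
    new("Connectome", neuronNames = neuronNames, Ng = Ng, Ns = Ns,
        polarity = polarity[neuronNames], classes = classes[neuronNames],
        groups = groups)
}

#' Read connectivity tables into a Connectome
#'
#' Reads gap-junction and chemical-synapse count tables plus a per-neuron
#' polarity/class table and returns a validated \linkS4class{Connectome}.
#' Count tables may be CSV edge lists with header \code{pre, post, count}
#' or dense matrices (first column = postsynaptic neuron names, remaining
#' headers = presynaptic names). The polarity table is CSV with columns
#' \code{neuron, polarity, class} (class optional). Asymmetric gap counts
#' are symmetrized by summing reciprocal entries and halving, with a
#' warning.
#'
#' @param gapFile,synFile paths to the count tables.
#' @param polarityFile path to the polarity/class table.
#' @param groups named list of neuron-name subsets; subsets naming unknown
#'   neurons are an error. Groups \code{"forward_motor"} (classes DB, VB,
#'   DD, VD) and \code{"input"} (PLML, PLMR) are derived automatically
#'   when the labels are present.
#' @return a \linkS4class{Connectome}.
#' @seealso \code{\link{writeConnectome}} for the inverse.
#' @export
loadConnectome <- function(gapFile, synFile, polarityFile, groups = list()) {
    pol <- utils::read.csv(polarityFile, stringsAsFactors = FALSE)
    if (!all(c("neuron", "polarity") %in% names(pol)))
        stop("polarity table needs columns 'neuron' and 'polarity'")
    nms <- pol$neuron
    Ng <- .readCountTable(gapFile, nms)[nms, nms]
    Ns <- .readCountTable(synFile, nms)[nms, nms]
    classes <- if ("class" %in% names(pol)) as.character(pol$class) else NULL
    polarity <- pol$polarity
    names(polarity) <- nms
    if (!is.null(classes)) names(classes) <- nms
    Connectome(Ng, Ns, polarity, classes, groups, neuronNames = nms)
}

#' Write a Connectome to delimited tables
#'
#' Emits \code{gap.csv} and \code{syn.csv} edge lists (header
#' \code{pre, post, count}) and \code{polarity.csv}
#' (\code{neuron, polarity, class}) in \code{dir}; the exact dialects
#' \code{\link{loadConnectome}} reads, so write -> read round-trips.
#'
#' @param c a \linkS4class{Connectome}.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeConnectome <- function(c, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    edge <- function(m) {
        idx <- which(m != 0, arr.ind = TRUE)
        data.frame(pre = colnames(m)[idx[, 2]], post = rownames(m)[idx[, 1]],
                   count = m[idx])
    }
    paths <- file.path(dir, c("gap.csv", "syn.csv", "polarity.csv"))
    utils::write.csv(edge(c@Ng), paths[1], row.names = FALSE)
    utils::write.csv(edge(c@Ns), paths[2], row.names = FALSE)
    utils::write.csv(data.frame(neuron = c@neuronNames,
        polarity = c@polarity, class = c@classes), paths[3], row.names = FALSE)
    invisible(paths)
}

#' Drop pharyngeal neurons and neurons without chemical synapses
#'
#' Restricts a connectome to the somatic neurons that make synaptic
#' connections: neurons on the \code{pharyngeal} list are removed, as is
#' any neuron whose synapse row and column sums are both zero. Applied to
#' the full hermaphrodite wiring tables this retains the 279 somatic
#' neurons used throughout. Idempotent.
#'
#' @param c a \linkS4class{Connectome}.
#' @param pharyngeal character vector of neuron names to exclude
#'   (must be a subset of \code{neuronNames(c)}).
#' @return the filtered \linkS4class{Connectome}.
#' @export
filterSomatic <- function(c, pharyngeal = character()) {
    stopifnot(all(pharyngeal %in% c@neuronNames))
    keep <- setdiff(c@neuronNames, pharyngeal)
    Ns <- c@Ns[keep, keep, drop = FALSE]
    synless <- keep[rowSums(Ns) == 0 & colSums(Ns) == 0]
    keep <- setdiff(keep, synless)
    groups <- lapply(c@groups, intersect, keep)
    groups <- groups[lengths(groups) > 0]
    new("Connectome", neuronNames = keep,
        Ng = c@Ng[keep, keep, drop = FALSE],
        Ns = c@Ns[keep, keep, drop = FALSE],
        polarity = c@polarity[keep], classes = c@classes[keep],
        groups = groups)
}

#' Derive conductance matrices from connection counts
#'
#' Every individual gap junction and synapse carries the same conductivity
#' \code{g} (default 100 pS), so \code{Gg = g * Ng} and \code{Gs = g * Ns}.
#'
#' @param c a \linkS4class{Connectome}.
#' @param g per-connection conductivity in pS (> 0).
#' @return a \linkS4class{ConductanceSet}.
#' @export
buildConductances <- function(c, g = 100) {
    if (g <= 0) stop("g must be positive")
    new("ConductanceSet", Gg = g * c@Ng, Gs = g * c@Ns, g = g)
}

#' Random synthetic connectome fixture
#'
#' Draws a random directed synapse-count matrix and a random symmetric
#' gap-count matrix at a given edge density, assigns polarity at a given
#' inhibitory fraction, designates the first two neurons as the
#' \code{"input"} pair and the last third as the \code{"forward_motor"}
#' subset. Deterministic under \code{seed}. This emulates the format and
#' invariants of real wiring tables at small n, not their topology.
#'
#' @param n neuron count (>= 2).
#' @param density fraction of ordered pairs carrying a synapse (and of
#'   unordered pairs carrying a gap junction), in [0, 1].
#' @param inhibitoryFraction expected fraction of inhibitory neurons.
#' @param seed integer RNG seed.
#' @param maxCount synapse multiplicities are drawn uniformly from
#'   \code{1:maxCount}.
#' @return a \linkS4class{Connectome}.
#' @export
syntheticConnectome <- function(n, density = 0.3, inhibitoryFraction = 0.3,
                                seed = 1, maxCount = 5) {
    stopifnot(n >= 2)
    if (density < 0 || density > 1) stop("density must be in [0, 1]")
    rs <- .withSeed(seed, {
        nms <- paste0("N", formatC(seq_len(n), width = 3, flag = "0"))
        Ns <- matrix(0, n, n)
        mask <- matrix(stats::runif(n * n) < density, n, n)
        diag(mask) <- FALSE
        Ns[mask] <- sample(maxCount, sum(mask), replace = TRUE)
        Ng <- matrix(0, n, n)
        up <- upper.tri(Ng)
        gm <- stats::runif(sum(up)) < density
        Ng[up][gm] <- sample(maxCount, sum(gm), replace = TRUE)
        Ng <- Ng + t(Ng)
        pol <- ifelse(stats::runif(n) < inhibitoryFraction,
                      "inhibitory", "excitatory")
        list(nms = nms, Ng = Ng, Ns = Ns, pol = pol)
    })
    motor <- rs$nms[seq.int(n - ceiling(n / 3) + 1, n)]
    Connectome(rs$Ng, rs$Ns, rs$pol,
        groups = list(input = rs$nms[1:2], forward_motor = motor),
        neuronNames = rs$nms)
}

#' Hand-crafted oscillator motif connectome
#'
#' A small frozen network, verified at build time to produce a periodic
#' orbit under constant input to its stimulated pair. Five recurrent
#' neurons R1..R5 (grouped as \code{"forward_motor"}) form a directed
#' ring R1 -> R2 -> ... -> R5 -> R1 with heterogeneous synapse counts;
#' R1..R3 are inhibitory (an odd number of sign inversions makes the
#' loop a delayed negative feedback), R4..R5 excitatory. The input pair
#' IN1, IN2 (grouped as \code{"input"}, gap-coupled to each other)
#' touches the ring through a single weak synapse IN1 -> R1, so constant
#' stimulation perturbs the ring off its (unstable) stationary state and
#' sustains a limit cycle of about 0.5 Hz without saturating the loop.
#'
#' The motif's frozen constants include a steeper synaptic activation
#' slope (beta = 1 / mV) than the connectome-wide default: the
#' oscillatory instability of the full-scale network is a collective
#' effect that a compact circuit cannot reproduce at the shallow default
#' slope, so the fixture realises the same limit-cycle phenomenology in
#' a five-neuron loop by sharpening the activation. The recommended
#' model parameters are returned in attribute \code{"params"} and the
#' recommended constant input amplitude in attribute
#' \code{"inputCurrent"}; the dynamics equations are identical in every
#' other respect.
#'
#' @return a \linkS4class{Connectome} with attributes \code{"params"}
#'   (a \linkS4class{ModelParams}) and \code{"inputCurrent"}.
#' @export
oscillatorMotif <- function() {
    ring <- paste0("R", 1:5)
    nms <- c("IN1", "IN2", ring)
    n <- length(nms)
    het <- c(1.12, 0.9, 1.03, 0.95, 1.06)  # breaks ring symmetry
    Ns <- matrix(0, n, n, dimnames = list(nms, nms))
    for (i in 1:5)
        Ns[ring[i %% 5 + 1], ring[i]] <- max(1, round(2 * het[i]))
    Ns["R1", "IN1"] <- 1
    Ng <- matrix(0, n, n, dimnames = list(nms, nms))
    Ng["IN1", "IN2"] <- Ng["IN2", "IN1"] <- 1
    pol <- stats::setNames(rep("excitatory", n), nms)
    pol[c("R1", "R2", "R3")] <- "inhibitory"
    cl <- stats::setNames(c("IN", "IN", rep("RING", 5)), nms)
    cx <- Connectome(Ng, Ns, pol, cl,
        groups = list(input = c("IN1", "IN2"), forward_motor = ring),
        neuronNames = nms)
    attr(cx, "inputCurrent") <- 2e4
    attr(cx, "params") <- modelParams(beta = 1)
    cx
}
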