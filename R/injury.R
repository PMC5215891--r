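#' @include AllClasses.R
NULL

#' Swelling distribution from a two-column histogram
#'
#' Reads (or accepts) a two-column table of relative swelling magnitudes
#' and probabilities, validates nonnegativity, and normalises the
#' probabilities to sum to one.
#'
#' @param x path to a two-column CSV (\code{value, probability}) or a
#'   data.frame/matrix with those two columns.
#' @return a list of class \code{"SwellingDistribution"} with components
#'   \code{values} and \code{probabilities}.
#' @export
distributionFromHistogram <- function(x) {
    tab <- if (is.character(x))
        utils::read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
    v <- as.numeric(tab[[1]]); p <- as.numeric(tab[[2]])
    if (any(v < 0) || any(p < 0)) stop("histogram entries must be nonnegative")
    if (sum(p) == 0) stop("all-zero probability histogram")
    structure(list(values = v, probabilities = p / sum(p)),
              class = "SwellingDistribution")
}

#' Synthetic stand-in swelling distribution
#'
#' A discretised log-normal histogram of relative swelling magnitudes.
#' This is a clearly synthetic stand-in for an experimentally measured
#' axonal-swelling histogram (which is not bundled); any user histogram
#' in the same two-column format can be used instead, and analyses should
#' record which distribution was used.
#'
#' @param meanlog,sdlog log-normal parameters of the swelling magnitude.
#' @param nbins number of histogram bins.
#' @param qmax upper quantile at which the support is truncated.
#' @return a \code{"SwellingDistribution"}.
#' @export
syntheticSwellingDistribution <- function(meanlog = 0, sdlog = 0.5,
                                          nbins = 30, qmax = 0.995) {
    edges <- seq(0, stats::qlnorm(qmax, meanlog, sdlog), length.out = nbins + 1)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    p <- stats::plnorm(edges[-1], meanlog, sdlog) -
        stats::plnorm(edges[-length(edges)], meanlog, sdlog)
    distributionFromHistogram(data.frame(value = mids, probability = p))
}

#' Sample a swelling distribution
#'
#' @param dist a \code{"SwellingDistribution"}.
#' @param n number of draws.
#' @return numeric vector of swelling magnitudes.
#' @export
sampleSwellings <- function(dist, n) {
    sample(dist$values, n, replace = TRUE, prob = dist$probabilities)
}

#' Draw a per-neuron injury vector
#'
#' Assigns i.i.d. swellings from \code{dist} to every non-protected
#' neuron, forces protected neurons (by default the stimulated input
#' pair, which is left uninjured) to zero, and L2-normalises the vector
#' to unit norm. Deterministic under \code{seed}. If every draw is zero
#' the vector is redrawn with a warning. An optional per-neuron
#' \code{weight} multiplies the draws before normalisation, as a hook for
#' spatially-biased injury variants (the default, uniform weighting,
#' deliberately ignores spatial structure).
#'
#' @param dist a \code{"SwellingDistribution"}.
#' @param c a \linkS4class{Connectome}.
#' @param protected neuron names forced to zero swelling; default the
#'   \code{"input"} group (if present).
#' @param seed integer RNG seed.
#' @param weight optional named per-neuron nonnegative weights.
#' @return an \linkS4class{InjuryVector} with \code{mu} unset (NA).
#' @export
sampleInjury <- function(dist, c, protected = NULL, seed = 1, weight = NULL) {
    if (is.null(protected))
        protected <- if (!is.null(c@groups[["input"]]))
            c@groups[["input"]] else character()
    stopifnot(all(protected %in% c@neuronNames))
    nms <- c@neuronNames
    m <- .withSeed(seed, {
        for (try in 1:100) {
            draw <- sampleSwellings(dist, length(nms))
            names(draw) <- nms
            if (!is.null(weight)) draw <- draw * weight[nms]
            draw[protected] <- 0
            if (sum(draw) > 0) break
            if (try == 1) warning("all swelling draws were zero; resampling")
        }
        draw
    })
    if (sum(m) == 0) stop("could not draw a nonzero injury vector")
    m <- m / sqrt(sum(m^2))
    new("InjuryVector", m = m, protected = protected, mu = NA_real_,
        seed = as.numeric(seed))
}

#' Set the amplitude of an injury vector
#'
#' @param injury an \linkS4class{InjuryVector}.
#' @param mu global injury amplitude (>= 0).
#' @return the injury with \code{mu} set.
#' @export
setMu <- function(injury, mu) {
    stopifnot(mu >= 0)
    injury@mu <- mu
    injury
}

#' Amplitude reproducing a target mean swelling ratio
#'
#' The mean swollen-to-healthy area ratio satisfies
#' \code{<a_i/a_H> = 1 + mu <m_i>}, so the amplitude reproducing a target
#' ratio is \code{mu = (<a_i/a_H> - 1) / <m_i>}. The mean \code{<m_i>} is
#' taken over the non-protected neurons.
#'
#' @param targetRatio target mean area ratio (>= 1).
#' @param injury an \linkS4class{InjuryVector}.
#' @return the amplitude \code{mu}.
#' @export
muFromMeanSwelling <- function(targetRatio, injury) {
    stopifnot(targetRatio >= 1)
    keep <- setdiff(names(injury@m), injury@protected)
    mbar <- mean(injury@m[keep])
    if (mbar == 0) stop("mean swelling is zero")
    (targetRatio - 1) / mbar
}

#' Per-neuron swelling factors 1 + mu * m_i
#'
#' The factor by which each neuron's membrane area (hence capacitance and
#' leak conductance) is inflated; it divides the coupling currents in the
#' injured governing equation. Exactly 1 for protected neurons and at
#' \code{mu = 0}.
#'
#' @param injury an \linkS4class{InjuryVector}.
#' @param mu amplitude; default the one stored in \code{injury}.
#' @return named per-neuron factor vector (>= 1).
#' @export
injuryScale <- function(injury, mu = injury@mu) {
    stopifnot(length(mu) == 1, !is.na(mu), mu >= 0)
    1 + mu * injury@m
}

#' Serialize an injury ensemble
#'
#' Writes the injury matrix (rows = injuries, columns = neurons) as CSV
#' plus a JSON metadata sidecar (seeds, protected set, distribution id),
#' so published injury sets can be exported/imported.
#'
#' @param injuries list of \linkS4class{InjuryVector}s over one connectome.
#' @param path output CSV path; metadata goes to \code{<path>.json}.
#' @param distributionId free-text identifier of the swelling
#'   distribution used.
#' @return invisibly, \code{path}.
#' @export
writeInjuryEnsemble <- function(injuries, path, distributionId = "unspecified") {
    m <- do.call(rbind, lapply(injuries, slot, "m"))
    rownames(m) <- paste0("injury", seq_along(injuries))
    utils::write.csv(m, path, row.names = TRUE)
    .writeJSON(list(
        seeds = vapply(injuries, slot, numeric(1), "seed"),
        protected = injuries[[1]]@protected,
        distribution = distributionId), paste0(path, ".json"))
    invisible(path)
}

#' Read an injury ensemble written by \code{writeInjuryEnsemble}
#'
#' @param path CSV path (with \code{<path>.json} sidecar).
#' @return list of \linkS4class{InjuryVector}s (mu unset).
#' @export
readInjuryEnsemble <- function(path) {
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    lapply(seq_len(nrow(m)), function(i) {
        v <- m[i, ]
        v <- v / sqrt(sum(v^2))    # guard round-trip rounding
        new("InjuryVector", m = v, protected = as.character(meta$protected),
            mu = NA_real_, seed = as.numeric(meta$seeds[i]))
    })
}
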