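#' @include AllClasses.R connectome.R injury.R
NULL

#' Analytic plane trajectories with known attractors
#'
#' Closed-form test inputs for the attractor and shape machinery:
#' \describe{
#'   \item{circle}{radius \code{r}, frequency \code{f} Hz, centred at
#'     \code{center}.}
#'   \item{ellipse}{semi-axes \code{a}, \code{b}, frequency \code{f}.}
#'   \item{shrinking_cycle}{circle whose radius decays as
#'     \code{r exp(-decay t)} (shape preserved, scale shrinking).}
#'   \item{decaying_spiral}{spiral converging to \code{center} with rate
#'     \code{decay}: a fixed point with an oscillatory transient.}
#'   \item{fixed_point}{constant at \code{center}.}
#' }
#'
#' @param kind trajectory kind (see above).
#' @param T duration (s).
#' @param dt sampling interval (s).
#' @param r,a,b,f,decay,center,phase geometry parameters.
#' @param noiseSd optional Gaussian coordinate noise (requires
#'   \code{seed}).
#' @param seed RNG seed for the noise.
#' @return a \linkS4class{PlaneTrajectory}.
#' @export
analyticTrajectory <- function(kind = c("circle", "ellipse",
        "shrinking_cycle", "decaying_spiral", "fixed_point"),
        T = 20, dt = 1e-3, r = 1, a = 2, b = 1, f = 0.5, decay = 0.5,
        center = c(0, 0), phase = 0, noiseSd = 0, seed = 1) {
    kind <- match.arg(kind)
    tt <- seq(0, T, by = dt)
    th <- 2 * pi * f * tt + phase
    xy <- switch(kind,
        circle = cbind(r * cos(th), r * sin(th)),
        ellipse = cbind(a * cos(th), b * sin(th)),
        shrinking_cycle = cbind(r * exp(-decay * tt) * cos(th),
                                r * exp(-decay * tt) * sin(th)),
        decaying_spiral = cbind(r * exp(-decay * tt) * cos(th),
                                r * exp(-decay * tt) * sin(th)),
        fixed_point = matrix(0, length(tt), 2))
    xy <- sweep(xy, 2, -center)
    if (noiseSd > 0)
        xy <- xy + .withSeed(seed,
            matrix(stats::rnorm(length(xy), 0, noiseSd), ncol = 2))
    new("PlaneTrajectory", times = tt, xy = xy)
}

#' Planted-structure injury ensemble
#'
#' Generates K injury vectors over an n-neuron universe (i.i.d. swellings
#' from a log-normal stand-in distribution, L2-normalised) together with
#' endpoint class labels that depend, by construction, only on two
#' designated "driver" neurons: label = \code{"upper"} iff
#' \code{m[driver1] + noise1 > t1} or \code{m[driver2] + noise2 > t2},
#' with the thresholds at the \code{thresholdQuantile} of each driver
#' column (so the label marginal is about
#' \code{1 - thresholdQuantile^2}). With \code{noiseSd = 0} the labels
#' are a deterministic, axis-aligned function of the driver swellings, so
#' a classification tree of depth two expresses the rule exactly: its
#' cross-validation error approaches zero and the drivers are recovered
#' as the implicated features. The Bayes error under noise is computable
#' by simulation from this same generator (the noiseless rule applied to
#' the noisy scores). Reproducible under \code{seed}.
#'
#' @param K ensemble size (>= 10).
#' @param n neuron count.
#' @param drivers integer length-2, indices of the driver neurons.
#' @param noiseSd standard deviation of the Gaussian noise added to the
#'   driver swellings before thresholding (label noise).
#' @param thresholdQuantile quantile of each driver column at which its
#'   threshold sits (default 0.7).
#' @param seed integer RNG seed.
#' @param dist swelling distribution (default the synthetic log-normal
#'   stand-in).
#' @return list with \code{X} (K x n injury matrix, columns named),
#'   \code{y} (factor "upper"/"lower"), \code{drivers} (column names),
#'   \code{thresholds}, and \code{spec} (the generating parameters).
#' @export
plantedEnsemble <- function(K, n = 20, drivers = c(1, 2), noiseSd = 0,
                            thresholdQuantile = 0.7, seed = 1,
                            dist = syntheticSwellingDistribution()) {
    stopifnot(K >= 10, length(drivers) == 2, all(drivers <= n))
    nms <- paste0("N", formatC(seq_len(n), width = 3, flag = "0"))
    out <- .withSeed(seed, {
        X <- matrix(sampleSwellings(dist, K * n), K, n)
        X <- X / sqrt(rowSums(X^2))
        eps <- matrix(stats::rnorm(2 * K, 0, noiseSd), K, 2)
        list(X = X, eps = eps)
    })
    colnames(out$X) <- nms
    thr <- c(stats::quantile(out$X[, drivers[1]], thresholdQuantile),
             stats::quantile(out$X[, drivers[2]], thresholdQuantile))
    up <- (out$X[, drivers[1]] + out$eps[, 1] > thr[1]) |
          (out$X[, drivers[2]] + out$eps[, 2] > thr[2])
    y <- factor(ifelse(up, "upper", "lower"), levels = c("upper", "lower"))
    list(X = out$X, y = y, drivers = nms[drivers], thresholds = unname(thr),
         spec = list(K = K, n = n, drivers = drivers, noiseSd = noiseSd,
                     thresholdQuantile = thresholdQuantile, seed = seed))
}

#' Write a self-contained demo workspace
#'
#' Emits the oscillator-motif connectome tables, a synthetic swelling
#' histogram, and a run-configuration JSON into \code{dir} --- the same
#' dialects the pipeline reads, so the generator doubles as a format
#' conformance fixture.
#'
#' @param dir output directory.
#' @param seed master seed recorded in the config.
#' @param K ensemble size recorded in the config.
#' @return invisibly, the config path.
#' @export
writeFixtureWorkspace <- function(dir, seed = 1, K = 3) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cx <- oscillatorMotif()
    writeConnectome(cx, dir)
    dist <- syntheticSwellingDistribution()
    utils::write.csv(data.frame(value = dist$values,
        probability = dist$probabilities),
        file.path(dir, "swelling_histogram.csv"), row.names = FALSE)
    cfg <- list(
        connectome = list(gap = "gap.csv", syn = "syn.csv",
                          polarity = "polarity.csv"),
        histogram = "swelling_histogram.csv",
        inputCurrent = attr(cx, "inputCurrent"),
        stimulated = neuronGroups(cx)$input,
        K = K, seed = seed)
    path <- file.path(dir, "config.json")
    .writeJSON(cfg, path)
    invisible(path)
}
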