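#' @include AllClasses.R dynamics.R neural_modes.R attractor.R shape.R trees.R
NULL

#' Run the full injury-ensemble study
#'
#' Orchestrates the stages in order: resting state, healthy simulation
#' and response plane, then per injury (collapse amplitude by bisection,
#' amplitude schedule, Procrustes deficit curve, paralysis endpoint),
#' then the endpoint upper/lower split, classification trees on injury
#' features and on PD-curve shape features, and shuffled-label baselines.
#' Per-injury results are checkpointed as JSON in \code{outDir} and
#' reused on rerun, so interrupted runs resume; reruns with identical
#' configuration reproduce identical artifacts. Per-injury failures are
#' flagged, not fatal. Injury seeds derive from the master seed by a
#' counter scheme (\code{\link{childSeed}}), so enlarging \code{K} never
#' changes earlier injuries.
#'
#' @param c a \linkS4class{Connectome} with an \code{"input"} and a
#'   \code{"forward_motor"} group.
#' @param params a \linkS4class{ModelParams}.
#' @param dist a swelling distribution
#'   (\code{\link{distributionFromHistogram}}).
#' @param K number of injuries.
#' @param inputCurrent constant current applied to each input-group
#'   neuron (pS * mV).
#' @param seed master seed.
#' @param outDir optional checkpoint directory; \code{NULL} disables
#'   checkpointing.
#' @param Thealthy healthy simulation length used for the plane (s);
#'   snapshots after the transient feed the SVD.
#' @param Tinit per-classification initial simulation length (s).
#' @param transient transient discard (s).
#' @param N resampled points per cycle shape.
#' @param minLeaf minimum leaf size for the classification trees.
#' @param baselineTrials shuffled-label trials (default 100).
#' @param featureGrid PD-curve feature length.
#' @param folds cross-validation folds (clamped to the usable ensemble
#'   size for small smoke runs).
#' @param cvSeed seed for fold assignment and shuffles.
#' @param verbose log progress?
#' @return list of class \code{"EnsembleRun"}: config, healthy plane and
#'   shape, per-injury profiles/curves/endpoints, the
#'   \linkS4class{EndpointSet}, fitted trees, cross-validation errors and
#'   baselines, and per-injury status flags.
#' @export
runEnsemble <- function(c, params = modelParams(), dist, K,
                        inputCurrent = 2e4, seed = 1, outDir = NULL,
                        Thealthy = 25, Tinit = 20, transient = 5, N = 200,
                        minLeaf = max(2, round(K / 10)),
                        baselineTrials = 100, featureGrid = 20,
                        folds = 10, cvSeed = seed, verbose = FALSE) {
    stopifnot(!is.null(c@groups[["input"]]),
              !is.null(c@groups[["forward_motor"]]))
    say <- function(...) if (verbose) message(sprintf(...))
    if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                     recursive = TRUE)
    cfg <- list(K = K, seed = seed, inputCurrent = inputCurrent,
                g = params@g, dt = params@dt, Thealthy = Thealthy,
                Tinit = Tinit, transient = transient, N = N,
                minLeaf = minLeaf, baselineTrials = baselineTrials,
                featureGrid = featureGrid)
    cfgHash <- .configHash(cfg)

    say("stage 1/5: resting state + healthy plane")
    rest <- restingState(c, params)
    params <- rest$params
    Iext <- stats::setNames(rep(inputCurrent, length(c@groups$input)),
                            c@groups$input)
    healthyTraj <- simulateNetwork(c, params, Iext = Iext, T = Thealthy,
                                   init = rest$state)
    plane <- computePlane(healthyTraj, transient = transient)
    healthyPt <- projectOnPlane(healthyTraj, plane)
    healthyShape <- resampleClosedCurve(
        extractPeriod(healthyPt, transient = transient), N)
    healthyFreq <- cycleFrequency(healthyPt, transient = transient)

    say("stage 2/5: %d injuries (mu* bisection + PD curves)", K)
    injuries <- vector("list", K)
    profiles <- vector("list", K)
    curves <- vector("list", K)
    status <- character(K)
    endpoints <- matrix(NA_real_, K, 2)
    for (k in seq_len(K)) {
        ckpt <- if (!is.null(outDir))
            file.path(outDir, sprintf("injury%04d_%s.json", k, cfgHash))
        inj <- sampleInjury(dist, c, seed = childSeed(seed, k))
        injuries[[k]] <- inj
        if (!is.null(ckpt) && file.exists(ckpt)) {
            rec <- jsonlite::read_json(ckpt, simplifyVector = TRUE)
            profiles[[k]] <- new("MuProfile", muStar = rec$muStar,
                muSamples = rec$muSamples, results = list(),
                endpoint = rec$endpoint, bracket = rec$bracket)
            curves[[k]] <- new("PDCurve", mu = rec$curve$mu,
                pd = rec$curve$pd, scaling = rec$curve$scaling,
                translation = rec$curve$translation,
                frequency = rec$curve$frequency, muStar = rec$muStar)
            endpoints[k, ] <- rec$endpoint
            status[k] <- rec$status
            say("  injury %d: resumed from checkpoint", k)
            next
        }
        res <- tryCatch({
            prof <- findMuStar(c, params, inj, plane, Iext,
                               Tinit = Tinit, init = rest$state,
                               transient = transient)
            crv <- pdCurve(c, params, inj, prof, plane, healthyShape,
                           Iext, N = N, Tinit = Tinit, init = rest$state,
                           transient = transient)
            list(prof = prof, crv = crv, status = "ok")
        }, error = function(e)
            list(prof = NULL, crv = NULL, status = conditionMessage(e)))
        profiles[[k]] <- res$prof
        curves[[k]] <- res$crv
        status[k] <- res$status
        if (!is.null(res$prof)) endpoints[k, ] <- res$prof@endpoint
        say("  injury %d: %s (mu* = %s)", k, res$status,
            if (!is.null(res$prof)) signif(res$prof@muStar, 4) else NA)
        if (!is.null(ckpt) && res$status == "ok") {
            .writeJSON(list(muStar = res$prof@muStar,
                muSamples = res$prof@muSamples,
                endpoint = res$prof@endpoint, bracket = res$prof@bracket,
                status = res$status,
                curve = list(mu = res$crv@mu, pd = res$crv@pd,
                    scaling = res$crv@scaling,
                    translation = res$crv@translation,
                    frequency = res$crv@frequency),
                configHash = cfgHash, seed = childSeed(seed, k)), ckpt)
        }
    }

    ok <- status == "ok" & !is.na(endpoints[, 1])
    say("stage 3/5: endpoint split (%d usable injuries)", sum(ok))
    eps <- if (sum(ok) >= 2)
        splitEndpoints(endpoints[ok, , drop = FALSE]) else NULL

    say("stage 4/5: classification trees")
    trees <- NULL
    if (!is.null(eps) && nlevels(droplevels(eps@labels)) == 2) {
        Xinj <- do.call(rbind, lapply(injuries[ok], slot, "m"))
        Xpd <- do.call(rbind, lapply(curves[ok], pdCurveFeatures,
                                     gridSize = featureGrid))
        colnames(Xpd) <- paste0("g", seq_len(featureGrid))
        y <- eps@labels
        nf <- min(folds, length(y))   # small smoke runs fall back to LOO
        trees <- list(
            injury = list(
                tree = fitTree(Xinj, y, minLeaf),
                cvError = kfoldCvError(Xinj, y, minLeaf, folds = nf,
                                       seed = cvSeed),
                baseline = shuffledBaseline(Xinj, y, minLeaf,
                    trials = baselineTrials, folds = nf, seed = cvSeed)),
            pdShape = list(
                tree = fitTree(Xpd, y, minLeaf),
                cvError = kfoldCvError(Xpd, y, minLeaf, folds = nf,
                                       seed = cvSeed),
                baseline = shuffledBaseline(Xpd, y, minLeaf,
                    trials = baselineTrials, folds = nf, seed = cvSeed)))
    }

    say("stage 5/5: done")
    structure(list(config = cfg, configHash = cfgHash,
        connectome = c, params = params, plane = plane,
        healthyShape = healthyShape, healthyFrequency = healthyFreq,
        injuries = injuries, profiles = profiles, curves = curves,
        endpoints = endpoints, endpointSet = eps, trees = trees,
        status = status), class = "EnsembleRun")
}

.configHash <- function(cfg) {
    s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    ## tiny polynomial rolling hash, enough to key checkpoints to a config
    h <- 0
    for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}

#' Summary report of an ensemble run
#'
#' Emits the study's headline quantities: endpoint class fractions,
#' class-averaged normalised PD / scaling / translation curves,
#' cross-validation errors with shuffled baselines, the implicated
#' features of the injury tree, and the mean cycle-frequency reduction
#' over the highly-injured interval \code{(0.9 muStar, muStar)} (computed
#' per injury as the mean of \code{1 - f(mu)/f(0)} over that interval's
#' periodic samples, then averaged over injuries).
#'
#' @param run an \code{"EnsembleRun"} from \code{\link{runEnsemble}}.
#' @param gridSize grid for the class-averaged curves.
#' @return list of class \code{"EnsembleReport"}.
#' @export
ensembleReport <- function(run, gridSize = 50) {
    ok <- run$status == "ok" & !is.na(run$endpoints[, 1])
    out <- list(K = run$config$K, usable = sum(ok))
    eps <- run$endpointSet
    if (!is.null(eps)) {
        tab <- table(eps@labels)
        out$classFractions <- as.list(tab / sum(tab))
    }
    ## class-averaged curves (absent classes noted, not an error)
    if (!is.null(eps)) {
        curvesOk <- run$curves[ok]
        for (cls in levels(eps@labels)) {
            sel <- eps@labels == cls
            if (!any(sel)) {
                out$curveAverages[[cls]] <- "no injuries in this class"
                next
            }
            sub <- curvesOk[sel]
            out$curveAverages[[cls]] <- list(
                pd = normalizeAndAverage(sub, "pd", gridSize),
                scaling = normalizeAndAverage(sub, "scaling", gridSize),
                translation = normalizeAndAverage(sub, "translation",
                                                  gridSize))
        }
    }
    if (!is.null(run$trees)) {
        out$cv <- list(
            injury = list(cvError = run$trees$injury$cvError,
                baselineMean = run$trees$injury$baseline$mean,
                baselineSd = run$trees$injury$baseline$sd),
            pdShape = list(cvError = run$trees$pdShape$cvError,
                baselineMean = run$trees$pdShape$baseline$mean,
                baselineSd = run$trees$pdShape$baseline$sd))
        out$implicated <- implicatedFeatures(run$trees$injury$tree)
    }
    ## frequency reduction over (0.9 mu*, mu*)
    freqRed <- vapply(which(ok), function(k) {
        crv <- run$curves[[k]]
        f0 <- crv@frequency[crv@mu == 0]
        hi <- crv@mu > 0.9 * crv@muStar & !is.na(crv@frequency)
        if (!is.finite(f0) || !any(hi)) return(NA_real_)
        mean(1 - crv@frequency[hi] / f0)
    }, numeric(1))
    out$frequencyReduction <- mean(freqRed, na.rm = TRUE)
    class(out) <- "EnsembleReport"
    out
}

#' @export
print.EnsembleReport <- function(x, ...) {
    cat("Ensemble report:", x$usable, "of", x$K, "injuries usable\n")
    if (!is.null(x$classFractions))
        cat("  endpoint classes:",
            paste(sprintf("%s %.1f%%", names(x$classFractions),
                100 * unlist(x$classFractions)), collapse = ", "), "\n")
    if (!is.null(x$cv)) {
        cat(sprintf("  injury-feature tree CV error: %.1f%% (baseline %.1f +/- %.1f%%)\n",
            100 * x$cv$injury$cvError, 100 * x$cv$injury$baselineMean,
            100 * x$cv$injury$baselineSd))
        cat(sprintf("  PD-shape tree CV error: %.1f%% (baseline %.1f +/- %.1f%%)\n",
            100 * x$cv$pdShape$cvError, 100 * x$cv$pdShape$baselineMean,
            100 * x$cv$pdShape$baselineSd))
        if (nrow(x$implicated))
            cat("  implicated neurons:",
                paste(x$implicated$feature, collapse = ", "), "\n")
    }
    if (is.finite(x$frequencyReduction))
        cat(sprintf("  mean frequency reduction in (0.9 mu*, mu*): %.1f%%\n",
            100 * x$frequencyReduction))
    invisible(x)
}
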