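#' @include AllClasses.R dynamics.R neural_modes.R injury.R
NULL

## Passage events of a polyline within `radius` of `center`: distance from
## center to each segment (not just vertices), so a cycle cannot step over
## the disc between samples. Returns times of closest approach, one per
## contiguous passage.
.passageTimes <- function(times, xy, center, radius) {
    p <- sweep(xy, 2, center)
    a <- p[-nrow(p), , drop = FALSE]
    d <- p[-1, , drop = FALSE] - a
    len2 <- rowSums(d^2)
    tpar <- -rowSums(a * d) / pmax(len2, .Machine$double.eps)
    tpar <- pmin(pmax(tpar, 0), 1)
    near <- a + d * tpar
    dist <- sqrt(rowSums(near^2))
    inside <- dist <= radius
    if (!any(inside)) return(numeric(0))
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segT <- times[-length(times)] + tpar * diff(times)
    out <- numeric(0)
    for (k in which(runs$values)) {
        idx <- starts[k]:ends[k]
        out <- c(out, segT[idx[which.min(dist[idx])]])
    }
    out
}

## Poincare section through `center`: same-direction (upward) crossings of
## the horizontal axis on the positive-x side, linearly interpolated. A
## hysteresis band (a fraction of the vertical spread) suppresses the
## spurious re-crossings a noisy trajectory makes near the section.
.poincareCrossings <- function(times, xy, center = colMeans(xy),
                               hysteresis = 0.3) {
    yh <- xy[, 2] - center[2]
    h <- hysteresis * stats::sd(yh)
    if (!is.finite(h)) h <- 0
    out <- numeric(0)
    armed <- FALSE
    for (i in seq_along(yh)) {
        if (!armed) {
            if (yh[i] < -h) armed <- TRUE
        } else if (yh[i] >= 0) {
            if (i > 1) {
                frac <- -yh[i - 1] / (yh[i] - yh[i - 1])
                out <- c(out, times[i - 1] + frac * (times[i] - times[i - 1]))
            }
            armed <- FALSE
        }
    }
    out
}

#' Classify asymptotic dynamics on the response plane
#'
#' Ignores the first \code{transient} seconds, then evaluates successive
#' \code{window}-second windows of the projected trajectory:
#' \itemize{
#'   \item \emph{fixed point} if every point of the window lies within
#'     \code{radius} of the window's reference centre (the window mean by
#'     default, its final point with \code{center = "last"});
#'   \item \emph{periodic} if the trajectory leaves a disc of the same
#'     radius centred on the window's final point (which lies on the
#'     trajectory) and re-enters it recurrently: at least three passages
#'     whose interval coefficient of variation is below \code{cvMax}.
#'     Passages are detected against trajectory segments, so a coarsely
#'     sampled cycle cannot step over the disc.
#' }
#' If neither criterion holds and a \code{extend} continuation hook is
#' supplied, the trajectory is extended window by window until a
#' criterion holds or \code{maxWindows} windows have been checked; then
#' an "undetermined" error with diagnostics is thrown. The radius default
#' (0.01) is about three orders of magnitude below a healthy cycle
#' radius, so very small periodic orbits classify as fixed points by
#' design.
#'
#' @param pt a \linkS4class{PlaneTrajectory} spanning at least
#'   \code{transient + window} seconds.
#' @param radius confinement radius on the plane (default 0.01).
#' @param transient initial span to ignore (s).
#' @param window test-window length (s).
#' @param center fixed-point reference centre: \code{"mean"} (default) or
#'   \code{"last"}.
#' @param cvMax re-entry interval coefficient-of-variation bound
#'   (guards slow oscillatory transients being read as periodic).
#' @param extend optional continuation hook \code{function(pt, addT)}
#'   returning \code{pt} extended by \code{addT} seconds.
#' @param maxWindows cap on windows checked.
#' @return list with \code{kind} ("fixed_point" or "periodic"),
#'   \code{endpoint} (fixed points: trailing-window mean), \code{period}
#'   and \code{frequency} (periodic), and \code{windowsChecked}.
#' @export
classifyAttractor <- function(pt, radius = 0.01, transient = 5, window = 5,
                              center = c("mean", "last"), cvMax = 0.2,
                              extend = NULL, maxWindows = 40) {
    center <- match.arg(center)
    t0 <- pt@times[1]
    w <- 0
    wxy <- NULL
    while (w < maxWindows) {
        wStart <- t0 + transient + w * window
        wEnd <- wStart + window
        if (wEnd > pt@times[length(pt@times)] + 1e-9) {
            if (is.null(extend)) {
                if (w == 0) stop("trajectory too short: spans less than ",
                                 transient + window, " s")
                break
            }
            pt <- extend(pt, wEnd - pt@times[length(pt@times)] + window)
            next
        }
        w <- w + 1
        sel <- pt@times >= wStart & pt@times <= wEnd
        wxy <- pt@xy[sel, , drop = FALSE]
        ref <- if (center == "mean") colMeans(wxy) else wxy[nrow(wxy), ]
        if (max(sqrt(rowSums(sweep(wxy, 2, ref)^2))) <= radius) {
            return(list(kind = "fixed_point", endpoint = colMeans(wxy),
                        period = NA_real_, frequency = NA_real_,
                        windowsChecked = w))
        }
        post <- pt@times >= t0 + transient & pt@times <= wEnd
        lastPt <- wxy[nrow(wxy), ]
        postT <- pt@times[post]
        postXY <- pt@xy[post, , drop = FALSE]
        ev <- .passageTimes(postT, postXY, lastPt, radius)
        if (length(ev) >= 3) {
            iv <- diff(ev)
            ## near-constant re-entry intervals, and a stationary excursion
            ## amplitude between re-entries: a contracting spiral re-enters
            ## at constant intervals too, but its excursions decay, so it is
            ## treated as a transient and the windows keep advancing
            dists <- sqrt(rowSums(sweep(postXY, 2, lastPt)^2))
            exc <- vapply(seq_len(length(ev) - 1), function(k) {
                span <- postT > ev[k] & postT < ev[k + 1]
                if (!any(span)) return(NA_real_)
                max(dists[span])
            }, numeric(1))
            exc <- exc[is.finite(exc)]
            stationary <- length(exc) >= 2 &&
                exc[length(exc)] >= 0.9 * max(exc)
            if (stats::sd(iv) / mean(iv) < cvMax && stationary) {
                per <- mean(iv)
                return(list(kind = "periodic", endpoint = c(NA_real_, NA_real_),
                            period = per, frequency = 1 / per,
                            windowsChecked = w))
            }
        }
    }
    stop("undetermined attractor after ", w, " windows (",
         "trajectory span ", round(diff(range(pt@times)), 2), " s",
         if (!is.null(wxy)) paste0(", last window radius ",
             signif(max(sqrt(rowSums(sweep(wxy, 2, colMeans(wxy))^2))), 3)),
         ")")
}

#' Limit-cycle frequency from Poincare crossings
#'
#' Estimates the period as the mean interval between same-direction
#' crossings of a Poincare half-line through the cycle centroid, and
#' returns its reciprocal.
#'
#' For noisy trajectories the coordinates are first smoothed with a
#' centred running mean spanning about 1 percent of the record, which is
#' phase-neutral and suppresses spurious section crossings.
#'
#' @param pt a \linkS4class{PlaneTrajectory} on a (near-)periodic orbit.
#' @param transient initial span to ignore (s).
#' @param smoothFrac running-mean window as a fraction of the record
#'   length (0 disables smoothing).
#' @return frequency in Hz.
#' @export
cycleFrequency <- function(pt, transient = 0, smoothFrac = 0.01) {
    keep <- pt@times >= pt@times[1] + transient
    tt <- pt@times[keep]
    xy <- pt@xy[keep, , drop = FALSE]
    k <- max(1, round(smoothFrac * nrow(xy)))
    if (k > 1) {
        sm <- apply(xy, 2, function(z)
            stats::filter(z, rep(1 / k, k), sides = 2))
        ok <- stats::complete.cases(sm)
        tt <- tt[ok]; xy <- sm[ok, , drop = FALSE]
    }
    tc <- .poincareCrossings(tt, xy)
    if (length(tc) < 2)
        stop("fewer than 2 Poincare crossings; is the trajectory periodic?")
    1 / mean(diff(tc))
}

#' Injury amplitude sampling schedule
#'
#' Five amplitudes linearly spaced through the interior of
#' \code{(0, 0.9 muStar)} and ten through \code{(0.9 muStar, muStar)},
#' endpoints excluded, strictly increasing.
#'
#' @param muStar collapse amplitude (> 0).
#' @return numeric vector of 15 amplitudes.
#' @export
muSchedule <- function(muStar) {
    stopifnot(muStar > 0)
    lo <- 0.9 * muStar * seq_len(5) / 6
    hi <- 0.9 * muStar + 0.1 * muStar * seq_len(10) / 11
    c(lo, hi)
}

## Continue a simulation from the stored final state and append the new
## samples to both the Trajectory and its plane projection.
.makeExtender <- function(c, params, injury, Iext, plane, record, stride,
                          trajEnv) {
    force(plane)
    function(pt, addT) {
        more <- simulateNetwork(c, params, injury = injury, Iext = Iext,
            T = addT, record = record, stride = stride,
            init = trajEnv$traj@finalState)
        keep <- -1L   # first sample duplicates the previous final state
        traj <- trajEnv$traj
        newTraj <- new("Trajectory",
            times = c(traj@times, more@times[keep]),
            V = rbind(traj@V, more@V[keep, , drop = FALSE]),
            stride = stride, dt = params@dt, finalState = more@finalState)
        trajEnv$traj <- newTraj
        projectOnPlane(newTraj, plane)
    }
}

#' Simulate one injury amplitude and classify its attractor
#'
#' Convenience wrapper: simulates the injured network, projects onto the
#' healthy response plane, and classifies the asymptotic dynamics,
#' extending the simulation as needed.
#'
#' @param c a \linkS4class{Connectome}.
#' @param params a \linkS4class{ModelParams} with \code{Vth} set.
#' @param injury an \linkS4class{InjuryVector}.
#' @param mu amplitude at which to simulate.
#' @param plane the healthy \linkS4class{NeuralPlane}.
#' @param Iext stimulation currents (see \code{\link{simulateNetwork}}).
#' @param Tinit initial simulated duration (s).
#' @param stride recording stride.
#' @param init optional initial state.
#' @param ... passed to \code{\link{classifyAttractor}}.
#' @return list with the classification \code{result}, the plane
#'   trajectory \code{pt}, and the \code{traj}ectory itself.
#' @export
attractorAtMu <- function(c, params, injury, mu, plane, Iext,
                          Tinit = 20, stride = 100, init = NULL, ...) {
    inj <- if (mu == 0) NULL else setMu(injury, mu)
    record <- plane@subset
    traj <- simulateNetwork(c, params, injury = inj, Iext = Iext, T = Tinit,
                            record = record, stride = stride, init = init)
    trajEnv <- new.env()
    trajEnv$traj <- traj
    pt <- projectOnPlane(traj, plane)
    ext <- .makeExtender(c, params, inj, Iext, plane, record, stride, trajEnv)
    res <- classifyAttractor(pt, extend = ext, ...)
    list(result = res, pt = projectOnPlane(trajEnv$traj, plane),
         traj = trajEnv$traj)
}

#' Bisection for a collapse threshold of a classifier
#'
#' Generic bisection on an amplitude axis given a classifier function:
#' verifies \code{classify(0)} is \code{"periodic"}, finds a
#' \code{"fixed_point"} upper bound by doubling from \code{muInit}, then
#' bisects until the bracket's relative width is below \code{tolRel}.
#' The bracket endpoints straddle the two classifications on return.
#'
#' @param classify function(mu) returning \code{"periodic"} or
#'   \code{"fixed_point"}.
#' @param muInit first upper-bound candidate.
#' @param muMax abort if doubling exceeds this.
#' @param tolRel relative bracket-width tolerance.
#' @return list with \code{muStar} (bracket midpoint), \code{bracket}
#'   (periodic lower end, fixed upper end) and \code{calls} (number of
#'   classifications).
#' @export
bisectCollapse <- function(classify, muInit = 1, muMax = 2^16,
                           tolRel = 1e-3) {
    calls <- 0L
    cl <- function(mu) { calls <<- calls + 1L; classify(mu) }
    if (cl(0) != "periodic")
        stop("dynamics at mu = 0 are not periodic; degenerate network")
    lo <- 0
    hi <- muInit
    while (cl(hi) != "fixed_point") {
        lo <- hi
        hi <- 2 * hi
        if (hi > muMax) stop("no collapse found below mu = ", muMax)
    }
    while ((hi - lo) > tolRel * hi) {
        mid <- (lo + hi) / 2
        if (cl(mid) == "fixed_point") hi <- mid else lo <- mid
    }
    list(muStar = (lo + hi) / 2, bracket = c(lo, hi), calls = calls)
}

#' Collapse amplitude by bisection
#'
#' Verifies the healthy (\code{mu = 0}) dynamics are periodic, finds a
#' fixed-point upper bound by doubling from \code{muInit}, then bisects
#' the periodic/fixed-point bracket until its relative width is below
#' \code{tolRel}. Returns the bracket midpoint as \code{muStar}, the
#' sampling schedule, and the collapse endpoint (the trailing-window mean
#' of the plane projection at the fixed-point bracket end).
#'
#' @inheritParams attractorAtMu
#' @param muInit first upper-bound candidate for the doubling search.
#' @param muMax abort if no fixed point is found below this amplitude.
#' @param tolRel relative bracket-width tolerance (default 1e-3).
#' @param verbose log each classification?
#' @return a \linkS4class{MuProfile} (with \code{muSamples} filled from
#'   \code{\link{muSchedule}} but not yet classified).
#' @export
findMuStar <- function(c, params, injury, plane, Iext, muInit = 1,
                       muMax = 2^16, tolRel = 1e-3, Tinit = 20,
                       stride = 100, init = NULL, verbose = FALSE, ...) {
    endpoint <- c(NA_real_, NA_real_)
    cls <- function(mu) {
        r <- attractorAtMu(c, params, injury, mu, plane, Iext,
                           Tinit = Tinit, stride = stride, init = init, ...)
        if (verbose)
            message(sprintf("  mu = %.6g -> %s", mu, r$result$kind))
        if (r$result$kind == "fixed_point") endpoint <<- r$result$endpoint
        r$result$kind
    }
    bs <- bisectCollapse(cls, muInit = muInit, muMax = muMax, tolRel = tolRel)
    new("MuProfile", muStar = bs$muStar, muSamples = muSchedule(bs$muStar),
        results = list(), endpoint = endpoint, bracket = bs$bracket)
}
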