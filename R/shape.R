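#' @include AllClasses.R attractor.R
NULL

#' Extract one limit-cycle period from a plane trajectory
#'
#' Finds same-direction Poincare crossings through the cycle centroid
#' (after discarding a transient) and returns the raw sample points
#' between the first two consecutive crossings: one full period of the
#' closed orbit.
#'
#' @param pt a \linkS4class{PlaneTrajectory} classified periodic.
#' @param transient initial span to discard (s).
#' @return 2 x K matrix of raw cycle points, with attribute
#'   \code{"period"} (s).
#' @export
extractPeriod <- function(pt, transient = 5) {
    keep <- pt@times >= pt@times[1] + transient
    tt <- pt@times[keep]
    xy <- pt@xy[keep, , drop = FALSE]
    tc <- .poincareCrossings(tt, xy)
    if (length(tc) < 2)
        stop("no full period found; trajectory may not be periodic")
    sel <- tt >= tc[1] & tt < tc[2]
    if (sum(sel) < 4) stop("fewer than 4 samples in one period")
    out <- t(xy[sel, , drop = FALSE])
    attr(out, "period") <- tc[2] - tc[1]
    out
}

#' Uniformly resample a closed curve by periodic splines
#'
#' Interpolates each coordinate with a periodic cubic spline in the
#' (normalised-time) cycle parameter and samples N points at uniform
#' parameter spacing.
#'
#' @param points 2 x K matrix of cycle points (>= 4), ordered along the
#'   cycle, first point not repeated.
#' @param N number of output points (default 200).
#' @return a \linkS4class{Shape}.
#' @export
resampleClosedCurve <- function(points, N = 200) {
    stopifnot(nrow(points) == 2, ncol(points) >= 4)
    if (max(apply(points, 1, function(r) diff(range(r)))) == 0)
        stop("degenerate (zero-extent) curve")
    K <- ncol(points)
    par <- (seq_len(K) - 1) / K
    newPar <- (seq_len(N) - 1) / N
    out <- matrix(NA_real_, 2, N)
    for (d in 1:2) {
        f <- stats::splinefun(c(par, 1), c(points[d, ], points[d, 1]),
                              method = "periodic")
        out[d, ] <- f(newPar)
    }
    rownames(out) <- c("x", "y")
    new("Shape", points = out)
}

## Core Procrustes solution (closed form). Transforms S_A onto S_B:
## minimizes ||Bc - b Ac R||^2 over rotations R (det +1), scale b > 0.
## Returns the scale-normalised dissimilarity 1 - tr^2/(ssA ssB) (which is
## symmetric in A and B), the raw residual, b, R and the translation.
.procrustesCore <- function(XA, XB) {
    muA <- colMeans(XA); muB <- colMeans(XB)
    Ac <- sweep(XA, 2, muA); Bc <- sweep(XB, 2, muB)
    ssA <- sum(Ac^2); ssB <- sum(Bc^2)
    if (ssA == 0 || ssB == 0) stop("zero-variance shape")
    M <- crossprod(Ac, Bc)
    sv <- svd(M)
    sgn <- sign(det(sv$u %*% t(sv$v)))
    D <- c(sv$d[1], sgn * sv$d[2])
    R <- sv$u %*% diag(c(1, sgn)) %*% t(sv$v)
    trc <- sum(D)
    b <- trc / ssA
    pd <- 1 - trc^2 / (ssA * ssB)
    rss <- ssB - trc^2 / ssA
    ctr <- muB - b * drop(muA %*% R)
    list(pd = max(pd, 0), b = b, R = R, c = ctr, rss = max(rss, 0))
}

#' Procrustes superimposition of two shapes
#'
#' Closed-form solution of the similarity-transform alignment problem:
#' centres both shapes, finds the optimal rotation (det +1; reflections
#' excluded) from the SVD of the cross-covariance, the optimal scale
#' \code{b} applied to \code{SA}, and the translation. The reported
#' dissimilarity \code{pd} is the residual sum of squares normalised by
#' the centred sum of squares (the standardised Procrustes dissimilarity,
#' symmetric in the two shapes and zero iff they are similar); the raw
#' minimised residual of \code{||SB - b SA R - c||^2} is also returned.
#'
#' @param SA,SB \linkS4class{Shape}s with equal point counts. \code{SA}
#'   is the reference (healthy) shape; \code{b} is the factor by which it
#'   must be scaled to best match \code{SB}, so a shrunken \code{SB}
#'   gives \code{b < 1}.
#' @return list with \code{pd}, \code{b}, \code{R} (2 x 2 rotation),
#'   \code{c} (translation 2-vector), \code{rss} (raw residual),
#'   \code{phaseShift} (0 here; see \code{\link{phaseAlignedPD}}) and
#'   \code{reversed} (FALSE here).
#' @export
procrustesFit <- function(SA, SB) {
    stopifnot(ncol(SA@points) == ncol(SB@points))
    out <- .procrustesCore(t(SA@points), t(SB@points))
    out$phaseShift <- 0L
    out$reversed <- FALSE
    out
}

#' Phase-aligned Procrustes distance between closed cycles
#'
#' The point correspondence of two closed curves is defined only up to a
#' cyclic phase shift (and possibly traversal direction). This evaluates
#' the Procrustes fit over all N cyclic index shifts of \code{SB} --- and
#' over both traversal directions unless \code{directions = FALSE} ---
#' and returns the minimising fit.
#'
#' @inheritParams procrustesFit
#' @param directions also try the reversed traversal of \code{SB}?
#'   Default TRUE (direction reversal is a correspondence change, not a
#'   rotation).
#' @return as \code{\link{procrustesFit}}, with \code{phaseShift} and
#'   \code{reversed} filled in.
#' @export
phaseAlignedPD <- function(SA, SB, directions = TRUE) {
    N <- ncol(SA@points)
    stopifnot(ncol(SB@points) == N)
    XA <- t(SA@points)
    best <- NULL
    for (rev in c(FALSE, if (directions) TRUE)) {
        XB0 <- t(SB@points)
        if (rev) XB0 <- XB0[N:1, , drop = FALSE]
        for (k in 0:(N - 1)) {
            idx <- ((seq_len(N) - 1 + k) %% N) + 1
            out <- .procrustesCore(XA, XB0[idx, , drop = FALSE])
            if (is.null(best) || out$pd < best$pd) {
                out$phaseShift <- k
                out$reversed <- rev
                best <- out
            }
        }
    }
    best
}

#' Procrustes deficit curve over an injury's amplitude schedule
#'
#' For each amplitude in the profile's schedule (prepended with
#' \code{mu = 0}), simulates the injured network, extracts and resamples
#' one limit-cycle period, and evaluates the phase-aligned Procrustes
#' distance to the healthy cycle, together with the optimal scale factor,
#' the displacement of the cycle centroid from the healthy centroid, and
#' the cycle frequency. Amplitudes whose dynamics have already collapsed
#' to a fixed point (possible near \code{muStar} given the bisection
#' tolerance) are recorded as \code{NA} gaps rather than aborting. The
#' curve terminates at \code{muStar}.
#'
#' @inheritParams attractorAtMu
#' @param profile a \linkS4class{MuProfile} from \code{\link{findMuStar}}.
#' @param healthyShape the healthy cycle \linkS4class{Shape} (mu = 0).
#' @param N resampled points per cycle (default 200).
#' @param transient transient discard used for period extraction (s).
#' @return a \linkS4class{PDCurve}.
#' @export
pdCurve <- function(c, params, injury, profile, plane, healthyShape, Iext,
                    N = 200, Tinit = 20, stride = 100, init = NULL,
                    transient = 5) {
    mus <- c(0, profile@muSamples)
    k <- length(mus)
    pd <- scl <- trn <- frq <- rep(NA_real_, k)
    healthyCentroid <- rowMeans(healthyShape@points)
    for (i in seq_len(k)) {
        res <- tryCatch(
            attractorAtMu(c, params, injury, mus[i], plane, Iext,
                          Tinit = Tinit, stride = stride, init = init,
                          transient = transient),
            error = function(e) NULL)
        if (is.null(res) || res$result$kind != "periodic") next
        per <- tryCatch(extractPeriod(res$pt, transient = transient),
                        error = function(e) NULL)
        if (is.null(per)) next
        shp <- resampleClosedCurve(per, N)
        fit <- phaseAlignedPD(healthyShape, shp)
        pd[i] <- fit$pd
        scl[i] <- fit$b
        trn[i] <- sqrt(sum((rowMeans(shp@points) - healthyCentroid)^2))
        frq[i] <- res$result$frequency
    }
    new("PDCurve", mu = mus, pd = pd, scaling = scl, translation = trn,
        frequency = frq, muStar = profile@muStar)
}

#' Normalise and average deficit curves on a common grid
#'
#' Each curve's amplitude axis is rescaled to [0, 1] by its maximum
#' sampled amplitude (which approaches \code{muStar}); for \code{which =
#' "pd"} the value axis is additionally rescaled to maximum 1 (scaling
#' and translation curves are left in their natural units). Curves are
#' then spline-interpolated onto a common grid and averaged pointwise.
#'
#' @param curves list of \linkS4class{PDCurve}s.
#' @param which one of \code{"pd"}, \code{"scaling"}, \code{"translation"}.
#' @param gridSize number of grid points (default 50).
#' @return data.frame with columns \code{grid}, \code{mean}, \code{sd}.
#' @export
normalizeAndAverage <- function(curves, which = c("pd", "scaling",
                                "translation"), gridSize = 50) {
    which <- match.arg(which)
    if (!length(curves)) stop("empty curve list")
    grid <- seq(0, 1, length.out = gridSize)
    vals <- vapply(curves, function(cv) {
        .normalizedCurve(cv, which, grid)
    }, numeric(gridSize))
    vals <- matrix(vals, nrow = gridSize)
    data.frame(grid = grid,
               mean = rowMeans(vals),
               sd = if (ncol(vals) > 1) apply(vals, 1, stats::sd)
                    else rep(0, gridSize))
}

.normalizedCurve <- function(cv, which, grid) {
    y <- slot(cv, which)
    ok <- !is.na(y)
    x <- cv@mu[ok]; y <- y[ok]
    if (length(x) < 2) stop("curve has fewer than 2 usable samples")
    x <- x / max(x)
    if (which == "pd" && max(y) > 0) y <- y / max(y)
    stats::spline(x, y, xout = grid, method = "natural")$y
}

#' Fixed-length feature vector from a deficit curve
#'
#' The normalised PD curve (amplitude axis scaled to [0, 1], value axis
#' to maximum 1) resampled to \code{gridSize} points; this is the feature
#' row used by the curve-shape classification tree, and is invariant to a
#' rescaling of \code{muStar}.
#'
#' @param curve a \linkS4class{PDCurve}.
#' @param gridSize feature length (default 20).
#' @return numeric vector of length \code{gridSize}.
#' @export
pdCurveFeatures <- function(curve, gridSize = 20) {
    .normalizedCurve(curve, "pd", seq(0, 1, length.out = gridSize))
}

#' Write a deficit curve as CSV (+ JSON metadata)
#'
#' @param curve a \linkS4class{PDCurve}.
#' @param path output CSV path; \code{muStar} goes to \code{<path>.json}.
#' @return invisibly, \code{path}.
#' @export
writePDCurve <- function(curve, path) {
    utils::write.csv(data.frame(mu = curve@mu, pd = curve@pd,
        scaling = curve@scaling, translation = curve@translation,
        frequency = curve@frequency), path, row.names = FALSE)
    .writeJSON(list(muStar = curve@muStar), paste0(path, ".json"))
    invisible(path)
}
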