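#' @include AllClasses.R
NULL

#' Calibrate the affine map from the neural plane onto a unit circle
#'
#' Finds the least-squares affine map (2 x 2 matrix \code{A} plus offset)
#' sending the healthy cycle shape onto the unit circle at matched
#' uniform phase. Target phases start at the angular position of the
#' shape's first point about its centroid and advance in the shape's own
#' traversal direction, which resolves the rotation ambiguity of the
#' behavioural plane: a unit circle input recovers the identity map. The
#' calibration is fitted once, from healthy dynamics, and reused
#' unchanged for all injured trajectories.
#'
#' @param healthy a closed non-degenerate \linkS4class{Shape}
#'   (uniformly resampled healthy cycle).
#' @param offset include an offset term? Default TRUE (affine); FALSE
#'   fits a pure linear map.
#' @return list of class \code{"CircleCalibration"} with \code{A} (2 x 2),
#'   \code{offset} (2-vector) and \code{residual} (root-mean-square fit
#'   error).
#' @export
calibrateCircleMap <- function(healthy, offset = TRUE) {
    P <- t(healthy@points)               # N x 2
    N <- nrow(P)
    ctr <- colMeans(P)
    rel <- sweep(P, 2, ctr)
    if (max(abs(rel)) == 0) stop("degenerate cycle")
    theta0 <- atan2(rel[1, 2], rel[1, 1])
    ## traversal direction from the signed area (shoelace)
    nxt <- c(2:N, 1)
    area <- sum(P[, 1] * P[nxt, 2] - P[nxt, 1] * P[, 2]) / 2
    dir <- if (area >= 0) 1 else -1
    th <- theta0 + dir * 2 * pi * (seq_len(N) - 1) / N
    target <- cbind(cos(th), sin(th))
    D <- if (offset) cbind(P, 1) else P
    coef <- qr.solve(D, target)          # (2|3) x 2
    A <- t(coef[1:2, , drop = FALSE])
    off <- if (offset) coef[3, ] else c(0, 0)
    pred <- D %*% coef
    structure(list(A = A, offset = off,
        residual = sqrt(mean(rowSums((pred - target)^2)))),
        class = "CircleCalibration")
}

#' Map plane dynamics onto behavioural (eigenworm) coefficients
#'
#' Applies the fixed circle calibration to a projected trajectory,
#' yielding the two behavioural mode coefficients over time; optionally
#' reconstructs body-angle profiles from a user-supplied two-mode
#' eigenworm basis over body segments. A fixed-point trajectory maps to
#' constant coefficients: a static posture, read as paralysis.
#'
#' @param pt a \linkS4class{PlaneTrajectory}.
#' @param cal a \code{"CircleCalibration"} from
#'   \code{\link{calibrateCircleMap}}.
#' @param basis optional segments x 2 eigenworm mode matrix (the basis is
#'   user-supplied; see \code{\link{syntheticEigenwormBasis}} for a
#'   clearly non-biological demo stand-in).
#' @return list with \code{times}, \code{coefficients} (T x 2) and, when
#'   a basis is given, \code{angles} (T x segments body-angle profiles).
#' @export
mapToBehavior <- function(pt, cal, basis = NULL) {
    stopifnot(inherits(cal, "CircleCalibration"))
    coefs <- t(cal$A %*% t(pt@xy) + cal$offset)
    colnames(coefs) <- c("c1", "c2")
    out <- list(times = pt@times, coefficients = coefs)
    if (!is.null(basis)) {
        basis <- as.matrix(basis)
        stopifnot(ncol(basis) == 2)
        out$angles <- coefs %*% t(basis)
    }
    out
}

#' Synthetic sinusoidal two-mode eigenworm basis
#'
#' A quadrature pair of sinusoidal body-angle profiles for demos and
#' tests. This is a synthetic stand-in, not a biological eigenworm basis
#' (which must be supplied by the user as a segments x 2 matrix).
#'
#' @param segments number of body segments (default 100).
#' @param wavelengths undulation wavelengths along the body (default 1.5).
#' @return segments x 2 matrix with columns \code{mode1}, \code{mode2}.
#' @export
syntheticEigenwormBasis <- function(segments = 100, wavelengths = 1.5) {
    sgrid <- seq(0, 1, length.out = segments)
    b <- cbind(mode1 = sin(2 * pi * wavelengths * sgrid),
               mode2 = cos(2 * pi * wavelengths * sgrid))
    b / rep(sqrt(colSums(b^2)), each = segments)
}
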