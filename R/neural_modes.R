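#' @include AllClasses.R
NULL

#' Two-mode response plane from motorneuron snapshots
#'
#' Collects the recorded motorneuron voltage snapshots (after discarding
#' an initial transient) into a neurons-by-time matrix and takes its
#' singular value decomposition. The first two left singular vectors are
#' the orthonormal modes spanning the response plane; the full singular
#' spectrum is retained for energy accounting. Snapshots are not
#' mean-centred by default (the decomposition acts on the raw snapshot
#' matrix); set \code{center = TRUE} for centred PCA. The sign of each
#' mode is fixed so its largest-magnitude component is positive, making
#' stored planes reproducible.
#'
#' The plane computed from the healthy network is reused unchanged to
#' project all injured dynamics.
#'
#' @param traj a \linkS4class{Trajectory} of the motorneuron subset.
#' @param transient initial time span to discard (s); default 5.
#' @param center mean-centre snapshots before the SVD? Default FALSE.
#' @return a \linkS4class{NeuralPlane}.
#' @export
computePlane <- function(traj, transient = 5, center = FALSE) {
    keep <- traj@times >= traj@times[1] + transient
    if (sum(keep) < 2) stop("need at least 2 post-transient snapshots")
    X <- t(traj@V[keep, , drop = FALSE])   # neurons x time
    if (center) X <- X - rowMeans(X)
    if (max(abs(X)) == 0) stop("rank-0 snapshot matrix")
    sv <- svd(X)
    modes <- sv$u[, 1:2, drop = FALSE]
    for (k in 1:2) {
        i <- which.max(abs(modes[, k]))
        if (modes[i, k] < 0) modes[, k] <- -modes[, k]
    }
    rownames(modes) <- colnames(traj@V)
    new("NeuralPlane", modes = modes, singularValues = sv$d,
        subset = colnames(traj@V))
}

#' Energy fraction captured by the leading k modes
#'
#' \code{sum_{i<=k} sigma_i^2 / sum_i sigma_i^2}.
#'
#' @param plane a \linkS4class{NeuralPlane}.
#' @param k number of leading modes (default 2).
#' @return fraction in (0, 1].
#' @export
energyFraction <- function(plane, k = 2) {
    stopifnot(k >= 1)
    d2 <- plane@singularValues^2
    sum(d2[seq_len(min(k, length(d2)))]) / sum(d2)
}

#' Project a trajectory onto the response plane
#'
#' \code{xy_t = (V_t . mode1, V_t . mode2)}; linear, and idempotent on
#' the plane.
#'
#' @param traj a \linkS4class{Trajectory} recorded over exactly the
#'   plane's neuron subset.
#' @param plane a \linkS4class{NeuralPlane}.
#' @return a \linkS4class{PlaneTrajectory}.
#' @export
projectOnPlane <- function(traj, plane) {
    if (!identical(colnames(traj@V), plane@subset))
        stop("trajectory subset does not match plane subset")
    xy <- traj@V %*% plane@modes
    colnames(xy) <- c("x", "y")
    new("PlaneTrajectory", times = traj@times, xy = xy)
}

#' Serialize a response plane
#'
#' Writes modes as CSV (neuron, mode1, mode2) and the singular spectrum
#' as a JSON sidecar \code{<path>.json}.
#'
#' @param plane a \linkS4class{NeuralPlane}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writePlane <- function(plane, path) {
    utils::write.csv(data.frame(neuron = plane@subset,
        mode1 = plane@modes[, 1], mode2 = plane@modes[, 2]),
        path, row.names = FALSE)
    .writeJSON(list(singularValues = plane@singularValues),
               paste0(path, ".json"))
    invisible(path)
}

#' Read a response plane written by \code{writePlane}
#'
#' @param path CSV path.
#' @return a \linkS4class{NeuralPlane}.
#' @export
readPlane <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    modes <- as.matrix(df[, c("mode1", "mode2")])
    dimnames(modes) <- list(df$neuron, NULL)
    new("NeuralPlane", modes = modes,
        singularValues = as.numeric(meta$singularValues),
        subset = df$neuron)
}
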