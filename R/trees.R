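#' @include AllClasses.R
NULL

#' Split paralysis endpoints along their principal axis
#'
#' Takes the SVD of the endpoint cloud (mean-centred by default), projects
#' each endpoint onto the leading principal mode, and labels projections
#' \code{>= threshold} as \code{"upper"} and the rest as \code{"lower"}.
#' The default threshold is -0.01. The leading mode's sign is fixed
#' (largest-magnitude component positive) so labels are reproducible.
#'
#' @param endpoints K x 2 matrix of plane coordinates (K >= 2).
#' @param threshold projection split value (default -0.01).
#' @param center mean-centre the cloud before the SVD? Default TRUE; the
#'   raw-projection variant is available with \code{center = FALSE}.
#' @return an \linkS4class{EndpointSet}.
#' @export
splitEndpoints <- function(endpoints, threshold = -0.01, center = TRUE) {
    endpoints <- as.matrix(endpoints)
    stopifnot(ncol(endpoints) == 2, nrow(endpoints) >= 2)
    X <- if (center) sweep(endpoints, 2, colMeans(endpoints)) else endpoints
    if (max(abs(X)) == 0) stop("degenerate endpoint cloud (zero variance)")
    sv <- svd(X)
    axis <- sv$v[, 1]
    if (axis[which.max(abs(axis))] < 0) axis <- -axis
    proj <- drop(X %*% axis)
    lab <- factor(ifelse(proj >= threshold, "upper", "lower"),
                  levels = c("upper", "lower"))
    new("EndpointSet", endpoints = endpoints, principalAxis = axis,
        projections = proj, labels = lab, threshold = threshold,
        centered = center)
}

.gini <- function(y, levs) {
    p <- tabulate(match(y, levs), length(levs)) / length(y)
    1 - sum(p^2)
}

## Best split of one node: exhaustive over features (in column order) and
## midpoint thresholds (in increasing order); ties broken by the first
## candidate found, i.e. lowest feature index then lowest threshold.
.bestSplit <- function(X, y, levs, minLeaf) {
    n <- length(y)
    parent <- .gini(y, levs)
    best <- NULL
    for (j in seq_len(ncol(X))) {
        xs <- X[, j]
        u <- sort(unique(xs))
        if (length(u) < 2) next
        thr <- (u[-1] + u[-length(u)]) / 2
        for (tt in thr) {
            left <- xs < tt
            nl <- sum(left)
            if (nl < minLeaf || n - nl < minLeaf) next
            dec <- parent - (nl / n) * .gini(y[left], levs) -
                ((n - nl) / n) * .gini(y[!left], levs)
            if (is.null(best) || dec > best$dec + 1e-12) {
                best <- list(j = j, thr = tt, dec = dec, left = left)
            }
        }
    }
    if (!is.null(best) && best$dec <= 1e-12) best <- NULL
    best
}

#' Fit a CART classification tree
#'
#' Greedy binary splitting on single features, choosing at each node the
#' (feature, midpoint threshold) pair that maximises the decrease in Gini
#' impurity; candidate thresholds are midpoints between consecutive
#' sorted unique feature values. A split is admissible only if both
#' children hold at least \code{minLeaf} training samples; nodes stop
#' when pure, when no admissible split decreases impurity, or when
#' smaller than \code{2 * minLeaf}. Ties in impurity decrease are broken
#' by lowest feature index, then lowest threshold, making fitted trees
#' deterministic. Leaf labels are the majority class (earlier factor
#' level on a tie). A single-class response yields a root-only tree.
#'
#' @param X numeric feature matrix or data.frame (rows = samples); column
#'   names become feature names.
#' @param y class labels (factor or character), one per row of \code{X}.
#' @param minLeaf minimum leaf size (>= 1).
#' @return a \linkS4class{TreeModel}.
#' @export
fitTree <- function(X, y, minLeaf = 1) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- factor(y)
    stopifnot(nrow(X) == length(y), minLeaf >= 1)
    levs <- levels(y)
    nodes <- data.frame(id = integer(), isLeaf = logical(),
        feature = character(), threshold = numeric(), left = integer(),
        right = integer(), pred = character(), n = integer(),
        decrease = numeric(), stringsAsFactors = FALSE)
    addNode <- function(rows) {
        id <- nrow(nodes) + 1L
        yy <- y[rows]
        pred <- levs[which.max(tabulate(match(yy, levs), length(levs)))]
        nodes[id, ] <<- list(id, TRUE, NA_character_, NA_real_, NA_integer_,
                             NA_integer_, pred, length(rows), 0)
        sp <- if (length(unique(yy)) > 1)
            .bestSplit(X[rows, , drop = FALSE], yy, levs, minLeaf) else NULL
        if (!is.null(sp)) {
            lid <- addNode(rows[sp$left])
            rid <- addNode(rows[!sp$left])
            nodes[id, "isLeaf"] <<- FALSE
            nodes[id, "feature"] <<- colnames(X)[sp$j]
            nodes[id, "threshold"] <<- sp$thr
            nodes[id, "left"] <<- lid
            nodes[id, "right"] <<- rid
            nodes[id, "decrease"] <<- sp$dec * length(rows) / nrow(X)
        }
        id
    }
    addNode(seq_len(nrow(X)))
    new("TreeModel", nodes = nodes, minLeaf = minLeaf,
        features = colnames(X), classes = levs)
}

#' Predict classes from a fitted tree
#'
#' @param tree a \linkS4class{TreeModel}.
#' @param X feature matrix with the training columns.
#' @return factor of predicted classes.
#' @export
predictTree <- function(tree, X) {
    X <- as.matrix(X)
    nodes <- tree@nodes
    out <- character(nrow(X))
    for (i in seq_len(nrow(X))) {
        id <- 1L
        while (!nodes$isLeaf[id]) {
            id <- if (X[i, nodes$feature[id]] < nodes$threshold[id])
                nodes$left[id] else nodes$right[id]
        }
        out[i] <- nodes$pred[id]
    }
    factor(out, levels = tree@classes)
}

#' k-fold cross-validation error of a CART fit
#'
#' Samples are assigned to folds uniformly at random (seeded, not
#' stratified); the reported error is the overall held-out
#' misclassification fraction.
#'
#' @inheritParams fitTree
#' @param folds number of folds (default 10).
#' @param seed integer RNG seed for the fold assignment.
#' @return misclassification fraction in [0, 1].
#' @export
kfoldCvError <- function(X, y, minLeaf = 1, folds = 10, seed = 1) {
    X <- as.matrix(X)
    y <- factor(y)
    n <- nrow(X)
    stopifnot(n >= folds)
    fold <- .withSeed(seed, sample(rep_len(seq_len(folds), n)))
    wrong <- 0L
    for (f in seq_len(folds)) {
        te <- fold == f
        tr <- fitTree(X[!te, , drop = FALSE], y[!te], minLeaf)
        wrong <- wrong + sum(predictTree(tr, X[te, , drop = FALSE]) != y[te])
    }
    wrong / n
}

#' Cross-validation error as a function of minimum leaf size
#'
#' @inheritParams kfoldCvError
#' @param sizes vector of minimum leaf sizes to evaluate.
#' @return data.frame with columns \code{size} and \code{cvError}, with
#'   attribute \code{"best"} = the size minimising the error (first on
#'   ties). A minimum leaf size of 40 is the study default for
#'   full-ensemble fits.
#' @export
leafSizeSweep <- function(X, y, sizes, folds = 10, seed = 1) {
    stopifnot(length(sizes) > 0)
    err <- vapply(sizes, function(s)
        kfoldCvError(X, y, minLeaf = s, folds = folds, seed = seed),
        numeric(1))
    out <- data.frame(size = sizes, cvError = err)
    attr(out, "best") <- sizes[which.min(err)]
    out
}

#' Shuffled-label cross-validation baseline
#'
#' Repeats the cross-validation with randomly permuted class labels,
#' giving the error expected when features carry no class information.
#'
#' @inheritParams kfoldCvError
#' @param trials number of shuffles (default 100).
#' @return list with \code{mean}, \code{sd} and the per-trial
#'   \code{errors}.
#' @export
shuffledBaseline <- function(X, y, minLeaf = 1, trials = 100, folds = 10,
                             seed = 1) {
    stopifnot(trials >= 2)
    errs <- vapply(seq_len(trials), function(t) {
        ys <- .withSeed(childSeed(seed, t), sample(y))
        kfoldCvError(X, ys, minLeaf = minLeaf, folds = folds,
                     seed = childSeed(seed, t + trials))
    }, numeric(1))
    list(mean = mean(errs), sd = stats::sd(errs), errors = errs)
}

#' Features implicated by a fitted tree
#'
#' Features appearing in splits, ordered by their total (sample-weighted)
#' Gini impurity decrease. A root-only tree implicates nothing.
#'
#' @param tree a \linkS4class{TreeModel}.
#' @param names optional feature renaming (named character vector).
#' @return data.frame with columns \code{feature} and \code{decrease},
#'   ordered by decreasing importance.
#' @export
implicatedFeatures <- function(tree, names = NULL) {
    sp <- tree@nodes[!tree@nodes$isLeaf, , drop = FALSE]
    if (!nrow(sp))
        return(data.frame(feature = character(), decrease = numeric()))
    agg <- tapply(sp$decrease, sp$feature, sum)
    out <- data.frame(feature = names(agg), decrease = as.numeric(agg))
    out <- out[order(-out$decrease), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(names))
        out$feature <- ifelse(out$feature %in% base::names(names),
                              names[out$feature], out$feature)
    out
}

#' Export a tree as text and JSON
#'
#' @param tree a \linkS4class{TreeModel}.
#' @param path base path; writes \code{<path>.txt} and \code{<path>.json}.
#' @return invisibly, the two paths.
#' @export
writeTree <- function(tree, path) {
    lines <- character()
    walk <- function(id, depth) {
        nd <- tree@nodes[id, ]
        pad <- strrep("  ", depth)
        if (nd$isLeaf) {
            lines <<- c(lines, sprintf("%s-> %s (n=%d)", pad, nd$pred, nd$n))
        } else {
            lines <<- c(lines, sprintf("%sif %s < %.6g:", pad, nd$feature,
                                       nd$threshold))
            walk(nd$left, depth + 1)
            lines <<- c(lines, sprintf("%selse:", pad))
            walk(nd$right, depth + 1)
        }
    }
    walk(1L, 0)
    writeLines(lines, paste0(path, ".txt"))
    .writeJSON(tree@nodes, paste0(path, ".json"))
    invisible(paste0(path, c(".txt", ".json")))
}
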