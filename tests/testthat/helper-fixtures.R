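## Shared fixtures. Heavy simulation artifacts are computed once per test
## process and cached.

.cache <- new.env(parent = emptyenv())

toyConnectome <- function(n = 3, Ng = NULL, Ns = NULL, polarity = NULL) {
    if (is.null(Ng)) Ng <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
    if (is.null(Ns)) Ns <- matrix(c(0, 1, 0, 0, 0, 2, 1, 0, 0), 3, 3)
    if (is.null(polarity)) polarity <- rep("excitatory", nrow(Ng))
    Connectome(Ng, Ns, polarity)
}

## healthy motif context: resting state, trajectory, plane, shape, frequency
motifContext <- function() {
    if (!is.null(.cache$motif)) return(.cache$motif)
    cx <- oscillatorMotif()
    params <- attr(cx, "params")
    Iext <- c(IN1 = attr(cx, "inputCurrent"), IN2 = attr(cx, "inputCurrent"))
    rest <- restingState(cx, params)
    traj <- simulateNetwork(cx, rest$params, Iext = Iext, T = 25,
                            init = rest$state)
    plane <- computePlane(traj)
    pt <- projectOnPlane(traj, plane)
    shape <- resampleClosedCurve(extractPeriod(pt), 200)
    .cache$motif <- list(cx = cx, params = rest$params, Iext = Iext,
                         rest = rest, traj = traj, plane = plane, pt = pt,
                         shape = shape, freq = cycleFrequency(pt, transient = 5))
    .cache$motif
}

## seeded K = 3 pipeline run on the motif, cached (reused by pipeline and
## acceptance tests)
motifEnsembleRun <- function() {
    if (!is.null(.cache$run)) return(.cache$run)
    cx <- oscillatorMotif()
    .cache$run <- runEnsemble(cx, attr(cx, "params"),
        syntheticSwellingDistribution(), K = 3,
        inputCurrent = attr(cx, "inputCurrent"), seed = 7,
        baselineTrials = 5, minLeaf = 1)
    .cache$run
}

## independent brute-force Procrustes oracle: grid over rotation angle with
## closed-form scale/translation at each angle (no SVD)
procrustesOracle <- function(A, B, nTheta = 2000) {
    XA <- t(A); XB <- t(B)
    muA <- colMeans(XA); muB <- colMeans(XB)
    Ac <- sweep(XA, 2, muA); Bc <- sweep(XB, 2, muB)
    ssA <- sum(Ac^2); ssB <- sum(Bc^2)
    best <- Inf
    for (th in seq(0, 2 * pi, length.out = nTheta)) {
        R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
        AR <- Ac %*% R
        b <- sum(AR * Bc) / ssA
        rss <- sum((Bc - b * AR)^2)
        if (rss < best) best <- rss
    }
    best / ssB          # scale-normalised dissimilarity
}

## independent exhaustive CART fit (same deterministic conventions),
## written as a flat recursion distinct from the package implementation
oracleTree <- function(X, y, minLeaf) {
    gini <- function(yy) 1 - sum((table(yy) / length(yy))^2)
    grow <- function(idx) {
        yy <- y[idx]
        node <- list(pred = names(sort(table(factor(yy, levels(y))),
                                       decreasing = TRUE))[1],
                     n = length(idx))
        if (length(unique(yy)) == 1) return(node)
        bestDec <- 1e-12; best <- NULL
        for (j in seq_len(ncol(X))) {
            v <- sort(unique(X[idx, j]))
            if (length(v) < 2) next
            for (thr in (v[-1] + v[-length(v)]) / 2) {
                L <- idx[X[idx, j] < thr]; R <- idx[X[idx, j] >= thr]
                if (length(L) < minLeaf || length(R) < minLeaf) next
                dec <- gini(yy) -
                    length(L) / length(idx) * gini(y[L]) -
                    length(R) / length(idx) * gini(y[R])
                if (dec > bestDec + 1e-12) {
                    bestDec <- dec
                    best <- list(j = j, thr = thr, L = L, R = R)
                }
            }
        }
        if (is.null(best)) return(node)
        node$feature <- colnames(X)[best$j]
        node$threshold <- best$thr
        node$left <- grow(best$L)
        node$right <- grow(best$R)
        node
    }
    grow(seq_along(y))
}

oraclePredict <- function(node, x) {
    while (!is.null(node$feature)) {
        node <- if (x[node$feature] < node$threshold) node$left else node$right
    }
    node$pred
}

## flatten a package TreeModel into (feature, threshold) pairs in preorder
treeSplitsPreorder <- function(tree) {
    nodes <- tree@nodes
    out <- list()
    walk <- function(id) {
        nd <- nodes[id, ]
        if (nd$isLeaf) { out[[length(out) + 1]] <<- list(leaf = nd$pred); return() }
        out[[length(out) + 1]] <<- list(feature = nd$feature, thr = nd$threshold)
        walk(nd$left); walk(nd$right)
    }
    walk(1L)
    out
}

oracleSplitsPreorder <- function(node) {
    out <- list()
    walk <- function(nd) {
        if (is.null(nd$feature)) { out[[length(out) + 1]] <<- list(leaf = nd$pred); return() }
        out[[length(out) + 1]] <<- list(feature = nd$feature, thr = nd$threshold)
        walk(nd$left); walk(nd$right)
    }
    walk(node)
    out
}
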