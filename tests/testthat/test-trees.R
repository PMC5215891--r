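test_that("endpoint clouds split along their principal axis at the threshold", {
    ## points on the line y = x -> axis (1,1)/sqrt(2)
    pts <- cbind(seq(-2, 2, length.out = 9), seq(-2, 2, length.out = 9))
    es <- splitEndpoints(pts)
    expect_equal(abs(es@principalAxis), rep(1 / sqrt(2), 2), tolerance = 1e-10)

    ## threshold is inclusive on the upper side
    es2 <- new("EndpointSet", endpoints = matrix(0, 2, 2),
               principalAxis = c(1, 0), projections = c(-0.01, -0.0100001),
               labels = factor(c("upper", "lower"),
                               levels = c("upper", "lower")),
               threshold = -0.01, centered = TRUE)
    expect_true(validObject(es2))
    expect_error(new("EndpointSet", endpoints = matrix(0, 2, 2),
        principalAxis = c(1, 0), projections = c(-0.01, 0),
        labels = factor(c("lower", "upper"), levels = c("upper", "lower")),
        threshold = -0.01, centered = TRUE))

    expect_error(splitEndpoints(matrix(1, 5, 2)), "degenerate")

    ## labels depend only on the cloud geometry, not ambient coordinates:
    ## re-fitting after a common rotation reproduces the same classes
    set.seed(9)
    cloud <- cbind(rnorm(40, sd = 2), rnorm(40, sd = 0.3))
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    a <- splitEndpoints(cloud)
    b <- splitEndpoints(cloud %*% R)
    expect_equal(as.character(endpointLabels(a)),
                 as.character(endpointLabels(b)))
})

test_that("CART fits separate separable data and respect leaf-size limits", {
    x <- matrix(c(1:10), ncol = 1, dimnames = list(NULL, "f1"))
    y <- rep(c("a", "b"), each = 5)
    tr <- fitTree(x, y, minLeaf = 1)
    expect_equal(as.character(predictTree(tr, x)), y)

    trRoot <- fitTree(x, y, minLeaf = 10)
    expect_equal(nrow(trRoot@nodes), 1)
    expect_true(trRoot@nodes$isLeaf[1])

    ## single-class response -> single leaf, not an error
    tr1 <- fitTree(x, rep("a", 10), minLeaf = 1)
    expect_equal(nrow(tr1@nodes), 1)

    ## structural audit: every leaf >= minLeaf on noisy data
    set.seed(10)
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
    yy <- factor(ifelse(X[, 2] + rnorm(50, sd = 0.6) > 0, "u", "l"))
    for (ml in c(3, 7, 15)) {
        fit <- fitTree(X, yy, minLeaf = ml)
        expect_true(all(fit@nodes$n[fit@nodes$isLeaf] >= ml))
    }
})

test_that("fitted trees match an exhaustive-split oracle exactly", {
    set.seed(12)
    for (trial in 1:5) {
        n <- sample(20:40, 1)
        X <- matrix(round(rnorm(2 * n), 2), n, 2,
                    dimnames = list(NULL, c("f1", "f2")))
        y <- factor(ifelse(X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.4) > 0,
                           "u", "l"))
        ml <- sample(c(2, 4, 6), 1)
        fit <- fitTree(X, y, minLeaf = ml)
        orc <- oracleTree(X, y, minLeaf = ml)
        a <- treeSplitsPreorder(fit)
        b <- oracleSplitsPreorder(orc)
        expect_equal(length(a), length(b))
        for (k in seq_along(a)) {
            if (!is.null(a[[k]]$feature)) {
                expect_equal(a[[k]]$feature, b[[k]]$feature)
                expect_equal(a[[k]]$thr, b[[k]]$thr)
            } else expect_equal(a[[k]]$leaf, b[[k]]$leaf)
        }
    }
})

test_that("tree predictions agree with rpart on clean separable data", {
    skip_if_not_installed("rpart")
    set.seed(13)
    X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- factor(ifelse(X[, 1] > 0.2, "u", "l"))
    fit <- fitTree(X, y, minLeaf = 5)
    rp <- rpart::rpart(y ~ ., data = data.frame(X, y = y),
                       method = "class",
                       control = rpart::rpart.control(minbucket = 5,
                           minsplit = 10, cp = 0, xval = 0))
    expect_equal(as.character(predictTree(fit, X)),
                 as.character(predict(rp, data.frame(X), type = "class")))
})

test_that("cross-validation error separates signal from noise", {
    set.seed(14)
    X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
    ySig <- factor(ifelse(X[, 1] > 0, "u", "l"))
    expect_lt(kfoldCvError(X, ySig, minLeaf = 5, seed = 2), 0.1)
    yNull <- factor(rep(c("u", "l"), 50))
    err <- kfoldCvError(X, yNull, minLeaf = 5, seed = 2)
    expect_gt(err, 0.3)    # about 0.5 up to sampling noise
})

test_that("leaf-size sweeps report one error per size and the argmin", {
    set.seed(15)
    X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("f1", "f2")))
    ## 2:1 class margin so every training fold keeps the same majority
    y <- factor(ifelse(X[, 1] > stats::quantile(X[, 1], 1 / 3), "u", "l"))
    sw <- leafSizeSweep(X, y, sizes = c(2, 10, 60), folds = 5, seed = 3)
    expect_equal(nrow(sw), 3)
    expect_true(attr(sw, "best") %in% sw$size)
    ## minLeaf = n forces the majority-class error exactly
    expect_equal(sw$cvError[sw$size == 60], mean(y != "u"))
})

test_that("shuffled baselines hover near chance for balanced labels", {
    set.seed(16)
    X <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- factor(rep(c("u", "l"), 30))
    bl <- shuffledBaseline(X, y, minLeaf = 5, trials = 20, folds = 5, seed = 4)
    expect_length(bl$errors, 20)
    expect_lt(abs(bl$mean - 0.5), 3 * max(bl$sd, 0.02))
    expect_gte(min(bl$errors), 0)
})

test_that("implicated features are ranked by total impurity decrease", {
    x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "f1"))
    root <- fitTree(x, rep("a", 10), minLeaf = 1)
    expect_equal(nrow(implicatedFeatures(root)), 0)

    y <- rep(c("a", "b"), each = 5)
    one <- fitTree(x, y, minLeaf = 5)
    imp <- implicatedFeatures(one)
    expect_equal(imp$feature, "f1")

    set.seed(17)
    X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("noise1", "sig", "noise2")))
    yy <- factor(ifelse(X[, "sig"] > 0, "u", "l"))
    imp2 <- implicatedFeatures(fitTree(X, yy, minLeaf = 10))
    expect_equal(imp2$feature[1], "sig")
})
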