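test_that("feature expansion produces the expected counts and hinge values", {
  set.seed(31)
  st <- stackFromMatrices(a = matrix(rnorm(100), 10, 10),
                          b = matrix(rnorm(100), 10, 10))
  bg <- 1:100
  f1 <- buildFeatures(subsetStack(st, "a"), 1:5, bg, classes = "linear")
  expect_equal(nrow(f1@defs), 1L)
  f5 <- buildFeatures(st, 1:5, bg,
                      classes = c("linear", "quadratic", "product"))
  expect_equal(nrow(f5@defs), 5L)  # 2 linear + 2 quadratic + 1 product
  fh <- buildFeatures(subsetStack(st, "a"), 1:5, bg, classes = "hinge",
                      hingeKnots = 10)
  expect_equal(nrow(fh@defs), 20L)  # both orientations at 10 knots
  # hinge values match the closed-form oracle on a probe grid
  X <- extractPredictors(subsetStack(st, "a"), bg)
  xmax <- max(X[, "a"]); xmin <- min(X[, "a"])
  Fm <- featureMatrix(fh, X)
  for (j in seq_len(nrow(fh@defs))) {
    k <- fh@defs$knot[j]
    oracle <- if (fh@defs$class[j] == "hinge")
      pmin(pmax((X[, "a"] - k) / (xmax - k), 0), 1)
    else pmin(pmax((k - X[, "a"]) / (k - xmin), 0), 1)
    expect_equal(unname(Fm[, j]), unname(oracle), tolerance = 1e-12)
  }
  # constant layers contribute no features
  stc <- stackFromMatrices(a = matrix(rnorm(100), 10, 10),
                           k = matrix(1, 10, 10))
  expect_warning(fc <- buildFeatures(stc, 1:5, bg, classes = "linear"),
                 "constant")
  expect_equal(fc@defs$layer, "a")
})

test_that("background sampling is reproducible, exhaustive at n >= valid, and uniform", {
  st <- stackFromMatrices(a = matrix(rnorm(100), 10, 10))
  expect_identical(sampleBackground(st, 5, seed = 9),
                   sampleBackground(st, 5, seed = 9))
  expect_identical(sampleBackground(st, 200, seed = 1), validCells(st))
  # inclusion frequency on a 10-cell mask with n = 5 is ~0.5
  m <- matrix(NA_real_, 2, 10); m[1, ] <- rnorm(10)
  st10 <- stackFromMatrices(a = m)
  counts <- integer(10)
  for (i in 1:1000) {
    s <- sampleBackground(st10, 5, seed = 10000 + i)
    counts[s] <- counts[s] + 1L
  }
  sdBin <- sqrt(1000 * 0.5 * 0.5)
  expect_true(all(abs(counts - 500) <= 3 * sdBin))
})

test_that("no-signal presences give the uniform fixed point p = 0.5", {
  set.seed(41)
  st <- stackFromMatrices(a = matrix(rnorm(64), 8, 8),
                          b = matrix(rnorm(64), 8, 8))
  bg <- validCells(st)
  m <- fitMaxent(st, bg, bg, classes = c("linear", "quadratic"),
                 betaMultiplier = 1)
  expect_true(all(m@lambda == 0))
  expect_equal(max(abs(m@q - 1 / length(bg))), 0, tolerance = 1e-12)
  p <- valuesAtCells(predictSuitability(m, st), bg)
  expect_equal(unname(p), rep(0.5, length(bg)), tolerance = 1e-9)
})

test_that("single-feature fit matches a dense 1-D brute-force search", {
  # 3 background cells with scaled feature values 0, 0.5, 1; presence
  # mass on the x = 1 cell; beta = 0 -> lambda solves mean matching
  Fbg <- matrix(c(0, 0.5, 1), 3, 1)
  fit <- fitGibbs(Fbg, presenceMeans = 0.9, beta = 0, tol = 1e-9,
                  maxIter = 2000)
  obj <- function(l) 0.9 * l - log(sum(exp(l * Fbg[, 1])))
  grid <- seq(-20, 20, by = 1e-3)
  best <- grid[which.max(vapply(grid, obj, 0))]
  expect_equal(fit$lambda, best, tolerance = 2e-3)
  expect_equal(sum(fit$q * Fbg[, 1]), 0.9, tolerance = 1e-6)
  expect_equal(sum(fit$q), 1, tolerance = 1e-12)
})

test_that("the optimiser attains the brute-force optimum on small instances", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(10:30, 1); J <- sample(2:4, 1)
    Fbg <- matrix(runif(n * J), n, J)
    # feasible presence means: an empirical mean over actual cells
    pbar <- colMeans(Fbg[sample(n, max(3, n %/% 3)), , drop = FALSE])
    beta <- runif(J, 0.001, 0.05)
    fit <- fitGibbs(Fbg, pbar, beta, tol = 1e-9, maxIter = 5000)
    penObj <- function(l) {
      eta <- as.numeric(Fbg %*% l)
      m <- max(eta)
      sum(pbar * l) - (m + log(sum(exp(eta - m)))) - sum(beta * abs(l))
    }
    # coarse lattice then a local refinement around the best lattice point
    pts <- as.matrix(expand.grid(rep(list(seq(-8, 8, by = 1)), J)))
    vals <- apply(pts, 1, penObj)
    ctr <- pts[which.max(vals), ]
    fine <- as.matrix(expand.grid(lapply(ctr, function(c0)
      seq(c0 - 1, c0 + 1, by = 0.05))))
    bestGrid <- max(apply(fine, 1, penObj))
    expect_gte(penObj(fit$lambda), bestGrid - 1e-4)
  }
})

test_that("every fitted model carries a valid KKT certificate", {
  land <- tinyLandscape()
  bg <- tinyBackground()
  m <- fitMaxent(land$stack, land$presences$cells, bg, hingeKnots = 8,
                 classes = c("linear", "quadratic", "product", "hinge"))
  cert <- maxentCertificate(m, tol = 1e-3)
  expect_equal(cert$qSum, 1, tolerance = 1e-9)
  expect_true(cert$ok)
  expect_gte(m@H, 0)
})

test_that("stronger regularisation never adds active features and kills all at the limit", {
  set.seed(61)
  st <- stackFromMatrices(a = matrix(rnorm(64), 8, 8),
                          b = matrix(rnorm(64), 8, 8))
  bg <- validCells(st)
  pres <- sampleBackground(st, 20, seed = 8)
  active <- vapply(c(0.5, 1, 2, 4, 50), function(mult) {
    m <- fitMaxent(st, pres, bg, classes = c("linear", "quadratic"),
                   betaMultiplier = mult)
    sum(m@lambda != 0)
  }, 0L)
  expect_true(all(diff(active) <= 0))
  expect_equal(active[length(active)], 0L)
})

test_that("prediction is consistent with training and monotone across outputs", {
  land <- tinyLandscape()
  bg <- tinyBackground()
  m <- fitMaxent(land$stack, land$presences$cells, bg, hingeKnots = 8,
                 classes = c("linear", "quadratic", "hinge"))
  # raw output over the training background reproduces the training q
  praw <- predictSuitability(m, land$stack, output = "raw")
  qPred <- valuesAtCells(praw, bg)
  expect_equal(qPred / sum(qPred), m@q, tolerance = 1e-9)
  # logistic and raw are rank-identical
  plog <- predictSuitability(m, land$stack, output = "logistic")
  cells <- validCells(land$stack)
  expect_equal(cor(valuesAtCells(praw, cells), valuesAtCells(plog, cells),
                   method = "spearman"), 1)
  pv <- valuesAtCells(plog, cells)
  expect_true(all(pv > 0 & pv < 1))
})

test_that("the fit is invariant under affine rescaling of an input layer", {
  set.seed(71)
  a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
  st1 <- stackFromMatrices(a = a, b = b)
  st2 <- stackFromMatrices(a = 100 * a - 7, b = b)
  bg <- validCells(st1)
  pres <- sampleBackground(st1, 25, seed = 3)
  m1 <- fitMaxent(st1, pres, bg, classes = c("linear", "hinge"),
                  hingeKnots = 5, tol = 1e-8)
  m2 <- fitMaxent(st2, pres, bg, classes = c("linear", "hinge"),
                  hingeKnots = 5, tol = 1e-8)
  expect_equal(m1@q, m2@q, tolerance = 1e-4)
})
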