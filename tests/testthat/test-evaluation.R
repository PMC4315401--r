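test_that("AUC matches closed forms and exhaustive pair counting", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucScore(rep(0.4, 5), rep(0.4, 7)), 0.5)
  # 3 wins, 0 ties of 4 pairs
  expect_equal(aucScore(c(0.7, 0.4), c(0.5, 0.3)), 0.75)
  # exhaustive pair enumeration on random score sets with ties
  set.seed(81)
  for (rep in 1:20) {
    p <- sample(seq(0, 1, 0.1), 6, replace = TRUE)
    b <- sample(seq(0, 1, 0.1), 9, replace = TRUE)
    pairs <- outer(p, b, function(x, y)
      (x > y) + 0.5 * (x == y))
    expect_equal(aucScore(p, b), mean(pairs))
  }
  expect_error(aucScore(numeric(), 1), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  p <- rnorm(40, 1); b <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(p, b),
    direction = "<", quiet = TRUE)))
  expect_equal(aucScore(p, b), ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(83)
  p <- rnorm(20, 0.5); b <- rnorm(30)
  a0 <- aucScore(p, b)
  expect_equal(aucScore(exp(p), exp(b)), a0)
  expect_equal(aucScore(2 * p - 5, 2 * b - 5), a0)
})

test_that("replicate evaluation is deterministic and recovers a strong niche", {
  land <- tinyLandscape()
  bg <- tinyBackground()
  ev1 <- replicateEvaluation(land$stack, land$presences$cells, bg,
                             replicates = 3, seed = 7, hingeKnots = 6,
                             classes = c("linear", "quadratic", "hinge"))
  ev2 <- replicateEvaluation(land$stack, land$presences$cells, bg,
                             replicates = 3, seed = 7, hingeKnots = 6,
                             classes = c("linear", "quadratic", "hinge"))
  expect_identical(ev1$replicates, ev2$replicates)
  expect_identical(gridValues(ev1$meanMap), gridValues(ev2$meanMap))
  expect_gt(ev1$summary$meanTestAUC, 0.9)
  expect_gt(ev1$summary$meanTrainAUC, ev1$summary$meanTestAUC - 0.05)
})

test_that("uninformative landscapes score AUC near one half", {
  set.seed(84)
  st <- stackFromMatrices(noise = matrix(rnorm(400), 20, 20))
  bg <- validCells(st)
  aucs <- replicate(20, {
    pres <- sample(bg, 40)
    sp <- sample(pres)
    m <- fitMaxent(st, sp[1:30], bg, classes = "linear")
    aucScore(valuesAtCells(predictSuitability(m, st), sp[31:40]),
             valuesAtCells(predictSuitability(m, st), bg))
  })
  # 3 SD band around 0.5 for the Monte-Carlo mean
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.02)
})

test_that("jackknife isolates the driving variable", {
  set.seed(85)
  a <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  noise <- matrix(rnorm(400), 20, 20)
  st <- stackFromMatrices(a = a, acopy = a + 1e-6 * noise, noise = noise)
  bg <- validCells(st)
  # presences generated by variable a alone
  truth <- geoGrid(plogis(8 * (a - 0.7)), 110, 30, 0.1)
  pres <- unique(sampleOccurrences(st, truth, n = 150, seed = 4)$cell)
  jk <- jackknifeAUC(st, pres, bg, seed = 6, classes = c("linear", "quadratic"))
  full <- attr(jk, "aucFull")
  aOnly <- jk$aucOnly[jk$variable == "a"]
  expect_gt(aOnly, full - 0.05)
  # dropping a keeps its information through the near-copy
  expect_gt(jk$aucWithout[jk$variable == "a"], full - 0.05)
  # noise alone carries no signal
  expect_lt(abs(jk$aucOnly[jk$variable == "noise"] - 0.5), 0.15)
  expect_error(jackknifeAUC(subsetStack(st, "a"), pres, bg), "2 variables")
})

test_that("permutation importance concentrates on the informative variable and sums to 100", {
  set.seed(86)
  a <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  st <- stackFromMatrices(a = a, noise = matrix(rnorm(400), 20, 20))
  bg <- validCells(st)
  truth <- geoGrid(plogis(8 * (a - 0.7)), 110, 30, 0.1)
  pres <- unique(sampleOccurrences(st, truth, n = 150, seed = 4)$cell)
  m <- fitMaxent(st, pres, bg, classes = c("linear", "quadratic"))
  imp <- permutationImportance(m, st, pres, bg, seed = 5)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_gt(imp[["a"]], 85)
  expect_true(all(imp >= 0))
})

test_that("pruning respects its threshold and never removes everything", {
  set.seed(87)
  a <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  st <- stackFromMatrices(a = a, noise = matrix(rnorm(400), 20, 20))
  bg <- validCells(st)
  truth <- geoGrid(plogis(8 * (a - 0.7)), 110, 30, 0.1)
  pres <- unique(sampleOccurrences(st, truth, n = 150, seed = 4)$cell)
  pr0 <- pruneAndRefit(st, pres, bg, threshold = 0, seed = 5,
                       classes = c("linear", "quadratic"))
  expect_equal(length(pr0$dropped), 0L)
  expect_identical(layerNames(pr0$stack), layerNames(st))
  pr <- pruneAndRefit(st, pres, bg, threshold = 1, seed = 5,
                      classes = c("linear", "quadratic"))
  expect_true("noise" %in% pr$dropped)
  expect_error(pruneAndRefit(st, pres, bg, threshold = 101, seed = 5,
                             classes = c("linear", "quadratic")),
               "every variable")
})

test_that("response curves reflect the fitted dependence", {
  set.seed(88)
  a <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  b <- matrix(rnorm(400), 20, 20)
  st <- stackFromMatrices(a = a, b = b)
  bg <- validCells(st)
  # uniform model -> flat at 0.5
  mU <- fitMaxent(st, bg, bg, classes = "linear")
  rcU <- responseCurve(mU, st, bg, "a", gridPoints = 25)
  expect_equal(rcU$mean, rep(0.5, 25), tolerance = 1e-9)
  # positive monotone dependence -> non-decreasing curve
  truth <- geoGrid(plogis(8 * (a - 0.7)), 110, 30, 0.1)
  pres <- unique(sampleOccurrences(st, truth, n = 150, seed = 4)$cell)
  mA <- fitMaxent(st, pres, bg, classes = "linear")
  rcA <- responseCurve(mA, st, bg, "a", gridPoints = 25)
  expect_true(all(diff(rcA$mean) >= -1e-9))
  # a known unimodal niche puts the curve maximum near the optimum
  landNiche <- geoGrid(plogis(4 - ((a - 0.5) / 0.08)^2), 110, 30, 0.1)
  presN <- unique(sampleOccurrences(st, landNiche, n = 250, seed = 9)$cell)
  mN <- fitMaxent(st, presN, bg, classes = c("linear", "quadratic"))
  rcN <- responseCurve(mN, st, bg, "a", gridPoints = 41)
  vstep <- diff(rcN$value[1:2])
  expect_lt(abs(rcN$value[which.max(rcN$mean)] - 0.5), 2 * vstep + 1e-9)
  expect_error(responseCurve(mN, st, bg, "zz"), "unknown variable")
})
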