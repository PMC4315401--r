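test_that("noise-free climate is an exact gradient with the stated seasonal range", {
  cl <- makeClimate(nrow = 10, ncol = 10, noiseSD = 0, precNoiseSD = 0,
                    lonGradient = 0, seasonalAmp = 12, seed = 5)
  # no spatial structure beyond latitude: rows constant across columns
  expect_equal(cl@tmin[, 1, 1], cl@tmin[, 10, 1])
  # seasonal range of the monthly mean temperature is exactly 2A
  tavg <- (cl@tmin + cl@tmax) / 2
  rng <- apply(tavg, c(1, 2), function(v) diff(range(v)))
  expect_equal(as.vector(rng), rep(24, 100), tolerance = 1e-12)
  expect_true(all(cl@tmax > cl@tmin))
  expect_true(all(cl@prec >= 0))
})

test_that("generators are deterministic in their seed", {
  c1 <- makeClimate(nrow = 20, ncol = 20, seed = 7)
  c2 <- makeClimate(nrow = 20, ncol = 20, seed = 7)
  expect_identical(c1@tmin, c2@tmin)
  expect_identical(c1@prec, c2@prec)
  r1 <- makeRivers(nrow = 30, ncol = 30, nSources = 20, seed = 8)
  r2 <- makeRivers(nrow = 30, ncol = 30, nSources = 20, seed = 8)
  expect_identical(r1@lines, r2@lines)
  expect_identical(r1@attrs, r2@attrs)
  land1 <- syntheticLandscape(seed = 3, nrow = 30, ncol = 30,
                              nSources = 30, nOcc = 50)
  land2 <- syntheticLandscape(seed = 3, nrow = 30, ncol = 30,
                              nSources = 30, nOcc = 50)
  expect_identical(land1$survey$count, land2$survey$count)
  expect_identical(land1$occurrences, land2$occurrences)
})

test_that("a single source yields one order-1 line", {
  net <- makeRivers(nrow = 20, ncol = 20, nSources = 1, seed = 9)
  expect_equal(length(net@lines), 1L)
  expect_equal(net@attrs$order, 1L)
})

test_that("Strahler orders match an independent post-order traversal", {
  strahlerOracle <- function(topology) {
    kids <- split(topology$cells[!is.na(topology$downstream[topology$cells])],
                  topology$downstream[topology$cells][
                    !is.na(topology$downstream[topology$cells])])
    rec <- function(cell) {
      ch <- kids[[as.character(cell)]]
      if (is.null(ch)) return(1L)
      ords <- vapply(ch, rec, 0L)
      k <- max(ords)
      if (sum(ords == k) >= 2) k + 1L else k
    }
    vapply(topology$cells, rec, 0L)
  }
  for (s in c(4, 5)) {
    net <- makeRivers(nrow = 40, ncol = 40, nSources = 30, seed = s)
    topo <- attr(net, "topology")
    oracle <- strahlerOracle(topo)
    expect_identical(topo$order[topo$cells], oracle)
    expect_true(all(net@attrs$order >= 1))
  }
})

test_that("occurrence sampling follows the truth field", {
  st <- stackFromMatrices(a = matrix(rnorm(25), 5, 5))
  # mass on one cell -> every record lands there
  w <- matrix(0, 5, 5); w[3, 4] <- 1
  point <- geoGrid(w, 110, 30, 0.1)
  occ <- sampleOccurrences(st, point, n = 50, seed = 2)
  expect_true(all(occ$cell == cellFromXY(st@layers$a, 110.35, 29.75)))
  # records are jittered inside the cell
  expect_true(all(abs(occ$longitude - 110.35) < 0.05))
  # uniform truth -> near-uniform empirical frequencies
  unif <- geoGrid(matrix(1, 5, 5), 110, 30, 0.1)
  occU <- sampleOccurrences(st, unif, n = 1000, seed = 3)
  freq <- tabulate(occU$cell, 25)
  sdBin <- sqrt(1000 * (1 / 25) * (24 / 25))
  expect_true(all(abs(freq - 40) <= 3.5 * sdBin))
  expect_identical(sampleOccurrences(st, unif, n = 20, seed = 4),
                   sampleOccurrences(st, unif, n = 20, seed = 4))
  zero <- geoGrid(matrix(0, 5, 5), 110, 30, 0.1)
  expect_error(sampleOccurrences(st, zero, n = 5, seed = 1), "zero")
})

test_that("survey counts are Poisson around the true density", {
  sec <- riverNetwork(list(cbind(x = c(110, 110), y = c(29, 29.8993))),
                      data.frame(id = 1, order = 6, name = "s1"))
  len <- geodesicLength(sec@lines[[1]])
  expect_equal(len, 100, tolerance = 1e-3)
  expect_equal(simulateSurvey(sec, dTrue = 0, seed = 1)$count, 0L)
  counts <- vapply(1:2000, function(i)
    simulateSurvey(sec, dTrue = 0.5, seed = i)$count, 0L)
  se <- sqrt(50 / 2000)
  expect_lt(abs(mean(counts) - 0.5 * len), 3 * se * 1.01 + 0.05)
  d <- simulateSurvey(sec, dTrue = 0.5, seed = 9)
  expect_true(all(d$count / d$length_km >= 0))
})
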