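# fixtures are built in code; the tiny landscape is generated once per
# test run and shared across files

grid1 <- function(values, xmin = 110, ymax = 30, cellsize = 0.1)
  geoGrid(values, xmin = xmin, ymax = ymax, cellsize = cellsize)

stackFromMatrices <- function(..., kind = "continuous",
                              xmin = 110, ymax = 30, cellsize = 0.1) {
  mats <- list(...)
  envStack(lapply(mats, grid1, xmin = xmin, ymax = ymax,
                  cellsize = cellsize), kind)
}

# constant-month climate helper
constantClimate <- function(tmin, tmax, prec, nrow = 2, ncol = 2) {
  monthlyClimate(array(tmin, c(nrow, ncol, 12)),
                 array(tmax, c(nrow, ncol, 12)),
                 array(prec, c(nrow, ncol, 12)),
                 xmin = 110, ymax = 30, cellsize = 0.1)
}

# climate from per-month vectors (same value at every cell)
vectorClimate <- function(tminV, tmaxV, precV, nrow = 2, ncol = 2) {
  mk <- function(v) {
    a <- array(0, c(nrow, ncol, 12))
    for (m in 1:12) a[, , m] <- v[m]
    a
  }
  monthlyClimate(mk(tminV), mk(tmaxV), mk(precV),
                 xmin = 110, ymax = 30, cellsize = 0.1)
}

# independent brute-force oracle for quarter-based bioclim layers
quarterOracle <- function(tav, pre) {
  qt <- sapply(1:12, function(w) mean(tav[((w - 1):(w + 1)) %% 12 + 1]))
  qp <- sapply(1:12, function(w) sum(pre[((w - 1):(w + 1)) %% 12 + 1]))
  list(bio8 = qt[which.max(qp)], bio9 = qt[which.min(qp)],
       bio10 = max(qt), bio11 = min(qt),
       bio16 = max(qp), bio17 = min(qp),
       bio18 = qp[which.max(qt)], bio19 = qp[which.min(qt)])
}

tinyLandscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- syntheticLandscape(seed = 42, nOcc = 200)
    cache
  }
})

tinyBackground <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sampleBackground(tinyLandscape()$stack, 2000, seed = 43)
    cache
  }
})
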