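# smooth unit-variance Gaussian random field: white noise convolved with
# a separable Gaussian kernel (reflected at the edges)
gaussianField <- function(nrow, ncol, range = 8) {
  w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  smooth1 <- function(v) {
    h <- min(ceiling(3 * range), length(v) - 1L)
    if (h < 1) return(v)
    k <- stats::dnorm(-h:h, sd = range)
    k <- k / sum(k)
    pv <- c(rev(v[seq_len(h)]), v, rev(v)[seq_len(h)])
    stats::convolve(pv, rev(k), type = "filter")
  }
  w <- apply(w, 2, smooth1)
  w <- t(apply(w, 1, smooth1))
  s <- stats::sd(w)
  if (s == 0) return(w * 0)
  (w - mean(w)) / s
}

#' Generate synthetic monthly climate grids
#'
#' Monthly minimum/maximum temperature and precipitation built from a
#' latitudinal gradient, a smooth Gaussian random field (shared across
#' months) and a seasonal sinusoid; tmax = tmin + a positive diurnal
#' range everywhere and precipitation is clipped at zero. With
#' \code{noiseSD = 0} the fields are exact deterministic gradients, and
#' the range over months of each cell's monthly mean temperature is
#' exactly twice \code{seasonalAmp}.
#'
#' @param nrow,ncol grid dimensions (default 100 x 100).
#' @param xmin,ymax,cellsize geometry (default 0.01-degree cells).
#' @param meanTemp annual mean temperature at the grid's mid latitude
#'   (degrees C).
#' @param latGradient temperature change per degree latitude.
#' @param seasonalAmp seasonal half-amplitude (degrees C; January
#'   coldest).
#' @param diurnalRange tmax - tmin (degrees C, > 0).
#' @param noiseSD SD of the spatial noise field (degrees C).
#' @param precMean,precAmp,precNoiseSD monthly precipitation mean,
#'   seasonal half-amplitude (January driest) and spatial noise SD (mm).
#' @param lonGradient precipitation change per degree longitude (mm;
#'   east wetter, emulating continentality).
#' @param smoothness correlation range of the noise fields, in cells.
#' @param seed RNG seed.
#' @return A \linkS4class{MonthlyClimate}.
#' @export
makeClimate <- function(nrow = 100, ncol = 100, xmin = 110, ymax = 30,
                        cellsize = 0.01, meanTemp = 8, latGradient = 8,
                        seasonalAmp = 12, diurnalRange = 8, noiseSD = 2,
                        precMean = 80, precAmp = 50, precNoiseSD = 25,
                        lonGradient = 60, smoothness = 8, seed = 1) {
  stopifnot(nrow >= 1, ncol >= 1, diurnalRange > 0)
  set.seed(seed)
  lat <- ymax - (seq_len(nrow) - 0.5) * cellsize
  latDev <- matrix(lat - mean(lat), nrow, ncol)
  tfield <- if (noiseSD > 0) noiseSD * gaussianField(nrow, ncol, smoothness)
            else matrix(0, nrow, ncol)
  pfield <- if (precNoiseSD > 0)
    precNoiseSD * gaussianField(nrow, ncol, smoothness)
    else matrix(0, nrow, ncol)
  lon <- xmin + (seq_len(ncol) - 0.5) * cellsize
  pfield <- pfield + matrix(lonGradient * (lon - mean(lon)), nrow, ncol,
                            byrow = TRUE)
  tavgBase <- meanTemp + latGradient * latDev + tfield
  tmin <- array(0, c(nrow, ncol, 12))
  tmax <- array(0, c(nrow, ncol, 12))
  prec <- array(0, c(nrow, ncol, 12))
  for (m in 1:12) {
    season <- -cos(2 * pi * (m - 1) / 12)
    tmin[, , m] <- tavgBase + seasonalAmp * season - diurnalRange / 2
    tmax[, , m] <- tmin[, , m] + diurnalRange
    prec[, , m] <- pmax(precMean + precAmp * season + pfield, 0)
  }
  monthlyClimate(tmin, tmax, prec, xmin, ymax, cellsize)
}

#' Generate a dendritic river network with Strahler orders
#'
#' Grows rivers by steepest descent (8-neighbour) on a synthetic
#' elevation field (an east-sloping gradient plus a smooth random
#' field, so trunk rivers run broadly west to east) from randomly
#' placed sources; a walk joining an earlier river terminates at the
#' junction. Strahler orders follow from the
#' topology: headwaters are order 1, a junction of equal orders k
#' yields k + 1, unequal orders yield their maximum.
#'
#' @inheritParams makeClimate
#' @param nSources number of headwater sources (>= 1).
#' @param reliefSD relief of the random field relative to the gradient.
#' @return A \linkS4class{RiverNetwork}; \code{attr(, "topology")}
#'   carries the per-cell downstream links and orders.
#' @export
makeRivers <- function(nrow = 100, ncol = 100, xmin = 110, ymax = 30,
                       cellsize = 0.01, nSources = 150, reliefSD = 15,
                       smoothness = 10, seed = 1) {
  stopifnot(nSources >= 1)
  set.seed(seed)
  lon <- xmin + (seq_len(ncol) - 0.5) * cellsize
  elev <- matrix(100 * (max(lon) - lon) / max(cellsize, diff(range(lon))),
                 nrow, ncol, byrow = TRUE) +
    reliefSD * gaussianField(nrow, ncol, smoothness)
  if (diff(range(elev)) < 1e-9) stop("degenerate flat elevation field")
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  idx <- function(r, c) (r - 1) * ncol + c
  downstream <- rep(NA_integer_, nrow * ncol)
  visited <- rep(FALSE, nrow * ncol)
  steepest <- function(r, c) {
    rr <- r + nbr$dr; cc <- c + nbr$dc
    ok <- rr >= 1 & rr <= nrow & cc >= 1 & cc <= ncol
    if (!any(ok)) return(NA_integer_)
    e <- elev[cbind(rr[ok], cc[ok])]
    b <- which.min(e)
    if (e[b] >= elev[r, c]) return(NA_integer_)
    idx(rr[ok][b], cc[ok][b])
  }
  top <- stats::quantile(elev, 0.7)
  pool <- which(t(elev) >= top)   # row-major indices of high ground
  sources <- sample(pool, min(nSources, length(pool)))
  for (s in sources) {
    cur <- s
    if (visited[cur]) next
    repeat {
      visited[cur] <- TRUE
      r <- (cur - 1) %/% ncol + 1; c <- (cur - 1) %% ncol + 1
      nxt <- steepest(r, c)
      if (is.na(nxt)) break
      downstream[cur] <- nxt
      if (visited[nxt]) break
      cur <- nxt
    }
  }
  cells <- which(visited)
  children <- split(cells[!is.na(downstream[cells])],
                    downstream[cells][!is.na(downstream[cells])])
  ord <- rep(NA_integer_, nrow * ncol)
  elevVec <- as.vector(t(elev))  # row-major
  for (cell in cells[order(-elevVec[cells])]) {
    ch <- children[[as.character(cell)]]
    ch <- ch[!is.na(ord[ch])]
    ord[cell] <- if (!length(ch)) 1L else {
      k <- max(ord[ch])
      if (sum(ord[ch] == k) >= 2) k + 1L else k
    }
  }
  # a junction has >= 2 upstream children; split polylines there
  nChildren <- rep(0L, nrow * ncol)
  tb <- table(downstream[cells])
  nChildren[as.integer(names(tb))] <- as.integer(tb)
  isStart <- visited & (nChildren == 0 | nChildren >= 2)
  lines <- list(); orders <- integer()
  ctr <- function(cell) {
    r <- (cell - 1) %/% ncol + 1; c <- (cell - 1) %% ncol + 1
    c(xmin + (c - 0.5) * cellsize, ymax - (r - 0.5) * cellsize)
  }
  for (s in which(isStart)) {
    path <- s; cur <- s
    while (!is.na(downstream[cur])) {
      cur <- downstream[cur]
      path <- c(path, cur)
      if (nChildren[cur] >= 2) break
    }
    if (length(path) < 2) next
    lines[[length(lines) + 1]] <- {
      m <- t(vapply(path, ctr, numeric(2)))
      colnames(m) <- c("x", "y"); m
    }
    orders <- c(orders, ord[s])
  }
  net <- riverNetwork(lines, data.frame(id = seq_along(lines),
                                        order = orders,
                                        name = sprintf("river_%03d",
                                                       seq_along(lines))))
  attr(net, "topology") <- list(cells = cells, downstream = downstream,
                                order = ord, nChildren = nChildren)
  net
}

#' True suitability field of a synthetic niche
#'
#' A logistic suitability over chosen layers with Gaussian-bump terms:
#' \eqn{s(x) = logistic(a_0 - \sum_i ((x_i - opt_i)/width_i)^2)}.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param niche list with \code{layers}, \code{opt}, \code{width} and
#'   intercept \code{a0}.
#' @return A \linkS4class{GeoGrid} of true probabilities in (0, 1).
#' @export
trueSuitability <- function(stack, niche) {
  g <- stackGeometry(stack)
  cells <- validCells(stack)
  X <- extractPredictors(stack, cells)
  z <- rep(niche$a0, length(cells))
  for (i in seq_along(niche$layers))
    z <- z - ((X[, niche$layers[i]] - niche$opt[i]) / niche$width[i])^2
  v <- rep(NA_real_, g$nrow * g$ncol)
  v[cells] <- stats::plogis(z)
  geoGrid(matrix(v, g$nrow, g$ncol, byrow = TRUE), g$xmin, g$ymax,
          g$cellsize)
}

#' Sample occurrence records from a known truth
#'
#' Draws \code{n} records (with replacement) from the valid cells with
#' probability proportional to true suitability times an optional
#' observation-bias field, jittering coordinates uniformly within each
#' cell.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param suitability \linkS4class{GeoGrid} of true suitability (e.g.
#'   [trueSuitability()]).
#' @param n number of records.
#' @param bias optional \linkS4class{GeoGrid} of relative observation
#'   effort (uniform when NULL).
#' @param seed RNG seed.
#' @return data.frame (longitude, latitude, cell).
#' @export
sampleOccurrences <- function(stack, suitability, n = 100, bias = NULL,
                              seed = 1) {
  set.seed(seed)
  cells <- validCells(stack)
  w <- valuesAtCells(suitability, cells)
  if (!is.null(bias)) w <- w * valuesAtCells(bias, cells)
  if (all(w <= 0)) stop("all sampling weights are zero")
  drawn <- sample(cells, n, replace = TRUE, prob = w)
  ctr <- xyFromCell(stack@layers[[1]], drawn)
  cs <- stackGeometry(stack)$cellsize
  data.frame(longitude = ctr[, 1] + stats::runif(n, -0.499, 0.499) * cs,
             latitude = ctr[, 2] + stats::runif(n, -0.499, 0.499) * cs,
             cell = drawn)
}

#' Cut survey sections from a river network
#'
#' Takes the longest lines (optionally after clipping to a habitat
#' ring set) as survey sections, splitting long lines so that roughly
#' \code{nSections} comparable sections result.
#'
#' @param network a \linkS4class{RiverNetwork}.
#' @param nSections number of sections wanted.
#' @param rings optional ring set to clip to first.
#' @return A \linkS4class{RiverNetwork} of section sub-lines.
#' @export
makeSections <- function(network, nSections = 8, rings = NULL) {
  if (!is.null(rings)) network <- clipToPolygons(network, rings)$network
  len <- vapply(network@lines, geodesicLength, 0)
  keep <- len > 0.1   # drop degenerate corner slivers (< 100 m)
  network <- new("RiverNetwork", lines = network@lines[keep],
                 attrs = network@attrs[keep, , drop = FALSE])
  if (!length(network@lines)) stop("no river lines to section")
  len <- len[keep]
  ordIdx <- order(-len)
  lines <- list(); orders <- integer()
  for (i in ordIdx) {
    line <- network@lines[[i]]
    # split lines with many vertices into two sections
    if (nrow(line) >= 20 && length(lines) + 2 <= nSections) {
      h <- floor(nrow(line) / 2)
      lines <- c(lines, list(line[1:h, ], line[h:nrow(line), ]))
      orders <- c(orders, rep(network@attrs$order[i], 2))
    } else {
      lines <- c(lines, list(line))
      orders <- c(orders, network@attrs$order[i])
    }
    if (length(lines) >= nSections) break
  }
  riverNetwork(lines, data.frame(id = seq_along(lines), order = orders,
                                 name = sprintf("section_%02d",
                                                seq_along(lines))))
}

#' Simulate line-transect survey counts
#'
#' Counts per section are Poisson with mean \code{dTrue} x section
#' length (km).
#'
#' @param sections a \linkS4class{RiverNetwork} of survey sections.
#' @param dTrue true density (birds per km, >= 0).
#' @param seed RNG seed.
#' @return A \code{surveyTable} (see [surveyTable()]).
#' @export
simulateSurvey <- function(sections, dTrue = 0.5, seed = 1) {
  set.seed(seed)
  len <- vapply(sections@lines, geodesicLength, 0)
  if (any(len <= 0)) stop("zero-length section")
  surveyTable(river = sections@attrs$name, section = sections@attrs$name,
              length_km = len,
              count = stats::rpois(length(len), dTrue * len),
              source = "synthetic")
}

#' Generate a complete synthetic landscape with known truth
#'
#' Composes the generators into the full study input set: monthly
#' climate, the derived bioclim predictor stack, a known logistic
#' niche and its true suitability, occurrence records sampled from it,
#' a dendritic river network, survey sections with Poisson counts, and
#' the true population quantities. The truth analogue of the pipeline
#' estimand is computed by applying the pipeline's own thresholding
#' rule to the true suitability (threshold = mean true suitability at
#' the occurrence cells), giving \code{LTrue} and
#' \code{NTrue = dTrue x LTrue}.
#'
#' @inheritParams makeClimate
#' @param nOcc number of occurrence records (default 100).
#' @param dTrue true density (birds per km).
#' @param nSources headwater sources for the river network.
#' @param minOrder stream-order cutoff used for the true river length.
#' @param layers bioclim layers kept in the predictor stack.
#' @param niche niche definition (see [trueSuitability()]); the default
#'   is a strong two-variable niche on annual mean temperature (bio_1)
#'   and driest-quarter precipitation (bio_17).
#' @param bias optional observation-bias field.
#' @param seed master seed; all component seeds derive from it.
#' @return List with climate, stack, niche, truth (GeoGrid),
#'   occurrences, presences (cleaned), rivers, sections, survey, and
#'   the truth scalars (dTrue, tTrue, LTrue, NTrue).
#' @export
syntheticLandscape <- function(seed = 1, nrow = 100, ncol = 100,
                               nOcc = 100, dTrue = 0.5, nSources = 150,
                               minOrder = 2,
                               layers = c("bio_1", "bio_6", "bio_11",
                                          "bio_17"),
                               niche = NULL, bias = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4)
  climate <- makeClimate(nrow = nrow, ncol = ncol, seed = seeds[1])
  bio <- deriveBioclim(climate)
  stack <- envStack(bio[layers])
  if (is.null(niche)) {
    X <- extractPredictors(stack, validCells(stack))
    niche <- list(layers = c("bio_1", "bio_11"),
                  opt = c(stats::quantile(X[, "bio_1"], 0.75, names = FALSE),
                          stats::quantile(X[, "bio_11"], 0.75, names = FALSE)),
                  width = c(diff(range(X[, "bio_1"])) / 52,
                            diff(range(X[, "bio_11"])) / 52),
                  a0 = 6)
  }
  truth <- trueSuitability(stack, niche)
  occ <- sampleOccurrences(stack, truth, n = nOcc, bias = bias,
                           seed = seeds[2])
  pres <- cleanOccurrences(occ, stack)
  rivers <- makeRivers(nrow = nrow, ncol = ncol, nSources = nSources,
                       seed = seeds[3])
  # truth analogue of the pipeline estimand: threshold the true field
  # at the mean true suitability of the occurrence cells
  tTrue <- mean(valuesAtCells(truth, occ$cell))
  truthMap <- new("SuitabilityMap", values = truth@values,
                  xmin = truth@xmin, ymax = truth@ymax,
                  cellsize = truth@cellsize, replicate = 0L)
  maskTrue <- binarizeSuitability(truthMap, tTrue)
  lenTrue <- suitableRiverLength(rivers, maskTrue, minOrder)
  filt <- filterByOrder(rivers, minOrder)
  sections <- makeSections(filt, nSections = 8, rings = maskTrue@rings)
  survey <- simulateSurvey(sections, dTrue, seed = seeds[4])
  list(climate = climate, stack = stack, niche = niche, truth = truth,
       occurrences = occ, presences = pres, rivers = rivers,
       sections = sections, survey = survey, dTrue = dTrue,
       tTrue = tTrue, LTrue = lenTrue$totalKm,
       NTrue = dTrue * lenTrue$totalKm, minOrder = minOrder,
       maskTrue = maskTrue, seed = seed)
}
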