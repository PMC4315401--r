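#' Create a monthly climate object
#'
#' @param tmin,tmax,prec numeric arrays with dim c(rows, cols, 12):
#'   monthly mean daily minimum and maximum temperature (degrees C) and
#'   monthly precipitation total (mm).
#' @param xmin,ymax,cellsize grid geometry (decimal degrees).
#' @return A \linkS4class{MonthlyClimate}.
#' @export
monthlyClimate <- function(tmin, tmax, prec, xmin, ymax, cellsize) {
  new("MonthlyClimate", tmin = tmin, tmax = tmax, prec = prec,
      xmin = xmin, ymax = ymax, cellsize = cellsize)
}

#' Derive the 19 standard bioclimatic variables
#'
#' Computes BIO1-BIO19 from monthly climate grids using the
#' ANUCLIM/WorldClim definitions. Monthly mean temperature is
#' (tmin + tmax)/2. Quarters are the 12 circular windows of three
#' consecutive months; the warmest/coldest quarter is selected by mean
#' temperature and the wettest/driest by precipitation sum, with ties
#' broken by the earliest start month. Any cell with a missing month in
#' any input layer is missing in every output layer.
#'
#' Units: degrees C for BIO1, BIO2 and BIO5-BIO11; BIO3 and BIO15 are
#' dimensionless percentages; BIO4 is 100 x the (population) standard
#' deviation of monthly mean temperature; mm for BIO12-BIO14 and
#' BIO16-BIO19.
#'
#' @param climate a \linkS4class{MonthlyClimate}.
#' @return Named list of 19 \linkS4class{GeoGrid} layers,
#'   \code{bio_1} ... \code{bio_19}.
#' @examples
#' cl <- monthlyClimate(array(0, c(2, 2, 12)), array(10, c(2, 2, 12)),
#'                      array(50, c(2, 2, 12)), 110, 30, 0.5)
#' b <- deriveBioclim(cl)
#' gridValues(b$bio_1)[1, 1]  # 5: annual mean temperature
#' @export
deriveBioclim <- function(climate) {
  d <- dim(climate@tmin)
  nc <- d[1] * d[2]
  tmn <- matrix(climate@tmin, nc, 12)
  tmx <- matrix(climate@tmax, nc, 12)
  pre <- matrix(climate@prec, nc, 12)
  bad <- rowSums(is.na(tmn)) + rowSums(is.na(tmx)) + rowSums(is.na(pre)) > 0
  tmn[bad, ] <- 0; tmx[bad, ] <- 0; pre[bad, ] <- 0

  tav <- (tmn + tmx) / 2
  popSD <- function(m) sqrt(rowMeans(m^2) - rowMeans(m)^2)

  # circular 3-month windows: column w = months (w, w+1, w+2) mod 12
  qsum <- function(m) {
    out <- matrix(0, nrow(m), 12)
    for (w in 1:12) {
      idx <- ((w - 1):(w + 1)) %% 12 + 1
      out[, w] <- m[, idx[1]] + m[, idx[2]] + m[, idx[3]]
    }
    out
  }
  qtemp <- qsum(tav) / 3
  qprec <- qsum(pre)
  pick <- function(values, by, decreasing) {
    w <- max.col(if (decreasing) by else -by, ties.method = "first")
    values[cbind(seq_len(nrow(values)), w)]
  }

  bio <- vector("list", 19)
  bio[[1]] <- rowMeans(tav)
  bio[[2]] <- rowMeans(tmx - tmn)
  bio[[5]] <- apply(tmx, 1, max)
  bio[[6]] <- apply(tmn, 1, min)
  bio[[7]] <- bio[[5]] - bio[[6]]
  bio[[3]] <- ifelse(bio[[7]] > 0, 100 * bio[[2]] / bio[[7]], NA)
  bio[[4]] <- 100 * popSD(tav)
  bio[[8]] <- pick(qtemp, qprec, TRUE)    # mean temp, wettest quarter
  bio[[9]] <- pick(qtemp, qprec, FALSE)   # mean temp, driest quarter
  bio[[10]] <- apply(qtemp, 1, max)       # warmest quarter
  bio[[11]] <- apply(qtemp, 1, min)       # coldest quarter
  bio[[12]] <- rowSums(pre)
  bio[[13]] <- apply(pre, 1, max)
  bio[[14]] <- apply(pre, 1, min)
  bio[[15]] <- 100 * popSD(pre) / (1 + bio[[12]] / 12)
  bio[[16]] <- apply(qprec, 1, max)
  bio[[17]] <- apply(qprec, 1, min)
  bio[[18]] <- pick(qprec, qtemp, TRUE)   # precipitation, warmest quarter
  bio[[19]] <- pick(qprec, qtemp, FALSE)  # precipitation, coldest quarter

  names(bio) <- paste0("bio_", 1:19)
  lapply(bio, function(v) {
    v[bad] <- NA
    geoGrid(matrix(v, d[1], d[2]), climate@xmin, climate@ymax,
            climate@cellsize)
  })
}
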