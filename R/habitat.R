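#' Mean presence probability threshold
#'
#' The arithmetic mean of the (averaged) suitability at the presence
#' cells — the thresholding rule used to reclassify the suitability map
#' into suitable/unsuitable habitat. Optionally the map-wide mean over
#' all valid cells.
#'
#' @param suitability a \linkS4class{SuitabilityMap} (or
#'   \linkS4class{GeoGrid}) of probabilities.
#' @param presences presence cell indices, all on valid cells.
#' @param rule "presence" (default) or "map" for the map-wide mean.
#' @return The threshold t.
#' @export
meanPresenceThreshold <- function(suitability, presences,
                                  rule = c("presence", "map")) {
  rule <- match.arg(rule)
  if (rule == "map") return(mean(suitability@values, na.rm = TRUE))
  if (!length(presences)) stop("presence set is empty")
  p <- valuesAtCells(suitability, presences)
  if (anyNA(p)) stop("presences fall on invalid cells")
  mean(p)
}

#' Threshold a suitability map into a habitat mask
#'
#' A cell is suitable iff its probability is >= t (inclusive, so the
#' threshold-defining average case counts as suitable; set
#' \code{inclusive = FALSE} for a strict rule). Missing cells stay
#' missing. The suitable area is traced into polygon rings on cell
#' edges (4-connected regions; outer rings counter-clockwise, holes
#' clockwise, even-odd containment).
#'
#' @param suitability a \linkS4class{SuitabilityMap}.
#' @param t threshold in (0, 1), e.g. from [meanPresenceThreshold()].
#' @param inclusive treat p == t as suitable (default TRUE).
#' @return A \linkS4class{HabitatMask}.
#' @export
binarizeSuitability <- function(suitability, t, inclusive = TRUE) {
  stopifnot(t > 0, t < 1)
  v <- suitability@values
  b <- if (inclusive) (v >= t) else (v > t)
  mode(b) <- "double"
  grid <- geoGrid(b, suitability@xmin, suitability@ymax,
                  suitability@cellsize)
  new("HabitatMask", threshold = t, grid = grid,
      rings = traceRings(grid),
      provenance = list(inclusive = inclusive,
                        replicate = if (is(suitability, "SuitabilityMap"))
                          suitability@replicate else NA_integer_))
}

#' @describeIn binarizeSuitability number of suitable cells in a mask.
#' @param mask a \linkS4class{HabitatMask}.
#' @export
suitableCellCount <- function(mask) sum(mask@grid@values == 1, na.rm = TRUE)

setMethod("show", "HabitatMask", function(object) {
  cat(sprintf("HabitatMask: t = %.4g, %d suitable cells, %d rings\n",
              object@threshold, suitableCellCount(object),
              length(object@rings)))
})

# Trace boundary rings of the suitable (==1) region of a binary grid.
# Directed so the suitable region lies on the left: outer rings CCW,
# holes CW. Vertices are lattice corners in lon/lat on cell edges.
traceRings <- function(grid) {
  g <- gridGeometry(grid)
  m <- grid@values
  m[is.na(m)] <- 0
  nr <- g$nrow; nc <- g$ncol
  suit <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c] == 1
  # vertex (i, j) = corner at x = xmin + j*cs, y = ymax - i*cs,
  # i in 0..nr, j in 0..nc; key = i * (nc + 1) + j + 1
  vkey <- function(i, j) i * (nc + 1) + j + 1
  edges <- list()  # each: c(i0, j0, i1, j1)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] != 1) next
    if (!suit(r - 1, c)) edges[[length(edges) + 1]] <- c(r - 1, c, r - 1, c - 1)  # north: E->W
    if (!suit(r + 1, c)) edges[[length(edges) + 1]] <- c(r, c - 1, r, c)          # south: W->E
    if (!suit(r, c - 1)) edges[[length(edges) + 1]] <- c(r - 1, c - 1, r, c - 1)  # west: N->S
    if (!suit(r, c + 1)) edges[[length(edges) + 1]] <- c(r, c, r - 1, c)          # east: S->N
  }
  if (!length(edges)) return(list())
  E <- do.call(rbind, edges)
  from <- vkey(E[, 1], E[, 2])
  byFrom <- split(seq_len(nrow(E)), from)
  used <- rep(FALSE, nrow(E))
  rings <- list()
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    path <- E[e0, 1:2]
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- rbind(path, E[e, 3:4])
      nxt <- byFrom[[as.character(vkey(E[e, 3], E[e, 4]))]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      if (length(nxt) > 1) {
        # junction of diagonally touching regions: take the sharpest
        # left turn to keep components separate
        din <- E[e, 3:4] - E[e, 1:2]
        turn <- vapply(nxt, function(k) {
          dout <- E[k, 3:4] - E[k, 1:2]
          # cross product in (col, -row) plane; left turn > 0
          din[2] * (-dout[1]) - (-din[1]) * dout[2]
        }, 0)
        nxt <- nxt[which.max(turn)]
      }
      e <- nxt[1]
    }
    xy <- cbind(g$xmin + path[, 2] * g$cellsize,
                g$ymax - path[, 1] * g$cellsize)
    colnames(xy) <- c("x", "y")
    rings[[length(rings) + 1]] <- xy
  }
  rings
}

#' Signed area of a lon/lat ring (degrees squared; CCW positive)
#' @param ring closed two-column coordinate matrix.
#' @export
ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Even-odd point-in-polygon test over a set of rings
#'
#' Points lying exactly on a ring edge count as inside (consistent with
#' the inclusive habitat threshold).
#'
#' @param x,y point coordinate vectors.
#' @param rings list of closed ring matrices (e.g. from a
#'   \linkS4class{HabitatMask}).
#' @return Logical vector.
#' @export
pointInRings <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  onEdge <- rep(FALSE, length(x))
  eps <- 1e-12
  for (ring in rings) {
    n <- nrow(ring) - 1
    for (s in seq_len(n)) {
      x1 <- ring[s, 1]; y1 <- ring[s, 2]
      x2 <- ring[s + 1, 1]; y2 <- ring[s + 1, 2]
      # on-segment test
      cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      on <- abs(cr) < 1e-9 &
        x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
        y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
      onEdge <- onEdge | on
      # ray casting (ray towards +x)
      crosses <- ((y1 > y) != (y2 > y))
      if (any(crosses)) {
        xin <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        inside <- xor(inside, crosses & (x < xin))
      }
    }
  }
  inside | onEdge
}

#' Rasterize a habitat mask's rings back onto its grid
#'
#' Point-in-polygon at cell centres (even-odd rule); the round trip
#' through [binarizeSuitability()]'s polygonization recovers the binary
#' grid exactly because cell centres never lie on cell edges.
#'
#' @param mask a \linkS4class{HabitatMask}.
#' @return A \linkS4class{GeoGrid} of 0/1.
#' @export
rasterizeMask <- function(mask) {
  g <- gridGeometry(mask@grid)
  ctr <- xyFromCell(mask@grid, seq_len(g$nrow * g$ncol))
  v <- as.numeric(pointInRings(ctr[, 1], ctr[, 2], mask@rings))
  geoGrid(matrix(v, g$nrow, g$ncol, byrow = TRUE),
          g$xmin, g$ymax, g$cellsize)
}
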