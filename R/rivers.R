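#' Create a river network
#'
#' @param lines list of two-column (lon, lat) coordinate matrices, each
#'   with at least two vertices.
#' @param attrs data.frame with one row per line; must contain
#'   \code{id} and (Strahler) \code{order}, optionally \code{name}.
#' @return A \linkS4class{RiverNetwork}.
#' @export
riverNetwork <- function(lines, attrs) {
  if (is.null(attrs$name)) attrs$name <- as.character(attrs$id)
  new("RiverNetwork", lines = lines, attrs = attrs)
}

setMethod("show", "RiverNetwork", function(object) {
  cat(sprintf("RiverNetwork: %d lines, orders %s, total %.1f km\n",
              length(object@lines),
              paste(range(object@attrs$order), collapse = "-"),
              networkLength(object)))
})

#' @describeIn riverNetwork total geodesic length (km) of all lines.
#' @param network a \linkS4class{RiverNetwork}.
#' @export
networkLength <- function(network)
  sum(vapply(network@lines, geodesicLength, 0))

#' Filter a network by stream order
#'
#' Retains only lines whose (Strahler) order is at least
#' \code{minOrder}; the default drops small rivers of order five and
#' below, where the species is absent.
#'
#' @param network a \linkS4class{RiverNetwork}.
#' @param minOrder smallest order retained (default 6).
#' @return The filtered \linkS4class{RiverNetwork} (possibly empty).
#' @export
filterByOrder <- function(network, minOrder = 6) {
  if (is.null(network@attrs$order)) stop("order attribute missing")
  keep <- network@attrs$order >= minOrder
  new("RiverNetwork", lines = network@lines[keep],
      attrs = network@attrs[keep, , drop = FALSE])
}

#' Great-circle length of a polyline
#'
#' Sum of haversine segment lengths on a sphere of radius 6371.0088 km;
#' a one-degree meridian arc measures 111.195 km.
#'
#' @param line two-column (lon, lat) matrix with >= 2 vertices.
#' @return Length in km.
#' @export
geodesicLength <- function(line) {
  if (!is.matrix(line) || nrow(line) < 2)
    stop("a polyline needs at least 2 vertices")
  n <- nrow(line)
  sum(geosphere::distHaversine(line[-n, , drop = FALSE],
                               line[-1, , drop = FALSE],
                               r = 6371.0088)) # km
}

# flatten a ring list into edge arrays for vectorised geometry
flattenRings <- function(rings) {
  segs <- lapply(rings, function(ring) {
    n <- nrow(ring) - 1
    cbind(ring[-(n + 1), 1], ring[-(n + 1), 2], ring[-1, 1], ring[-1, 2])
  })
  E <- do.call(rbind, segs)
  list(x1 = E[, 1], y1 = E[, 2], x2 = E[, 3], y2 = E[, 4],
       xlo = pmin(E[, 1], E[, 3]), xhi = pmax(E[, 1], E[, 3]),
       ylo = pmin(E[, 2], E[, 4]), yhi = pmax(E[, 2], E[, 4]))
}

# parameters t in (0,1) where segment p0->p1 crosses any flattened edge
segmentCrossings <- function(p0, p1, ed) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  box <- ed$xlo <= max(p0[1], p1[1]) & ed$xhi >= min(p0[1], p1[1]) &
         ed$ylo <= max(p0[2], p1[2]) & ed$yhi >= min(p0[2], p1[2])
  if (!any(box)) return(numeric())
  x1 <- ed$x1[box]; y1 <- ed$y1[box]
  ex <- ed$x2[box] - x1; ey <- ed$y2[box] - y1
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-15
  t <- ((x1 - p0[1]) * ey - (y1 - p0[2]) * ex) / den
  u <- ((x1 - p0[1]) * dy - (y1 - p0[2]) * dx) / den
  hit <- ok & t > 1e-12 & t < 1 - 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
  sort(unique(t[hit]))
}

#' Clip a river network to a polygon set
#'
#' Splits every polyline at polygon-boundary crossings (linear
#' interpolation in lon/lat) and keeps the portions inside the polygons
#' (even-odd rule over the rings); pieces lying exactly on a polygon
#' edge count as inside.
#'
#' @param network a \linkS4class{RiverNetwork}.
#' @param rings list of closed ring matrices (e.g.
#'   \code{mask@rings} from [binarizeSuitability()]).
#' @return List: \code{network} (clipped \linkS4class{RiverNetwork},
#'   with a \code{sourceId} attribute column) and \code{insideKm}
#'   (named per-source-line inside length, km).
#' @export
clipToPolygons <- function(network, rings) {
  outLines <- list(); outSrc <- integer(); outOrder <- integer()
  insideKm <- stats::setNames(numeric(length(network@lines)),
                              network@attrs$name)
  if (!length(rings)) {
    clipped <- new("RiverNetwork", lines = list(),
                   attrs = data.frame(id = integer(), order = integer(),
                                      name = character(),
                                      sourceId = integer()))
    return(list(network = clipped, insideKm = insideKm))
  }
  ed <- flattenRings(rings)
  # pass 1: split every segment at boundary crossings, collect sub-pieces
  sub <- vector("list", length(network@lines))
  for (li in seq_along(network@lines)) {
    line <- network@lines[[li]]
    rows <- list()
    for (s in seq_len(nrow(line) - 1)) {
      p0 <- line[s, ]; p1 <- line[s + 1, ]
      ts <- c(0, segmentCrossings(p0, p1, ed), 1)
      a <- ts[-length(ts)]; b <- ts[-1]
      keep <- b > a
      rows[[s]] <- cbind(seg = s, a = a[keep], b = b[keep])
    }
    sub[[li]] <- do.call(rbind, rows)
  }
  # single batched inside test on all sub-piece midpoints
  mids <- do.call(rbind, lapply(seq_along(sub), function(li) {
    line <- network@lines[[li]]; m <- sub[[li]]
    tmid <- (m[, "a"] + m[, "b"]) / 2
    cbind(line[m[, "seg"], 1] + tmid * (line[m[, "seg"] + 1, 1] -
                                          line[m[, "seg"], 1]),
          line[m[, "seg"], 2] + tmid * (line[m[, "seg"] + 1, 2] -
                                          line[m[, "seg"], 2]))
  }))
  inside <- pointInRings(mids[, 1], mids[, 2], rings)
  off <- 0L
  for (li in seq_along(network@lines)) {
    line <- network@lines[[li]]; m <- sub[[li]]
    ins <- inside[off + seq_len(nrow(m))]; off <- off + nrow(m)
    pieces <- list(); current <- NULL
    for (k in seq_len(nrow(m))) {
      s <- m[k, "seg"]; a <- m[k, "a"]; b <- m[k, "b"]
      p0 <- line[s, ]; p1 <- line[s + 1, ]
      if (ins[k]) {
        pa <- p0 + a * (p1 - p0); pb <- p0 + b * (p1 - p0)
        if (is.null(current)) current <- rbind(pa)
        current <- rbind(current, pb)
      } else if (!is.null(current)) {
        pieces[[length(pieces) + 1]] <- current; current <- NULL
      }
    }
    if (!is.null(current)) pieces[[length(pieces) + 1]] <- current
    pieces <- Filter(function(p) nrow(p) >= 2, pieces)
    if (length(pieces)) {
      insideKm[li] <- sum(vapply(pieces, geodesicLength, 0))
      outLines <- c(outLines, pieces)
      outSrc <- c(outSrc, rep(network@attrs$id[li], length(pieces)))
      outOrder <- c(outOrder, rep(network@attrs$order[li], length(pieces)))
    }
  }
  clipped <- new("RiverNetwork", lines = outLines,
                 attrs = data.frame(id = seq_along(outLines),
                                    order = outOrder,
                                    name = as.character(outSrc),
                                    sourceId = outSrc))
  list(network = clipped, insideKm = insideKm)
}

#' Suitable river length
#'
#' The pipeline composition behind the habitat-size figure: filter the
#' network by stream order, clip it to the suitable-habitat polygons,
#' and sum the great-circle lengths of the inside portions.
#'
#' @param network a \linkS4class{RiverNetwork}.
#' @param mask a \linkS4class{HabitatMask}.
#' @param minOrder smallest stream order retained (default 6).
#' @return List: \code{totalKm} (L), \code{perLineKm} (named
#'   contributions), \code{clipped} (the clipped network),
#'   \code{minOrder}, \code{threshold}.
#' @export
suitableRiverLength <- function(network, mask, minOrder = 6) {
  filt <- filterByOrder(network, minOrder)
  if (!length(filt@lines))
    return(list(totalKm = 0, perLineKm = numeric(), clipped = filt,
                minOrder = minOrder, threshold = mask@threshold))
  cl <- clipToPolygons(filt, mask@rings)
  list(totalKm = sum(cl$insideKm), perLineKm = cl$insideKm,
       clipped = cl$network, minOrder = minOrder,
       threshold = mask@threshold)
}
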