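#' Read and write river networks as GeoJSON
#'
#' LineString and MultiLineString features are supported; the stream
#' order is read from the property named by \code{orderField}.
#'
#' @param file path to a GeoJSON file.
#' @param orderField property holding the Strahler order (default
#'   "order").
#' @return \code{readRiversGeoJSON}: a \linkS4class{RiverNetwork}.
#' @export
readRiversGeoJSON <- function(file, orderField = "order") {
  gj <- jsonlite::read_json(file)
  lines <- list(); ids <- integer(); orders <- integer(); nms <- character()
  toMat <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  for (ft in gj$features) {
    props <- ft$properties
    ord <- props[[orderField]]
    if (is.null(ord)) stop("feature without '", orderField, "' property")
    geom <- ft$geometry
    parts <- if (geom$type == "LineString") list(geom$coordinates)
             else if (geom$type == "MultiLineString") geom$coordinates
             else stop("unsupported geometry type: ", geom$type)
    for (part in parts) {
      lines[[length(lines) + 1]] <- toMat(part)
      ids <- c(ids, length(lines))
      orders <- c(orders, as.integer(ord))
      nms <- c(nms, if (!is.null(props$name)) props$name
               else as.character(length(lines)))
    }
  }
  riverNetwork(lines, data.frame(id = ids, order = orders, name = nms))
}

#' @rdname readRiversGeoJSON
#' @param network a \linkS4class{RiverNetwork} to write.
#' @export
writeRiversGeoJSON <- function(network, file) {
  features <- lapply(seq_along(network@lines), function(i) {
    m <- network@lines[[i]]
    list(type = "Feature",
         properties = list(id = network@attrs$id[i],
                           order = network@attrs$order[i],
                           name = network@attrs$name[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(r) as.numeric(m[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write habitat polygons as GeoJSON
#'
#' Each ring becomes one Polygon feature with its orientation recorded
#' (\code{outer} = TRUE for counter-clockwise rings); containment of
#' the ring set follows the even-odd rule.
#'
#' @param mask a \linkS4class{HabitatMask}.
#' @param file output path.
#' @export
writeMaskGeoJSON <- function(mask, file) {
  features <- lapply(mask@rings, function(ring)
    list(type = "Feature",
         properties = list(outer = ringArea(ring) > 0),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r)
                                                     as.numeric(ring[r, ]))))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features,
                            properties = list(threshold = mask@threshold)),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read occurrence records from CSV
#'
#' Expects header columns \code{longitude} and \code{latitude}
#' (\code{species}, \code{source}, \code{date}, \code{excluded}
#' optional).
#'
#' @param file path to a CSV file.
#' @return data.frame suitable for [cleanOccurrences()].
#' @export
readOccurrencesCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("longitude", "latitude") %in% names(df)))
  df
}

#' Export a fitted model as a lambdas-style text file
#'
#' One line per feature: name, class, weight, penalty, and the raw
#' value range used for scaling; a trailing block records logZ, the
#' entropy H and tau.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param file output path.
#' @export
writeLambdas <- function(model, file) {
  d <- model@features@defs
  hdr <- "name\tclass\tlambda\tbeta\tmin\tmax"
  body <- sprintf("%s\t%s\t%.10g\t%.10g\t%.10g\t%.10g",
                  d$name, d$class, model@lambda, model@features@beta,
                  model@features@fmin, model@features@fmax)
  tail <- c(sprintf("logZ\t%.10g", model@logZ),
            sprintf("entropy\t%.10g", model@H),
            sprintf("tau\t%.10g", model@tau))
  writeLines(c(hdr, body, tail), file)
  invisible(file)
}
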