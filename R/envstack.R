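#' Assemble an environmental stack from aligned layers
#'
#' @param layers named list of \linkS4class{GeoGrid} sharing one geometry.
#' @param kind character vector ("continuous"/"categorical"), one per
#'   layer, recycled if unnamed; defaults to all continuous.
#' @return An \linkS4class{EnvStack}; the validity mask is the
#'   intersection of per-layer validity.
#' @export
envStack <- function(layers, kind = "continuous") {
  if (is.null(names(kind)))
    kind <- stats::setNames(rep(kind, length.out = length(layers)),
                            names(layers))
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l@values)))
  for (nm in names(layers))
    if (kind[[nm]] == "categorical") {
      v <- layers[[nm]]@values
      if (any(v[!is.na(v)] != round(v[!is.na(v)])))
        stop("categorical layer '", nm, "' contains non-integer codes")
    }
  new("EnvStack", layers = layers, kind = kind[names(layers)], mask = mask)
}

#' @describeIn envStack layer names.
#' @param x an EnvStack.
#' @export
layerNames <- function(x) names(x@layers)

#' @describeIn envStack the validity mask (logical matrix).
#' @export
validMask <- function(x) x@mask

#' @describeIn envStack indices of valid cells (row-major, north first).
#' @export
validCells <- function(x) which(t(x@mask))

#' @describeIn envStack geometry of the stack (see [gridGeometry()]).
#' @export
stackGeometry <- function(x) gridGeometry(x@layers[[1]])

#' @describeIn envStack keep only the named layers.
#' @param which layer names to keep.
#' @export
subsetStack <- function(x, which) envStack(x@layers[which], x@kind[which])

setMethod("show", "EnvStack", function(object) {
  g <- stackGeometry(object)
  cat(sprintf("EnvStack: %d layers on %d x %d cells (%g deg), %d valid\n",
              length(object@layers), g$nrow, g$ncol, g$cellsize,
              sum(object@mask)))
  cat("  ", paste0(names(object@layers), " [",
                   substr(object@kind, 1, 4), "]", collapse = ", "), "\n")
})

resampleLayer <- function(layer, target, kind) {
  if (sameGeometry(layer, target)) return(layer)
  gt <- gridGeometry(target); gs <- gridGeometry(layer)
  ctr <- xyFromCell(target, seq_len(gt$nrow * gt$ncol))
  out <- rep(NA_real_, nrow(ctr))
  inext <- ctr[, 1] >= gs$xmin & ctr[, 1] <= gs$xmax &
           ctr[, 2] >= gs$ymin & ctr[, 2] <= gs$ymax
  if (!any(inext)) stop("target extent is disjoint from layer extent")
  v <- layer@values
  if (kind == "continuous") {
    # bilinear on source cell centres, clamped at the border
    cx <- (ctr[inext, 1] - gs$xmin) / gs$cellsize - 0.5
    cy <- (gs$ymax - ctr[inext, 2]) / gs$cellsize - 0.5
    cx <- pmin(pmax(cx, 0), gs$ncol - 1); cy <- pmin(pmax(cy, 0), gs$nrow - 1)
    c0 <- pmin(floor(cx), gs$ncol - 2); r0 <- pmin(floor(cy), gs$nrow - 2)
    if (gs$ncol == 1) c0 <- 0; if (gs$nrow == 1) r0 <- 0
    fx <- cx - c0; fy <- cy - r0
    idx <- function(r, c) v[cbind(pmin(r, gs$nrow - 1) + 1,
                                  pmin(c, gs$ncol - 1) + 1)]
    out[inext] <- (1 - fx) * (1 - fy) * idx(r0, c0) +
      fx * (1 - fy) * idx(r0, c0 + 1) +
      (1 - fx) * fy * idx(r0 + 1, c0) +
      fx * fy * idx(r0 + 1, c0 + 1)
  } else {
    # majority of source cells falling in each target cell (ties -> lowest
    # code); nearest neighbour when upsampling leaves a cell empty
    sctr <- xyFromCell(layer, seq_len(gs$nrow * gs$ncol))
    tcell <- cellFromXY(target, sctr[, 1], sctr[, 2])
    keep <- !is.na(tcell) & !is.na(as.vector(t(v)))
    if (any(keep)) {
      sv <- as.vector(t(v))[keep]
      grp <- split(sv, tcell[keep])
      modes <- vapply(grp, function(z) {
        tab <- table(z)
        vals <- as.numeric(names(tab))
        vals[order(-as.vector(tab), vals)][1]  # ties: lowest code
      }, 0)
      out[as.integer(names(grp))] <- modes
    }
    fill <- inext & is.na(out)
    if (any(fill)) {
      c0 <- pmin(pmax(round((ctr[fill, 1] - gs$xmin) / gs$cellsize + 0.5),
                      1), gs$ncol)
      r0 <- pmin(pmax(round((gs$ymax - ctr[fill, 2]) / gs$cellsize + 0.5),
                      1), gs$nrow)
      out[fill] <- v[cbind(r0, c0)]
    }
  }
  geoGrid(matrix(out, gt$nrow, gt$ncol, byrow = TRUE),
          gt$xmin, gt$ymax, gt$cellsize)
}

#' Align heterogeneous layers onto one analysis grid
#'
#' Resamples every layer to the target geometry: continuous layers
#' bilinearly on cell centres, categorical layers by majority of the
#' source cells falling in each target cell (ties broken by the lowest
#' code; nearest neighbour when upsampling). Aligning a layer already on
#' the target geometry returns it unchanged.
#'
#' @param layers named list of \linkS4class{GeoGrid}, each with its own
#'   geometry.
#' @param kind per-layer "continuous"/"categorical" (recycled).
#' @param target a \linkS4class{GeoGrid} (or \linkS4class{EnvStack})
#'   defining the analysis geometry.
#' @return An \linkS4class{EnvStack} on the target geometry.
#' @export
alignStack <- function(layers, kind = "continuous", target) {
  if (is(target, "EnvStack")) target <- target@layers[[1]]
  if (is.null(names(kind)))
    kind <- stats::setNames(rep(kind, length.out = length(layers)),
                            names(layers))
  aligned <- lapply(names(layers), function(nm)
    resampleLayer(layers[[nm]], target, kind[[nm]]))
  names(aligned) <- names(layers)
  envStack(aligned, kind)
}

#' Clean occurrence records against a stack
#'
#' Drops records flagged for exclusion (e.g. migratory stopover
#' sightings), records falling outside the stack extent or on invalid
#' cells, and (by default) collapses duplicate records within one grid
#' cell to a single presence. The result is order-independent: permuting
#' the input rows yields the same presence-cell set.
#'
#' @param records data.frame with columns \code{longitude},
#'   \code{latitude} and optionally \code{excluded} (logical).
#' @param stack an \linkS4class{EnvStack}.
#' @param onePerCell collapse duplicates within a cell (default TRUE).
#' @return List with \code{cells} (sorted unique presence cell indices),
#'   \code{records} (retained rows with a \code{cell} column) and
#'   \code{log} (dropped-record counts).
#' @export
cleanOccurrences <- function(records, stack, onePerCell = TRUE) {
  stopifnot(all(c("longitude", "latitude") %in% names(records)))
  n0 <- nrow(records)
  excl <- if ("excluded" %in% names(records))
    records$excluded %in% TRUE else rep(FALSE, n0)
  records <- records[!excl, , drop = FALSE]
  grid <- stack@layers[[1]]
  cell <- cellFromXY(grid, records$longitude, records$latitude)
  valid <- validCells(stack)
  inside <- !is.na(cell) & cell %in% valid
  droppedOutside <- sum(!inside)
  if (droppedOutside)
    message(droppedOutside, " record(s) outside the valid mask dropped")
  records <- records[inside, , drop = FALSE]
  records$cell <- cell[inside]
  dup <- 0L
  if (onePerCell) {
    keep <- !duplicated(records$cell)
    dup <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no occurrence records left after cleaning")
  list(cells = sort(unique(records$cell)), records = records,
       log = list(input = n0, droppedExcluded = sum(excl),
                  droppedOutside = droppedOutside,
                  droppedDuplicate = dup))
}

#' Extract per-cell predictor vectors
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param cells row-major cell indices (see [cellFromXY()]).
#' @return Numeric matrix, one row per cell, one named column per layer.
#'   Requesting a cell outside the validity mask is an error.
#' @export
extractPredictors <- function(stack, cells) {
  valid <- which(t(stack@mask))
  if (!all(cells %in% valid))
    stop("cells outside the validity mask requested")
  out <- vapply(stack@layers, function(l) valuesAtCells(l, cells),
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, 1,
                                         dimnames = list(NULL,
                                                         layerNames(stack)))
  out
}
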