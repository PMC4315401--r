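#' @import methods
NULL

#' Geographic raster grid
#'
#' A single-band raster on a regular geographic (lon/lat, WGS84) grid.
#' Values are stored as a numeric matrix whose first row is the
#' northernmost row; missing data are \code{NA}. A cell value refers to
#' the cell centre, and a point maps to the cell containing it under
#' half-open cell intervals \eqn{[west, east) \times (south, north]}.
#'
#' @slot values numeric matrix, row 1 = northernmost row.
#' @slot xmin western edge of the grid (decimal degrees).
#' @slot ymax northern edge of the grid (decimal degrees).
#' @slot cellsize cell size in decimal degrees (square cells).
#' @export
setClass("GeoGrid",
  representation(values = "matrix", xmin = "numeric", ymax = "numeric",
                 cellsize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
        object@cellsize <= 0)
      msg <- c(msg, "cellsize must be a single positive number")
    if (length(object@xmin) != 1L || length(object@ymax) != 1L)
      msg <- c(msg, "xmin and ymax must be single numbers")
    if (length(msg)) msg else TRUE
  })

#' Monthly climate grids
#'
#' Twelve months of minimum temperature, maximum temperature (degrees C)
#' and precipitation totals (mm) on a shared geographic grid, stored as
#' \code{nrow x ncol x 12} arrays.
#'
#' @slot tmin,tmax,prec numeric arrays with dim c(rows, cols, 12).
#' @slot xmin,ymax,cellsize grid geometry as in \linkS4class{GeoGrid}.
#' @export
setClass("MonthlyClimate",
  representation(tmin = "array", tmax = "array", prec = "array",
                 xmin = "numeric", ymax = "numeric", cellsize = "numeric"),
  validity = function(object) {
    d <- dim(object@tmin)
    msg <- character()
    if (length(d) != 3L || d[3] != 12L)
      msg <- c(msg, "tmin must be an array with 12 month slices")
    if (!identical(dim(object@tmax), d) || !identical(dim(object@prec), d))
      msg <- c(msg, "tmin, tmax and prec must share dimensions")
    bad <- which(object@tmax < object@tmin)
    if (length(bad)) msg <- c(msg, "tmax must be >= tmin wherever both valid")
    if (any(object@prec < 0, na.rm = TRUE))
      msg <- c(msg, "precipitation must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Aligned environmental predictor stack
#'
#' Named raster layers sharing one geometry, each flagged continuous or
#' categorical, with a validity mask equal to the intersection of
#' per-layer validity.
#'
#' @slot layers named list of \linkS4class{GeoGrid}.
#' @slot kind named character, "continuous" or "categorical" per layer.
#' @slot mask logical matrix; TRUE where every layer is valid.
#' @export
setClass("EnvStack",
  representation(layers = "list", kind = "character", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
      msg <- c(msg, "layers must have unique names")
    if (!all(vapply(object@layers, is, TRUE, "GeoGrid")))
      msg <- c(msg, "all layers must be GeoGrid objects")
    if (!setequal(names(object@kind), names(object@layers)))
      msg <- c(msg, "kind must be named after the layers")
    if (!all(object@kind %in% c("continuous", "categorical")))
      msg <- c(msg, "kind must be 'continuous' or 'categorical'")
    if (length(object@layers)) {
      g <- object@layers[[1]]
      same <- vapply(object@layers, function(l)
        identical(dim(l@values), dim(g@values)) &&
        isTRUE(all.equal(c(l@xmin, l@ymax, l@cellsize),
                         c(g@xmin, g@ymax, g@cellsize))), TRUE)
      if (!all(same)) msg <- c(msg, "layers must share one geometry")
      if (!identical(dim(object@mask), dim(g@values)))
        msg <- c(msg, "mask must match layer dimensions")
    }
    if (length(msg)) msg else TRUE
  })

#' Maxent feature expansion
#'
#' Feature definitions over stack layers (linear, quadratic, product,
#' hinge, threshold, categorical indicator), the background min-max
#' scaling that maps each feature to [0, 1], and per-feature L1
#' penalties.
#'
#' @slot defs data.frame with columns name, layer, layer2, class, knot.
#' @slot fmin,fmax per-feature raw value range on the background sample.
#' @slot beta per-feature regularisation constant (>= 0).
#' @export
setClass("FeatureSet",
  representation(defs = "data.frame", fmin = "numeric", fmax = "numeric",
                 beta = "numeric"),
  validity = function(object) {
    n <- nrow(object@defs)
    msg <- character()
    if (length(object@fmin) != n || length(object@fmax) != n ||
        length(object@beta) != n)
      msg <- c(msg, "fmin, fmax and beta must have one entry per feature")
    if (any(object@beta < 0)) msg <- c(msg, "beta must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Fitted maximum-entropy model
#'
#' The L1-regularised Gibbs distribution over background cells:
#' \eqn{q(x) = \exp(\sum_j \lambda_j f_j(x)) / Z}, with entropy H of q
#' and the logistic transform \eqn{p = q e^H / (1 + q e^H)} at default
#' prevalence tau = 0.5.
#'
#' @slot features the \linkS4class{FeatureSet}.
#' @slot lambda fitted feature weights.
#' @slot H entropy of the fitted background distribution.
#' @slot tau logistic prevalence parameter.
#' @slot bgCells background cell indices (row-major, north to south).
#' @slot q fitted probability per background cell (sums to 1).
#' @slot presenceMeans empirical feature means at presence cells.
#' @slot bgMeans expected feature values under the fitted q.
#' @slot logZ log partition function at the fitted weights.
#' @slot converged,iterations,objective optimiser diagnostics.
#' @export
setClass("MaxentModel",
  representation(features = "FeatureSet", lambda = "numeric", H = "numeric",
                 tau = "numeric", bgCells = "integer", q = "numeric",
                 presenceMeans = "numeric", bgMeans = "numeric",
                 logZ = "numeric",
                 converged = "logical", iterations = "integer",
                 objective = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@lambda) != nrow(object@features@defs))
      msg <- c(msg, "one lambda per feature required")
    if (length(object@q) &&
        abs(sum(object@q) - 1) > 1e-9)
      msg <- c(msg, "q must sum to 1")
    if (length(object@H) && object@H < -1e-12)
      msg <- c(msg, "entropy must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Suitability map
#'
#' A \linkS4class{GeoGrid} of logistic occurrence probabilities in
#' (0, 1) on valid cells, tagged with a replicate identifier (0 for a
#' single or averaged model).
#' @export
setClass("SuitabilityMap", contains = "GeoGrid",
  representation(replicate = "integer"))

#' River network
#'
#' Polylines in lon/lat with per-line attributes, including a Strahler
#' stream order.
#'
#' @slot lines list of two-column (lon, lat) coordinate matrices.
#' @slot attrs data.frame with columns id, order, name (one row per line).
#' @export
setClass("RiverNetwork",
  representation(lines = "list", attrs = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@attrs) != length(object@lines))
      msg <- c(msg, "attrs must have one row per line")
    if (!all(c("id", "order") %in% names(object@attrs)))
      msg <- c(msg, "attrs must contain id and order columns")
    if (length(object@lines)) {
      ok <- vapply(object@lines, function(m)
        is.matrix(m) && ncol(m) == 2L && nrow(m) >= 2L, TRUE)
      if (!all(ok)) msg <- c(msg, "each line needs >= 2 lon/lat vertices")
      if (any(object@attrs$order < 1)) msg <- c(msg, "order must be >= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Binary habitat mask
#'
#' The thresholded suitability map: a binary grid (1 = suitable), the
#' threshold used, and the suitable area traced as polygon rings on cell
#' edges (even-odd rule; outer rings counter-clockwise, holes clockwise).
#'
#' @slot threshold the probability threshold t.
#' @slot grid \linkS4class{GeoGrid} of 0/1/NA.
#' @slot rings list of closed (lon, lat) ring matrices.
#' @slot provenance list recording how the mask was derived.
#' @export
setClass("HabitatMask",
  representation(threshold = "numeric", grid = "GeoGrid", rings = "list",
                 provenance = "list"),
  validity = function(object) {
    v <- object@grid@values
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      "grid must contain only 0, 1 and NA" else TRUE
  })
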