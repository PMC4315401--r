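#' Build a Maxent feature expansion
#'
#' Expands continuous layers into linear, quadratic, pairwise-product,
#' hinge and threshold features and categorical layers into one 0/1
#' indicator per observed code. Hinge and threshold knots sit at
#' equally spaced background quantiles. Every feature is min-max scaled
#' to [0, 1] using the background sample; a forward hinge with knot k
#' takes the value max(0, (x - k) / (max - k)) capped at 1, a reverse
#' hinge max(0, (k - x) / (k - min)). Constant layers contribute no
#' features (warned). Per-feature L1 penalties follow
#' \eqn{\beta_j = \mu \, s_j \, c / \sqrt{m}} with \eqn{s_j} the
#' feature's background standard deviation, m the presence count, and
#' c = 0.5 for hinge features and 1 otherwise.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param presences presence cell indices (used only for m in the
#'   penalty formula).
#' @param background background cell indices.
#' @param classes feature classes for continuous layers.
#' @param hingeKnots knots per layer for hinge/threshold features.
#' @param betaMultiplier global multiplier on the default penalties.
#' @return A \linkS4class{FeatureSet}.
#' @export
buildFeatures <- function(stack, presences, background,
                          classes = c("linear", "quadratic", "product",
                                      "hinge", "threshold"),
                          hingeKnots = 50, betaMultiplier = 1) {
  Xbg <- extractPredictors(stack, background)
  cont <- names(stack@kind)[stack@kind == "continuous"]
  cat_ <- names(stack@kind)[stack@kind == "categorical"]
  rng <- apply(Xbg, 2, range)
  flat <- colnames(Xbg)[rng[1, ] == rng[2, ]]
  if (length(flat)) {
    warning("constant layer(s) dropped from features: ",
            paste(flat, collapse = ", "))
    cont <- setdiff(cont, flat); cat_ <- setdiff(cat_, flat)
  }
  defs <- list(); fmin <- c(); fmax <- c(); cls <- c()
  add <- function(name, layer, layer2, class, knot, lo, hi) {
    defs[[length(defs) + 1L]] <<- data.frame(
      name = name, layer = layer, layer2 = layer2, class = class,
      knot = knot, stringsAsFactors = FALSE)
    fmin <<- c(fmin, lo); fmax <<- c(fmax, hi); cls <<- c(cls, class)
  }
  for (l in cont) {
    x <- Xbg[, l]
    if ("linear" %in% classes)
      add(l, l, NA, "linear", NA, min(x), max(x))
    if ("quadratic" %in% classes)
      add(paste0(l, "^2"), l, NA, "quadratic", NA, min(x^2), max(x^2))
    if (any(c("hinge", "threshold") %in% classes) && hingeKnots > 0) {
      ks <- unique(stats::quantile(x, seq_len(hingeKnots) / (hingeKnots + 1),
                                   names = FALSE))
      for (k in ks) {
        if ("hinge" %in% classes) {
          if (k < max(x)) add(paste0("h(", l, ">", signif(k, 6), ")"),
                              l, NA, "hinge", k, k, max(x))
          if (k > min(x)) add(paste0("h(", l, "<", signif(k, 6), ")"),
                              l, NA, "hinge_rev", k, min(x), k)
        }
        if ("threshold" %in% classes && k > min(x) && k < max(x))
          add(paste0("t(", l, ">", signif(k, 6), ")"),
              l, NA, "threshold", k, 0, 1)
      }
    }
  }
  if ("product" %in% classes && length(cont) > 1)
    for (i in seq_len(length(cont) - 1)) for (j in (i + 1):length(cont)) {
      p <- Xbg[, cont[i]] * Xbg[, cont[j]]
      if (min(p) < max(p))
        add(paste0(cont[i], "*", cont[j]), cont[i], cont[j], "product",
            NA, min(p), max(p))
    }
  for (l in cat_)
    for (code in sort(unique(Xbg[, l])))
      add(paste0(l, "==", code), l, NA, "categorical", code, 0, 1)
  if (!length(defs)) stop("no usable features could be built")
  defs <- do.call(rbind, defs)
  fs <- new("FeatureSet", defs = defs, fmin = fmin, fmax = fmax,
            beta = rep(0, nrow(defs)))
  Fbg <- featureMatrix(fs, Xbg)
  s <- apply(Fbg, 2, stats::sd)
  cc <- ifelse(defs$class %in% c("hinge", "hinge_rev"), 0.5, 1.0)
  fs@beta <- betaMultiplier * s * cc / sqrt(length(presences))
  fs
}

#' Evaluate scaled feature values
#'
#' @param features a \linkS4class{FeatureSet}.
#' @param X predictor matrix (rows = cells, named columns = layers).
#' @return Matrix of feature values in [0, 1] (values outside the
#'   training range are clamped).
#' @export
featureMatrix <- function(features, X) {
  d <- features@defs
  out <- matrix(0, nrow(X), nrow(d), dimnames = list(NULL, d$name))
  for (j in seq_len(nrow(d))) {
    x <- X[, d$layer[j]]
    raw <- switch(d$class[j],
      linear = x,
      quadratic = x^2,
      product = x * X[, d$layer2[j]],
      hinge = x,
      hinge_rev = -x,
      threshold = as.numeric(x > d$knot[j]),
      categorical = as.numeric(x == d$knot[j]))
    lo <- features@fmin[j]; hi <- features@fmax[j]
    if (d$class[j] == "hinge_rev") { lo <- -features@fmax[j]; hi <- -features@fmin[j] }
    out[, j] <- if (d$class[j] %in% c("threshold", "categorical")) raw
                else pmin(pmax((raw - lo) / (hi - lo), 0), 1)
  }
  out
}

#' Sample background cells
#'
#' Uniform sample without replacement from the validity mask; presence
#' cells remain eligible. If \code{n} is at least the number of valid
#' cells, all valid cells are returned deterministically.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param n requested background size (default 10000).
#' @param seed RNG seed (set when non-NULL).
#' @return Integer vector of cell indices.
#' @export
sampleBackground <- function(stack, n = 10000, seed = NULL) {
  cells <- validCells(stack)
  if (!length(cells)) stop("validity mask is empty")
  if (n >= length(cells)) return(cells)
  if (!is.null(seed)) set.seed(seed)
  sort(sample(cells, n))
}

#' Fit the L1-regularised Gibbs distribution
#'
#' Maximises the penalised presence log-likelihood
#' \deqn{\bar f \cdot \lambda - \log Z(\lambda) - \sum_j \beta_j |\lambda_j|}
#' over background cells by cyclic coordinate descent with
#' soft-thresholding, where \eqn{\bar f} are the empirical feature means
#' at presences and \eqn{Z = \sum_{bg} \exp(\lambda \cdot f(x))}. At the
#' optimum the KKT mean-matching condition
#' \eqn{|\bar f_j - E_q f_j| \le \beta_j} holds for every feature, with
#' equality for active features.
#'
#' @param Fbg background feature matrix (rows = background cells), e.g.
#'   from [featureMatrix()].
#' @param presenceMeans empirical feature means at presence cells.
#' @param beta per-feature L1 penalties (>= 0).
#' @param tol convergence tolerance on the objective between passes.
#' @param maxIter maximum coordinate-descent passes.
#' @return List with lambda, q, logZ, H, bgMeans, objective, converged,
#'   iterations.
#' @export
fitGibbs <- function(Fbg, presenceMeans, beta, tol = 1e-5, maxIter = 500) {
  J <- ncol(Fbg); n <- nrow(Fbg)
  lambda <- numeric(J)
  eta <- numeric(n)
  objective <- function(lambda, eta) {
    m <- max(eta)
    sum(presenceMeans * lambda) - (m + log(sum(exp(eta - m)))) -
      sum(beta * abs(lambda))
  }
  obj <- objective(lambda, eta)
  cap <- 4        # per-coordinate step bound; halved on objective decrease
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    lambda0 <- lambda; eta0 <- eta; obj0 <- obj
    for (j in seq_len(J)) {
      w <- exp(eta - max(eta)); q <- w / sum(w)
      f <- Fbg[, j]
      Ef <- sum(q * f)
      h <- max(sum(q * f * f) - Ef * Ef, 1e-10)
      g <- presenceMeans[j] - Ef
      z <- lambda[j] + g / h
      lnew <- sign(z) * max(abs(z) - beta[j] / h, 0)
      delta <- max(min(lnew - lambda[j], cap), -cap)
      if (delta != 0) {
        lambda[j] <- lambda[j] + delta
        eta <- eta + delta * f
      }
    }
    obj <- objective(lambda, eta)
    if (obj < obj0 - 1e-12) {      # overshoot: back off and damp
      lambda <- lambda0; eta <- eta0; obj <- obj0
      cap <- cap / 2
      if (cap < 1e-8) break
      next
    }
    if (obj - obj0 < tol) { converged <- TRUE; break }
  }
  w <- exp(eta - max(eta)); Z <- sum(w); q <- w / Z
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  list(lambda = lambda, q = q, logZ = max(eta) + log(Z), H = H,
       bgMeans = as.numeric(crossprod(q, Fbg)), objective = obj,
       converged = converged, iterations = it,
       gap = max(abs(presenceMeans - as.numeric(crossprod(q, Fbg))) - beta))
}

#' Fit a maximum-entropy species distribution model
#'
#' High-level wrapper: extracts predictors, builds the feature
#' expansion ([buildFeatures()]), and fits the penalised Gibbs
#' distribution ([fitGibbs()]) over the background cells.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param presences presence cell indices (>= 2, within the valid mask).
#' @param background background cell indices (e.g. from
#'   [sampleBackground()]).
#' @param features optional prebuilt \linkS4class{FeatureSet}; when
#'   supplied, \code{classes}/\code{hingeKnots}/\code{betaMultiplier}
#'   are ignored.
#' @param tau logistic prevalence parameter (default 0.5).
#' @inheritParams buildFeatures
#' @inheritParams fitGibbs
#' @return A \linkS4class{MaxentModel}.
#' @export
fitMaxent <- function(stack, presences, background,
                      classes = c("linear", "quadratic", "product",
                                  "hinge", "threshold"),
                      hingeKnots = 50, betaMultiplier = 1,
                      features = NULL, tau = 0.5,
                      tol = 1e-5, maxIter = 500) {
  if (length(presences) < 2) stop("at least 2 presence cells required")
  if (is.null(features))
    features <- buildFeatures(stack, presences, background, classes,
                              hingeKnots, betaMultiplier)
  Fbg <- featureMatrix(features, extractPredictors(stack, background))
  Fpr <- featureMatrix(features, extractPredictors(stack, presences))
  fit <- fitGibbs(Fbg, colMeans(Fpr), features@beta, tol, maxIter)
  if (!fit$converged)
    warning(sprintf("coordinate descent stopped after %d passes (KKT gap %.3g)",
                    fit$iterations, fit$gap))
  new("MaxentModel", features = features, lambda = fit$lambda, H = fit$H,
      tau = tau, bgCells = as.integer(background), q = fit$q,
      presenceMeans = colMeans(Fpr), bgMeans = fit$bgMeans,
      logZ = fit$logZ, converged = fit$converged,
      iterations = fit$iterations, objective = fit$objective)
}

setMethod("show", "MaxentModel", function(object) {
  cat(sprintf(
    "MaxentModel: %d features (%d active), %d background cells\n",
    length(object@lambda), sum(object@lambda != 0), length(object@bgCells)))
  cat(sprintf("  entropy H = %.4f, tau = %g, converged = %s (%d passes)\n",
              object@H, object@tau, object@converged, object@iterations))
})

#' KKT certificate of a fitted model
#'
#' @param model a \linkS4class{MaxentModel}.
#' @return List: \code{qSum} (sum of the fitted q), \code{gaps}
#'   (per-feature \eqn{|\bar f_j - E_q f_j| - \beta_j}; all <= tol at a
#'   valid optimum), \code{ok}.
#' @param tol slack allowed on the mean-matching condition.
#' @export
maxentCertificate <- function(model, tol = 1e-3) {
  gaps <- abs(model@presenceMeans - model@bgMeans) - model@features@beta
  list(qSum = sum(model@q), gaps = gaps,
       ok = abs(sum(model@q) - 1) < 1e-9 && all(gaps <= tol))
}

# linear predictor / suitability at arbitrary cells of a stack
predictAtCells <- function(model, stack, cells,
                           type = c("logistic", "raw", "eta")) {
  type <- match.arg(type)
  need <- unique(stats::na.omit(c(model@features@defs$layer,
                                  model@features@defs$layer2)))
  miss <- setdiff(need, layerNames(stack))
  if (length(miss)) stop("stack lacks model layer(s): ",
                         paste(miss, collapse = ", "))
  Fm <- featureMatrix(model@features, extractPredictors(stack, cells))
  eta <- as.numeric(Fm %*% model@lambda)
  switch(type,
    eta = eta,
    raw = { w <- exp(eta - max(eta)); w / sum(w) },
    logistic = {
      qeH <- exp(eta - model@logZ + model@H)
      qeH / (1 + qeH)
    })
}

#' Predict a suitability map
#'
#' Applies a fitted model across the valid cells of a stack. The raw
#' output is the Gibbs distribution renormalised over the prediction
#' region; the logistic output is
#' \eqn{p = q e^H / (1 + q e^H)} using the training partition function
#' and entropy, so it is comparable across maps. Feature values outside
#' the training range are clamped to [0, 1] after scaling.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param stack an \linkS4class{EnvStack} containing (at least) the
#'   model's source layers.
#' @param output "logistic" (default) or "raw".
#' @param replicate replicate identifier stored in the map.
#' @return A \linkS4class{SuitabilityMap}.
#' @export
predictSuitability <- function(model, stack, output = c("logistic", "raw"),
                               replicate = 0L) {
  output <- match.arg(output)
  g <- stackGeometry(stack)
  cells <- validCells(stack)
  p <- predictAtCells(model, stack, cells,
                      if (output == "logistic") "logistic" else "raw")
  v <- rep(NA_real_, g$nrow * g$ncol)
  v[cells] <- p
  new("SuitabilityMap",
      values = matrix(v, g$nrow, g$ncol, byrow = TRUE),
      xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize,
      replicate = as.integer(replicate))
}
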