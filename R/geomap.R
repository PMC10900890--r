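#' @include AllClasses.R
NULL

#' Depth filter for mapping samples
#'
#' Keeps surface samples: marine depth <= 100 m, soil depth <= 30 cm. Samples
#' with missing depth are treated as surface samples and kept.
#'
#' @param samples data.frame with a `depth` column (m for marine, cm for
#'   soil; `NA` allowed).
#' @param habitat "marine" or "soil".
#' @param maxDepth override the habitat default (100 m / 30 cm).
#' @return The retained rows.
#' @export
depthFilter <- function(samples, habitat = c("marine", "soil"), maxDepth = NULL) {
  habitat <- match.arg(habitat)
  if (is.null(maxDepth)) maxDepth <- if (habitat == "marine") 100 else 30
  keep <- is.na(samples$depth) | samples$depth <= maxDepth
  samples[keep, , drop = FALSE]
}

#' Tukey-fence outlier flags (boxplot rule)
#'
#' Flags values outside `[lower hinge - 1.5 IQR, upper hinge + 1.5 IQR]`,
#' with hinges from the five-number summary — the same fences as R's
#' `boxplot.stats`. The mapping workflow applies this exactly once to the
#' response before model fitting; re-application can flag more points and is
#' deliberately not done anywhere in the package.
#'
#' @param values numeric vector.
#' @return Logical flags (`TRUE` = outlier); `NA` values are never flagged.
#' @export
tukeyOutliers <- function(values) {
  f <- stats::fivenum(values, na.rm = TRUE)
  spread <- f[4] - f[2]
  lo <- f[2] - 1.5 * spread
  hi <- f[4] + 1.5 * spread
  flags <- values < lo | values > hi
  flags[is.na(flags)] <- FALSE
  flags
}

#' Specification for the random-forest tuning workflow
#'
#' @param ntreeGrid candidate numbers of trees.
#' @param mtryGrid candidate `mtry` values; `NULL` uses
#'   `unique(c(floor(p/3), floor(sqrt(p)), ceiling(p/2)))` at fit time.
#' @param kFolds cross-validation folds (default 10).
#' @param rfeSizes candidate variable-subset sizes; `NULL` means
#'   `{3, 5, 8, p}` truncated to p.
#' @param responseTransform "log2p" (log2 with data-driven pseudocount,
#'   default) or "identity".
#' @param seed RNG seed fixing fold assignment and forests.
#' @return A list of class `rfModelSpec`.
#' @export
rfModelSpec <- function(ntreeGrid = c(250, 500, 1000), mtryGrid = NULL,
                        kFolds = 10, rfeSizes = NULL,
                        responseTransform = c("log2p", "identity"), seed = 1) {
  stopifnot(kFolds >= 2, length(ntreeGrid) >= 1)
  structure(list(ntreeGrid = ntreeGrid, mtryGrid = mtryGrid, kFolds = kFolds,
                 rfeSizes = rfeSizes,
                 responseTransform = match.arg(responseTransform),
                 seed = seed),
            class = "rfModelSpec")
}

# RFE elimination path on one training set: permutation importance
# (%IncMSE) is recomputed after each drop; returns variables ordered from
# most to least important survivor order.
.rfePath <- function(x, y, ntree, seed) {
  vars <- colnames(x)
  eliminated <- character(0)
  while (length(vars) > 1) {
    set.seed(seed + length(vars))
    fit <- randomForest::randomForest(x[, vars, drop = FALSE], y,
                                      ntree = ntree, importance = TRUE)
    imp <- randomForest::importance(fit, type = 1)[, 1]
    worst <- names(sort(imp))[1]
    eliminated <- c(worst, eliminated)
    vars <- setdiff(vars, worst)
  }
  c(vars, eliminated)  # best-first ranking
}

#' Grid-search random-forest tuning with RFE and k-fold cross-validation
#'
#' For every combination of variable-subset size (from recursive feature
#' elimination), `ntree` and `mtry`, computes the k-fold cross-validated RMSE
#' with fold assignments fixed by the seed; RFE re-ranks variables by
#' permutation importance within each training fold. The best combination
#' (minimum RMSE; ties break to fewer variables, then fewer trees, then
#' smaller `mtry`) is refit on all data.
#'
#' @param covariates data.frame/matrix of predictors (samples x variables).
#' @param response numeric response (producer abundance; transformed per the
#'   spec's `responseTransform`).
#' @param spec an [rfModelSpec()].
#' @return List: `model` (final randomForest), `selected_variables`,
#'   `best` (chosen row), `cv_rmse_table`, `folds`, `pseudocount`.
#' @export
tuneAndFit <- function(covariates, response, spec = rfModelSpec()) {
  x <- as.data.frame(covariates)
  stopifnot(nrow(x) == length(response))
  if (length(unique(response)) < 2) stop("response is constant; nothing to fit")
  if (nrow(x) < 5 * spec$kFolds)
    stop("need at least ", 5 * spec$kFolds, " samples for ", spec$kFolds, "-fold CV")
  pseudo <- NULL
  y <- response
  if (spec$responseTransform == "log2p") {
    lg <- log2Abundance(response)
    y <- lg$values
    pseudo <- lg$pseudocount
  }
  p <- ncol(x)
  mtryGrid <- spec$mtryGrid %||% sort(unique(pmax(1, c(floor(p / 3), floor(sqrt(p)), ceiling(p / 2)))))
  mtryGrid <- mtryGrid[mtryGrid <= p]
  rfeSizes <- sort(unique(pmin(p, spec$rfeSizes %||% c(3, 5, 8, p))))
  set.seed(spec$seed)
  folds <- sample(rep(seq_len(spec$kFolds), length.out = nrow(x)))
  refNtree <- min(spec$ntreeGrid)

  grid <- expand.grid(rfe_size = rfeSizes, ntree = spec$ntreeGrid,
                      mtry = mtryGrid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$mtry <= grid$rfe_size, , drop = FALSE]
  sqerr <- matrix(0, nrow(grid), spec$kFolds)
  nheld <- integer(spec$kFolds)
  for (fold in seq_len(spec$kFolds)) {
    tr <- folds != fold
    path <- .rfePath(as.matrix(x[tr, , drop = FALSE]), y[tr], refNtree,
                     spec$seed * 1000 + fold)
    nheld[fold] <- sum(!tr)
    for (i in seq_len(nrow(grid))) {
      vars <- path[seq_len(grid$rfe_size[i])]
      set.seed(spec$seed * 100 + fold)
      fit <- randomForest::randomForest(x[tr, vars, drop = FALSE], y[tr],
                                        ntree = grid$ntree[i],
                                        mtry = min(grid$mtry[i], length(vars)))
      pred <- stats::predict(fit, x[!tr, vars, drop = FALSE])
      sqerr[i, fold] <- sum((pred - y[!tr])^2)
    }
  }
  grid$cv_rmse <- sqrt(rowSums(sqerr) / sum(nheld))
  ord <- order(grid$cv_rmse, grid$rfe_size, grid$ntree, grid$mtry)
  best <- grid[ord[1], , drop = FALSE]

  set.seed(spec$seed)
  finalPath <- .rfePath(as.matrix(x), y, refNtree, spec$seed)
  vars <- finalPath[seq_len(best$rfe_size)]
  set.seed(spec$seed)
  model <- randomForest::randomForest(x[, vars, drop = FALSE], y,
                                      ntree = best$ntree,
                                      mtry = min(best$mtry, length(vars)),
                                      importance = TRUE)
  list(model = model, selected_variables = vars, best = best,
       cv_rmse_table = grid, folds = folds, pseudocount = pseudo,
       responseTransform = spec$responseTransform)
}

#' Predict a fitted model over a covariate grid
#'
#' Predicts every grid cell with complete covariates; cells with any missing
#' covariate stay `NA` (never imputed). Uncertainty is the standard deviation
#' of the per-tree predictions; the coefficient of variation is also emitted.
#'
#' @param fit result of [tuneAndFit()] (or a bare randomForest).
#' @param grid data.frame with `lat`, `lon` and covariate columns (e.g. from
#'   [rasterFromLong()]).
#' @return `grid` with added `prediction`, `uncertainty_sd`,
#'   `uncertainty_cv` columns.
#' @export
predictGrid <- function(fit, grid) {
  model <- if (inherits(fit, "randomForest")) fit else fit$model
  vars <- if (inherits(fit, "randomForest")) rownames(model$importance) else fit$selected_variables
  miss <- setdiff(vars, names(grid))
  if (length(miss)) stop("grid lacks covariate(s): ", paste(miss, collapse = ", "))
  complete <- stats::complete.cases(grid[, vars, drop = FALSE])
  pred <- sd <- rep(NA_real_, nrow(grid))
  if (any(complete)) {
    pr <- stats::predict(model, grid[complete, vars, drop = FALSE],
                         predict.all = TRUE)
    pred[complete] <- pr$aggregate
    sd[complete] <- apply(pr$individual, 1, stats::sd)
  }
  grid$prediction <- pred
  grid$uncertainty_sd <- sd
  grid$uncertainty_cv <- ifelse(is.na(pred) | pred == 0, NA_real_, sd / abs(pred))
  grid
}

#' Reshape a long-format raster to wide
#'
#' @param long data.frame with `lat`, `lon`, `var`, `value`.
#' @return Wide data.frame, one row per (lat, lon), one column per variable.
#' @export
rasterFromLong <- function(long) {
  stopifnot(all(c("lat", "lon", "var", "value") %in% names(long)))
  wide <- stats::reshape(long, idvar = c("lat", "lon"), timevar = "var",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Regular 0.2-degree prediction grid covering given bounds
#'
#' @param latRange,lonRange numeric ranges in degrees.
#' @param resolution cell size in degrees (default 0.2).
#' @return data.frame of cell-center `lat`, `lon`.
#' @export
predictionGrid <- function(latRange = c(-90, 90), lonRange = c(-180, 180),
                           resolution = 0.2) {
  lat <- seq(latRange[1] + resolution / 2, latRange[2] - resolution / 2,
             by = resolution)
  lon <- seq(lonRange[1] + resolution / 2, lonRange[2] - resolution / 2,
             by = resolution)
  expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
}

#' Latitudinal profile of a predicted surface
#'
#' Mean and dispersion of the predicted value in 1-degree latitude bands;
#' the band mean weights every non-missing cell equally.
#'
#' @param raster data.frame with `lat` and a value column.
#' @param value name of the value column (default "prediction").
#' @param bandWidth band width in degrees (default 1).
#' @return data.frame: `lat_band` (band center), `mean`, `sd`, `n`.
#' @export
latitudinalProfile <- function(raster, value = "prediction", bandWidth = 1) {
  v <- raster[[value]]
  ok <- !is.na(v)
  band <- floor(raster$lat[ok] / bandWidth) * bandWidth + bandWidth / 2
  v <- v[ok]
  out <- data.frame(
    lat_band = sort(unique(band)),
    mean = as.numeric(tapply(v, band, mean)),
    sd = as.numeric(tapply(v, band, stats::sd)),
    n = as.integer(tapply(v, band, length)))
  rownames(out) <- NULL
  out
}
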