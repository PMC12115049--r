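#' Read a source-location table
#'
#' CSV with columns `name`, `x`, `y` and optionally `vertex` (ordered
#' vertex index). Sources with a single row are points; sources with
#' several rows are polylines through their vertices in `vertex`
#' order.
#'
#' @param path CSV path.
#' @return data.frame of class `source_table` with columns `name`,
#'   `vertex`, `x`, `y`.
#' @export
read_sources <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  source_table(df)
}

#' @rdname read_sources
#' @param df data.frame with columns `name`, `x`, `y` and optionally
#'   `vertex`.
#' @export
source_table <- function(df) {
  need <- c("name", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("source table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"vertex" %in% names(df)) {
    df$vertex <- stats::ave(seq_len(nrow(df)), df$name,
                            FUN = seq_along)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("non-finite source coordinates", call. = FALSE)
  df <- df[order(match(df$name, unique(df$name)), df$vertex),
           c("name", "vertex", "x", "y")]
  rownames(df) <- NULL
  structure(df, class = c("source_table", "data.frame"))
}

# internal: distance from point p to segment ab (planar km)
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# internal: distance from each (x, y) sample to a source geometry
# (point, or nearest point on the polyline through its vertices)
dist_to_source <- function(x, y, geom) {
  if (nrow(geom) == 1)
    return(sqrt((x - geom$x)^2 + (y - geom$y)^2))
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(geom) - 1)) {
    d <- pmin(d, dist_point_segment(x, y, geom$x[k], geom$y[k],
                                    geom$x[k + 1], geom$y[k + 1]))
  }
  d
}

#' Build a source-proximity feature matrix
#'
#' One feature per named source: exp(-d / lambda), where d is the
#' planar Euclidean distance (km) from the sample to the source point,
#' or to the nearest point on the source polyline. Proximity (rather
#' than raw distance) makes forest importances read as source
#' influence: the feature is 1 at the source and decays to 0 far away.
#'
#' @param samples a `concentration_table` (or data.frame) with `x`,
#'   `y` coordinate columns in km.
#' @param sources a `source_table`.
#' @param lambda decay length in km (default 10).
#' @return Samples x sources numeric matrix of class
#'   `source_feature_matrix`, with attributes `lambda` and `metric`.
#' @export
build_feature_matrix <- function(samples, sources, lambda = 10) {
  if (!all(c("x", "y") %in% names(samples)))
    stop("samples need x and y coordinate columns", call. = FALSE)
  bad <- !is.finite(samples$x) | !is.finite(samples$y)
  if (any(bad))
    stop("missing coordinates for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "), call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  nm <- unique(sources$name)
  feat <- vapply(nm, function(s) {
    geom <- sources[sources$name == s, , drop = FALSE]
    exp(-dist_to_source(samples$x, samples$y, geom) / lambda)
  }, numeric(nrow(samples)))
  feat <- matrix(feat, nrow = nrow(samples),
                 dimnames = list(samples$sample_id, nm))
  structure(feat, lambda = lambda, metric = "euclidean_km",
            class = c("source_feature_matrix", class(feat)))
}

#' Regression evaluation metrics
#'
#' R-squared (1 - SSres/SStot), RMSE, MAE and RPD (standard deviation
#' of the observations divided by RMSE, the chemometrics residual
#' prediction deviation; RPD > 2 conventionally indicates a reliable
#' model). A perfect fit yields RMSE = MAE = 0 and RPD = Inf.
#'
#' @param obs observed values (length >= 2, not constant).
#' @param pred predicted values, same length.
#' @return Named numeric: r2, rmse, mae, rpd.
#' @export
evaluate <- function(obs, pred) {
  if (length(obs) != length(pred))
    stop("obs and pred must have equal length", call. = FALSE)
  if (length(obs) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(obs) == 0)
    stop("constant observations: R-squared undefined", call. = FALSE)
  res <- obs - pred
  rmse <- sqrt(mean(res^2))
  c(r2 = 1 - sum(res^2) / sum((obs - mean(obs))^2),
    rmse = rmse,
    mae = mean(abs(res)),
    rpd = if (rmse == 0) Inf else stats::sd(obs) / rmse)
}

#' Normalized impurity importance shares
#'
#' Impurity-based (IncNodePurity) feature importances of a fitted
#' forest, normalized to percentages summing to 100.
#'
#' @param forest a fitted [randomForest::randomForest] regression
#'   forest.
#' @return Named numeric percentages per feature.
#' @export
importance_shares <- function(forest) {
  imp <- randomForest::importance(forest, type = 2)[, 1]
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) return(stats::setNames(rep(100 / length(imp),
                                                length(imp)), names(imp)))
  100 * imp / sum(imp)
}

#' Fit a random forest of one metal on source-proximity features
#'
#' Trains a regression forest on a train split, evaluates on both
#' splits, records the OOB estimate, and normalizes the impurity
#' importances to percent shares per source. Fully reproducible given
#' `seed`: the split and the forest use a seeded RNG.
#'
#' @param features a `source_feature_matrix` (or numeric matrix).
#' @param y numeric response (metal concentrations, mg/kg), one per
#'   feature row.
#' @param seed integer RNG seed (default 42).
#' @param split train fraction (default 0.7).
#' @param strata optional factor (e.g. species) for stratified
#'   splitting; each stratum is split at `split` separately.
#' @param ntree,mtry forest size and candidate features per split
#'   (defaults 500 and floor(sqrt(p))).
#' @return List of class `rf_fit`: `forest`, `metrics` (data.frame
#'   with train/test rows of r2, rmse, mae, rpd), `oob_r2`,
#'   `importance_share`, `split` metadata.
#' @export
fit_rf <- function(features, y, seed = 42, split = 0.7, strata = NULL,
                   ntree = 500, mtry = NULL) {
  feat <- as.matrix(features)
  if (length(y) != nrow(feat))
    stop("y length must match feature rows", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("constant response: R-squared undefined", call. = FALSE)
  if (nrow(feat) < 20)
    stop("need at least 20 samples for a meaningful split", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(feat))))
  set.seed(seed)
  idx <- seq_len(nrow(feat))
  if (is.null(strata)) strata <- rep("all", nrow(feat))
  strata <- as.factor(strata)
  train <- unlist(lapply(split(idx, strata), function(i) {
    n_tr <- max(1L, round(split * length(i)))
    if (n_tr >= length(i)) n_tr <- length(i) - 1L
    sample(i, n_tr)
  }), use.names = FALSE)
  test <- setdiff(idx, train)
  forest <- randomForest::randomForest(
    x = feat[train, , drop = FALSE], y = y[train],
    ntree = ntree, mtry = mtry, importance = FALSE)
  m_train <- evaluate(y[train],
                      stats::predict(forest, feat[train, , drop = FALSE]))
  m_test <- evaluate(y[test],
                     stats::predict(forest, feat[test, , drop = FALSE]))
  metrics <- data.frame(split = c("train", "test"),
                        rbind(m_train, m_test), row.names = NULL)
  oob_r2 <- 1 - forest$mse[forest$ntree] / stats::var(y[train])
  structure(list(forest = forest, metrics = metrics, oob_r2 = oob_r2,
                 importance_share = importance_shares(forest),
                 split = list(fraction = split, seed = seed,
                              n_train = length(train),
                              n_test = length(test))),
            class = "rf_fit")
}

#' Random-forest source apportionment over all metals
#'
#' Fits one regression forest per metal on the source-proximity
#' features and collects evaluation metrics (train/test R-squared,
#' RMSE, MAE, and test RPD) and percent importance shares per source.
#'
#' @param plants a plant `concentration_table` with coordinates, or a
#'   response matrix whose rows align with `features`.
#' @param features a `source_feature_matrix`; built from `sources`
#'   when omitted.
#' @param sources a `source_table` (used when `features` is missing).
#' @param metals metals to model (default: the table's metal set).
#' @param seed,split,ntree,mtry,lambda see [fit_rf()] and
#'   [build_feature_matrix()].
#' @param stratify_by_species stratify the split by the plant species
#'   column when present (default TRUE).
#' @param normalize_species divide each metal by its species mean
#'   before fitting (default TRUE when a species column is present).
#'   Species-specific uptake differences otherwise dominate the
#'   variance of plant-tissue concentrations and mask the spatial
#'   source signal; the normalized response is the dimensionless
#'   within-species relative enrichment, and evaluation metrics are
#'   then on that scale. Set to FALSE for metrics in mg/kg.
#' @return Object of class `rf_apportionment`: `fits` (per-metal
#'   `rf_fit`), `metrics` (long data.frame: metal, split, r2, rmse,
#'   mae, rpd), `importance` (metal x source percent matrix, rows
#'   summing to 100), `oob_r2`, and split metadata.
#' @export
rf_apportion <- function(plants, features = NULL, sources = NULL,
                         metals = NULL, seed = 42, split = 0.7,
                         ntree = 500, mtry = NULL, lambda = 10,
                         stratify_by_species = TRUE,
                         normalize_species = NULL) {
  if (is.null(metals)) metals <- attr(plants, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(plants))
  if (is.null(features)) {
    if (is.null(sources))
      stop("supply either features or sources", call. = FALSE)
    features <- build_feature_matrix(plants, sources, lambda = lambda)
  }
  has_species <- "species" %in% names(plants)
  if (is.null(normalize_species)) normalize_species <- has_species
  if (normalize_species && !has_species)
    stop("normalize_species requires a species column", call. = FALSE)
  strata <- if (stratify_by_species && has_species)
    plants$species else NULL
  fits <- list(); metrics <- NULL
  imp <- matrix(NA_real_, length(metals), ncol(features),
                dimnames = list(metals, colnames(features)))
  for (m in metals) {
    y <- plants[[m]]
    if (normalize_species)
      y <- y / stats::ave(y, plants$species)
    f <- fit_rf(features, y, seed = seed, split = split,
                strata = strata, ntree = ntree, mtry = mtry)
    fits[[m]] <- f
    metrics <- rbind(metrics, data.frame(metal = m, f$metrics,
                                         row.names = NULL))
    imp[m, ] <- f$importance_share
  }
  structure(list(fits = fits, metrics = metrics, importance = imp,
                 oob_r2 = vapply(fits, `[[`, numeric(1), "oob_r2"),
                 split = fits[[1]]$split,
                 lambda = attr(features, "lambda"),
                 normalize_species = normalize_species),
            class = "rf_apportionment")
}

#' @export
print.rf_apportionment <- function(x, digits = 3, ...) {
  cat("Random-forest source apportionment:", length(x$fits), "metals,",
      ncol(x$importance), "sources;", x$split$n_train, "train /",
      x$split$n_test, "test samples\n")
  test <- x$metrics[x$metrics$split == "test", ]
  num <- vapply(test, is.numeric, logical(1))
  test[num] <- lapply(test[num], round, digits = digits)
  cat("Test-split metrics:\n")
  print(test, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rf_apportionment <- function(object, digits = 1, ...) {
  print(object)
  cat("\nImportance shares (percent, rows sum to 100):\n")
  print(round(object$importance, digits))
  invisible(object)
}

#' @export
plot.rf_apportionment <- function(x, ...) {
  graphics::barplot(t(x$importance), beside = FALSE,
                    col = grDevices::hcl.colors(ncol(x$importance),
                                                "Temps"),
                    ylab = "importance share (%)",
                    legend.text = colnames(x$importance),
                    args.legend = list(x = "topright", cex = 0.7,
                                       bg = "white"), ...)
  invisible(x)
}
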