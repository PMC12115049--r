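#' Standardize a concentration matrix
#'
#' Centers and scales each metal column to mean 0 and sample standard
#' deviation 1 (n - 1 denominator): Z = (C - Cbar) / sigma.
#'
#' @param x a `concentration_table` or numeric matrix (samples x
#'   metals).
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  mat <- if (is.matrix(x)) x else metal_matrix(x)
  ctr <- colMeans(mat)
  scl <- apply(mat, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance metal(s): ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(mat, 2, ctr, `-`), 2, scl, `/`)
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Principal component analysis of standardized concentrations
#'
#' Eigendecomposition of the metal correlation matrix. Loadings are
#' scaled eigenvectors (eigenvector times sqrt(eigenvalue)), ordered
#' by descending eigenvalue; each component's sign is flipped so its
#' largest-magnitude loading is positive. Components with eigenvalue
#' above 1 are retained (Kaiser criterion).
#'
#' @param z standardized matrix from [standardize()].
#' @param kaiser_threshold eigenvalue retention cutoff (default 1).
#' @return List of class `metal_pca`: `loadings` (metal x component),
#'   `eigenvalues`, `q` (retained component count), `score_coef`
#'   (metal x retained-component score-coefficient matrix),
#'   `variance_explained` (percent per component).
#' @export
fit_pca <- function(z, kaiser_threshold = 1) {
  if (ncol(z) < 2) stop("need at least 2 metals", call. = FALSE)
  if (nrow(z) < 3) stop("need at least 3 samples", call. = FALSE)
  R <- stats::cor(z)
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-8))
    warning("correlation matrix numerically rank-deficient; ",
            "negative eigenvalues truncated to 0", call. = FALSE)
  lam <- pmax(lam, 0)
  V <- e$vectors
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  loadings <- V %*% diag(sqrt(lam), nrow = length(lam))
  dimnames(loadings) <- list(colnames(z),
                             paste0("PC", seq_along(lam)))
  q <- sum(lam > kaiser_threshold)
  if (q == 0) {
    warning("no eigenvalue exceeds the Kaiser threshold; retaining PC1",
            call. = FALSE)
    q <- 1L
  }
  # score coefficients give unit-variance component scores: Z V / sqrt(lam)
  keep <- seq_len(q)
  score_coef <- V[, keep, drop = FALSE] %*%
    diag(1 / sqrt(lam[keep]), nrow = q)
  dimnames(score_coef) <- list(colnames(z), paste0("PC", keep))
  structure(list(loadings = loadings, eigenvalues = lam, q = q,
                 score_coef = score_coef,
                 variance_explained = 100 * lam / length(lam)),
            class = "metal_pca")
}

#' Absolute principal component scores
#'
#' Component scores for each sample minus the score of an artificial
#' sample whose concentrations are all zero: APCS_jk = (AZ)_jk -
#' (A0)_j, with (Z0)_i = (0 - Cbar_i) / sigma_i. The zero-sample
#' offset makes scores interpretable as non-negative-origin source
#' intensities.
#'
#' @param pca a `metal_pca` fit.
#' @param z the standardized matrix the fit was built from (carrying
#'   `center`/`scale` attributes).
#' @return Sample x retained-component APCS matrix with attribute
#'   `a0` (the zero-sample score vector).
#' @export
absolute_scores <- function(pca, z) {
  ctr <- attr(z, "center"); scl <- attr(z, "scale")
  if (is.null(ctr) || is.null(scl))
    stop("z must carry center/scale attributes from standardize()",
         call. = FALSE)
  az <- z %*% pca$score_coef
  z0 <- (0 - ctr) / scl
  a0 <- drop(z0 %*% pca$score_coef)
  apcs <- sweep(az, 2, a0, `-`)
  attr(apcs, "a0") <- a0
  apcs
}

#' Per-metal regression of concentrations on APCS
#'
#' Ordinary least squares per metal: C_metal = b0 + sum_j b_j *
#' APCS_j. The intercept b0 is the part of the mean concentration not
#' attributed to any retained component (the "unidentified" source in
#' the contribution accounting).
#'
#' @param apcs APCS matrix from [absolute_scores()].
#' @param x the `concentration_table` (or matrix) of dependent
#'   concentrations.
#' @param max_condition condition-number threshold above which the
#'   APCS design is declared collinear (default 1e8).
#' @return List: `coefficients` (metal x (intercept, components)
#'   matrix), `r2` (named per-metal R-squared), `fitted` (matrix).
#' @export
fit_source_regression <- function(apcs, x, max_condition = 1e8) {
  mat <- if (is.matrix(x)) x else metal_matrix(x)
  if (nrow(mat) != nrow(apcs))
    stop("APCS and concentration tables disagree on sample count",
         call. = FALSE)
  if (nrow(apcs) <= ncol(apcs) + 1)
    stop("need more samples than components + 1", call. = FALSE)
  kap <- kappa(cbind(1, apcs), exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("collinear APCS columns (condition number ",
         format(kap, digits = 3), ")", call. = FALSE)
  df <- as.data.frame(apcs)
  coefs <- matrix(NA_real_, nrow = ncol(mat), ncol = ncol(apcs) + 1,
                  dimnames = list(colnames(mat),
                                  c("(Intercept)", colnames(apcs))))
  r2 <- stats::setNames(numeric(ncol(mat)), colnames(mat))
  fitted <- matrix(NA_real_, nrow(mat), ncol(mat),
                   dimnames = dimnames(mat))
  for (m in colnames(mat)) {
    fit <- stats::lm(mat[, m] ~ ., data = df)
    coefs[m, ] <- stats::coef(fit)
    r2[m] <- summary(fit)$r.squared
    fitted[, m] <- stats::fitted(fit)
  }
  list(coefficients = coefs, r2 = r2, fitted = fitted)
}

#' Fit the APCS-MLR receptor model
#'
#' The full Thurston-style receptor model: standardize the metal
#' concentrations, run a PCA on the correlation matrix retaining
#' Kaiser components (eigenvalue > 1), convert component scores to
#' absolute principal component scores by subtracting the
#' zero-concentration sample's score, regress each metal on the APCS
#' columns, and convert regression terms into percent source
#' contributions (including an unidentified term from the intercept).
#'
#' @param x a `concentration_table` (typically the plant table) or a
#'   samples x metals matrix.
#' @param kaiser_threshold eigenvalue retention cutoff (default 1).
#' @param ncomp optional fixed number of components, overriding the
#'   Kaiser rule.
#' @param rotate `"none"` (default; loadings presented as raw PCs) or
#'   `"varimax"`.
#' @return Object of class `apcs_mlr`; see Details. Use `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()` and
#'   `plot()` on the result, and [source_contributions()] for the
#'   contribution table.
#' @details The returned object carries `center`/`scale`, the PCA
#'   (`pca`), the APCS matrix (`apcs`), the per-metal regression
#'   (`regression`), and `contributions`: for metal i and component j
#'   the mean attributed concentration is b_ij * mean(APCS_j), the
#'   unidentified term is the intercept b0_i, and percent shares are
#'   absolute mean contributions normalized to sum to 100.
#' @export
apcs_mlr <- function(x, kaiser_threshold = 1, ncomp = NULL,
                     rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  mat <- if (is.matrix(x)) x else metal_matrix(x)
  z <- standardize(mat)
  pca <- fit_pca(z, kaiser_threshold = kaiser_threshold)
  if (!is.null(ncomp)) {
    ncomp <- as.integer(ncomp)
    if (ncomp < 1 || ncomp > ncol(mat))
      stop("ncomp out of range", call. = FALSE)
    keep <- seq_len(ncomp)
    lam <- pca$eigenvalues
    pca$q <- ncomp
    V <- pca$loadings %*% diag(1 / sqrt(pmax(lam, 1e-12)),
                               nrow = length(lam))
    pca$score_coef <- V[, keep, drop = FALSE] %*%
      diag(1 / sqrt(lam[keep]), nrow = ncomp)
    dimnames(pca$score_coef) <- list(colnames(mat), paste0("PC", keep))
  }
  if (rotate == "varimax" && pca$q > 1) {
    keep <- seq_len(pca$q)
    vm <- stats::varimax(pca$loadings[, keep, drop = FALSE])
    rot <- vm$rotmat
    pca$loadings[, keep] <- pca$loadings[, keep, drop = FALSE] %*% rot
    pca$score_coef <- pca$score_coef %*% rot
    colnames(pca$score_coef) <- paste0("PC", keep)
  }
  apcs <- absolute_scores(pca, z)
  reg <- fit_source_regression(apcs, mat)

  comp_names <- colnames(apcs)
  mean_apcs <- colMeans(apcs)
  contrib <- matrix(NA_real_, nrow = ncol(mat),
                    ncol = length(comp_names) + 1,
                    dimnames = list(colnames(mat),
                                    c(comp_names, "unidentified")))
  for (m in colnames(mat)) {
    b0 <- reg$coefficients[m, 1]
    bj <- reg$coefficients[m, -1]
    contrib[m, ] <- c(bj * mean_apcs, b0)
  }
  abs_c <- abs(contrib)
  pct <- 100 * abs_c / rowSums(abs_c)

  structure(list(
    call = match.call(),
    metals = colnames(mat), n = nrow(mat),
    center = attr(z, "center"), scale = attr(z, "scale"),
    pca = pca, z = z, apcs = apcs, a0 = attr(apcs, "a0"),
    regression = reg, r2 = reg$r2,
    mean_contribution = contrib, contribution_percent = pct,
    rotate = rotate), class = "apcs_mlr")
}

#' Percent source contributions from a fitted APCS-MLR model
#'
#' @param object a fitted `apcs_mlr` model.
#' @return data.frame: metal, source_component (retained components
#'   plus "unidentified"), mean_contribution (mg/kg, signed), percent
#'   (absolute shares summing to 100 per metal), regression_r2.
#' @export
source_contributions <- function(object) {
  stopifnot(inherits(object, "apcs_mlr"))
  if (all(abs(object$mean_contribution) == 0))
    stop("all-zero mean contributions; cannot form percent shares",
         call. = FALSE)
  comp <- colnames(object$contribution_percent)
  out <- expand.grid(metal = object$metals, source_component = comp,
                     stringsAsFactors = FALSE)
  out$mean_contribution <-
    object$mean_contribution[cbind(out$metal, out$source_component)]
  out$percent <-
    object$contribution_percent[cbind(out$metal, out$source_component)]
  out$regression_r2 <- unname(object$r2[out$metal])
  out[order(match(out$metal, object$metals)), , drop = FALSE]
}

#' @export
print.apcs_mlr <- function(x, digits = 3, ...) {
  cat("APCS-MLR receptor model:", x$n, "samples,", length(x$metals),
      "metals,", x$pca$q, "retained component(s)",
      if (x$rotate != "none") paste0("(", x$rotate, " rotation)"), "\n")
  cat("Eigenvalues:", paste(round(x$pca$eigenvalues, digits),
                            collapse = ", "), "\n")
  cat("Per-metal regression R-squared:\n")
  print(round(x$r2, digits))
  invisible(x)
}

#' @export
summary.apcs_mlr <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  keep <- seq_len(object$pca$q)
  cat("\nLoadings (retained components):\n")
  print(round(object$pca$loadings[, keep, drop = FALSE], digits))
  cat("\nContribution shares (percent, rows sum to 100):\n")
  print(round(object$contribution_percent, 1))
  invisible(object)
}

#' @export
coef.apcs_mlr <- function(object, ...) object$regression$coefficients

#' @export
fitted.apcs_mlr <- function(object, ...) object$regression$fitted

#' @export
residuals.apcs_mlr <- function(object, ...) {
  mat <- sweep(sweep(object$z, 2, object$scale, `*`), 2, object$center,
               `+`)
  mat - object$regression$fitted
}

#' Predict concentrations for new samples from a fitted APCS-MLR model
#'
#' Projects new samples onto the fitted components (using the training
#' centering/scaling), forms their APCS values, and applies the
#' per-metal regressions.
#'
#' @param object a fitted `apcs_mlr` model.
#' @param newdata a `concentration_table` or matrix with the model's
#'   metal columns; omitted, returns fitted values.
#' @param ... unused.
#' @return Matrix of predicted concentrations (samples x metals).
#' @export
predict.apcs_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  mat <- if (is.matrix(newdata)) newdata else
    metal_matrix(newdata, metals = object$metals)
  z <- sweep(sweep(mat[, object$metals, drop = FALSE], 2, object$center,
                   `-`), 2, object$scale, `/`)
  apcs <- sweep(z %*% object$pca$score_coef, 2, object$a0, `-`)
  b <- object$regression$coefficients
  pred <- cbind(1, apcs) %*% t(b)
  dimnames(pred) <- list(rownames(mat), object$metals)
  pred
}

#' @export
plot.apcs_mlr <- function(x, ...) {
  pct <- t(x$contribution_percent)
  graphics::barplot(pct, beside = FALSE, col = grDevices::hcl.colors(
    nrow(pct), "Zissou 1"), ylab = "contribution (%)",
    legend.text = rownames(pct),
    args.legend = list(x = "topright", cex = 0.7, bg = "white"), ...)
  invisible(x)
}
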