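#' Single-factor pollution index
#'
#' Pi = Ci / Bi: the measured concentration divided by the regional
#' geochemical background value. Values above 1 indicate enrichment
#' over background.
#'
#' @param conc measured concentration (mg/kg), >= 0. Vectorized.
#' @param background regional background value (mg/kg), > 0.
#' @return Dimensionless index, same length as `conc`.
#' @export
single_factor_index <- function(conc, background) {
  if (any(!is.finite(background)) || any(background <= 0))
    stop("background value must be positive", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be non-negative", call. = FALSE)
  conc / background
}

#' Nemerow composite pollution index
#'
#' The quadratic mean of the average and maximum single-factor
#' indices, NIPI = sqrt((Pave^2 + Pmax^2) / 2). Weighting the maximum
#' emphasizes the most polluted component.
#'
#' @param p_ave average single-factor index, >= 0.
#' @param p_max maximum single-factor index, >= 0.
#' @return Dimensionless composite index.
#' @export
nemerow_index <- function(p_ave, p_max) {
  if (any(!is.finite(p_ave)) || any(!is.finite(p_max)) ||
      any(p_ave < 0) || any(p_max < 0))
    stop("Nemerow inputs must be non-negative", call. = FALSE)
  sqrt((p_ave^2 + p_max^2) / 2)
}

#' Classify a Nemerow index value
#'
#' Standard Nemerow scheme with right-closed intervals:
#' NIPI <= 0.7 Safe; (0.7, 1] Alert; (1, 2] Light Pollution;
#' (2, 3] Moderate Pollution; > 3 Heavy Pollution.
#'
#' @param nipi index value(s), >= 0.
#' @param refs a [reference_set()] supplying the thresholds.
#' @return Character label(s).
#' @export
classify_nipi <- function(nipi, refs = default_references()) {
  if (any(nipi < 0)) stop("NIPI must be non-negative", call. = FALSE)
  classify_by_breaks(nipi, refs$nipi_classes)
}

#' Hakanson single-metal potential ecological risk
#'
#' Er = Tr * Pi: the single-factor index weighted by the metal's
#' toxicity coefficient.
#'
#' @param pi single-factor pollution index, >= 0. Vectorized.
#' @param tr toxicity coefficient, > 0.
#' @return Dimensionless risk index.
#' @export
ecological_risk <- function(pi, tr) {
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop("toxicity coefficient must be positive", call. = FALSE)
  if (any(!is.finite(pi)) || any(pi < 0))
    stop("pollution index must be non-negative", call. = FALSE)
  tr * pi
}

#' Aggregate single-metal risks into a composite RI
#'
#' RI is the plain sum of the supplied Er values. The caller chooses
#' the aggregation axis: summing a sample's Er across metals gives the
#' sample's composite risk; summing a metal's per-sample Er across the
#' survey gives the per-metal survey total.
#'
#' @param er numeric vector of Er values, all >= 0, non-empty.
#' @return The sum.
#' @export
aggregate_ri <- function(er) {
  if (length(er) == 0) stop("cannot aggregate an empty Er vector",
                            call. = FALSE)
  if (any(!is.finite(er)) || any(er < 0))
    stop("Er values must be non-negative", call. = FALSE)
  sum(er)
}

#' Classify Er and RI values on the standard Hakanson scheme
#'
#' Er: < 40 Low, [40, 80) Moderate, [80, 160) Considerable,
#' [160, 320) High, >= 320 Very High. RI: < 150 Low, [150, 300)
#' Moderate, [300, 600) High, >= 600 Very High.
#'
#' @param er,ri index value(s).
#' @param refs a [reference_set()] supplying the thresholds.
#' @return Character label(s).
#' @export
classify_er <- function(er, refs = default_references()) {
  classify_by_breaks(er, refs$er_classes)
}

#' @rdname classify_er
#' @export
classify_ri <- function(ri, refs = default_references()) {
  classify_by_breaks(ri, refs$ri_classes)
}

#' Full pollution-index report for a soil survey
#'
#' Computes, per metal: the per-sample single-factor indices Pi, the
#' survey-average and survey-maximum indices, the Nemerow composite
#' NIPI with its class label, the per-sample Hakanson risks Er, the
#' survey-total RI (sum of per-sample Er across all samples) with its
#' class label.
#'
#' @param soil a soil `concentration_table`.
#' @param refs a [reference_set()].
#' @return An object of class `index_report`: a list with `summary`
#'   (data.frame: metal, p_ave, p_max, nipi, nipi_level, ri,
#'   risk_level), `pi` and `er` (sample x metal matrices).
#' @export
pollution_indices <- function(soil, refs = default_references()) {
  mat <- metal_matrix(soil)
  metals <- colnames(mat)
  check_metals_covered(metals, refs$background, "background")
  check_metals_covered(metals, refs$toxicity, "toxicity")
  pi_mat <- sweep(mat, 2, refs$background[metals], `/`)
  er_mat <- sweep(pi_mat, 2, refs$toxicity[metals], `*`)
  p_ave <- colMeans(pi_mat)
  p_max <- apply(pi_mat, 2, max)
  nipi <- nemerow_index(p_ave, p_max)
  ri <- apply(er_mat, 2, aggregate_ri)
  summary <- data.frame(
    metal = metals,
    p_ave = unname(p_ave), p_max = unname(p_max),
    nipi = unname(nipi),
    nipi_level = classify_nipi(nipi, refs),
    ri = unname(ri),
    risk_level = classify_ri(ri, refs),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, pi = pi_mat, er = er_mat, refs = refs),
            class = "index_report")
}

#' @export
print.index_report <- function(x, digits = 4, ...) {
  cat("Pollution indices over", nrow(x$pi), "samples\n")
  out <- x$summary
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  print(out, row.names = FALSE)
  invisible(x)
}
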