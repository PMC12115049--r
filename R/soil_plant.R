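#' Bioconcentration factor
#'
#' BCF = Cp / Cs: plant-tissue concentration divided by the paired
#' soil concentration. Values above 1 indicate active accumulation in
#' the plant.
#'
#' @param cp plant concentration (mg/kg), >= 0. Vectorized.
#' @param cs paired soil concentration (mg/kg), > 0.
#' @return Dimensionless factor.
#' @export
bcf <- function(cp, cs) {
  if (any(!is.finite(cs)) || any(cs <= 0))
    stop("soil concentration must be positive for a BCF", call. = FALSE)
  if (any(!is.finite(cp)) || any(cp < 0))
    stop("plant concentration must be non-negative", call. = FALSE)
  cp / cs
}

#' Exceedance fold against a plant standard limit
#'
#' @param mean_c mean plant concentration (mg/kg).
#' @param limit plant standard limit (mg/kg), > 0.
#' @return mean_c / limit; values above 1 exceed the standard.
#' @export
exceedance_fold <- function(mean_c, limit) {
  if (any(!is.finite(limit)) || any(limit <= 0))
    stop("standard limit must be positive", call. = FALSE)
  mean_c / limit
}

# internal: align plant rows with their paired soil rows by sample_id.
# Returns list(plants, soil) with identical row order.
pair_tables <- function(plants, soil) {
  idx <- match(plants$sample_id, soil$sample_id)
  if (anyNA(idx))
    stop("plant sample(s) without a paired soil sample: ",
         paste(plants$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  list(plants = as.data.frame(plants),
       soil = as.data.frame(soil)[idx, , drop = FALSE])
}

#' Per-species and cross-species BCF summary
#'
#' Computes per-sample BCFs on matched sample_id pairs, averages them
#' within species, then averages the species means (unweighted) into a
#' cross-species mean per metal. The cross-species mean is the
#' unweighted mean of species means, not the pooled per-sample mean.
#' Samples whose paired soil concentration is zero are excluded with a
#' warning; species with no usable pairs are omitted with a warning.
#'
#' @param plants a plant `concentration_table`.
#' @param soil the paired soil `concentration_table`.
#' @return An object of class `bcf_report`: a list with `samples`
#'   (long data.frame: sample_id, species, metal, bcf), `species`
#'   (species x metal mean BCF with n), and `overall` (metal,
#'   mean_bcf: the unweighted mean of species means).
#' @export
species_bcf_summary <- function(plants, soil) {
  metals <- attr(plants, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(plants))
  pr <- pair_tables(plants, soil)
  pm <- as.matrix(pr$plants[, metals, drop = FALSE])
  sm <- as.matrix(pr$soil[, metals, drop = FALSE])
  species <- pr$plants$species

  long <- NULL
  for (m in metals) {
    ok <- sm[, m] > 0
    if (any(!ok))
      warning(sum(!ok), " sample(s) with zero soil ", m,
              " excluded from BCF", call. = FALSE)
    long <- rbind(long, data.frame(
      sample_id = pr$plants$sample_id[ok], species = species[ok],
      metal = m, bcf = pm[ok, m] / sm[ok, m], stringsAsFactors = FALSE))
  }
  sp_levels <- unique(species)
  usable <- vapply(sp_levels, function(s) sum(long$species == s) > 0,
                   logical(1))
  if (any(!usable))
    warning("species with no paired samples omitted: ",
            paste(sp_levels[!usable], collapse = ", "), call. = FALSE)
  sp_levels <- sp_levels[usable]

  species_tab <- do.call(rbind, lapply(sp_levels, function(s) {
    sub <- long[long$species == s, ]
    data.frame(species = s, metal = metals,
               mean_bcf = vapply(metals, function(m)
                 mean(sub$bcf[sub$metal == m]), numeric(1)),
               n = vapply(metals, function(m)
                 sum(sub$metal == m), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  overall <- data.frame(
    metal = metals,
    mean_bcf = vapply(metals, function(m)
      mean(species_tab$mean_bcf[species_tab$metal == m]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(samples = long, species = species_tab, overall = overall),
            class = "bcf_report")
}

#' @export
print.bcf_report <- function(x, digits = 3, ...) {
  cat("Bioconcentration factors:", length(unique(x$species$species)),
      "species,", length(unique(x$species$metal)), "metals\n")
  cat("Cross-species means (unweighted over species):\n")
  out <- x$overall
  out$mean_bcf <- round(out$mean_bcf, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Exceedance folds of species-mean plant concentrations
#'
#' @param plants a plant `concentration_table`.
#' @param refs a [reference_set()] supplying plant standard limits.
#' @return data.frame: species, metal, mean_conc, limit, fold.
#' @export
exceedance_table <- function(plants, refs = default_references()) {
  metals <- attr(plants, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(plants))
  check_metals_covered(metals, refs$plant_limit, "plant_limit")
  sp <- unique(plants$species)
  out <- expand.grid(species = sp, metal = metals,
                     stringsAsFactors = FALSE)
  out$mean_conc <- mapply(function(s, m)
    mean(plants[[m]][plants$species == s]), out$species, out$metal)
  out$limit <- refs$plant_limit[out$metal]
  out$fold <- exceedance_fold(out$mean_conc, out$limit)
  rownames(out) <- NULL
  out
}

#' Per-species soil-plant Pearson correlation matrices
#'
#' For every species, the Pearson correlation between each plant-metal
#' column and each soil-metal column over that species' paired
#' samples. Zero-variance columns yield NA entries with a warning.
#'
#' @param plants a plant `concentration_table`.
#' @param soil the paired soil `concentration_table`.
#' @param min_n minimum paired samples required per species (default 3).
#' @return Named list (one element per species) of matrices with
#'   plant metals in rows and soil metals in columns; class
#'   `correlation_set`.
#' @export
soil_plant_correlations <- function(plants, soil, min_n = 3) {
  metals <- attr(plants, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(plants))
  pr <- pair_tables(plants, soil)
  out <- list()
  for (s in unique(pr$plants$species)) {
    sel <- pr$plants$species == s
    if (sum(sel) < min_n)
      stop("species ", s, " has fewer than ", min_n, " paired samples",
           call. = FALSE)
    pm <- as.matrix(pr$plants[sel, metals, drop = FALSE])
    sm <- as.matrix(pr$soil[sel, metals, drop = FALSE])
    zv <- c(colnames(pm)[apply(pm, 2, stats::sd) == 0],
            colnames(sm)[apply(sm, 2, stats::sd) == 0])
    if (length(zv))
      warning("zero-variance column(s) for species ", s, ": ",
              paste(unique(zv), collapse = ", "),
              "; correlations reported as NA", call. = FALSE)
    r <- suppressWarnings(stats::cor(pm, sm))
    dimnames(r) <- list(plant = metals, soil = metals)
    out[[s]] <- r
  }
  structure(out, class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, digits = 2, ...) {
  for (s in names(x)) {
    cat("Species:", s, "(plant rows vs soil columns)\n")
    print(round(unclass(x)[[s]], digits))
    cat("\n")
  }
  invisible(x)
}

#' Nonparametric group-difference tests across species
#'
#' Per metal, a Kruskal-Wallis omnibus test of equality across species
#' groups; when the omnibus p-value is below `alpha`, pairwise
#' Mann-Whitney (Wilcoxon rank-sum) comparisons with Bonferroni
#' adjustment. Groups with fewer than 2 observations are excluded with
#' a warning. When all observations of a metal are identical the
#' omnibus p-value is reported as 1 (no evidence of a difference).
#'
#' @param plants a plant `concentration_table` with >= 2 species.
#' @param alpha omnibus significance gate for running pairwise
#'   comparisons (default 0.05).
#' @return List with `omnibus` (metal, statistic, df, p) and
#'   `pairwise` (metal, group1, group2, p_raw, p_adj) data.frames;
#'   `pairwise` is empty when no omnibus test crosses `alpha`.
#' @export
group_difference_tests <- function(plants, alpha = 0.05) {
  metals <- attr(plants, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(plants))
  species <- plants$species
  counts <- table(species)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("species with < 2 observations excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !species %in% small
    plants <- as.data.frame(plants)[keep, , drop = FALSE]
    species <- plants$species
  }
  groups <- unique(species)
  if (length(groups) < 2)
    stop("need at least 2 species groups with >= 2 observations",
         call. = FALSE)

  omnibus <- NULL; pairwise <- NULL
  for (m in metals) {
    v <- plants[[m]]
    if (stats::sd(v) == 0) {
      omnibus <- rbind(omnibus, data.frame(
        metal = m, statistic = 0, df = length(groups) - 1L, p = 1))
      next
    }
    kw <- stats::kruskal.test(v, factor(species))
    omnibus <- rbind(omnibus, data.frame(
      metal = m, statistic = unname(kw$statistic),
      df = unname(kw$parameter), p = kw$p.value))
    if (is.finite(kw$p.value) && kw$p.value < alpha) {
      cmb <- utils::combn(groups, 2)
      praw <- apply(cmb, 2, function(g)
        suppressWarnings(stats::wilcox.test(v[species == g[1]],
                                            v[species == g[2]],
                                            exact = FALSE))$p.value)
      pairwise <- rbind(pairwise, data.frame(
        metal = m, group1 = cmb[1, ], group2 = cmb[2, ],
        p_raw = praw,
        p_adj = pmin(1, praw * ncol(cmb)),
        stringsAsFactors = FALSE))
    }
  }
  rownames(omnibus) <- NULL
  if (is.null(pairwise))
    pairwise <- data.frame(metal = character(), group1 = character(),
                           group2 = character(), p_raw = numeric(),
                           p_adj = numeric())
  list(omnibus = omnibus, pairwise = pairwise)
}

#' One-sample tests of concentrations against reference values
#'
#' Per metal, a Wilcoxon signed-rank test of the sample concentrations
#' against a fixed reference value (the regional background for soil
#' tables, the plant standard limit for plant tables).
#'
#' @param x a `concentration_table`.
#' @param refs a [reference_set()].
#' @param against `"background"` or `"plant_limit"`.
#' @param alternative passed to [stats::wilcox.test()].
#' @return data.frame: metal, reference, p.
#' @export
reference_difference_tests <- function(x, refs = default_references(),
                                       against = c("background",
                                                   "plant_limit"),
                                       alternative = "two.sided") {
  against <- match.arg(against)
  metals <- attr(x, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(x))
  ref <- refs[[against]]
  check_metals_covered(metals, ref, against)
  p <- vapply(metals, function(m)
    suppressWarnings(stats::wilcox.test(x[[m]], mu = ref[m],
                                        alternative = alternative,
                                        exact = FALSE))$p.value,
    numeric(1))
  data.frame(metal = metals, reference = unname(ref[metals]),
             p = unname(p), row.names = NULL, stringsAsFactors = FALSE)
}
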