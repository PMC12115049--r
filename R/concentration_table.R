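#' Build and validate a concentration table
#'
#' The universal survey record: one row per sample, one column per
#' metal (mg/kg), a `sample_id` column, planar `x`/`y` coordinates in
#' km where available, and a `species` column for plant tables.
#'
#' Validation enforces that all concentrations are finite and
#' non-negative, that the metal columns are present, and that
#' `sample_id` values are unique.
#'
#' @param df a data.frame.
#' @param kind `"soil"` or `"plant"`.
#' @param metals character vector of metal column names (default the
#'   seven survey metals).
#' @return The validated data.frame with class `concentration_table`
#'   and attributes `kind` and `metals`.
#' @export
concentration_table <- function(df, kind = c("soil", "plant"),
                                metals = METALS) {
  kind <- match.arg(kind)
  if (!is.data.frame(df)) stop("df must be a data.frame", call. = FALSE)
  if (!"sample_id" %in% names(df))
    stop("missing required column: sample_id", call. = FALSE)
  miss <- setdiff(metals, names(df))
  if (length(miss))
    stop("missing metal column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (kind == "plant" && !"species" %in% names(df))
    stop("plant table requires a species column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  for (m in metals) {
    v <- df[[m]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-finite or non-numeric concentration in column ", m,
           call. = FALSE)
    if (any(v < 0))
      stop("negative concentration for metal ", m, " in sample(s): ",
           paste(df$sample_id[v < 0], collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  structure(as.data.frame(df), kind = kind, metals = metals,
            class = c("concentration_table", "data.frame"))
}

#' Extract the metal concentration matrix from a concentration table
#'
#' @param x a `concentration_table` (or plain data.frame containing the
#'   metal columns).
#' @param metals metal columns to extract; defaults to the table's own
#'   metal set.
#' @return Numeric matrix, samples in rows (named by `sample_id`),
#'   metals in columns.
#' @export
metal_matrix <- function(x, metals = NULL) {
  if (is.null(metals)) metals <- attr(x, "metals")
  if (is.null(metals)) metals <- intersect(METALS, names(x))
  m <- as.matrix(as.data.frame(x)[, metals, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' Read a concentration table from CSV
#'
#' @param path CSV file with a header containing `sample_id` and the
#'   metal columns; plant tables additionally need `species`.
#' @inheritParams concentration_table
#' @return A `concentration_table`.
#' @export
read_concentration_table <- function(path, kind = c("soil", "plant"),
                                     metals = METALS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  concentration_table(df, kind = kind, metals = metals)
}

#' Write a concentration table to CSV
#'
#' @param x a `concentration_table`.
#' @param path output path.
#' @export
write_concentration_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read and pair a soil-plant survey
#'
#' Reads the soil table, the plant table, and (optionally) a reference
#' file; validates both tables; and enforces pairing: every plant
#' sample must have a soil sample with the same `sample_id`. Unpaired
#' plant rows are dropped with a warning. When a reference set is
#' given (or the default is used), every metal column must have
#' background, plant-limit and toxicity entries.
#'
#' @param soil_path,plant_path CSV paths.
#' @param refs_path optional path to a reference CSV/YAML; when `NULL`
#'   the bundled defaults ([default_references()]) are used.
#' @param metals metal columns expected in both tables.
#' @return A list with elements `soil`, `plants` (both
#'   `concentration_table`) and `refs` (a `reference_set`).
#' @export
read_survey <- function(soil_path, plant_path, refs_path = NULL,
                        metals = METALS) {
  soil <- read_concentration_table(soil_path, kind = "soil", metals = metals)
  plants <- read_concentration_table(plant_path, kind = "plant",
                                     metals = metals)
  refs <- if (is.null(refs_path)) default_references() else
    read_references(refs_path)
  for (what in c("background", "plant_limit", "toxicity"))
    check_metals_covered(metals, refs[[what]], what)
  unpaired <- setdiff(plants$sample_id, soil$sample_id)
  if (length(unpaired)) {
    warning(length(unpaired), " plant sample(s) without a paired soil ",
            "sample dropped: ", paste(unpaired, collapse = ", "),
            call. = FALSE)
    plants <- concentration_table(
      as.data.frame(plants)[!plants$sample_id %in% unpaired, , drop = FALSE],
      kind = "plant", metals = metals)
  }
  list(soil = soil, plants = plants, refs = refs)
}

#' Per-metal descriptive statistics
#'
#' Computes, for each metal column, the maximum, minimum, median, mean,
#' sample standard deviation (n - 1 denominator), coefficient of
#' variation in percent (100 * sd / mean), excess kurtosis and adjusted
#' Fisher-Pearson skewness (the SPSS/Excel estimators, `type = 2` in
#' \pkg{e1071}).
#'
#' @param x a `concentration_table` with at least 2 rows.
#' @return data.frame with one row per metal and columns `metal`,
#'   `max`, `min`, `median`, `mean`, `sd`, `cv_percent`, `kurtosis`,
#'   `skewness`.
#' @export
describe <- function(x) {
  mat <- metal_matrix(x)
  if (nrow(mat) < 2)
    stop("need at least 2 samples (sd undefined for a single row)",
         call. = FALSE)
  one <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    c(max = max(v), min = min(v), median = stats::median(v), mean = m,
      sd = s,
      cv_percent = if (m > 0) 100 * s / m else NA_real_,
      kurtosis = if (nrow(mat) >= 4) e1071::kurtosis(v, type = 2) else NA_real_,
      skewness = if (nrow(mat) >= 3) e1071::skewness(v, type = 2) else NA_real_)
  }
  res <- t(apply(mat, 2, one))
  out <- data.frame(metal = colnames(mat), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
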