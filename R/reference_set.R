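#' Metals covered by the default survey configuration
#'
#' The seven trace metals routinely assayed in arid-region soil-plant
#' surveys: Cr, Cu, Zn, Cd, Pb, Hg, As.
#'
#' @export
METALS <- c("Cr", "Cu", "Zn", "Cd", "Pb", "Hg", "As")

#' Construct a reference set for pollution assessment
#'
#' A reference set bundles the per-metal constants every index needs:
#' regional geochemical background values (the denominator of the
#' single-factor index), plant standard limits (for exceedance folds),
#' Hakanson toxicity coefficients, national risk-screening values, and
#' the classification thresholds used to label Nemerow and ecological
#' risk indices.
#'
#' @param background named numeric, regional background concentration
#'   per metal (mg/kg). Must be positive.
#' @param plant_limit named numeric, plant standard limit per metal
#'   (mg/kg). Must be positive.
#' @param toxicity named numeric, dimensionless Hakanson toxicity
#'   coefficient per metal. Must be positive.
#' @param screening optional named numeric, national risk-screening
#'   value per metal (mg/kg).
#' @param nipi_classes,er_classes,ri_classes lists with elements
#'   `breaks` (strictly increasing numeric thresholds) and `labels`
#'   (length `length(breaks) + 1`). Defaults follow the standard
#'   Nemerow and Hakanson schemes.
#' @return An object of class `reference_set`.
#' @seealso [default_references()] for the bundled Xinjiang defaults.
#' @export
reference_set <- function(background, plant_limit, toxicity,
                          screening = NULL,
                          nipi_classes = NULL, er_classes = NULL,
                          ri_classes = NULL) {
  check_ref_vec <- function(x, what) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " must be a named numeric vector", call. = FALSE)
    if (any(!is.finite(x)) || any(x <= 0))
      stop("all ", what, " values must be positive and finite", call. = FALSE)
    x
  }
  background <- check_ref_vec(background, "background")
  plant_limit <- check_ref_vec(plant_limit, "plant_limit")
  toxicity <- check_ref_vec(toxicity, "toxicity")
  if (!is.null(screening)) screening <- check_ref_vec(screening, "screening")

  default_classes <- list(
    nipi = list(breaks = c(0.7, 1, 2, 3),
                labels = c("Safe", "Alert", "Light Pollution",
                           "Moderate Pollution", "Heavy Pollution"),
                right = TRUE),
    er = list(breaks = c(40, 80, 160, 320),
              labels = c("Low Risk", "Moderate Risk", "Considerable Risk",
                         "High Risk", "Very High Risk"),
              right = FALSE),
    ri = list(breaks = c(150, 300, 600),
              labels = c("Low Risk", "Moderate Risk", "High Risk",
                         "Very High Risk"),
              right = FALSE)
  )
  fix_classes <- function(cls, default) {
    if (is.null(cls)) return(default)
    stopifnot(is.list(cls), !is.null(cls$breaks), !is.null(cls$labels))
    if (any(diff(cls$breaks) <= 0))
      stop("class thresholds must be strictly increasing", call. = FALSE)
    if (length(cls$labels) != length(cls$breaks) + 1L)
      stop("need one more label than breaks", call. = FALSE)
    if (is.null(cls$right)) cls$right <- default$right
    cls
  }
  obj <- list(
    background = background,
    plant_limit = plant_limit,
    toxicity = toxicity,
    screening = screening,
    nipi_classes = fix_classes(nipi_classes, default_classes$nipi),
    er_classes = fix_classes(er_classes, default_classes$er),
    ri_classes = fix_classes(ri_classes, default_classes$ri)
  )
  class(obj) <- "reference_set"
  obj
}

#' Default reference values for the Xinjiang arid-region survey
#'
#' Bundles the regional soil background values for Xinjiang, plant
#' standard limits, canonical Hakanson toxicity coefficients
#' (Cd 30, Hg 40, As 10, Pb 5, Cu 5, Cr 2, Zn 1) and the GB 15618-2018
#' risk-screening values for the seven survey metals.
#'
#' @return A `reference_set`.
#' @export
default_references <- function() {
  reference_set(
    background = c(Cr = 49.30, Cu = 26.70, Zn = 68.80, Cd = 0.12,
                   Pb = 19.40, Hg = 0.02, As = 11.20),
    plant_limit = c(Cr = 2.00, Cu = 45.80, Zn = 100.00, Cd = 0.20,
                    Pb = 3.00, Hg = 0.01, As = 5.00),
    toxicity = c(Cr = 2, Cu = 5, Zn = 1, Cd = 30, Pb = 5, Hg = 40, As = 10),
    screening = c(Cr = 250, Cu = 100, Zn = 300, Cd = 0.60, Pb = 170,
                  Hg = 3.40, As = 25)
  )
}

#' Read a reference set from a CSV or YAML file
#'
#' CSV files need columns `metal`, `background`, `plant_limit`,
#' `toxicity` and optionally `screening`. YAML files carry the same
#' fields as metal-named maps.
#'
#' @param path path to a `.csv`, `.yaml` or `.yml` file.
#' @return A `reference_set`.
#' @export
read_references <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    as_vec <- function(f) if (is.null(y[[f]])) NULL else unlist(y[[f]])
    return(reference_set(as_vec("background"), as_vec("plant_limit"),
                         as_vec("toxicity"), as_vec("screening")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metal", "background", "plant_limit", "toxicity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pull <- function(col) {
    if (!col %in% names(df)) return(NULL)
    stats::setNames(df[[col]], df$metal)
  }
  reference_set(pull("background"), pull("plant_limit"), pull("toxicity"),
                pull("screening"))
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set for", length(x$background), "metals:",
      paste(names(x$background), collapse = ", "), "\n")
  tab <- data.frame(metal = names(x$background),
                    background = unname(x$background),
                    plant_limit = unname(x$plant_limit[names(x$background)]),
                    toxicity = unname(x$toxicity[names(x$background)]))
  if (!is.null(x$screening))
    tab$screening <- unname(x$screening[names(x$background)])
  print(tab, row.names = FALSE)
  invisible(x)
}

# internal: require that every metal has an entry in a reference vector
check_metals_covered <- function(metals, ref, what) {
  miss <- setdiff(metals, names(ref))
  if (length(miss))
    stop("no ", what, " value for metal(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# internal: map values to ordered class labels given breaks.
# right = TRUE means intervals are (a, b] (Nemerow convention);
# right = FALSE means [a, b) (Hakanson convention).
classify_by_breaks <- function(x, classes) {
  idx <- findInterval(x, classes$breaks, left.open = classes$right,
                      rightmost.closed = FALSE) + 1L
  classes$labels[idx]
}
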