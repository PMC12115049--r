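#' Build a synthetic survey scenario
#'
#' A scenario fully specifies a paired soil-plant survey with known
#' source structure: sampling domain, species composition, geogenic
#' background distributions, point/polyline pollution sources with
#' per-metal emission strengths and distance-decay lengths,
#' species-specific soil-to-plant transfer factors, an additive
#' atmospheric deposition term for plant tissue, and multiplicative
#' log-normal noise.
#'
#' The `"kalamaili-like"` preset emulates an arid-reserve survey: 36
#' samples over a 40 x 40 km domain, 4 shrub species with counts
#' (9, 7, 6, 14), 7 metals, and 5 sources (two factories, a railway,
#' and two highways). Cd, Zn and Cr load on the factories, Pb on the
#' roads (dominated by one highway), and Hg is split between a factory
#' and atmospheric deposition. Background means and transfer factors
#' are set so that noise-free survey means land near regionally
#' typical soil and plant concentrations.
#'
#' @param seed integer seed stored in the scenario; all simulation
#'   randomness derives from it.
#' @param preset currently `"kalamaili-like"`.
#' @param ... named overrides for any scenario field (`n_samples`,
#'   `species_counts`, `domain`, `sources`, `emissions`,
#'   `background_mean`, `background_sdlog`, `transfer`, `atmospheric`,
#'   `noise_soil`, `noise_plant`, `metals`).
#' @return Object of class `source_scenario`.
#' @export
make_scenario <- function(seed = 1, preset = "kalamaili-like", ...) {
  preset <- match.arg(preset)
  metals <- METALS
  species <- c("Anabasis aphylla", "Alhagi camelorum",
               "Reaumuria songonica", "Haloxylon ammodendron")
  sources <- list(
    factory_1 = list(geom = data.frame(x = 12, y = 26), lambda = 10),
    factory_2 = list(geom = data.frame(x = 28, y = 30), lambda = 10),
    railway = list(geom = data.frame(x = c(0, 40), y = c(20, 24)),
                   lambda = 10),
    G216 = list(geom = data.frame(x = c(18, 22), y = c(0, 40)),
                lambda = 10),
    S11 = list(geom = data.frame(x = c(0, 40), y = c(8, 4)),
               lambda = 10))
  # emission strength (mg/kg at distance 0) per source x metal,
  # scaled so noise-free survey means land near regionally typical
  # soil concentrations with the intended per-source shares
  emissions <- rbind(
    factory_1 = c(Cr = 57, Cu = 18, Zn = 84, Cd = 0.23, Pb = 0,
                  Hg = 0, As = 3.0),
    factory_2 = c(Cr = 30, Cu = 0, Zn = 51, Cd = 0.12, Pb = 0,
                  Hg = 0.017, As = 0),
    railway = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 3.1, Hg = 0,
                As = 2.4),
    G216 = c(Cr = 0, Cu = 4.8, Zn = 0, Cd = 0, Pb = 20.3, Hg = 0,
             As = 0),
    S11 = c(Cr = 0, Cu = 5.9, Zn = 0, Cd = 0, Pb = 6.2, Hg = 0,
            As = 2.9))
  background_mean <- c(Cr = 24.4, Cu = 12.5, Zn = 25.2, Cd = 0.054,
                       Pb = 4.6, Hg = 0.0056, As = 4.2)
  transfer <- rbind(
    "Anabasis aphylla" = c(Cr = 7.30, Cu = 0.31, Zn = 0.21,
                           Cd = 1.42, Pb = 0.113, Hg = 0.68,
                           As = 0.220),
    "Alhagi camelorum" = c(Cr = 1.78, Cu = 0.18, Zn = 0.09,
                           Cd = 0.71, Pb = 0.038, Hg = 0.73,
                           As = 0.066),
    "Reaumuria songonica" = c(Cr = 2.60, Cu = 0.28, Zn = 0.15,
                              Cd = 0.71, Pb = 0.216, Hg = 0.63,
                              As = 0.132),
    "Haloxylon ammodendron" = c(Cr = 1.45, Cu = 0.18, Zn = 0.13,
                                Cd = 0.84, Pb = 0.023, Hg = 0.41,
                                As = 0.037))
  scn <- list(
    n_samples = 36L,
    species_counts = stats::setNames(c(9L, 7L, 6L, 14L), species),
    domain = c(40, 40),
    metals = metals,
    sources = sources,
    emissions = emissions,
    background_mean = background_mean,
    background_sdlog = 0.25,
    transfer = transfer,
    atmospheric = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 0,
                    Hg = 0.005, As = 0),
    noise_soil = 0.2,
    noise_plant = 0.2,
    seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(scn))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scn[names(dots)] <- dots
  validate_scenario(scn)
}

validate_scenario <- function(scn) {
  if (sum(scn$species_counts) != scn$n_samples)
    stop("species counts (", sum(scn$species_counts),
         ") do not sum to n_samples (", scn$n_samples, ")",
         call. = FALSE)
  if (any(scn$background_mean <= 0) || scn$background_sdlog <= 0)
    stop("background parameters must be positive", call. = FALSE)
  if (any(scn$emissions < 0) || any(scn$transfer < 0) ||
      any(scn$atmospheric < 0))
    stop("emissions, transfer factors and atmospheric terms must be ",
         "non-negative", call. = FALSE)
  if (scn$noise_soil < 0 || scn$noise_plant < 0)
    stop("noise sds must be non-negative", call. = FALSE)
  for (s in scn$sources)
    if (s$lambda <= 0) stop("decay lengths must be positive",
                            call. = FALSE)
  chk <- function(x, what) {
    if (!setequal(names(x), scn$metals))
      stop(what, " must cover exactly the scenario metals", call. = FALSE)
  }
  chk(scn$background_mean, "background_mean")
  chk(scn$atmospheric, "atmospheric")
  if (!setequal(colnames(scn$emissions), scn$metals) ||
      !setequal(rownames(scn$emissions), names(scn$sources)))
    stop("emissions must be a source x metal matrix", call. = FALSE)
  if (!setequal(colnames(scn$transfer), scn$metals) ||
      !setequal(rownames(scn$transfer), names(scn$species_counts)))
    stop("transfer must be a species x metal matrix", call. = FALSE)
  structure(scn, class = "source_scenario")
}

#' @export
print.source_scenario <- function(x, ...) {
  cat("Synthetic survey scenario:", x$n_samples, "samples,",
      length(x$species_counts), "species,", length(x$metals),
      "metals,", length(x$sources), "sources; seed", x$seed, "\n")
  cat("Sources:", paste(names(x$sources), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a scenario's sources to a source table
#'
#' @param scenario a `source_scenario`.
#' @return A [source_table()] suitable for [build_feature_matrix()].
#' @export
scenario_sources <- function(scenario) {
  source_table(do.call(rbind, lapply(names(scenario$sources), function(s) {
    g <- scenario$sources[[s]]$geom
    data.frame(name = s, vertex = seq_len(nrow(g)), x = g$x, y = g$y)
  })))
}

# internal: per-source noise-free contribution matrices (n x metals)
source_terms <- function(scenario, x, y) {
  lapply(names(scenario$sources), function(s) {
    src <- scenario$sources[[s]]
    prox <- exp(-dist_to_source(x, y, src$geom) / src$lambda)
    outer(prox, scenario$emissions[s, scenario$metals])
  }) |> stats::setNames(names(scenario$sources))
}

#' Simulate the soil table of a scenario
#'
#' Soil concentration of metal m at sample i is a log-normal geogenic
#' background draw plus the sum over sources of E_s(m) * exp(-d_is /
#' lambda_s), all multiplied by mean-one log-normal noise. The ground
#' truth records, per metal, the percent share of each source (and of
#' the background) in the noise-free mixture: the mean of the source's
#' term over samples divided by the mean noise-free total.
#'
#' @param scenario a `source_scenario`.
#' @return List of class `soil_simulation`: `soil` (a soil
#'   `concentration_table` with x/y), `truth` (list: `shares`
#'   data.frame of metal/source/share_percent, `terms` per-source
#'   noise-free matrices, `background` and `noisefree` matrices).
#' @export
simulate_soil <- function(scenario) {
  stopifnot(inherits(scenario, "source_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_samples
  metals <- scenario$metals
  x <- stats::runif(n, 0, scenario$domain[1])
  y <- stats::runif(n, 0, scenario$domain[2])
  sdl <- scenario$background_sdlog
  bg <- vapply(metals, function(m)
    stats::rlnorm(n, log(scenario$background_mean[m]) - sdl^2 / 2, sdl),
    numeric(n))
  terms <- source_terms(scenario, x, y)
  noisefree <- bg + Reduce(`+`, terms)
  noise <- matrix(exp(stats::rnorm(n * length(metals), 0,
                                   scenario$noise_soil) -
                        scenario$noise_soil^2 / 2),
                  n, length(metals))
  conc <- noisefree * noise
  soil <- concentration_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)), x = x, y = y,
    as.data.frame(conc)), kind = "soil", metals = metals)

  tot <- colMeans(noisefree)
  shares <- do.call(rbind, lapply(c(names(terms), "background"),
                                  function(s) {
    num <- if (s == "background") colMeans(bg) else colMeans(terms[[s]])
    data.frame(metal = metals, source = s,
               share_percent = 100 * unname(num) / unname(tot),
               stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  structure(list(soil = soil,
                 truth = list(shares = shares, terms = terms,
                              background = bg, noisefree = noisefree)),
            class = "soil_simulation")
}

#' Simulate the paired plant table
#'
#' Plant concentration of metal m at sample i is transfer(species_i,
#' m) * soil_i(m) + atmospheric(m), multiplied by mean-one log-normal
#' noise. Species are assigned to samples in the scenario's count
#' order.
#'
#' @param scenario a `source_scenario`.
#' @param soil the soil `concentration_table` from [simulate_soil()].
#' @return A plant `concentration_table` paired with `soil`.
#' @export
simulate_plants <- function(scenario, soil) {
  stopifnot(inherits(scenario, "source_scenario"))
  set.seed(scenario$seed + 1L)
  metals <- scenario$metals
  n <- nrow(soil)
  species <- rep(names(scenario$species_counts), scenario$species_counts)
  sm <- metal_matrix(soil, metals)
  tf <- scenario$transfer[species, metals, drop = FALSE]
  noisefree <- tf * sm +
    matrix(scenario$atmospheric[metals], n, length(metals), byrow = TRUE)
  noise <- matrix(exp(stats::rnorm(n * length(metals), 0,
                                   scenario$noise_plant) -
                        scenario$noise_plant^2 / 2),
                  n, length(metals))
  conc <- noisefree * noise
  dimnames(conc) <- list(NULL, metals)
  concentration_table(data.frame(
    sample_id = soil$sample_id, species = species,
    x = soil$x, y = soil$y, as.data.frame(conc)),
    kind = "plant", metals = metals)
}

#' Simulate a full paired survey
#'
#' @param scenario a `source_scenario`.
#' @return List: `soil`, `plants`, `sources` (a [source_table()]),
#'   `truth` (see [simulate_soil()]), `scenario`.
#' @export
simulate_survey <- function(scenario) {
  sim <- simulate_soil(scenario)
  plants <- simulate_plants(scenario, sim$soil)
  list(soil = sim$soil, plants = plants,
       sources = scenario_sources(scenario), truth = sim$truth,
       scenario = scenario)
}

#' Source family of a named source
#'
#' Maps source names to coarse families: factories to `"factory"`,
#' rail/road corridors to `"road"`.
#'
#' @param name character vector of source names.
#' @return Character vector of families.
#' @export
source_family <- function(name) {
  ifelse(grepl("factory", name, ignore.case = TRUE), "factory", "road")
}

#' Family-aggregated APCS-MLR shares against scenario ground truth
#'
#' Validation helper for synthetic surveys: labels each retained
#' APCS-MLR component with the source family (factory or road) whose
#' noise-free per-sample signal for the given metal it correlates with
#' most strongly, then sums the metal's contribution shares by family.
#'
#' @param fit a fitted [apcs_mlr()] model on the simulated plant table.
#' @param truth the `truth` element of [simulate_survey()].
#' @param metal metal name.
#' @return Named numeric: percent share attributed to `factory`,
#'   `road`, and `unidentified`.
#' @export
family_shares <- function(fit, truth, metal) {
  stopifnot(inherits(fit, "apcs_mlr"))
  fams <- source_family(names(truth$terms))
  signal <- function(fam) {
    mats <- truth$terms[fams == fam]
    rowSums(vapply(mats, function(m) m[, metal], numeric(nrow(fit$apcs))))
  }
  sig <- list(factory = signal("factory"), road = signal("road"))
  comp_fam <- apply(fit$apcs, 2, function(a) {
    r <- vapply(sig, function(s)
      if (stats::sd(s) == 0 || stats::sd(a) == 0) 0 else
        abs(stats::cor(a, s)), numeric(1))
    names(sig)[which.max(r)]
  })
  pct <- fit$contribution_percent[metal, ]
  out <- c(factory = sum(pct[names(comp_fam)[comp_fam == "factory"]]),
           road = sum(pct[names(comp_fam)[comp_fam == "road"]]),
           unidentified = unname(pct["unidentified"]))
  out
}
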