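test_that("BCF and exceedance folds are guarded ratios", {
  expect_equal(bcf(294.24, 44.38), 6.630, tolerance = 5e-4)
  expect_equal(bcf(5, 5), 1)
  expect_equal(bcf(0, 3), 0)
  expect_error(bcf(1, 0), "positive")
  expect_equal(exceedance_fold(294.24, 2.00), 147.12)
  expect_equal(exceedance_fold(115.46, 2.00), 57.73)
  expect_equal(exceedance_fold(3, 3), 1)
  expect_error(exceedance_fold(1, 0), "positive")
})

test_that("species BCF summary averages per sample, then species, then across", {
  soil <- concentration_table(
    data.frame(sample_id = c("a", "b", "c"), Cr = c(5, 10, 4)),
    metals = "Cr")
  plants <- concentration_table(
    data.frame(sample_id = c("a", "b", "c"),
               species = c("sp1", "sp1", "sp2"),
               Cr = c(10, 10, 2)),
    kind = "plant", metals = "Cr")
  rep <- species_bcf_summary(plants, soil)
  # sp1 per-sample BCFs 2 and 1 -> mean 1.5; sp2 -> 0.5
  expect_equal(rep$species$mean_bcf[rep$species$species == "sp1"], 1.5)
  expect_equal(rep$species$mean_bcf[rep$species$species == "sp2"], 0.5)
  # cross-species mean is the unweighted mean of species means (1.0),
  # not the pooled per-sample mean (7/6)
  expect_equal(rep$overall$mean_bcf, 1.0)
  expect_false(isTRUE(all.equal(rep$overall$mean_bcf,
                                mean(rep$samples$bcf))))
})

test_that("single species, single pair reduces to the plain ratio", {
  soil <- concentration_table(
    data.frame(sample_id = "a", Cr = 5), metals = "Cr")
  plants <- concentration_table(
    data.frame(sample_id = "a", species = "sp1", Cr = 10),
    kind = "plant", metals = "Cr")
  rep <- species_bcf_summary(plants, soil)
  expect_equal(rep$overall$mean_bcf, 2)
})

test_that("BCFs and correlations are invariant to sample order", {
  srv <- read_survey(example_survey_path("soil.csv"),
                     example_survey_path("plants.csv"))
  rep1 <- species_bcf_summary(srv$plants, srv$soil)
  cor1 <- soil_plant_correlations(srv$plants, srv$soil)
  set.seed(3)
  perm <- sample(nrow(srv$plants))
  plants2 <- concentration_table(as.data.frame(srv$plants)[perm, ],
                                 kind = "plant")
  soil2 <- concentration_table(
    as.data.frame(srv$soil)[sample(nrow(srv$soil)), ], kind = "soil")
  rep2 <- species_bcf_summary(plants2, soil2)
  cor2 <- soil_plant_correlations(plants2, soil2)
  expect_equal(rep1$overall, rep2$overall, tolerance = 1e-12)
  for (s in names(cor1))
    expect_equal(unclass(cor1)[[s]], unclass(cor2)[[s]],
                 tolerance = 1e-12)
})

test_that("correlation matrices match the explicit-loop oracle", {
  expect_equal(oracle_pearson(1:5, c(2, 1, 4, 3, 5)), 0.8)
  for (rep in 1:5) {
    n <- 8
    soil <- random_table(n, c("Cr", "Cu", "Zn"), seed = 100 + rep)
    set.seed(200 + rep)
    plants <- concentration_table(
      data.frame(sample_id = soil$sample_id, species = "sp1",
                 Cr = abs(rnorm(n, 10, 2)), Cu = abs(rnorm(n, 10, 2)),
                 Zn = max(soil$Zn) + 1 - soil$Zn),  # exact negative slope
      kind = "plant", metals = c("Cr", "Cu", "Zn"))
    r <- unclass(soil_plant_correlations(plants, soil))[["sp1"]]
    for (pm in c("Cr", "Cu", "Zn")) for (sm in c("Cr", "Cu", "Zn"))
      expect_equal(r[pm, sm],
                   oracle_pearson(plants[[pm]], soil[[sm]]),
                   tolerance = 1e-12)
    expect_equal(r["Zn", "Zn"], -1, tolerance = 1e-12)
  }
})

test_that("identical plant and soil columns correlate exactly 1", {
  soil <- random_table(6, c("Cr", "Cu"), seed = 8)
  pdf <- as.data.frame(soil)
  pdf$species <- "sp1"
  plants <- concentration_table(pdf, kind = "plant",
                                metals = c("Cr", "Cu"))
  r <- unclass(soil_plant_correlations(plants, soil))[["sp1"]]
  expect_equal(diag(r), c(Cr = 1, Cu = 1), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("zero-variance columns yield NA correlations with a warning", {
  soil <- random_table(5, c("Cr", "Cu"), seed = 12)
  pdf <- as.data.frame(soil)
  pdf$species <- "sp1"
  pdf$Cu <- 3
  plants <- concentration_table(pdf, kind = "plant",
                                metals = c("Cr", "Cu"))
  expect_warning(r <- soil_plant_correlations(plants, soil), "Cu")
  expect_true(all(is.na(unclass(r)[["sp1"]]["Cu", ])))
})

test_that("group tests: identical groups give p = 1, shifted groups p < 0.01", {
  base <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9)
  tab <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:12),
               species = rep(c("sp1", "sp2"), each = 6),
               Cr = c(base, base)),
    kind = "plant", metals = "Cr")
  res <- group_difference_tests(tab)
  expect_equal(res$omnibus$p, 1, tolerance = 1e-9)

  set.seed(77)
  g1 <- rnorm(12, 0, 1); g2 <- rnorm(12, 3, 1)  # 3-sd shift
  tab2 <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:24),
               species = rep(c("sp1", "sp2"), each = 12),
               Cr = abs(c(g1, g2)) + 1),
    kind = "plant", metals = "Cr")
  res2 <- group_difference_tests(tab2)
  expect_lt(res2$omnibus$p, 0.01)
  expect_gt(nrow(res2$pairwise), 0)
  expect_true(all(res2$pairwise$p_adj >= res2$pairwise$p_raw))
})

test_that("degenerate constant groups are handled without crashing", {
  tab <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:12),
               species = rep(paste0("sp", 1:4), each = 3),
               Cr = rep(c(1, 2, 3, 4), each = 3)),
    kind = "plant", metals = "Cr")
  res <- group_difference_tests(tab)
  expect_lt(res$omnibus$p, 0.05)
  # all values identical across groups: no evidence, p = 1
  tab2 <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:12),
               species = rep(c("sp1", "sp2"), each = 6),
               Cr = rep(5, 12)),
    kind = "plant", metals = "Cr")
  expect_equal(group_difference_tests(tab2)$omnibus$p, 1)
})

test_that("undersized species groups are excluded with a warning", {
  tab <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:7),
               species = c(rep("sp1", 3), rep("sp2", 3), "sp3"),
               Cr = c(1, 2, 3, 4, 5, 6, 7)),
    kind = "plant", metals = "Cr")
  expect_warning(res <- group_difference_tests(tab), "sp3")
  expect_equal(res$omnibus$df, 1)
})

test_that("one-sample reference tests flag shifted metals only", {
  set.seed(5)
  tab <- concentration_table(
    data.frame(sample_id = sprintf("s%02d", 1:20),
               Cr = rnorm(20, 49.3, 5),      # at background
               Cu = rnorm(20, 80, 5)),       # far above background
    metals = c("Cr", "Cu"))
  res <- reference_difference_tests(tab)
  expect_gt(res$p[res$metal == "Cr"], 0.05)
  expect_lt(res$p[res$metal == "Cu"], 0.001)
})
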