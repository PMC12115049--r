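test_that("standardization centers, scales, and names zero-variance metals", {
  m <- cbind(Cr = c(0, 2), Cu = c(1, 5))
  z <- standardize(m)
  expect_equal(unname(z[, "Cr"]), c(-sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-12)
  tab <- random_table(20, seed = 4)
  z2 <- standardize(tab)
  expect_equal(unname(colMeans(z2)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 3), tolerance = 1e-12)
  m_flat <- cbind(Cr = c(1, 2, 3), Cu = c(4, 4, 4))
  expect_error(standardize(m_flat), "Cu")
})

test_that("PCA of two perfectly correlated metals collapses to one component", {
  x <- seq(1, 10, length.out = 12)
  z <- standardize(cbind(Cr = x, Cu = 2 * x + 3))
  p <- fit_pca(z)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p$q, 1)
  # trace identity
  expect_equal(sum(p$eigenvalues), 2, tolerance = 1e-9)
})

test_that("independent metals give near-unit eigenvalues at large n", {
  set.seed(31)
  z <- standardize(matrix(rnorm(10000 * 4), ncol = 4,
                          dimnames = list(NULL, c("a", "b", "c", "d"))))
  p <- fit_pca(z)
  expect_true(all(abs(p$eigenvalues - 1) < 0.05))
})

test_that("eigenvalue trace equals the number of metals", {
  tab <- random_table(30, METALS, seed = 17)
  p <- fit_pca(standardize(tab))
  expect_equal(sum(p$eigenvalues), length(METALS), tolerance = 1e-9)
})

test_that("APCS of the artificial zero-concentration sample is zero", {
  tab <- random_table(25, METALS, seed = 2)
  fit <- apcs_mlr(tab)
  z0 <- (0 - fit$center) / fit$scale
  apcs0 <- drop(z0 %*% fit$pca$score_coef) - fit$a0
  expect_equal(unname(apcs0), rep(0, fit$pca$q), tolerance = 1e-12)
  # mean(APCS_j) = -(A0)_j since standardized scores average to zero
  expect_equal(unname(colMeans(fit$apcs)), unname(-fit$a0),
               tolerance = 1e-12)
})

test_that("source regression recovers exact linear structure", {
  tab <- random_table(40, METALS, seed = 13)
  z <- standardize(tab)
  pca <- fit_pca(z)
  apcs <- absolute_scores(pca, z)
  y <- 2 + 3 * apcs[, 1]
  # lm warns that an exact fit makes its summary unreliable; expected here
  reg <- suppressWarnings(fit_source_regression(apcs, cbind(Y = y)))
  expect_equal(unname(reg$coefficients["Y", "(Intercept)"]), 2,
               tolerance = 1e-9)
  expect_equal(unname(reg$coefficients["Y", "PC1"]), 3, tolerance = 1e-9)
  expect_equal(unname(reg$r2["Y"]), 1, tolerance = 1e-9)
})

test_that("regression R2 is near zero for unrelated responses", {
  tab <- random_table(1000, METALS, seed = 23)
  z <- standardize(tab)
  pca <- fit_pca(z)
  apcs <- absolute_scores(pca, z)
  set.seed(24)
  y <- rnorm(1000)
  reg <- fit_source_regression(apcs, cbind(Y = y))
  expect_lt(unname(reg$r2["Y"]), 0.02)
})

test_that("collinear APCS columns are rejected with a diagnostic", {
  tab <- random_table(30, METALS, seed = 3)
  z <- standardize(tab)
  pca <- fit_pca(z)
  apcs <- absolute_scores(pca, z)
  bad <- cbind(apcs, dup = apcs[, 1])
  expect_error(fit_source_regression(bad, metal_matrix(tab)),
               "condition number")
})

test_that("contribution shares sum to 100 and survive sample relabeling", {
  tab <- random_table(30, METALS, seed = 19)
  fit <- apcs_mlr(tab)
  expect_equal(unname(rowSums(fit$contribution_percent)),
               rep(100, length(METALS)), tolerance = 1e-6)
  perm <- sample(30)
  fit2 <- apcs_mlr(metal_matrix(tab)[perm, ])
  expect_equal(fit2$contribution_percent, fit$contribution_percent,
               tolerance = 1e-9)
  sc <- source_contributions(fit)
  expect_setequal(unique(sc$source_component),
                  c(colnames(fit$apcs), "unidentified"))
})

test_that("noise-free single-source data attributes sourced metals to one component", {
  scn <- make_scenario(
    seed = 6,
    background_mean = structure(rep(1e-8, 7), names = METALS),
    background_sdlog = 1e-6,
    noise_soil = 0, noise_plant = 0,
    emissions = rbind(
      factory_1 = c(Cr = 57, Cu = 18, Zn = 84, Cd = 0.23, Pb = 2,
                    Hg = 0.01, As = 3.0),
      factory_2 = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 0, Hg = 0,
                    As = 0),
      railway = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 0, Hg = 0,
                  As = 0),
      G216 = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 0, Hg = 0, As = 0),
      S11 = c(Cr = 0, Cu = 0, Zn = 0, Cd = 0, Pb = 0, Hg = 0, As = 0)),
    transfer = matrix(1, 4, 7, dimnames = list(
      c("Anabasis aphylla", "Alhagi camelorum", "Reaumuria songonica",
        "Haloxylon ammodendron"), METALS)),
    atmospheric = structure(rep(0, 7), names = METALS))
  sv <- simulate_survey(scn)
  fit <- apcs_mlr(sv$soil)
  expect_equal(fit$pca$q, 1)
  expect_true(all(fit$contribution_percent[, "PC1"] > 99))
})

test_that("metals unrelated to the retained component stay unidentified", {
  set.seed(41)
  n <- 400
  base <- rnorm(n)
  m <- cbind(Cr = abs(5 + base), Cu = abs(5 + base + rnorm(n, 0, 0.2)),
             Zn = abs(rnorm(n, 20, 1)))
  fit <- apcs_mlr(m, ncomp = 1)
  # Zn is independent of the single retained common factor: the
  # intercept (unidentified source) carries essentially all of it
  expect_gt(fit$contribution_percent["Zn", "unidentified"], 85)
  expect_lt(fit$contribution_percent["Cr", "unidentified"], 60)
})

test_that("predict reproduces fitted values and handles new samples", {
  tab <- random_table(30, METALS, seed = 29)
  fit <- apcs_mlr(tab)
  expect_equal(predict(fit), fitted(fit))
  pred <- predict(fit, newdata = metal_matrix(tab)[1:5, ])
  expect_equal(pred, fitted(fit)[1:5, ], tolerance = 1e-12)
  expect_equal(dim(coef(fit)), c(7L, fit$pca$q + 1L))
  res <- residuals(fit)
  expect_equal(res + fitted(fit), metal_matrix(tab),
               tolerance = 1e-9, ignore_attr = TRUE)
})
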