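test_that("proximity features follow exp(-d/lambda) for points and lines", {
  src <- source_table(data.frame(
    name = c("pt", "line", "line"),
    x = c(5, 0, 10), y = c(5, 0, 0)))
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        x = c(5, 5, 15, 3), y = c(5, 15, 0, 4))
  f <- build_feature_matrix(samples, src, lambda = 10)
  expect_equal(f["a", "pt"], 1)                       # at the source
  expect_equal(f["b", "pt"], exp(-1))                 # d = lambda
  expect_equal(f["c", "line"], exp(-5 / 10))          # beyond endpoint
  expect_equal(f["d", "line"], exp(-4 / 10))          # perpendicular foot
  # equidistant from two sources -> equal features
  src2 <- source_table(data.frame(name = c("s1", "s2"),
                                  x = c(0, 10), y = c(0, 0)))
  f2 <- build_feature_matrix(data.frame(sample_id = "m", x = 5, y = 2),
                             src2, lambda = 7)
  expect_equal(f2[1, "s1"], f2[1, "s2"])
  expect_error(
    build_feature_matrix(data.frame(sample_id = "q", x = NA, y = 1),
                         src2), "q")
})

test_that("feature matrix matches an independent geometric oracle", {
  scn <- make_scenario(seed = 44)
  sv <- simulate_survey(scn)
  f <- build_feature_matrix(sv$plants, sv$sources, lambda = 10)
  for (s in unique(sv$sources$name)) {
    geom <- sv$sources[sv$sources$name == s, ]
    o <- oracle_source_proximity(sv$plants$x, sv$plants$y, geom, 10)
    expect_equal(unname(f[, s]), o, tolerance = 1e-6)
  }
})

test_that("evaluation metrics match hand arithmetic and the loop oracle", {
  m <- evaluate(c(1, 2, 3, 4), c(1, 2, 3, 8))
  expect_equal(unname(m["rmse"]), 2)
  expect_equal(unname(m["mae"]), 1)
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(perfect[c("r2", "rmse", "mae")]), c(1, 0, 0))
  expect_equal(unname(perfect["rpd"]), Inf)
  obs <- c(2, 4, 6, 8)
  const <- evaluate(obs, rep(mean(obs), 4))
  expect_equal(unname(const["r2"]), 0)
  expect_equal(unname(const["rpd"]), sd(obs) / sqrt(mean((obs - mean(obs))^2)))
  expect_error(evaluate(c(1, 1, 1), c(1, 2, 3)), "constant")
  set.seed(55)
  for (i in 1:20) {
    o <- rnorm(15); p <- rnorm(15)
    expect_equal(unname(evaluate(o, p)), unname(oracle_metrics(o, p)),
                 tolerance = 1e-12)
  }
})

test_that("forest fits are reproducible and learn monotone structure", {
  set.seed(61)
  n <- 200
  feat <- matrix(runif(n * 3), ncol = 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  y <- 5 * feat[, "s1"]^2 + rnorm(n, 0, 0.05)
  f1 <- fit_rf(feat, y, seed = 9)
  f2 <- fit_rf(feat, y, seed = 9)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$importance_share, f2$importance_share)
  expect_gt(f1$metrics$r2[f1$metrics$split == "test"], 0.9)
  expect_gt(f1$importance_share["s1"], 60)
  expect_equal(unname(sum(f1$importance_share)), 100, tolerance = 1e-6)
})

test_that("pure-noise responses score near zero out of sample", {
  r2s <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 200
    feat <- matrix(runif(n * 3), ncol = 3,
                   dimnames = list(NULL, c("s1", "s2", "s3")))
    y <- rnorm(n)
    f <- fit_rf(feat, y, seed = s, ntree = 300)
    f$metrics$r2[f$metrics$split == "test"]
  }, numeric(1))
  expect_lte(median(r2s), 0.1)
})

test_that("shuffling the response destroys out-of-sample skill", {
  sv <- simulate_survey(make_scenario(seed = 3))
  feat <- build_feature_matrix(sv$plants, sv$sources)
  set.seed(8)
  r2s <- vapply(1:10, function(i) {
    y <- sample(sv$soil$Pb)
    f <- fit_rf(feat, y, seed = i, ntree = 300)
    f$metrics$r2[f$metrics$split == "test"]
  }, numeric(1))
  expect_lte(median(r2s), 0.1)
})

test_that("identical feature copies split importance roughly evenly", {
  set.seed(71)
  n <- 300
  base <- runif(n)
  feat <- cbind(s1 = base, s2 = base, s3 = base)
  y <- 3 * base + rnorm(n, 0, 0.1)
  f <- fit_rf(feat, y, seed = 5)
  expect_true(all(abs(f$importance_share - 100 / 3) < 10))
})

test_that("rf_apportion is reproducible and returns coherent summaries", {
  sv <- simulate_survey(make_scenario(seed = 12))
  rf1 <- rf_apportion(sv$plants, sources = sv$sources, seed = 42,
                      metals = c("Pb", "Cd"), ntree = 300)
  rf2 <- rf_apportion(sv$plants, sources = sv$sources, seed = 42,
                      metals = c("Pb", "Cd"), ntree = 300)
  expect_identical(rf1$metrics, rf2$metrics)
  expect_equal(unname(rowSums(rf1$importance)), c(100, 100),
               tolerance = 1e-6)
  expect_true(all(rf1$metrics$rmse >= 0))
  expect_true(all(rf1$metrics$mae <= rf1$metrics$rmse + 1e-12))
  expect_error(
    fit_rf(matrix(runif(40), ncol = 2), rep(1, 20)), "constant")
})
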