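test_that("path models validate structure and parse from edge lists", {
  m <- pathModel(c("a -> b", "b -> c"))
  expect_s4_class(m, "PathModel")
  expect_setequal(exogenousVariables(m), "a")
  expect_error(pathModel(c("a -> b", "b -> a")), "acyclic")
  expect_error(pathModel("a -- b"), "malformed")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "map -> total_n", "total_n -> resistance  # tail"),
             path)
  m2 <- readPathModel(path)
  expect_equal(nrow(m2@edges), 2L)
})

test_that("saturated models fit perfectly with zero degrees of freedom", {
  set.seed(2)
  d <- as.data.frame(matrix(rnorm(200 * 4), 200))
  names(d) <- c("a", "b", "c", "e")
  edges <- c("a -> b", "a -> c", "a -> e", "b -> c", "b -> e", "c -> e")
  fit <- fitPathModel(pathModel(edges), d)
  expect_equal(fit@chi2, 0, tolerance = 1e-8)
  expect_equal(fit@df, 0)
  expect_equal(fit@rmsea, 0)
  expect_true(fit@saturated)
  expect_equal(fit@pFit, 1)
  expect_equal(fit@implied, fit@observed, tolerance = 1e-10)
})

test_that("chain coefficients are recovered at large n", {
  d <- semChainData(5000, seed = 3)
  fit <- fitPathModel(pathModel(c("map -> total_n", "total_n -> resistance")),
                      d)
  et <- fit@edges
  expect_equal(et$beta[et$from == "map"], 0.6, tolerance = 0.03)
  expect_equal(et$beta[et$from == "total_n"], 0.5, tolerance = 0.03)
  # implied variances stay on the correlation diagonal
  expect_equal(unname(diag(fit@implied)), rep(1, 3), tolerance = 1e-6)
})

test_that("standardized coefficients and p-values match the lm oracle", {
  set.seed(4)
  d <- data.frame(mat = rnorm(80), map = rnorm(80))
  d$total_n <- 0.5 * d$map - 0.3 * d$mat + rnorm(80, 0, 0.7)
  d$resistance <- 0.6 * d$total_n + rnorm(80, 0, 0.6)
  model <- pathModel(c("mat -> total_n", "map -> total_n",
                       "total_n -> resistance", "mat -> resistance"))
  fit <- fitPathModel(model, d)
  zd <- as.data.frame(scale(d))
  o1 <- summary(lm(total_n ~ mat + map, zd))$coefficients
  o2 <- summary(lm(resistance ~ total_n + mat, zd))$coefficients
  et <- fit@edges
  expect_equal(et$beta[et$from == "mat" & et$to == "total_n"],
               o1["mat", 1], tolerance = 1e-9)
  expect_equal(et$p[et$from == "map" & et$to == "total_n"],
               o1["map", 4], tolerance = 1e-9)
  expect_equal(et$beta[et$from == "total_n"], o2["total_n", 1],
               tolerance = 1e-9)
  expect_equal(et$p[et$from == "mat" & et$to == "resistance"],
               o2["mat", 4], tolerance = 1e-9)
  expect_equal(unname(fit@r2["total_n"]),
               summary(lm(total_n ~ mat + map, zd))$r.squared,
               tolerance = 1e-9)
})

test_that("removing an edge never decreases chi-square", {
  d <- semChainData(300, seed = 5)
  d$mat <- rnorm(300)
  full <- pathModel(c("map -> total_n", "mat -> total_n",
                      "total_n -> resistance", "map -> resistance"))
  chiFull <- fitPathModel(full, d)@chi2
  for (k in seq_len(nrow(full@edges))) {
    sub <- new("PathModel", variables = full@variables,
               edges = full@edges[-k, , drop = FALSE])
    expect_gte(fitPathModel(sub, d)@chi2 + 1e-9, chiFull)
  }
})

test_that("fit evaluation applies the published thresholds", {
  d <- semChainData(800, seed = 6)
  d$noise <- rnorm(800)
  good <- fitPathModel(pathModel(c("map -> total_n",
                                   "total_n -> resistance"),
                                 variables = c("map", "total_n",
                                               "resistance")), d)
  v <- evaluateFit(good)
  expect_true(v$good)
  # a badly wrong model: resistance caused by an unrelated variable only
  bad <- fitPathModel(pathModel(c("noise -> resistance", "map -> total_n"),
                                variables = c("map", "total_n", "noise",
                                              "resistance")), d)
  vb <- evaluateFit(bad)
  expect_false(vb$good)
  expect_gt(bad@rmsea, 0.05)
})

test_that("backward pruning removes exactly the noise edge", {
  hits <- 0L
  for (s in 1:20) {
    d <- semChainData(400, b1 = 0.6, b2 = 0.6, seed = 100 + s)
    set.seed(200 + s)
    d$mat <- rnorm(400)
    model <- pathModel(c("map -> total_n", "total_n -> resistance",
                         "mat -> resistance"))
    pr <- pruneToOptimal(model, d, alpha = 0.05)
    hits <- hits + identical(pr$removed, "mat -> resistance")
  }
  expect_gte(hits, 15L)

  # strong edges survive untouched
  d <- semChainData(1000, seed = 7)
  pr <- pruneToOptimal(pathModel(c("map -> total_n",
                                   "total_n -> resistance")), d)
  expect_length(pr$removed, 0)
  # pruning pure noise collapses with a warning
  set.seed(8)
  d2 <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_warning(pruneToOptimal(pathModel("a -> b"), d2), "edgeless")
})

test_that("parameter recovery over repeated simulated DAGs is unbiased", {
  errs <- c()
  for (s in 1:25) {
    set.seed(s)
    n <- 500
    mat <- rnorm(n); map <- rnorm(n)
    tc <- 0.4 * map - 0.2 * mat + rnorm(n, 0, sqrt(1 - 0.4^2 - 0.2^2))
    tn <- 0.5 * map + rnorm(n, 0, sqrt(1 - 0.25))
    res <- 0.35 * tc + 0.3 * tn + rnorm(n, 0, 0.8)
    d <- data.frame(mat = mat, map = map, total_c = tc, total_n = tn,
                    resistance = res)
    fit <- fitPathModel(pathModel(c("map -> total_c", "mat -> total_c",
                                    "map -> total_n",
                                    "total_c -> resistance",
                                    "total_n -> resistance")), d)
    et <- fit@edges
    truth <- c("map.total_c" = 0.4, "mat.total_c" = -0.2,
               "map.total_n" = 0.5)
    for (nm in names(truth)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      errs <- c(errs, abs(et$beta[et$from == parts[1] &
                                    et$to == parts[2]] - truth[[nm]]))
    }
  }
  expect_lte(mean(errs), 0.05)
})
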