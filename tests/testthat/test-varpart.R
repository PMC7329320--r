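test_that("the Hellinger transform produces unit-sum-of-squares rows", {
  expect_equal(hellinger(rbind(c(4, 0)))[1, ], c(1, 0), tolerance = 1e-15)
  expect_equal(hellinger(rbind(c(1, 1)))[1, ], rep(sqrt(0.5), 2),
               tolerance = 1e-9)
  set.seed(5)
  m <- matrix(rexp(60), nrow = 6)
  h <- hellinger(m)
  expect_equal(rowSums(h^2), rep(1, 6), tolerance = 1e-12)
  expect_error(hellinger(rbind(c(-1, 2))), "negative")
  expect_error(hellinger(rbind(c(1, 1), c(0, 0))), "degenerate row.*2")
})

test_that("multivariate R2 matches the column-wise OLS oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- 40
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
    Y <- X %*% matrix(rnorm(3 * 4), 3) + matrix(rnorm(n * 4), n)
    fit <- rdaAdjR2(Y, X)
    expect_equal(fit$r2, oracleMultR2(Y, X), tolerance = 1e-10)
    expect_equal(fit$adj_r2, oracleAdjR2(fit$r2, n, 3), tolerance = 1e-12)
  }
  # exact linear map and constructed orthogonality
  X <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("a", "b")))
  expect_equal(rdaAdjR2(X %*% matrix(1:4, 2), X)$r2, 1, tolerance = 1e-12)
  Y <- matrix(rnorm(30 * 3), 30)
  Yorth <- Y - qr.fitted(qr(cbind(1, X)), Y)
  expect_equal(rdaAdjR2(Yorth, X)$r2, 0, tolerance = 1e-9)
  # collinearity is an informative error
  Xc <- cbind(X, c2 = X[, 1] * 2)
  expect_error(rdaAdjR2(Y, Xc), "collinearity.*c2")
})

test_that("adjusted R2 converges to R2 at large n", {
  set.seed(2)
  n <- 1e5
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  Y <- X %*% matrix(c(1, 0.5, -0.3, 0.2), 2) + matrix(rnorm(n * 2), n)
  fit <- rdaAdjR2(Y, X)
  expect_lt(abs(fit$adj_r2 - fit$r2), 1e-4)
})

test_that("varpart2 obeys the inclusion-exclusion identity and its edge cases", {
  set.seed(21)
  n <- 60
  XM <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("mat", "map")))
  XS <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("tc", "tn", "tp")))
  Y <- XS %*% matrix(rnorm(3 * 5), 3) + matrix(rnorm(n * 5), n)
  vp <- varpart2(Y, XM, XS)
  expect_equal(vp$frac_unique_M + vp$frac_shared + vp$frac_unique_S +
                 vp$frac_residual, 1, tolerance = 1e-9)
  ora <- oracleVarpart(Y, XM, XS)
  expect_equal(unlist(vp[1, 1:4], use.names = FALSE), unname(ora),
               tolerance = 1e-10)
  # shared fraction symmetric in the two sets
  vp2 <- varpart2(Y, XS, XM)
  expect_equal(vp2$frac_shared, vp$frac_shared, tolerance = 1e-12)
  expect_equal(vp2$frac_unique_M, vp$frac_unique_S, tolerance = 1e-12)
  # duplicated sets: no unique fractions, shared is the set's adjusted R2
  dup <- varpart2(Y, XM, XM)
  expect_equal(dup$frac_unique_M, 0, tolerance = 1e-9)
  expect_equal(dup$frac_unique_S, 0, tolerance = 1e-9)
  expect_equal(dup$frac_shared, rdaAdjR2(Y, XM)$adj_r2, tolerance = 1e-9)
})

test_that("a response built from one set leaves the other set no unique share", {
  set.seed(31)
  n <- 2000
  XM <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("mat", "map")))
  XS <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("tc", "tn", "tp")))
  Y <- XS %*% matrix(rnorm(3 * 4, sd = 0.5), 3) + matrix(rnorm(n * 4), n)
  vp <- varpart2(Y, XM, XS)
  expect_lt(abs(vp$frac_unique_M), 0.02)
  expect_gt(vp$frac_unique_S, 0.1)
})

test_that("varpart2 agrees with vegan's partitioning", {
  skip_if_not_installed("vegan")
  set.seed(41)
  n <- 50
  XM <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("mat", "map")))
  XS <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("tc", "tn", "tp")))
  Y <- XS %*% matrix(rnorm(3 * 6, sd = 0.4), 3) +
    XM %*% matrix(rnorm(2 * 6, sd = 0.2), 2) + matrix(rnorm(n * 6), n)
  vp <- varpart2(Y, XM, XS)
  # vegan's indfract rows: [a] unique X1, [b] unique X2, [c] shared, [d] resid
  vg <- vegan::varpart(Y, XM, XS)$part$indfract$Adj.R.square
  expect_equal(vp$frac_unique_M, vg[1], tolerance = 1e-6)
  expect_equal(vp$frac_unique_S, vg[2], tolerance = 1e-6)
  expect_equal(vp$frac_shared, vg[3], tolerance = 1e-6)
  expect_equal(vp$frac_residual, vg[4], tolerance = 1e-6)
})

test_that("permutation tests saturate under strong signal and are seed-stable", {
  set.seed(51)
  n <- 54
  XM <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("mat", "map")))
  XS <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("tc", "tn", "tp")))
  Y <- XS %*% matrix(2, 3, 4) + matrix(rnorm(n * 4, sd = 0.3), n)
  p <- permutationTestFraction(Y, XM, XS, "S", nPerm = 999, seed = 3)$p
  expect_equal(p, 1 / 1000, tolerance = 1e-12)
  p1 <- permutationTestFraction(Y, XM, XS, "M", nPerm = 99, seed = 5)$p
  p2 <- permutationTestFraction(Y, XM, XS, "M", nPerm = 99, seed = 5)$p
  expect_identical(p1, p2)
  expect_error(permutationTestFraction(Y, XM, XS, "M", nPerm = 50), ">= 99")
})

test_that("correlation heat-map cells match the closed-form Pearson test", {
  set.seed(61)
  n <- 30
  sv <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("mat", "tn")))
  ga <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("nifH", "phoD", "nosZ")))
  ga[, 1] <- sv[, 1]  # perfect correlation
  out <- correlationHeatmapStats(sv, ga)
  cell <- out[out$var_x == "mat" & out$var_y == "nifH", ]
  expect_equal(cell$r, 1, tolerance = 1e-12)
  expect_identical(cell$stars, "***")
  for (k in which(!(out$var_x == "mat" & out$var_y == "nifH"))) {
    r <- cor(sv[, out$var_x[k]], ga[, out$var_y[k]])
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    expect_equal(out$r[k], r, tolerance = 1e-10)
    expect_equal(out$p[k], p, tolerance = 1e-10)
  }
  # constant column flagged, not fatal
  sv2 <- sv; sv2[, 2] <- 5
  out2 <- correlationHeatmapStats(sv2, ga)
  expect_true(all(out2$undefined[out2$var_x == "tn"]))
})
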