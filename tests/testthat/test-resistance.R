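test_that("the resistance index matches its analytic anchor points", {
  expect_identical(resistanceIndex(100, 100), 1)
  expect_identical(resistanceIndex(50, 100), 0)
  expect_equal(resistanceIndex(4, 2), 1 / 3, tolerance = 1e-15)
  rs <- resistanceIndex(1, 1e6)
  expect_gt(rs, -1)
  expect_lt(abs(rs + 1), 2.001e-6)
  expect_error(resistanceIndex(0, 10), "undefined control")
  expect_error(resistanceIndex(-5, 10), "undefined control")
})

test_that("the index is strictly decreasing in |D0| and bounded in (-1, 1]", {
  c0 <- 7.3
  d0 <- seq(0, 1e4, length.out = 2000)
  rs <- resistanceIndex(c0, c0 + d0)
  expect_identical(rs[1], 1)
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs > -1))
  expect_identical(resistanceIndex(c0, 0), 0)  # complete loss = 100% change
  # symmetric in the sign of the change
  expect_equal(resistanceIndex(10, 4), resistanceIndex(10, 16),
               tolerance = 1e-15)
})

test_that("resistance tables align keys and count site x gene records", {
  set.seed(1)
  control <- matrix(10^runif(16 * 54, 4, 8), nrow = 16,
                    dimnames = list(paste0("g", 1:16), sprintf("S%02d", 1:54)))
  rec <- resistanceTable(control, control, "warming")
  expect_equal(nrow(rec), 864L)
  expect_true(all(rec$rs == 1))

  treated <- control[, -3]
  expect_error(resistanceTable(control, treated, "warming"), "S03")
  expect_error(resistanceTable(control[-1, ], control, "warming"), "g1")
})

test_that("group normalization reproduces hand-computed shares", {
  expect_equal(unname(normalizeGroup(cbind(g = c(2, 2, 2, 2)))),
               rep(0.25, 4), tolerance = 1e-15)
  m <- cbind(g1 = c(1, 3), g2 = c(2, 2))
  expect_equal(unname(normalizeGroup(m)), c(0.375, 0.625), tolerance = 1e-15)
})

test_that("group scores sum to one and are gene-rescaling invariant", {
  set.seed(99)
  for (i in 1:50) {
    m <- matrix(rexp(8 * 5), nrow = 8)
    colnames(m) <- paste0("g", 1:5)
    sc <- normalizeGroup(m)
    expect_equal(sum(sc), 1, tolerance = 1e-9)
    m2 <- m
    m2[, 3] <- m2[, 3] * 1000
    expect_equal(normalizeGroup(m2), sc, tolerance = 1e-12)
  }
  expect_error(normalizeGroup(cbind(g = c(-1, 2))), "invalid input")
  expect_error(normalizeGroup(cbind(g1 = c(1, 2), g2 = c(0, 0))),
               "degenerate gene")
})

test_that("group resistance aggregates per site in both modes", {
  rec <- data.frame(site_id = rep(c("S1", "S2"), each = 3),
                    gene = rep(c("a", "b", "c"), 2),
                    stressor = "warming",
                    c0 = 1, treated = 1,
                    rs = c(0.2, 0.4, 0.6, 1, 1, 1))
  g <- groupResistance(rec, c("a", "b", "c"))
  expect_equal(unname(g["S1"]), 0.4, tolerance = 1e-15)
  expect_equal(unname(g["S2"]), 1, tolerance = 1e-15)
  # brute-force mean oracle
  brute <- vapply(split(rec$rs, rec$site_id), mean, numeric(1))
  expect_equal(g[names(brute)], brute, tolerance = 1e-12,
               ignore_attr = TRUE)
  # eq2 mode: shifted shares sum to one across sites
  g2 <- groupResistance(rec, c("a", "b", "c"), mode = "eq2")
  expect_equal(sum(g2), 1, tolerance = 1e-9)
  expect_error(groupResistance(rec[-1, ], c("a", "b", "c")), "a")
})

test_that("stressor comparison flags real shifts and not identical populations", {
  set.seed(7)
  base <- rnorm(54, 0.5, 0.1)
  rec <- do.call(rbind, lapply(c("drying_wetting", "warming", "n_deposition"),
    function(s) data.frame(site_id = sprintf("S%02d", 1:54), gene = "nifH",
                           stressor = s, c0 = 1, treated = 1, rs = base)))
  out <- compareStressors(rec)
  expect_gt(out$omnibus$p, 0.05)
  expect_false(out$omnibus$signif)

  shifted <- rec
  shifted$rs[shifted$stressor == "warming"] <-
    shifted$rs[shifted$stressor == "warming"] - 0.3
  out2 <- compareStressors(shifted)
  expect_lt(out2$omnibus$p_adj, 0.05)
  pw <- out2$pairwise
  wd <- pw[pw$group1 == "drying_wetting" & pw$group2 == "warming", ]
  expect_lt(wd$p_adj, 0.05)
  expect_gt(wd$statistic, 0)   # warming ranks lower

  expect_error(compareStressors(rec[rec$stressor == "warming", ]),
               "at least two")
})

test_that("under the default simulation amoA-b resists N deposition most", {
  x <- generateExperiment(nSites = 54, seed = 17)
  rec <- experimentResistance(x)
  m <- tapply(rec$rs[rec$gene == "amoA-b"], rec$stressor[rec$gene == "amoA-b"],
              mean)
  expect_gt(m[["n_deposition"]], m[["warming"]])
  expect_gt(m[["n_deposition"]], m[["drying_wetting"]])
  out <- compareStressors(rec, genes = "amoA-b")
  expect_true(is.finite(out$omnibus$p))
  expect_equal(nrow(out$pairwise), 3L)
})

test_that("stressor comparison keeps its nominal size under the null", {
  set.seed(1234)
  rejections <- 0L
  nSim <- 400L
  stressors <- c("drying_wetting", "warming", "n_deposition")
  for (i in seq_len(nSim)) {
    rec <- data.frame(site_id = rep(sprintf("S%02d", 1:20), 3),
                      gene = "nifH",
                      stressor = rep(stressors, each = 20),
                      c0 = 1, treated = 1, rs = rnorm(60))
    rejections <- rejections + (compareStressors(rec)$omnibus$p < 0.05)
  }
  expect_lt(rejections / nSim, 0.075)
})
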