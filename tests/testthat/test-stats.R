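test_that("contrast fold changes and directions follow the log2 means", {
  set.seed(7)
  se <- randomExpr(20, sprintf("s%d", 1:6),
                   groups = rep(c("ctl", "case"), each = 3))
  x <- exprValues(se)
  cc <- probeContrast(se, "ctl", "case")
  expect_equal(cc$log2fc,
               unname(rowMeans(x[, 4:6]) - rowMeans(x[, 1:3])))
  expect_equal(cc$fc, 2^cc$log2fc, tolerance = 1e-12)
  expect_identical(cc$direction,
                   ifelse(cc$log2fc > 0, "increased", "decreased"))
  expect_true(all(cc$p_bh >= cc$p_raw))
  # identical group means: all unchanged
  m <- matrix(rep(c(5, 6), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  cc0 <- probeContrast(exprMatrix(m), c("s1", "s2"), c("s3", "s4"),
                       method = "ordinary")
  expect_true(all(cc0$direction == "unchanged"))
  expect_true(all(cc0$log2fc == 0))
  expect_true(all(cc0$flag == "zero_variance"))
  expect_true(all(cc0$p_raw == 1))
  expect_error(probeContrast(se, "ctl", c("s4", "s5", "s1")), "disjoint")
  expect_error(probeContrast(se, c("s1"), c("s4", "s5")), "at least 2")
})

test_that("moderated p-values match an independent direct evaluation", {
  set.seed(11)
  n <- 50
  x1 <- matrix(rnorm(n * 4, 8, 0.4), n,
               dimnames = list(sprintf("p%02d", 1:n), paste0("a", 1:4)))
  x2 <- matrix(rnorm(n * 3, 8, 0.4), n,
               dimnames = list(rownames(x1), paste0("b", 1:3)))
  x2[1:10, ] <- x2[1:10, ] + 2   # known shifts
  se <- exprMatrix(cbind(x1, x2))
  cc <- probeContrast(se, colnames(x1), colnames(x2), method = "moderated")
  expect_equal(cc$p_raw, unname(bruteModeratedP(x1, x2)), tolerance = 1e-10)
})

test_that("moderated t agrees with limma on the same data", {
  set.seed(13)
  n <- 200
  x <- matrix(rnorm(n * 7, 8, 0.5), n,
              dimnames = list(sprintf("p%03d", 1:n), sprintf("s%d", 1:7)))
  x[1:20, 5:7] <- x[1:20, 5:7] + 1.5
  se <- exprMatrix(x)
  cc <- probeContrast(se, sprintf("s%d", 1:4), sprintf("s%d", 5:7))
  design <- cbind(1, rep(c(0, 1), c(4, 3)))
  fit <- limma::eBayes(limma::lmFit(x, design))
  # homogeneous variances: the fitted prior df is infinite here; the
  # statistic agrees with limma, while our p is the z-like limit (limma
  # instead caps the df at the pooled residual df)
  expect_equal(cc$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(cc$p_raw, unname(2 * pnorm(-abs(fit$t[, 2]))),
               tolerance = 1e-10)
  # heterogeneous per-probe variances: finite prior df path
  sds <- sqrt(0.25 / rchisq(n, 5) * 5)
  x2 <- matrix(rnorm(n * 7, 8, rep(sds, 7)), n,
               dimnames = dimnames(x))
  cc2 <- probeContrast(exprMatrix(x2), sprintf("s%d", 1:4),
                       sprintf("s%d", 5:7))
  fit2 <- limma::eBayes(limma::lmFit(x2, design))
  expect_true(is.finite(fit2$df.prior))
  expect_equal(cc2$t, unname(fit2$t[, 2]), tolerance = 1e-8)
  expect_equal(cc2$p_raw, unname(fit2$p.value[, 2]), tolerance = 1e-8)
})

test_that("ordinary t is the d0 -> 0 limit of the moderated statistic", {
  set.seed(17)
  se <- randomExpr(30, sprintf("s%d", 1:6))
  x <- exprValues(se)
  cc <- probeContrast(se, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                      method = "ordinary")
  m1 <- rowMeans(x[, 1:3]); m2 <- rowMeans(x[, 4:6])
  s2 <- (rowSums((x[, 1:3] - m1)^2) + rowSums((x[, 4:6] - m2)^2)) / 4
  expect_equal(cc$t, unname((m2 - m1) / sqrt(s2 * (2 / 3))),
               tolerance = 1e-12)
  expect_equal(cc$df, rep(4, 30))
})

test_that("BH and Hochberg adjustments match the hand-evaluated step-up", {
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustHochberg(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(adjustHochberg(0.2), 0.2)
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(1:6, 1))
    expect_equal(adjustBH(p), bruteBH(p))
    expect_equal(adjustHochberg(p), bruteHochberg(p))
    # elementwise bounds: raw <= hochberg <= bonferroni; bh >= raw
    expect_true(all(adjustBH(p) >= p))
    expect_true(all(adjustHochberg(p) >= p))
    expect_true(all(adjustHochberg(p) <= pmin(1, length(p) * p)))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(adjustBH(p[o]), bruteBH(p)[o])
    expect_equal(adjustHochberg(p[o]), bruteHochberg(p)[o])
  }
  expect_error(adjustBH(c(0.5, 1.2)), "0,1")
  expect_error(adjustHochberg(c(-0.1)), "0,1")
})

test_that("hypergeometric tail matches exhaustive enumeration (m <= 12)", {
  expect_equal(hypergeomTail(4, 4, 5, 10), 5 / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(hypergeomTail(3, 3, 6, 6), 1)   # all successes, must draw them
  set.seed(29)
  for (i in 1:40) {
    m <- sample(2:12, 1)
    nd <- sample(1:m, 1)
    k <- sample(0:m, 1)
    x <- sample(0:nd, 1)
    if (x > k) next
    expect_equal(hypergeomTail(x, nd, k, m), bruteHyperTail(x, nd, k, m),
                 tolerance = 1e-12,
                 label = sprintf("tail(%d,%d,%d,%d)", x, nd, k, m))
  }
  # non-increasing in x
  tails <- vapply(0:6, function(x) hypergeomTail(x, 6, 7, 12), numeric(1))
  expect_true(all(diff(tails) <= 1e-14))
  expect_error(hypergeomTail(5, 4, 5, 10), "bounds")
  # log-space evaluation keeps extreme tails finite and accurate
  lp <- hypergeomTail(446, 454, 18406, 45101, log.p = TRUE)
  expect_lt(lp / log(10), -150)
  expect_gt(lp / log(10), -170)
})

test_that("contrast clustering reproduces hand-computed merges", {
  probes <- sprintf("p%02d", 1:12)
  set.seed(31)
  base <- rnorm(12)
  cA <- makeContrast(probes, rep("increased", 12), lfc = base)
  cB <- makeContrast(probes, rep("increased", 12), lfc = base + rnorm(12, sd = 0.05))
  cC <- makeContrast(probes, rep("increased", 12), lfc = -base)
  cl <- clusterContrasts(list(A = cA, B = cB, C = cC), probes)
  expect_equal(cl$correlation["A", "A"], 1)
  expect_equal(cl$correlation["A", "C"], cor(base, -base))
  # A and B merge first (distance near 0), C joins last at ~ mean distance
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$hclust$height[2],
               mean(1 - cl$correlation[c("A", "B"), "C"]), tolerance = 1e-12)
  expect_match(cl$newick, "^\\(")
  # identical contrasts: r = 1, merge height 0
  cl2 <- clusterContrasts(list(A = cA, A2 = cA), probes)
  expect_equal(cl2$hclust$height, 0, tolerance = 1e-12)
  flat <- makeContrast(probes, rep("unchanged", 12), lfc = rep(0, 12))
  expect_error(clusterContrasts(list(A = cA, flat = flat), probes), "flat")
})
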