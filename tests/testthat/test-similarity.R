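tpm_mat <- function(m) abundance_matrix(m, "TPM")

test_that("spearman similarity: monotone transforms, reversals, worked case", {
  g <- paste0("g", 1:4)
  bulk <- matrix(c(1, 2, 3, 4,  4, 3, 2, 1,  1, 2, 4, 3), 4,
                 dimnames = list(g, c("up", "down", "swap")))
  ref <- matrix(exp(1:4), 4, 1, dimnames = list(g, "r"))  # monotone in 1:4
  s <- spearman_similarity(tpm_mat(bulk), tpm_mat(ref))
  expect_equal(s$rho["up", "r"], 1.0)
  expect_equal(s$rho["down", "r"], -1.0)
  # ranks (1,2,4,3) vs (1,2,3,4): 1 - 6*2/(4*15) = 0.8
  expect_equal(s$rho["swap", "r"], 0.8)
  expect_identical(s$n_shared_genes, 4L)
})

test_that("too small a shared-gene set errors with the intersection size", {
  bulk <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  ref <- matrix(1:4, 2, dimnames = list(c("b", "c"), c("r1", "r2")))
  expect_error(spearman_similarity(tpm_mat(bulk), tpm_mat(ref)),
               "only 1 genes shared")
})

test_that("rank-sum p matches exhaustive enumeration for small test sets", {
  x <- c(0.9, 0.8)
  y <- c(0.9, 0.8, 0.2, 0.15, 0.1, 0.05)  # background includes test set
  rs <- rank_sum_greater(x, y)
  expect_true(rs$exact)
  expect_equal(rs$p, rank_sum_enum_oracle(x, y))

  set.seed(31)
  for (rep in 1:10) {
    m <- sample(1:5, 1)
    n <- sample(4:10, 1)
    x <- round(runif(m), 2)           # rounding forces occasional ties
    y <- round(runif(n), 2)
    if (max(c(x, y)) == min(c(x, y))) next
    expect_equal(rank_sum_greater(x, y)$p, rank_sum_enum_oracle(x, y),
                 info = sprintf("m=%d n=%d rep=%d", m, n, rep))
  }
})

test_that("rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(32)
  for (rep in 1:10) {
    x <- runif(sample(2:6, 1))
    y <- runif(sample(5:12, 1))
    expect_equal(rank_sum_greater(x, y)$p,
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value)
  }
})

test_that("a test set strictly above the background attains the minimal p", {
  y <- seq(0.1, 0.5, length.out = 8)
  x <- y[1:3] + 1                      # ranks strictly above background
  rs <- rank_sum_greater(x, y)
  expect_equal(rs$p, 1 / choose(11, 3))
})

test_that("normal approximation tracks the exact tail for sizes 8-10", {
  set.seed(33)
  for (m in 8:10) {
    x <- rnorm(m, 0.3)
    y <- rnorm(25)
    exact <- rank_sum_greater(x, y, exact_max = 10)$p
    approx <- rank_sum_greater(x, y, exact_max = 0)$p
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("degenerate background yields p = 1 with a warning", {
  expect_warning(rs <- rank_sum_greater(c(1, 1), rep(1, 6)), "degenerate")
  expect_equal(rs$p, 1)
})

test_that("group significance fills -log10 p and respects the background mode", {
  set.seed(34)
  g <- paste0("g", 1:30)
  bulk <- matrix(rexp(30 * 4), 30,
                 dimnames = list(g, c("CN_D1", "CN_D2", "F_D1", "F_D2")))
  ref <- matrix(rexp(30 * 2), 30, dimnames = list(g, c("rA", "rB")))
  sim <- spearman_similarity(tpm_mat(bulk), tpm_mat(ref))
  groups <- setNames(c("CN", "CN", "F", "F"), colnames(bulk))
  out <- group_significance(sim, groups)
  tests <- out$group_tests
  expect_identical(nrow(tests), 4L)
  expect_true(all(tests$p > 0 & tests$p <= 1))
  expect_true(all(tests$neg_log10_p >= 0))
  expect_equal(tests$neg_log10_p, -log10(tests$p))

  # "others" excludes the tested cells from the background
  out2 <- group_significance(sim, groups, background = "others")
  t1 <- out$group_tests[1, ]
  x <- sim$rho[c("CN_D1", "CN_D2"), "rA"]
  expect_equal(t1$p, rank_sum_enum_oracle(x, as.numeric(sim$rho)))
  expect_equal(out2$group_tests$p[1],
               rank_sum_enum_oracle(x, setdiff(as.numeric(sim$rho), x)))

  # BH adjustment is optional
  out3 <- group_significance(sim, groups, adjust = TRUE)
  expect_true("p_bh" %in% names(out3$group_tests))
})

test_that("sample sheets work directly as the group mapping", {
  set.seed(35)
  g <- paste0("g", 1:20)
  bulk <- matrix(rexp(20 * 2), 20, dimnames = list(g, c("CN_D1", "CN_D2")))
  ref <- matrix(rexp(20 * 2), 20, dimnames = list(g, c("rA", "rB")))
  sim <- spearman_similarity(tpm_mat(bulk), tpm_mat(ref))
  sheet <- sample_sheet(data.frame(sample_id = c("CN_D1", "CN_D2"),
                                   donor_id = c("D1", "D2"),
                                   cell_type = "CN"))
  out <- group_significance(sim, sheet)
  expect_identical(unique(out$group_tests$group), "CN")
})

test_that("classical MDS recovers collinear and Euclidean configurations", {
  # 3 collinear points at 0, 1, 2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  ord <- classical_mds(d, k = 1)
  rec <- as.matrix(dist(ord$points))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)

  # identical samples: all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  expect_equal(unname(classical_mds(z, k = 2)$points),
               matrix(0, 3, 2), tolerance = 1e-10)

  # random Euclidean-embeddable distances are reproduced at full rank
  set.seed(36)
  pts <- matrix(rnorm(5 * 3), 5)
  dd <- as.matrix(dist(pts))
  ord2 <- classical_mds(dd, k = 4)
  expect_equal(unname(as.matrix(dist(ord2$points))), unname(dd),
               tolerance = 1e-8)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-8))
})

test_that("classical MDS agrees with a direct eigen-decomposition oracle", {
  set.seed(37)
  pts <- matrix(rnorm(6 * 2), 6)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  ours <- classical_mds(d, k = 2)$points
  oracle <- mds_oracle(d, 2)
  # coordinates agree up to per-axis reflection
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(ours[, j], oracle[, j],
                                 tolerance = 1e-6,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(ours[, j], -oracle[, j],
                                 tolerance = 1e-6,
                                 check.attributes = FALSE)))
  }
})

test_that("MDS input validation", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(classical_mds(d, 1), "symmetric")
  d2 <- matrix(c(0.5, 1, 1, 0), 2)
  expect_error(classical_mds(d2, 1), "diagonal")
  d3 <- matrix(c(0, 1, 1, 0), 2)
  expect_error(classical_mds(d3, 2), "k must be")
})

test_that("1-spearman dissimilarity is symmetric with zero diagonal", {
  set.seed(38)
  m <- matrix(rexp(40), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  d <- sample_dissimilarity(tpm_mat(m))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 2))
})
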