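make_plate <- function(records) qpcr_plate(do.call(rbind, records))

rec <- function(gene, line, cts) {
  data.frame(gene = gene, cell_line = line, replicate = seq_along(cts),
             ct = cts, stringsAsFactors = FALSE)
}

test_that("delta_ct averages replicates against the housekeeping mean", {
  plate <- make_plate(list(
    rec("TGT", "CN", c(25, 25, 25)),
    rec("GAPDH", "CN", c(20, 20, 20)),
    rec("TBP", "CN", c(22, 22, 22))))
  d <- delta_ct(plate)
  expect_equal(d$delta_ct, 4)  # 25 - mean(20, 22)
  expect_identical(d$flag, "ok")

  # target equal to the housekeeping mean -> delta CT 0
  plate0 <- make_plate(list(
    rec("TGT", "CN", c(21, 21, 21)),
    rec("GAPDH", "CN", c(20, 20, 20)),
    rec("TBP", "CN", c(22, 22, 22))))
  expect_equal(delta_ct(plate0)$delta_ct, 0)
})

test_that("not-detected replicates are dropped and flagged", {
  plate <- make_plate(list(
    rec("TGT", "CN", c(24, 26, NA)),
    rec("NDG", "CN", c(NA, NA, NA)),
    rec("GAPDH", "CN", c(20, 20, 20)),
    rec("TBP", "CN", c(22, 22, 22))))
  d <- delta_ct(plate)
  tgt <- d[d$gene == "TGT", ]
  expect_equal(tgt$delta_ct, 4)  # mean of the two detected
  expect_identical(tgt$flag, "partial")
  ndg <- d[d$gene == "NDG", ]
  expect_true(is.na(ndg$delta_ct))
  expect_identical(ndg$flag, "nd")
})

test_that("missing housekeeping coverage is an error", {
  plate <- make_plate(list(
    rec("TGT", "CN", c(25, 25, 25)),
    rec("GAPDH", "CN", c(20, 20, 20))))
  expect_error(delta_ct(plate), "TBP.*missing.*CN")
})

test_that("relative expression sets the reference to 1 and 2^-ddct elsewhere", {
  dct <- data.frame(gene = "TGT", cell_line = c("CN", "F", "PBMC"),
                    delta_ct = c(2, 7, 4), n_detected = 3,
                    n_replicates = 3, flag = "ok")
  rel <- relative_expression(dct)
  expect_identical(unique(rel$reference_line), "CN")
  expect_identical(rel$relative[rel$cell_line == "CN"], 1)
  expect_equal(rel$relative[rel$cell_line == "F"], 0.03125)  # 2^-5
  expect_equal(rel$relative[rel$cell_line == "PBMC"], 0.25)
  expect_true(all(rel$relative <= 1))
})

test_that("reference ties break canonically and all-nd genes stay nd", {
  dct <- data.frame(gene = "TGT", cell_line = c("CN", "F"),
                    delta_ct = c(3, 3), n_detected = 3, n_replicates = 3,
                    flag = "ok")
  rel <- relative_expression(dct)
  expect_identical(unique(rel$reference_line), "F")  # F first canonically
  expect_true(all(rel$tie))

  nd <- relative_expression(data.frame(
    gene = "X", cell_line = c("CN", "F"), delta_ct = NA_real_,
    n_detected = 0, n_replicates = 3, flag = "nd"))
  expect_true(all(is.na(nd$relative)))
  expect_identical(unique(nd$flag), "nd")
})

test_that("relative expression is invariant to a constant CT shift per line", {
  base <- list(
    rec("TGT", "CN", c(24, 25, 26)), rec("TGT", "F", c(28, 29, 30)),
    rec("GAPDH", "CN", c(20, 20, 20)), rec("GAPDH", "F", c(19, 19, 19)),
    rec("TBP", "CN", c(22, 22, 22)), rec("TBP", "F", c(23, 23, 23)))
  rel1 <- relative_expression(delta_ct(make_plate(base)))
  shifted <- lapply(base, function(r) {
    if (any(r$cell_line == "F")) r$ct <- r$ct + 1.7
    r
  })
  rel2 <- relative_expression(delta_ct(make_plate(shifted)))
  expect_equal(rel1$relative, rel2$relative)
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  plate <- make_plate(list(
    rec("TGT", "CN", c(1, 2, 3) + 21), rec("TGT", "F", c(11, 12, 13) + 21),
    rec("GAPDH", "CN", c(20, 20, 20)), rec("GAPDH", "F", c(20, 20, 20)),
    rec("TBP", "CN", c(22, 22, 22)), rec("TBP", "F", c(22, 22, 22))))
  res <- anova_by_gene(plate)$TGT
  oracle <- anova_oracle(c(1, 2, 3, 11, 12, 13), rep(c("CN", "F"), each = 3))
  expect_equal(res$f, oracle$f, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_identical(nrow(res$pairwise), 1L)
  expect_identical(res$pairwise$stars, "***")

  set.seed(41)
  for (rep in 1:5) {
    cts <- lapply(1:3, function(i) rnorm(4, 24 + i))
    plate <- make_plate(list(
      rec("TGT", "PBMC", cts[[1]]), rec("TGT", "F", cts[[2]]),
      rec("TGT", "CN", cts[[3]]),
      rec("GAPDH", "PBMC", rep(20, 4)), rec("GAPDH", "F", rep(20, 4)),
      rec("GAPDH", "CN", rep(20, 4)),
      rec("TBP", "PBMC", rep(22, 4)), rec("TBP", "F", rep(22, 4)),
      rec("TBP", "CN", rep(22, 4))))
    res <- anova_by_gene(plate)$TGT
    oracle <- anova_oracle(unlist(cts) - 21,
                           rep(c("PBMC", "F", "CN"), each = 4))
    expect_equal(res$f, oracle$f, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("ANOVA F is invariant to scaling all observations", {
  base <- c(1.2, 1.4, 1.1, 2.2, 2.5, 2.4)
  groups <- rep(c("CN", "F"), each = 3)
  f1 <- anova_oracle(base, groups)$f
  f2 <- anova_oracle(base * 3.7, groups)$f
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("identical groups yield F = 0, p = 1 (degenerate case warned)", {
  plate <- make_plate(list(
    rec("TGT", "CN", c(22, 23, 24)), rec("TGT", "F", c(22, 23, 24)),
    rec("GAPDH", "CN", rep(20, 3)), rec("GAPDH", "F", rep(20, 3)),
    rec("TBP", "CN", rep(22, 3)), rec("TBP", "F", rep(22, 3))))
  res <- anova_by_gene(plate)$TGT
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)

  flat <- make_plate(list(
    rec("TGT", "CN", rep(25, 3)), rec("TGT", "F", rep(25, 3)),
    rec("GAPDH", "CN", rep(20, 3)), rec("GAPDH", "F", rep(20, 3)),
    rec("TBP", "CN", rep(22, 3)), rec("TBP", "F", rep(22, 3))))
  expect_warning(res2 <- anova_by_gene(flat)$TGT, "zero variance")
  expect_equal(res2$p, 1)
})

test_that("Tukey and Holm corrections both produce pairwise tables", {
  set.seed(42)
  plate <- make_plate(list(
    rec("TGT", "PBMC", rnorm(3, 28)), rec("TGT", "F", rnorm(3, 25)),
    rec("TGT", "CN", rnorm(3, 22)),
    rec("GAPDH", "PBMC", rep(20, 3)), rec("GAPDH", "F", rep(20, 3)),
    rec("GAPDH", "CN", rep(20, 3)),
    rec("TBP", "PBMC", rep(22, 3)), rec("TBP", "F", rep(22, 3)),
    rec("TBP", "CN", rep(22, 3))))
  tk <- anova_by_gene(plate, method = "tukey")$TGT
  hm <- anova_by_gene(plate, method = "holm")$TGT
  expect_identical(nrow(tk$pairwise), 3L)
  expect_identical(nrow(hm$pairwise), 3L)
  expect_true(all(tk$pairwise$p_adj >= 0 & tk$pairwise$p_adj <= 1))
  expect_true(all(hm$pairwise$p_adj >= 0 & hm$pairwise$p_adj <= 1))
})

test_that("plates reject non-positive CTs and duplicate replicate ids", {
  expect_error(qpcr_plate(data.frame(gene = "g", cell_line = "CN",
                                     replicate = 1, ct = -1)),
               "positive")
  dup <- rbind(rec("g", "CN", c(20, 21)), rec("g", "CN", 22))
  expect_error(qpcr_plate(dup), "duplicate")
})
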