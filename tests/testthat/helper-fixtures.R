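# Small programmatic fixtures and independent oracles used across tests.

# 2 genes x 2 samples with counts {{100,900},{10,0}} and lengths {500,2000}
two_gene_cm <- function() {
  counts <- matrix(c(100, 900, 10, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("s1", "s2")))
  count_matrix(counts, c(A = 500, B = 2000))
}

# single-sample matrix used for the hand-derived RPKM/TPM oracle values
ab_cm <- function() {
  counts <- matrix(c(100, 900), ncol = 1,
                   dimnames = list(c("A", "B"), "s1"))
  count_matrix(counts, c(A = 500, B = 2000))
}

write_counts_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  cm <- two_gene_cm()
  cp <- file.path(dir, "counts.tsv")
  lp <- file.path(dir, "lengths.tsv")
  write_count_matrix(cm, cp, lp)
  list(counts = cp, lengths = lp, cm = cm, dir = dir)
}

toy_sheet <- function(cell_types = c("CN", "F"), donors = 2) {
  grid <- expand.grid(donor = seq_len(donors), cell_type = cell_types,
                      stringsAsFactors = FALSE)
  sample_sheet(data.frame(
    sample_id = paste0(grid$cell_type, "_D", grid$donor),
    donor_id = paste0("D", grid$donor), cell_type = grid$cell_type))
}

toy_panel <- function(symbols, groups = "HSP") {
  gene_panel(data.frame(gene_symbol = symbols, alias = NA_character_,
                        disease_groups = rep_len(groups, length(symbols)),
                        stringsAsFactors = FALSE))
}

rpkm_mat <- function(m) abundance_matrix(m, "RPKM")

# --- independent oracles -------------------------------------------------

# brute-force exact one-sided rank-sum p: enumerate every m-subset of the
# combined midranks and count those with rank sum >= observed
rank_sum_enum_oracle <- function(x, y) {
  combined <- c(x, y)
  r <- rank(combined)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  subsets <- utils::combn(length(combined), m)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  mean(w_all >= w_obs - 1e-9)
}

# textbook one-way ANOVA decomposition
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ssb <- sum(sizes * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Torgerson MDS by direct eigen-decomposition of the double-centered matrix
mds_oracle <- function(d, k) {
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen(b, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 0)
  e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
}
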