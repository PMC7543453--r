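# qPCR relative quantification: delta-CT against housekeeping genes,
# delta-delta-CT relative to the highest-expressing cell line (lowest
# delta-CT, set to 1), and per-gene one-way ANOVA across cell lines with
# multiplicity-corrected pairwise comparisons.

hk_means <- function(plate, housekeeping) {
  lines <- unique(plate$cell_line)
  out <- stats::setNames(rep(NA_real_, length(lines)), lines)
  for (cl in lines) {
    per_gene <- vapply(housekeeping, function(h) {
      ct <- plate$ct[plate$gene == h & plate$cell_line == cl]
      if (length(ct) == 0)
        stop_pp("housekeeping gene '", h, "' missing for cell line '", cl,
                "'")
      ct <- ct[!is.na(ct)]
      if (length(ct) == 0)
        stop_pp("housekeeping gene '", h, "' not detected in cell line '",
                cl, "'")
      mean(ct)
    }, 0)
    out[cl] <- mean(per_gene)
  }
  out
}

#' Delta-CT per gene and cell line
#'
#' `delta_ct = mean(target CT replicates) - mean over housekeeping genes of
#' their replicate-mean CTs`. Not-detected replicates (`NA`) are dropped
#' from the target mean; a (gene, cell line) with no detected replicate is
#' reported as `NA` with flag `"nd"`, and one with some dropped replicates
#' is flagged `"partial"`.
#'
#' @param plate A [qpcr_plate()].
#' @param housekeeping Housekeeping gene names (default GAPDH and TBP);
#'   their mean CTs are combined by arithmetic mean, equivalent to
#'   geometric-mean normalization in linear expression space.
#' @return Data frame with `gene`, `cell_line`, `delta_ct`, `n_detected`,
#'   `n_replicates`, `flag` (`"ok"`, `"partial"`, `"nd"`).
#' @export
delta_ct <- function(plate, housekeeping = c("GAPDH", "TBP")) {
  if (!inherits(plate, "qpcr_plate")) plate <- qpcr_plate(plate)
  hk <- hk_means(plate, housekeeping)
  targets <- setdiff(unique(plate$gene), housekeeping)
  rows <- list()
  for (g in targets) {
    for (cl in unique(plate$cell_line[plate$gene == g])) {
      ct <- plate$ct[plate$gene == g & plate$cell_line == cl]
      det <- ct[!is.na(ct)]
      flag <- if (length(det) == 0) "nd"
              else if (length(det) < length(ct)) "partial" else "ok"
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, cell_line = cl,
        delta_ct = if (length(det) == 0) NA_real_ else mean(det) - hk[[cl]],
        n_detected = length(det), n_replicates = length(ct), flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by delta-delta-CT
#'
#' Per gene, the reference cell line is the one with the lowest delta-CT
#' (highest expression); `ddct = delta_ct - delta_ct(reference)` and
#' `relative = 2^(-ddct)`, so the reference line is exactly 1 and all other
#' lines fall in (0, 1]. Ties on the minimal delta-CT go to the first line
#' in canonical cell-type order and are flagged. A gene not detected in any
#' line is reported `nd` overall.
#'
#' @param dct Output of [delta_ct()].
#' @return A `relative_expression_result` data frame: `gene`, `cell_line`,
#'   `delta_ct`, `ddct`, `relative`, `reference_line`, `tie`, `flag`.
#' @export
relative_expression <- function(dct) {
  rows <- list()
  for (g in unique(dct$gene)) {
    sub <- dct[dct$gene == g, , drop = FALSE]
    ord <- c(intersect(canonical_cell_types(), sub$cell_line),
             setdiff(sub$cell_line, canonical_cell_types()))
    sub <- sub[match(ord, sub$cell_line), , drop = FALSE]
    if (all(is.na(sub$delta_ct))) {
      sub$ddct <- NA_real_
      sub$relative <- NA_real_
      sub$reference_line <- NA_character_
      sub$tie <- FALSE
      sub$flag <- "nd"
      rows[[length(rows) + 1]] <- sub
      next
    }
    dmin <- min(sub$delta_ct, na.rm = TRUE)
    winners <- sub$cell_line[!is.na(sub$delta_ct) & sub$delta_ct == dmin]
    ref <- winners[1]
    sub$ddct <- sub$delta_ct - dmin
    sub$relative <- 2^(-sub$ddct)
    sub$relative[sub$cell_line == ref] <- 1  # exact, not 2^-0 fuzz
    sub$reference_line <- ref
    sub$tie <- length(winners) > 1
    rows[[length(rows) + 1]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("relative_expression_result", "data.frame")
  out
}

#' Per-gene one-way ANOVA across cell lines
#'
#' Tests, for each target gene, whether replicate-level delta-CT values
#' differ between cell lines: one-way fixed-effects ANOVA, followed by all
#' pairwise comparisons corrected by Tukey's HSD (default) or Holm-adjusted
#' pairwise t tests with pooled SD. Significance stars: `*` < 0.05,
#' `**` < 0.01, `***` < 0.001, `****` < 0.0001.
#'
#' @param plate A [qpcr_plate()].
#' @param housekeeping Housekeeping gene names (see [delta_ct()]).
#' @param method `"tukey"` (default) or `"holm"`.
#' @return List per gene with `f`, `p`, `pairwise` (data frame of
#'   `comparison`, `p_adj`, `stars`).
#' @export
anova_by_gene <- function(plate, housekeeping = c("GAPDH", "TBP"),
                          method = c("tukey", "holm")) {
  method <- match.arg(method)
  if (!inherits(plate, "qpcr_plate")) plate <- qpcr_plate(plate)
  hk <- hk_means(plate, housekeeping)
  targets <- setdiff(unique(plate$gene), housekeeping)
  out <- list()
  for (g in targets) {
    sub <- plate[plate$gene == g & !is.na(plate$ct), , drop = FALSE]
    # replicate-level delta-CT: each replicate CT against its line's
    # housekeeping mean
    vals <- sub$ct - hk[sub$cell_line]
    line <- factor(sub$cell_line)
    sizes <- table(line)
    if (length(sizes) < 2 || any(sizes < 2))
      stop_pp("gene '", g, "': ANOVA needs >= 2 cell lines with >= 2 ",
              "detected replicates each")
    grand <- mean(vals)
    gm <- tapply(vals, line, mean)
    ssb <- sum(sizes * (gm - grand)^2)
    ssw <- sum((vals - gm[line])^2)
    if (ssw == 0 && ssb == 0) {
      warning("gene '", g, "': zero variance everywhere; p = 1",
              call. = FALSE)
      prs <- utils::combn(levels(line), 2)
      out[[g]] <- list(
        f = 0, p = 1,
        pairwise = data.frame(
          comparison = paste(prs[2, ], prs[1, ], sep = "-"), p_adj = 1,
          stars = "ns", stringsAsFactors = FALSE))
      next
    }
    fit <- stats::aov(vals ~ line)
    an <- summary(fit)[[1]]
    if (method == "tukey") {
      tk <- stats::TukeyHSD(fit)$line
      pw <- data.frame(comparison = rownames(tk),
                       p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
    } else {
      pt <- stats::pairwise.t.test(vals, line, p.adjust.method = "holm")$p.value
      idx <- which(!is.na(pt), arr.ind = TRUE)
      pw <- data.frame(
        comparison = paste(rownames(pt)[idx[, 1]], colnames(pt)[idx[, 2]],
                           sep = "-"),
        p_adj = pt[idx], stringsAsFactors = FALSE)
    }
    pw$stars <- significance_stars(pw$p_adj)
    rownames(pw) <- NULL
    out[[g]] <- list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                     pairwise = pw)
  }
  out
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}
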