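# Core classification procedure: average donors per cell type, express each
# gene's profile relative to its maximum (highest cell type = 100%), and
# assign the gene to its highest-expressing cell type — or NOT_DETECTABLE
# when no cell type shows any (floored) expression.

#' Average samples into per-cell-type columns
#'
#' Collapses a genes x samples matrix to genes x cell types by taking, for
#' each cell type, the arithmetic mean over that cell type's samples
#' (typically the two donors). Column order follows the canonical cell-type
#' order where applicable.
#'
#' @param am An [abundance_matrix()] (unit `"RPKM"`, usually floored).
#' @param sheet A [sample_sheet()] annotating every column of `am`.
#' @return An [abundance_matrix()] with one column per cell type.
#' @export
donor_mean <- function(am, sheet) {
  require_unit(am, "RPKM")
  sheet <- match_sheet(sheet, colnames(am))
  types <- unique(sheet$cell_type)
  types <- c(intersect(canonical_cell_types(), types),
             setdiff(types, canonical_cell_types()))
  vals <- unclass(am)
  attr(vals, "unit") <- NULL
  out <- vapply(types, function(ct) {
    cols <- sheet$sample_id[sheet$cell_type == ct]
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(am)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(am), types))
  abundance_matrix(out, "RPKM")
}

#' Classify one gene by its highest-expressing cell type
#'
#' An all-zero profile is NOT_DETECTABLE (the gene is not expressed in any
#' cell type). Otherwise the gene is assigned to the argmax cell type and
#' the profile is rescaled so the highest value is 100%. Exact ties are
#' broken by the canonical cell-type order (PBMC, LB, F, iPSC, CN, then any
#' further types in column order) and flagged.
#'
#' @param profile Named non-negative numeric vector, one value per cell
#'   type.
#' @return List with `category` (a cell type or `"NOT_DETECTABLE"`),
#'   `relative_percent` (named vector in \[0, 100\], all `NA` when not
#'   detectable) and `tie` (logical).
#' @examples
#' classify_gene(c(PBMC = 0, LB = 0, F = 5, iPSC = 0, CN = 10))
#' @export
classify_gene <- function(profile) {
  if (length(profile) == 0) stop_pp("empty expression profile")
  if (is.null(names(profile))) stop_pp("profile must be named by cell type")
  if (anyNA(profile) || any(profile < 0))
    stop_pp("profile values must be non-negative and non-missing")
  top <- max(profile)
  if (top == 0) {
    return(list(category = NOT_DETECTABLE,
                relative_percent = stats::setNames(
                  rep(NA_real_, length(profile)), names(profile)),
                tie = FALSE))
  }
  ord <- c(intersect(canonical_cell_types(), names(profile)),
           setdiff(names(profile), canonical_cell_types()))
  prof <- profile[ord]
  winners <- names(prof)[prof == top]
  list(category = winners[1],
       relative_percent = 100 * profile / top,
       tie = length(winners) > 1)
}

#' Classify every panel gene
#'
#' Runs [classify_gene()] over the panel genes present in the per-cell-type
#' mean matrix. Panel genes absent from the matrix are treated as
#' NOT_DETECTABLE (never quantified).
#'
#' @param means An [abundance_matrix()] with one column per cell type (see
#'   [donor_mean()]).
#' @param panel A [gene_panel()].
#' @return A `panel_classification` data frame: `gene_symbol`, `category`,
#'   `tie`, one `mean_<cell type>` and one `pct_<cell type>` column per cell
#'   type.
#' @export
classify_panel <- function(means, panel) {
  require_unit(means, "RPKM")
  if (!inherits(panel, "gene_panel")) stop_pp("panel must be a gene_panel")
  types <- colnames(means)
  n <- nrow(panel)
  category <- character(n)
  tie <- logical(n)
  mean_m <- matrix(0, n, length(types),
                   dimnames = list(panel$gene_symbol, types))
  pct_m <- matrix(NA_real_, n, length(types),
                  dimnames = list(panel$gene_symbol, types))
  for (i in seq_len(n)) {
    g <- panel$gene_symbol[i]
    if (g %in% rownames(means)) {
      prof <- stats::setNames(as.numeric(means[g, ]), types)
      cl <- classify_gene(prof)
      category[i] <- cl$category
      tie[i] <- cl$tie
      mean_m[i, ] <- prof
      pct_m[i, ] <- cl$relative_percent[types]
    } else {
      category[i] <- NOT_DETECTABLE
    }
  }
  out <- data.frame(gene_symbol = panel$gene_symbol, category = category,
                    tie = tie, stringsAsFactors = FALSE)
  colnames(mean_m) <- paste0("mean_", types)
  colnames(pct_m) <- paste0("pct_", types)
  out <- cbind(out, as.data.frame(mean_m), as.data.frame(pct_m))
  rownames(out) <- NULL
  class(out) <- c("panel_classification", "data.frame")
  out
}

#' Summarize panel classifications
#'
#' Counts genes per assigned category (cell types plus NOT_DETECTABLE) and
#' expresses them as percentages of the panel size, rounded half away from
#' zero to 1 decimal. The same bookkeeping is repeated within each disease
#' group over that group's own size; a gene belonging to several disease
#' groups is counted once overall and once in every group it belongs to.
#'
#' @param classification A `panel_classification` (see [classify_panel()]).
#' @param panel The [gene_panel()] the genes come from; every classified
#'   gene must appear in it.
#' @return A `classification_summary`: list with `panel_size`, `counts`,
#'   `percentages`, and `per_disease` (named list of
#'   `list(size, counts, percentages)`).
#' @export
summarize_panel <- function(classification, panel) {
  if (!inherits(panel, "gene_panel")) stop_pp("panel must be a gene_panel")
  genes <- classification$gene_symbol
  absent <- setdiff(genes, panel$gene_symbol)
  if (length(absent) > 0)
    stop_pp("classified genes absent from panel: ",
            paste(absent, collapse = ", "))
  cats <- category_order(setdiff(unique(classification$category),
                                 NOT_DETECTABLE))
  # cell types with zero assigned genes still deserve a 0 row when the
  # classification carries their columns
  mean_cols <- grep("^mean_", names(classification), value = TRUE)
  if (length(mean_cols) > 0)
    cats <- category_order(sub("^mean_", "", mean_cols))
  tab <- function(assigned, size) {
    counts <- vapply(cats, function(cc) sum(assigned == cc), 0L)
    list(size = size, counts = counts,
         percentages = round_half_up(100 * counts / size, 1))
  }
  overall <- tab(classification$category, nrow(panel))
  groups <- panel_groups(panel)
  all_groups <- unique(unlist(groups))
  all_groups <- c(intersect(disease_group_labels(), all_groups),
                  setdiff(all_groups, disease_group_labels()))
  per_disease <- lapply(all_groups, function(dg) {
    members <- names(groups)[vapply(groups, function(g) dg %in% g, TRUE)]
    assigned <- classification$category[genes %in% members]
    tab(assigned, length(members))
  })
  names(per_disease) <- all_groups
  structure(list(panel_size = nrow(panel), counts = overall$counts,
                 percentages = overall$percentages,
                 per_disease = per_disease),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> panel of %d genes\n", x$panel_size))
  df <- data.frame(category = names(x$counts), n = unname(x$counts),
                   pct = unname(x$percentages))
  print(df, row.names = FALSE)
  for (dg in names(x$per_disease)) {
    pd <- x$per_disease[[dg]]
    cat(sprintf("  %s (n = %d): %s\n", dg, pd$size,
                paste(sprintf("%s %d (%.1f%%)", names(pd$counts),
                              pd$counts, pd$percentages), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.panel_classification <- function(object, panel, ...) {
  summarize_panel(object, panel)
}

#' Full classification pipeline from raw counts
#'
#' Convenience wrapper chaining [rpkm()], [apply_detection_floor()],
#' [donor_mean()], [classify_panel()] and [summarize_panel()]. The floor is
#' applied per sample before donor averaging by default (`floor_stage =
#' "sample"`); `"mean"` floors the per-cell-type means instead.
#'
#' @param cm A [count_matrix()].
#' @param sheet A [sample_sheet()].
#' @param panel A [gene_panel()].
#' @param floor Detection floor in RPKM (default 0.5).
#' @param floor_stage `"sample"` (default) or `"mean"`.
#' @return List with `rpkm` (floored per-sample matrix), `means`
#'   (per-cell-type means), `classification` and `summary`.
#' @export
run_classification <- function(cm, sheet, panel, floor = 0.5,
                               floor_stage = c("sample", "mean")) {
  floor_stage <- match.arg(floor_stage)
  am <- rpkm(cm)
  if (floor_stage == "sample") {
    am <- apply_detection_floor(am, floor)
    means <- donor_mean(am, sheet)
  } else {
    means <- apply_detection_floor(donor_mean(am, sheet), floor)
  }
  cl <- classify_panel(means, panel)
  list(rpkm = am, means = means, classification = cl,
       summary = summarize_panel(cl, panel))
}
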