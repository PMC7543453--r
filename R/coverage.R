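# Gene-set (GO term) coverage: per set and cell type, how many member genes
# are expressed above a minimum mean RPKM, normalized to a reference cell
# type's column so the profile reads as "fraction of what the reference
# covers".

#' Gene-set coverage above an expression threshold
#'
#' For every gene set and cell type, counts the member genes (restricted to
#' genes present in the expression matrix) whose mean expression is
#' strictly greater than `min_expr` RPKM. Counts are normalized either to
#' the reference cell type's covered count (default) or to the set's total
#' gene number in the matrix. When the reference covers zero genes of a
#' set, its normalized values are undefined (`NA`) and flagged.
#'
#' @param means An [abundance_matrix()] (unit `"RPKM"`), columns = cell
#'   types (see [donor_mean()]).
#' @param catalog A [gene_set_catalog()].
#' @param min_expr Expression threshold in RPKM; strict `>` (default 3).
#' @param reference Reference cell type column (default `"CN"`).
#' @param normalize_to `"covered"` (reference column's covered count,
#'   default) or `"total"` (genes of the set present in the matrix).
#' @return A `coverage_table` data frame with one row per (term, cell
#'   type): `term_id`, `cell_type`, `covered_count`, `term_total`,
#'   `normalized`, `reference_undefined`.
#' @export
coverage <- function(means, catalog, min_expr = 3, reference = "CN",
                     normalize_to = c("covered", "total")) {
  require_unit(means, "RPKM")
  normalize_to <- match.arg(normalize_to)
  if (!inherits(catalog, "gene_set_catalog"))
    stop_pp("catalog must be a gene_set_catalog")
  if (!reference %in% colnames(means))
    stop_pp("reference cell type '", reference,
            "' is not a column of the expression matrix")
  types <- colnames(means)
  rows <- lapply(names(catalog), function(tid) {
    members <- intersect(catalog[[tid]], rownames(means))
    if (length(members) == 0) {
      warning("gene set '", tid,
              "' shares no genes with the expression matrix",
              call. = FALSE)
      return(data.frame(term_id = tid, cell_type = types,
                        covered_count = 0L, term_total = 0L,
                        normalized = NA_real_, reference_undefined = TRUE,
                        stringsAsFactors = FALSE))
    }
    sub <- unclass(means)[members, , drop = FALSE]
    covered <- colSums(sub > min_expr)
    denom <- if (normalize_to == "covered") covered[[reference]]
             else length(members)
    undef <- denom == 0
    data.frame(term_id = tid, cell_type = types,
               covered_count = as.integer(covered),
               term_total = length(members),
               normalized = if (undef) NA_real_ else covered / denom,
               reference_undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_table", "data.frame")
  out
}
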