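# Internal helpers shared across modules.

#' Canonical cell-type order
#'
#' The fixed display/tie-break order of the five profiled cell types:
#' PBMC (peripheral blood mononuclear cells), LB (lymphoblasts),
#' F (fibroblasts), iPSC (induced pluripotent stem cells) and
#' CN (iPSC-derived cortical neurons).
#'
#' @return Character vector of length 5.
#' @export
canonical_cell_types <- function() c("PBMC", "LB", "F", "iPSC", "CN")

#' Recognized disease-group labels
#'
#' @return Character vector of the disease groups a panel entry may carry.
#' @export
disease_group_labels <- function() c("HSP", "ALS", "SMA", "SPASTICITY")

# Category label for genes with no detectable expression in any cell type.
NOT_DETECTABLE <- "NOT_DETECTABLE"

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sorted display order for categories: canonical cell types first (those
# present), then any other cell types, NOT_DETECTABLE last
category_order <- function(cell_types) {
  canon <- canonical_cell_types()
  c(canon[canon %in% cell_types], setdiff(cell_types, canon), NOT_DETECTABLE)
}

stop_pp <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
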