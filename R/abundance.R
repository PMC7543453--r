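#' Expression abundance matrix with a unit tag
#'
#' A genes x columns numeric matrix tagged with the unit its values carry.
#' Columns are samples or cell types depending on the stage of the pipeline.
#' Operations that require a particular unit (e.g. the detection floor, which
#' is defined on RPKM) check the tag and refuse matrices in any other unit,
#' so values can never silently cross unit boundaries.
#'
#' @param values Numeric matrix with gene row names and column names.
#' @param unit One of `"RPKM"`, `"TPM"`, `"RELATIVE_PERCENT"`, `"CT"`,
#'   `"LOG10_LFQ"`.
#' @return An `abundance_matrix`: the matrix with a `unit` attribute.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' am <- abundance_matrix(m, "RPKM")
#' abundance_unit(am)
#' @export
abundance_matrix <- function(values,
                             unit = c("RPKM", "TPM", "RELATIVE_PERCENT",
                                      "CT", "LOG10_LFQ")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop_pp("abundance values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pp("abundance matrix needs gene row names and column names")
  if (anyDuplicated(rownames(values)))
    stop_pp("duplicate gene ids in abundance matrix")
  if (anyDuplicated(colnames(values)))
    stop_pp("duplicate column ids in abundance matrix")
  # CT and LOG10_LFQ may carry missing markers; the count-derived units not
  if (!unit %in% c("CT", "LOG10_LFQ")) {
    if (anyNA(values))
      stop_pp("missing values not allowed in a ", unit, " matrix")
    if (any(values < 0))
      stop_pp("negative values not allowed in a ", unit, " matrix")
  }
  structure(values, unit = unit, class = c("abundance_matrix", class(values)))
}

#' @rdname abundance_matrix
#' @param x An `abundance_matrix`.
#' @export
abundance_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop_pp("object carries no unit tag")
  u
}

# require a unit, with a clear error naming both
require_unit <- function(x, unit) {
  if (!inherits(x, "abundance_matrix"))
    stop_pp("expected an abundance_matrix (unit ", unit, ")")
  u <- abundance_unit(x)
  if (u != unit)
    stop_pp("unit mismatch: operation requires ", unit, " but matrix is ", u)
  invisible(x)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d genes x %d columns, unit = %s\n",
              nrow(x), ncol(x), abundance_unit(x)))
  y <- x
  attr(y, "unit") <- NULL
  class(y) <- "matrix"
  print(utils::head(y, 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more genes)\n", sep = "")
  invisible(x)
}

# subsetting keeps the unit tag when the result is still a matrix
#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- NextMethod(drop = drop)
  if (is.matrix(y))
    y <- structure(y, unit = attr(x, "unit"),
                   class = c("abundance_matrix", class(y)))
  y
}
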