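# Depth/length normalization of raw counts.
#
# RPKM: divide each sample's total reads by 1e6 (RPM), then divide each
# gene's RPM by its length in kb. TPM: length-normalize first, then scale
# each sample so its column sums to 1e6 — making TPM comparable across
# samples by construction. Within a sample the two differ only by a
# positive scale factor.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm(g, s) = count(g, s) / (total(s) / 1e6) / (length(g) / 1000)`.
#' The library size is the matrix's own column total, so every sample must
#' contain at least one read.
#'
#' @param cm A [count_matrix()].
#' @return An [abundance_matrix()] with unit `"RPKM"`, same dimensions.
#' @examples
#' cm <- count_matrix(matrix(c(100, 900), 2, 1,
#'                           dimnames = list(c("A", "B"), "s1")),
#'                    c(A = 500, B = 2000))
#' rpkm(cm)
#' @export
rpkm <- function(cm) {
  if (!inherits(cm, "count_matrix")) stop_pp("rpkm() needs a count_matrix")
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stop_pp("sample with zero total reads: ",
            paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  rpm <- sweep(cm$counts, 2, totals / 1e6, "/")
  vals <- sweep(rpm, 1, cm$gene_lengths / 1000, "/")
  abundance_matrix(vals, "RPKM")
}

#' Transcripts per million
#'
#' Per-gene length-normalized rates `count / (length/1000)` are rescaled so
#' that each column sums to exactly 1e6.
#'
#' @inheritParams rpkm
#' @return An [abundance_matrix()] with unit `"TPM"`; each column sums to
#'   1e6 within floating-point tolerance.
#' @export
tpm <- function(cm) {
  if (!inherits(cm, "count_matrix")) stop_pp("tpm() needs a count_matrix")
  rate <- sweep(cm$counts, 1, cm$gene_lengths / 1000, "/")
  rate_totals <- colSums(rate)
  if (any(rate_totals == 0))
    stop_pp("sample with zero total rate (no expressed gene): ",
            paste(colnames(cm$counts)[rate_totals == 0], collapse = ", "))
  vals <- sweep(rate, 2, rate_totals, "/") * 1e6
  abundance_matrix(vals, "TPM")
}

#' Apply the RPKM detection floor
#'
#' Values strictly below `floor` are set to exactly 0; everything else
#' (including values equal to the floor) is left unchanged. Genes below the
#' floor are treated as not expressed in that sample. The floor is defined
#' on RPKM only; matrices in any other unit are rejected.
#'
#' @param am An [abundance_matrix()] with unit `"RPKM"`.
#' @param floor Detection threshold, default 0.5 RPKM.
#' @return The floored matrix, same unit and dimensions.
#' @export
apply_detection_floor <- function(am, floor = 0.5) {
  require_unit(am, "RPKM")
  if (!is.numeric(floor) || length(floor) != 1 || floor < 0)
    stop_pp("floor must be a single non-negative number")
  vals <- unclass(am)
  attr(vals, "unit") <- NULL
  vals[vals < floor] <- 0
  abundance_matrix(vals, "RPKM")
}
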