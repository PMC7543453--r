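# Readers and writers for every external table the pipeline touches.
# All text formats are UTF-8, tab-delimited with a header row; gene sets use
# the GMT dialect. Validation happens here, at the boundary, so downstream
# code can assume the invariants hold.

#' Gene-level count matrix with gene lengths
#'
#' Non-negative integer read counts (genes x samples) paired with a per-gene
#' transcript length in base pairs. Every gene must have a length entry of
#' at least 1 bp; gene and sample ids must be unique.
#'
#' @param counts Integer-valued matrix, gene ids as row names, sample ids as
#'   column names.
#' @param gene_lengths Named numeric vector of lengths in bp covering (at
#'   least) every gene in `counts`.
#' @return A `count_matrix` object (list with elements `counts`,
#'   `gene_lengths`).
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) stop_pp("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_pp("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop_pp("duplicate gene ids: ",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_pp("duplicate sample ids: ",
            paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                  collapse = ", "))
  if (anyNA(counts)) stop_pp("counts contain missing cells")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_pp("negative or non-integer count for gene '",
            rownames(counts)[bad[1, 1]], "' in sample '",
            colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "double"  # keep exact integers, allow big totals
  if (is.null(names(gene_lengths))) stop_pp("gene_lengths must be named")
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len) > 0)
    stop_pp("genes missing from the length table: ",
            paste(missing_len, collapse = ", "))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths < 1))
    stop_pp("gene lengths must be >= 1 bp")
  storage.mode(gene_lengths) <- "double"
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (lengths %d-%d bp)\n",
              nrow(x$counts), ncol(x$counts),
              min(x$gene_lengths), max(x$gene_lengths)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_pp("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    na.strings = c("NA", ""))
}

#' Read a count matrix and its length table
#'
#' The counts file is a TSV whose header row holds sample ids and whose
#' first column holds gene ids; the lengths file has columns `gene_id` and
#' `length_bp`. Gene symbols are matched case-sensitively after whitespace
#' trimming.
#'
#' @param counts_path,lengths_path Paths to the two TSV files.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_path) {
  tab <- read_tsv_checked(counts_path)
  if (ncol(tab) < 2)
    stop_pp("malformed counts header: need a gene-id column plus >=1 sample")
  gene_ids <- trimws(as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop_pp("non-numeric count values in ", counts_path)
  rownames(m) <- gene_ids

  len <- read_tsv_checked(lengths_path)
  need <- c("gene_id", "length_bp")
  if (!all(need %in% names(len)))
    stop_pp("lengths file must have columns gene_id, length_bp")
  lengths <- len$length_bp
  names(lengths) <- trimws(as.character(len$gene_id))
  if (anyDuplicated(names(lengths)))
    stop_pp("duplicate gene ids in length table")
  count_matrix(m, lengths)
}

#' Write a count matrix to TSV
#'
#' Writes the counts (with a `gene_id` first column) and the length table
#' so that [read_count_matrix()] round-trips the object exactly.
#'
#' @param cm A [count_matrix()].
#' @param counts_path,lengths_path Output paths.
#' @export
write_count_matrix <- function(cm, counts_path, lengths_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  len <- data.frame(gene_id = names(cm$gene_lengths),
                    length_bp = unname(cm$gene_lengths))
  utils::write.table(len, lengths_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, lengths_path))
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `donor_id`, `cell_type`. Sample ids must be
#' unique and each (donor, cell type) pair may appear at most once.
#'
#' @param path Path to the TSV.
#' @return A `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- read_tsv_checked(path)
  sample_sheet(tab)
}

#' @rdname read_sample_sheet
#' @param df Data frame with the three required columns.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "donor_id", "cell_type")
  if (!all(need %in% names(df)))
    stop_pp("sample sheet needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  for (col in need) df[[col]] <- trimws(as.character(df[[col]]))
  if (anyDuplicated(df$sample_id))
    stop_pp("duplicate sample ids in sample sheet: ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]),
                  collapse = ", "))
  key <- paste(df$donor_id, df$cell_type, sep = "\r")
  if (anyDuplicated(key))
    stop_pp("duplicate (donor, cell type) pair in sample sheet")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

# check that a sheet annotates exactly the samples of a count or abundance
# matrix (each appears exactly once)
match_sheet <- function(sheet, sample_ids) {
  missing <- setdiff(sample_ids, sheet$sample_id)
  if (length(missing) > 0)
    stop_pp("samples absent from sample sheet: ",
            paste(missing, collapse = ", "))
  sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
}

#' Read a disease-gene panel
#'
#' TSV with columns `gene_symbol`, `alias` (may be empty, e.g. an SPG locus
#' number for HSP genes) and `disease_groups`, a semicolon-separated
#' non-empty subset of HSP, ALS, SMA, SPASTICITY. A gene may belong to more
#' than one disease group.
#'
#' @param path Path to the panel TSV.
#' @return A `gene_panel` data frame.
#' @export
read_panel <- function(path) {
  tab <- read_tsv_checked(path)
  gene_panel(tab)
}

#' @rdname read_panel
#' @param df Data frame with columns `gene_symbol`, `alias`,
#'   `disease_groups`.
#' @export
gene_panel <- function(df) {
  need <- c("gene_symbol", "alias", "disease_groups")
  if (!all(need %in% names(df)))
    stop_pp("panel needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$gene_symbol <- trimws(as.character(df$gene_symbol))
  df$alias <- trimws(as.character(df$alias))
  df$disease_groups <- trimws(as.character(df$disease_groups))
  if (anyDuplicated(df$gene_symbol))
    stop_pp("duplicate gene symbols in panel: ",
            paste(unique(df$gene_symbol[duplicated(df$gene_symbol)]),
                  collapse = ", "))
  groups <- panel_groups(df)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) == 0)
      stop_pp("panel entry '", df$gene_symbol[i], "' has no disease group")
    unknown <- setdiff(g, disease_group_labels())
    if (length(unknown) > 0)
      stop_pp("unknown disease group '", unknown[1], "' for panel entry '",
              df$gene_symbol[i], "'")
  }
  rownames(df) <- NULL
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' @rdname read_panel
#' @param panel A `gene_panel`.
#' @return `panel_groups`: a named list (gene symbol -> character vector of
#'   disease groups).
#' @export
panel_groups <- function(panel) {
  out <- lapply(strsplit(panel$disease_groups, ";", fixed = TRUE),
                function(g) {
                  g <- trimws(g)
                  g[nzchar(g) & !is.na(g)]
                })
  names(out) <- panel$gene_symbol
  out
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set catalog in GMT format
#'
#' One set per line: `term_id TAB description TAB gene TAB gene ...`.
#' Duplicate term ids and lines with fewer than three fields are rejected;
#' empty lines are skipped.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_catalog`: named list of character gene vectors with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_pp("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_catalog(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop_pp("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- ids
  names(desc) <- ids
  gene_set_catalog(sets, desc)
}

#' @rdname read_gene_sets
#' @param sets Named list of character gene vectors.
#' @param descriptions Optional named character vector of term names.
#' @export
gene_set_catalog <- function(sets, descriptions = NULL) {
  if (anyDuplicated(names(sets)))
    stop_pp("duplicate term ids in gene-set catalog: ",
            paste(unique(names(sets)[duplicated(names(sets))]),
                  collapse = ", "))
  if (any(lengths(sets) == 0))
    stop_pp("empty gene set: ",
            paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_catalog")
}

#' @rdname read_gene_sets
#' @param catalog A `gene_set_catalog`.
#' @export
write_gene_sets <- function(catalog, path) {
  desc <- attr(catalog, "descriptions")
  lines <- vapply(seq_along(catalog), function(i) {
    paste(c(names(catalog)[i], desc[[i]], catalog[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("<gene_set_catalog> %d terms, set sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Read a qPCR plate
#'
#' TSV with columns `gene`, `cell_line`, `replicate`, `ct`; an empty `ct`
#' cell marks a not-detected reaction. Replicates within a
#' (gene, cell line) group must carry distinct indices.
#'
#' @param path Path to the plate TSV.
#' @return A `qpcr_plate` data frame (`ct` is `NA` where not detected).
#' @export
read_qpcr_plate <- function(path) {
  tab <- read_tsv_checked(path)
  qpcr_plate(tab)
}

#' @rdname read_qpcr_plate
#' @param df Data frame with the four plate columns.
#' @export
qpcr_plate <- function(df) {
  need <- c("gene", "cell_line", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop_pp("qPCR plate needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$gene <- trimws(as.character(df$gene))
  df$cell_line <- trimws(as.character(df$cell_line))
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)
  if (any(!is.na(df$ct) & df$ct <= 0))
    stop_pp("CT values must be positive (or empty for not detected)")
  key <- paste(df$gene, df$cell_line, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop_pp("duplicate (gene, cell line, replicate) record in plate")
  class(df) <- c("qpcr_plate", "data.frame")
  df
}

#' Read/write an abundance matrix as TSV
#'
#' The TSV has a `gene_id` first column and one column per sample or cell
#' type. Floats are serialized with 6 significant digits, so write-then-read
#' is bit-stable on already-serialized values.
#'
#' @param path File path.
#' @param unit Unit tag to attach on read.
#' @export
read_abundance <- function(path, unit) {
  tab <- read_tsv_checked(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- trimws(as.character(tab[[1]]))
  abundance_matrix(m, unit)
}

#' @rdname read_abundance
#' @param am An [abundance_matrix()].
#' @export
write_abundance <- function(am, path) {
  vals <- signif(unclass(am), 6)
  df <- data.frame(gene_id = rownames(am), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any tabular result to TSV
#'
#' Generic table writer used by the reporting stage: floats at 6 significant
#' digits, no quoting, no row names.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], signif, 6)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
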