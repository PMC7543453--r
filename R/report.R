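# Orchestration and reporting: replicate aggregation for display tables,
# and the end-to-end run that chains normalize -> classify -> coverage ->
# similarity -> qPCR and writes the report bundle (TSV tables plus a
# machine-readable summary.json).

#' Aggregate replicate measurements per group
#'
#' Applies an optional transform per value (`log10` for, e.g., label-free
#' quantification intensities), then takes the arithmetic mean per group.
#' Missing values are dropped and counted.
#'
#' @param values Named list: group -> numeric vector of replicate values.
#' @param transform `"none"` (default) or `"log10"`.
#' @return Data frame with `group`, `mean`, `n_used`, `n_total`.
#' @examples
#' aggregate_replicates(list(CN = c(10, 100, 1000)), transform = "log10")
#' @export
aggregate_replicates <- function(values, transform = c("none", "log10")) {
  transform <- match.arg(transform)
  if (length(values) == 0 || is.null(names(values)))
    stop_pp("values must be a non-empty named list")
  rows <- lapply(names(values), function(g) {
    v <- values[[g]]
    if (length(v) == 0) stop_pp("group '", g, "' is empty")
    keep <- !is.na(v)
    v <- v[keep]
    if (transform == "log10") {
      if (any(v <= 0))
        stop_pp("log10 of non-positive value in group '", g, "'")
      v <- log10(v)
    }
    data.frame(group = g, mean = mean(v), n_used = length(v),
               n_total = length(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full profiling pipeline and write the report bundle
#'
#' Reads every configured input, executes the configured stages and writes
#' the result tables plus `summary.json`. Identical inputs and
#' configuration give byte-identical outputs. Any stage failure aborts
#' with the stage name in the error.
#'
#' @param config Path to a JSON run configuration, or an equivalent list.
#'   Required fields: `counts`, `lengths`, `samples`, `panel` (paths).
#'   Optional: `gmt`, `reference` (TPM TSV), `qpcr` (plate TSV);
#'   parameters `floor` (0.5), `floor_stage` ("sample"), `min_expr` (3),
#'   `reference_cell_type` ("CN"), `normalize_to` ("covered"),
#'   `background` ("all"), `correction` ("tukey"), `mds_metric`
#'   ("1-spearman"), `mds_k` (3), `housekeeping` (GAPDH, TBP).
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the parsed `summary.json` content.
#' @export
run_profiler <- function(config, outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_pp("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("counts", "lengths", "samples", "panel")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0)
    stop_pp("config missing required inputs: ", paste(miss, collapse = ", "))
  paths <- unlist(config[intersect(names(config),
                                   c(required, "gmt", "reference", "qpcr"))])
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0)
    stop_pp("configured input files not found: ",
            paste(absent, collapse = ", "))

  p <- function(name, default) config[[name]] %||% default
  floor <- p("floor", 0.5)
  min_expr <- p("min_expr", 3)
  ref_ct <- p("reference_cell_type", "CN")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_pp("stage '", name, "' failed: ", conditionMessage(e)))
  }

  cm <- stage("read", read_count_matrix(config$counts, config$lengths))
  sheet <- stage("read", read_sample_sheet(config$samples))
  panel <- stage("read", read_panel(config$panel))

  cls <- stage("classify", run_classification(
    cm, sheet, panel, floor = floor,
    floor_stage = p("floor_stage", "sample")))
  write_abundance(cls$rpkm, out("rpkm_floored.tsv"))
  write_abundance(cls$means, out("cell_type_means.tsv"))
  write_table(cls$classification, out("gene_classification.tsv"))
  sm <- cls$summary
  write_table(data.frame(category = names(sm$counts),
                         count = unname(sm$counts),
                         percent = unname(sm$percentages)),
              out("classification_summary.tsv"))

  summary_json <- list(
    schema_version = "1.0",
    parameters = list(floor = floor,
                      floor_stage = p("floor_stage", "sample"),
                      min_expr = min_expr, reference_cell_type = ref_ct,
                      normalize_to = p("normalize_to", "covered"),
                      background = p("background", "all"),
                      correction = p("correction", "tukey"),
                      mds_metric = p("mds_metric", "1-spearman"),
                      mds_k = p("mds_k", 3)),
    panel_size = sm$panel_size,
    counts = as.list(sm$counts),
    percentages = as.list(sm$percentages),
    per_disease = lapply(sm$per_disease, function(pd)
      list(size = pd$size, counts = as.list(pd$counts),
           percentages = as.list(pd$percentages))))

  if (!is.null(config$gmt)) {
    catalog <- stage("coverage", read_gene_sets(config$gmt))
    cov <- stage("coverage", coverage(
      cls$means, catalog, min_expr = min_expr, reference = ref_ct,
      normalize_to = p("normalize_to", "covered")))
    write_table(cov, out("coverage.tsv"))
    summary_json$n_gene_sets <- length(catalog)
  }

  tp <- stage("normalize", tpm(cm))
  dis <- stage("mds", sample_dissimilarity(
    tp, metric = p("mds_metric", "1-spearman")))
  ord <- stage("mds", classical_mds(dis, k = p("mds_k", 3)))
  write_table(data.frame(sample_id = rownames(ord$points), ord$points,
                         check.names = FALSE),
              out("mds_coordinates.tsv"))

  if (!is.null(config$reference)) {
    ref <- stage("similarity", read_abundance(config$reference, "TPM"))
    sim <- stage("similarity", spearman_similarity(tp, ref))
    sim <- stage("similarity", group_significance(
      sim, sheet, background = p("background", "all")))
    write_table(data.frame(sample_id = rownames(sim$rho), sim$rho,
                           check.names = FALSE),
                out("similarity_rho.tsv"))
    write_table(sim$group_tests, out("similarity_tests.tsv"))
    best <- sim$group_tests[order(sim$group_tests$group,
                                  -sim$group_tests$neg_log10_p), ]
    best <- best[!duplicated(best$group), c("group", "reference",
                                            "neg_log10_p")]
    summary_json$best_reference_per_group <- lapply(
      split(best, best$group),
      function(r) list(reference = r$reference,
                       neg_log10_p = r$neg_log10_p))
  }

  if (!is.null(config$qpcr)) {
    plate <- stage("qpcr", read_qpcr_plate(config$qpcr))
    hk <- p("housekeeping", c("GAPDH", "TBP"))
    dct <- stage("qpcr", delta_ct(plate, housekeeping = hk))
    rel <- stage("qpcr", relative_expression(dct))
    write_table(rel, out("qpcr_relative.tsv"))
    an <- stage("qpcr", anova_by_gene(plate, housekeeping = hk,
                                      method = p("correction", "tukey")))
    an_df <- do.call(rbind, lapply(names(an), function(g)
      data.frame(gene = g, f = an[[g]]$f, p = an[[g]]$p,
                 an[[g]]$pairwise, stringsAsFactors = FALSE)))
    write_table(an_df, out("qpcr_anova.tsv"))
    summary_json$n_qpcr_genes <- length(an)
  }

  json <- jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = 6,
                           pretty = TRUE, na = "null")
  writeLines(json, out("summary.json"))
  invisible(summary_json)
}
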