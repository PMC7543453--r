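# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth. Counts are negative binomial (mean mu, variance
# mu + alpha * mu^2); each gene's planted cell type gets a fold_change
# higher mean, NOT_DETECTABLE genes get identically zero counts. The
# defaults emulate the study design the package targets: a gene panel
# profiled in 5 cell types x 2 donors of bulk RNA-seq, a correlated
# per-cell-type reference profile, gene-set annotations and triplicate
# qPCR plates.

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param cell_types Cell types (default the canonical five).
#' @param donors Donors per cell type (default 2).
#' @param planted_category Character vector (length `n_genes`, optionally
#'   named by gene id) of planted winning cell types or
#'   `"NOT_DETECTABLE"`. Default: round-robin over the cell types.
#' @param base_mean Baseline negative binomial mean in counts (default 50).
#' @param fold_change Winner-vs-others expression fold (default 10; must
#'   be > 1).
#' @param nb_dispersion NB dispersion alpha in `var = mu + alpha * mu^2`
#'   (default 0.1; 0 degenerates to Poisson).
#' @param baseline_sdlog SD (log2 scale) of the per-gene baseline
#'   abundance factor shared across cell types (default 0.8).
#' @param library_size Expected total counts per sample (default 1e6).
#' @param seed RNG seed; the whole module is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 168,
                              cell_types = canonical_cell_types(),
                              donors = 2, planted_category = NULL,
                              base_mean = 50, fold_change = 10,
                              nb_dispersion = 0.1, baseline_sdlog = 0.8,
                              library_size = 1e6, seed = 1) {
  if (n_genes < 1) stop_pp("need at least one gene")
  if (fold_change <= 1) stop_pp("fold_change must be > 1")
  if (library_size <= 0) stop_pp("library_size must be > 0")
  if (nb_dispersion < 0) stop_pp("nb_dispersion must be >= 0")
  if (is.null(planted_category))
    planted_category <- rep_len(cell_types, n_genes)
  if (length(planted_category) != n_genes)
    stop_pp("planted_category must have one entry per gene")
  bad <- setdiff(planted_category, c(cell_types, NOT_DETECTABLE))
  if (length(bad) > 0)
    stop_pp("planted categories outside cell_types: ",
            paste(unique(bad), collapse = ", "))
  if (all(planted_category == NOT_DETECTABLE))
    stop_pp("at least one gene must be detectable")
  if (is.null(names(planted_category)))
    names(planted_category) <- sprintf("gene%03d", seq_len(n_genes))
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 donors = donors, planted_category = planted_category,
                 base_mean = base_mean, fold_change = fold_change,
                 nb_dispersion = nb_dispersion,
                 baseline_sdlog = baseline_sdlog,
                 library_size = library_size, seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic generative means: seeds the RNG, draws gene lengths
# (log-uniform 500-10000 bp so RPKM and TPM differ nontrivially) and a
# shared per-gene baseline factor, and builds the genes x cell-types mean
# matrix scaled so each sample's expected total equals library_size.
# Callers that need more randomness keep drawing from the stream.
sim_means <- function(cfg) {
  set.seed(cfg$seed)
  genes <- names(cfg$planted_category)
  n <- cfg$n_genes
  lengths <- stats::setNames(
    round(exp(stats::runif(n, log(500), log(10000)))), genes)
  baseline <- 2^stats::rnorm(n, 0, cfg$baseline_sdlog)
  mu <- matrix(cfg$base_mean * baseline, n, length(cfg$cell_types),
               dimnames = list(genes, cfg$cell_types))
  for (ct in cfg$cell_types)
    mu[cfg$planted_category == ct, ct] <-
      mu[cfg$planted_category == ct, ct] * cfg$fold_change
  mu[cfg$planted_category == NOT_DETECTABLE, ] <- 0
  mu <- sweep(mu, 2, colSums(mu) / cfg$library_size, "/")
  list(gene_lengths = lengths, mu = mu)
}

#' Simulate a bulk count matrix with planted cell-type winners
#'
#' Draws negative binomial counts for `donors` samples of each cell type.
#' A gene's planted cell type has `fold_change`-times the baseline mean;
#' `NOT_DETECTABLE` genes have mean 0 (hence identically zero counts).
#' Column means are scaled so each sample's expected library size equals
#' `library_size`. Identical seeds give bit-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return List with `counts` (a [count_matrix()]), `sheet` (a
#'   [sample_sheet()]) and `truth` (list with `planted_category` and the
#'   config).
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop_pp("cfg must be a simulation_config")
  gen <- sim_means(cfg)
  samples <- expand.grid(donor = seq_len(cfg$donors),
                         cell_type = cfg$cell_types,
                         stringsAsFactors = FALSE)
  sample_ids <- paste0(samples$cell_type, "_D", samples$donor)
  n <- cfg$n_genes
  counts <- matrix(0, n, nrow(samples),
                   dimnames = list(rownames(gen$mu), sample_ids))
  for (j in seq_len(nrow(samples))) {
    m <- gen$mu[, samples$cell_type[j]]
    counts[, j] <- if (cfg$nb_dispersion == 0) stats::rpois(n, m)
                   else stats::rnbinom(n, size = 1 / cfg$nb_dispersion,
                                       mu = m)
  }
  sheet <- sample_sheet(data.frame(
    sample_id = sample_ids, donor_id = paste0("D", samples$donor),
    cell_type = samples$cell_type, stringsAsFactors = FALSE))
  list(counts = count_matrix(counts, gen$gene_lengths), sheet = sheet,
       truth = list(planted_category = cfg$planted_category, config = cfg))
}

#' Simulate a per-cell-type reference expression profile
#'
#' Builds one reference TPM column per cell type whose per-gene latent
#' profile correlates (Gaussian latent correlation `rho`) with the bulk
#' generative log-means of the same cell type — emulating an externally
#' averaged single-cell reference of matched cell populations. At `rho = 1`
#' the reference preserves the bulk mean ranks exactly.
#'
#' @param cfg The [simulation_config()] used for the matching bulk run.
#' @param rho Latent correlation with the bulk generative means, in
#'   \[-1, 1\] (default 0.95).
#' @return An [abundance_matrix()] with unit `"TPM"`, one column per cell
#'   type (columns named `ref_<cell type>`).
#' @export
simulate_reference <- function(cfg, rho = 0.95) {
  if (!inherits(cfg, "simulation_config"))
    stop_pp("cfg must be a simulation_config")
  if (rho < -1 || rho > 1) stop_pp("rho must be within [-1, 1]")
  gen <- sim_means(cfg)
  set.seed(cfg$seed + 1L)
  lmu <- log2(gen$mu + 1)
  latent <- apply(lmu, 2, function(col) {
    z <- if (stats::sd(col) > 0) (col - mean(col)) / stats::sd(col)
         else col * 0
    rho * z + sqrt(1 - rho^2) * stats::rnorm(length(col))
  })
  vals <- 2^(2 * latent)  # positive, rank-preserving in the latent
  vals <- sweep(vals, 2, colSums(vals) / 1e6, "/")
  dimnames(vals) <- list(rownames(gen$mu), paste0("ref_", cfg$cell_types))
  abundance_matrix(vals, "TPM")
}

#' Simulate a gene-set catalog over the planted genes
#'
#' Samples `n_terms` sets of `set_size` genes. With `enrich_cell_type`
#' set, a fraction `enrichment` of each set is drawn from that cell type's
#' planted winner genes (so coverage is highest in that cell type).
#'
#' @param cfg A [simulation_config()].
#' @param n_terms,set_size Catalog shape (default 8 sets of 15 genes).
#' @param enrich_cell_type Optional cell type whose planted winners are
#'   over-sampled.
#' @param enrichment Fraction of each set drawn from the enriched winners
#'   (default 0.8).
#' @return A [gene_set_catalog()].
#' @export
simulate_go_catalog <- function(cfg, n_terms = 8, set_size = 15,
                                enrich_cell_type = NULL, enrichment = 0.8) {
  if (!inherits(cfg, "simulation_config"))
    stop_pp("cfg must be a simulation_config")
  if (set_size > cfg$n_genes)
    stop_pp("set_size exceeds the number of simulated genes")
  set.seed(cfg$seed + 2L)
  genes <- names(cfg$planted_category)
  sets <- lapply(seq_len(n_terms), function(i) {
    if (is.null(enrich_cell_type)) return(sample(genes, set_size))
    winners <- genes[cfg$planted_category == enrich_cell_type]
    n_win <- min(length(winners), round(enrichment * set_size))
    c(sample(winners, n_win),
      sample(setdiff(genes, winners), set_size - n_win))
  })
  names(sets) <- sprintf("TERM%04d", seq_len(n_terms))
  gene_set_catalog(sets, stats::setNames(
    rep("synthetic gene set", n_terms), names(sets)))
}

#' Simulate a triplicate qPCR plate from the planted expression pattern
#'
#' CT model: `CT = base_ct - log2(relative abundance) + N(0, noise_sd)`,
#' with the planted winner cell line at `fold_change` relative abundance
#' and all others at 1. Housekeeping genes are flat across lines.
#' `NOT_DETECTABLE` genes yield empty (not-detected) CTs everywhere. With
#' `noise_sd = 0` the delta-delta-CT analysis inverts the model exactly.
#'
#' @param cfg A [simulation_config()].
#' @param genes Target genes to put on the plate (default the first 8).
#' @param replicates Technical replicates (default 3).
#' @param noise_sd Replicate noise in cycles (default 0.15).
#' @param base_ct Baseline cycle threshold for unit abundance (default 30).
#' @param housekeeping Named numeric vector of housekeeping CT levels
#'   (default `c(GAPDH = 20, TBP = 22)`).
#' @return List with `plate` (a [qpcr_plate()]) and `expected_relative`
#'   (genes x cell lines matrix of the planted ratios, max = 1 per gene).
#' @export
simulate_qpcr <- function(cfg, genes = NULL, replicates = 3,
                          noise_sd = 0.15, base_ct = 30,
                          housekeeping = c(GAPDH = 20, TBP = 22)) {
  if (!inherits(cfg, "simulation_config"))
    stop_pp("cfg must be a simulation_config")
  all_genes <- names(cfg$planted_category)
  if (is.null(genes)) genes <- utils::head(all_genes, 8)
  if (!all(genes %in% all_genes))
    stop_pp("unknown genes requested for the qPCR plate")
  set.seed(cfg$seed + 3L)
  lines <- cfg$cell_types
  abundance <- matrix(1, length(genes), length(lines),
                      dimnames = list(genes, lines))
  for (i in seq_along(genes)) {
    cat_i <- cfg$planted_category[[genes[i]]]
    if (cat_i == NOT_DETECTABLE) abundance[i, ] <- NA_real_
    else abundance[i, cat_i] <- cfg$fold_change
  }
  rows <- list()
  for (g in c(genes, names(housekeeping))) {
    for (cl in lines) {
      if (g %in% names(housekeeping)) {
        mu_ct <- housekeeping[[g]]
      } else if (anyNA(abundance[g, ])) {
        mu_ct <- NA_real_
      } else {
        mu_ct <- base_ct - log2(abundance[g, cl])
      }
      ct <- if (is.na(mu_ct)) rep(NA_real_, replicates)
            else mu_ct + stats::rnorm(replicates, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, cell_line = cl, replicate = seq_len(replicates), ct = ct,
        stringsAsFactors = FALSE)
    }
  }
  plate <- qpcr_plate(do.call(rbind, rows))
  expected <- sweep(abundance, 1, apply(abundance, 1, max), "/")
  list(plate = plate, expected_relative = expected)
}

#' The canonical 168-gene synthetic fixture
#'
#' A synthetic gene panel reproducing the study design's published
#' bookkeeping: 168 genes split into disease groups of 65 HSP, 30 ALS,
#' 18 SMA and 55 SPASTICITY entries, with planted best-expressing cell
#' types distributed as 50 CN, 41 F, 26 LB, 22 iPSC, 14 PBMC and 15
#' NOT_DETECTABLE overall (HSP: 26 CN / 2 iPSC / 19 F / 10 LB / 3 PBMC /
#' 5 ND; ALS: 9/5/5/6/3/2; SMA: 5/2/3/4/1/3; SPASTICITY the remainder).
#' Gene symbols are synthetic (`HSP001`, ...); HSP entries carry synthetic
#' SPG-style aliases.
#'
#' @param seed RNG seed for the matching [simulation_config()].
#' @param ... Further arguments passed to [simulation_config()]
#'   (`fold_change`, `nb_dispersion`, ...).
#' @return List with `panel` (a [gene_panel()]), `planted` (named category
#'   vector) and `config` (a [simulation_config()] planting it).
#' @export
canonical_fixture <- function(seed = 1, ...) {
  dist <- list(
    HSP        = c(CN = 26, iPSC = 2, F = 19, LB = 10, PBMC = 3, ND = 5),
    ALS        = c(CN = 9, iPSC = 5, F = 5, LB = 6, PBMC = 3, ND = 2),
    SMA        = c(CN = 5, iPSC = 2, F = 3, LB = 4, PBMC = 1, ND = 3),
    SPASTICITY = c(CN = 10, iPSC = 13, F = 14, LB = 6, PBMC = 7, ND = 5))
  rows <- list()
  planted <- character(0)
  for (dg in names(dist)) {
    cats <- rep(names(dist[[dg]]), dist[[dg]])
    cats[cats == "ND"] <- NOT_DETECTABLE
    syms <- sprintf("%s%03d", dg, seq_along(cats))
    alias <- if (dg == "HSP") sprintf("SPG%d", seq_along(cats))
             else rep(NA_character_, length(cats))
    rows[[dg]] <- data.frame(gene_symbol = syms, alias = alias,
                             disease_groups = dg, stringsAsFactors = FALSE)
    planted <- c(planted, stats::setNames(cats, syms))
  }
  panel <- gene_panel(do.call(rbind, rows))
  cfg <- simulation_config(n_genes = length(planted),
                           planted_category = planted, seed = seed, ...)
  list(panel = panel, planted = planted, config = cfg)
}
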