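#' Simulate a bulk expression cohort with known ground truth
#'
#' Generates a normalized (log2-scale, Gaussian) genes x samples matrix
#' with a control class and one or more case classes, planted signal
#' genes, optional "null" cases (patients with no molecular signal, the
#' low-perturbation outliers), and optional globally perturbed controls
#' (high-perturbation outliers shifted on a random gene subset). All
#' randomness flows from `seed` through named substreams, so the same
#' seed always yields a bit-identical dataset.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_controls Number of control samples (default 15).
#' @param n_cases Cases per class; a named integer vector allows several
#'   case classes (default `c(disease = 15)`; a bare number gets class
#'   `"disease"`).
#' @param control_class Control class label (default `"healthy"`).
#' @param baseline_range Range of per-gene baseline means, log2 units
#'   (default `c(4, 12)`).
#' @param sd_range Range of per-gene noise SDs, log2 units (default
#'   `c(0.25, 0.75)`).
#' @param n_signal_genes Genes shifted in (non-null) cases (default 20).
#' @param effect_size Log2 mean shift of signal genes in cases (default 1);
#'   half the signal genes shift up, half down.
#' @param n_null_cases Cases per class carrying no signal (default 0).
#' @param n_outlier_controls Controls perturbed like a hidden condition
#'   (default 1).
#' @param outlier_shift Outlier shift in units of the per-gene SD (default
#'   4).
#' @param outlier_gene_fraction Fraction of genes each outlier control is
#'   perturbed on (default 0.25), drawn independently per outlier.
#' @param seed Integer seed.
#' @return A list of class `"mdp_sim"`: `expr`, `pheno`, and `truth`
#'   (signal gene ids, outlier ids with direction, null-case ids, the
#'   parameters, the seed).
#' @examples
#' sim <- simulate_bulk(seed = 42)
#' str(sim$truth[c("signal_genes", "outlier_samples")])
#' @export
simulate_bulk <- function(n_genes = 200L, n_controls = 15L,
                          n_cases = c(disease = 15L),
                          control_class = "healthy",
                          baseline_range = c(4, 12), sd_range = c(0.25, 0.75),
                          n_signal_genes = 20L, effect_size = 1,
                          n_null_cases = 0L, n_outlier_controls = 1L,
                          outlier_shift = 4, outlier_gene_fraction = 0.25,
                          seed = 1L) {
  if (is.null(names(n_cases))) names(n_cases) <- rep("disease", length(n_cases))
  stopifnot(n_genes >= 1L, n_controls >= 2L, all(n_cases >= 2L),
            is.finite(effect_size), is.finite(outlier_shift),
            outlier_gene_fraction > 0, outlier_gene_fraction <= 1)
  if (n_signal_genes > n_genes)
    .stopf("n_signal_genes (%d) exceeds n_genes (%d)", n_signal_genes, n_genes)
  if (n_outlier_controls > n_controls)
    .stopf("n_outlier_controls exceeds n_controls")
  if (any(n_null_cases > n_cases))
    .stopf("n_null_cases exceeds n_cases")

  genes <- sprintf("G%04d", seq_len(n_genes))
  ctrl_ids <- sprintf("%s_%02d", control_class, seq_len(n_controls))
  case_ids <- unlist(lapply(seq_along(n_cases), function(k)
    sprintf("%s_%02d", names(n_cases)[k], seq_len(n_cases[k]))), use.names = FALSE)
  case_cls <- rep(names(n_cases), n_cases)
  samples <- c(ctrl_ids, case_ids)
  pheno <- data.frame(Sample = samples,
                      Class = c(rep(control_class, n_controls), case_cls),
                      stringsAsFactors = FALSE)

  # structure substream: baselines, SDs, which genes/samples carry what
  set.seed(.substream(seed, 1L))
  baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
  gene_sd <- stats::runif(n_genes, sd_range[1L], sd_range[2L])
  signal_idx <- sort(sample.int(n_genes, n_signal_genes))
  signal_sign <- rep_len(c(1, -1), n_signal_genes)
  outlier_ids <- if (n_outlier_controls > 0L)
    sample(ctrl_ids, n_outlier_controls) else character()
  null_ids <- unlist(lapply(seq_along(n_cases), function(k) {
    members <- case_ids[case_cls == names(n_cases)[k]]
    if (n_null_cases[[min(k, length(n_null_cases))]] > 0L)
      sample(members, n_null_cases[[min(k, length(n_null_cases))]])
    else character()
  }), use.names = FALSE)
  n_outlier_genes <- max(1L, floor(outlier_gene_fraction * n_genes))
  outlier_gene_idx <- lapply(seq_len(n_outlier_controls), function(i)
    sort(sample.int(n_genes, n_outlier_genes)))
  names(outlier_gene_idx) <- outlier_ids

  # noise substream
  set.seed(.substream(seed, 2L))
  expr <- baseline +
    matrix(stats::rnorm(n_genes * length(samples), sd = gene_sd),
           nrow = n_genes, ncol = length(samples))
  dimnames(expr) <- list(genes, samples)

  signal_cases <- setdiff(case_ids, null_ids)
  if (length(signal_cases) > 0L && n_signal_genes > 0L)
    expr[signal_idx, signal_cases] <-
      expr[signal_idx, signal_cases] + signal_sign * effect_size
  for (oid in outlier_ids) {
    gi <- outlier_gene_idx[[oid]]
    expr[gi, oid] <- expr[gi, oid] + outlier_shift * gene_sd[gi]
  }

  structure(list(
    expr = expr, pheno = pheno,
    truth = list(signal_genes = genes[signal_idx],
                 signal_signs = stats::setNames(signal_sign, genes[signal_idx]),
                 outlier_samples = outlier_ids,
                 outlier_direction = stats::setNames(
                   rep("high", length(outlier_ids)), outlier_ids),
                 outlier_genes = lapply(outlier_gene_idx, function(i) genes[i]),
                 null_cases = null_ids,
                 control_class = control_class, seed = as.integer(seed),
                 params = list(n_genes = n_genes, n_controls = n_controls,
                               n_cases = as.list(n_cases),
                               baseline_range = baseline_range,
                               sd_range = sd_range,
                               n_signal_genes = n_signal_genes,
                               effect_size = effect_size,
                               n_null_cases = n_null_cases,
                               n_outlier_controls = n_outlier_controls,
                               outlier_shift = outlier_shift,
                               outlier_gene_fraction = outlier_gene_fraction)),
    type = "bulk"), class = "mdp_sim")
}

#' Simulate a virus-inclusive single-cell dataset with known ground truth
#'
#' Generates a genes x cells count matrix (Poisson draws around log-normal
#' per-gene rates, with optional uniform dropout), uninfected reference
#' cells, and infected cells carrying a latent perturbation state. Signal
#' genes are shifted in proportion to each cell's latent state, and the
#' per-cell viral load (VL) is drawn log-normally with a correlation to
#' the latent state controlled by `vl_perturbation_coupling` — coupling
#' below 1 reproduces the observation that viral load alone does not
#' track molecular perturbation. Uninfected cells carry VL = 0.
#'
#' @param n_genes Number of genes before filtering (default 500).
#' @param n_uninfected,n_infected Cell numbers (defaults 80 and 160).
#' @param baseline_log2_range Range of per-gene log2 mean rates (default
#'   `c(1, 9)`).
#' @param sd_range Per-gene biological noise SD, log2 units (default
#'   `c(0.4, 0.8)`).
#' @param n_signal_genes Perturbation-responsive genes (default 100),
#'   drawn from the top 30% of genes by baseline rate so they survive
#'   mean-expression filtering.
#' @param effect_size Maximal log2 shift of signal genes (default 3),
#'   scaled per cell by its latent state; half the genes respond up, half
#'   down.
#' @param zero_inflation_prob Probability that any entry is zeroed by
#'   dropout, on top of sampling zeros (default 0.02).
#' @param vl_log10_mean,vl_log10_sd Log10-scale location and spread of the
#'   infected cells' viral load (defaults 3 and 0.8, centering VL on the
#'   conventional 10^3 cutoff).
#' @param vl_perturbation_coupling Correlation in \[0, 1\] between the
#'   latent perturbation state and log-viral-load (default 0.4).
#' @param seed Integer seed.
#' @return A list of class `"mdp_sim"`: `expr` (counts), `pheno`
#'   (`Class` = `"uninfected"`/`"infected"`), `meta` (`Cell`, `VL`,
#'   `Status`), and `truth` (signal genes, per-cell latent state and VL,
#'   parameters, seed).
#' @export
simulate_singlecell <- function(n_genes = 500L, n_uninfected = 80L,
                                n_infected = 160L,
                                baseline_log2_range = c(1, 9),
                                sd_range = c(0.4, 0.8),
                                n_signal_genes = 100L, effect_size = 3,
                                zero_inflation_prob = 0.02,
                                vl_log10_mean = 3, vl_log10_sd = 0.8,
                                vl_perturbation_coupling = 0.4,
                                seed = 1L) {
  stopifnot(n_genes >= 2L, n_uninfected >= 2L, n_infected >= 2L,
            zero_inflation_prob >= 0, zero_inflation_prob < 1,
            vl_perturbation_coupling >= 0, vl_perturbation_coupling <= 1)
  if (n_signal_genes > n_genes)
    .stopf("n_signal_genes (%d) exceeds n_genes (%d)", n_signal_genes, n_genes)

  genes <- sprintf("G%04d", seq_len(n_genes))
  uninf <- sprintf("uninfected_%03d", seq_len(n_uninfected))
  inf <- sprintf("infected_%03d", seq_len(n_infected))
  cells <- c(uninf, inf)
  pheno <- data.frame(Sample = cells,
                      Class = rep(c("uninfected", "infected"),
                                  c(n_uninfected, n_infected)),
                      stringsAsFactors = FALSE)

  # structure substream
  set.seed(.substream(seed, 1L))
  mu <- stats::runif(n_genes, baseline_log2_range[1L], baseline_log2_range[2L])
  gene_sd <- stats::runif(n_genes, sd_range[1L], sd_range[2L])
  top_pool <- order(-mu)[seq_len(max(n_signal_genes, floor(0.3 * n_genes)))]
  signal_idx <- sort(sample(top_pool, n_signal_genes))
  signal_sign <- rep_len(c(1, -1), n_signal_genes)
  latent_raw <- stats::rnorm(n_infected)          # latent perturbation state
  latent <- pmax(latent_raw, 0)                   # only some cells respond
  rho <- vl_perturbation_coupling
  vl_noise <- stats::rnorm(n_infected)
  vl <- round(10^(vl_log10_mean +
                  vl_log10_sd * (rho * latent_raw + sqrt(1 - rho^2) * vl_noise)))

  # noise substream: expression rates, Poisson sampling, dropout
  set.seed(.substream(seed, 2L))
  logrates <- mu + matrix(stats::rnorm(n_genes * length(cells), sd = gene_sd),
                          nrow = n_genes, ncol = length(cells))
  shift <- outer(signal_sign * effect_size, latent)   # signal genes x infected
  logrates[signal_idx, n_uninfected + seq_len(n_infected)] <-
    logrates[signal_idx, n_uninfected + seq_len(n_infected)] + shift
  counts <- matrix(stats::rpois(length(logrates), lambda = 2^logrates),
                   nrow = n_genes, ncol = length(cells))
  if (zero_inflation_prob > 0)
    counts[stats::runif(length(counts)) < zero_inflation_prob] <- 0L
  dimnames(counts) <- list(genes, cells)

  structure(list(
    expr = counts, pheno = pheno,
    meta = data.frame(Cell = cells,
                      VL = c(rep(0, n_uninfected), vl),
                      Status = pheno$Class, stringsAsFactors = FALSE),
    truth = list(signal_genes = genes[signal_idx],
                 signal_signs = stats::setNames(signal_sign, genes[signal_idx]),
                 latent = stats::setNames(latent, inf),
                 vl = stats::setNames(vl, inf),
                 infected = inf, uninfected = uninf,
                 seed = as.integer(seed),
                 params = list(n_genes = n_genes, n_uninfected = n_uninfected,
                               n_infected = n_infected,
                               baseline_log2_range = baseline_log2_range,
                               sd_range = sd_range,
                               n_signal_genes = n_signal_genes,
                               effect_size = effect_size,
                               zero_inflation_prob = zero_inflation_prob,
                               vl_log10_mean = vl_log10_mean,
                               vl_log10_sd = vl_log10_sd,
                               vl_perturbation_coupling = vl_perturbation_coupling)),
    type = "singlecell"), class = "mdp_sim")
}

#' Simulate one of the two study-like presets
#'
#' `"outlier-cohort"`: a bulk cohort shaped like the heterogeneity case
#' study — 1000 genes, 12 controls of which one is a hidden-condition
#' outlier, 20 cases of which two carry no signal, 150 signal genes at a
#' 1.1 log2 effect.
#' `"viral-singlecell"`: the single-cell generator at its defaults —
#' infected cells whose perturbation is only partially coupled
#' (correlation 0.4) to their viral load.
#'
#' @param preset `"outlier-cohort"` or `"viral-singlecell"`.
#' @param seed Integer seed.
#' @return An `"mdp_sim"` dataset; see [simulate_bulk()] /
#'   [simulate_singlecell()].
#' @export
simulate_preset <- function(preset = c("outlier-cohort", "viral-singlecell"),
                            seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "outlier-cohort") {
    simulate_bulk(n_genes = 1000L, n_controls = 12L, n_cases = c(disease = 20L),
                  sd_range = c(0.2, 0.6), n_signal_genes = 150L,
                  effect_size = 1.1, n_null_cases = 2L,
                  n_outlier_controls = 1L, outlier_shift = 4,
                  outlier_gene_fraction = 0.25, seed = seed)
  } else {
    simulate_singlecell(seed = seed)
  }
}

#' @export
print.mdp_sim <- function(x, ...) {
  cat(sprintf("Simulated %s dataset: %d genes x %d samples (seed %d)\n",
              x$type, nrow(x$expr), ncol(x$expr), x$truth$seed))
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$pheno$Class)),
                                  table(x$pheno$Class)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix and phenotype table in the same TSV
#' formats [read_expression()] and [read_phenotype()] read, a cell
#' metadata table for single-cell datasets, and the ground truth as JSON.
#'
#' @param sim An `"mdp_sim"` dataset.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "mdp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(expr = file.path(dir, "expression.tsv"),
             pheno = file.path(dir, "phenotype.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, files[["expr"]])
  utils::write.table(sim$pheno, files[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sim$meta)) {
    files[["meta"]] <- file.path(dir, "cell_metadata.tsv")
    utils::write.table(sim$meta, files[["meta"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(sim$truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
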