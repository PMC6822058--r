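#' Per-gene center and scale from the control samples
#'
#' Estimates, for every gene, a centrality (median or mean) and a dispersion
#' (MAD or SD) over the control samples only. These are the parameters of
#' the modified z-score transform. Genes whose scale is exactly zero are
#' flagged as degenerate; they carry no dispersion information and are
#' excluded from z-scoring and perturbed-gene ranking downstream.
#'
#' @param expr Numeric genes x samples matrix.
#' @param control_ids Character vector of control sample ids (>= 2).
#' @param control An [mdp_control()] list.
#' @return A `data.frame` with columns `Gene`, `Center`, `Scale`,
#'   `Degenerate`, one row per gene in matrix order.
#' @export
estimate_gene_stats <- function(expr, control_ids, control = mdp_control()) {
  .check_expr(expr)
  if (!all(control_ids %in% colnames(expr)))
    .stopf("control id(s) not in matrix: %s",
           paste(setdiff(control_ids, colnames(expr)), collapse = ", "))
  if (length(control_ids) < 2L)
    .stopf("at least 2 control samples are required to estimate gene scales (got %d)",
           length(control_ids))
  sub <- expr[, control_ids, drop = FALSE]
  ctr <- if (control$center == "median") {
    apply(sub, 1L, stats::median)
  } else {
    rowMeans(sub)
  }
  scl <- if (control$scale == "mad") {
    control$mad_constant * apply(abs(sub - ctr), 1L, stats::median)
  } else {
    apply(sub, 1L, stats::sd)
  }
  data.frame(Gene = rownames(expr), Center = unname(ctr), Scale = unname(scl),
             Degenerate = scl == 0, stringsAsFactors = FALSE)
}

#' Thresholded absolute modified z-score matrix
#'
#' Transforms every expression value into its absolute standardized
#' deviation from the control reference, `|x - center| / scale`, and zeroes
#' entries below `z_cutoff` — the surviving values are the deviations large
#' enough to count as perturbation. Degenerate genes (zero scale) yield a
#' row of zeros; their count is reported via a message.
#'
#' @param expr Numeric genes x samples matrix.
#' @param stats Gene statistics from [estimate_gene_stats()], covering every
#'   gene of `expr`.
#' @param control An [mdp_control()] list (supplies `z_cutoff`).
#' @return A genes x samples matrix in which every entry is either 0 or
#'   `>= z_cutoff`, with attributes `z_cutoff` and `n_degenerate`.
#' @export
compute_z <- function(expr, stats, control = mdp_control()) {
  .check_expr(expr)
  idx <- match(rownames(expr), stats$Gene)
  if (anyNA(idx))
    .stopf("gene statistics missing for %d gene(s), e.g. '%s'",
           sum(is.na(idx)), rownames(expr)[is.na(idx)][1L])
  ctr <- stats$Center[idx]
  scl <- stats$Scale[idx]
  degen <- stats$Degenerate[idx]
  scl_safe <- ifelse(degen, 1, scl)   # avoid 0/0; rows zeroed below
  z <- abs(expr - ctr) / scl_safe     # per-row recycling down columns
  z[degen, ] <- 0
  z[z < control$z_cutoff] <- 0
  if (any(degen))
    message(sprintf("compute_z: %d degenerate gene(s) (zero scale) set to 0", sum(degen)))
  attr(z, "z_cutoff") <- control$z_cutoff
  attr(z, "n_degenerate") <- sum(degen)
  z
}

#' Rank genes by perturbation and keep the top fraction
#'
#' Genes are ranked by their mean thresholded |z| across a ranking group of
#' samples (by default all non-control samples), descending, with ties
#' broken by input gene order. The top `max(1, floor(fraction * G))` genes
#' form the "perturbed genes" universe. Degenerate genes never enter the
#' list.
#'
#' @param z Thresholded z matrix from [compute_z()].
#' @param ranking_ids Sample ids defining the ranking group (non-empty).
#' @param control An [mdp_control()] list (supplies `perturbed_fraction`).
#' @param degenerate Optional logical vector (per gene, matrix order)
#'   marking genes to exclude from ranking.
#' @return A `data.frame` with columns `Gene`, `RankStat`, `Rank`, ordered
#'   by decreasing `RankStat`.
#' @export
rank_perturbed_genes <- function(z, ranking_ids, control = mdp_control(),
                                 degenerate = NULL) {
  if (length(ranking_ids) == 0L)
    .stopf("ranking group is empty; perturbed genes need >= 1 ranking sample")
  if (!all(ranking_ids %in% colnames(z)))
    .stopf("ranking id(s) not in z matrix: %s",
           paste(setdiff(ranking_ids, colnames(z)), collapse = ", "))
  stat <- rowMeans(z[, ranking_ids, drop = FALSE])
  G <- nrow(z)
  n_top <- max(1L, floor(control$perturbed_fraction * G))
  eligible <- if (is.null(degenerate)) rep(TRUE, G) else !degenerate
  ord <- order(-stat)                 # stable: ties keep input gene order
  ord <- ord[eligible[ord]]
  if (length(ord) < n_top) {
    .warnf("only %d non-degenerate gene(s) available for a perturbed set of %d",
           length(ord), n_top)
    n_top <- max(1L, length(ord))
  }
  top <- ord[seq_len(n_top)]
  data.frame(Gene = rownames(z)[top], RankStat = unname(stat[top]),
             Rank = seq_len(n_top), stringsAsFactors = FALSE)
}

#' Per-sample perturbation scores over a gene universe
#'
#' The MDP score of a sample is the mean of its thresholded absolute
#' modified z-scores over the chosen gene universe.
#'
#' @param z Thresholded z matrix from [compute_z()].
#' @param genes Character vector of gene ids defining the universe, or
#'   `NULL` for all genes. Genes absent from the matrix are dropped
#'   (intersection semantics); the size actually used is reported.
#' @param universe Name recorded for the universe (e.g. `"allgenes"`).
#' @return A `data.frame` with columns `Sample`, `Score`, `Universe`, plus
#'   attribute `n_genes` (universe size actually used).
#' @export
score_samples <- function(z, genes = NULL, universe = "allgenes") {
  if (is.null(genes)) {
    used <- rownames(z)
  } else {
    used <- intersect(genes, rownames(z))
    if (length(used) == 0L)
      .stopf("gene universe '%s' shares no genes with the matrix", universe)
  }
  sc <- colMeans(z[used, , drop = FALSE])
  structure(data.frame(Sample = colnames(z), Score = unname(sc),
                       Universe = universe, stringsAsFactors = FALSE),
            n_genes = length(used))
}

#' Score every gene set of a GMT collection
#'
#' @param z Thresholded z matrix from [compute_z()].
#' @param gene_sets A `"gmt"` collection from [read_gmt()] (or any named
#'   list of gene-id vectors).
#' @param min_size Minimum overlap with the matrix genes for a set to be
#'   scored (default 5); smaller sets are skipped with a warning.
#' @return A named list of score data.frames as returned by
#'   [score_samples()]; skipped set names in attribute `skipped`.
#' @export
score_gene_sets <- function(z, gene_sets, min_size = 5L) {
  out <- list()
  skipped <- character()
  for (nm in names(gene_sets)) {
    used <- intersect(gene_sets[[nm]], rownames(z))
    if (length(used) < min_size) {
      .warnf("gene set '%s' skipped: %d gene(s) in matrix, minimum is %d",
             nm, length(used), min_size)
      skipped <- c(skipped, nm)
      next
    }
    out[[nm]] <- score_samples(z, used, universe = nm)
  }
  structure(out, skipped = skipped)
}

#' Fit the molecular degree of perturbation to an expression cohort
#'
#' The central entry point. Per gene, a robust center and scale are
#' estimated from the control class; every value is turned into an absolute
#' modified z-score, thresholded at `z_cutoff`; the top
#' `perturbed_fraction` of genes by mean thresholded |z| over the
#' non-control samples become the "perturbedgenes" universe; and every
#' sample (control and non-control alike) is scored as the mean thresholded
#' |z| over each universe: `"allgenes"`, `"perturbedgenes"`, and each
#' supplied GMT set.
#'
#' @param expr Numeric genes x samples matrix of normalized expression, or
#'   the result of [read_expression()].
#' @param pheno Phenotype `data.frame` with columns `Sample`, `Class`.
#'   Samples are aligned to the matrix via [align_samples()].
#' @param control_class Class label of the reference group (default
#'   `"healthy"`); needs >= 2 members, and >= 1 non-control sample must
#'   exist.
#' @param gene_sets Optional `"gmt"` collection to score as extra universes.
#' @param control An [mdp_control()] parameter list.
#' @return An object of class `"mdp"`: a list with components
#'   \describe{
#'     \item{gene_stats}{per-gene `Center`, `Scale`, `Degenerate`}
#'     \item{z}{the thresholded genes x samples z matrix}
#'     \item{perturbed_genes}{ranked top-fraction gene table (pooled mode),
#'       or a named list of such tables (per-class mode)}
#'     \item{scores}{long `data.frame`: `Sample`, `Class`, `Score`,
#'       `Universe`}
#'     \item{pheno}{the aligned phenotype table}
#'     \item{control_class, control, call}{metadata}
#'   }
#' @examples
#' sim <- simulate_bulk(seed = 1)
#' fit <- mdp(sim$expr, sim$pheno)
#' summary(fit)
#' @export
mdp <- function(expr, pheno, control_class = "healthy", gene_sets = NULL,
                control = mdp_control()) {
  cl <- match.call()
  stopifnot(inherits(control, "mdp_control"))
  al <- align_samples(expr, pheno, control_class = control_class)
  expr <- al$expr
  pheno <- al$pheno
  .check_pheno(pheno, control_class = control_class)
  control_ids <- pheno$Sample[pheno$Class == control_class]
  case_ids <- pheno$Sample[pheno$Class != control_class]

  gstats <- estimate_gene_stats(expr, control_ids, control)
  z <- compute_z(expr, gstats, control)

  if (control$ranking == "pooled") {
    pg <- rank_perturbed_genes(z, case_ids, control, degenerate = gstats$Degenerate)
    pg_universes <- list(perturbedgenes = pg$Gene)
    perturbed_genes <- pg
  } else {
    classes <- unique(pheno$Class[pheno$Class != control_class])
    perturbed_genes <- lapply(classes, function(cc) {
      rank_perturbed_genes(z, pheno$Sample[pheno$Class == cc], control,
                           degenerate = gstats$Degenerate)
    })
    names(perturbed_genes) <- classes
    pg_universes <- lapply(perturbed_genes, `[[`, "Gene")
    names(pg_universes) <- paste0("perturbedgenes_", classes)
  }

  score_list <- c(list(allgenes = score_samples(z, NULL, "allgenes")),
                  lapply(names(pg_universes), function(u)
                    score_samples(z, pg_universes[[u]], u)))
  names(score_list) <- c("allgenes", names(pg_universes))
  set_scores <- if (!is.null(gene_sets))
    score_gene_sets(z, gene_sets, min_size = control$min_set_size) else list()
  score_list <- c(score_list, set_scores)
  scores <- do.call(rbind, lapply(score_list, function(s) {
    s$Class <- pheno$Class[match(s$Sample, pheno$Sample)]
    s[, c("Sample", "Class", "Score", "Universe")]
  }))
  rownames(scores) <- NULL

  structure(list(gene_stats = gstats, z = z,
                 perturbed_genes = perturbed_genes,
                 scores = scores,
                 universe_sizes = vapply(score_list, attr, integer(1L), "n_genes"),
                 skipped_sets = attr(set_scores, "skipped"),
                 pheno = pheno, control_class = control_class,
                 control = control, call = cl),
            class = "mdp")
}

#' Extract per-sample scores from an MDP fit
#'
#' @param fit An `"mdp"` object.
#' @param universe Universe name to extract (e.g. `"allgenes"`,
#'   `"perturbedgenes"`, or a gene-set name); `NULL` returns all universes.
#' @return A `data.frame` with columns `Sample`, `Class`, `Score`,
#'   `Universe`.
#' @export
mdp_scores <- function(fit, universe = NULL) {
  stopifnot(inherits(fit, "mdp"))
  if (is.null(universe)) return(fit$scores)
  out <- fit$scores[fit$scores$Universe == universe, , drop = FALSE]
  if (nrow(out) == 0L)
    .stopf("no scores for universe '%s'; available: %s", universe,
           paste(unique(fit$scores$Universe), collapse = ", "))
  rownames(out) <- NULL
  out
}
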