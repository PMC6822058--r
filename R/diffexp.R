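#' Per-gene two-sample t-test between two sample groups
#'
#' Row-wise Student t-test (pooled variance by default, Welch optional)
#' comparing group A against group B for every gene. The log2 fold change
#' is the difference of group means, which assumes the matrix is on a
#' log2-like scale; use `log2_transform = TRUE` for linear-scale data.
#'
#' Genes with zero variance in both groups get `t = 0, p = 1` when the
#' means are equal; when the means differ with zero pooled variance the
#' p-value is set to 0 and the gene is marked in the `ZeroVariance`
#' column, so a constant-but-shifted gene is reported rather than NaN.
#'
#' @param expr Numeric genes x samples matrix.
#' @param ids_a,ids_b Disjoint sample-id vectors, each of size >= 2.
#'   `Log2FC = mean(A) - mean(B)`; conventionally A = cases, B = controls.
#' @param variance `"pooled"` (Student, default) or `"welch"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` before testing
#'   (for matrices not already on a log scale). Default `FALSE`.
#' @return A `data.frame` with columns `Gene`, `MeanA`, `MeanB`, `Log2FC`,
#'   `T`, `P`, `ZeroVariance`.
#' @export
deg_ttest <- function(expr, ids_a, ids_b, variance = c("pooled", "welch"),
                      log2_transform = FALSE) {
  variance <- match.arg(variance)
  .check_expr(expr)
  miss <- setdiff(c(ids_a, ids_b), colnames(expr))
  if (length(miss) > 0L)
    .stopf("sample id(s) not in matrix: %s", paste(miss, collapse = ", "))
  if (length(intersect(ids_a, ids_b)) > 0L)
    .stopf("groups overlap: %s", paste(intersect(ids_a, ids_b), collapse = ", "))
  na <- length(ids_a); nb <- length(ids_b)
  if (na < 2L || nb < 2L)
    .stopf("each group needs >= 2 samples (got %d and %d)", na, nb)
  if (log2_transform) {
    if (any(expr < 0)) .stopf("log2_transform requires non-negative values")
    expr <- log2(expr + 1)
  }
  xa <- expr[, ids_a, drop = FALSE]
  xb <- expr[, ids_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  diff <- ma - mb
  if (variance == "pooled") {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, nrow(expr))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  zerovar <- se == 0
  tstat <- ifelse(zerovar, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(zerovar, ifelse(diff == 0, 1, 0),
              2 * stats::pt(-abs(diff / ifelse(zerovar, 1, se)), df))
  data.frame(Gene = rownames(expr), MeanA = unname(ma), MeanB = unname(mb),
             Log2FC = unname(diff), T = unname(tstat), P = unname(p),
             ZeroVariance = unname(zerovar & diff != 0),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate control: p-values are sorted ascending,
#' `q_(i) = p_(i) * n / i`, made monotone from the largest down, capped at
#' 1, and returned in the original order.
#'
#' @param pvalues Numeric vector with all values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) .stopf("pvalues must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    .stopf("pvalues must all lie in [0, 1] with no NAs")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes under fold-change / FDR thresholds
#'
#' Adds BH-adjusted p-values and a significance call to a [deg_ttest()]
#' table: a gene is significant when `|Log2FC| >= min_abs_log2fc` and
#' `AdjP <= max_adj_p`.
#'
#' @param table A `data.frame` from [deg_ttest()].
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param max_adj_p Maximum BH-adjusted p (default 0.05).
#' @return The table with added `AdjP` and `Significant` columns and
#'   attribute `n_deg` (the significant-gene count).
#' @export
call_degs <- function(table, min_abs_log2fc = 1, max_adj_p = 0.05) {
  stopifnot(is.data.frame(table), all(c("Log2FC", "P") %in% names(table)))
  stopifnot(min_abs_log2fc >= 0, max_adj_p > 0, max_adj_p <= 1)
  table$AdjP <- bh_adjust(table$P)
  table$Significant <- abs(table$Log2FC) >= min_abs_log2fc &
    table$AdjP <= max_adj_p
  attr(table, "n_deg") <- sum(table$Significant)
  table
}

#' Number of significant genes in a called DEG table
#'
#' @param table A table from [call_degs()].
#' @return Integer count.
#' @export
deg_count <- function(table) {
  stopifnot(is.data.frame(table), "Significant" %in% names(table))
  sum(table$Significant)
}

#' DEG counts before and after outlier removal
#'
#' Runs the same case-vs-control DEG analysis on the full dataset and on
#' the dataset with flagged outliers removed, and reports both counts and
#' their ratio — the quantity that shows how much heterogeneous samples
#' were masking the disease signal.
#'
#' @param expr Numeric genes x samples matrix.
#' @param pheno Phenotype `data.frame` (`Sample`, `Class`).
#' @param report Outlier report from [flag_outliers()].
#' @param class_a Case class label (group A of the t-test).
#' @param class_b Control class label (group B).
#' @param min_abs_log2fc,max_adj_p DEG thresholds, see [call_degs()].
#' @param variance t-test variance mode, see [deg_ttest()].
#' @return A list: `count_before`, `count_after`, `fold_change`
#'   (`count_after / max(count_before, 1)`), `removed`, and the two called
#'   tables `table_before`, `table_after`.
#' @export
compare_outlier_removal <- function(expr, pheno, report, class_a, class_b,
                                    min_abs_log2fc = 1, max_adj_p = 0.05,
                                    variance = "pooled") {
  ids <- function(ph, cl) ph$Sample[ph$Class == cl]
  before <- call_degs(
    deg_ttest(expr, ids(pheno, class_a), ids(pheno, class_b), variance),
    min_abs_log2fc, max_adj_p)
  cleaned <- remove_outliers(expr, pheno, report)
  after <- call_degs(
    deg_ttest(cleaned$expr, ids(cleaned$pheno, class_a),
              ids(cleaned$pheno, class_b), variance),
    min_abs_log2fc, max_adj_p)
  cb <- deg_count(before); ca <- deg_count(after)
  list(count_before = cb, count_after = ca,
       fold_change = ca / max(cb, 1L), removed = cleaned$removed,
       table_before = before, table_after = after)
}

#' Random-removal null distribution of DEG counts
#'
#' Repeatedly removes, uniformly at random and stratified by class, the
#' same number of samples per class as were flagged as outliers, re-runs
#' the DEG analysis, and collects the counts. Comparing the observed
#' after-removal count against this distribution shows whether the gain
#' from outlier removal exceeds what removing arbitrary samples achieves.
#'
#' @param expr Numeric genes x samples matrix.
#' @param pheno Phenotype `data.frame` (`Sample`, `Class`).
#' @param removal_counts Named integer vector: how many samples to remove
#'   from each class (classes absent from the names lose none). Typically
#'   `table(report$Class[report$Flagged])`.
#' @param class_a,class_b Case and control class labels for the contrast.
#' @param min_abs_log2fc,max_adj_p DEG thresholds, see [call_degs()].
#' @param reps Number of repetitions (default 1000).
#' @param seed Master seed; each repetition uses a deterministically
#'   derived sub-seed, so the vector is reproducible and independent of
#'   evaluation order.
#' @param variance t-test variance mode.
#' @return An object of class `"mdp_null"`: list with `counts` (length
#'   `reps`), `mean`, `sd`, `reps`, `seed`, `removal_counts`.
#' @export
random_removal_null <- function(expr, pheno, removal_counts, class_a, class_b,
                                min_abs_log2fc = 1, max_adj_p = 0.05,
                                reps = 1000L, seed = 1L, variance = "pooled") {
  .check_expr(expr)
  .check_pheno(pheno)
  stopifnot(reps >= 1L)
  removal_counts <- removal_counts[removal_counts > 0]
  cls <- names(removal_counts)
  if (length(cls) > 0L) {
    if (is.null(cls) || any(!nzchar(cls)))
      .stopf("removal_counts must be a named vector (class -> count)")
    sizes <- table(pheno$Class)[cls]
    if (anyNA(sizes))
      .stopf("removal class not in phenotype: %s",
             paste(cls[is.na(sizes)], collapse = ", "))
    short <- cls[sizes - removal_counts < 2L & cls %in% c(class_a, class_b)]
    if (length(short) > 0L)
      .stopf("removing %d from class '%s' (size %d) leaves < 2 samples",
             removal_counts[short[1L]], short[1L], sizes[short[1L]])
  }
  ids <- function(ph, cl) ph$Sample[ph$Class == cl]
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    set.seed(.substream(seed, r))
    drop_ids <- unlist(lapply(cls, function(cc) {
      members <- ids(pheno, cc)
      sample(members, removal_counts[[cc]])
    }), use.names = FALSE)
    keep <- pheno[!(pheno$Sample %in% drop_ids), , drop = FALSE]
    tab <- call_degs(
      deg_ttest(expr[, keep$Sample, drop = FALSE],
                ids(keep, class_a), ids(keep, class_b), variance),
      min_abs_log2fc, max_adj_p)
    counts[r] <- deg_count(tab)
  }
  structure(list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
                 reps = as.integer(reps), seed = as.integer(seed),
                 removal_counts = removal_counts),
            class = "mdp_null")
}

#' @export
print.mdp_null <- function(x, ...) {
  cat(sprintf("Random-removal null: %d reps, removing {%s}; DEG count mean %.2f, SD %.2f\n",
              x$reps,
              paste(sprintf("%s: %d", names(x$removal_counts), x$removal_counts),
                    collapse = ", "),
              x$mean, x$sd))
  invisible(x)
}
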