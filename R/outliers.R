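#' Flag potential outlier samples from MDP scores, class-wise
#'
#' Within each class, a sample is flagged when its score deviates from the
#' class mean by at least `k` class standard deviations (two-sided by
#' default, so a suspiciously perturbed control and a suspiciously
#' unperturbed case are both caught). The class mean and SD (n-1) include
#' the candidate itself. Classes with fewer than `min_class_size` samples
#' or zero score SD yield no flags.
#'
#' @param x An `"mdp"` fit, or a `data.frame` with columns `Sample`,
#'   `Class`, `Score`.
#' @param universe For an `"mdp"` fit, the score universe to use (default
#'   `"perturbedgenes"`, the score usually inspected; `"allgenes"` is the
#'   common alternative).
#' @param k Number of class standard deviations for the flag threshold
#'   (default 2); must be > 0. The comparison is `>=`.
#' @param sidedness `"two_sided"` (default) or `"high_only"`.
#' @param min_class_size Classes smaller than this are never flagged
#'   (default 3; an SD from fewer samples is too unstable to threshold).
#' @return A `data.frame` of class `"mdp_outliers"` with columns `Sample`,
#'   `Class`, `Score`, `ClassMean`, `ClassSD`, `DeviationSDs`, `Flagged`,
#'   `Direction`, and attributes `k`, `universe`, `sidedness`.
#' @examples
#' sim <- simulate_bulk(seed = 1)
#' fit <- mdp(sim$expr, sim$pheno)
#' rep <- flag_outliers(fit)
#' rep[rep$Flagged, ]
#' @export
flag_outliers <- function(x, universe = "perturbedgenes", k = 2,
                          sidedness = c("two_sided", "high_only"),
                          min_class_size = 3L) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  sc <- if (inherits(x, "mdp")) mdp_scores(x, universe) else {
    if (!is.data.frame(x) || !all(c("Sample", "Class", "Score") %in% names(x)))
      .stopf("x must be an 'mdp' fit or a data.frame with Sample, Class, Score")
    universe <- if ("Universe" %in% names(x)) as.character(x$Universe[1L]) else "scores"
    x
  }
  out <- do.call(rbind, lapply(split(sc, sc$Class), function(d) {
    m <- mean(d$Score)
    s <- stats::sd(d$Score)
    dev <- if (is.na(s) || s == 0) rep(NA_real_, nrow(d)) else (d$Score - m) / s
    can_flag <- nrow(d) >= min_class_size && !is.na(s) && s > 0
    if (!can_flag && nrow(d) > 0L)
      message(sprintf("flag_outliers: class '%s' not assessed (n = %d, SD = %s)",
                      d$Class[1L], nrow(d),
                      if (is.na(s)) "NA" else format(s, digits = 3)))
    flagged <- if (!can_flag) rep(FALSE, nrow(d)) else if (sidedness == "two_sided")
      abs(dev) >= k else dev >= k
    data.frame(Sample = d$Sample, Class = d$Class, Score = d$Score,
               ClassMean = m, ClassSD = if (is.na(s)) NA_real_ else s,
               DeviationSDs = dev, Flagged = flagged,
               Direction = ifelse(is.na(dev), NA_character_,
                                  ifelse(dev >= 0, "high", "low")),
               stringsAsFactors = FALSE)
  }))
  out <- out[match(sc$Sample, out$Sample), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, universe = universe, sidedness = sidedness,
            class = c("mdp_outliers", "data.frame"))
}

#' @export
print.mdp_outliers <- function(x, ...) {
  cat(sprintf("Outlier report (universe '%s', k = %g, %s): %d of %d sample(s) flagged\n",
              attr(x, "universe"), attr(x, "k"), attr(x, "sidedness"),
              sum(x$Flagged), nrow(x)))
  if (any(x$Flagged))
    print(.signif_df(as.data.frame(x)[x$Flagged, , drop = FALSE], 4L),
          row.names = FALSE)
  invisible(x)
}

#' Remove flagged outlier samples from a dataset
#'
#' Drops every flagged sample from both the expression matrix and the
#' phenotype table, preserving the order of the survivors. Refuses to
#' produce a dataset in which any class retains fewer than two samples.
#'
#' @param expr Numeric genes x samples matrix.
#' @param pheno Phenotype `data.frame` (`Sample`, `Class`).
#' @param report An outlier report from [flag_outliers()] covering the
#'   current samples.
#' @return A list with `expr`, `pheno`, and `removed` (the dropped sample
#'   ids).
#' @export
remove_outliers <- function(expr, pheno, report) {
  .check_expr(expr)
  .check_pheno(pheno)
  if (!all(pheno$Sample %in% report$Sample))
    .stopf("outlier report does not cover all current samples")
  drop_ids <- report$Sample[report$Flagged]
  drop_ids <- intersect(drop_ids, pheno$Sample)
  if (length(drop_ids) == 0L)
    return(list(expr = expr, pheno = pheno, removed = character()))
  keep <- !(pheno$Sample %in% drop_ids)
  left <- table(pheno$Class[keep])
  gone <- setdiff(unique(pheno$Class), names(left))
  if (length(gone) > 0L)
    .stopf("removal would empty class '%s'", gone[1L])
  if (any(left < 2L))
    .stopf("removal would leave class '%s' with %d sample(s); >= 2 required",
           names(left)[left < 2L][1L], min(left))
  pheno2 <- pheno[keep, , drop = FALSE]
  rownames(pheno2) <- NULL
  keep_cols <- setdiff(colnames(expr), drop_ids)
  list(expr = expr[, keep_cols, drop = FALSE], pheno = pheno2,
       removed = drop_ids)
}
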