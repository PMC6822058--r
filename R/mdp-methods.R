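#' @export
print.mdp <- function(x, ...) {
  cat("Molecular degree of perturbation fit\n")
  cat(sprintf("  genes: %d (%d degenerate)  samples: %d  control class: '%s' (n = %d)\n",
              nrow(x$z), sum(x$gene_stats$Degenerate), ncol(x$z),
              x$control_class, sum(x$pheno$Class == x$control_class)))
  cat(sprintf("  z cutoff: %g  perturbed fraction: %g  center/scale: %s/%s\n",
              x$control$z_cutoff, x$control$perturbed_fraction,
              x$control$center, x$control$scale))
  cat(sprintf("  score universes: %s\n",
              paste(sprintf("%s (%d)", names(x$universe_sizes), x$universe_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize an MDP fit
#'
#' @param object An `"mdp"` object.
#' @param ... Unused.
#' @return A `"summary.mdp"` object: per class and universe, the number of
#'   samples and the mean/SD of the scores.
#' @export
summary.mdp <- function(object, ...) {
  sc <- object$scores
  agg <- do.call(rbind, lapply(split(sc, list(sc$Universe, sc$Class), drop = TRUE),
    function(d) data.frame(Universe = d$Universe[1L], Class = d$Class[1L],
                           N = nrow(d), Mean = mean(d$Score), SD = stats::sd(d$Score),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$Universe, agg$Class), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(fit = object, by_class = agg), class = "summary.mdp")
}

#' @export
print.summary.mdp <- function(x, digits = 4L, ...) {
  print(x$fit)
  cat("\nScores by class:\n")
  print(.signif_df(x$by_class, digits), row.names = FALSE)
  pg <- x$fit$perturbed_genes
  if (is.data.frame(pg)) {
    cat(sprintf("\nTop perturbed genes (%d total):\n", nrow(pg)))
    print(utils::head(.signif_df(pg, digits), 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Per-gene reference statistics of an MDP fit
#'
#' @param object An `"mdp"` object.
#' @param ... Unused.
#' @return The `gene_stats` data.frame (`Gene`, `Center`, `Scale`,
#'   `Degenerate`).
#' @export
coef.mdp <- function(object, ...) object$gene_stats

#' Thresholded z-scores of an MDP fit
#'
#' The residual-like quantity of the fit: each sample's thresholded
#' absolute deviation from the control reference, per gene.
#'
#' @param object An `"mdp"` object.
#' @param ... Unused.
#' @return The genes x samples thresholded z matrix.
#' @export
residuals.mdp <- function(object, ...) object$z

#' Score new samples against a fitted control reference
#'
#' Applies the gene centers/scales and the perturbed-gene universe learned
#' by [mdp()] to new expression columns, without re-estimating anything.
#'
#' @param object An `"mdp"` object.
#' @param newdata Numeric genes x samples matrix sharing gene ids with the
#'   fit (genes are intersected; a warning is raised if any training genes
#'   are missing).
#' @param ... Unused.
#' @return A long `data.frame` `Sample`, `Score`, `Universe` covering the
#'   fit's universes.
#' @export
predict.mdp <- function(object, newdata, ...) {
  .check_expr(newdata, "newdata")
  shared <- intersect(object$gene_stats$Gene, rownames(newdata))
  if (length(shared) == 0L) .stopf("newdata shares no genes with the fit")
  if (length(shared) < nrow(object$z))
    .warnf("newdata is missing %d of %d training genes; scoring on the shared set",
           nrow(object$z) - length(shared), nrow(object$z))
  nd <- newdata[shared, , drop = FALSE]
  stats <- object$gene_stats[match(shared, object$gene_stats$Gene), , drop = FALSE]
  z <- suppressMessages(compute_z(nd, stats, object$control))
  universes <- c(list(allgenes = NULL),
                 if (is.data.frame(object$perturbed_genes))
                   list(perturbedgenes = object$perturbed_genes$Gene)
                 else {
                   u <- lapply(object$perturbed_genes, `[[`, "Gene")
                   names(u) <- paste0("perturbedgenes_", names(u))
                   u
                 })
  out <- do.call(rbind, lapply(names(universes), function(nm)
    score_samples(z, universes[[nm]], nm)))
  rownames(out) <- NULL
  out
}

#' Plot MDP scores by class
#'
#' A boxplot (or per-sample barplot) of the perturbation scores for one
#' universe, the standard visual for spotting heterogeneous samples:
#' controls should sit low; a control reaching into the case range, or a
#' case at control level, stands out.
#'
#' @param x An `"mdp"` object.
#' @param universe Universe to plot (default `"perturbedgenes"`).
#' @param type `"boxplot"` (default) or `"barplot"` (one bar per sample,
#'   grouped by class).
#' @param ... Passed to the underlying graphics call.
#' @return `x`, invisibly.
#' @export
plot.mdp <- function(x, universe = "perturbedgenes",
                     type = c("boxplot", "barplot"), ...) {
  type <- match.arg(type)
  sc <- mdp_scores(x, universe)
  if (type == "boxplot") {
    graphics::boxplot(Score ~ Class, data = sc,
                      ylab = sprintf("MDP score (%s)", universe), ...)
    graphics::stripchart(Score ~ Class, data = sc, vertical = TRUE,
                         method = "jitter", pch = 19, add = TRUE,
                         col = grDevices::adjustcolor("steelblue", 0.7))
  } else {
    ord <- order(sc$Class, sc$Score)
    graphics::barplot(sc$Score[ord], names.arg = sc$Sample[ord], las = 2,
                      col = as.integer(factor(sc$Class[ord])) + 1L,
                      ylab = sprintf("MDP score (%s)", universe), ...)
  }
  invisible(x)
}
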