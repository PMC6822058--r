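#' Filter single-cell genes by mean expression, then by zero fraction
#'
#' The two-step filter applied before computing perturbation scores on
#' single cells: first keep only the top `top_fraction` of genes by mean
#' expression over all cells, then remove genes with zero values in
#' `max_zero_fraction` or more of the cells. The order of the two steps
#' matters and is fixed; gene order is preserved.
#'
#' @param counts Non-negative genes x cells matrix (raw or normalized
#'   counts; means are taken on the values as supplied).
#' @param top_fraction Fraction of genes kept by mean expression (default
#'   0.30); `max(1, floor(top_fraction * G))` genes survive step 1, ties
#'   broken by input order.
#' @param max_zero_fraction Genes whose zero fraction is `>=` this value
#'   are removed in step 2 (default 0.40).
#' @return The filtered matrix, with attributes `n_step1` and `n_removed_zeros`.
#' @export
filter_genes_sc <- function(counts, top_fraction = 0.30,
                            max_zero_fraction = 0.40) {
  .check_expr(counts, "counts matrix")
  if (any(counts < 0)) .stopf("counts matrix must be non-negative")
  stopifnot(top_fraction > 0, top_fraction <= 1,
            max_zero_fraction > 0, max_zero_fraction <= 1)
  G <- nrow(counts)
  n_keep <- max(1L, floor(top_fraction * G))
  ord <- order(-rowMeans(counts))          # stable: ties keep input order
  keep1 <- sort(ord[seq_len(n_keep)])      # restore input gene order
  step1 <- counts[keep1, , drop = FALSE]
  zero_frac <- rowMeans(step1 == 0)
  keep2 <- zero_frac < max_zero_fraction
  if (!any(keep2))
    .stopf("no genes survive the zero-fraction filter (>= %g zeros in all of the top %d genes)",
           max_zero_fraction, n_keep)
  out <- step1[keep2, , drop = FALSE]
  attr(out, "n_step1") <- n_keep
  attr(out, "n_removed_zeros") <- sum(!keep2)
  out
}

#' Assign infected cells to MDP-by-viral-load quadrants
#'
#' Splits cells into four subsets by crossing their perturbation score
#' with their viral load: `MDPhigh_VLhigh`, `MDPhigh_VLlow`,
#' `MDPlow_VLhigh`, `MDPlow_VLlow`. Both cutoffs are inclusive on the
#' high side (`score >= mdp_cut`, `VL >= vl_cut`).
#'
#' @param scores A score `data.frame` (`Sample`, `Score`; e.g. from
#'   [mdp_scores()]) or a named numeric vector of per-cell scores.
#' @param vl Named numeric vector of per-cell viral loads (virus read
#'   counts, >= 0). Cells are the intersection of score and VL names —
#'   normally the infected cells.
#' @param mdp_cut MDP cutoff (default 1).
#' @param vl_cut Viral-load cutoff (default 1000).
#' @return A `data.frame` of class `"mdp_quadrants"` with columns `Cell`,
#'   `Score`, `VL`, `Quadrant`, plus attributes `mdp_cut`, `vl_cut`, and
#'   `counts` (table of quadrant sizes).
#' @export
assign_quadrants <- function(scores, vl, mdp_cut = 1, vl_cut = 1000) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("Sample", "Score") %in% names(scores)))
    sc <- stats::setNames(scores$Score, scores$Sample)
  } else {
    sc <- scores
  }
  if (is.null(names(sc)) || is.null(names(vl)))
    .stopf("scores and vl must carry cell names")
  if (any(vl < 0)) .stopf("viral loads must be non-negative")
  cells <- intersect(names(sc), names(vl))
  if (length(cells) == 0L) .stopf("no cells shared between scores and viral loads")
  s <- sc[cells]; v <- vl[cells]
  quad <- paste0(ifelse(s >= mdp_cut, "MDPhigh", "MDPlow"),
                 "_",
                 ifelse(v >= vl_cut, "VLhigh", "VLlow"))
  out <- data.frame(Cell = cells, Score = unname(s), VL = unname(v),
                    Quadrant = quad, stringsAsFactors = FALSE)
  lv <- c("MDPhigh_VLhigh", "MDPhigh_VLlow", "MDPlow_VLhigh", "MDPlow_VLlow")
  structure(out, mdp_cut = mdp_cut, vl_cut = vl_cut,
            counts = table(factor(quad, levels = lv)),
            class = c("mdp_quadrants", "data.frame"))
}

#' @export
print.mdp_quadrants <- function(x, ...) {
  cat(sprintf("Quadrant assignment of %d cells (MDP cutoff %g, VL cutoff %g):\n",
              nrow(x), attr(x, "mdp_cut"), attr(x, "vl_cut")))
  print(attr(x, "counts"))
  invisible(x)
}

#' The three quadrant differential-expression contrasts
#'
#' Runs the bulk DEG machinery on three contrasts of the quadrant
#' partition: (1) doubly-high vs doubly-low cells (`MDPhigh_VLhigh` vs
#' `MDPlow_VLlow`), (2) the MDP axis (all MDP-high vs all MDP-low cells),
#' and (3) the VL axis (all VL-high vs all VL-low cells). When
#' perturbation and viral load are only partially coupled, the doubly-high
#' vs doubly-low contrast yields the most DEGs and the VL axis the fewest.
#'
#' @param expr Genes x cells matrix on a log-like scale (the same matrix
#'   the scores were computed on).
#' @param quadrants A `"mdp_quadrants"` assignment from
#'   [assign_quadrants()].
#' @param min_abs_log2fc,max_adj_p DEG thresholds, see [call_degs()].
#' @param variance t-test variance mode, see [deg_ttest()].
#' @return A list of three elements `hh_vs_ll`, `mdp_axis`, `vl_axis`,
#'   each a list with the called `table`, `n_deg`, and the two group
#'   sizes; plus `counts`, the named vector of the three DEG counts.
#' @export
quadrant_contrasts <- function(expr, quadrants, min_abs_log2fc = 1,
                               max_adj_p = 0.05, variance = "pooled") {
  stopifnot(inherits(quadrants, "mdp_quadrants"))
  q <- split(quadrants$Cell, quadrants$Quadrant)
  gid <- function(...) unlist(q[c(...)], use.names = FALSE)
  contrasts <- list(
    hh_vs_ll = list(a = gid("MDPhigh_VLhigh"), b = gid("MDPlow_VLlow")),
    mdp_axis = list(a = gid("MDPhigh_VLhigh", "MDPhigh_VLlow"),
                    b = gid("MDPlow_VLhigh", "MDPlow_VLlow")),
    vl_axis  = list(a = gid("MDPhigh_VLhigh", "MDPlow_VLhigh"),
                    b = gid("MDPhigh_VLlow", "MDPlow_VLlow")))
  out <- lapply(names(contrasts), function(nm) {
    co <- contrasts[[nm]]
    if (length(co$a) < 2L || length(co$b) < 2L)
      .stopf("contrast '%s' has group sizes %d vs %d; >= 2 cells per side required",
             nm, length(co$a), length(co$b))
    tab <- call_degs(deg_ttest(expr, co$a, co$b, variance),
                     min_abs_log2fc, max_adj_p)
    list(table = tab, n_deg = deg_count(tab),
         n_a = length(co$a), n_b = length(co$b))
  })
  names(out) <- names(contrasts)
  out$counts <- vapply(out[names(contrasts)], `[[`, integer(1L), "n_deg")
  out
}
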