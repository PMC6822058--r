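#' Control parameters for the MDP computation
#'
#' @param center Per-gene centrality estimated from the control samples:
#'   `"median"` (default, robust) or `"mean"`.
#' @param scale Per-gene dispersion from the control samples: `"mad"`
#'   (default, median absolute deviation) or `"sd"` (sample SD, n-1).
#' @param mad_constant Multiplier applied to the raw MAD; default 1.4826
#'   makes the MAD consistent with the SD under normality. Set to 1 for the
#'   raw MAD.
#' @param z_cutoff Threshold below which absolute modified z-scores are set
#'   to 0 (default 2); deviations smaller than this are treated as noise.
#'   The comparison is strict: a score exactly at the cutoff survives.
#' @param perturbed_fraction Fraction of genes, ranked by mean thresholded
#'   |z| over the ranking group, kept as the "perturbed genes" universe
#'   (default 0.25). The list length is `max(1, floor(fraction * G))`.
#' @param min_set_size Minimum overlap between a supplied gene set and the
#'   matrix genes for the set to be scored (default 5); smaller sets are
#'   skipped with a warning.
#' @param ranking Group over which perturbed genes are ranked: `"pooled"`
#'   (default) pools all non-control samples; `"per_class"` produces one
#'   perturbed-gene list and score universe per non-control class.
#' @return A list of validated parameters, class `"mdp_control"`.
#' @examples
#' mdp_control(scale = "sd", z_cutoff = 1.5)
#' @export
mdp_control <- function(center = c("median", "mean"),
                        scale = c("mad", "sd"),
                        mad_constant = 1.4826,
                        z_cutoff = 2,
                        perturbed_fraction = 0.25,
                        min_set_size = 5L,
                        ranking = c("pooled", "per_class")) {
  center <- match.arg(center)
  scale <- match.arg(scale)
  ranking <- match.arg(ranking)
  stopifnot(is.numeric(mad_constant), length(mad_constant) == 1L,
            is.finite(mad_constant), mad_constant > 0)
  stopifnot(is.numeric(z_cutoff), length(z_cutoff) == 1L,
            is.finite(z_cutoff), z_cutoff >= 0)
  stopifnot(is.numeric(perturbed_fraction), length(perturbed_fraction) == 1L,
            perturbed_fraction > 0, perturbed_fraction <= 1)
  stopifnot(is.numeric(min_set_size), length(min_set_size) == 1L,
            min_set_size >= 1)
  structure(list(center = center, scale = scale,
                 mad_constant = mad_constant, z_cutoff = z_cutoff,
                 perturbed_fraction = perturbed_fraction,
                 min_set_size = as.integer(min_set_size),
                 ranking = ranking),
            class = "mdp_control")
}
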