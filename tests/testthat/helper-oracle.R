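# Brute-force reference implementations, written with explicit loops and
# kept independent of the package code paths they check.

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

# per-gene center/scale, loop over genes
oracle_gene_stats <- function(expr, control_ids, center = "median",
                              scale = "mad", mad_constant = 1.4826) {
  ctr <- scl <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    v <- as.numeric(expr[i, control_ids])
    ctr[i] <- if (center == "median") oracle_median(v) else sum(v) / length(v)
    scl[i] <- if (scale == "mad") {
      devs <- numeric(length(v))
      for (j in seq_along(v)) devs[j] <- abs(v[j] - ctr[i])
      mad_constant * oracle_median(devs)
    } else {
      m <- sum(v) / length(v)
      sqrt(sum((v - m)^2) / (length(v) - 1L))
    }
  }
  list(center = ctr, scale = scl)
}

# thresholded |z|, loop over every entry
oracle_z <- function(expr, center, scale, z_cutoff = 2) {
  z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    for (j in seq_len(ncol(expr))) {
      if (scale[i] > 0) {
        v <- abs(expr[i, j] - center[i]) / scale[i]
        z[i, j] <- if (v < z_cutoff) 0 else v
      }
    }
  }
  z
}

# top-fraction gene selection by mean |z| over the ranking samples
oracle_perturbed <- function(z, ranking_ids, fraction = 0.25,
                             degenerate = rep(FALSE, nrow(z))) {
  stat <- numeric(nrow(z))
  for (i in seq_len(nrow(z)))
    stat[i] <- mean(as.numeric(z[i, ranking_ids]))
  n_top <- max(1L, floor(fraction * nrow(z)))
  ord <- order(-stat)
  ord <- ord[!degenerate[ord]]
  rownames(z)[ord[seq_len(min(n_top, length(ord)))]]
}

oracle_scores <- function(z, genes = rownames(z)) {
  genes <- intersect(genes, rownames(z))
  s <- numeric(ncol(z))
  for (j in seq_len(ncol(z)))
    s[j] <- mean(as.numeric(z[genes, j]))
  names(s) <- colnames(z)
  s
}

# step-up BH by its textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- p[ord[i]] * n / i
  for (i in seq(n - 1L, 1L)) if (i >= 1L && n > 1L) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# small deterministic fixture factory
random_expr <- function(n_genes, n_samples, seed, prefix = "S") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 1.5),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("%s%02d", prefix, seq_len(n_samples))))
  m
}

two_class_pheno <- function(expr, n_controls) {
  data.frame(Sample = colnames(expr),
             Class = rep(c("healthy", "disease"),
                         c(n_controls, ncol(expr) - n_controls)),
             stringsAsFactors = FALSE)
}
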