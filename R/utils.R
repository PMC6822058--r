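# internal helpers shared across the package

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic sub-seed for a named random substream; kept < 2^31 - 1
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

# validate a genes x samples expression matrix
.check_expr <- function(expr, what = "expression matrix") {
  if (!is.matrix(expr) || !is.numeric(expr))
    .stopf("%s must be a numeric matrix (genes x samples)", what)
  g <- rownames(expr)
  s <- colnames(expr)
  if (is.null(g) || is.null(s))
    .stopf("%s must carry gene rownames and sample colnames", what)
  if (anyDuplicated(g))
    .stopf("duplicate gene id in %s: '%s'", what, g[duplicated(g)][1L])
  if (any(!nzchar(g)))
    .stopf("%s contains an empty gene id", what)
  if (anyDuplicated(s))
    .stopf("duplicate sample id in %s: '%s'", what, s[duplicated(s)][1L])
  if (!all(is.finite(expr)))
    .stopf("%s contains non-finite values", what)
  invisible(expr)
}

# validate a phenotype data.frame (Sample, Class)
.check_pheno <- function(pheno, control_class = NULL) {
  if (!is.data.frame(pheno) || !all(c("Sample", "Class") %in% names(pheno)))
    .stopf("phenotype table must be a data.frame with columns Sample and Class")
  if (anyDuplicated(pheno$Sample))
    .stopf("duplicate sample id in phenotype table: '%s'",
           pheno$Sample[duplicated(pheno$Sample)][1L])
  if (!is.null(control_class)) {
    n_ctrl <- sum(pheno$Class == control_class)
    if (n_ctrl == 0L)
      .stopf("control class '%s' not present in phenotype table", control_class)
    if (n_ctrl < 2L)
      .stopf("control class '%s' has %d sample(s); at least 2 are required",
             control_class, n_ctrl)
    if (n_ctrl == nrow(pheno))
      .stopf("phenotype table has no non-control samples")
  }
  invisible(pheno)
}

.signif_df <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
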