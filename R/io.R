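#' Read a normalized gene-expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose remaining columns hold one sample each. Values are expected to be
#' already normalized (e.g. log-CPM, TMM, FPKM, RMA); the package performs no
#' normalization of its own.
#'
#' @param path Path to a tab- or comma-delimited text file with a header row.
#'   The first header cell names the gene-id column; the remaining header
#'   cells are sample ids.
#' @param delimiter `"auto"` (default; sniffed from the header line), `"tab"`,
#'   or `"comma"`.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("Gene\tS1\tS2", "ACTB\t5.1\t4.9", "GAPDH\t7.0\t7.2"), f)
#' read_expression(f)
#' @seealso [read_phenotype()], [read_gmt()], [write_expression()]
#' @export
read_expression <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) .stopf("expression file not found: %s", path)
  sep <- switch(delimiter,
    tab = "\t", comma = ",",
    auto = if (grepl("\t", readLines(path, n = 1L))) "\t" else ",")
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    .stopf("ragged expression file: line %d has %d fields but line 1 has %d",
           bad, nf[bad], nf[1L])
  }
  if (nf[1L] < 2L) .stopf("expression file needs a gene-id column plus >= 1 sample column")
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = character(),
                           quote = "\"", comment.char = "")
  if (nrow(tab) == 0L) .stopf("expression file has no data rows")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (any(!nzchar(gene_ids))) .stopf("empty gene id at data row %d", which(!nzchar(gene_ids))[1L])
  if (anyDuplicated(gene_ids))
    .stopf("duplicate gene id: '%s'", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    .stopf("duplicate sample column: '%s'", sample_ids[duplicated(sample_ids)][1L])
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
           nrow = nrow(tab), ncol = length(sample_ids)))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    .stopf("non-numeric value '%s' at gene row %d, sample column %d ('%s')",
           tab[i, j + 1L], i, j, sample_ids[j])
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  .check_expr(vals)
}

#' Read a phenotype table mapping samples to classes
#'
#' @param path Path to a tab- or comma-delimited file with columns `Sample`
#'   and `Class` (header names matched case-insensitively).
#' @param control_class Label of the reference (control) class; validated to
#'   be present with at least two members. Default `"healthy"`.
#' @param delimiter `"auto"`, `"tab"`, or `"comma"`.
#' @return A `data.frame` with character columns `Sample` and `Class`, in
#'   file order.
#' @export
read_phenotype <- function(path, control_class = "healthy",
                           delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  sep <- switch(delimiter,
    tab = "\t", comma = ",",
    auto = if (grepl("\t", readLines(path, n = 1L))) "\t" else ",")
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  idx <- match(c("sample", "class"), tolower(colnames(tab)))
  if (anyNA(idx))
    .stopf("phenotype file must have columns 'Sample' and 'Class' (found: %s)",
           paste(colnames(tab), collapse = ", "))
  pheno <- data.frame(Sample = tab[[idx[1L]]], Class = tab[[idx[2L]]],
                      stringsAsFactors = FALSE)
  .check_pheno(pheno, control_class = control_class)
  pheno
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited fields
#' `name`, `description`, then member gene ids. Genes within a set are
#' deduplicated with order preserved.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character gene-id vectors, one per set, of class
#'   `"gmt"`. Each element carries its description in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("GMT file is empty: %s", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stopf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
             i, length(f))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L) .stopf("GMT set '%s' (line %d) has no genes", f[1L], i)
    nms[i] <- f[1L]
    sets[[i]] <- structure(genes, description = f[2L])
  }
  if (anyDuplicated(nms))
    .stopf("duplicate gene-set name: '%s'", nms[duplicated(nms)][1L])
  names(sets) <- nms
  structure(sets, class = "gmt")
}

#' Align an expression matrix and a phenotype table on shared samples
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' expression matrix's column order, and reports how many samples were
#' dropped from each side.
#'
#' @param expr Numeric genes x samples matrix.
#' @param pheno Phenotype `data.frame` (columns `Sample`, `Class`).
#' @param control_class Optional control label; if given, an error is raised
#'   when fewer than two control samples survive the intersection.
#' @return A list with elements `expr`, `pheno`, `dropped_expr`,
#'   `dropped_pheno`.
#' @export
align_samples <- function(expr, pheno, control_class = NULL) {
  .check_expr(expr)
  .check_pheno(pheno)
  common <- intersect(colnames(expr), pheno$Sample)
  if (length(common) == 0L)
    .stopf("no samples shared between expression matrix and phenotype table")
  keep <- colnames(expr)[colnames(expr) %in% common]
  d_expr <- setdiff(colnames(expr), common)
  d_pheno <- setdiff(pheno$Sample, common)
  if (length(d_expr) || length(d_pheno))
    message(sprintf("align_samples: dropped %d expression column(s), %d phenotype row(s)",
                    length(d_expr), length(d_pheno)))
  pheno2 <- pheno[match(keep, pheno$Sample), , drop = FALSE]
  rownames(pheno2) <- NULL
  if (!is.null(control_class) && sum(pheno2$Class == control_class) < 2L)
    .stopf("fewer than 2 control ('%s') samples remain after alignment",
           control_class)
  list(expr = expr[, keep, drop = FALSE], pheno = pheno2,
       dropped_expr = d_expr, dropped_pheno = d_pheno)
}

#' Write an expression matrix as TSV
#'
#' Full precision is preserved so that `read_expression()` round-trips the
#' matrix exactly (to within double formatting, < 1e-12).
#'
#' @param expr Numeric genes x samples matrix.
#' @param path Output path.
#' @param gene_column Header name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, gene_column = "Gene") {
  .check_expr(expr)
  df <- data.frame(rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(gene_column, colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Numeric columns are rounded to 6 significant digits; use
#' [write_expression()] for full-precision matrices.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(.signif_df(as.data.frame(df)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
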