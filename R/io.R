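#' Construct and validate an expression study
#'
#' An expression study bundles a genes x samples matrix of log2 expression
#' values with a binary case/control label per sample and an optional
#' covariate table. It is the sole primary input of the pipeline.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param condition Integer/logical vector per sample: case = 1, control = 0.
#'   May be named; if so, names must match the sample names.
#' @param covariates Optional data.frame of per-sample covariates (numeric or
#'   factor columns), rows aligned with the samples. May be `NULL`.
#' @return An object of class `expression_study`: a list with elements
#'   `values`, `condition`, `covariates`, and `zero_variance` (logical flag per
#'   gene marking constant profiles, which are retained but flagged).
#' @export
expression_study <- function(values, condition, covariates = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  condition <- as.integer(condition)
  if (length(condition) != ncol(values))
    stop("'condition' must have one label per sample")
  if (!all(condition %in% c(0L, 1L)))
    stop("'condition' must be binary (case = 1, control = 0)")
  if (sum(condition == 1L) < 2L || sum(condition == 0L) < 2L)
    stop("both classes need at least 2 samples")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(values))
      stop("'covariates' must have one row per sample")
  }
  zv <- apply(values, 1L, function(x) max(x) == min(x))
  structure(
    list(values = values, condition = condition, covariates = covariates,
         zero_variance = zv),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%d cases / %d controls)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == 1L), sum(x$condition == 0L)))
  if (any(x$zero_variance))
    cat(sprintf("  %d zero-variance gene(s) flagged\n", sum(x$zero_variance)))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a genes x samples expression matrix
#'
#' Reads a delimited text file into a numeric matrix. Duplicate gene rows
#' (repeated probe measurements of the same gene) are collapsed into a single
#' row by taking their mean.
#'
#' @param path Path to a TSV/CSV file with a header row and gene identifiers
#'   in the first column (or first row, see `genes_in_rows`).
#' @param genes_in_rows If `FALSE` the matrix on disk is samples x genes and is
#'   transposed after reading.
#' @param sep Field separator; guessed from the file extension by default.
#' @param uppercase Uppercase gene identifiers after reading (default `TRUE`),
#'   so that later gene-set intersections are case-insensitive.
#' @return Numeric matrix, genes in rows, with duplicate gene rows collapsed.
#' @export
read_expression_matrix <- function(path, genes_in_rows = TRUE, sep = NULL,
                                   uppercase = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(num[[j]]))) & !is.na(num[[j]]))
      stop(sprintf("non-numeric value in column '%s'%s",
                   names(num)[j],
                   if (length(bad)) sprintf(", row %d ('%s')", bad[1L], num[[j]][bad[1L]]) else ""))
    }
  }
  m <- as.matrix(num)
  rownames(m) <- if (uppercase) toupper(ids) else ids
  if (!genes_in_rows) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, group = rownames(m)) / as.vector(table(rownames(m))[unique(sort(rownames(m)))])
    # rowsum sorts groups; divide by the per-group count to collapse by mean
  }
  m
}

#' Read an expression study (matrix + phenotype table)
#'
#' @param expr_path Expression matrix file (see [read_expression_matrix()]).
#' @param pheno_path CSV/TSV with columns `sample_id`, `condition` (case = 1,
#'   control = 0) and any number of covariate columns.
#' @param covariates Character vector of covariate column names to keep
#'   (default: all extra columns).
#' @inheritParams read_expression_matrix
#' @return An [expression_study()] object with samples ordered as in the
#'   expression matrix.
#' @export
read_expression <- function(expr_path, pheno_path, covariates = NULL,
                            genes_in_rows = TRUE, sep = NULL, uppercase = TRUE) {
  m <- read_expression_matrix(expr_path, genes_in_rows = genes_in_rows,
                              sep = sep, uppercase = uppercase)
  psep <- if (grepl("\\.tsv$", pheno_path, ignore.case = TRUE)) "\t" else ","
  ph <- utils::read.table(pheno_path, header = TRUE, sep = psep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "condition") %in% names(ph)))
    stop("phenotype table needs 'sample_id' and 'condition' columns")
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample IDs in phenotype table")
  miss <- setdiff(colnames(m), ph$sample_id)
  if (length(miss))
    stop("samples missing from phenotype table: ", paste(miss, collapse = ", "))
  ph <- ph[match(colnames(m), ph$sample_id), , drop = FALSE]
  extra <- setdiff(names(ph), c("sample_id", "condition"))
  keep <- if (is.null(covariates)) extra else {
    bad <- setdiff(covariates, extra)
    if (length(bad)) stop("unknown covariate columns: ", paste(bad, collapse = ", "))
    covariates
  }
  cov <- if (length(keep)) ph[, keep, drop = FALSE] else NULL
  if (!is.null(cov)) rownames(cov) <- ph$sample_id
  expression_study(m, ph$condition, cov)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated within each set.
#'
#' @param path GMT file path.
#' @param uppercase Uppercase gene symbols (default `TRUE`).
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nms[i] <- f[1L]
    g <- unique(f[-(1:2)])
    g <- g[nzchar(g)]
    if (!length(g)) stop(sprintf("GMT line %d ('%s') has no genes", i, f[1L]))
    sets[[i]] <- if (uppercase) toupper(g) else g
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interactome edge list
#'
#' @param path Two-column TSV of gene/protein symbols (header optional,
#'   detected from the first line).
#' @param uppercase Uppercase symbols (default `TRUE`).
#' @return Simple undirected `igraph` graph (self-loops and duplicate edges
#'   removed).
#' @export
read_interactome <- function(path, uppercase = TRUE) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene|protein|node|source|target|symbol", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("interactome file needs two columns")
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  if (uppercase) { a <- toupper(a); b <- toupper(b) }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an expression matrix to TSV
#' @param values Numeric matrix with row and column names.
#' @param path Output path.
#' @param digits Significant digits to print (default 10).
#' @export
write_expression_matrix <- function(values, path, digits = 10L) {
  df <- data.frame(gene = rownames(values),
                   signif(values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: write a data.frame as TSV with fixed column order.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
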