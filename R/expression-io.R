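#' Read a gene-by-sample RPKM expression matrix
#'
#' Reads a tab-separated expression table with a header row of sample IDs and
#' gene IDs in the first column, validating it into an `expression_matrix`
#' tibble (one row per gene, one numeric column per sample). All values must
#' be finite, non-negative RPKM; gene and sample IDs must be unique.
#'
#' @param path Path to the TSV (or CSV, see `delim`) file.
#' @param role_map Optional sample-role assignment: a two-column data frame
#'   or TSV path with columns `sample_id` and `role` (`parent`, `progeny` or
#'   `unspecified`), or a named character vector. Samples not listed default
#'   to `"unspecified"`.
#' @param delim Field delimiter; tab by default, `","` for CSV exports.
#' @param na_action `"error"` (default) rejects missing cells; `"drop_genes"`
#'   removes genes with any missing value and reports how many were dropped.
#'   Complete profiles are required downstream by Pearson correlation.
#'
#' @return A tibble of class `expression_matrix`: column `gene_id` followed by
#'   one numeric column per sample, with a `sample_roles` attribute (named
#'   character vector).
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "g1\t0\t1", "g2\t2\t3", "g3\t4\t5"), path)
#' read_expression_matrix(path)
read_expression_matrix <- function(path, role_map = NULL, delim = "\t",
                                   na_action = c("error", "drop_genes")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           name_repair = "minimal", progress = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(paste0("empty or malformed expression table: ", path))
  }
  sample_ids <- names(raw)[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort(paste0("duplicated sample ID(s): ", paste(dup_s, collapse = ", ")))
  }
  gene_ids <- raw[[1L]]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort(paste0("duplicated gene ID(s): ", paste(dup_g, collapse = ", ")))
  }

  body <- raw[-1L]
  parsed <- lapply(sample_ids, function(s) {
    txt <- body[[s]]
    missing_cell <- is.na(txt) | txt == "" | txt == "NA"
    val <- suppressWarnings(as.numeric(txt))
    bad <- !missing_cell & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      abort(paste0("non-numeric value ", encodeString(txt[i], quote = "'"),
                   " at gene ", gene_ids[i], ", sample ", s))
    }
    neg <- !is.na(val) & (val < 0 | !is.finite(val))
    if (any(neg)) {
      i <- which(neg)[1L]
      abort(paste0("negative or non-finite RPKM ", txt[i],
                   " at gene ", gene_ids[i], ", sample ", s))
    }
    val
  })
  mat <- tibble::tibble(gene_id = gene_ids)
  for (i in seq_along(sample_ids)) mat[[sample_ids[i]]] <- parsed[[i]]

  n_missing_genes <- 0L
  if (anyNA(mat[-1L])) {
    if (na_action == "error") {
      miss <- which(is.na(as.matrix(mat[-1L])), arr.ind = TRUE)[1L, ]
      abort(paste0("missing value at gene ", gene_ids[miss[["row"]]],
                   ", sample ", sample_ids[miss[["col"]]],
                   " (use na_action = 'drop_genes' to discard incomplete genes)"))
    }
    keep <- !apply(is.na(as.matrix(mat[-1L])), 1L, any)
    n_missing_genes <- sum(!keep)
    inform(paste0("dropped ", n_missing_genes, " gene(s) with missing values"))
    mat <- mat[keep, ]
  }

  as_expression_matrix(mat, roles = .resolve_roles(role_map, sample_ids))
}

.resolve_roles <- function(role_map, sample_ids) {
  roles <- setNames(rep("unspecified", length(sample_ids)), sample_ids)
  if (is.null(role_map)) return(roles)
  if (is.character(role_map) && length(role_map) == 1L && file.exists(role_map)) {
    role_map <- readr::read_tsv(role_map, col_types = "cc", progress = FALSE)
  }
  if (is.data.frame(role_map)) {
    role_map <- setNames(as.character(role_map[[2L]]), as.character(role_map[[1L]]))
  }
  bad <- setdiff(unique(role_map), c("parent", "progeny", "unspecified"))
  if (length(bad)) abort(paste0("unknown sample role(s): ", paste(bad, collapse = ", ")))
  hit <- intersect(names(role_map), sample_ids)
  roles[hit] <- role_map[hit]
  roles
}

#' Validate a data frame as an expression matrix
#'
#' @param x A data frame whose first column is `gene_id` and whose remaining
#'   columns are numeric, non-negative RPKM values (one column per sample).
#' @param roles Optional named character vector mapping sample IDs to
#'   `parent` / `progeny` / `unspecified`.
#'
#' @return The validated `expression_matrix` tibble.
#' @export
as_expression_matrix <- function(x, roles = NULL) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  x <- as_tibble(x)
  if (names(x)[1L] != "gene_id") names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicated gene ID(s): ",
                 paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  vals <- as.matrix(x[-1L])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("expression values must be finite and non-negative")
  }
  samples <- names(x)[-1L]
  if (is.null(roles)) {
    roles <- attr(x, "sample_roles") %||%
      setNames(rep("unspecified", length(samples)), samples)
  }
  attr(x, "sample_roles") <- roles[samples]
  class(x) <- unique(c("expression_matrix", class(x)))
  x
}

#' Write an expression matrix to TSV
#'
#' @param x An `expression_matrix` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(unclass(x)), path, progress = FALSE)
  invisible(path)
}

#' Sample identifiers, roles and the numeric value matrix
#'
#' Small accessors used throughout the pipeline: `expr_samples()` returns the
#' sample IDs, `sample_roles()` the role assignment, and `expr_values()` the
#' numeric matrix (genes in rows, named by `gene_id`).
#'
#' @param x An `expression_matrix`.
#' @return Character vector, named character vector, or numeric matrix.
#' @export
expr_samples <- function(x) names(x)[-1L]

#' @rdname expr_samples
#' @export
sample_roles <- function(x) {
  attr(x, "sample_roles") %||%
    setNames(rep("unspecified", ncol(x) - 1L), expr_samples(x))
}

#' @rdname expr_samples
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- x$gene_id
  m
}
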