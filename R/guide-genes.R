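#' Canonical flavonoid-pathway guide roles
#'
#' The 15 flavonoid biosynthetic pathway roles used to seed the co-expression
#' screen, with their pathway branch: the general phenylpropanoid entry steps
#' (PAL1/PAL2, C4H, 4CL), the anthocyanin branch (CHS1/CHS2, CHI, F3H, F3pH,
#' DFR, ANS, UFGT), the condensed-tannin branch (LAR, ANR) and the flavonol
#' branch (FLS). `F3pH` stands for flavanone 3'-hydroxylase (F3'H).
#'
#' @return A tibble with columns `role` and `branch`.
#' @export
#' @examples
#' guide_roles()
guide_roles <- function() {
  tibble(
    role = c("PAL1", "PAL2", "C4H", "4CL", "CHS1", "CHS2", "CHI", "F3H",
             "F3pH", "FLS", "DFR", "LAR", "ANR", "ANS", "UFGT"),
    branch = c("general", "general", "general", "general", "anthocyanin",
               "anthocyanin", "anthocyanin", "anthocyanin", "anthocyanin",
               "flavonol", "anthocyanin", "tannin", "tannin", "anthocyanin",
               "anthocyanin")
  )
}

#' Build a guide-gene set from role-to-gene assignments
#'
#' @param gene_ids Named character vector mapping pathway roles (see
#'   [guide_roles()]) to gene IDs, or a data frame with columns `role` and
#'   `gene_id` (and optionally `branch`).
#'
#' @return A tibble of class `guide_gene_set` with columns `role`, `gene_id`,
#'   `branch`. Roles outside the 15 canonical labels are kept with branch
#'   `"other"` and a warning.
#' @export
#' @examples
#' roles <- guide_roles()$role
#' guide_gene_set(setNames(paste0("gene", seq_along(roles)), roles))
guide_gene_set <- function(gene_ids) {
  if (is.data.frame(gene_ids)) {
    df <- as_tibble(gene_ids)
    stopifnot(all(c("role", "gene_id") %in% names(df)))
  } else {
    df <- tibble(role = names(gene_ids), gene_id = unname(as.character(gene_ids)))
  }
  df$role <- as.character(df$role)
  if (anyDuplicated(df$role)) {
    abort(paste0("duplicated guide role(s): ",
                 paste(unique(df$role[duplicated(df$role)]), collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicated guide gene ID(s): ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  canon <- guide_roles()
  extra <- setdiff(df$role, canon$role)
  if (length(extra)) {
    warn(paste0("non-canonical guide role(s): ", paste(extra, collapse = ", ")))
  }
  if (!"branch" %in% names(df)) {
    df$branch <- canon$branch[match(df$role, canon$role)]
    df$branch[is.na(df$branch)] <- "other"
  }
  df <- df[c("role", "gene_id", "branch")]
  class(df) <- unique(c("guide_gene_set", class(df)))
  df
}

#' Read guide or candidate gene lists from TSV
#'
#' `read_guide_genes()` expects a two-column table (`role`, `gene_id`;
#' optional third column `branch`). `read_candidate_list()` expects one or
#' two columns (`gene_id`, optional `description`); an empty file yields an
#' empty, valid candidate list.
#'
#' @param path Path to a TSV file. Header row optional for candidates,
#'   detected by the literal `gene_id` in the first field.
#' @param guides Optional `guide_gene_set`; candidate IDs overlapping the
#'   guide set are a hard error (the screen requires disjoint sets).
#' @param matrix Optional `expression_matrix` for cross-validation: listed
#'   gene IDs absent from the matrix raise an error.
#'
#' @return A `guide_gene_set` tibble, or a tibble with columns `gene_id` and
#'   `description`.
#' @export
read_guide_genes <- function(path, matrix = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("role", "gene_id") %in% names(df))) {
    names(df)[1:2] <- c("role", "gene_id")
  }
  gs <- guide_gene_set(df)
  if (!is.null(matrix)) {
    missing <- setdiff(gs$gene_id, matrix$gene_id)
    if (length(missing)) {
      abort(paste0("guide gene(s) absent from matrix: ",
                   paste(missing, collapse = ", ")))
    }
  }
  gs
}

#' @rdname read_guide_genes
#' @export
read_candidate_list <- function(path, guides = NULL, matrix = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), description = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(fields[[1L]][1L], "gene_id")) fields <- fields[-1L]
  df <- tibble(
    gene_id = vapply(fields, `[`, character(1L), 1L),
    description = vapply(fields, function(f) {
      if (length(f) >= 2L) f[2L] else NA_character_
    }, character(1L))
  )
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicated candidate gene ID(s): ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  if (!is.null(guides)) {
    overlap <- intersect(df$gene_id, guides$gene_id)
    if (length(overlap)) {
      abort(paste0("candidate list overlaps guide set: ",
                   paste(overlap, collapse = ", ")))
    }
  }
  if (!is.null(matrix)) {
    missing <- setdiff(df$gene_id, matrix$gene_id)
    if (length(missing)) {
      abort(paste0("candidate gene(s) absent from matrix: ",
                   paste(missing, collapse = ", ")))
    }
  }
  df
}
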