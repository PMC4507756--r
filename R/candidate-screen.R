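#' Screen candidate genes by positive links to the guide set
#'
#' The guilt-by-association screen: each candidate's expression profile is
#' correlated against every guide role, positive links (Pearson `r > r_min`,
#' two-tailed `P < p_max`) are counted, and candidates with at least
#' `min_links` links are retained — the rule that a gene sharing four or more
#' positive correlations with pathway members is likely functionally
#' connected to the pathway. Isoform roles (e.g. PAL1 and PAL2) count as
#' separate links.
#'
#' Candidates absent from the matrix are skipped with a message (annotation
#' pipelines routinely list unexpressed genes); candidates overlapping the
#' guide set are an error.
#'
#' @param x An `expression_matrix`.
#' @param guides A `guide_gene_set`.
#' @param candidates A tibble with columns `gene_id` (+ optional
#'   `description`), or a character vector of gene IDs.
#' @param min_links Minimum number of positive guide links to retain a
#'   candidate (default 4).
#' @inheritParams build_guide_network
#'
#' @return A tibble of class `candidate_screen`, one row per retained
#'   candidate sorted by `n_positive_links` (descending) then `gene_id`:
#'   `gene_id`, `n_positive_links`, `linked_roles` (comma-separated),
#'   `rpkm_max`, `rpkm_min`, `rpkm_mean` (across all samples, untransformed),
#'   `description`. Attributes: `link_counts` (per-candidate counts for the
#'   full list), `link_matrix` (candidate x role tibble of r values for
#'   positive links, the per-gene correlation report), `n_skipped`, `config`.
#' @export
screen_candidates <- function(x, guides, candidates, min_links = 4L,
                              r_min = 0.65, p_max = 0.05, df_override = NULL,
                              transform = c("none", "log2p1")) {
  .check_network_cfg(r_min, p_max)
  if (nrow(guides) == 0L) abort("empty guide set")
  if (min_links < 1L || min_links > nrow(guides)) {
    abort("min_links must be between 1 and the number of guide roles")
  }
  if (is.character(candidates)) candidates <- tibble(gene_id = candidates)
  if (!"description" %in% names(candidates)) candidates$description <- NA_character_
  overlap <- intersect(candidates$gene_id, guides$gene_id)
  if (length(overlap)) {
    abort(paste0("candidate list overlaps guide set: ",
                 paste(overlap, collapse = ", ")))
  }
  present <- candidates$gene_id %in% x$gene_id
  n_skipped <- sum(!present)
  if (n_skipped) {
    inform(paste0("skipping ", n_skipped, " candidate(s) absent from the matrix"))
  }
  cand <- candidates[present, ]

  raw <- expr_values(x)
  v <- .resolve_transform(raw, match.arg(transform))
  n <- ncol(v)
  df <- .check_df(df_override, n)
  gmat <- t(v[guides$gene_id, , drop = FALSE])
  cmat <- t(v[cand$gene_id, , drop = FALSE])
  g_ok <- apply(gmat, 2L, sd) > 0
  c_ok <- apply(cmat, 2L, sd) > 0
  rmat <- suppressWarnings(cor(cmat, gmat))     # candidates x roles
  rmat[!c_ok, ] <- NA_real_
  rmat[, !g_ok] <- NA_real_
  pmat <- .r_to_tp(rmat, df)$p
  pos <- !is.na(rmat) & rmat > r_min & !is.na(pmat) & pmat < p_max
  n_links <- rowSums(pos)

  link_counts <- tibble(gene_id = cand$gene_id,
                        n_positive_links = as.integer(n_links))
  keep <- which(n_links >= min_links)
  linked_roles <- vapply(keep, function(i) {
    paste(guides$role[pos[i, ]], collapse = ",")
  }, character(1L))
  res <- tibble(
    gene_id = cand$gene_id[keep],
    n_positive_links = as.integer(n_links[keep]),
    linked_roles = linked_roles,
    rpkm_max = unname(apply(raw[cand$gene_id[keep], , drop = FALSE], 1L, max)),
    rpkm_min = unname(apply(raw[cand$gene_id[keep], , drop = FALSE], 1L, min)),
    rpkm_mean = unname(rowMeans(raw[cand$gene_id[keep], , drop = FALSE])),
    description = cand$description[keep]
  )
  res <- res[order(-res$n_positive_links, res$gene_id), ]

  link_matrix <- as_tibble(rmat[keep, , drop = FALSE])
  names(link_matrix) <- guides$role
  link_matrix <- dplyr::bind_cols(tibble(gene_id = cand$gene_id[keep]), link_matrix)
  link_matrix <- link_matrix[match(res$gene_id, link_matrix$gene_id), ]

  attr(res, "link_counts") <- link_counts
  attr(res, "link_matrix") <- link_matrix
  attr(res, "n_skipped") <- n_skipped
  attr(res, "config") <- list(min_links = as.integer(min_links), r_min = r_min,
                              p_max = p_max, df = df, n_obs = n,
                              transform = match.arg(transform))
  class(res) <- unique(c("candidate_screen", class(res)))
  res
}

#' Count positive links from printed per-role correlation coefficients
#'
#' Reproduces a retained candidate's link count from its per-role correlation
#' row (as printed in a correlation report: a coefficient where the link is
#' positive, absent otherwise): the number of present coefficients strictly
#' greater than `r_min`. Significance is taken as already satisfied for
#' printed entries — at 11 df the critical r for two-tailed P = 0.05 is about
#' 0.553, so every coefficient above 0.65 clears it.
#'
#' @param row A named numeric vector (role -> r, `NA` for absent links) or a
#'   data frame with columns `role` and `r`.
#' @param r_min Correlation threshold, strict `>`.
#' @return Integer link count.
#' @export
#' @examples
#' count_positive_links(c(PAL2 = 0.72, CHS1 = 0.80, CHS2 = 0.75, F3H = 0.69))
count_positive_links <- function(row, r_min = 0.65) {
  if (is.data.frame(row)) row <- setNames(row$r, row$role)
  row <- as.numeric(row)
  present <- !is.na(row)
  if (any(abs(row[present]) > 1)) {
    abort("correlation coefficients must lie in [-1, 1]")
  }
  sum(row[present] > r_min)
}

#' @export
print.candidate_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Candidate screen:", nrow(x), "candidate(s) with >=", cfg$min_links,
      sprintf("positive links (r > %g, P < %g at %d df)\n",
              cfg$r_min, cfg$p_max, cfg$df))
  NextMethod()
}

#' Per-candidate guide-link correlation matrix
#'
#' @param x A `candidate_screen` result.
#' @return A tibble, one row per retained candidate, one column per guide
#'   role holding the Pearson r (all evaluated values, positive or not).
#' @export
screen_link_matrix <- function(x) attr(x, "link_matrix")

#' Write a candidate screen report to TSV
#'
#' Columns mirror the candidate-table layout: `n_positive_links`, `gene_id`,
#' `rpkm_max`, `rpkm_min`, `description`.
#'
#' @param x A `candidate_screen` result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(x, path) {
  out <- tibble(n_positive_links = x$n_positive_links, gene_id = x$gene_id,
                rpkm_max = x$rpkm_max, rpkm_min = x$rpkm_min,
                description = x$description)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
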