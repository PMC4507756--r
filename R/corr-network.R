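#' Pearson correlation with two-tailed t-test significance
#'
#' Computes the Pearson product-moment correlation between two expression
#' profiles together with its t statistic, degrees of freedom and two-tailed
#' P-value, `t = r * sqrt(df) / sqrt(1 - r^2)` referred to the t
#' distribution. By default `df = n - 2`; `df_override` evaluates the
#' P-value at a stated df instead (the replication profile for datasets whose
#' reported df differs from the sample count implies).
#'
#' A zero-variance profile does not crash: the correlation is flagged
#' undefined (`defined = FALSE`, statistics `NA`) and such results never form
#' network edges.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param df_override Optional positive integer df at which to evaluate the
#'   P-value.
#'
#' @return A one-row tibble: `r`, `t_stat`, `df`, `p_two_tailed`, `n_obs`,
#'   `defined`.
#' @export
#' @examples
#' pearson_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
#' pearson_test(c(1, 2, 3), c(2, 4, 6)) # perfect correlation, p = 0
pearson_test <- function(x, y, df_override = NULL) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("at least 3 observations are required")
  df <- .check_df(df_override, n)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, t_stat = NA_real_, df = df,
                  p_two_tailed = NA_real_, n_obs = n, defined = FALSE))
  }
  r <- cor(x, y)
  tp <- .r_to_tp(r, df)
  tibble(r = r, t_stat = tp$t, df = df, p_two_tailed = tp$p,
         n_obs = n, defined = TRUE)
}

.check_df <- function(df_override, n) {
  if (is.null(df_override)) return(n - 2L)
  if (!is.numeric(df_override) || length(df_override) != 1L || df_override < 1) {
    abort("df_override must be a positive integer")
  }
  as.integer(df_override)
}

# t statistic and two-tailed P for a vector of r at fixed df; |r| = 1 maps
# to t = +/-Inf and the limiting P of 0.
.r_to_tp <- function(r, df) {
  t <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df) / sqrt(1 - r^2))
  list(t = t, p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}

#' Critical correlation coefficient for a two-tailed t-test
#'
#' The smallest |r| significant at level `alpha` (two-tailed) for the given
#' degrees of freedom: `r_crit = t_crit / sqrt(df + t_crit^2)` with
#' `t_crit = qt(1 - alpha/2, df)`. At df = 11 and alpha = 0.05 this is about
#' 0.553, below the 0.65 hard threshold — so at that df the r-threshold is
#' the binding condition of the positive-edge rule.
#'
#' @param df Degrees of freedom (positive).
#' @param alpha Two-tailed significance level.
#' @return The critical r as a single number.
#' @export
critical_r <- function(df, alpha = 0.05) {
  tcrit <- qt(1 - alpha / 2, df = df)
  tcrit / sqrt(df + tcrit^2)
}

.resolve_transform <- function(values, transform = c("none", "log2p1")) {
  transform <- match.arg(transform)
  if (transform == "log2p1") log2(values + 1) else values
}

.check_network_cfg <- function(r_min, p_max) {
  if (!is.numeric(r_min) || r_min <= 0 || r_min >= 1) abort("r_min must be in (0, 1)")
  if (!is.numeric(p_max) || p_max <= 0 || p_max >= 1) abort("p_max must be in (0, 1)")
}

#' Build the guide-gene correlation network
#'
#' Evaluates every unordered pair of guide genes on the expression matrix and
#' retains positive edges: pairs with Pearson `r > r_min` and two-tailed
#' `P < p_max` (both strict). Negative and sub-threshold correlations are
#' reported in the edge table with `positive = FALSE` but never enter the
#' network degree counts. Undefined correlations (a zero-variance guide) are
#' kept as a distinct `defined = FALSE` state rather than silently as r = 0.
#'
#' @param x An `expression_matrix` containing every guide gene.
#' @param guides A `guide_gene_set` (see [guide_gene_set()]).
#' @param r_min Positive-edge correlation threshold (default 0.65, strict).
#' @param p_max Positive-edge significance threshold (default 0.05, strict).
#' @param df_override Optional df at which P-values are evaluated (see
#'   [pearson_test()]).
#' @param transform `"none"` correlates RPKM as loaded; `"log2p1"` correlates
#'   log2(RPKM+1).
#'
#' @return An object of class `correlation_network`: list with `edges` (all
#'   evaluated pairs: `role_a`, `role_b`, `gene_a`, `gene_b`, `r`, `t_stat`,
#'   `df`, `p_two_tailed`, `defined`, `positive`), `nodes` (`role`,
#'   `gene_id`, `degree` over positive edges) and `config`.
#' @export
build_guide_network <- function(x, guides, r_min = 0.65, p_max = 0.05,
                                df_override = NULL,
                                transform = c("none", "log2p1")) {
  .check_network_cfg(r_min, p_max)
  missing <- setdiff(guides$gene_id, x$gene_id)
  if (length(missing)) {
    roles <- guides$role[match(missing, guides$gene_id)]
    abort(paste0("guide gene(s) missing from matrix: ",
                 paste(paste0(roles, " (", missing, ")"), collapse = ", ")))
  }
  v <- .resolve_transform(expr_values(x), match.arg(transform))
  g <- t(v[guides$gene_id, , drop = FALSE])
  n <- nrow(g)
  df <- .check_df(df_override, n)

  pairs <- which(upper.tri(diag(nrow(guides))), arr.ind = TRUE)
  sds <- apply(g, 2L, sd)
  rmat <- suppressWarnings(cor(g))
  r <- rmat[pairs]
  defined <- sds[pairs[, 1L]] > 0 & sds[pairs[, 2L]] > 0
  r[!defined] <- NA_real_
  tp <- .r_to_tp(r, df)
  edges <- tibble(
    role_a = guides$role[pairs[, 1L]], role_b = guides$role[pairs[, 2L]],
    gene_a = guides$gene_id[pairs[, 1L]], gene_b = guides$gene_id[pairs[, 2L]],
    r = r, t_stat = tp$t, df = df, p_two_tailed = tp$p,
    defined = defined,
    positive = defined & !is.na(r) & r > r_min &
      !is.na(tp$p) & tp$p < p_max
  )
  pos <- edges[edges$positive, ]
  degree <- vapply(guides$role, function(ro) {
    sum(pos$role_a == ro) + sum(pos$role_b == ro)
  }, integer(1L))
  nodes <- tibble(role = guides$role, gene_id = guides$gene_id,
                  branch = guides$branch, degree = unname(degree))
  structure(
    list(edges = edges, nodes = nodes,
         config = list(r_min = r_min, p_max = p_max, df = df,
                       n_obs = n, transform = match.arg(transform))),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network:", nrow(x$nodes), "nodes,",
      sum(x$edges$positive), "positive edges",
      sprintf("(r > %g, two-tailed P < %g at %d df)\n",
              x$config$r_min, x$config$p_max, x$config$df))
  invisible(x)
}

#' Correlate one gene against every guide role
#'
#' The per-candidate computation of the guilt-by-association screen: one
#' Pearson test per guide role, with positivity flags under the hard
#' threshold rule (`r > r_min`, two-tailed `P < p_max`).
#'
#' @param gene A gene ID present in the matrix.
#' @inheritParams build_guide_network
#' @return A tibble with one row per guide role: `role`, `gene_id` (the
#'   guide's), `r`, `t_stat`, `df`, `p_two_tailed`, `defined`, `positive`.
#' @export
correlate_to_guides <- function(x, guides, gene, r_min = 0.65, p_max = 0.05,
                                df_override = NULL,
                                transform = c("none", "log2p1")) {
  .check_network_cfg(r_min, p_max)
  if (!gene %in% x$gene_id) abort(paste0("gene not in matrix: ", gene))
  missing <- setdiff(guides$gene_id, x$gene_id)
  if (length(missing)) {
    abort(paste0("guide gene(s) missing from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  v <- .resolve_transform(expr_values(x), match.arg(transform))
  target <- v[gene, ]
  df <- .check_df(df_override, length(target))
  res <- purrr::map_dfr(seq_len(nrow(guides)), function(i) {
    out <- pearson_test(target, v[guides$gene_id[i], ], df_override = df)
    out$role <- guides$role[i]
    out$gene_id <- guides$gene_id[i]
    out
  })
  res$positive <- res$defined & !is.na(res$r) & res$r > r_min &
    !is.na(res$p_two_tailed) & res$p_two_tailed < p_max
  res[c("role", "gene_id", "r", "t_stat", "df", "p_two_tailed",
        "defined", "positive")]
}

#' Write or read a network edge list
#'
#' TSV edge lists carry the positive edges with columns `gene_a`, `gene_b`,
#' `r`, `p`, `df`; GraphML export (via igraph) stores r as the edge `weight`
#' attribute, so line thickness in downstream renderers can track correlation
#' strength.
#'
#' @param network A `correlation_network`.
#' @param path Output (input) file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `write_edge_list()`: `path`, invisibly. `read_edge_list()`: a
#'   tibble with the TSV columns.
#' @export
write_edge_list <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  pos <- network$edges[network$edges$positive, ]
  if (format == "tsv") {
    out <- tibble(gene_a = pos$gene_a, gene_b = pos$gene_b, r = pos$r,
                  p = pos$p_two_tailed, df = pos$df)
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    gr <- igraph::graph_from_data_frame(
      data.frame(from = pos$gene_a, to = pos$gene_b, weight = pos$r),
      directed = FALSE,
      vertices = data.frame(name = network$nodes$gene_id,
                            role = network$nodes$role)
    )
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", r = "d", p = "d", df = "i"
  ), progress = FALSE)
}
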