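# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths and stats::cor/cor.test shortcuts where the thing
# under test is the correlation machinery itself.

# Pearson r by direct evaluation of sum((x-xbar)(y-ybar)) / sqrt(...)
brute_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# two-tailed P from the t transform at the given df
brute_p <- function(r, df) {
  t <- r * sqrt(df) / sqrt(1 - r^2)
  2 * pt(abs(t), df = df, lower.tail = FALSE)
}

# brute-force positive-edge set over the rows of a gene x sample value
# matrix: plain double loop, direct-formula r, strict thresholds
brute_edges <- function(values, r_min = 0.65, p_max = 0.05,
                        df_override = NULL) {
  g <- nrow(values)
  n <- ncol(values)
  df <- if (is.null(df_override)) n - 2L else df_override
  out <- character()
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      xi <- values[i, ]
      xj <- values[j, ]
      if (sd(xi) == 0 || sd(xj) == 0) next
      r <- brute_r(xi, xj)
      if (abs(r) >= 1) {
        p <- 0
      } else {
        p <- brute_p(r, df)
      }
      if (r > r_min && p < p_max) {
        out <- c(out, paste(rownames(values)[i], rownames(values)[j], sep = "|"))
      }
    }
  }
  sort(out)
}

# permutation null for the two-tailed Pearson test: proportion of label
# permutations with |r| at least the observed |r| (vectorised over a
# permutation matrix for speed)
perm_pvalue <- function(x, y, n_perm = 1e4) {
  robs <- abs(brute_r(x, y))
  perm <- replicate(n_perm, sample(y))
  rperm <- abs(as.vector(cor(x, perm)))
  mean(rperm >= robs - 1e-12)
}

# small expression matrix straight from a value matrix
em_from_matrix <- function(values, sample_ids = NULL, roles = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  df <- tibble::tibble(gene_id = rownames(values))
  for (j in seq_along(sample_ids)) df[[sample_ids[j]]] <- values[, j]
  as_expression_matrix(df, roles = roles)
}

# guide set over arbitrary gene ids using the first k canonical roles
toy_guides <- function(gene_ids) {
  roles <- guide_roles()$role[seq_along(gene_ids)]
  guide_gene_set(setNames(gene_ids, roles))
}
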