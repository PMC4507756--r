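#' Count and filter expressed genes by an RPKM floor
#'
#' A transcript counts as expressed in a sample when its RPKM is strictly
#' above `rpkm_min` (default 0.5; a value of exactly 0.5 is not expressed).
#' `count_expressed()` tallies expressed genes per sample — the per-genotype
#' "number of expressed genes" statistic. `filter_expressed()` returns the
#' matrix restricted to genes expressed in at least one sample
#' (`scope = "any_sample"`) or, with `scope = "per_sample"`, the matrix
#' unchanged (the per-sample tally is not a gene filter); either way the
#' per-sample counts travel along as the `n_expressed` attribute.
#'
#' @param x An `expression_matrix`.
#' @param rpkm_min Expression floor in RPKM units; strict `>`.
#' @param scope `"any_sample"` keeps genes expressed in >= 1 sample;
#'   `"per_sample"` leaves the gene set untouched and only reports counts.
#'
#' @return `count_expressed()`: a tibble with columns `sample_id`,
#'   `n_expressed`. `filter_expressed()`: an `expression_matrix` with
#'   attribute `n_expressed` (that same tibble).
#' @export
#' @examples
#' m <- as_expression_matrix(tibble::tibble(
#'   gene_id = c("g1", "g2"), S1 = c(0.4, 3), S2 = c(2, 0)
#' ))
#' count_expressed(m)
#' filter_expressed(m)
count_expressed <- function(x, rpkm_min = 0.5) {
  v <- expr_values(x)
  tibble(sample_id = colnames(v),
         n_expressed = unname(colSums(v > rpkm_min)))
}

#' @rdname count_expressed
#' @export
filter_expressed <- function(x, rpkm_min = 0.5,
                             scope = c("any_sample", "per_sample")) {
  scope <- match.arg(scope)
  stopifnot(rpkm_min >= 0)
  counts <- count_expressed(x, rpkm_min)
  if (scope == "any_sample") {
    keep <- rowSums(expr_values(x) > rpkm_min) >= 1L
    x <- as_expression_matrix(x[keep, ], roles = sample_roles(x))
  }
  attr(x, "n_expressed") <- counts
  x
}

#' Count differentially expressed genes between two genotypes
#'
#' A gene is counted up-regulated in the query genotype when its RPKM ratio
#' over the comparator is strictly greater than `fold` (default 2, i.e. the
#' ">2-fold" rule), and down-regulated when the reciprocal ratio is. Only
#' genes expressed (RPKM > `rpkm_min`) in at least one of the two samples
#' enter the tally, which avoids 0/0 comparisons among doubly-silent genes.
#' With `pseudocount = 0` a gene with zero comparator RPKM but positive query
#' RPKM has an infinite ratio and counts as up; supply a positive
#' `pseudocount` (e.g. 0.5) to damp zero-denominator calls instead.
#'
#' @param x An `expression_matrix`.
#' @param query,comparator Sample IDs to compare (must differ).
#' @param fold Fold-change threshold, strict `>`; must exceed 1.
#' @param pseudocount Added to both profiles before forming ratios.
#' @param rpkm_min Expression floor defining the tested gene universe.
#'
#' @return A one-row tibble: `query`, `comparator`, `n_up`, `n_down`,
#'   `n_tested`, `fold`, `pseudocount`.
#' @export
#' @examples
#' m <- as_expression_matrix(tibble::tibble(
#'   gene_id = paste0("g", 1:3), A = c(10, 8, 1), B = c(4, 4, 4)
#' ))
#' count_deg(m, "A", "B")
count_deg <- function(x, query, comparator, fold = 2, pseudocount = 0,
                      rpkm_min = 0.5) {
  if (identical(query, comparator)) abort("query and comparator must differ")
  if (!is.numeric(fold) || fold <= 1) abort("fold threshold must exceed 1")
  v <- expr_values(x)
  for (s in c(query, comparator)) {
    if (!s %in% colnames(v)) abort(paste0("sample not in matrix: ", s))
  }
  q <- v[, query]
  c_ <- v[, comparator]
  tested <- q > rpkm_min | c_ > rpkm_min
  qs <- q[tested] + pseudocount
  cs <- c_[tested] + pseudocount
  # 0-denominator ratios become Inf (counts as up) or NaN for 0/0 (excluded
  # from both tails); NaN cannot occur once the expressed filter is applied
  # with rpkm_min >= 0 and pseudocount = 0 unless rpkm_min = 0.
  up <- qs / cs
  down <- cs / qs
  tibble(
    query = query, comparator = comparator,
    n_up = sum(up > fold, na.rm = TRUE),
    n_down = sum(down > fold, na.rm = TRUE),
    n_tested = sum(tested),
    fold = fold, pseudocount = pseudocount
  )
}

#' Differential-expression counts of every genotype against comparators
#'
#' Convenience wrapper producing the population summary table: one row per
#' (sample, comparator) pair, by default every sample against each parent.
#'
#' @param x An `expression_matrix`.
#' @param comparators Sample IDs to compare against; defaults to samples with
#'   role `"parent"`.
#' @inheritParams count_deg
#' @return A tibble of [count_deg()] rows.
#' @export
deg_table <- function(x, comparators = NULL, fold = 2, pseudocount = 0,
                      rpkm_min = 0.5) {
  roles <- sample_roles(x)
  if (is.null(comparators)) comparators <- names(roles)[roles == "parent"]
  if (length(comparators) == 0L) abort("no comparator samples given or marked as parents")
  pairs <- expand.grid(query = expr_samples(x), comparator = comparators,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query != pairs$comparator, ]
  purrr::pmap_dfr(pairs, function(query, comparator) {
    count_deg(x, query, comparator, fold = fold, pseudocount = pseudocount,
              rpkm_min = rpkm_min)
  })
}

#' Hierarchical clustering of genotypes by expression profile
#'
#' Clusters the samples of an expression matrix, by default with correlation
#' distance (1 - Pearson r between log2(RPKM+1) profiles) and average
#' linkage — the conventional choice for expression-profile dendrograms.
#' `euclidean_log` uses Euclidean distance on the log2(RPKM+1) profiles.
#'
#' @param x An `expression_matrix` with at least two samples.
#' @param metric `"correlation"` or `"euclidean_log"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#'
#' @return An object of class `genotype_dendrogram`: a list with elements
#'   `hclust` (the [stats::hclust] tree), `metric` and `linkage`.
#' @export
cluster_genotypes <- function(x, metric = c("correlation", "euclidean_log"),
                              linkage = c("average", "complete", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  v <- log2(expr_values(x) + 1)
  if (ncol(v) < 2L) abort("clustering needs at least two samples")
  d <- switch(metric,
    correlation = as.dist(1 - cor(v)),
    euclidean_log = stats::dist(t(v))
  )
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage),
            class = "genotype_dendrogram")
}

#' @export
print.genotype_dendrogram <- function(x, ...) {
  cat("Genotype dendrogram:", length(x$hclust$labels), "samples;",
      x$metric, "distance,", x$linkage, "linkage\n")
  invisible(x)
}

#' Export a genotype dendrogram as a Newick tree
#'
#' @param x A `genotype_dendrogram`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "genotype_dendrogram"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
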