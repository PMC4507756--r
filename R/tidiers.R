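#' Tidy a correlation network into its edge table
#'
#' @param x A `correlation_network`.
#' @param positive_only Keep only positive edges (default `FALSE`: every
#'   evaluated pair with its `positive` flag).
#' @param ... Unused.
#' @return A tibble of edges.
#' @export
tidy.correlation_network <- function(x, positive_only = FALSE, ...) {
  e <- x$edges
  if (positive_only) e <- e[e$positive, ]
  e
}

#' @rdname tidy.correlation_network
#' @export
glance.correlation_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_pairs = nrow(x$edges),
    n_positive_edges = sum(x$edges$positive),
    n_undefined = sum(!x$edges$defined),
    max_degree = max(x$nodes$degree),
    r_min = x$config$r_min, p_max = x$config$p_max,
    df = x$config$df, n_obs = x$config$n_obs,
    transform = x$config$transform
  )
}

#' Tidy methods for screen and qPCR results
#'
#' `candidate_screen` and `fold_change_result` objects are already tibbles;
#' `tidy()` strips their class decoration, and `glance()` gives one-row
#' summaries (screen size and thresholds; fold-change range and baseline).
#'
#' @param x A `candidate_screen` or `fold_change_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.candidate_screen <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.candidate_screen
#' @export
glance.candidate_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- attr(x, "link_counts")
  tibble(
    n_retained = nrow(x),
    n_candidates_tested = nrow(counts),
    n_skipped = attr(x, "n_skipped"),
    min_links = cfg$min_links, r_min = cfg$r_min, p_max = cfg$p_max,
    df = cfg$df
  )
}

#' @rdname tidy.candidate_screen
#' @export
tidy.fold_change_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.candidate_screen
#' @export
glance.fold_change_result <- function(x, ...) {
  tr <- x$fold_change[x$group == "treatment"]
  tibble(
    target = attr(x, "target"),
    reference = attr(x, "reference"),
    n_treatment = sum(x$group == "treatment"),
    n_control = sum(x$group == "control"),
    mean_fold_treatment = mean(tr),
    min_fold_treatment = if (length(tr)) min(tr) else NA_real_,
    max_fold_treatment = if (length(tr)) max(tr) else NA_real_,
    control_mean_delta_ct = attr(x, "control_mean_delta_ct")
  )
}
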