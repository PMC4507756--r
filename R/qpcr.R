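#' Relative quantification by the 2^-ddCt method
#'
#' Livak-style relative quantification from a long-format Ct table. Replicate
#' Cts are averaged per (sample, gene); each sample's dCt is the target mean
#' Ct minus the reference-gene mean Ct (so any per-sample cycle shift common
#' to target and reference cancels); ddCt is the sample dCt minus the mean
#' dCt of the control group; the fold change is `2^-ddCt`. Replicate spread
#' is propagated to the dCt scale as `sqrt(sd_target^2 + sd_reference^2)`.
#'
#' Control samples are reported too (their fold changes are relative to the
#' control-group mean), which is what the group significance test consumes.
#'
#' @param ct A data frame with columns `sample_id`, `gene_id`, `replicate`,
#'   `ct` (threshold cycles, finite and positive).
#' @param target Target gene ID.
#' @param reference Reference (normalizer) gene ID; must be measured in every
#'   sample.
#' @param groups Sample-to-group assignment: named character vector or a data
#'   frame with columns `sample_id`, `group`, values `"treatment"` /
#'   `"control"`.
#'
#' @return A tibble of class `fold_change_result`, one row per sample:
#'   `gene_id`, `sample_id`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`, `sd` (replicate SD on the dCt scale), `n_replicates`.
#'   Attributes `target`, `reference`, `control_mean_delta_ct`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("T1", "C1"), each = 2),
#'   gene_id = rep(c("tgt", "ref"), 2),
#'   replicate = 1L,
#'   ct = c(20, 18, 24, 18)
#' )
#' delta_delta_ct(ct, "tgt", "ref", c(T1 = "treatment", C1 = "control"))
delta_delta_ct <- function(ct, target, reference, groups) {
  ct <- .validate_ct(ct)
  groups <- .resolve_groups(groups)
  samples <- unique(ct$sample_id)
  missing_grp <- setdiff(samples, names(groups))
  if (length(missing_grp)) {
    abort(paste0("no group assignment for sample(s): ",
                 paste(missing_grp, collapse = ", ")))
  }
  for (g in c(target, reference)) {
    have <- unique(ct$sample_id[ct$gene_id == g])
    lack <- setdiff(samples, have)
    if (length(lack)) {
      abort(paste0(if (g == reference) "reference" else "target", " gene ", g,
                   " not measured in sample(s): ", paste(lack, collapse = ", ")))
    }
  }
  agg <- ct |>
    dplyr::filter(.data$gene_id %in% c(target, reference)) |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::summarise(mean_ct = mean(.data$ct), sd_ct = sd(.data$ct),
                     n = dplyr::n(), .groups = "drop")
  agg$sd_ct[is.na(agg$sd_ct)] <- 0  # single replicate
  wide <- agg |>
    tidyr::pivot_wider(names_from = "gene_id",
                       values_from = c("mean_ct", "sd_ct", "n"))
  res <- tibble(
    gene_id = target,
    sample_id = wide$sample_id,
    group = unname(groups[wide$sample_id]),
    delta_ct = wide[[paste0("mean_ct_", target)]] -
      wide[[paste0("mean_ct_", reference)]],
    sd = sqrt(wide[[paste0("sd_ct_", target)]]^2 +
                wide[[paste0("sd_ct_", reference)]]^2),
    n_replicates = pmin(wide[[paste0("n_", target)]],
                        wide[[paste0("n_", reference)]])
  )
  n_control <- sum(res$group == "control")
  if (n_control == 0L) abort("no control samples in the group map")
  if (n_control == 1L) warn("only one control sample; its dCt is the baseline")
  baseline <- mean(res$delta_ct[res$group == "control"])
  res$delta_delta_ct <- res$delta_ct - baseline
  res$fold_change <- 2^(-res$delta_delta_ct)
  res <- res[c("gene_id", "sample_id", "group", "delta_ct", "delta_delta_ct",
               "fold_change", "sd", "n_replicates")]
  attr(res, "target") <- target
  attr(res, "reference") <- reference
  attr(res, "control_mean_delta_ct") <- baseline
  class(res) <- unique(c("fold_change_result", class(res)))
  res
}

.validate_ct <- function(ct) {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "gene_id", "replicate", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  as_tibble(ct)
}

.resolve_groups <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), as.character(groups$sample_id))
  }
  bad <- setdiff(unique(groups), c("treatment", "control"))
  if (length(bad)) {
    abort(paste0("groups must be 'treatment' or 'control'; got: ",
                 paste(bad, collapse = ", ")))
  }
  groups
}

#' Significance of relative-abundance differences between groups
#'
#' Tests per-sample relative transcript abundance (log2 fold change, i.e.
#' `-ddCt`) across groups: a two-sided Welch t-test of all treatment samples
#' against all controls, or a one-way ANOVA across three or more groups
#' (e.g. developmental stages, using the `group` column of `results`).
#'
#' Degenerate inputs — all values identical within both groups — do not
#' crash: the P-value is reported as the limiting value (1 when group means
#' coincide, 0 otherwise) with `degenerate = TRUE`.
#'
#' @param results A `fold_change_result` (or any data frame with columns
#'   `group` and `delta_delta_ct` or `log2_fold`).
#' @param method `"t_test"` (Welch, treatment vs control) or `"anova"`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
group_significance <- function(results, method = c("t_test", "anova")) {
  method <- match.arg(method)
  val <- if ("delta_delta_ct" %in% names(results)) {
    -results$delta_delta_ct
  } else if ("log2_fold" %in% names(results)) {
    results$log2_fold
  } else {
    abort("results must carry delta_delta_ct or log2_fold")
  }
  grp <- results$group
  if (method == "t_test") {
    a <- val[grp == "treatment"]
    b <- val[grp == "control"]
    if (length(a) < 2L || length(b) < 2L) {
      abort("need at least 2 values per group for the t-test")
    }
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(method = "welch_t", statistic = NA_real_, df = NA_real_,
                    p_value = if (mean(a) == mean(b)) 1 else 0,
                    degenerate = TRUE))
    }
    tt <- t.test(a, b)
    tibble(method = "welch_t", statistic = unname(tt$statistic),
           df = unname(tt$parameter), p_value = tt$p.value,
           degenerate = FALSE)
  } else {
    groups <- unique(grp)
    if (length(groups) < 3L) abort("ANOVA needs at least 3 groups")
    if (any(table(grp) < 2L)) abort("need at least 2 values per group")
    if (sd(val) == 0) {
      return(tibble(method = "anova", statistic = NA_real_, df = NA_real_,
                    p_value = 1, degenerate = TRUE))
    }
    fit <- aov(val ~ factor(grp))
    s <- summary(fit)[[1L]]
    tibble(method = "anova", statistic = s[["F value"]][1L],
           df = s[["Df"]][1L], p_value = s[["Pr(>F)"]][1L],
           degenerate = FALSE)
  }
}

#' Primer amplification efficiency from a serial dilution
#'
#' Least-squares regression of Ct on log10 template dilution; the
#' amplification efficiency is `10^(-1/slope) - 1`, so perfect doubling per
#' cycle corresponds to a slope of `-1/log10(2)` (about -3.32) and an
#' efficiency of 1 (100%).
#'
#' @param series A data frame with columns `log10_dilution` and `ct`
#'   (at least 3 points).
#' @return A one-row tibble: `slope`, `intercept`, `efficiency`, `r_squared`,
#'   `n_points`.
#' @export
#' @examples
#' d <- tibble::tibble(log10_dilution = -(0:4),
#'                     ct = 20 + 3.3219 * (0:4))
#' primer_efficiency(d)
primer_efficiency <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("log10_dilution", "ct") %in% names(series)))
  if (nrow(series) < 3L) abort("need at least 3 dilution points")
  if (sd(series$log10_dilution) == 0) abort("dilutions have zero variance")
  fit <- lm(ct ~ log10_dilution, data = series)
  slope <- unname(stats::coef(fit)[2L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((series$ct - mean(series$ct))^2)
  tibble(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    efficiency = 10^(-1 / slope) - 1,
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    n_points = nrow(series)
  )
}

#' Read a long-format Ct table from TSV
#'
#' @param path TSV with columns `sample_id`, `gene_id`, `replicate`, `ct`.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  .validate_ct(readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", gene_id = "c", replicate = "i", ct = "d"
  ), progress = FALSE))
}
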