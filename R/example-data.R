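#' Packaged example: per-role correlations of three strawberry TF candidates
#'
#' Ships the reported per-guide-role Pearson coefficients for three
#' flavonoid-associated strawberry transcription factors — FaTCP11
#' (gene09614), FaPCL1-like (gene17673) and FaSCL8 (gene13212) — together
#' with the per-role RPKM range of the guide transcripts in the ripe-fruit
#' population they were screened in. Coefficients are printed only where the
#' link passed the hard threshold rule (r > 0.65, two-tailed P < 0.05); `NA`
#' marks absent links. Feeding each candidate column to
#' [count_positive_links()] reproduces the published link counts (5, 6, 4).
#'
#' @return A tibble with columns `role`, `FaTCP11`, `FaPCL1_like`, `FaSCL8`,
#'   `rpkm_min`, `rpkm_max`, `rpkm_avg`.
#' @export
#' @examples
#' tbl <- tf_correlation_example()
#' count_positive_links(setNames(tbl$FaTCP11, tbl$role))
tf_correlation_example <- function() {
  path <- system.file("extdata", "flavonoid_tf_correlations.tsv",
                      package = "coexscreen", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    role = "c", FaTCP11 = "d", FaPCL1_like = "d", FaSCL8 = "d",
    rpkm_min = "d", rpkm_max = "d", rpkm_avg = "d"
  ), progress = FALSE)
}
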