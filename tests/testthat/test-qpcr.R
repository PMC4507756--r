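make_ct <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(sample_id = r[[1]], gene_id = r[[2]],
                   replicate = seq_along(r[[3]]), ct = r[[3]])
  }))
}

test_that("the hand-worked ddCt example gives fold change 16", {
  ct <- make_ct(list(
    list("T1", "tgt", 20), list("T1", "ref", 18),
    list("C1", "tgt", 24), list("C1", "ref", 18)
  ))
  expect_warning(
    res <- delta_delta_ct(ct, "tgt", "ref", c(T1 = "treatment", C1 = "control")),
    "one control"
  )
  t1 <- res[res$sample_id == "T1", ]
  expect_equal(t1$delta_ct, 2)
  expect_equal(t1$delta_delta_ct, -4)
  expect_equal(t1$fold_change, 16)
  expect_equal(res$fold_change[res$sample_id == "C1"], 1)
})

test_that("identical target and reference behaviour gives fold change 1", {
  ct <- make_ct(list(
    list("T1", "tgt", c(20, 20.2)), list("T1", "ref", c(18, 18.2)),
    list("T2", "tgt", c(21, 21.2)), list("T2", "ref", c(19, 19.2)),
    list("C1", "tgt", c(22, 22.2)), list("C1", "ref", c(20, 20.2)),
    list("C2", "tgt", c(23, 23.2)), list("C2", "ref", c(21, 21.2))
  ))
  res <- delta_delta_ct(ct, "tgt", "ref",
                        c(T1 = "treatment", T2 = "treatment",
                          C1 = "control", C2 = "control"))
  expect_equal(res$delta_delta_ct, rep(0, 4))
  expect_equal(res$fold_change, rep(1, 4))
})

test_that("a per-sample cycle shift common to target and reference cancels", {
  sim <- simulate_qpcr(c(g = 8), ct_noise_sd = 0.3, seed = 7)
  res1 <- delta_delta_ct(sim$ct, "g", "REF", sim$groups)
  shifted <- sim$ct
  shifted$ct[shifted$sample_id == "T01"] <- shifted$ct[shifted$sample_id == "T01"] + 1
  res2 <- delta_delta_ct(shifted, "g", "REF", sim$groups)
  expect_equal(res2$delta_ct, res1$delta_ct, tolerance = 1e-12)
  expect_equal(res2$fold_change, res1$fold_change, tolerance = 1e-12)
})

test_that("swapping treatment and control inverts the mean fold change", {
  sim <- simulate_qpcr(c(g = 16), ct_noise_sd = 0.2, seed = 17,
                       n_treatment = 3, n_control = 3)
  res <- delta_delta_ct(sim$ct, "g", "REF", sim$groups)
  swapped <- ifelse(sim$groups == "treatment", "control", "treatment")
  names(swapped) <- names(sim$groups)
  res_sw <- delta_delta_ct(sim$ct, "g", "REF", swapped)
  gm <- function(x, grp) 2^mean(-x$delta_delta_ct[x$group == grp])
  expect_equal(gm(res_sw, "treatment"), 1 / gm(res, "treatment"),
               tolerance = 1e-10)
})

test_that("a reference gene missing from any sample is a hard error", {
  ct <- make_ct(list(
    list("T1", "tgt", 20), list("T1", "ref", 18),
    list("C1", "tgt", 24)
  ))
  expect_error(
    delta_delta_ct(ct, "tgt", "ref", c(T1 = "treatment", C1 = "control")),
    "reference gene ref not measured.*C1"
  )
  expect_error(delta_delta_ct(
    make_ct(list(list("T1", "tgt", -1))), "tgt", "ref", c(T1 = "treatment")),
    "finite and positive")
})

test_that("group significance matches the textbook Welch formula", {
  res <- tibble::tibble(
    group = rep(c("treatment", "control"), each = 4),
    delta_delta_ct = -c(3.9, 4.2, 4.4, 3.7, 0.1, -0.2, 0.3, -0.1)
  )
  got <- group_significance(res, "t_test")

  a <- -res$delta_delta_ct[res$group == "treatment"]
  b <- -res$delta_delta_ct[res$group == "control"]
  se2a <- stats::var(a) / 4
  se2b <- stats::var(b) / 4
  tstat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_w <- (se2a + se2b)^2 / (se2a^2 / 3 + se2b^2 / 3)
  p_oracle <- 2 * pt(abs(tstat), df = df_w, lower.tail = FALSE)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(got$statistic, tstat, tolerance = 1e-8)

  # identical groups: t = 0, p = 1
  same <- tibble::tibble(group = rep(c("treatment", "control"), each = 3),
                         delta_delta_ct = rep(c(-1, 0, 1), 2))
  expect_equal(group_significance(same, "t_test")$p_value, 1)

  # wide separation with tiny jitter
  sep <- tibble::tibble(
    group = rep(c("treatment", "control"), each = 3),
    delta_delta_ct = -c(4.001, 4.000, 3.999, 0.001, 0.000, -0.001)
  )
  expect_lt(group_significance(sep, "t_test")$p_value, 0.01)

  # degenerate all-constant groups are flagged, not crashed
  flat <- tibble::tibble(group = rep(c("treatment", "control"), each = 2),
                         delta_delta_ct = c(-4, -4, 0, 0))
  out <- group_significance(flat, "t_test")
  expect_true(out$degenerate)
  expect_equal(out$p_value, 0)
})

test_that("one-way ANOVA across stages matches aov and validates groups", {
  df <- tibble::tibble(
    group = rep(c("green", "white", "red"), each = 3),
    log2_fold = c(0.1, 0.2, 0.0, 1.1, 1.3, 1.2, 3.0, 3.2, 2.9)
  )
  got <- group_significance(df, "anova")
  s <- summary(aov(log2_fold ~ factor(group), data = df))[[1]]
  expect_equal(got$p_value, s[["Pr(>F)"]][1], tolerance = 1e-12)
  expect_error(group_significance(df[df$group != "red", ], "anova"),
               "3 groups")
})

test_that("primer efficiency follows the dilution-slope formula", {
  # perfect doubling: slope exactly -1/log10(2)
  dil <- tibble::tibble(log10_dilution = -(0:4),
                        ct = 20 + (0:4) / log10(2))
  eff <- primer_efficiency(dil)
  expect_equal(eff$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(eff$efficiency, 1, tolerance = 1e-12)
  expect_equal(eff$r_squared, 1, tolerance = 1e-12)

  dil36 <- tibble::tibble(log10_dilution = -(0:3), ct = 21 + 3.6 * (0:3))
  expect_equal(primer_efficiency(dil36)$efficiency, 10^(1 / 3.6) - 1,
               tolerance = 1e-12)

  # an intercept shift leaves the efficiency untouched
  shifted <- dil36
  shifted$ct <- shifted$ct + 5
  expect_equal(primer_efficiency(shifted)$efficiency,
               primer_efficiency(dil36)$efficiency, tolerance = 1e-12)
  expect_equal(primer_efficiency(shifted)$intercept,
               primer_efficiency(dil36)$intercept + 5, tolerance = 1e-10)

  expect_error(primer_efficiency(dil36[1:2, ]), "3 dilution points")
  expect_error(primer_efficiency(
    tibble::tibble(log10_dilution = rep(-1, 3), ct = c(20, 21, 22))),
    "zero variance")
})

test_that("Ct tables round-trip through TSV", {
  sim <- simulate_qpcr(c(g = 4), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$ct, path)
  back <- read_ct_table(path)
  expect_equal(back$ct, sim$ct$ct, tolerance = 1e-12)
  expect_identical(back$sample_id, sim$ct$sample_id)
})
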