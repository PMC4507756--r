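test_that("perfect linear relationships give |r| = 1 with limiting P of 0", {
  res <- pearson_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$r, 1)
  expect_equal(res$p_two_tailed, 0)
  expect_true(is.infinite(res$t_stat))

  res2 <- pearson_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(res2$r, -1)
  expect_equal(res2$p_two_tailed, 0)
})

test_that("r, t and P match direct-formula and permutation oracles", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  res <- pearson_test(x, y)
  expect_equal(res$r, brute_r(x, y), tolerance = 1e-14)
  expect_equal(res$t_stat, res$r * sqrt(res$df) / sqrt(1 - res$r^2))
  expect_equal(res$p_two_tailed, brute_p(brute_r(x, y), 3), tolerance = 1e-14)

  # symmetry is exact
  expect_identical(res$r, pearson_test(y, x)$r)

  # permutation null agreement on a larger normal fixture
  set.seed(61)
  x2 <- stats::rnorm(13)
  y2 <- 0.5 * x2 + stats::rnorm(13)
  p_an <- pearson_test(x2, y2)$p_two_tailed
  p_perm <- perm_pvalue(x2, y2, n_perm = 2e4)
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  expect_lt(abs(p_an - p_perm), 4 * se + 0.01)
})

test_that("affine transforms preserve |r| and flip its sign with negative scale", {
  set.seed(71)
  x <- stats::rnorm(10)
  y <- stats::rnorm(10)
  r0 <- pearson_test(x, y)$r
  expect_equal(pearson_test(3.2 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(-2 * x + 1, y)$r, -r0, tolerance = 1e-12)
})

test_that("degenerate inputs are signalled, not crashed", {
  expect_error(pearson_test(1:4, 1:5), "equal length")
  expect_error(pearson_test(1:2, 2:3), "3 observations")
  res <- pearson_test(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_false(res$defined)
  expect_true(is.na(res$r))
})

test_that("a df override changes only the reference distribution", {
  set.seed(81)
  x <- stats::rnorm(16)
  y <- 0.6 * x + stats::rnorm(16)
  a <- pearson_test(x, y)
  b <- pearson_test(x, y, df_override = 11)
  expect_identical(a$r, b$r)
  expect_equal(b$df, 11L)
  expect_equal(b$p_two_tailed, brute_p(a$r, 11), tolerance = 1e-14)
})

test_that("at 11 df the r > 0.65 rule is the binding condition", {
  # independent oracle straight from the t quantile
  tcrit <- qt(0.975, df = 11)
  r_crit_oracle <- tcrit / sqrt(11 + tcrit^2)
  expect_equal(critical_r(11), r_crit_oracle, tolerance = 1e-14)
  expect_lt(critical_r(11), 0.65)
  expect_lt(brute_p(0.65, 11), 0.05)
  # implication: any r above 0.65 is significant at df = 11
  for (r in seq(0.651, 0.999, by = 0.02)) {
    expect_lt(brute_p(r, 11), 0.05)
  }
})

test_that("identical guide profiles yield the saturated network", {
  base <- c(3, 1, 4, 1, 5, 9, 2, 6)
  v <- t(sapply(1:15, function(i) base * i))  # affine copies, pairwise r = 1
  rownames(v) <- paste0("g", 1:15)
  guides <- toy_guides(rownames(v))
  net <- build_guide_network(em_from_matrix(v), guides)
  expect_equal(sum(net$edges$positive), choose(15, 2))
  expect_true(all(net$nodes$degree == 14L))
})

test_that("positive edges match a brute-force reference on random small matrices", {
  set.seed(91)
  for (i in 1:30) {
    g <- sample(3:6, 1)
    n <- sample(4:8, 1)
    v <- matrix(sample(0:9, g * n, replace = TRUE), nrow = g,
                dimnames = list(paste0("g", seq_len(g)), NULL))
    guides <- toy_guides(rownames(v))
    net <- build_guide_network(em_from_matrix(v), guides)
    pos <- net$edges[net$edges$positive, ]
    got <- sort(paste(pos$gene_a, pos$gene_b, sep = "|"))
    expect_identical(got, brute_edges(v))
  }
})

test_that("tightening thresholds never adds edges", {
  set.seed(101)
  v <- matrix(stats::rlnorm(15 * 10, 2), nrow = 15,
              dimnames = list(paste0("g", 1:15), NULL))
  m <- em_from_matrix(v)
  guides <- toy_guides(rownames(v))
  loose <- build_guide_network(m, guides, r_min = 0.3, p_max = 0.2)
  tight_r <- build_guide_network(m, guides, r_min = 0.5, p_max = 0.2)
  tight_p <- build_guide_network(m, guides, r_min = 0.3, p_max = 0.05)
  key <- function(net) {
    e <- net$edges[net$edges$positive, ]
    paste(e$gene_a, e$gene_b, sep = "|")
  }
  expect_true(all(key(tight_r) %in% key(loose)))
  expect_true(all(key(tight_p) %in% key(loose)))
  expect_true(all(tight_r$nodes$degree <= loose$nodes$degree))
})

test_that("a planted module yields edges only within the module", {
  # deterministic construction: module roles are positive affine copies of one
  # orthogonal-polynomial column; the remaining guides are the other columns,
  # exactly uncorrelated with the base and with each other
  n <- 16
  po <- poly(seq_len(n), degree = 5)
  roles <- guide_roles()$role
  module <- setdiff(roles, c("F3pH", "FLS", "LAR", "ANR"))
  v <- matrix(0, nrow = 15, ncol = n, dimnames = list(paste0("id_", roles), NULL))
  for (i in seq_along(roles)) {
    if (roles[i] %in% module) {
      v[i, ] <- 10 + i * (po[, 1] - min(po[, 1]) + 0.1)
    } else {
      k <- match(roles[i], setdiff(roles, module)) + 1L
      v[i, ] <- 10 * (po[, k] - min(po[, k]) + 0.1)
    }
  }
  guides <- guide_gene_set(setNames(rownames(v), roles))
  net <- build_guide_network(em_from_matrix(v), guides)
  pos <- net$edges[net$edges$positive, ]
  expect_equal(nrow(pos), choose(length(module), 2))
  expect_true(all(pos$role_a %in% module) && all(pos$role_b %in% module))
  expect_true(all(net$nodes$degree[!net$nodes$role %in% module] == 0L))
})

test_that("missing guides and zero-variance guides are handled explicitly", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(2, 3, 1, 4))
  guides <- guide_gene_set(c(PAL1 = "a", PAL2 = "b", C4H = "zzz"))
  expect_error(build_guide_network(em_from_matrix(v), guides), "C4H")

  v2 <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  net <- build_guide_network(em_from_matrix(v2), toy_guides(c("a", "b")))
  expect_false(net$edges$defined[1])
  expect_equal(sum(net$edges$positive), 0L)
})

test_that("correlate_to_guides reproduces the per-candidate row", {
  set.seed(111)
  v <- matrix(stats::rlnorm(6 * 13, 2), nrow = 6,
              dimnames = list(c(paste0("g", 1:5), "cand"), NULL))
  v["cand", ] <- v["g3", ]  # candidate mirrors one guide exactly
  m <- em_from_matrix(v)
  guides <- toy_guides(paste0("g", 1:5))
  row <- correlate_to_guides(m, guides, "cand")
  expect_equal(nrow(row), 5L)
  expect_equal(row$r[row$gene_id == "g3"], 1)
  expect_true(row$positive[row$gene_id == "g3"])

  # a constant candidate has only undefined correlations
  v["cand", ] <- 5
  row0 <- correlate_to_guides(em_from_matrix(v), guides, "cand")
  expect_true(all(!row0$defined))
  expect_equal(sum(row0$positive), 0L)
})

test_that("a strongly tracking candidate is flagged on its linked guides", {
  # latent rho = 0.95 against 5 designated guides; analytic power per link at
  # n = 16 is > 0.999, so across 20 seeds virtually every run flags all five
  linked <- c("PAL2", "4CL", "CHS1", "CHS2", "F3H")
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_population(n_samples = 16, n_background = 5,
                               guide_module_rho = 0.9,
                               planted_links = list(tfX = linked),
                               planted_rho = 0.95, dropout_fraction = 0,
                               seed = seed)
    row <- correlate_to_guides(sim$expression, sim$guides, "tfX",
                               transform = "log2p1")
    if (all(row$positive[row$role %in% linked])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
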