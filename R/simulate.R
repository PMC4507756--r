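#' Simulate an RPKM population with planted co-expression structure
#'
#' Generates a gene-by-sample RPKM matrix emulating a segregating fruit
#' population profiled by RNA-seq: two parents plus progeny, log-normal RPKM
#' marginals, a planted high-correlation module over a subset of the guide
#' roles, planted TF candidates tracking chosen guide subsets, and
#' independent background genes. The latent structure is Gaussian on the log
#' scale (RPKM = exp(mu + sigma * z)): module guides share a common factor F
#' with loading sqrt(rho), so every within-module latent pair has correlation
#' exactly `guide_module_rho`; each planted TF is a convex mix
#' `w * u + sqrt(1 - w^2) * noise` of the standardized mean u of its linked
#' guides' latents, with w solved so that the latent-scale correlation with
#' each linked guide hits the target rho (w = rho / cor(u, z_j); w > 1 means
#' the request is infeasible and is a hard error). A `dropout_fraction` of
#' background genes is silenced (RPKM far below the 0.5 expressed floor).
#'
#' @param n_samples Number of genotypes (>= 4); the first two are parents,
#'   the rest progeny. Default 16 (2 parents + 14 F1).
#' @param guide_module_rho Latent-scale correlation within the planted guide
#'   module, in \[0, 1).
#' @param module_roles Guide roles forming the correlated module; defaults to
#'   all roles except F3pH, FLS, LAR and ANR (the anthocyanin-directed core,
#'   mirroring the observed ripe-fruit pattern where tannin- and
#'   flavonol-specific genes stay unlinked).
#' @param planted_links Named list: planted TF gene ID -> character vector of
#'   guide roles it tracks (subsets of `module_roles`). Default: three TFs
#'   linked to 5, 6 and 5 anthocyanin-branch roles.
#' @param planted_rho Target latent correlation between a planted TF and each
#'   of its linked guides.
#' @param n_background Number of independent background candidate genes
#'   (default 1894, so with the 3 default planted TFs the candidate list has
#'   1897 entries, the size of a genome-wide TF homologue list; silenced
#'   genes — see `dropout_fraction` — stay in the list).
#' @param guide_log_mu,gene_log_mu Mean of log RPKM for guide genes
#'   (default log(300), matching the hundreds-scale RPKM of pathway
#'   structural genes) and for TF/background genes (default 3, RPKM ~ 20).
#' @param log_sigma SD of log RPKM for all expressed genes.
#' @param dropout_fraction Fraction of background genes forced far below the
#'   0.5 RPKM expressed filter (meanlog log(0.05)).
#' @param seed Optional integer seed; a fixed seed makes the output
#'   bit-reproducible.
#'
#' @return A list: `expression` (an `expression_matrix`), `guides`
#'   (a `guide_gene_set`), `candidates` (tibble `gene_id`, `description`),
#'   and `truth` (list recording `module_roles`, `guide_module_rho`,
#'   `planted` — tibble of gene_id, linked roles, rho, mixing weight —
#'   and `dropout_gene_ids`).
#' @export
#' @examples
#' sim <- simulate_population(n_samples = 8, n_background = 20, seed = 1)
#' sim$expression
simulate_population <- function(n_samples = 16L,
                                guide_module_rho = 0.8,
                                module_roles = NULL,
                                planted_links = NULL,
                                planted_rho = 0.9,
                                n_background = 1894L,
                                guide_log_mu = log(300),
                                gene_log_mu = 3,
                                log_sigma = 1,
                                dropout_fraction = 0.1,
                                seed = NULL) {
  if (n_samples < 4L) abort("n_samples must be at least 4")
  if (guide_module_rho < 0 || guide_module_rho >= 1) {
    abort("guide_module_rho must be in [0, 1)")
  }
  if (planted_rho <= -1 || planted_rho >= 1) abort("planted_rho must be in (-1, 1)")
  roles <- guide_roles()
  if (is.null(module_roles)) {
    module_roles <- setdiff(roles$role, c("F3pH", "FLS", "LAR", "ANR"))
  }
  stopifnot(all(module_roles %in% roles$role))
  if (is.null(planted_links)) {
    planted_links <- list(
      tf_planted01 = c("PAL2", "4CL", "CHS1", "CHS2", "F3H"),
      tf_planted02 = c("PAL1", "PAL2", "C4H", "4CL", "CHS1", "CHS2"),
      tf_planted03 = c("PAL2", "CHI", "CHS1", "CHS2", "F3H")
    )
  }
  bad <- setdiff(unlist(planted_links), module_roles)  # empty list = no planted TFs
  if (length(bad)) {
    abort(paste0("planted links must target module roles; outside: ",
                 paste(unique(bad), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_samples)
  sample_ids <- c("ParentA", "ParentB",
                  sprintf("P%03d", seq_len(n - 2L)))
  role_map <- setNames(c("parent", "parent", rep("progeny", n - 2L)), sample_ids)

  rho <- guide_module_rho
  in_mod <- roles$role %in% module_roles
  f <- stats::rnorm(n)                       # shared module factor
  z_guides <- sapply(seq_len(nrow(roles)), function(i) {
    if (in_mod[i]) sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
    else stats::rnorm(n)
  })
  colnames(z_guides) <- roles$role

  # latent correlation between the standardized mean of k module guides and
  # any one of them: c = sqrt((1 + (k-1) rho) / k)
  planted <- tibble(gene_id = character(), linked_roles = character(),
                    rho = numeric(), weight = numeric())
  if (length(planted_links)) {
    planted <- purrr::imap_dfr(planted_links, function(linked, id) {
      k <- length(linked)
      cval <- sqrt((1 + (k - 1) * rho) / k)
      w <- planted_rho / cval
      tibble(gene_id = id, linked_roles = paste(linked, collapse = ","),
             rho = planted_rho, weight = w)
    })
    if (any(planted$weight > 1)) {
      abort("infeasible planted correlation: target rho exceeds what the guide module supports")
    }
  }
  z_planted <- matrix(0, nrow = n, ncol = length(planted_links))
  for (i in seq_along(planted_links)) {
    linked <- planted_links[[i]]
    u <- rowMeans(z_guides[, linked, drop = FALSE])
    u <- u / sqrt((1 + (length(linked) - 1) * rho) / length(linked))
    w <- planted$weight[i]
    z_planted[, i] <- w * u + sqrt(1 - w^2) * stats::rnorm(n)
  }

  n_bg <- as.integer(n_background)
  z_bg <- matrix(stats::rnorm(n * n_bg), nrow = n)
  n_drop <- as.integer(floor(dropout_fraction * n_bg))
  bg_mu <- c(rep(gene_log_mu, n_bg - n_drop), rep(log(0.05), n_drop))
  # silenced genes get a tight marginal so they stay below the 0.5 RPKM
  # expressed floor in essentially every sample
  bg_sigma <- c(rep(log_sigma, n_bg - n_drop), rep(0.3, n_drop))

  guide_ids <- paste0("guide_", roles$role)
  planted_ids <- names(planted_links)
  bg_ids <- sprintf("tf_bg%05d", seq_len(n_bg))

  bg_mu_mat <- matrix(bg_mu, nrow = n, ncol = n_bg, byrow = TRUE)
  bg_sigma_mat <- matrix(bg_sigma, nrow = n, ncol = n_bg, byrow = TRUE)
  rpkm <- rbind(
    t(exp(guide_log_mu + log_sigma * z_guides)),
    t(exp(gene_log_mu + log_sigma * z_planted)),
    t(exp(bg_mu_mat + bg_sigma_mat * z_bg))
  )
  mat <- tibble(gene_id = c(guide_ids, planted_ids, bg_ids))
  for (j in seq_len(n)) mat[[sample_ids[j]]] <- rpkm[, j]

  list(
    expression = as_expression_matrix(mat, roles = role_map),
    guides = guide_gene_set(setNames(guide_ids, roles$role)),
    candidates = tibble(
      gene_id = c(planted_ids, bg_ids),
      description = c(rep("planted pathway-linked TF", length(planted_ids)),
                      rep("background TF", n_bg))
    ),
    truth = list(
      module_roles = module_roles,
      guide_module_rho = rho,
      planted = planted,
      dropout_gene_ids = if (n_drop) bg_ids[(n_bg - n_drop + 1L):n_bg] else character()
    )
  )
}

#' Simulate a qPCR Ct table under known fold changes
#'
#' Generates triplicate threshold-cycle measurements for target genes and a
#' stable reference gene (`"REF"`, relative abundance 1 in every sample).
#' Each replicate Ct is `baseline - log2(relative abundance) + N(0, sd)`;
#' treatment samples carry the gene's true fold change, controls abundance 1.
#' With zero noise the 2^-ddCt pipeline recovers the true folds exactly.
#'
#' @param true_fold_changes Named positive numeric: target gene -> fold
#'   change in treatment vs control.
#' @param n_treatment,n_control Numbers of treatment and control samples.
#' @param n_replicates Technical replicates per (sample, gene).
#' @param ct_noise_sd Per-replicate Ct noise SD in cycles (default 0.2).
#' @param target_baseline_ct,reference_baseline_ct Control-condition mean Ct
#'   of targets and of the reference gene.
#' @param seed Optional integer seed.
#'
#' @return A list: `ct` (long tibble: `sample_id`, `gene_id`, `replicate`,
#'   `ct`), `groups` (named vector), and `truth` (list with `fold_changes`
#'   and `reference`).
#' @export
#' @examples
#' sim <- simulate_qpcr(c(myb = 16), ct_noise_sd = 0, seed = 1)
#' delta_delta_ct(sim$ct, "myb", sim$truth$reference, sim$groups)
simulate_qpcr <- function(true_fold_changes,
                          n_treatment = 4L, n_control = 3L,
                          n_replicates = 3L, ct_noise_sd = 0.2,
                          target_baseline_ct = 24, reference_baseline_ct = 18,
                          seed = NULL) {
  stopifnot(is.numeric(true_fold_changes), length(true_fold_changes) >= 1L,
            !is.null(names(true_fold_changes)))
  if (any(true_fold_changes <= 0)) abort("fold changes must be positive")
  if (ct_noise_sd < 0) abort("ct_noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  samples <- c(sprintf("T%02d", seq_len(n_treatment)),
               sprintf("C%02d", seq_len(n_control)))
  groups <- setNames(rep(c("treatment", "control"), c(n_treatment, n_control)),
                     samples)
  genes <- c(names(true_fold_changes), "REF")
  grid <- tidyr::expand_grid(sample_id = samples, gene_id = genes,
                             replicate = seq_len(as.integer(n_replicates)))
  abundance <- ifelse(
    grid$gene_id == "REF", 1,
    ifelse(groups[grid$sample_id] == "treatment",
           true_fold_changes[grid$gene_id], 1)
  )
  baseline <- ifelse(grid$gene_id == "REF", reference_baseline_ct,
                     target_baseline_ct)
  grid$ct <- baseline - log2(abundance) +
    stats::rnorm(nrow(grid), sd = ct_noise_sd)
  list(ct = grid, groups = groups,
       truth = list(fold_changes = true_fold_changes, reference = "REF"))
}
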