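# Hand-built call-set fixture: explicit matrices, no simulator involvement.
make_calls <- function(gt, dp = NULL, ad_called = NULL, ad_other = NULL,
                       pos = NULL, type = NULL, mean_depth = 30,
                       low_coverage = FALSE, L = 1000) {
  n <- nrow(gt); p <- ncol(gt)
  ids <- rownames(gt) %||% sprintf("S%03d", seq_len(n))
  rownames(gt) <- ids
  if (is.null(dp)) dp <- matrix(30L, n, p)
  if (is.null(ad_called)) ad_called <- dp
  if (is.null(ad_other)) ad_other <- matrix(0L, n, p)
  if (is.null(pos)) pos <- seq_len(p) * 10L
  if (is.null(type)) type <- rep("SNV", p)
  bases <- rep(c("A", "G"), length.out = p)
  haploid_calls(
    samples = tibble::tibble(sample_id = ids,
                             mean_depth = rep_len(mean_depth, n),
                             low_coverage = rep_len(low_coverage, n)),
    sites = tibble::tibble(chrom = "chrY", pos = as.integer(pos),
                           ref = bases, alt = "T", type = type),
    gt = gt, dp = dp, ad_called = ad_called, ad_other = ad_other, L = L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force tally of the whole filter chain, written as plain
# per-genotype loops against the published rules; used as the oracle for
# FilterReport counts.
reference_filter_tally <- function(calls, gap = 5, sample_max = 0.05,
                                   site_max = 0.03) {
  sites <- calls$sites
  gt <- calls$gt; dp <- calls$dp
  adc <- calls$ad_called; ado <- calls$ad_other
  n <- nrow(gt)
  out <- list(sites_in = nrow(sites))

  indel_pos <- sites$pos[sites$type == "indel"]
  keep <- rep(TRUE, nrow(sites)); snpgap <- 0L
  for (s in seq_len(nrow(sites))) {
    if (sites$type[s] == "indel") { keep[s] <- FALSE; next }
    if (length(indel_pos) && any(abs(sites$pos[s] - indel_pos) <= gap)) {
      snpgap <- snpgap + 1L; keep[s] <- FALSE
    }
  }
  out$snvs_removed_snpgap <- snpgap
  out$indels_removed <- sum(sites$type == "indel")
  removed_records <- sum(!keep)
  gt <- gt[, keep, drop = FALSE]; dp <- dp[, keep, drop = FALSE]
  adc <- adc[, keep, drop = FALSE]; ado <- ado[, keep, drop = FALSE]
  pos <- sites$pos[keep]

  n_depth <- 0L
  for (i in seq_len(n)) {
    min_dp <- if (calls$samples$low_coverage[i]) 0L
              else if (calls$samples$mean_depth[i] >= 12) 3L else 2L
    for (s in seq_len(ncol(gt))) {
      if (!is.na(gt[i, s]) && dp[i, s] < min_dp) {
        gt[i, s] <- NA; n_depth <- n_depth + 1L
      }
    }
  }
  out$genotypes_missing_depth <- n_depth

  n_ab <- 0L
  for (i in seq_len(n)) for (s in seq_len(ncol(gt))) {
    if (is.na(gt[i, s])) next
    if (adc[i, s] >= 1 && ado[i, s] >= 1 &&
        adc[i, s] / (adc[i, s] + ado[i, s]) < 0.85) {
      gt[i, s] <- NA; n_ab <- n_ab + 1L
    }
  }
  out$genotypes_missing_allele_balance <- n_ab

  drop_sample <- rep(FALSE, n)
  for (i in seq_len(n)) {
    frac <- sum(is.na(gt[i, ])) / ncol(gt)
    if (frac >= sample_max && !calls$samples$low_coverage[i])
      drop_sample[i] <- TRUE
  }
  out$samples_removed_missingness <- sum(drop_sample)
  gt <- gt[!drop_sample, , drop = FALSE]

  drop_site <- rep(FALSE, ncol(gt))
  for (s in seq_len(ncol(gt)))
    if (sum(is.na(gt[, s])) / nrow(gt) >= site_max) drop_site[s] <- TRUE
  out$sites_removed_missingness <- sum(drop_site)
  gt <- gt[, !drop_site, drop = FALSE]

  out$final_sites <- calls$L - removed_records - sum(drop_site)
  derived <- integer(ncol(gt))
  for (s in seq_len(ncol(gt))) derived[s] <- sum(gt[, s] == 1L, na.rm = TRUE)
  out$final_variant_sites <- sum(derived >= 1L)
  out$singletons <- sum(derived == 1L)
  out
}

# small simulated replicate used by several tree/dating tests
sim_replicate <- function(seed, n = 20, tmrca = NULL) {
  cfg <- sim_config(n_samples = n, seed = seed, tmrca_target = tmrca)
  gen <- simulate_genealogy(cfg)
  list(gen = gen, matrix = drop_mutations(gen), cfg = cfg)
}

# true mutation-count tree of a simulated replicate, zero-length edges
# contracted (for topology comparisons)
true_mutation_phylo <- function(m) {
  gen <- attr(m, "genealogy")
  phy <- gen$phy
  phy$edge.length <- lengths(attr(m, "edge_sites"))
  ape::di2multi(phy, tol = 0.5)
}
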