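#' Haploid call set
#'
#' Per-sample, per-site haploid genotype calls with read-depth and
#' allele-support metadata, the product of joint haploid calling over a
#' callable region of length `L`. Only variant and indel records are
#' materialized; the remaining callable sites are invariant and carried via
#' `L`.
#'
#' @param samples Tibble with columns `sample_id`, `mean_depth` (mean chrY
#'   read depth), `low_coverage` (logical; exempt from minimum-depth
#'   filtering).
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `type` (`"SNV"` or `"indel"`), sorted by position.
#' @param gt Integer matrix samples x sites: called allele index (0 = ref,
#'   1 = alt) or NA for missing.
#' @param dp Integer matrix of per-genotype read depths.
#' @param ad_called,ad_other Integer matrices: reads supporting the called
#'   allele and total reads supporting any other allele.
#' @param L Callable region length in sites.
#' @return An object of class `haploid_calls`.
#' @export
haploid_calls <- function(samples, sites, gt, dp, ad_called, ad_other, L) {
  stopifnot(nrow(gt) == nrow(samples), ncol(gt) == nrow(sites))
  if (is.unsorted(sites$pos)) abort("`sites` must be sorted by position.")
  if (any(ad_called < 0, na.rm = TRUE) || any(ad_other < 0, na.rm = TRUE))
    abort("AD entries must be non-negative.")
  for (m in c("gt", "dp", "ad_called", "ad_other")) {
    x <- get(m); storage.mode(x) <- "integer"
    dimnames(x) <- list(samples$sample_id, NULL)
    assign(m, x)
  }
  structure(list(samples = samples, sites = sites, gt = gt, dp = dp,
                 ad_called = ad_called, ad_other = ad_other, L = as.numeric(L)),
            class = "haploid_calls")
}

#' @export
print.haploid_calls <- function(x, ...) {
  cat(sprintf(
    "<haploid_calls> %d samples x %d records (%d SNV, %d indel), L = %.4g\n",
    nrow(x$samples), nrow(x$sites), sum(x$sites$type == "SNV"),
    sum(x$sites$type == "indel"), x$L))
  invisible(x)
}

#' @method as_tibble haploid_calls
#' @export
as_tibble.haploid_calls <- function(x, ...) {
  tibble(
    sample_id = rep(x$samples$sample_id, times = nrow(x$sites)),
    pos = rep(x$sites$pos, each = nrow(x$samples)),
    type = rep(x$sites$type, each = nrow(x$samples)),
    allele = as.vector(x$gt),
    dp = as.vector(x$dp),
    ad_called = as.vector(x$ad_called),
    ad_other = as.vector(x$ad_other)
  )
}

#' Inject sequencing artifacts into a clean haplotype matrix
#'
#' Turns a noise-free binary matrix into a VCF-ready haploid call set with
#' the imperfections the filter chain is designed to remove: per-sample mean
#' depths (Normal, truncated at 1) with per-genotype Poisson DP; contaminated
#' genotypes whose called-allele read fraction falls below 0.85; genotypes
#' dropped at `missing_rate`; and indel records placed within 5 bp of
#' existing SNVs. A ground-truth mask of corrupted/dropped genotypes is
#' attached for recovery tests.
#'
#' @param matrix A [hap_matrix()] of true genotypes.
#' @param config A [sim_config()]; `allele_error_rate` may be per-sample.
#' @return A [haploid_calls()] with attribute `truth`: a list with
#'   `geno` (the input matrix), `corrupt` and `dropped` masks (samples x SNV
#'   sites), and `snv_cols` (columns of the call set that are SNVs, in input
#'   column order).
#' @export
inject_artifacts <- function(matrix, config) {
  stopifnot(inherits(matrix, "hap_matrix"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "artifacts"))
  geno <- matrix$geno
  n <- nrow(geno); p <- ncol(geno)
  err <- rep_len(config$allele_error_rate, n)

  mean_depth <- pmax(1, rnorm(n, config$depth_mean, config$depth_sd))
  low_cov <- rbinom(n, 1L, config$low_coverage_fraction) == 1L
  samples <- tibble(sample_id = rownames(geno), mean_depth = mean_depth,
                    low_coverage = low_cov)

  dp <- base::matrix(rpois(n * p, rep(mean_depth, times = p)), nrow = n)
  corrupt <- base::matrix(rbinom(n * p, 1L, rep(err, times = p)) == 1L, nrow = n)
  dropped <- base::matrix(rbinom(n * p, 1L, config$missing_rate) == 1L, nrow = n)

  ad_other <- base::matrix(0L, n, p)
  # contaminated calls: force DP >= 5 and give >= 20% of reads to a second
  # allele, so the called-allele fraction is <= 0.8 (< the 0.85 threshold)
  dp[corrupt] <- pmax(dp[corrupt], 5L)
  ad_other[corrupt] <- ceiling(0.2 * dp[corrupt])
  ad_called <- dp - ad_other
  gt <- geno
  gt[dropped] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  snv_sites <- tibble(chrom = "chrY", pos = matrix$pos, ref = ref, alt = alt,
                      type = "SNV")

  # indels near randomly chosen SNVs (within 5 bp), at fresh positions
  n_indel <- rpois(1L, config$indel_rate * p)
  indel_sites <- tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(), type = character())
  if (n_indel > 0 && p > 0) {
    anchor <- sample.int(p, min(n_indel, p))
    ipos <- matrix$pos[anchor] + sample(c(-5:-1, 1:5), length(anchor),
                                        replace = TRUE)
    keep <- !(ipos %in% matrix$pos) & ipos >= 1 & ipos <= matrix$L_effective &
      !duplicated(ipos)
    ipos <- ipos[keep]
    if (length(ipos) > 0) {
      iref <- paste0(sample(bases, length(ipos), TRUE),
                     sample(bases, length(ipos), TRUE))
      indel_sites <- tibble(chrom = "chrY", pos = as.integer(ipos),
                            ref = iref, alt = substr(iref, 1L, 1L),
                            type = "indel")
    }
  }
  n_i <- nrow(indel_sites)
  sites <- dplyr::bind_rows(snv_sites, indel_sites)
  ord <- order(sites$pos)
  sites <- sites[ord, ]
  # indel records: everyone called REF at the sample's depth
  pad <- function(x, fill) cbind(x, base::matrix(fill, n, n_i))[, ord, drop = FALSE]
  dp_i <- base::matrix(rpois(n * n_i, rep(mean_depth, times = n_i)), nrow = n)
  calls <- haploid_calls(
    samples, sites,
    gt = pad(gt, 0L),
    dp = cbind(dp, dp_i)[, ord, drop = FALSE],
    ad_called = cbind(ad_called, dp_i)[, ord, drop = FALSE],
    ad_other = pad(ad_other, 0L),
    L = matrix$L_effective
  )
  attr(calls, "truth") <- list(geno = matrix, corrupt = corrupt,
                               dropped = dropped,
                               snv_cols = order(ord)[seq_len(p)])
  calls
}
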