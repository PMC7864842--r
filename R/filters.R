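#' Genotype, site and sample filters for haploid call sets
#'
#' The filter chain reproduces the standard hard-filtering of jointly called
#' haploid (Y-chromosome) genotypes, in this fixed order:
#' SNVs near indels and indels ([snpgap_filter()]), per-genotype minimum
#' depth ([depth_filter()]), per-genotype allele balance
#' ([allele_balance_filter()]), then sample- and site-level missingness
#' ([missingness_filter()]), which emits the analysis-ready binary matrix
#' and a [filter report][filter_report]. [filter_calls()] runs the whole
#' chain.
#'
#' @name genotype-filters
NULL

filter_counts <- function(calls) {
  attr(calls, "filter_counts") %||% list(sites_in = nrow(calls$sites))
}

#' Remove SNVs near indels, then indels
#'
#' Drops every SNV record within `gap` bp of any indel record (bcftools
#' SnpGap semantics: distance <= `gap` removes), then drops all indel
#' records. Callable length is reduced by each removed record.
#'
#' @param calls A [haploid_calls()] object with sites sorted by position.
#' @param gap Maximum SNV-to-indel distance (bp) at which the SNV is removed.
#' @return The filtered `haploid_calls`.
#' @export
snpgap_filter <- function(calls, gap = 5L) {
  stopifnot(inherits(calls, "haploid_calls"))
  if (is.unsorted(calls$sites$pos)) abort("Sites must be sorted by position.")
  cnt <- filter_counts(calls)
  is_indel <- calls$sites$type == "indel"
  ipos <- calls$sites$pos[is_indel]
  near <- rep(FALSE, nrow(calls$sites))
  if (length(ipos) > 0) {
    for (p in ipos)
      near <- near | abs(calls$sites$pos - p) <= gap
  }
  drop <- (near & !is_indel) | is_indel
  cnt$snvs_removed_snpgap <- sum(near & !is_indel)
  cnt$indels_removed <- sum(is_indel)
  out <- subset_sites(calls, !drop)
  out$L <- calls$L - sum(drop)
  attr(out, "filter_counts") <- cnt
  out
}

#' Mask genotypes below the minimum read depth
#'
#' Genotypes are set to missing when DP < 3 for samples with mean chrY depth
#' >= 12x, or DP < 2 for samples below that; samples flagged `low_coverage`
#' are exempt.
#'
#' @inheritParams snpgap_filter
#' @param min_dp_high,min_dp_low Minimum DP for samples with mean depth at
#'   or above / below `mean_depth_split`.
#' @param mean_depth_split Mean-depth threshold separating the two regimes.
#' @return The filtered `haploid_calls`.
#' @export
depth_filter <- function(calls, min_dp_high = 3L, min_dp_low = 2L,
                         mean_depth_split = 12) {
  stopifnot(inherits(calls, "haploid_calls"))
  cnt <- filter_counts(calls)
  min_dp <- ifelse(calls$samples$low_coverage, 0L,
                   ifelse(calls$samples$mean_depth >= mean_depth_split,
                          min_dp_high, min_dp_low))
  mask <- sweep(calls$dp, 1L, min_dp, `<`) & !is.na(calls$gt)
  cnt$genotypes_missing_depth <- sum(mask)
  calls$gt[mask] <- NA_integer_
  attr(calls, "filter_counts") <- cnt
  calls
}

#' Mask genotypes with poor allele balance
#'
#' Where reads support more than one allele (both the called allele and at
#' least one other have >= 1 read), the genotype is set to missing unless
#' the fraction of reads supporting the called allele is at least
#' `threshold`.
#'
#' @inheritParams snpgap_filter
#' @param threshold Minimum called-allele read fraction (default 0.85).
#' @return The filtered `haploid_calls`.
#' @export
allele_balance_filter <- function(calls, threshold = 0.85) {
  stopifnot(inherits(calls, "haploid_calls"))
  cnt <- filter_counts(calls)
  frac <- calls$ad_called / (calls$ad_called + calls$ad_other)
  mask <- !is.na(calls$gt) & calls$ad_called > 0L & calls$ad_other > 0L &
    frac < threshold
  cnt$genotypes_missing_allele_balance <- sum(mask)
  calls$gt[mask] <- NA_integer_
  attr(calls, "filter_counts") <- cnt
  calls
}

#' Remove high-missingness samples and sites; emit the binary matrix
#'
#' Removes samples whose missing fraction across all retained records is
#' >= `sample_max` (low-coverage samples exempt when `exempt_low_coverage`),
#' then sites whose missing fraction across the retained samples is
#' >= `site_max` (closed bounds: removal at exactly the threshold). Variant
#' sites (>= 1 derived call) among the survivors form the
#' [binary haplotype matrix][hap_matrix]; sites left with no derived call
#' are counted as invariant and retained only in the callable length.
#'
#' @inheritParams snpgap_filter
#' @param sample_max Maximum tolerated per-sample missing fraction.
#' @param site_max Maximum tolerated per-site missing fraction.
#' @param exempt_low_coverage Keep `low_coverage` samples regardless of
#'   missingness.
#' @return A list with `matrix` (a [hap_matrix()]) and `report` (a
#'   [filter_report]).
#' @export
missingness_filter <- function(calls, sample_max = 0.05, site_max = 0.03,
                               exempt_low_coverage = TRUE) {
  stopifnot(inherits(calls, "haploid_calls"))
  cnt <- filter_counts(calls)
  miss_s <- rowMeans(is.na(calls$gt))
  drop_s <- miss_s >= sample_max
  if (exempt_low_coverage) drop_s <- drop_s & !calls$samples$low_coverage
  cnt$samples_removed_missingness <- sum(drop_s)
  if (all(drop_s)) abort("All samples removed by the missingness filter.")
  gt <- calls$gt[!drop_s, , drop = FALSE]

  miss_v <- colMeans(is.na(gt))
  drop_v <- miss_v >= site_max
  cnt$sites_removed_missingness <- sum(drop_v)
  gt <- gt[, !drop_v, drop = FALSE]
  pos <- calls$sites$pos[!drop_v]

  L_eff <- calls$L - cnt$sites_removed_missingness
  derived <- colSums(gt == 1L, na.rm = TRUE)
  variant <- derived >= 1L
  cnt$final_sites <- L_eff
  cnt$final_variant_sites <- sum(variant)
  cnt$singletons <- sum(derived[variant] == 1L)
  cnt$multiallelic_sites <- 0L  # binary matrix: non-ref alleles collapsed
  m <- hap_matrix(gt[, variant, drop = FALSE], pos[variant], L_eff)
  list(matrix = m, report = filter_report(cnt))
}

#' Run the full filter chain
#'
#' Applies, in order: [snpgap_filter()], [depth_filter()],
#' [allele_balance_filter()], [missingness_filter()].
#'
#' @inheritParams snpgap_filter
#' @param gap,threshold,sample_max,site_max,exempt_low_coverage Passed to the
#'   component filters.
#' @return A list with `matrix` and `report`, as [missingness_filter()].
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 6, seed = 3))
#' calls <- inject_artifacts(drop_mutations(gen), gen$config)
#' res <- filter_calls(calls)
#' res$report
filter_calls <- function(calls, gap = 5L, threshold = 0.85,
                         sample_max = 0.05, site_max = 0.03,
                         exempt_low_coverage = TRUE) {
  calls |>
    snpgap_filter(gap = gap) |>
    depth_filter() |>
    allele_balance_filter(threshold = threshold) |>
    missingness_filter(sample_max = sample_max, site_max = site_max,
                       exempt_low_coverage = exempt_low_coverage)
}

# subset site records (columns) of a haploid_calls
subset_sites <- function(calls, keep) {
  calls$sites <- calls$sites[keep, , drop = FALSE]
  for (m in c("gt", "dp", "ad_called", "ad_other"))
    calls[[m]] <- calls[[m]][, keep, drop = FALSE]
  calls
}

#' Filter report
#'
#' Stage-by-stage accounting of the filter chain: records in, SNVs removed
#' near indels, indels removed, genotypes masked by depth and by allele
#' balance, samples and sites removed by missingness, and the final callable
#' length, variant-site and singleton counts.
#'
#' @param counts Named list of stage counts.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(counts) {
  if (any(unlist(counts) < 0)) abort("Filter counts must be non-negative.")
  structure(counts, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @rdname filter_report
#' @param x A `filter_report`.
#' @param ... Unused.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  tibble(stage = names(unclass(x)), count = as.numeric(unlist(x)))
}
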