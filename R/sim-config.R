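#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: a dated haploid
#' genealogy, infinite-sites mutations over a callable region, and the
#' sequencing artifacts the downstream filter chain is designed to remove.
#'
#' Defaults follow the study conditions the package validates against: a
#' point mutation rate of 0.76e-9 mutations/site/year over a 10.3 Mb callable
#' region, with a haploid effective size of 1000 and 30 years/generation so
#' that coalescent TMRCAs land on the ~60 ky timescale typical of
#' non-African Y-chromosome variation.
#'
#' @param n_samples Number of haploid samples (tips). Must be >= 2.
#' @param mu Mutation rate, mutations per site per year.
#' @param L Callable region length in sites.
#' @param demographic_model `"constant_Ne"` or `"expansion"` (constant size
#'   before `T_expand` years ago, `growth`-fold larger afterwards, i.e. more
#'   recently).
#' @param Ne Haploid effective population size (pre-expansion size under the
#'   expansion model).
#' @param T_expand Expansion epoch in years before present (expansion model).
#' @param growth Fold-increase of Ne after (more recent than) `T_expand`.
#' @param generation_time Years per generation; the coalescent runs in
#'   generations internally, all reported ages are in years.
#' @param tmrca_target If non-`NULL`, node ages are rescaled so the root age
#'   equals this value (years) exactly.
#' @param depth_mean,depth_sd Per-sample mean chrY read depth is drawn from
#'   Normal(`depth_mean`, `depth_sd`) truncated below at 1; per-genotype DP
#'   is Poisson around the sample mean.
#' @param missing_rate Per-genotype probability of being dropped (GT = ".").
#' @param allele_error_rate Per-genotype probability of contamination
#'   (called-allele read fraction forced below 0.85). Scalar, or one value
#'   per sample.
#' @param indel_rate Expected number of injected indel records per SNV site;
#'   each indel lands within 5 bp of an existing SNV so the SnpGap filter is
#'   exercised.
#' @param low_coverage_fraction Fraction of samples flagged as low-coverage
#'   (exempt from the minimum-depth filter, as 1000G-style samples are).
#' @param seed Master integer seed for all randomness.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 8, seed = 1)
#' cfg$mu
sim_config <- function(n_samples = 20,
                       mu = 0.76e-9,
                       L = 10.3e6,
                       demographic_model = c("constant_Ne", "expansion"),
                       Ne = 1000,
                       T_expand = 54000,
                       growth = 10,
                       generation_time = 30,
                       tmrca_target = NULL,
                       depth_mean = 30,
                       depth_sd = 8,
                       missing_rate = 0.01,
                       allele_error_rate = 0.005,
                       indel_rate = 0.01,
                       low_coverage_fraction = 0,
                       seed = 1L) {
  demographic_model <- match.arg(demographic_model)
  if (n_samples < 2) abort("`n_samples` must be >= 2.")
  if (mu <= 0) abort("`mu` must be > 0.")
  if (L <= 0) abort("`L` must be > 0.")
  if (Ne <= 0) abort("`Ne` must be > 0.")
  if (growth <= 0) abort("`growth` must be > 0.")
  if (any(missing_rate < 0) || any(missing_rate >= 1))
    abort("`missing_rate` must be in [0, 1).")
  if (any(allele_error_rate < 0) || any(allele_error_rate > 1))
    abort("`allele_error_rate` must be in [0, 1].")
  if (!is.null(tmrca_target) && tmrca_target <= 0)
    abort("`tmrca_target` must be > 0 years.")
  structure(
    list(
      n_samples = as.integer(n_samples), mu = mu, L = L,
      demographic_model = demographic_model, Ne = Ne,
      T_expand = T_expand, growth = growth,
      generation_time = generation_time, tmrca_target = tmrca_target,
      depth_mean = depth_mean, depth_sd = depth_sd,
      missing_rate = missing_rate, allele_error_rate = allele_error_rate,
      indel_rate = indel_rate, low_coverage_fraction = low_coverage_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, mu = %.3g /site/yr, L = %.3g sites\n",
              x$n_samples, x$mu, x$L))
  cat(sprintf("  demography: %s (Ne = %g", x$demographic_model, x$Ne))
  if (x$demographic_model == "expansion")
    cat(sprintf(", %g-fold growth at %g y", x$growth, x$T_expand))
  cat(sprintf("), %g y/gen, seed %d\n", x$generation_time, x$seed))
  invisible(x)
}
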