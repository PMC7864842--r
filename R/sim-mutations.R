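#' Binary haplotype matrix
#'
#' Container for filtered samples-by-sites genotypes over {0 ancestral,
#' 1 derived, NA missing}, plus the 1-based site positions and the effective
#' callable length (sites) used as the denominator of per-site divergences.
#'
#' @param geno Integer matrix, samples in rows (rownames = sample IDs),
#'   variant sites in columns; entries 0/1/NA.
#' @param pos Integer vector of 1-based positions, one per column.
#' @param L_effective Callable length in sites (>= `ncol(geno)`).
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(geno, pos, L_effective) {
  stopifnot(is.matrix(geno), length(pos) == ncol(geno))
  if (L_effective < ncol(geno))
    abort("`L_effective` must be at least the number of variant sites.")
  if (ncol(geno) > 0 && any(colSums(geno == 1L, na.rm = TRUE) == 0))
    abort("Every site must carry at least one derived call.")
  storage.mode(geno) <- "integer"
  colnames(geno) <- as.character(pos)
  structure(list(geno = geno, pos = as.integer(pos),
                 L_effective = as.numeric(L_effective)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d samples x %d variant sites (L_eff = %.4g)\n",
              nrow(x$geno), ncol(x$geno), x$L_effective))
  invisible(x)
}

#' @method as_tibble hap_matrix
#' @export
as_tibble.hap_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$geno), times = ncol(x$geno)),
    pos = rep(x$pos, each = nrow(x$geno)),
    state = as.vector(x$geno)
  )
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places mutations on each edge as a Poisson process with rate
#' `mu * L * edge_length_years`, each mutation at a previously unmutated
#' site (infinite-sites model), and returns the resulting binary haplotype
#' matrix: the derived allele is carried by exactly the tips below the
#' mutated edge.
#'
#' @param gen A [simulate_genealogy()] result.
#' @param mu Mutation rate per site per year (default from `gen$config`).
#' @param L Callable length in sites (default from `gen$config`).
#' @param seed Integer seed (default derived from `gen$config$seed`).
#' @return A [hap_matrix()] with attributes `edge_sites` (list: column
#'   indices of the sites on each phylo edge) and `genealogy`.
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 5, seed = 7))
#' m <- drop_mutations(gen)
#' dim(m$geno)
drop_mutations <- function(gen, mu = gen$config$mu, L = gen$config$L,
                           seed = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  seed <- seed %||% derive_seed(gen$config$seed, "mutations")
  set.seed(seed)
  phy <- gen$phy
  expected <- mu * L * sum(phy$edge.length)
  if (expected > L)
    abort("Expected mutation count exceeds L: infinite-sites model violated.")
  n_mut <- rpois(nrow(phy$edge), mu * L * phy$edge.length)
  total <- sum(n_mut)
  positions <- sort(sample.int(L, total))
  # shuffle site->edge assignment so positions are exchangeable across edges
  edge_rep <- rep.int(seq_len(nrow(phy$edge)), n_mut)
  edge_of_site <- edge_rep[sample.int(length(edge_rep))]

  below <- descendant_tips(phy)
  n <- length(phy$tip.label)
  geno <- matrix(0L, nrow = n, ncol = total,
                 dimnames = list(phy$tip.label, NULL))
  for (s in seq_len(total)) {
    carriers <- below[[phy$edge[edge_of_site[s], 2L]]]
    geno[carriers, s] <- 1L
  }
  m <- hap_matrix(geno, positions, L)
  attr(m, "edge_sites") <- split(seq_len(total),
                                 factor(edge_of_site, seq_len(nrow(phy$edge))))
  attr(m, "genealogy") <- gen
  m
}
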