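#' Dating configuration
#'
#' Parameters of rho-statistic node dating: the point mutation rate and its
#' uncertainty range used for the confidence interval, the subsampling rule
#' applied to large clades, and the divergence-to-age conversion factor.
#'
#' @param mu Point mutation rate, mutations/site/year (default 0.76e-9).
#' @param mu_low,mu_high Bounds of the mutation-rate uncertainty used for
#'   the CI (defaults 0.67e-9 and 0.86e-9).
#' @param subsample_threshold When a child clade holds more than this many
#'   samples (default 100), it is subsampled before pairing.
#' @param subsample_fraction Fraction retained when subsampling (default
#'   1/3; `ceiling(n * fraction)` samples are kept).
#' @param pair_divergence_factor Pairwise divergence spans two lineages, so
#'   age = divergence / (factor * mu) with factor 2 by default.
#' @param seed Integer seed; subsampling is keyed per node so dating is
#'   independent of node and sample order.
#' @return A list of class `dating_config`.
#' @export
dating_config <- function(mu = 0.76e-9, mu_low = 0.67e-9, mu_high = 0.86e-9,
                          subsample_threshold = 100L,
                          subsample_fraction = 1 / 3,
                          pair_divergence_factor = 2,
                          seed = 1L) {
  if (!(0 < mu_low && mu_low <= mu && mu <= mu_high))
    abort("Require 0 < mu_low <= mu <= mu_high.")
  structure(list(mu = mu, mu_low = mu_low, mu_high = mu_high,
                 subsample_threshold = as.integer(subsample_threshold),
                 subsample_fraction = subsample_fraction,
                 pair_divergence_factor = pair_divergence_factor,
                 seed = as.integer(seed)),
            class = "dating_config")
}

#' Pairwise divergence between two samples
#'
#' Mutational distance per site between two haploid samples: the number of
#' sites where both are called and differ, divided by the number of
#' comparable sites — the effective callable length minus sites missing in
#' either sample (invariant sites are comparable by construction).
#'
#' @param matrix A [hap_matrix()].
#' @param i,j Sample IDs or row indices, `i != j`.
#' @return Divergence in mutations per site.
#' @export
#' @examples
#' g <- rbind(a = c(1L, 0L), b = c(0L, 1L))
#' pairwise_divergence(hap_matrix(g, 1:2, 10), "a", "b")  # 2/10
pairwise_divergence <- function(matrix, i, j) {
  stopifnot(inherits(matrix, "hap_matrix"))
  gi <- matrix$geno[i, ]; gj <- matrix$geno[j, ]
  if (identical(i, j)) abort("`i` and `j` must differ.")
  both <- !is.na(gi) & !is.na(gj)
  denom <- matrix$L_effective - sum(!both)
  if (denom <= 0) abort("No comparable sites between the two samples.")
  sum(gi[both] != gj[both]) / denom
}

# divergence of every (i in A) x (j in B) pair; vectorized over sites
cross_pair_divergences <- function(matrix, A, B) {
  g <- matrix$geno
  out <- numeric(length(A) * length(B))
  k <- 0L
  for (i in A) {
    gi <- g[i, ]
    nai <- is.na(gi)
    for (j in B) {
      gj <- g[j, ]
      both <- !nai & !is.na(gj)
      denom <- matrix$L_effective - sum(!both)
      if (denom <= 0) abort("No comparable sites between a sample pair.")
      k <- k + 1L
      out[k] <- sum(gi[both] != gj[both]) / denom
    }
  }
  out
}

clade_subsample <- function(tips, config, node_key) {
  n <- length(tips)
  if (n <= config$subsample_threshold) return(tips)
  keep <- ceiling(n * config$subsample_fraction)
  withr::with_seed(derive_seed(config$seed, node_key),
                   sort(sample(sort(tips), keep)))
}

#' Mean cross-clade divergence at a node
#'
#' Averages [pairwise_divergence()] over all pairs with one sample from each
#' child clade of `node` (for multifurcations, over every pair of distinct
#' child clades). A child clade holding more than
#' `config$subsample_threshold` samples is first reduced to
#' `ceiling(n * subsample_fraction)` randomly selected samples, with a seed
#' keyed to the clade content so results do not depend on traversal or
#' sample order.
#'
#' @param tree A `mutation_tree`, [ape::phylo], or `genealogy`.
#' @param node Internal node number (phylo numbering).
#' @param matrix A [hap_matrix()] whose rows cover the tree's tips.
#' @param config A [dating_config()].
#' @return List: `divergence` (mutations/site), `n_pairs`.
#' @export
clade_divergence <- function(tree, node, matrix, config = dating_config()) {
  phy <- tree_phylo(tree)
  below <- descendant_tips(phy)
  children <- phylo_children(phy)[[node]]
  if (length(children) < 2) abort("Node must have at least two child clades.")
  groups <- lapply(children, function(ch) {
    tips <- match(phy$tip.label[below[[ch]]], rownames(matrix$geno))
    if (length(tips) == 0 || anyNA(tips))
      abort("Child clade has no samples in the matrix.")
    clade_subsample(tips, config,
                    paste(sort(phy$tip.label[below[[ch]]]), collapse = "|"))
  })
  vals <- numeric(); n_pairs <- 0L
  for (a in seq_along(groups)[-length(groups)]) {
    for (b in seq((a + 1L), length(groups))) {
      v <- cross_pair_divergences(matrix, groups[[a]], groups[[b]])
      vals <- c(vals, v)
    }
  }
  list(divergence = mean(vals), n_pairs = length(vals))
}

#' Convert a divergence to an age with a rate-uncertainty CI
#'
#' `age = divergence / (factor * mu)`; the confidence interval propagates
#' the mutation-rate uncertainty: `(d / (factor * mu_high),
#' d / (factor * mu_low))`.
#'
#' @param divergence Mutations per site, >= 0.
#' @param config A [dating_config()].
#' @return Tibble with `age`, `ci_low`, `ci_high` (years).
#' @export
#' @examples
#' date_node(8.2e-5)  # ~53,947 years, CI ~(47,674; 61,194)
date_node <- function(divergence, config = dating_config()) {
  stopifnot(all(divergence >= 0))
  f <- config$pair_divergence_factor
  tibble(age = divergence / (f * config$mu),
         ci_low = divergence / (f * config$mu_high),
         ci_high = divergence / (f * config$mu_low))
}

#' Date every internal node of a tree by the rho statistic
#'
#' @inheritParams clade_divergence
#' @return An object of class `dated_tree`: `phy`, `ages` (per-node ages in
#'   years, tips 0), and `nodes`, a tibble with one row per internal node:
#'   `node`, `divergence`, `n_pairs`, `age`, `ci_low`, `ci_high`.
#' @export
date_tree <- function(tree, matrix, config = dating_config()) {
  phy <- tree_phylo(tree)
  n <- length(phy$tip.label)
  internal <- sort(unique(phy$edge[, 1L]))
  rows <- lapply(internal, function(nd) {
    cd <- clade_divergence(tree, nd, matrix, config)
    cbind(tibble(node = nd, divergence = cd$divergence, n_pairs = cd$n_pairs),
          date_node(cd$divergence, config))
  })
  nodes <- dplyr::bind_rows(rows)
  ages <- numeric(max(phy$edge))
  ages[nodes$node] <- nodes$age
  structure(list(phy = phy, ages = ages, nodes = nodes, config = config),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  root <- x$nodes[x$nodes$node == length(x$phy$tip.label) + 1L, ]
  cat(sprintf("<dated_tree> %d tips; root age %.0f y (CI %.0f-%.0f)\n",
              length(x$phy$tip.label), root$age, root$ci_low, root$ci_high))
  invisible(x)
}

#' @rdname date_tree
#' @param x A `dated_tree`.
#' @param ... Unused.
#' @method tidy dated_tree
#' @export
tidy.dated_tree <- function(x, ...) x$nodes

#' @rdname date_tree
#' @method glance dated_tree
#' @export
glance.dated_tree <- function(x, ...) {
  root <- x$nodes[x$nodes$node == length(x$phy$tip.label) + 1L, ]
  tibble(n_tips = length(x$phy$tip.label),
         n_internal = nrow(x$nodes),
         root_age = root$age, root_ci_low = root$ci_low,
         root_ci_high = root$ci_high)
}

#' Count lineages extant at a time horizon
#'
#' The number of branches crossing time `t`: edges whose parent is older
#' than `t` and whose child is not. At `t = 0` this is the number of tips;
#' for `t` at or beyond the (clade) root age it returns 1, the stem lineage,
#' by convention.
#'
#' @param dtree A `dated_tree` (or a `genealogy`, whose true ages are used).
#' @param t Time horizon in years, >= 0.
#' @param clade Optional internal node; counting is restricted to the
#'   subtree below it.
#' @return Integer lineage count.
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 8, seed = 5))
#' lineages_through_time(gen, 0)  # 8 tips
lineages_through_time <- function(dtree, t, clade = NULL) {
  stopifnot(t >= 0)
  phy <- tree_phylo(dtree)
  ages <- dtree$ages
  edge <- phy$edge
  if (!is.null(clade)) {
    keep_nodes <- c(clade, unlist(phylo_descendants(phy, clade)))
    edge <- edge[edge[, 1L] %in% keep_nodes, , drop = FALSE]
    root_age <- ages[clade]
  } else {
    root_age <- ages[length(phy$tip.label) + 1L]
  }
  if (t >= root_age) return(1L)
  sum(ages[edge[, 1L]] > t & ages[edge[, 2L]] <= t)
}

# all nodes (internal + tips) below a node
phylo_descendants <- function(phy, node) {
  ch <- phylo_children(phy)
  out <- integer()
  stack <- ch[[node]]
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, x)
    if (x <= length(ch) && !is.null(ch[[x]])) stack <- c(stack, ch[[x]])
  }
  out
}

tree_phylo <- function(tree) {
  if (inherits(tree, "phylo")) tree
  else if (!is.null(tree$phy)) tree$phy
  else abort("Cannot extract a phylo from this object.")
}
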