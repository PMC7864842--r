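#' Simulate a dated haploid genealogy
#'
#' Draws a Kingman coalescent tree for `n_samples` haploid lineages under a
#' constant-size or piecewise-constant expansion demography. The coalescent
#' runs in generations (pairwise coalescence rate 1/Ne, so the expected
#' TMRCA is `2 Ne (1 - 1/n)` generations at constant size) and node ages are
#' reported in years via `generation_time`. If `tmrca_target` is set, all
#' node ages are rescaled so the root age equals it exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `genealogy`: a list with `phy` (rooted binary
#'   [ape::phylo] with edge lengths in years), `ages` (node ages in years,
#'   indexed by phylo node number; tips are 0), and `config`.
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 5, seed = 7))
#' max(gen$ages)  # TMRCA in years
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  if (n < 2) abort("Need at least 2 samples to coalesce.")
  set.seed(derive_seed(config$seed, "genealogy"))

  gen_time <- config$generation_time
  t_expand_gen <- config$T_expand / gen_time
  pop_size <- function(t) {
    if (config$demographic_model == "constant_Ne") return(config$Ne)
    if (t < t_expand_gen) config$Ne * config$growth else config$Ne
  }

  active <- seq_len(n)
  age_gen <- numeric(2L * n - 1L)     # provisional ids: tips 1..n, internals n+1..2n-1
  kids <- matrix(0L, nrow = n - 1L, ncol = 2L)
  t <- 0
  for (j in seq_len(n - 1L)) {
    k <- length(active)
    repeat {
      rate <- choose(k, 2) / pop_size(t)
      w <- rexp(1L, rate)
      # truncate at the demographic epoch boundary and redraw with the new rate
      if (config$demographic_model == "expansion" &&
          t < t_expand_gen && t + w > t_expand_gen) {
        t <- t_expand_gen
      } else {
        t <- t + w
        break
      }
    }
    pair <- sample(active, 2L)
    node <- n + j
    kids[j, ] <- pair
    age_gen[node] <- t
    active <- c(setdiff(active, pair), node)
  }

  ages <- age_gen * gen_time
  if (!is.null(config$tmrca_target))
    ages <- ages * (config$tmrca_target / ages[2L * n - 1L])

  # phylo numbering: tips 1..n unchanged; internal created j-th -> 2n - j,
  # so the root (last created, oldest) becomes n + 1.
  remap <- seq_len(2L * n - 1L)
  remap[n + seq_len(n - 1L)] <- 2L * n - seq_len(n - 1L)
  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  for (j in seq_len(n - 1L)) {
    edge[2L * j - 1L, ] <- c(remap[n + j], remap[kids[j, 1L]])
    edge[2L * j, ] <- c(remap[n + j], remap[kids[j, 2L]])
  }
  ages_final <- numeric(2L * n - 1L)
  ages_final[remap] <- ages
  phy <- structure(
    list(
      edge = edge,
      edge.length = ages_final[edge[, 1L]] - ages_final[edge[, 2L]],
      Nnode = n - 1L,
      tip.label = sprintf("S%03d", seq_len(n))
    ),
    class = "phylo"
  )
  phy <- ape::reorder.phylo(phy, "cladewise")
  structure(list(phy = phy, ages = ages_final, config = config),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA %.0f years\n",
              length(x$phy$tip.label), max(x$ages)))
  invisible(x)
}

# children list and descendant-tip index sets for each node of a phylo
phylo_children <- function(phy) {
  nn <- max(phy$edge)
  ch <- vector("list", nn)
  for (r in seq_len(nrow(phy$edge)))
    ch[[phy$edge[r, 1L]]] <- c(ch[[phy$edge[r, 1L]]], phy$edge[r, 2L])
  ch
}

# tips (indices) below each node, as a list indexed by node number
descendant_tips <- function(phy) {
  n <- length(phy$tip.label)
  nn <- max(phy$edge)
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  # postorder: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    below[[ord[r, 1L]]] <- c(below[[ord[r, 1L]]], below[[ord[r, 2L]]])
  }
  lapply(below, sort)
}
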