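#' Plant haplogroup-defining markers on a genealogy
#'
#' Assigns named markers to the edges above chosen internal nodes of a
#' simulated genealogy, emulating an ISOGG-style marker set: each named
#' clade receives `n_per_clade` markers on its stem edge, and the haplogroup
#' hierarchy is derived from the nesting of the named clades in the tree
#' (the parent of a haplogroup is the nearest named ancestor, or the root
#' label `"Y"`).
#'
#' @param gen A [simulate_genealogy()] result.
#' @param clade_names Either a named integer vector mapping haplogroup names
#'   to internal phylo node numbers, or the string `"auto"` to name every
#'   internal node below the root `HG1`, `HG2`, ... in cladewise order.
#' @param n_per_clade Markers planted per named clade (default 2).
#' @param seed Integer seed for marker positions/alleles.
#' @return A list of class `marker_set`: `markers` (tibble: `name`, `pos`,
#'   `ancestral`, `derived`, `haplogroup`), `haplogroups` (tibble:
#'   `haplogroup`, `parent`, `node`), `genotypes` (samples x markers matrix
#'   over {0 ancestral, 1 derived}), and `truth` (tibble: `sample_id`,
#'   `clade` — each tip's smallest named enclosing clade).
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 6, seed = 2))
#' ms <- plant_markers(gen, "auto")
#' head(ms$markers)
plant_markers <- function(gen, clade_names = "auto", n_per_clade = 2L,
                          seed = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  phy <- gen$phy
  n <- length(phy$tip.label)
  root <- n + 1L
  if (identical(clade_names, "auto")) {
    internals <- setdiff(sort(unique(phy$edge[, 1L])), root)
    clade_names <- setNames(internals, paste0("HG", seq_along(internals)))
  }
  if (is.null(names(clade_names)) || any(names(clade_names) == ""))
    abort("`clade_names` must be a named vector: haplogroup -> node number.")
  nodes <- as.integer(clade_names)
  if (any(nodes <= n) || any(nodes > 2L * n - 1L) || any(nodes == root))
    abort("Unknown clade: nodes must be internal, non-root node numbers.")
  if (anyDuplicated(nodes)) abort("Each node may carry one haplogroup name.")

  seed <- seed %||% derive_seed(gen$config$seed, "markers")
  set.seed(seed)

  # parent of each named node = nearest named ancestor (or root label "Y")
  parent_of <- integer(max(phy$edge))
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  name_of <- setNames(names(clade_names), nodes)
  hg_parent <- vapply(nodes, function(nd) {
    p <- parent_of[nd]
    while (p != root && is.na(name_of[as.character(p)])) p <- parent_of[p]
    if (p == root) "Y" else unname(name_of[as.character(p)])
  }, character(1))
  haplogroups <- tibble(haplogroup = names(clade_names), parent = hg_parent,
                        node = nodes)

  below <- descendant_tips(phy)
  L <- gen$config$L
  total <- length(nodes) * n_per_clade
  pos <- sample.int(L, total)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, total, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), character(1))
  markers <- tibble(
    name = paste0(rep(names(clade_names), each = n_per_clade), "-M",
                  seq_len(total)),
    pos = as.integer(pos), ancestral = anc, derived = der,
    haplogroup = rep(names(clade_names), each = n_per_clade)
  )

  geno <- matrix(0L, nrow = n, ncol = total,
                 dimnames = list(phy$tip.label, markers$name))
  for (k in seq_along(nodes)) {
    cols <- (k - 1L) * n_per_clade + seq_len(n_per_clade)
    geno[below[[nodes[k]]], cols] <- 1L
  }

  # each tip's smallest named enclosing clade (root label if none)
  sizes <- lengths(below)[nodes]
  truth_clade <- rep("Y", n)
  for (k in order(sizes, decreasing = TRUE))
    truth_clade[below[[nodes[k]]]] <- names(clade_names)[k]
  structure(
    list(markers = markers, haplogroups = haplogroups, genotypes = geno,
         truth = tibble(sample_id = phy$tip.label, clade = truth_clade)),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers on %d haplogroups, %d samples\n",
              nrow(x$markers), nrow(x$haplogroups), nrow(x$genotypes)))
  invisible(x)
}
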