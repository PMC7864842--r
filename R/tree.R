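#' Four-gamete incompatibility scan
#'
#' Two biallelic sites are incompatible with a single mutation each on one
#' tree exactly when the jointly called samples exhibit all four gametes
#' 00, 01, 10, 11. An empty result on complete data certifies that a perfect
#' phylogeny exists.
#'
#' @param matrix A [hap_matrix()]; missing entries are allowed (each pair is
#'   evaluated on its jointly non-missing samples).
#' @return A tibble of incompatible pairs: `site_a`, `site_b` (column
#'   indices, `site_a < site_b`).
#' @export
four_gamete_scan <- function(matrix) {
  stopifnot(inherits(matrix, "hap_matrix"))
  g <- matrix$geno
  if (ncol(g) < 2) return(tibble(site_a = integer(), site_b = integer()))
  A1 <- (!is.na(g)) & g == 1L
  A0 <- (!is.na(g)) & g == 0L
  storage.mode(A1) <- storage.mode(A0) <- "numeric"
  n11 <- crossprod(A1)
  n00 <- crossprod(A0)
  n10 <- crossprod(A1, A0)  # [a,b]: derived at a, ancestral at b
  bad <- n11 > 0 & n00 > 0 & n10 > 0 & t(n10) > 0
  bad[lower.tri(bad, diag = TRUE)] <- FALSE
  idx <- which(bad, arr.ind = TRUE)
  tibble(site_a = as.integer(idx[, 1L]), site_b = as.integer(idx[, 2L]))
}

#' Build a rooted mutation tree from a binary haplotype matrix
#'
#' Constructs the perfect phylogeny implied by the derived-carrier sets of
#' the sites (the ancestral state roots the tree): identical carrier sets
#' share one edge; the laminar family of carrier sets becomes the clade
#' hierarchy. Sites incompatible with the family are placed by greedy
#' parsimony on the minimal set of existing clades covering their carriers
#' (recurrent placement) and reported in `conflicts`. A sample missing at a
#' site is imputed derived when every non-missing member of the enclosing
#' clade is derived (the carrier set is "snapped" to that clade), otherwise
#' ancestral.
#'
#' @param matrix A [hap_matrix()] with at least one sample.
#' @return An object of class `mutation_tree`: `phy` (rooted [ape::phylo],
#'   edge lengths = mutation counts, possibly multifurcating), `edge_sites`
#'   (per-edge column indices), `n_sites`, `conflicts` (tibble: `site`,
#'   `n_placements`), `fixed_sites` (sites derived in every sample; they
#'   define no split).
#' @export
#' @examples
#' g <- rbind(A = c(1L, 1L, 0L), B = c(1L, 0L, 0L), C = c(0L, 0L, 1L))
#' tr <- build_tree(hap_matrix(g, c(10L, 20L, 30L), 100))
#' ape::is.rooted(tr$phy)
build_tree <- function(matrix) {
  stopifnot(inherits(matrix, "hap_matrix"))
  g <- matrix$geno
  n <- nrow(g)
  if (n == 0) abort("Empty matrix: no samples.")
  p <- ncol(g)
  ids <- rownames(g) %||% sprintf("S%03d", seq_len(n))

  key_of <- function(s) paste(s, collapse = ",")
  full <- seq_len(n)
  fam <- new.env(parent = emptyenv())      # key -> sorted member vector
  sites_of <- new.env(parent = emptyenv()) # key -> site columns
  assign(key_of(full), full, envir = fam)
  for (i in full) assign(key_of(i), i, envir = fam)

  carriers <- lapply(seq_len(p), function(s) which(!is.na(g[, s]) & g[, s] == 1L))
  missing_at <- lapply(seq_len(p), function(s) which(is.na(g[, s])))
  fixed_sites <- integer()
  conflicts <- list()

  add_site <- function(key, s) {
    cur <- if (exists(key, envir = fam)) get0(key, envir = sites_of) else NULL
    assign(key, c(cur, s), envir = sites_of)
  }

  for (s in order(lengths(carriers), decreasing = TRUE)) {
    S <- carriers[[s]]
    if (length(S) == 0L) next  # all carriers missing; leave unplaced
    clades <- as.list(fam)
    # snap to the largest existing non-root clade whose extra members are all
    # missing at this site: dropout inside a derived clade imputes derived
    snap <- NULL
    for (C in clades) {
      if (length(C) < n && length(C) >= length(S) && all(S %in% C) &&
          all(setdiff(C, S) %in% missing_at[[s]]) &&
          (is.null(snap) || length(C) > length(snap))) snap <- C
    }
    if (!is.null(snap) && length(snap) > length(S)) S <- snap
    if (length(S) == n) { fixed_sites <- c(fixed_sites, s); next }
    compatible <- all(vapply(clades, function(C) {
      ov <- sum(S %in% C)
      ov == 0L || ov == length(S) || (ov == length(C) && all(C %in% S))
    }, logical(1)))
    if (compatible) {
      assign(key_of(S), S, envir = fam)
      add_site(key_of(S), s)
    } else {
      # greedy cover of S by existing clades (singletons guarantee progress)
      remaining <- S
      n_placed <- 0L
      while (length(remaining) > 0L) {
        best <- NULL
        for (C in clades) {
          if (all(C %in% remaining) &&
              (is.null(best) || length(C) > length(best))) best <- C
        }
        add_site(key_of(best), s)
        n_placed <- n_placed + 1L
        remaining <- setdiff(remaining, best)
      }
      conflicts[[length(conflicts) + 1L]] <-
        tibble(site = s, n_placements = n_placed)
    }
  }

  # clade hierarchy: parent = smallest strictly containing internal clade
  clades <- as.list(fam)
  internal <- clades[lengths(clades) >= 2L]
  internal <- internal[order(lengths(internal), decreasing = TRUE)]
  if (length(internal) == 0L || length(internal[[1L]]) < n)
    internal <- c(list(full), internal)
  n_int <- length(internal)
  parent_int <- rep(NA_integer_, n_int)
  for (k in seq_len(n_int)[-1L]) {
    for (j in seq_len(n_int)) {
      if (j != k && length(internal[[j]]) > length(internal[[k]]) &&
          all(internal[[k]] %in% internal[[j]]) &&
          (is.na(parent_int[k]) ||
           length(internal[[j]]) < length(internal[[parent_int[k]]])))
        parent_int[k] <- j
    }
  }
  tip_parent <- vapply(full, function(i) {
    best <- 1L
    for (j in seq_len(n_int))
      if (i %in% internal[[j]] &&
          length(internal[[j]]) < length(internal[[best]])) best <- j
    best
  }, integer(1))

  # DFS pre-order construction (cladewise edges; children sorted by
  # smallest member for lexicographic determinism)
  kids_int <- lapply(seq_len(n_int), function(j) which(parent_int == j))
  kids_tip <- lapply(seq_len(n_int), function(j) which(tip_parent == j))
  node_num <- integer(n_int)
  edges <- list(); edge_sites <- list()
  next_internal <- n + 1L
  visit <- function(j) {
    node_num[j] <<- next_internal
    next_internal <<- next_internal + 1L
    ch_i <- kids_int[[j]][order(vapply(kids_int[[j]],
                                       function(q) min(internal[[q]]), 1L))]
    ch_all <- c(lapply(ch_i, function(q) list(type = "int", id = q)),
                lapply(kids_tip[[j]], function(i) list(type = "tip", id = i)))
    ord <- order(vapply(ch_all, function(ch)
      if (ch$type == "int") min(internal[[ch$id]]) else ch$id, 1L))
    for (ch in ch_all[ord]) {
      if (ch$type == "int") {
        me <- node_num[j]
        child_num <- next_internal  # assigned on visit
        edges[[length(edges) + 1L]] <<- c(me, NA)
        slot <- length(edges)
        edge_sites[[slot]] <<-
          get0(key_of(internal[[ch$id]]), envir = sites_of) %||% integer()
        visit(ch$id)
        edges[[slot]][2L] <<- node_num[ch$id]
      } else {
        edges[[length(edges) + 1L]] <<- c(node_num[j], ch$id)
        edge_sites[[length(edges)]] <<-
          get0(key_of(ch$id), envir = sites_of) %||% integer()
      }
    }
  }
  if (n == 1L) {
    phy <- structure(list(edge = base::matrix(c(2L, 1L), 1L, 2L),
                          edge.length = p, Nnode = 1L, tip.label = ids),
                     class = "phylo", order = "cladewise")
    return(structure(list(phy = phy, edge_sites = list(seq_len(p)),
                          n_sites = p,
                          conflicts = tibble(site = integer(),
                                             n_placements = integer()),
                          fixed_sites = integer()),
                     class = "mutation_tree"))
  }
  visit(1L)
  edge <- do.call(rbind, edges)
  storage.mode(edge) <- "integer"
  phy <- structure(
    list(edge = edge,
         edge.length = as.numeric(lengths(edge_sites)),
         Nnode = n_int, tip.label = ids),
    class = "phylo", order = "cladewise")
  structure(
    list(phy = phy, edge_sites = edge_sites, n_sites = p,
         conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts)
                     else tibble(site = integer(), n_placements = integer()),
         fixed_sites = fixed_sites),
    class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("<mutation_tree> %d tips, %d sites placed, %d conflicting\n",
              length(x$phy$tip.label), x$n_sites, nrow(x$conflicts)))
  invisible(x)
}

#' Regenerate genotypes implied by a mutation tree
#'
#' Inverse of [build_tree()]: every sample below an edge carrying a site is
#' derived there, all others ancestral (fixed sites are derived everywhere).
#'
#' @param tree A `mutation_tree`.
#' @return Integer samples x sites matrix over {0, 1}.
#' @export
tree_genotypes <- function(tree) {
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  n <- length(phy$tip.label)
  below <- descendant_tips(phy)
  g <- base::matrix(0L, n, tree$n_sites, dimnames = list(phy$tip.label, NULL))
  for (e in seq_along(tree$edge_sites)) {
    ss <- tree$edge_sites[[e]]
    if (length(ss)) g[below[[phy$edge[e, 2L]]], ss] <- 1L
  }
  if (length(tree$fixed_sites)) g[, tree$fixed_sites] <- 1L
  g
}

#' Midpoint rooting
#'
#' Re-roots a tree at the midpoint of its longest tip-to-tip path in the
#' edge-length (mutation-count) metric. Ties between equally long paths are
#' broken on the lexicographically smallest tip-label pair, making the
#' result deterministic. The unrooted topology is unchanged.
#'
#' @param tree A `mutation_tree` or [ape::phylo] with edge lengths.
#' @return Same class as the input with `phy` re-rooted (for a
#'   `mutation_tree`, per-edge site lists are dropped since edge identities
#'   change; lengths remain mutation counts).
#' @export
midpoint_root <- function(tree) {
  phy <- if (inherits(tree, "mutation_tree")) tree$phy else tree
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  n <- length(phy$tip.label)
  if (n < 2) return(tree)
  D <- ape::dist.nodes(phy)
  Dt <- D[seq_len(n), seq_len(n), drop = FALSE]
  dmax <- max(Dt)
  cand <- which(Dt >= dmax - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
  labs <- phy$tip.label
  pair_lab <- t(apply(cand, 1L, function(r) sort(labs[r])))
  best <- order(pair_lab[, 1L], pair_lab[, 2L])[1L]
  a <- cand[best, 1L]; b <- cand[best, 2L]
  path <- ape::nodepath(phy, a, b)
  target <- dmax / 2
  # walk from a; find the edge containing the midpoint
  acc <- 0
  for (k in seq_len(length(path) - 1L)) {
    step <- D[path[k], path[k + 1L]]
    if (acc + step >= target - 1e-9) {
      into <- target - acc               # distance from path[k]
      u <- path[k]; v <- path[k + 1L]
      # identify the child end of edge (u,v)
      ek <- which((phy$edge[, 1L] == u & phy$edge[, 2L] == v) |
                  (phy$edge[, 1L] == v & phy$edge[, 2L] == u))
      child <- phy$edge[ek, 2L]
      # phytools::reroot measures position from the parent end of the edge
      dist_from_parent <- if (phy$edge[ek, 1L] == u) into else step - into
      newphy <- phytools::reroot(phy, child,
                                 position = min(max(dist_from_parent, 0), step))
      if (inherits(tree, "mutation_tree")) {
        tree$phy <- newphy
        tree$edge_sites <- NULL
        return(tree)
      }
      return(newphy)
    }
    acc <- acc + step
  }
  tree
}

#' Flag samples with unusually long terminal branches
#'
#' Tips whose terminal mutation count exceeds `median + threshold_mads * MAD`
#' of all terminal branch lengths are flagged for QC (not removed). The MAD
#' uses the usual 1.4826 consistency constant.
#'
#' @param tree A `mutation_tree` or [ape::phylo] with edge lengths.
#' @param threshold_mads Number of MADs above the median (default 6);
#'   `Inf` flags nothing.
#' @return Character vector of flagged sample IDs.
#' @export
flag_long_terminal_branches <- function(tree, threshold_mads = 6) {
  phy <- if (inherits(tree, "mutation_tree")) tree$phy else tree
  stopifnot(inherits(phy, "phylo"))
  if (is.infinite(threshold_mads)) return(character())
  n <- length(phy$tip.label)
  is_tip <- phy$edge[, 2L] <= n
  len <- phy$edge.length[is_tip]
  tip <- phy$edge[is_tip, 2L]
  cut <- median(len) + threshold_mads * mad(len)
  sort(phy$tip.label[tip[len > cut]])
}
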