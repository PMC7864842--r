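#' Assign a haplogroup to one sample by marker-tree descent
#'
#' Walks the haplogroup hierarchy from its root: at each node the walk
#' descends into the child whose typed markers show the highest fraction of
#' derived states, requiring at least one derived marker and a fraction of
#' at least 0.5; it stops when no child qualifies. The assignment is the
#' deepest node reached, named by its most terminal derived marker. Derived
#' markers off the accepted path are reported as conflicts (they never
#' retract an assignment); path markers with missing genotypes are listed
#' under `missing`.
#'
#' @param genotypes Named vector of marker states for one sample: 1 derived,
#'   0 ancestral, NA missing; names are marker names.
#' @param markers Marker table: tibble with `name` and `haplogroup` columns
#'   (e.g. from [plant_markers()]).
#' @param haplogroups Haplogroup hierarchy: tibble with `haplogroup` and
#'   `parent` columns; parents not themselves listed are roots (conventional
#'   root label `"Y"`).
#' @param min_fraction Minimum derived fraction to enter a child (default
#'   0.5).
#' @return A one-row tibble: `haplogroup`, `terminal_marker`, `path`
#'   (slash-joined), `n_derived_path`, `conflicts`, `missing`.
#' @export
call_haplogroup <- function(genotypes, markers, haplogroups,
                            min_fraction = 0.5) {
  stopifnot(all(c("name", "haplogroup") %in% names(markers)),
            all(c("haplogroup", "parent") %in% names(haplogroups)))
  root <- setdiff(haplogroups$parent, haplogroups$haplogroup)
  if (length(root) != 1)
    abort("Haplogroup names must form a tree with a single root.")
  g <- genotypes[markers$name]
  names(g) <- markers$name
  if (all(is.na(g))) {
    return(tibble(haplogroup = "unresolved", terminal_marker = NA_character_,
                  path = "", n_derived_path = 0L, conflicts = "",
                  missing = ""))
  }
  hg_markers <- split(markers$name, markers$haplogroup)
  children <- split(haplogroups$haplogroup, haplogroups$parent)

  score <- function(hg) {
    states <- g[hg_markers[[hg]]]
    typed <- sum(!is.na(states))
    derived <- sum(states == 1L, na.rm = TRUE)
    c(frac = if (typed == 0) 0 else derived / typed, typed = typed,
      derived = derived)
  }
  # derived markers anywhere in the subtree rooted at hg (for walking past a
  # node whose own markers are all untyped: the most terminal derived SNV
  # decides, not an uncheckable intermediate)
  subtree_derived <- function(hg) {
    own <- sum(g[hg_markers[[hg]]] == 1L, na.rm = TRUE)
    own + sum(vapply(children[[hg]] %||% character(), subtree_derived,
                     numeric(1)))
  }

  node <- root
  path <- character(); path_markers <- character()
  repeat {
    ch <- sort(children[[node]])
    if (length(ch) == 0) break
    sc <- vapply(ch, score, c(frac = 0, typed = 0, derived = 0))
    ok <- sc["frac", ] >= min_fraction & sc["derived", ] >= 1
    if (any(ok)) {
      node <- ch[ok][which.max(sc["frac", ok])]
    } else {
      # children with no typed markers but derived evidence below
      deeper <- vapply(ch, function(h)
        if (sc["typed", h] == 0) subtree_derived(h) else 0,
        numeric(1))
      if (!any(deeper > 0)) break
      node <- ch[which.max(deeper)]
    }
    path <- c(path, node)
    path_markers <- c(path_markers, hg_markers[[node]])
  }

  derived_markers <- names(g)[!is.na(g) & g == 1L]
  terminal <- utils::tail(intersect(
    markers$name[markers$haplogroup == node], derived_markers), 1L)
  tibble(
    haplogroup = node,
    terminal_marker = if (length(terminal)) terminal else NA_character_,
    path = paste(path, collapse = "/"),
    n_derived_path = sum(path_markers %in% derived_markers),
    conflicts = paste(sort(setdiff(derived_markers, path_markers)),
                      collapse = ","),
    missing = paste(sort(path_markers[is.na(g[path_markers])]),
                    collapse = ",")
  )
}

#' Call haplogroups for a cohort
#'
#' One [call_haplogroup()] per sample; calls are independent across samples
#' and invariant to sample order.
#'
#' @param genotypes Samples x markers matrix over {0, 1, NA} (e.g.
#'   `plant_markers()$genotypes`), or a [marker_set] (its genotypes are
#'   used).
#' @inheritParams call_haplogroup
#' @return Tibble with one row per sample (`sample_id` + the
#'   [call_haplogroup()] columns); a per-haplogroup count table is attached
#'   as attribute `summary`.
#' @export
#' @examples
#' gen <- simulate_genealogy(sim_config(n_samples = 6, seed = 2))
#' ms <- plant_markers(gen, "auto")
#' call_haplogroups(ms$genotypes, ms$markers, ms$haplogroups)
call_haplogroups <- function(genotypes, markers, haplogroups,
                             min_fraction = 0.5) {
  if (inherits(genotypes, "marker_set")) {
    ms <- genotypes
    genotypes <- ms$genotypes
    if (missing(markers)) markers <- ms$markers
    if (missing(haplogroups)) haplogroups <- ms$haplogroups
  }
  if (nrow(genotypes) == 0) {
    out <- tibble(sample_id = character(), haplogroup = character(),
                  terminal_marker = character(), path = character(),
                  n_derived_path = integer(), conflicts = character(),
                  missing = character())
    attr(out, "summary") <- tibble(haplogroup = character(), n = integer())
    return(out)
  }
  rows <- lapply(rownames(genotypes), function(s) {
    dplyr::bind_cols(tibble(sample_id = s),
                     call_haplogroup(genotypes[s, ], markers, haplogroups,
                                     min_fraction))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- dplyr::count(out, .data$haplogroup)
  out
}

#' Apply nomenclature overrides to haplogroup calls
#'
#' Replaces the haplogroup label of listed samples (keys may be sample IDs
#' or terminal marker names), keeping the original call as provenance.
#' Overrides naming absent samples produce a warning, not an error.
#'
#' @param calls Tibble from [call_haplogroups()].
#' @param overrides Named character vector: sample ID (or terminal marker
#'   name) -> replacement haplogroup label.
#' @return `calls` with updated `haplogroup` plus `original_haplogroup` and
#'   `override_applied` columns.
#' @export
apply_nomenclature_overrides <- function(calls, overrides) {
  calls$original_haplogroup <- calls$haplogroup
  calls$override_applied <- FALSE
  if (length(overrides) == 0) return(calls)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    abort("`overrides` must be a named vector.")
  for (key in names(overrides)) {
    hit <- calls$sample_id == key |
      (!is.na(calls$terminal_marker) & calls$terminal_marker == key)
    if (!any(hit)) {
      warn(sprintf("Override key '%s' matches no sample or terminal marker.",
                   key))
      next
    }
    calls$haplogroup[hit] <- overrides[[key]]
    calls$override_applied[hit] <- TRUE
  }
  calls
}
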