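#' Pipeline configuration
#'
#' Assembles stage toggles and per-module parameters for [run_pipeline()].
#' Accepts a YAML file path or nested lists; anything omitted falls back to
#' the module defaults ([sim_config()], [dating_config()], the filter
#' thresholds and map parameters).
#'
#' @param config YAML path or named list with optional entries `stages`
#'   (character subset of simulate/filter/tree/date/haplogroup/map, in
#'   pipeline order), `seed`, `sim`, `dating`, `filters`, `maps` (each a
#'   named list of arguments), and `input` (paths `vcf` and `sample_meta`
#'   used by the filter stage when the simulate stage is disabled).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "filter", "tree", "date", "haplogroup", "map")
  stages <- config$stages %||% stages_all
  if (!all(stages %in% stages_all)) abort("Unknown stage name.")
  input <- config$input %||% list()
  for (f in unlist(input))
    if (!file.exists(f)) abort(sprintf("Input file not found: %s", f))
  structure(list(
    stages = stages_all[stages_all %in% stages],
    seed = as.integer(config$seed %||% 1L),
    sim = config$sim %||% list(),
    dating = config$dating %||% list(),
    filters = config$filters %||% list(),
    maps = config$maps %||% list(),
    input = input
  ), class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes, in order, the enabled stages: simulate (genealogy, mutations,
#' artifacts, markers, populations; writes the VCF and truth files), filter
#' (the genotype/sample/site filter chain), tree (perfect-phylogeny
#' construction + terminal-branch QC), date (rho dating of internal nodes),
#' haplogroup (marker-tree descent calls), and map (per-haplogroup Shepard
#' frequency, presence and combination grids). Every output file is
#' recorded in a manifest with its MD5 hash; reruns with the same seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()] (or YAML path / list coerced to one).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `manifest` (tibble: stage, file, md5) and
#'   `objects` (the in-memory stage results).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- character(); stage_of <- character()
  emit <- function(stage, f) {
    files <<- c(files, path(f)); stage_of <<- c(stage_of, stage)
  }
  obj <- list()
  run <- function(stage, body) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    tryCatch(body(), error = function(e)
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e))))
  }

  run("simulate", function() {
    scfg <- do.call(sim_config, c(config$sim,
                                  if (is.null(config$sim$seed))
                                    list(seed = config$seed)))
    gen <- simulate_genealogy(scfg)
    truth <- drop_mutations(gen)
    calls <- inject_artifacts(truth, scfg)
    markers <- plant_markers(gen, "auto")
    pops <- simulate_populations(gen)
    write_haploid_vcf(calls, path("calls.vcf"),
                      params = scfg[c("n_samples", "mu", "L", "seed")])
    readr::write_tsv(calls$samples, path("sample_metadata.tsv"))
    write_dated_newick(gen, path("true_genealogy.nwk"))
    readr::write_tsv(markers$markers, path("markers.tsv"))
    readr::write_tsv(markers$haplogroups, path("haplogroup_tree.tsv"))
    readr::write_tsv(pops, path("populations.tsv"))
    for (f in c("calls.vcf", "sample_metadata.tsv", "true_genealogy.nwk",
                "markers.tsv", "haplogroup_tree.tsv", "populations.tsv"))
      emit("simulate", f)
    obj <<- c(obj, list(sim_config = scfg, genealogy = gen, truth = truth,
                        calls = calls, markers = markers, pops = pops))
  })

  run("filter", function() {
    if (is.null(obj$calls) && !is.null(config$input$vcf)) {
      meta <- if (!is.null(config$input$sample_meta))
        readr::read_tsv(config$input$sample_meta, show_col_types = FALSE)
      obj$calls <<- read_haploid_vcf(config$input$vcf, sample_meta = meta)
    }
    if (is.null(obj$calls))
      abort("filter stage needs simulated calls or an input VCF.")
    res <- do.call(filter_calls, c(list(obj$calls), config$filters))
    jsonlite::write_json(unclass(res$report), path("filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(as_tibble(res$matrix), path("matrix.tsv"))
    emit("filter", "filter_report.json"); emit("filter", "matrix.tsv")
    obj <<- c(obj, list(matrix = res$matrix, report = res$report))
  })

  run("tree", function() {
    if (is.null(obj$matrix)) abort("tree stage needs a filtered matrix.")
    tr <- build_tree(obj$matrix)
    flagged <- flag_long_terminal_branches(tr)
    ape::write.tree(tr$phy, path("tree.nwk"))
    writeLines(flagged, path("flagged_samples.txt"))
    emit("tree", "tree.nwk"); emit("tree", "flagged_samples.txt")
    obj <<- c(obj, list(tree = tr, flagged = flagged))
  })

  run("date", function() {
    if (is.null(obj$tree)) abort("date stage needs a tree.")
    dcfg <- do.call(dating_config, c(config$dating,
                                     if (is.null(config$dating$seed))
                                       list(seed = config$seed)))
    dt <- date_tree(obj$tree, obj$matrix, dcfg)
    write_dated_newick(dt, path("dated_tree.nwk"))
    write_dating_table(dt, path("node_ages.tsv"))
    emit("date", "dated_tree.nwk"); emit("date", "node_ages.tsv")
    obj <<- c(obj, list(dated_tree = dt))
  })

  run("haplogroup", function() {
    if (is.null(obj$markers)) abort("haplogroup stage needs markers.")
    hg <- call_haplogroups(obj$markers)
    readr::write_tsv(hg, path("haplogroup_calls.tsv"))
    emit("haplogroup", "haplogroup_calls.tsv")
    obj <<- c(obj, list(haplogroup_calls = hg)) # nolint
  })

  run("map", function() {
    if (is.null(obj$haplogroup_calls)) abort("map stage needs calls.")
    ptab <- population_haplogroup_counts(obj$pops, obj$haplogroup_calls)
    cols <- grep("^count_", names(ptab), value = TRUE)
    totals <- vapply(cols, function(cc) sum(ptab[[cc]]), numeric(1))
    focal <- head(cols[order(-totals)], 3L)
    presence <- list()
    for (cc in focal) {
      merged <- do.call(merge_populations,
                        c(list(ptab, cc),
                          config$maps[intersect(names(config$maps),
                                                "target_mean")]))
      fg <- do.call(shepard_interpolate,
                    c(list(merged, merged[[cc]] / merged$n),
                      config$maps[intersect(names(config$maps),
                                            c("power", "radius_km", "kernel",
                                              "cell_deg"))]))
      readr::write_tsv(fg, path(paste0("freq_", sub("count_", "", cc), ".tsv")))
      emit("map", paste0("freq_", sub("count_", "", cc), ".tsv"))
      presence[[cc]] <- presence_map(fg)
    }
    combo <- combine_presence(unname(presence))
    readr::write_tsv(combo, path("combination_map.tsv"))
    emit("map", "combination_map.tsv")
    obj <<- c(obj, list(presence_maps = presence, combination = combo))
  })

  manifest <- tibble(stage = stage_of, file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  manifest_out <- dplyr::bind_rows(
    manifest, tibble(stage = "run", file = "seed",
                     md5 = as.character(config$seed)))
  readr::write_tsv(manifest_out, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, objects = obj, out_dir = out_dir))
}
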