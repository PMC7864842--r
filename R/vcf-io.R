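#' Write a haploid call set as VCF 4.2
#'
#' Plain-text VCF with `GT:DP:AD` genotypes, ploidy 1, contig `chrY`, and
#' the simulation/provenance parameters recorded as `##ylineage_*` header
#' lines. Formatting is deterministic, so identical call sets yield
#' byte-identical files.
#'
#' @param calls A [haploid_calls()].
#' @param path Output path (`.vcf`).
#' @param params Optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_haploid_vcf <- function(calls, path, params = list()) {
  stopifnot(inherits(calls, "haploid_calls"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrY,length=%d>", as.integer(calls$L)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    vapply(names(params), function(k)
      sprintf("##ylineage_%s=%s", k, format(params[[k]], scientific = FALSE)),
      character(1)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$samples$sample_id), collapse = "\t")
  )
  n <- nrow(calls$samples); p <- nrow(calls$sites)
  gt_chr <- base::matrix(".", n, p)
  gt_chr[!is.na(calls$gt)] <- as.character(calls$gt[!is.na(calls$gt)])
  ad_ref <- ifelse(calls$gt == 1L & !is.na(calls$gt),
                   calls$ad_other, calls$ad_called)
  ad_alt <- ifelse(calls$gt == 1L & !is.na(calls$gt),
                   calls$ad_called, calls$ad_other)
  ad_ref[is.na(calls$gt)] <- calls$ad_called[is.na(calls$gt)]
  ad_alt[is.na(calls$gt)] <- calls$ad_other[is.na(calls$gt)]
  cell <- base::matrix(
    paste0(gt_chr, ":", calls$dp, ":", ad_ref, ",", ad_alt), n, p)
  body <- vapply(seq_len(p), function(s) {
    paste(c("chrY", calls$sites$pos[s], ".", calls$sites$ref[s],
            calls$sites$alt[s], ".", "PASS",
            paste0("TYPE=", calls$sites$type[s]), "GT:DP:AD", cell[, s]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a haploid VCF 4.2 back into a call set
#'
#' Parses a `GT:DP:AD` haploid VCF (as written by [write_haploid_vcf()] or
#' produced by a joint caller) with vcfR. Record type is taken from the
#' `TYPE` INFO key when present, otherwise inferred from allele lengths.
#'
#' @param path VCF path.
#' @param sample_meta Optional tibble (`sample_id`, `mean_depth`,
#'   `low_coverage`); defaults assume high coverage (mean 30x, not
#'   low-coverage).
#' @param L Callable length; defaults to the `chrY` contig length in the
#'   header.
#' @return A [haploid_calls()].
#' @export
read_haploid_vcf <- function(path, sample_meta = NULL, L = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(L)) {
    ctg <- grep("^##contig=<ID=chrY", v@meta, value = TRUE)
    if (length(ctg) == 1)
      L <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg))
    else abort("No chrY contig length in header; supply `L`.")
  }
  type <- ifelse(grepl("TYPE=indel", fix$INFO %||% ""), "indel",
                 ifelse(nchar(fix$REF) != nchar(fix$ALT), "indel", "SNV"))
  sites <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT, type = type)
  gt_raw <- t(vcfR::extract.gt(v, "GT"))
  dp <- t(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  ad <- t(vcfR::extract.gt(v, "AD"))
  gt <- base::matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  gt[gt_raw == "0"] <- 0L
  gt[gt_raw == "1"] <- 1L
  ad_ref <- apply(ad, 2L, function(x) as.integer(sub(",.*", "", x)))
  ad_alt <- apply(ad, 2L, function(x) as.integer(sub(".*,", "", x)))
  if (is.null(dim(ad_ref))) {  # single sample
    ad_ref <- base::matrix(ad_ref, nrow = 1L)
    ad_alt <- base::matrix(ad_alt, nrow = 1L)
  }
  ad_called <- ifelse(!is.na(gt) & gt == 1L, ad_alt, ad_ref)
  ad_other <- ifelse(!is.na(gt) & gt == 1L, ad_ref, ad_alt)
  ids <- rownames(gt_raw)
  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = ids, mean_depth = 30,
                          low_coverage = FALSE)
  }
  sample_meta <- sample_meta[match(ids, sample_meta$sample_id), ]
  ord <- order(sites$pos)
  haploid_calls(sample_meta, sites[ord, ],
                gt = gt[, ord, drop = FALSE],
                dp = base::matrix(as.integer(dp), nrow(gt))[, ord, drop = FALSE],
                ad_called = ad_called[, ord, drop = FALSE],
                ad_other = ad_other[, ord, drop = FALSE],
                L = L)
}

#' Write/read a dated tree as Newick with node-age labels
#'
#' Node ages (years) are stored as internal node labels of the Newick
#' string; [read_dated_newick()] restores them.
#'
#' @param x A `genealogy` or `dated_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dated_newick <- function(x, path) {
  phy <- tree_phylo(x)
  n <- length(phy$tip.label)
  internal <- (n + 1L):(n + phy$Nnode)
  phy$node.label <- sprintf("%.6f", x$ages[internal])
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_dated_newick
#' @return For `read_dated_newick()`: a list with `phy` and `ages`.
#' @export
read_dated_newick <- function(path) {
  phy <- ape::read.tree(path)
  n <- length(phy$tip.label)
  ages <- numeric(n + phy$Nnode)
  ages[(n + 1L):(n + phy$Nnode)] <- as.numeric(phy$node.label)
  list(phy = phy, ages = ages)
}

#' Write the per-node dating table
#'
#' @param dtree A `dated_tree`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dating_table <- function(dtree, path) {
  readr::write_tsv(dtree$nodes, path)
  invisible(path)
}
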