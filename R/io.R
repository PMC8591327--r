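# Tab-separated and VCF interfaces.  All tabular files carry headers and
# are tab-separated.

#' Read / write a haplotype panel as TSV
#'
#' Layout: rows are haplotypes (two consecutive rows per individual, in
#' panel order), columns are loci; the header holds locus ids and the
#' first column (`haplotype`) the `<id>_h1` / `<id>_h2` labels.
#'
#' @param file Path.
#' @param panel A `haplotype_panel`.
#' @param generation Generation index to assign on read.
#' @return `read_haplotypes_tsv()` returns a `haplotype_panel`;
#'   `write_haplotypes_tsv()` returns `file` invisibly.
#' @export
write_haplotypes_tsv <- function(panel, file) {
  stopifnot(inherits(panel, "haplotype_panel"))
  df <- data.frame(haplotype = rownames(panel$alleles), panel$alleles,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_haplotypes_tsv
#' @export
read_haplotypes_tsv <- function(file, generation = 0L) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1]]
  a <- as.matrix(df[, -1, drop = FALSE])
  ids <- unique(sub("_h[12]$", "", labels))
  haplotype_panel(a, ids = ids, generation = generation)
}

#' Read / write a genetic map as TSV
#'
#' Columns: `locus`, `chrom`, `pos_cM`.
#'
#' @param map A `genetic_map`.
#' @param file Path.
#' @return `read_map_tsv()` returns a `genetic_map`.
#' @export
write_map_tsv <- function(map, file) {
  utils::write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  genetic_map(df$locus, df$chrom, df$pos_cM)
}

#' Read / write allelic effects as TSV
#'
#' Columns: `locus`, `effect`.
#'
#' @param effects Numeric vector; names (or `locus`) give locus ids.
#' @param locus Locus ids; defaults to `names(effects)`.
#' @param file Path.
#' @return `read_effects_tsv()` returns a named numeric vector.
#' @export
write_effects_tsv <- function(effects, file, locus = NULL) {
  if (is.null(locus)) locus <- names(effects)
  if (is.null(locus)) locus <- paste0("L", seq_along(effects))
  utils::write.table(data.frame(locus = locus, effect = effects), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_effects_tsv
#' @export
read_effects_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$effect, df$locus)
}

#' Read phased haplotypes from a VCF
#'
#' Requires every genotype to be phased (`|` separator) and biallelic;
#' unphased or multiallelic records raise an error.  Parsing is delegated
#' to the vcfR package.
#'
#' @param file Path to a VCF (plain or gzipped).
#' @param generation Generation index to assign.
#' @return A list with `panel` (a `haplotype_panel`) and `map` (a
#'   `genetic_map` with positions taken from the `POS` column, in the
#'   absence of a genetic map interpreted as 1 cM per Mb).
#' @export
read_vcf_haplotypes <- function(file, generation = 0L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes ('/') found; phased '|' genotypes are required")
  }
  if (!all(gt %in% c("0|0", "0|1", "1|0", "1|1"))) {
    stop("only biallelic phased genotypes 0|0, 0|1, 1|0, 1|1 are supported")
  }
  ids <- colnames(gt)
  L <- nrow(gt)
  N <- length(ids)
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = L)
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = L)
  a <- matrix(0L, nrow = 2L * N, ncol = L)
  a[seq(1L, 2L * N, 2L), ] <- t(h1)
  a[seq(2L, 2L * N, 2L), ] <- t(h2)
  loci <- rownames(gt)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  colnames(a) <- loci
  panel <- haplotype_panel(a, ids = ids, generation = generation)
  fix <- vcfR::getFIX(v)
  map <- genetic_map(loci, fix[, "CHROM"], as.numeric(fix[, "POS"]) / 1e6)
  list(panel = panel, map = map)
}

#' Write a panel as a phased VCF
#'
#' Minimal VCFv4.2 output with phased GT fields; physical positions are
#' the map's cM positions scaled to integer base pairs (1 cM = 1 Mb).
#'
#' @param panel A `haplotype_panel`.
#' @param map A `genetic_map` aligned with the panel.
#' @param file Output path.
#' @export
write_vcf_haplotypes <- function(panel, map, file) {
  stopifnot(inherits(panel, "haplotype_panel"))
  check_map_panel(map, panel)
  a <- panel$alleles
  N <- n_individuals(panel)
  h1 <- a[seq(1L, 2L * N, 2L), , drop = FALSE]
  h2 <- a[seq(2L, 2L * N, 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(a))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$ids), collapse = "\t")), con)
  pos_bp <- as.integer(round(map$pos_cM * 1e6)) + 1L
  for (l in seq_len(ncol(a))) {
    writeLines(paste(c(map$chrom[l], pos_bp[l], map$locus[l], "A", "T", ".",
                       "PASS", ".", "GT", gt[l, ]), collapse = "\t"), con)
  }
  invisible(file)
}

#' Write a mate plan as TSV
#'
#' Columns: `parent_i`, `parent_j`, `count`, one row per mated pair.
#'
#' @param plan A `mate_plan`.
#' @param file Path.
#' @export
write_plan_tsv <- function(plan, file) {
  stopifnot(inherits(plan, "mate_plan"))
  pc <- plan$pair_counts
  idx <- which(upper.tri(pc) & pc > 0L, arr.ind = TRUE)
  ids <- rownames(pc)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(pc)))
  df <- data.frame(parent_i = ids[idx[, 1]], parent_j = ids[idx[, 2]],
                   count = pc[idx])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
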