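# Plain-text readers/writers for the pipeline's exchange formats.

#' Write and read the standard pipeline tables
#'
#' Thin CSV wrappers fixing the column contracts: participants
#' (id, generation, group, sex, age, mother_id, father_id,
#' maternal_hs_lineage, dna_conc_ng_ul), plate wells (plate_id, batch_id,
#' well, role, sample_id, gene, replicate, ct, ct_threshold), copy-number
#' (sample_id, ddct_raw, residual, cn_normalized).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_*`: data.frame. Writers return `path` invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write a depth profile pair to a TSV (chrom, pos, depth)
#'
#' @param profiles list with `mt` and `nuc` [depth_profile()]s (or a single
#'   profile).
#' @param path file path.
#' @export
write_depth_tsv <- function(profiles, path) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(chrom = p$chrom, pos = seq(p$start, p$end), depth = p$depth)
  })
  d <- do.call(rbind, rows)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read haploid mtDNA genotypes as a minimal VCF
#'
#' Sites-only biallelic VCF v4.2 with haploid GT fields (`0`, `1`, `.`).
#' REF/ALT alleles are placeholders (`A`/`G`) — the analysis consumes only
#' positions and carrier status.
#'
#' @param geno list as from [simulate_mtdna_genotypes()] (uses `genotypes`
#'   and `positions`).
#' @param path file path.
#' @param chrom chromosome name to write (default "chrM").
#' @export
write_haploid_vcf <- function(geno, path, chrom = "chrM") {
  g <- geno$genotypes
  pos <- geno$positions
  ids <- rownames(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=16569>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  gt <- matrix(as.character(t(g)), nrow = ncol(g))
  gt[is.na(gt)] <- "."
  lines <- paste(
    chrom, pos, colnames(g), "A", "G", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_haploid_vcf
#' @return `read_haploid_vcf`: list with `genotypes` (0/1/NA matrix,
#'   individuals x variants), `positions`, `chrom`.
#' @export
read_haploid_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stop("not a VCF: missing #CHROM header line in ", path)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  pos <- as.integer(vapply(f, `[[`, "", 2))
  vid <- vapply(f, `[[`, "", 3)
  alts <- vapply(f, `[[`, "", 5)
  if (any(grepl(",", alts, fixed = TRUE))) {
    stop("multi-allelic records are not supported")
  }
  gm <- vapply(f, function(x) {
    gt <- sub(":.*$", "", x[-(1:9)])  # haploid GT is the first FORMAT field
    suppressWarnings(as.integer(gt))
  }, integer(length(ids)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = length(ids))
  geno <- gm
  dimnames(geno) <- list(ids, vid)
  list(genotypes = geno, positions = pos,
       chrom = vapply(f, `[[`, "", 1)[1])
}
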