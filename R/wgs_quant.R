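#' SAM flag vocabulary used for depth filtering
#'
#' The six flags whose union (3852) excludes unmapped, mate-unmapped,
#' secondary, QC-fail, duplicate and supplementary reads before depth
#' computation.
#' @export
sam_flags <- c(
  read_unmapped = 0x4L,
  mate_unmapped = 0x8L,
  not_primary_alignment = 0x100L,
  fails_quality_checks = 0x200L,
  duplicate = 0x400L,
  supplementary_alignment = 0x800L
)

#' Build a SAM-flag exclusion mask
#'
#' @param flags character vector of names from [sam_flags] (default: all six,
#'   giving mask 3852).
#' @return integer bitwise-OR of the named flag values.
#' @export
build_exclusion_mask <- function(flags = names(sam_flags)) {
  if (length(flags) == 0) return(0L)
  unknown <- setdiff(flags, names(sam_flags))
  if (length(unknown)) {
    stop("unknown SAM flag name(s): ", paste(unknown, collapse = ", "))
  }
  Reduce(bitwOr, unname(sam_flags[flags]))
}

#' Filter read records by an exclusion mask
#'
#' Keeps exactly the records whose flag shares no bit with the mask
#' (`bitwAnd(flag, mask) == 0`); order preserved.
#'
#' @param records data.frame with at least a `flag` column (see
#'   [read_sam_text()]).
#' @param mask non-negative integer exclusion mask.
#' @return filtered records.
#' @export
filter_records <- function(records, mask) {
  stopifnot(mask >= 0)
  records[bitwAnd(as.integer(records$flag), as.integer(mask)) == 0L, ,
          drop = FALSE]
}

#' Minimal SAM text reader
#'
#' Parses mandatory fields of SAM text lines into reference name, flag,
#' 1-based leftmost position and aligned reference span (sum of CIGAR
#' operations that consume the reference: M, D, N, =, X). Header lines are
#' skipped. No BAM, no tags, no CIGAR-gap awareness in downstream depth
#' accumulation (a read covers every position of its span).
#'
#' @param path path to a SAM text file.
#' @return data.frame: qname, flag, rname, pos, span.
#' @export
read_sam_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      span = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[[`, "", 1),
    flag = as.integer(vapply(f, `[[`, "", 2)),
    rname = vapply(f, `[[`, "", 3),
    pos = as.integer(vapply(f, `[[`, "", 4)),
    span = vapply(f, function(x) cigar_ref_span(x[[6]]), 0L),
    stringsAsFactors = FALSE
  )
}

cigar_ref_span <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Per-base depth profile container
#'
#' @param chrom reference name.
#' @param start,end 1-based inclusive region bounds.
#' @param depth integer vector of per-position depths, length `end-start+1`.
#' @return object of class `depth_profile`.
#' @export
depth_profile <- function(chrom, start, end, depth) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end >= start, length(depth) == end - start + 1L,
            all(depth >= 0, na.rm = TRUE))
  structure(list(chrom = chrom, start = start, end = end,
                 depth = as.numeric(depth)),
            class = "depth_profile")
}

#' Accumulate a depth profile from read records
#'
#' Counts each record at every position of its aligned span clipped to the
#' region (1-based inclusive coordinates throughout).
#'
#' @param records (filtered) read records for one reference.
#' @param chrom reference name to select.
#' @param start,end region bounds (1-based inclusive).
#' @return a [depth_profile()].
#' @export
depth_from_records <- function(records, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end >= start)
  r <- records[records$rname == chrom & records$span > 0, , drop = FALSE]
  len <- end - start + 1L
  d <- integer(len)
  if (nrow(r) > 0) {
    s <- pmax(r$pos, start) - start + 1L
    e <- pmin(r$pos + r$span - 1L, end) - start + 1L
    for (i in seq_len(nrow(r))) {
      if (e[i] >= s[i] && s[i] <= len && e[i] >= 1L) {
        lo <- max(s[i], 1L); hi <- min(e[i], len)
        d[lo:hi] <- d[lo:hi] + 1L
      }
    }
  }
  depth_profile(chrom, start, end, d)
}

#' Read a per-base depth TSV (chrom, pos, depth)
#'
#' Positions absent from the file contribute depth 0; the region defaults to
#' the min..max position present per chromosome.
#'
#' @param path TSV path (with or without a header line).
#' @param chrom chromosome to extract.
#' @param start,end optional region bounds; default to observed range.
#' @return a [depth_profile()].
#' @export
read_depth_tsv <- function(path, chrom, start = NULL, end = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom|pos|depth", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "pos", "depth")
  d <- d[d$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for chromosome ", chrom, " in ", path)
  start <- as.integer(start %||% min(d$pos))
  end <- as.integer(end %||% max(d$pos))
  depth <- numeric(end - start + 1L)
  in_rng <- d$pos >= start & d$pos <= end
  depth[d$pos[in_rng] - start + 1L] <- d$depth[in_rng]
  depth_profile(chrom, start, end, depth)
}

#' Mean depth over a region of a profile
#'
#' Arithmetic mean over every position of the region; positions with no
#' coverage contribute 0.
#'
#' @param profile a [depth_profile()].
#' @param start,end optional sub-region (1-based inclusive, must lie within
#'   the profile's region); default: the whole profile.
#' @return mean depth (numeric scalar).
#' @export
region_mean_depth <- function(profile, start = NULL, end = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  start <- as.integer(start %||% profile$start)
  end <- as.integer(end %||% profile$end)
  if (end < start) stop("empty region")
  if (start < profile$start || end > profile$end) {
    stop("region outside the profile's declared region")
  }
  mean(profile$depth[(start - profile$start + 1L):(end - profile$start + 1L)])
}

#' Coverage-ratio copy number and cohort normalization
#'
#' `coverage_cn` returns the mtDNA/nuclear mean-depth ratio; `cohort_normalize`
#' maps a cohort of ratios to inverse-normal scores (delegating to
#' [inverse_normal_transform()]), making the normalized measure invariant to
#' any common monotone rescaling of the raw ratios.
#'
#' @param mt_mean,nuc_mean mean depths over mtDNA and the autosomal reference
#'   region.
#' @return `coverage_cn`: raw ratio. `cohort_normalize`: normal scores.
#' @export
coverage_cn <- function(mt_mean, nuc_mean) {
  if (any(nuc_mean <= 0)) {
    stop("nuclear mean depth is zero: sample unusable for the coverage ratio")
  }
  mt_mean / nuc_mean
}

#' @rdname coverage_cn
#' @param ratios numeric vector of raw coverage ratios (>= 2 samples).
#' @export
cohort_normalize <- function(ratios) {
  inverse_normal_transform(ratios)
}

#' End-to-end coverage copy number for a set of samples
#'
#' @param profiles named list (sample id) of lists with `mt` and `nuc`
#'   [depth_profile()]s, as produced by [simulate_depth_profiles()].
#' @return data.frame: sample_id, mt_mean, nuc_mean, ratio, cn_normalized.
#' @export
coverage_cn_table <- function(profiles) {
  ids <- names(profiles)
  mt <- vapply(profiles, function(p) region_mean_depth(p$mt), 0)
  nuc <- vapply(profiles, function(p) region_mean_depth(p$nuc), 0)
  ratio <- coverage_cn(mt, nuc)
  data.frame(
    sample_id = ids, mt_mean = mt, nuc_mean = nuc, ratio = ratio,
    cn_normalized = if (length(ratio) >= 2) cohort_normalize(ratio)
                    else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
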