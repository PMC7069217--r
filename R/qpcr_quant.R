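#' QC-filter qPCR plate wells
#'
#' A *run* is the replicate set of one sample for one gene on one plate. The
#' plate-and-gene NTC gates every run on that plate and gene: if the NTC
#' amplified at or below `ntc_min_ct` cycles the whole plate-gene is discarded
#' (`NTC_FAIL`); if the NTC is missing the plate-gene is discarded
#' (`MISSING_REPLICATE`). A surviving run is kept only if every one of its
#' wells has a determined CT below `sample_max_ct` (`SAMPLE_CT_HIGH`
#' otherwise). An undetermined (NA) NTC counts as passing — no amplification
#' at all; an undetermined sample well counts as failing.
#'
#' @param wells data.frame with columns plate_id, role, sample_id, gene,
#'   replicate, ct (see [simulate_qpcr_plates()]).
#' @param ntc_min_ct NTC passes when its CT exceeds this (default 38).
#' @param sample_max_ct sample wells must be strictly below this (default 30).
#' @return list with `kept` (wells surviving QC, NTCs of passing plate-genes
#'   included) and `report` (list: `kept_wells`, `discarded_wells`,
#'   `discarded` data.frame with plate_id, gene, sample_id, reason, n_wells).
#' @export
qc_filter <- function(wells, ntc_min_ct = 38, sample_max_ct = 30) {
  stopifnot(all(c("plate_id", "role", "sample_id", "gene", "ct") %in%
                  names(wells)))
  keep <- rep(TRUE, nrow(wells))
  disc <- list()
  note <- function(plate, gene, sample, reason, n) {
    disc[[length(disc) + 1L]] <<- data.frame(
      plate_id = plate, gene = gene, sample_id = sample,
      reason = reason, n_wells = n, stringsAsFactors = FALSE)
  }
  for (pg in unique(paste(wells$plate_id, wells$gene, sep = "\r"))) {
    parts <- strsplit(pg, "\r", fixed = TRUE)[[1]]
    p <- parts[1]; g <- parts[2]
    ix <- which(wells$plate_id == p & wells$gene == g)
    ntc <- ix[wells$role[ix] == "NTC"]
    if (length(ntc) == 0) {
      keep[ix] <- FALSE
      note(p, g, NA_character_, "MISSING_REPLICATE", length(ix))
      next
    }
    ntc_ct <- wells$ct[ntc]
    if (any(!is.na(ntc_ct) & ntc_ct <= ntc_min_ct)) {
      keep[ix] <- FALSE
      note(p, g, NA_character_, "NTC_FAIL", length(ix))
      next
    }
    smp <- ix[wells$role[ix] %in% c("SAMPLE", "REF")]
    for (sid in unique(wells$sample_id[smp])) {
      run <- smp[wells$sample_id[smp] == sid]
      ct <- wells$ct[run]
      if (any(is.na(ct) | ct >= sample_max_ct)) {
        keep[run] <- FALSE
        note(p, g, sid, "SAMPLE_CT_HIGH", length(run))
      }
    }
  }
  discarded <- if (length(disc)) do.call(rbind, disc) else
    data.frame(plate_id = character(0), gene = character(0),
               sample_id = character(0), reason = character(0),
               n_wells = integer(0), stringsAsFactors = FALSE)
  list(
    kept = wells[keep, , drop = FALSE],
    report = list(
      kept_wells = sum(keep),
      discarded_wells = sum(!keep),
      discarded = discarded
    )
  )
}

#' Compute per-sample ddCT from QC-passed wells
#'
#' Per sample and gene, surviving replicate CTs are averaged; the plate's REF
#' replicates are averaged per gene; `dCT(gene) = meanCT(sample, gene) -
#' meanCT(REF, gene)` on the same plate corrects plate effects; `ddCT =
#' dCT(RNASEP) - dCT(MT_CYB)`, so one extra unit of ddCT corresponds to a
#' two-fold higher mitochondrial template relative to the reference. Replicate
#' spread above `discordance_warn` cycles triggers a warning (never a drop).
#'
#' @param wells QC-passed wells (see [qc_filter()]); NTC rows are ignored.
#' @param discordance_warn replicate range (cycles) above which to warn.
#' @return data.frame: sample_id, plate_id, batch_id, ct_threshold,
#'   ct_RNASEP, ct_MT_CYB, dct_RNASEP, dct_MT_CYB, ddct. Samples lacking a
#'   surviving replicate for either gene are dropped with a warning.
#' @export
compute_ddct <- function(wells, discordance_warn = 1) {
  w <- wells[wells$role %in% c("SAMPLE", "REF"), , drop = FALSE]
  refs <- w[w$role == "REF", , drop = FALSE]
  smps <- w[w$role == "SAMPLE", , drop = FALSE]
  if (nrow(smps) == 0) stop("no samples survived QC")

  ref_mean <- stats::aggregate(ct ~ plate_id + gene, data = refs, FUN = mean)
  ref_n <- stats::aggregate(ct ~ plate_id + gene, data = refs, FUN = length)
  if (any(ref_n$ct < 3)) {
    warning("REF has fewer than 3 surviving replicates on plate(s): ",
            paste(unique(ref_n$plate_id[ref_n$ct < 3]), collapse = ", "))
  }
  ref_lookup <- function(plate, gene) {
    v <- ref_mean$ct[ref_mean$plate_id == plate & ref_mean$gene == gene]
    if (length(v) == 0) stop("missing REF replicates for plate ", plate,
                             " gene ", gene)
    v
  }

  out <- list()
  dropped <- character(0)
  for (sid in unique(smps$sample_id)) {
    sw <- smps[smps$sample_id == sid, , drop = FALSE]
    plates <- unique(sw$plate_id)
    if (length(plates) > 1) {
      stop("sample ", sid, " split across plates ",
           paste(plates, collapse = ", "), ": reference is ambiguous")
    }
    genes <- c("RNASEP", "MT_CYB")
    if (!all(genes %in% sw$gene)) {
      dropped <- c(dropped, sid)
      next
    }
    mean_ct <- vapply(genes, function(g) mean(sw$ct[sw$gene == g]), 0)
    spread <- vapply(genes, function(g) {
      ct <- sw$ct[sw$gene == g]
      if (length(ct) > 1) diff(range(ct)) else 0
    }, 0)
    if (any(spread > discordance_warn)) {
      warning("replicate discordance > ", discordance_warn,
              " cycle(s) for sample ", sid)
    }
    dct <- vapply(genes, function(g) {
      mean_ct[[g]] - ref_lookup(plates, g)
    }, 0)
    out[[sid]] <- data.frame(
      sample_id = sid, plate_id = plates, batch_id = sw$batch_id[1],
      ct_threshold = sw$ct_threshold[1],
      ct_RNASEP = mean_ct[["RNASEP"]], ct_MT_CYB = mean_ct[["MT_CYB"]],
      dct_RNASEP = dct[["RNASEP"]], dct_MT_CYB = dct[["MT_CYB"]],
      ddct = dct[["RNASEP"]] - dct[["MT_CYB"]],
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    warning(length(dropped), " sample(s) lacked a surviving replicate for ",
            "both genes and were dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residualize ddCT on technical covariates with a variance decomposition
#'
#' Ordinary least squares of ddCT on plate CT threshold (continuous), PCR
#' batch (categorical) and DNA concentration (continuous). Variance shares
#' are sequential (type-I) sums of squares divided by the total sum of
#' squares, in the stated term order, with per-term F-test p-values. Constant
#' covariates are dropped with a warning (share 0); rows with missing
#' covariates are excluded and reported.
#'
#' @param ddct numeric vector of ddCT values.
#' @param covariates data.frame with columns ct_threshold, batch,
#'   dna_concentration, aligned with `ddct`.
#' @return list: `residuals` (numeric, NA where excluded), `decomposition`
#'   (data.frame term, share, p), `n_used`, `excluded` (row indices).
#' @export
residualize_cn <- function(ddct, covariates) {
  stopifnot(length(ddct) == nrow(covariates))
  need <- c("ct_threshold", "batch", "dna_concentration")
  stopifnot(all(need %in% names(covariates)))
  cc <- stats::complete.cases(covariates[need]) & !is.na(ddct)
  excluded <- which(!cc)
  y <- ddct[cc]
  cov <- covariates[cc, need, drop = FALSE]
  cov$batch <- factor(cov$batch)

  terms <- c("ct_threshold", "batch", "dna_concentration")
  use <- vapply(terms, function(t) {
    v <- cov[[t]]
    length(unique(v)) > 1
  }, TRUE)
  if (!all(use)) {
    warning("constant covariate(s) dropped: ",
            paste(terms[!use], collapse = ", "))
  }
  active <- terms[use]
  if (length(active) == 0) {
    res <- y - mean(y)
    decomp <- data.frame(term = terms, share = 0, p = NA_real_,
                         stringsAsFactors = FALSE)
  } else {
    fml <- stats::as.formula(paste("y ~", paste(active, collapse = " + ")))
    fit <- stats::lm(fml, data = cbind(y = y, cov))
    av <- stats::anova(fit)  # sequential (type-I) SS in formula order
    ss_total <- sum((y - mean(y))^2)
    decomp <- data.frame(term = terms, share = 0, p = NA_real_,
                         stringsAsFactors = FALSE)
    for (t in active) {
      i <- match(t, rownames(av))
      decomp$share[decomp$term == t] <- av[i, "Sum Sq"] / ss_total
      decomp$p[decomp$term == t] <- av[i, "Pr(>F)"]
    }
    res <- stats::residuals(fit)
  }
  residuals_full <- rep(NA_real_, length(ddct))
  residuals_full[cc] <- res
  list(residuals = residuals_full, decomposition = decomp,
       n_used = sum(cc), excluded = excluded)
}

#' Rank-based inverse normal (Blom) transform
#'
#' Maps values to standard-normal quantiles of their offset ranks:
#' `qnorm((rank - 3/8) / (n + 1/4))`, average ranks for ties. Order-preserving
#' and idempotent on ranks; scores of distinct values sum to ~0.
#'
#' @param x numeric vector (n >= 2 finite values; NAs propagate).
#' @return numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2) stop("need at least 2 finite values")
  if (length(unique(v)) == 1) {
    stop("all values identical: no ordering information to transform")
  }
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}
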