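#' Variants private to one group
#'
#' A variant is private to a group when it has at least one carrier and every
#' carrier belongs to that group. Monomorphic variants (no carriers) are never
#' private to anything.
#'
#' @param genotypes 0/1 (and NA) matrix, individuals x variants, with
#'   dimnames.
#' @param labels character vector of group labels, one per individual (or a
#'   data.frame with sample_id and haplogroup columns).
#' @param group the group to test.
#' @return character vector of private variant ids.
#' @export
private_variants <- function(genotypes, labels, group) {
  labels <- normalize_labels(labels, rownames(genotypes))
  if (!group %in% labels) stop("unknown group label: ", group)
  in_group <- labels == group
  carriers <- colSums(genotypes == 1, na.rm = TRUE)
  carriers_out <- colSums(genotypes[!in_group, , drop = FALSE] == 1,
                          na.rm = TRUE)
  colnames(genotypes)[carriers > 0 & carriers_out == 0]
}

normalize_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "haplogroup") %in% names(labels)))
    labels <- labels$haplogroup[match(ids, labels$sample_id)]
  }
  if (anyNA(labels)) stop("every individual must be labelled")
  labels
}

#' Equal-weight haploid genetic relatedness matrix
#'
#' Each biallelic haploid variant is centered by its observed allele
#' frequency p and divided by the observed (population-denominator) standard
#' deviation `sqrt(p(1-p))` — not the diploid Hardy-Weinberg `sqrt(2p(1-p))` —
#' so every SNP contributes equally to the genetic covariance regardless of
#' its frequency. For fully observed data `GRM = Z Z' / m` and
#' `trace(GRM) = n` exactly. Missing genotypes are handled pairwise-complete:
#' each pair's covariance averages over the variants observed in both
#' individuals.
#'
#' @param genotypes 0/1 (and NA) matrix, individuals x variants.
#' @return list of class `haploid_grm`: `grm` (n x n), `n_variants` (variants
#'   used), `pair_m` (per-pair variant counts; NULL when fully observed).
#' @export
haploid_grm <- function(genotypes) {
  g <- as.matrix(genotypes)
  p <- colMeans(g, na.rm = TRUE)
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all variants monomorphic: no relatedness information")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) dropped")
  }
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2, p, "-")
  z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  m <- ncol(z)
  if (!anyNA(z)) {
    grm <- tcrossprod(z) / m
    pair_m <- NULL
  } else {
    obs <- !is.na(z)
    z0 <- z
    z0[!obs] <- 0
    num <- tcrossprod(z0)
    pair_m <- tcrossprod(obs * 1)
    grm <- num / pair_m
    grm[pair_m == 0] <- NA_real_
  }
  dimnames(grm) <- list(rownames(genotypes), rownames(genotypes))
  structure(list(grm = grm, n_variants = m, pair_m = pair_m),
            class = "haploid_grm")
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs; scores are eigenvectors scaled by the square root of
#' their (non-negative part of the) eigenvalue, so score covariance matches
#' the genetic covariance captured by each axis.
#'
#' @param grm a [haploid_grm()] or a symmetric numeric matrix.
#' @param k number of components (default: all).
#' @return list of class `grm_pca`: `scores` (n x k), `eigenvalues`
#'   (nonincreasing, length k).
#' @export
grm_pca <- function(grm, k = NULL) {
  m <- if (inherits(grm, "haploid_grm")) grm$grm else as.matrix(grm)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("GRM must be symmetric")
  k <- as.integer(k %||% nrow(m))
  stopifnot(k >= 1, k <= nrow(m))
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  scores <- sweep(e$vectors[, seq_len(k), drop = FALSE], 2,
                  sqrt(pmax(vals, 0)), "*")
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = vals), class = "grm_pca")
}

#' One-vs-rest haplogroup association with copy number
#'
#' For each haplogroup with at least `min_carriers` members, ordinary least
#' squares of normalized copy number on the one-vs-rest indicator (plus
#' optional covariates); rows ordered by beta, descending.
#'
#' @param cn numeric vector of normalized copy-number scores.
#' @param labels haplogroup labels (vector, or data.frame with sample_id +
#'   haplogroup matched against `names(cn)`).
#' @param covariates optional data.frame of covariates.
#' @param min_carriers minimum group size to test (default 2).
#' @return data.frame: haplogroup, beta, se, p, n (ordered by beta
#'   descending).
#' @export
haplogroup_onevsrest <- function(cn, labels, covariates = NULL,
                                 min_carriers = 2) {
  labels <- normalize_labels(labels, names(cn))
  stopifnot(length(labels) == length(cn))
  out <- list()
  for (g in unique(labels)) {
    ind <- as.numeric(labels == g)
    n_g <- sum(ind)
    if (n_g < min_carriers) next
    if (n_g == length(cn)) {
      warning("haplogroup ", g, " equals the whole cohort: skipped")
      next
    }
    df <- data.frame(cn = cn, ind = ind)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- stats::lm(cn ~ ., data = df)
    cf <- summary(fit)$coefficients
    out[[g]] <- data.frame(
      haplogroup = g, beta = cf["ind", 1], se = cf["ind", 2],
      p = cf["ind", 4], n = n_g, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(-res$beta), , drop = FALSE]
  rownames(res) <- NULL
  res
}
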