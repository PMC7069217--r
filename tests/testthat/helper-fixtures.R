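# shared fixtures built in code

# small cohort config for fast tests
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_hs = c(G1 = 5L, G2 = 15L, G3 = 10L),
    n_ctrl = c(G1 = 6L, G2 = 10L, G3 = 6L),
    n_plates = 5L, n_batches = 2L,
    nuc_region_length = 2000L,
    n_variants = 60L, n_private = c(L = 8L), n_defining = 3L,
    blood_subset_n = 20L,
    seed = seed, ...
  )
}

# hand-built plate wells: one plate, both genes, REF triplicate, one sample
# duplicate per gene, one NTC per gene
make_wells <- function(sample_cyb = c(18, 18), sample_rp = c(25, 25),
                       ref_cyb = c(20, 20, 20), ref_rp = c(25, 25, 25),
                       ntc_ct = c(RNASEP = NA, MT_CYB = NA),
                       plate = "P01", batch = "B1", threshold = 0.2,
                       sample_id = "S1") {
  row <- function(role, sid, gene, rep_i, ct) {
    data.frame(plate_id = plate, batch_id = batch, well = "A01", role = role,
               sample_id = sid, gene = gene, replicate = rep_i, ct = ct,
               ct_threshold = threshold, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_along(ref_rp)) rows <- c(rows, list(row("REF", "REF", "RNASEP", i, ref_rp[i])))
  for (i in seq_along(ref_cyb)) rows <- c(rows, list(row("REF", "REF", "MT_CYB", i, ref_cyb[i])))
  for (i in seq_along(sample_rp)) rows <- c(rows, list(row("SAMPLE", sample_id, "RNASEP", i, sample_rp[i])))
  for (i in seq_along(sample_cyb)) rows <- c(rows, list(row("SAMPLE", sample_id, "MT_CYB", i, sample_cyb[i])))
  rows <- c(rows, list(row("NTC", NA_character_, "RNASEP", 1, ntc_ct[["RNASEP"]]),
                       row("NTC", NA_character_, "MT_CYB", 1, ntc_ct[["MT_CYB"]])))
  do.call(rbind, rows)
}

# independent brute-force GRM: explicit double loop over individual pairs
brute_force_grm <- function(g) {
  p <- colMeans(g)
  keep <- p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(g)
  m <- ncol(g)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (v in seq_len(m)) {
        zi <- (g[i, v] - p[v]) / sqrt(p[v] * (1 - p[v]))
        zj <- (g[j, v] - p[v]) / sqrt(p[v] * (1 - p[v]))
        s <- s + zi * zj
      }
      out[i, j] <- s / m
    }
  }
  out
}

# independent hypergeometric enumeration for a 2x2 table using choose()
enumerate_fisher_p <- function(t2) {
  m <- sum(t2[1, ]); n <- sum(t2[2, ]); k <- sum(t2[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, t2[1, 1]) * choose(n, k - t2[1, 1]) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
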