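#' Configuration for the synthetic three-generation cohort
#'
#' Builds the single configuration object consumed by every `simulate_*`
#' generator. Defaults describe a three-generation cohort of trauma-exposed
#' families and unexposed controls with the structure reported for the study
#' system this package targets: group sizes 15/22 (G1), 60/37 (G2), 42/20 (G3)
#' for exposed-lineage vs control, 196 participants in total, genotyped on 17
#' qPCR plates in 3 batches, with technical variance shares 0.45 (plate CT
#' threshold), 0.05 (batch) and 0.01 (DNA concentration).
#'
#' Effect sizes (`group_beta`, `age_slope`, `sex_beta`) are expressed in units
#' of the latent log copy-number standard deviation, so the coefficient
#' recovered after inverse-normal transformation matches the configured value
#' directly. `h` is the maternal transmission coefficient: a child's latent
#' standardized deviation is `h` times the mother's plus unit-variance noise.
#'
#' @param n_hs,n_ctrl named integer vectors (G1,G2,G3): exposed-lineage and
#'   control counts per generation.
#' @param p_male probability a participant is male (cohort default 77/196).
#' @param age_dist list per generation with `mean`, `sd`, `min`, `max` (years).
#' @param group_beta,age_slope,sex_beta standardized effects on latent log
#'   copy number (per indicator; `age_slope` per year).
#' @param h maternal transmission coefficient in [0,1].
#' @param transmission_noise_sd SD of the child's own standardized latent
#'   innovation when a mother is recorded (1 = default; 0 with h = 1 gives
#'   perfect maternal transmission of the latent deviation).
#' @param log_cn_sd latent log copy-number noise SD (natural log scale).
#' @param prop_recorded_mother probability a G2/G3 participant has a recorded
#'   mother among previous-generation participants of the same group.
#' @param prop_recorded_father probability a recorded father accompanies a
#'   recorded mother.
#' @param ptsd_prev 2x3 matrix (rows HS/CTRL, cols G1..G3) of probable-PTSD
#'   prevalence.
#' @param n_plates,n_batches,plate_wells,sample_reps,ref_reps,ntc_per_gene
#'   qPCR plate layout.
#' @param variance_shares named numeric (ct_threshold, batch, concentration):
#'   target shares of total ddCT variance.
#' @param well_noise_sd per-well CT noise SD in cycles.
#' @param ct_baseline named numeric: CT of the reference template for each gene.
#' @param ntc_contam_rate,well_fail_rate QC-path injection rates.
#' @param dna_conc_mean,dna_conc_sd,dna_conc_min DNA concentration (ng/uL).
#' @param nuclear_depth,mt_depth_multiplier,nuc_region_length,mt_length depth
#'   model: nuclear mean depth d, mtDNA mean depth d*multiplier*CN, region
#'   sizes (mtDNA defaults to the 16,569 bp rCRS length).
#' @param haplogroup_freqs data.frame (haplogroup, freq) summing to 1.
#' @param n_variants,n_private,n_defining,shared_maf_range mtDNA SNP panel:
#'   total biallelic SNP count, named vector of private-variant counts per
#'   haplogroup (defaults 626 private to L, echoing the 1000 Genomes panel of
#'   3,779 SNPs), haplogroup-defining SNPs per group (counted inside the
#'   private total), and the carrier-frequency range of shared SNPs.
#' @param blood_subset_n number of participants with blood counts (default 70).
#' @param blood_sex_effects named standardized sex (male) effects on blood
#'   measures; defaults carry the reported RBC/HGB/HCT/monocyte effects.
#' @param plt_cn_beta optional platelet-to-copy-number measurement coupling
#'   (per 10^9/L on the normalized scale); 0 disables it.
#' @param pclc_item_range,pclc_cutoff PCL-C item scale and probable-PTSD
#'   cutoff (inclusive).
#' @param dropout_rate fraction of recruited participants dropped before
#'   analysis (the study recruited 235 and analysed 196; the mechanism is
#'   unmodelled, so the default generates the analysed cohort directly).
#' @param seed global seed; each generator derives its own substream.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_hs = c(G1 = 15L, G2 = 60L, G3 = 42L),
    n_ctrl = c(G1 = 22L, G2 = 37L, G3 = 20L),
    p_male = 77 / 196,
    age_dist = list(
      G1 = c(mean = 84, sd = 4, min = 75, max = 98),
      G2 = c(mean = 52, sd = 10, min = 30, max = 73),
      G3 = c(mean = 30, sd = 8, min = 15, max = 48)
    ),
    group_beta = 0,
    age_slope = -0.002,
    sex_beta = 0.37,
    h = 0,
    transmission_noise_sd = 1,
    log_cn_sd = 0.35,
    prop_recorded_mother = 0.25,
    prop_recorded_father = 0.5,
    ptsd_prev = rbind(
      HS = c(G1 = 0.47, G2 = 0.35, G3 = 0.20),
      CTRL = c(G1 = 0.12, G2 = 0.12, G3 = 0.10)
    ),
    n_plates = 17L, n_batches = 3L, plate_wells = 96L,
    sample_reps = 2L, ref_reps = 3L, ntc_per_gene = 1L,
    variance_shares = c(ct_threshold = 0.45, batch = 0.05, concentration = 0.01),
    well_noise_sd = 0.15,
    ct_baseline = c(RNASEP = 25, MT_CYB = 20),
    ntc_contam_rate = 0.02, well_fail_rate = 0.02,
    dna_conc_mean = 75, dna_conc_sd = 20, dna_conc_min = 10,
    nuclear_depth = 30, mt_depth_multiplier = 20,
    nuc_region_length = 100000L, mt_length = 16569L,
    haplogroup_freqs = data.frame(
      haplogroup = c("L", "H", "U", "T", "J", "K", "B", "C", "D", "A", "F", "M"),
      freq = c(0.26, 0.15, 0.08, 0.05, 0.05, 0.04, 0.07, 0.04, 0.06, 0.05,
               0.05, 0.10)
    ),
    n_variants = 3779L,
    n_private = c(L = 626L),
    n_defining = 10L,
    shared_maf_range = c(0.05, 0.5),
    blood_subset_n = 70L,
    blood_sex_effects = c(
      RBC_x10.12_per_L = 0.857, HGB_g_per_L = 1.087, HCT_L_per_L = 1.067,
      MONO_percent = 0.955, PLT_x10.9_per_L = -0.820
    ),
    plt_cn_beta = 0,
    pclc_item_range = c(0L, 5L),
    pclc_cutoff = 30L,
    dropout_rate = 0,
    seed = 1L) {
  cfg <- list(
    n_hs = n_hs, n_ctrl = n_ctrl, p_male = p_male, age_dist = age_dist,
    group_beta = group_beta, age_slope = age_slope, sex_beta = sex_beta,
    h = h, transmission_noise_sd = transmission_noise_sd,
    log_cn_sd = log_cn_sd,
    prop_recorded_mother = prop_recorded_mother,
    prop_recorded_father = prop_recorded_father,
    ptsd_prev = ptsd_prev,
    n_plates = as.integer(n_plates), n_batches = as.integer(n_batches),
    plate_wells = as.integer(plate_wells),
    sample_reps = as.integer(sample_reps), ref_reps = as.integer(ref_reps),
    ntc_per_gene = as.integer(ntc_per_gene),
    variance_shares = variance_shares, well_noise_sd = well_noise_sd,
    ct_baseline = ct_baseline,
    ntc_contam_rate = ntc_contam_rate, well_fail_rate = well_fail_rate,
    dna_conc_mean = dna_conc_mean, dna_conc_sd = dna_conc_sd,
    dna_conc_min = dna_conc_min,
    nuclear_depth = nuclear_depth, mt_depth_multiplier = mt_depth_multiplier,
    nuc_region_length = as.integer(nuc_region_length),
    mt_length = as.integer(mt_length),
    haplogroup_freqs = haplogroup_freqs,
    n_variants = as.integer(n_variants), n_private = n_private,
    n_defining = as.integer(n_defining), shared_maf_range = shared_maf_range,
    blood_subset_n = as.integer(blood_subset_n),
    blood_sex_effects = blood_sex_effects, plt_cn_beta = plt_cn_beta,
    pclc_item_range = as.integer(pclc_item_range),
    pclc_cutoff = as.integer(pclc_cutoff),
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  gens <- c("G1", "G2", "G3")
  if (!all(gens %in% names(cfg$n_hs)) || !all(gens %in% names(cfg$n_ctrl))) {
    stop_config("group sizes must be named G1, G2, G3")
  }
  if (any(cfg$n_hs < 0) || any(cfg$n_ctrl < 0)) {
    stop_config("group sizes must be non-negative")
  }
  vs <- cfg$variance_shares
  if (any(vs < 0) || any(vs > 1) || sum(vs) >= 1) {
    stop_config("variance shares must each lie in [0,1] and sum to < 1")
  }
  if (cfg$h < 0 || cfg$h > 1) stop_config("h must lie in [0,1]")
  if (any(cfg$ptsd_prev < 0) || any(cfg$ptsd_prev > 1)) {
    stop_config("ptsd_prev entries must lie in [0,1]")
  }
  if (abs(sum(cfg$haplogroup_freqs$freq) - 1) > 1e-8) {
    stop_config("haplogroup frequencies must sum to 1")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop_config("dropout_rate must lie in [0,1)")
  }
  invisible(cfg)
}

#' Simulate the pedigree-structured cohort and its latent states
#'
#' Draws participants generation by generation (G1 founders first), assigns
#' sexes, ages, DNA concentrations, and — for a configurable fraction of G2/G3
#' participants — a recorded mother (and possibly father) among the
#' previous-generation participants of the same group. Latent relative copy
#' number is log-normal: effects (group, age, sex, maternal transmission) act
#' additively on the log scale in units of `log_cn_sd`, so positivity is
#' automatic and one CT cycle corresponds to one doubling of template.
#'
#' `maternal_hs_lineage` is TRUE iff an unbroken mother-to-mother chain of
#' recorded links ends at a G1 exposed-group participant (G1 exposed
#' participants themselves carry the flag).
#'
#' @param config a [cohort_config()].
#' @return list with `participants` (data.frame: id, generation, group, sex,
#'   age, mother_id, father_id, maternal_hs_lineage, dna_conc_ng_ul) and
#'   `latents` (data.frame: id, cn_true, log_dev_std, ptsd_latent).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  with_substream(config$seed, "cohort", {
    gens <- c("G1", "G2", "G3")
    rows <- list()
    for (g in seq_along(gens)) {
      gen <- gens[g]
      for (grp in c("HS", "CTRL")) {
        n <- if (grp == "HS") config$n_hs[[gen]] else config$n_ctrl[[gen]]
        if (n == 0) next
        ad <- config$age_dist[[gen]]
        rows[[paste(gen, grp)]] <- data.frame(
          id = sprintf("%s_%s_%03d", gen, grp, seq_len(n)),
          generation = gen, group = grp,
          sex = ifelse(stats::runif(n) < config$p_male, "M", "F"),
          age = round(rnorm_trunc(n, ad[["mean"]], ad[["sd"]],
                                  ad[["min"]], ad[["max"]]), 1),
          stringsAsFactors = FALSE
        )
      }
    }
    part <- do.call(rbind, rows)
    rownames(part) <- NULL
    part$mother_id <- NA_character_
    part$father_id <- NA_character_

    # recorded parents: mother drawn (with replacement) from same-group
    # females one generation up; father likewise from males
    for (g in 2:3) {
      gen <- gens[g]
      prev <- gens[g - 1]
      idx <- which(part$generation == gen)
      for (i in idx) {
        grp <- part$group[i]
        if (stats::runif(1) < config$prop_recorded_mother) {
          mothers <- part$id[part$generation == prev & part$group == grp &
                               part$sex == "F"]
          if (length(mothers) == 0) {
            stop_config("impossible pedigree: no assignable mothers for ",
                        gen, " ", grp)
          }
          part$mother_id[i] <- sample(mothers, 1)
          if (stats::runif(1) < config$prop_recorded_father) {
            fathers <- part$id[part$generation == prev & part$group == grp &
                                 part$sex == "M"]
            if (length(fathers) > 0) part$father_id[i] <- sample(fathers, 1)
          }
        }
      }
    }

    part$maternal_hs_lineage <- maternal_lineage_flags(part)
    part$dna_conc_ng_ul <- round(rnorm_trunc(
      nrow(part), config$dna_conc_mean, config$dna_conc_sd,
      lower = config$dna_conc_min), 1)

    if (config$dropout_rate > 0) {
      keep <- stats::runif(nrow(part)) >= config$dropout_rate
      part <- part[keep, , drop = FALSE]
      rownames(part) <- NULL
      part$maternal_hs_lineage <- maternal_lineage_flags(part)
    }

    # latent standardized deviation u: maternal transmission + noise
    u <- stats::rnorm(nrow(part))
    names(u) <- part$id
    if (config$h > 0 || config$transmission_noise_sd != 1) {
      for (g in 2:3) {
        idx <- which(part$generation == gens[g])
        mom <- part$mother_id[idx]
        has <- !is.na(mom) & mom %in% names(u)
        u[idx[has]] <- config$h * u[mom[has]] +
          config$transmission_noise_sd * u[idx[has]]
      }
    }

    mean_age <- mean(part$age)
    z <- config$group_beta * (part$group == "HS") +
      config$age_slope * (part$age - mean_age) +
      config$sex_beta * (part$sex == "M") + u
    log_cn <- config$log_cn_sd * z
    latents <- data.frame(
      id = part$id,
      cn_true = exp(log_cn),
      log_dev_std = as.numeric(u),
      ptsd_latent = stats::rnorm(nrow(part)),
      stringsAsFactors = FALSE
    )
    list(participants = part, latents = latents)
  })
}

# recompute maternal exposed-lineage flags by chain traversal
maternal_lineage_flags <- function(part) {
  flag <- part$generation == "G1" & part$group == "HS"
  names(flag) <- part$id
  ord <- order(match(part$generation, c("G1", "G2", "G3")))
  for (i in ord) {
    mom <- part$mother_id[i]
    if (!is.na(mom) && mom %in% names(flag) && flag[[mom]]) {
      flag[[part$id[i]]] <- TRUE
    }
  }
  unname(flag[part$id])
}

#' Simulate qPCR plate tables
#'
#' Lays participants out on `n_plates` 96-well plates (random permutation,
#' near-equal plate sizes), each plate carrying a constant-concentration
#' reference sample (REF) in triplicate per gene and one NTC per gene. Sample
#' CT follows `baseline(gene) - log2(relative template) + technical effects +
#' well noise`; the mitochondrial gene's template is the participant's true
#' relative copy number. Plate CT-threshold, batch and concentration effects
#' are injected on sample wells of the mitochondrial gene (REF is untouched —
#' this is what lets the effects survive the per-plate ΔΔCT correction) and
#' are empirically scaled and sequentially orthogonalized so that their
#' shares of total ΔΔCT variance equal `config$variance_shares`.
#'
#' @param participants,latents output of [simulate_cohort()].
#' @param config a [cohort_config()].
#' @return data.frame of wells: plate_id, batch_id, well, role (SAMPLE, REF,
#'   NTC), sample_id, gene (RNASEP, MT_CYB), replicate, ct, ct_threshold.
#' @export
simulate_qpcr_plates <- function(participants, latents, config) {
  validate_cohort_config(config)
  n <- nrow(participants)
  genes <- c("RNASEP", "MT_CYB")
  fixed_per_plate <- length(genes) * (config$ref_reps + config$ntc_per_gene)
  cap <- config$plate_wells - fixed_per_plate
  per_sample <- length(genes) * config$sample_reps
  max_per_plate <- cap %/% per_sample
  if (ceiling(n / config$n_plates) > max_per_plate) {
    stop_config("wells-per-plate capacity exceeded: ",
                ceiling(n / config$n_plates), " samples/plate needed, ",
                max_per_plate, " fit")
  }

  with_substream(config$seed, "qpcr", {
    plate_ids <- sprintf("P%02d", seq_len(config$n_plates))
    batch_of_plate <- sort(rep_len(seq_len(config$n_batches),
                                   config$n_plates))
    thresholds <- round(stats::runif(config$n_plates, 0.1, 0.4), 3)
    names(thresholds) <- names(batch_of_plate) <- plate_ids

    # balanced random assignment (see vignette): permute, deal into plates
    assign_plate <- plate_ids[rep_len(seq_len(config$n_plates), n)]
    assign_plate <- assign_plate[order(stats::runif(n))]
    names(assign_plate) <- participants$id

    cn <- latents$cn_true[match(participants$id, latents$id)]
    signal <- log2(cn)

    # target effect variances from configured shares; residual share carries
    # the biological signal plus well-noise contribution to ddCT
    vs <- config$variance_shares
    s0 <- 1 - sum(vs)
    noise_var <- config$well_noise_sd^2 *
      (2 / config$sample_reps + 2 / config$ref_reps)
    v_resid <- stats::var(signal) + noise_var
    v_total <- v_resid / s0

    scale_to <- function(x, target_var) {
      x <- x - mean(x)
      if (stats::sd(x) < 1e-12 || target_var <= 0) return(x * 0)
      x / stats::sd(x) * sqrt(target_var)
    }
    orth <- function(x, basis) {
      stats::residuals(stats::lm.fit(cbind(1, basis), x))
    }
    thr_x <- thresholds[assign_plate]
    e_thr <- scale_to(thr_x, vs[["ct_threshold"]] * v_total)
    batch_dev <- stats::rnorm(config$n_batches)
    b_x <- batch_dev[batch_of_plate[assign_plate]]
    e_bat <- scale_to(orth(b_x, cbind(thr_x)), vs[["batch"]] * v_total)
    conc <- participants$dna_conc_ng_ul
    e_con <- scale_to(orth(conc, cbind(thr_x, b_x)),
                      vs[["concentration"]] * v_total)
    eff <- e_thr + e_bat + e_con  # added to ddCT => subtracted from MT_CYB CT

    wells <- list()
    k <- 0L
    add <- function(plate, role, sample_id, gene, rep_i, ct) {
      k <<- k + 1L
      wells[[k]] <<- data.frame(
        plate_id = plate, batch_id = paste0("B", batch_of_plate[[plate]]),
        role = role, sample_id = sample_id, gene = gene, replicate = rep_i,
        ct = ct, ct_threshold = thresholds[[plate]],
        stringsAsFactors = FALSE
      )
    }
    noise <- function(m) stats::rnorm(m, 0, config$well_noise_sd)

    for (p in plate_ids) {
      for (gene in genes) {
        for (r in seq_len(config$ref_reps)) {
          add(p, "REF", "REF", gene, r,
              config$ct_baseline[[gene]] + noise(1))
        }
        for (r in seq_len(config$ntc_per_gene)) {
          if (stats::runif(1) < config$ntc_contam_rate) {
            ct <- stats::runif(1, 30, 38)  # contamination: failing NTC
          } else if (stats::runif(1) < 0.3) {
            ct <- NA_real_                  # no amplification at all
          } else {
            ct <- stats::runif(1, 38.5, 40)
          }
          add(p, "NTC", NA_character_, gene, r, ct)
        }
      }
      on_plate <- which(assign_plate == p)
      for (i in on_plate) {
        sid <- participants$id[i]
        for (gene in genes) {
          base <- config$ct_baseline[[gene]]
          mu <- if (gene == "MT_CYB") base - signal[i] - eff[i] else base
          for (r in seq_len(config$sample_reps)) {
            ct <- mu + noise(1)
            if (stats::runif(1) < config$well_fail_rate) ct <- NA_real_
            add(p, "SAMPLE", sid, gene, r, ct)
          }
        }
      }
    }
    out <- do.call(rbind, wells)
    # well positions: sequential within plate (layout itself carries no signal)
    out$well <- NA_character_
    for (p in unique(out$plate_id)) {
      ix <- which(out$plate_id == p)
      out$well[ix] <- sprintf("%s%02d",
                              LETTERS[((seq_along(ix) - 1) %/% 12) + 1],
                              ((seq_along(ix) - 1) %% 12) + 1)
    }
    out[, c("plate_id", "batch_id", "well", "role", "sample_id", "gene",
            "replicate", "ct", "ct_threshold")]
  })
}

#' Simulate per-base depth profiles for mtDNA and an autosomal toy region
#'
#' Per-base depths are Poisson: mean `nuclear_depth` over the autosomal
#' region, mean `nuclear_depth * mt_depth_multiplier * cn_true` over the
#' mtDNA (length `mt_length`, defaulting to the 16,569 bp rCRS).
#'
#' @param participants,latents output of [simulate_cohort()]; pass a subset of
#'   participants to simulate fewer samples.
#' @param config a [cohort_config()].
#' @return named list (by participant id) of lists with `mt` and `nuc`
#'   [depth_profile()] objects.
#' @export
simulate_depth_profiles <- function(participants, latents, config) {
  if (config$nuclear_depth <= 0 || config$mt_depth_multiplier < 0) {
    stop_config("depth parameters must be positive (multiplier >= 0)")
  }
  cn <- latents$cn_true[match(participants$id, latents$id)]
  with_substream(config$seed, "depth", {
    out <- lapply(seq_len(nrow(participants)), function(i) {
      list(
        mt = depth_profile("chrM", 1L, config$mt_length,
                           stats::rpois(config$mt_length,
                                        config$nuclear_depth *
                                          config$mt_depth_multiplier * cn[i])),
        nuc = depth_profile("chr20", 1L, config$nuc_region_length,
                            stats::rpois(config$nuc_region_length,
                                         config$nuclear_depth))
      )
    })
    names(out) <- participants$id
    out
  })
}

#' Simulate haplogroup-structured haploid mtDNA genotypes
#'
#' Each individual is assigned a haplogroup from the configured frequency
#' table. The SNP panel has three variant classes: haplogroup-defining SNPs
#' (carried by every member of the group and nobody else — these count toward
#' that group's private total), additional private SNPs (carried by a random
#' non-empty subset of one group), and shared SNPs constructed to have
#' carriers in at least two haplogroups so that exactly the configured number
#' of variants is private to each group.
#'
#' @param n number of individuals, or a participants data.frame (its row count
#'   is used and ids are reused).
#' @param config a [cohort_config()]; `haplogroup_freqs`, `n_variants`,
#'   `n_private`, `n_defining`, `shared_maf_range` are consumed.
#' @return list with `genotypes` (0/1 matrix, individuals x variants),
#'   `positions` (1-based mtDNA positions), `haplogroups` (data.frame
#'   sample_id, haplogroup).
#' @export
simulate_mtdna_genotypes <- function(n, config) {
  freqs <- config$haplogroup_freqs
  if (is.null(freqs) || nrow(freqs) == 0) stop_config("empty haplogroup frequency table")
  if (abs(sum(freqs$freq) - 1) > 1e-8) stop_config("haplogroup frequencies must sum to 1")
  if (is.data.frame(n)) {
    ids <- n$id
    n <- nrow(n)
  } else {
    n <- as.integer(n)
    ids <- sprintf("S%04d", seq_len(n))
  }
  with_substream(config$seed, "geno", {
    groups <- freqs$haplogroup
    hg <- sample(groups, n, replace = TRUE, prob = freqs$freq)
    present <- intersect(groups, unique(hg))
    multi <- length(present) > 1

    n_private <- vapply(groups, function(g) {
      as.integer(config$n_private[g] %||% NA_integer_)
    }, integer(1))
    names(n_private) <- groups
    n_private[is.na(n_private)] <- config$n_defining
    # groups with no members cannot carry private variants
    n_private[!(groups %in% present)] <- 0L
    n_shared <- config$n_variants - sum(n_private)
    if (n_shared < 0) stop_config("n_private exceeds n_variants")

    cols <- list()
    class_of <- character(0)
    priv_of <- character(0)
    for (g in groups) {
      m <- n_private[[g]]
      if (m == 0) next
      members <- which(hg == g)
      n_def <- min(config$n_defining, m)
      for (j in seq_len(m)) {
        col <- integer(n)
        if (j <= n_def) {
          col[members] <- 1L  # defining: all members carry
        } else {
          f <- stats::runif(1, 0.05, 0.6)
          carriers <- members[stats::runif(length(members)) < f]
          if (length(carriers) == 0) carriers <- sample(members, 1)
          col[carriers] <- 1L
        }
        cols[[length(cols) + 1L]] <- col
        class_of <- c(class_of, if (j <= n_def) "defining" else "private")
        priv_of <- c(priv_of, g)
      }
    }
    if (n_shared > 0) {
      for (j in seq_len(n_shared)) {
        f <- stats::runif(1, config$shared_maf_range[1], config$shared_maf_range[2])
        col <- as.integer(stats::runif(n) < f)
        if (multi) {
          # force carriers in >= 2 haplogroups so the variant is never private
          two <- sample(present, 2)
          for (g2 in two) {
            members <- which(hg == g2)
            if (sum(col[members]) == 0) col[sample(members, 1)] <- 1L
          }
        } else if (sum(col) == 0) {
          col[sample.int(n, 1)] <- 1L
        }
        cols[[length(cols) + 1L]] <- col
        class_of <- c(class_of, "shared")
        priv_of <- c(priv_of, NA_character_)
      }
    }
    geno <- do.call(cbind, cols)
    pos <- sort(sample.int(config$mt_length, ncol(geno)))
    dimnames(geno) <- list(ids, sprintf("mt%d", pos))
    list(
      genotypes = geno,
      positions = pos,
      variant_class = class_of,
      private_group = priv_of,
      haplogroups = data.frame(sample_id = ids, haplogroup = hg,
                               stringsAsFactors = FALSE)
    )
  })
}

#' Simulate PCL-C item responses and blood-count records
#'
#' PCL-C: each participant's probable-PTSD flag is Bernoulli with the
#' configured prevalence for their group x generation cell; a total at or
#' above (below) the cutoff is then drawn and spread over the 17 items within
#' the configured item scale, so downstream scoring reproduces the flag
#' exactly. Blood counts: each of the 20 measures is drawn around an
#' age-sex-independent reference mean with configured standardized sex
#' effects; a random subset of `blood_subset_n` participants receives records.
#'
#' @param participants output of [simulate_cohort()].
#' @param config a [cohort_config()].
#' @param latents optional latents (only used when `plt_cn_beta != 0`, to
#'   report the platelet-coupled copy-number perturbation).
#' @return list with `pclc` (data.frame id + item_01..item_17) and `blood`
#'   (data.frame id + 20 measures named as in standard full blood counts).
#' @export
simulate_phenotypes <- function(participants, config, latents = NULL) {
  if (any(config$ptsd_prev < 0) || any(config$ptsd_prev > 1)) {
    stop_config("ptsd_prev entries must lie in [0,1]")
  }
  with_substream(config$seed, "pheno", {
    n <- nrow(participants)
    gen_i <- match(participants$generation, colnames(config$ptsd_prev))
    grp_i <- match(participants$group, rownames(config$ptsd_prev))
    prev <- config$ptsd_prev[cbind(grp_i, gen_i)]
    flagged <- stats::runif(n) < prev

    lo <- config$pclc_item_range[1]
    hi <- config$pclc_item_range[2]
    max_total <- 17L * hi
    cutoff <- config$pclc_cutoff
    totals <- integer(n)
    totals[flagged] <- pmin(max_total,
                            cutoff + stats::rpois(sum(flagged), 8))
    totals[!flagged] <- 17L * lo +
      floor(stats::runif(sum(!flagged)) * (cutoff - 17L * lo))
    items <- t(vapply(totals, spread_items, integer(17),
                      lo = lo, hi = hi))
    colnames(items) <- sprintf("item_%02d", 1:17)
    pclc <- data.frame(id = participants$id, items,
                       stringsAsFactors = FALSE)

    ref <- blood_reference()
    m <- min(config$blood_subset_n, n)
    subset_ids <- sample(participants$id, m)
    sub <- participants[match(subset_ids, participants$id), , drop = FALSE]
    male <- as.numeric(sub$sex == "M")
    blood <- data.frame(id = sub$id, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ref))) {
      meas <- ref$measure[j]
      beta <- config$blood_sex_effects[meas] %||% 0
      if (is.na(beta)) beta <- 0
      z <- beta * male + stats::rnorm(m)
      x <- ref$mean[j] + ref$sd[j] * z
      x <- pmax(x, 0)
      if (grepl("percent", meas)) x <- pmin(x, 100)
      blood[[meas]] <- round(x, 3)
    }
    out <- list(pclc = pclc, blood = blood)
    if (!is.null(latents) && config$plt_cn_beta != 0) {
      plt <- blood$PLT_x10.9_per_L
      out$cn_shift <- data.frame(
        id = blood$id,
        shift = config$plt_cn_beta * (plt - mean(plt)),
        stringsAsFactors = FALSE
      )
    }
    out
  })
}

# spread an item total over 17 items by unit increments within [lo, hi]
spread_items <- function(total, lo, hi) {
  items <- rep(as.integer(lo), 17L)
  remaining <- total - 17L * lo
  while (remaining > 0L) {
    open <- which(items < hi)
    pick <- open[sample.int(length(open), 1L)]
    items[pick] <- items[pick] + 1L
    remaining <- remaining - 1L
  }
  items
}

# reference means/SDs for the 20 full-blood-count measures (adult values)
blood_reference <- function() {
  data.frame(
    measure = c("WBC_x10.9_per_L", "RBC_x10.12_per_L", "HGB_g_per_L",
                "HCT_L_per_L", "MCV_fL", "PLT_x10.9_per_L", "MCH_pg",
                "MCHC_g_per_L", "RDW_percent", "MPV_fL",
                "NEU_percent", "LYM_percent", "MONO_percent", "EOS_percent",
                "BASO_percent", "NEU_x10.9_per_L", "LYM_x10.9_per_L",
                "MONO_x10.9_per_L", "EOS_x10.9_per_L", "BASO_x10.9_per_L"),
    mean = c(6.5, 4.7, 140, 0.42, 90, 250, 30, 340, 13, 10,
             58, 30, 8, 2.7, 0.5, 3.8, 2.0, 0.5, 0.17, 0.03),
    sd = c(1.6, 0.5, 15, 0.04, 5, 60, 2, 10, 1, 1,
           8, 7, 2, 1.5, 0.3, 1.2, 0.6, 0.15, 0.1, 0.02),
    stringsAsFactors = FALSE
  )
}
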