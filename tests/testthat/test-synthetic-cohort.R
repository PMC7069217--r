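test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(variance_shares = c(ct_threshold = 0.6,
                                                 batch = 0.3,
                                                 concentration = 0.2)),
               "variance shares")
  expect_error(cohort_config(h = 1.2), "h must")
  expect_error(cohort_config(ptsd_prev = rbind(HS = c(G1 = 1.5, G2 = 0, G3 = 0),
                                               CTRL = c(G1 = 0, G2 = 0, G3 = 0))),
               "ptsd_prev")
  expect_error(cohort_config(n_hs = c(G1 = -1L, G2 = 1L, G3 = 1L)),
               "non-negative")
})

test_that("simulate_cohort reproduces configured counts and pedigree rules", {
  cfg <- cohort_config()
  sim <- simulate_cohort(cfg)
  part <- sim$participants
  expect_equal(nrow(part), 196)
  tab <- table(part$generation, part$group)
  expect_equal(unname(tab["G1", "HS"]), 15)
  expect_equal(unname(tab["G2", "HS"]), 60)
  expect_equal(unname(tab["G3", "HS"]), 42)
  expect_equal(unname(tab["G1", "CTRL"]), 22)
  expect_equal(unname(tab["G2", "CTRL"]), 37)
  expect_equal(unname(tab["G3", "CTRL"]), 20)
  expect_false(any(duplicated(part$id)))
  expect_true(all(part$age > 0))
  expect_true(all(sim$latents$cn_true > 0))

  # every recorded mother is a female of the previous generation
  gen_i <- match(part$generation, c("G1", "G2", "G3"))
  has_mom <- !is.na(part$mother_id)
  mom <- match(part$mother_id[has_mom], part$id)
  expect_true(all(part$sex[mom] == "F"))
  expect_true(all(gen_i[mom] == gen_i[has_mom] - 1))

  # stored lineage flag equals graph traversal recomputation
  recompute <- mitocn:::maternal_lineage_flags(part)
  expect_identical(part$maternal_hs_lineage, recompute)
})

test_that("simulate_cohort is deterministic under seed and responsive to it", {
  cfg <- small_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_cohort(small_config(seed = 43))
  expect_false(identical(a$latents$cn_true, c$latents$cn_true))
})

test_that("null cohort has i.i.d. latents; h=1 noiseless transmits exactly", {
  cfg0 <- cohort_config(group_beta = 0, age_slope = 0, sex_beta = 0, h = 0,
                        seed = 5)
  sim0 <- simulate_cohort(cfg0)
  lcn <- log(sim0$latents$cn_true)
  grp <- sim0$participants$group
  se <- sqrt(var(lcn[grp == "HS"]) / sum(grp == "HS") +
               var(lcn[grp == "CTRL"]) / sum(grp == "CTRL"))
  expect_lt(abs(mean(lcn[grp == "HS"]) - mean(lcn[grp == "CTRL"])), 3 * se)

  cfg1 <- cohort_config(h = 1, transmission_noise_sd = 0,
                        prop_recorded_mother = 1, seed = 6)
  sim1 <- simulate_cohort(cfg1)
  part <- sim1$participants
  dev <- setNames(sim1$latents$log_dev_std, sim1$latents$id)
  kids <- part[!is.na(part$mother_id), ]
  expect_true(nrow(kids) > 50)
  expect_equal(unname(dev[kids$id]), unname(dev[kids$mother_id]))
})

test_that("impossible pedigree raises a configuration error", {
  # all-male G1 makes mothers unassignable
  cfg <- small_config(p_male = 1, prop_recorded_mother = 1)
  expect_error(simulate_cohort(cfg), "impossible pedigree")
})

test_that("qPCR plates have the configured layout and controls", {
  cfg <- cohort_config(seed = 2)
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr_plates(sim$participants, sim$latents, cfg)
  expect_equal(length(unique(wells$plate_id)), 17)
  expect_equal(length(unique(wells$batch_id)), 3)
  for (p in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == p, ]
    expect_lte(nrow(pw), cfg$plate_wells)
    for (g in c("RNASEP", "MT_CYB")) {
      expect_equal(sum(pw$role == "REF" & pw$gene == g), 3)
      expect_gte(sum(pw$role == "NTC" & pw$gene == g), 1)
    }
  }
  # every sample in duplicate for both genes on a single plate
  smp <- wells[wells$role == "SAMPLE", ]
  cnt <- table(smp$sample_id, smp$gene)
  expect_true(all(cnt == 2))
  expect_true(all(tapply(smp$plate_id, smp$sample_id,
                         function(x) length(unique(x))) == 1))
})

test_that("noiseless qPCR follows the log2 template model", {
  cfg <- small_config(
    variance_shares = c(ct_threshold = 0, batch = 0, concentration = 0),
    well_noise_sd = 0, ntc_contam_rate = 0, well_fail_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  sim$latents$cn_true[] <- 1
  sim$latents$cn_true[1] <- 4  # 4x the reference template
  wells <- simulate_qpcr_plates(sim$participants, sim$latents, cfg)
  smp <- wells[wells$role == "SAMPLE", ]
  # duplicates identical without noise
  spread <- tapply(smp$ct, paste(smp$sample_id, smp$gene),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # 4x template: CYB CT exactly 2 cycles below the REF CYB CT
  sid <- sim$participants$id[1]
  ct_cyb <- smp$ct[smp$sample_id == sid & smp$gene == "MT_CYB"][1]
  plate <- smp$plate_id[smp$sample_id == sid][1]
  ref_cyb <- wells$ct[wells$plate_id == plate & wells$role == "REF" &
                        wells$gene == "MT_CYB"][1]
  expect_equal(ct_cyb, ref_cyb - 2)
})

test_that("plate capacity errors are raised", {
  cfg <- small_config()
  cfg$n_plates <- 1L
  expect_error(simulate_qpcr_plates(simulate_cohort(cfg)$participants,
                                    simulate_cohort(cfg)$latents, cfg),
               "capacity")
})

test_that("depth profiles follow the Poisson coverage model", {
  cfg <- small_config(seed = 8)
  sim <- simulate_cohort(cfg)
  sim$latents$cn_true[1:2] <- c(1, 2)
  prof <- simulate_depth_profiles(sim$participants[1:2, ], sim$latents, cfg)
  expect_length(prof[[1]]$mt$depth, 16569)
  expect_length(prof[[1]]$nuc$depth, cfg$nuc_region_length)
  # CN=1, d=30, m=20: ratio within 3 Poisson SEs of 20
  r1 <- region_mean_depth(prof[[1]]$mt) / region_mean_depth(prof[[1]]$nuc)
  se <- 20 * sqrt(1 / (600 * 16569) + 1 / (30 * cfg$nuc_region_length))
  expect_lt(abs(r1 - 20), 3 * se)
  # linearity: CN=2 sample has ~2x the ratio
  r2 <- region_mean_depth(prof[[2]]$mt) / region_mean_depth(prof[[2]]$nuc)
  expect_lt(abs(r2 / r1 - 2), 0.05)

  # m = 0: mtDNA depth identically zero
  cfg0 <- small_config(mt_depth_multiplier = 0)
  p0 <- simulate_depth_profiles(sim$participants[1, ], sim$latents, cfg0)
  expect_true(all(p0[[1]]$mt$depth == 0))
  expect_error(simulate_depth_profiles(sim$participants, sim$latents,
                                       small_config(nuclear_depth = 0)),
               "positive")
})

test_that("genotype panel has exactly the configured private-variant counts", {
  cfg <- cohort_config(seed = 11)
  g <- simulate_mtdna_genotypes(400, cfg)
  expect_equal(ncol(g$genotypes), 3779)
  expect_length(private_variants(g$genotypes, g$haplogroups, "L"), 626)
  # one haplogroup only: no variants private to absent groups
  cfg1 <- small_config()
  cfg1$haplogroup_freqs <- data.frame(haplogroup = "H", freq = 1)
  cfg1$n_private <- c(H = 5L)
  g1 <- simulate_mtdna_genotypes(30, cfg1)
  expect_true(all(g1$haplogroups$haplogroup == "H"))
  expect_error(private_variants(g1$genotypes, g1$haplogroups, "L"),
               "unknown group")
  expect_error(
    simulate_mtdna_genotypes(10, local({
      x <- small_config(); x$haplogroup_freqs <- x$haplogroup_freqs[0, ]; x
    })), "empty")
})

test_that("phenotypes respect prevalence cells and subset size", {
  cfg <- cohort_config(seed = 9)
  sim <- simulate_cohort(cfg)
  # prevalence 1 in every cell: all flagged by downstream scoring
  cfg1 <- cfg
  cfg1$ptsd_prev[] <- 1
  ph1 <- simulate_phenotypes(sim$participants, cfg1)
  sc1 <- score_pclc(ph1$pclc)
  expect_true(all(sc1$probable_ptsd))
  # prevalence 0: none flagged
  cfg0 <- cfg
  cfg0$ptsd_prev[] <- 0
  sc0 <- score_pclc(simulate_phenotypes(sim$participants, cfg0)$pclc)
  expect_false(any(sc0$probable_ptsd))
  # default subset: exactly 70 blood records, 20 measures, valid ranges
  ph <- simulate_phenotypes(sim$participants, cfg)
  expect_equal(nrow(ph$blood), 70)
  expect_equal(ncol(ph$blood) - 1, 20)
  vals <- as.matrix(ph$blood[-1])
  expect_true(all(vals >= 0))
  pct <- grepl("percent", colnames(ph$blood[-1]))
  expect_true(all(vals[, pct] <= 100))
  expect_error(simulate_phenotypes(sim$participants, local({
    x <- cfg; x$ptsd_prev[1, 1] <- 2; x
  })), "ptsd_prev")
})

test_that("blood sex effect is recovered by OLS at large n", {
  cfg <- cohort_config(
    n_hs = c(G1 = 200L, G2 = 200L, G3 = 200L),
    n_ctrl = c(G1 = 200L, G2 = 200L, G3 = 200L),
    blood_subset_n = 1200L, seed = 13)
  cfg$blood_sex_effects <- c(RBC_x10.12_per_L = 1.0)
  sim <- simulate_cohort(cfg)
  ph <- simulate_phenotypes(sim$participants, cfg)
  male <- as.numeric(sim$participants$sex[
    match(ph$blood$id, sim$participants$id)] == "M")
  fit <- summary(lm(inverse_normal_transform(ph$blood$RBC_x10.12_per_L) ~ male))
  expect_lt(abs(fit$coefficients["male", 1] - 1.0),
            3 * fit$coefficients["male", 2])
})

test_that("all generators are substream-independent and deterministic", {
  cfg <- small_config(seed = 21)
  sim <- simulate_cohort(cfg)
  w1 <- simulate_qpcr_plates(sim$participants, sim$latents, cfg)
  g1 <- simulate_mtdna_genotypes(50, cfg)
  # re-running one generator does not perturb another
  w2 <- simulate_qpcr_plates(sim$participants, sim$latents, cfg)
  g2 <- simulate_mtdna_genotypes(50, cfg)
  expect_identical(w1, w2)
  expect_identical(g1, g2)
  ph1 <- simulate_phenotypes(sim$participants, cfg)
  ph2 <- simulate_phenotypes(sim$participants, cfg)
  expect_identical(ph1, ph2)
})
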