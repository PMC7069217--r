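test_that("score_pclc totals, cutoff and validation", {
  expect_equal(score_pclc(rep(0, 17))$total, 0)
  expect_false(score_pclc(rep(0, 17))$probable_ptsd)
  top <- score_pclc(rep(5, 17))
  expect_equal(top$total, 85)
  expect_true(top$probable_ptsd)
  # inclusive cutoff: exactly 30 flags
  items30 <- c(rep(2, 15), 0, 0)
  expect_true(score_pclc(items30)$probable_ptsd)
  expect_false(score_pclc(c(rep(2, 14), 1, 0, 0))$probable_ptsd)
  # permutation invariance and additivity
  set.seed(1)
  it <- sample(0:5, 17, replace = TRUE)
  expect_equal(score_pclc(it)$total, score_pclc(sample(it))$total)
  expect_error(score_pclc(rep(1, 16)), "17 items")
  expect_error(score_pclc(c(rep(1, 16), 6)), "ratings must lie")
  # 1-5 scale supported
  expect_error(score_pclc(rep(0, 17), item_range = c(1, 5)), "ratings")
  expect_equal(score_pclc(rep(1, 17), item_range = c(1, 5))$total, 17)
})

test_that("fit_group_model: perfect signal, interactions, collinearity", {
  set.seed(2)
  d <- data.frame(grp = rep(0:1, each = 20), age = rnorm(40, 50, 10))
  d$cn <- d$grp
  fit <- suppressWarnings(fit_group_model(d, "cn", "grp", covariates = "age"))
  expect_equal(fit$beta[fit$term == "grp"], 1, tolerance = 1e-10)
  expect_lt(fit$p[fit$term == "grp"], 1e-12)

  d$cn <- rnorm(40) + 0.5 * d$grp * scale(d$age)[, 1]
  fiti <- fit_group_model(d, "cn", "grp", covariates = "age",
                          interaction = "age")
  expect_true("grp:age" %in% fiti$term)

  d$dup <- d$grp * 2
  expect_error(fit_group_model(d, "cn", "grp", covariates = "dup"),
               "collinear")
  d$konst <- 1
  expect_error(fit_group_model(d, "cn", "konst"), "does not vary")
})

test_that("fit_group_model p-values agree with a permutation null at n=30", {
  set.seed(31)
  d <- data.frame(grp = rep(0:1, 15), age = rnorm(30, 40, 12))
  d$cn <- rnorm(30)
  obs <- fit_group_model(d, "cn", "grp", covariates = "age")
  p_lm <- obs$p[obs$term == "grp"]
  b_obs <- abs(obs$beta[obs$term == "grp"])
  B <- 10000
  perm <- replicate(B, {
    d2 <- d
    d2$grp <- sample(d2$grp)
    f <- fit_group_model(d2, "cn", "grp", covariates = "age")
    abs(f$beta[f$term == "grp"])
  })
  expect_lt(abs(mean(perm >= b_obs) - p_lm), 0.02)
})

test_that("fisher_2x2 matches enumeration and has sane OR/CI", {
  f <- fisher_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(f$p, 1 / 3, tolerance = 1e-12)
  expect_true(f$continuity_corrected)

  f2 <- fisher_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(f2$or, 1)
  expect_equal(f2$p, 1)
  expect_true(f2$ci[1] <= f2$or && f2$or <= f2$ci[2])

  # transpose symmetry
  t1 <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_2x2(t1)$p, fisher_2x2(t(t1))$p, tolerance = 1e-12)

  expect_error(fisher_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")

  # random spot-checks against the independent enumeration oracle
  set.seed(5)
  for (rep in 1:50) {
    t2 <- matrix(rpois(4, 4) + matrix(c(1, 0, 0, 1), 2), 2)
    expect_equal(fisher_2x2(t2)$p, enumerate_fisher_p(t2), tolerance = 1e-12)
  }
})

test_that("min_detectable_f solves the noncentral-F power equation", {
  f <- min_detectable_f(97, 2)
  v <- 97 - 2 - 2
  # round-trip: plugging f back yields the requested power to 1e-6
  power <- pf(qf(0.95, 1, v), 1, v, ncp = f^2 * (v + 2), lower.tail = FALSE)
  expect_equal(power, 0.8, tolerance = 1e-6)
  expect_equal(round(f, 2), 0.29)
  # f window for the smallest generation under this lambda convention
  expect_gt(min_detectable_f(37, 2), 0.47)
  expect_lt(min_detectable_f(37, 2), 0.49)
  # strictly decreasing in n
  ns <- c(20, 50, 100, 200, 1000)
  fs <- vapply(ns, min_detectable_f, 0, n_covariates = 2)
  expect_true(all(diff(fs) < 0))
  expect_error(min_detectable_f(4, 2), "unattainable")
})

test_that("parent_child_model recovers transmission and degenerates safely", {
  # children duplicated from parents: beta = 1
  set.seed(41)
  n <- 40
  parents <- data.frame(
    id = paste0("P", 1:n), generation = "G1", group = "HS",
    sex = rep(c("F", "M"), n / 2), age = rnorm(n, 80, 4),
    mother_id = NA_character_, father_id = NA_character_,
    stringsAsFactors = FALSE)
  children <- data.frame(
    id = paste0("C", 1:n), generation = "G2", group = "HS",
    sex = sample(c("F", "M"), n, TRUE), age = rnorm(n, 50, 8),
    mother_id = ifelse(rep(c(TRUE, FALSE), n / 2), paste0("P", 1:n), NA),
    father_id = ifelse(rep(c(FALSE, TRUE), n / 2), paste0("P", 1:n), NA),
    stringsAsFactors = FALSE)
  part <- rbind(parents, children)
  cn <- c(rnorm(n), rep(NA, n))
  names(cn) <- part$id
  cn[children$id] <- cn[paste0("P", 1:n)]
  res <- suppressWarnings(parent_child_model(cn, part))
  expect_equal(res$beta[res$term == "parent_cn"], 1, tolerance = 1e-8)

  # h = 0.5 at ~100 pairs: recovered within 3 SE
  n2 <- 100
  p2 <- data.frame(id = paste0("P", 1:n2), generation = "G1", group = "HS",
                   sex = "F", age = rnorm(n2, 80, 4),
                   mother_id = NA_character_, father_id = NA_character_)
  c2 <- data.frame(id = paste0("C", 1:n2), generation = "G2", group = "HS",
                   sex = sample(c("F", "M"), n2, TRUE), age = rnorm(n2, 50, 8),
                   mother_id = paste0("P", 1:n2), father_id = NA_character_)
  part2 <- rbind(p2, c2)
  cn2 <- setNames(rnorm(2 * n2), part2$id)
  cn2[c2$id] <- 0.5 * cn2[p2$id] + rnorm(n2)
  res2 <- parent_child_model(cn2, part2, mothers_only = TRUE)
  r <- res2[res2$term == "parent_cn", ]
  expect_lt(abs(r$beta - 0.5), 3 * r$se)

  # parental exposure predictor variant
  part2$group[1:50] <- "CTRL"
  res3 <- parent_child_model(cn2, part2, predictor = "parent_group")
  expect_true("parent_group" %in% res3$term)

  expect_error(parent_child_model(cn2[1:2], part2[c(1, 101), ]),
               "at least 3")
})

test_that("blood screen flags at the Bonferroni threshold and joint model runs", {
  cfg <- cohort_config(seed = 43)
  sim <- simulate_cohort(cfg)
  ph <- simulate_phenotypes(sim$participants, cfg)
  sc <- score_pclc(ph$pclc)
  md <- data.frame(id = sim$participants$id, age = sim$participants$age,
                   sex = sim$participants$sex, group = sim$participants$group,
                   generation = sim$participants$generation,
                   probable_ptsd = sc$probable_ptsd)
  bs <- blood_screen(ph$blood, md)
  expect_equal(bs$n_tests, 80)
  expect_equal(bs$threshold, 0.05 / 80)  # = 6.25e-4
  expect_equal(nrow(bs$results), 80)
  expect_identical(bs$results$significant, bs$results$p < bs$threshold)

  cn <- setNames(rnorm(196), sim$participants$id)
  jb <- joint_blood_model(cn, ph$blood, md)
  expect_equal(nrow(jb), 22)  # 20 measures + age + sex
  expect_true(all(jb$se > 0))

  ph$blood$konst <- 5
  expect_warning(blood_screen(ph$blood, md), "constant measure")
})

test_that("clustering merges duplicates first and separates blobs", {
  set.seed(47)
  blood <- data.frame(id = paste0("i", 1:6),
                      a = rnorm(6), b = rnorm(6), c = rnorm(6))
  blood[6, -1] <- blood[5, -1]  # exact tie: identical normal scores
  cl <- cluster_blood(blood)
  merge1 <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-merge1], c("i5", "i6"))

  # two well-separated blobs recovered exactly at k = 2
  blob <- data.frame(id = paste0("s", 1:20),
                     x = c(rnorm(10), rnorm(10) + 50),
                     y = c(rnorm(10), rnorm(10) + 50))
  cl2 <- cluster_blood(blob, k = 2)
  expect_equal(length(unique(cl2$labels[1:10])), 1)
  expect_equal(length(unique(cl2$labels[11:20])), 1)
  expect_true(cl2$labels[1] != cl2$labels[11])
  expect_error(cluster_blood(blood[1:2, ]), "at least 3")
})

test_that("balance checks run the plate and per-generation tests", {
  cfg <- cohort_config(seed = 51)
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr_plates(sim$participants, sim$latents, cfg)
  smp <- wells[wells$role == "SAMPLE", c("sample_id", "plate_id")]
  smp <- smp[!duplicated(smp$sample_id), ]
  md <- data.frame(id = sim$participants$id, age = sim$participants$age,
                   sex = sim$participants$sex, group = sim$participants$group,
                   generation = sim$participants$generation,
                   probable_ptsd = rbinom(196, 1, 0.2) == 1)
  bc <- balance_checks(md, smp)
  expect_true(all(c("plate_x_sex", "plate_x_group") %in% bc$check))
  expect_true(any(grepl("G2_group_x_age", bc$check)))
  expect_true(all(bc$p >= 0 & bc$p <= 1, na.rm = TRUE))
})
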