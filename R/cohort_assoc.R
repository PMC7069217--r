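#' Score a PCL-C questionnaire response
#'
#' Totals the 17 item ratings; a total at or above the cutoff (inclusive)
#' flags probable PTSD. The default item scale is 0-5, which makes the
#' 0-85 total range attainable; a 1-5 scale can be configured.
#'
#' @param items numeric vector of 17 item ratings, or a matrix/data.frame of
#'   responses (17 item columns, one row per respondent).
#' @param cutoff probable-PTSD cutoff, inclusive (default 30).
#' @param item_range allowed rating range (default `c(0, 5)`).
#' @return data.frame: total, probable_ptsd (plus id when input had an `id`
#'   column).
#' @export
score_pclc <- function(items, cutoff = 30, item_range = c(0, 5)) {
  id <- NULL
  if (is.data.frame(items) && "id" %in% names(items)) {
    id <- items$id
    items <- items[setdiff(names(items), "id")]
  }
  m <- as.matrix(items)
  if (is.vector(items) && is.null(dim(items))) m <- matrix(items, nrow = 1)
  if (ncol(m) != 17) {
    stop("PCL-C requires exactly 17 items, got ", ncol(m))
  }
  if (any(is.na(m)) || any(m < item_range[1]) || any(m > item_range[2])) {
    stop("item ratings must lie in [", item_range[1], ", ", item_range[2],
         "] with no missing values")
  }
  total <- rowSums(m)
  out <- data.frame(total = total, probable_ptsd = total >= cutoff)
  if (!is.null(id)) out <- cbind(id = id, out)
  out
}

#' Linear association model with covariates
#'
#' Ordinary least squares of a copy-number score on a predictor plus
#' covariates, with a two-sided t-test on each coefficient. An optional
#' `predictor:covariate` interaction is reported as its own row.
#'
#' @param data data.frame holding all variables.
#' @param response,predictor column names.
#' @param covariates character vector of covariate column names.
#' @param interaction optional covariate name to interact with the predictor.
#' @return data.frame: term, beta, se, p, n.
#' @export
fit_group_model <- function(data, response, predictor, covariates = NULL,
                            interaction = NULL) {
  vars <- c(response, predictor, covariates, interaction)
  stopifnot(all(vars %in% names(data)))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (length(unique(df[[predictor]])) < 2) {
    stop("predictor '", predictor, "' does not vary")
  }
  rhs <- c(predictor, covariates)
  if (!is.null(interaction)) {
    rhs <- c(rhs, paste0(predictor, ":", interaction))
  }
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased terms: ", paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  data.frame(
    term = rownames(cf)[keep],
    beta = cf[keep, 1], se = cf[keep, 2], p = cf[keep, 4],
    n = nrow(df), row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing all hypergeometric probabilities not
#' exceeding that of the observed table (with the customary 1e-7 relative
#' tolerance for ties). The odds ratio is the sample cross-ratio `ad/bc`
#' (0.5 added to every cell when any cell is zero, flagged in the output);
#' the 95% CI uses the log-OR normal (Woolf) method, with the method
#' recorded.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `fisher_2x2`: `table`, `or`, `ci` (length 2), `p`,
#'   `continuity_corrected`, `ci_method`.
#' @export
fisher_2x2 <- function(table, conf_level = 0.95) {
  t2 <- as.matrix(table)
  stopifnot(all(dim(t2) == c(2, 2)), all(t2 >= 0), all(t2 == round(t2)))
  if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) {
    stop("both margins must be positive")
  }
  a <- t2[1, 1]
  m <- sum(t2[1, ])   # row-1 margin
  n <- sum(t2[2, ])   # row-2 margin
  k <- sum(t2[, 1])   # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  cc <- any(t2 == 0)
  tt <- if (cc) t2 + 0.5 else t2
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se_log <- sqrt(sum(1 / tt))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se_log)

  structure(list(table = t2, or = or, ci = ci, p = p,
                 continuity_corrected = cc, ci_method = "woolf_log_or"),
            class = "fisher_2x2")
}

#' Minimal detectable effect size (Cohen's f) for one regression coefficient
#'
#' Solves the noncentral-F power equation for a single-coefficient test:
#' numerator df 1, denominator df `v = n - n_covariates - 2`, noncentrality
#' `lambda = f^2 * (1 + v + 1)`; returns the f achieving the requested power
#' at the requested alpha. f is strictly decreasing in n.
#'
#' @param n total sample size.
#' @param n_covariates number of covariates besides the tested term.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @return Cohen's f (numeric scalar).
#' @export
min_detectable_f <- function(n, n_covariates, alpha = 0.05, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  v <- n - n_covariates - 2
  if (v < 1) stop("unattainable power: denominator df ", v, " < 1")
  crit <- stats::qf(1 - alpha, 1, v)
  pow <- function(f) {
    stats::pf(crit, 1, v, ncp = f^2 * (v + 2), lower.tail = FALSE) - power
  }
  stats::uniroot(pow, c(1e-8, 100), tol = 1e-10)$root
}

#' Parent-child copy-number inheritance model
#'
#' Builds all recorded parent-child pairs from the pedigree and regresses the
#' child's copy-number score on the parent's score (or, with
#' `predictor = "parent_group"`, on the parent's exposure group) controlling
#' for age and sex of both parent and child.
#'
#' @param cn named numeric vector of copy-number scores (names are
#'   participant ids).
#' @param participants participants data.frame (id, sex, age, mother_id,
#'   father_id, group).
#' @param predictor `"parent_cn"` (default) or `"parent_group"`.
#' @param mothers_only restrict pairs to mother-child links.
#' @return data.frame as from [fit_group_model()], one row per model term.
#' @export
parent_child_model <- function(cn, participants, predictor = c("parent_cn",
                                                               "parent_group"),
                               mothers_only = FALSE) {
  predictor <- match.arg(predictor)
  pairs <- list()
  for (col in c("mother_id", "father_id")) {
    if (mothers_only && col == "father_id") next
    has <- !is.na(participants[[col]]) &
      participants[[col]] %in% participants$id
    ch <- participants[has, , drop = FALSE]
    pa <- participants[match(ch[[col]], participants$id), , drop = FALSE]
    if (nrow(ch) == 0) next
    pairs[[col]] <- data.frame(
      child_cn = unname(cn[ch$id]), parent_cn = unname(cn[pa$id]),
      child_age = ch$age, child_sex = as.numeric(ch$sex == "M"),
      parent_age = pa$age, parent_sex = as.numeric(pa$sex == "M"),
      parent_group = as.numeric(pa$group == "HS"),
      stringsAsFactors = FALSE
    )
  }
  d <- do.call(rbind, pairs)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (is.null(d) || nrow(d) < 3) {
    stop("need at least 3 parent-child pairs with complete covariates")
  }
  covs <- c("child_age", "child_sex", "parent_age", "parent_sex")
  covs <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1, TRUE)]
  if (nrow(d) < length(covs) + 3) {
    stop("fewer pairs than model parameters")
  }
  fit_group_model(d, "child_cn", predictor, covariates = covs)
}

#' Blood-count confounder screen and joint model
#'
#' `blood_screen` inverse-normal-transforms every measure and regresses each
#' on age, sex, exposure group and probable PTSD jointly, reporting each
#' coefficient per measure; significance is flagged at the Bonferroni
#' threshold `alpha / (n_measures * n_covariates)`. `joint_blood_model`
#' regresses the copy-number score on all (raw-unit) measures plus age and
#' sex simultaneously.
#'
#' @param blood data.frame: id + measure columns.
#' @param metadata data.frame: id, age, sex, group, probable_ptsd.
#' @param alpha familywise alpha for the Bonferroni threshold.
#' @return `blood_screen`: list with `results` (measure, term, beta, se, p,
#'   significant), `threshold`, `n_tests`. Constant measures are dropped with
#'   a warning.
#' @export
blood_screen <- function(blood, metadata, alpha = 0.05) {
  measures <- setdiff(names(blood), "id")
  md <- metadata[match(blood$id, metadata$id), , drop = FALSE]
  covs <- data.frame(
    age = md$age, sex = as.numeric(md$sex == "M"),
    group = as.numeric(md$group == "HS"),
    ptsd = as.numeric(md$probable_ptsd)
  )
  keep <- vapply(measures, function(m) {
    length(unique(blood[[m]][!is.na(blood[[m]])])) > 1
  }, TRUE)
  if (any(!keep)) {
    warning("constant measure(s) dropped: ",
            paste(measures[!keep], collapse = ", "))
  }
  measures <- measures[keep]
  n_tests <- length(measures) * ncol(covs)
  threshold <- alpha / n_tests
  rows <- list()
  for (m in measures) {
    y <- inverse_normal_transform(blood[[m]])
    d <- cbind(y = y, covs)
    fit <- stats::lm(y ~ age + sex + group + ptsd, data = d)
    cf <- summary(fit)$coefficients
    for (term in c("age", "sex", "group", "ptsd")) {
      rows[[paste(m, term)]] <- data.frame(
        measure = m, term = term, beta = cf[term, 1], se = cf[term, 2],
        p = cf[term, 4], significant = cf[term, 4] < threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  list(results = res, threshold = threshold, n_tests = n_tests)
}

#' @rdname blood_screen
#' @param cn named numeric vector of copy-number scores (by participant id).
#' @return `joint_blood_model`: data.frame (term, beta, se, p, n) for every
#'   measure plus age and sex.
#' @export
joint_blood_model <- function(cn, blood, metadata) {
  md <- metadata[match(blood$id, metadata$id), , drop = FALSE]
  measures <- setdiff(names(blood), "id")
  d <- data.frame(cn = unname(cn[blood$id]), blood[measures],
                  age = md$age, sex = as.numeric(md$sex == "M"))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fit <- stats::lm(cn ~ ., data = d)
  cf <- summary(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  data.frame(term = rownames(cf)[keep], beta = cf[keep, 1],
             se = cf[keep, 2], p = cf[keep, 4], n = nrow(d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of blood measures and randomization balance checks
#'
#' `cluster_blood` inverse-normal-transforms the measures and clusters
#' individuals by Euclidean distance with average linkage; individuals
#' missing more than `max_missing` of their measures are excluded (reported
#' in the result). `balance_checks` runs chi-squared tests of plate against
#' sex/group/PTSD, and per-generation group-vs-age t-tests and group-vs-sex
#' Fisher tests.
#'
#' @param blood data.frame: id + measure columns.
#' @param k number of clusters for the returned cut (default 2).
#' @param max_missing maximum tolerated fraction of missing measures.
#' @return `cluster_blood`: list with `hclust`, `labels` (named cluster
#'   memberships), `excluded`.
#' @export
cluster_blood <- function(blood, k = 2, max_missing = 0.2) {
  measures <- setdiff(names(blood), "id")
  if (nrow(blood) < 3) stop("need at least 3 individuals to cluster")
  x <- sapply(blood[measures], inverse_normal_transform)
  rownames(x) <- blood$id
  miss <- rowMeans(is.na(x))
  excluded <- rownames(x)[miss > max_missing]
  x <- x[miss <= max_missing, , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, k = min(k, nrow(x)))
  list(hclust = hc, labels = labels, excluded = excluded)
}

#' @rdname cluster_blood
#' @param metadata data.frame: id, age, sex, group, generation,
#'   probable_ptsd (PTSD column optional).
#' @param plate_assignments data.frame: sample_id, plate_id.
#' @return `balance_checks`: data.frame (check, statistic, p).
#' @export
balance_checks <- function(metadata, plate_assignments) {
  md <- metadata
  md$plate <- plate_assignments$plate_id[match(md$id,
                                               plate_assignments$sample_id)]
  md <- md[!is.na(md$plate), , drop = FALSE]
  rows <- list()
  add <- function(check, statistic, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, statistic = statistic, p = p, stringsAsFactors = FALSE)
  }
  for (v in c("sex", "group", "probable_ptsd")) {
    if (!v %in% names(md) || length(unique(md[[v]])) < 2) next
    ct <- suppressWarnings(stats::chisq.test(table(md$plate, md[[v]])))
    add(paste0("plate_x_", v), unname(ct$statistic), ct$p.value)
  }
  for (g in unique(md$generation)) {
    sub <- md[md$generation == g, , drop = FALSE]
    if (length(unique(sub$group)) == 2) {
      tt <- stats::t.test(age ~ group, data = sub)
      add(paste0(g, "_group_x_age"), unname(tt$statistic), tt$p.value)
      tab <- table(sub$group, sub$sex)
      if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
          all(colSums(tab) > 0)) {
        ft <- fisher_2x2(tab)
        add(paste0(g, "_group_x_sex"), ft$or, ft$p)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
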