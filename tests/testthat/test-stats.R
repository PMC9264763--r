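test_that("exact signed-rank p matches closed cases and brute force", {
  # five pairs, all differences positive: two-sided p = 2 * (1/32) = 0.0625
  r5 <- exact_signed_rank(c(2, 3, 1, 5, 4), c(1, 1, 0, 1, 2))
  expect_equal(r5$p, 0.0625)
  expect_equal(r5$statistic, 15)
  expect_equal(min(1, 3 * r5$p), 0.1875)   # Bonferroni at family 3

  # brute-force enumeration oracle over all 2^n sign assignments,
  # including tied and mixed-sign samples
  set.seed(77)
  for (n in c(6, 8, 10, 12)) {
    d_cont <- rnorm(n, 0.3)
    d_tied <- round(rnorm(n, 0.3) * 2) / 2
    d_tied[d_tied == 0] <- 0.5
    for (d in list(d_cont, d_tied)) {
      expect_equal(exact_signed_rank(d)$p, brute_signed_rank_p(d),
                   tolerance = 1e-12)
    }
    # tie-free samples also agree with the stock exact implementation
    expect_equal(exact_signed_rank(d_cont)$p,
                 wilcox.test(d_cont, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # zeros are dropped before ranking
  expect_equal(exact_signed_rank(c(0, 0, 1, 2, 3))$n_used, 3)
  expect_error(exact_signed_rank(c(0, 0, 0)), "zero")

  # large-n branch: normal approximation close to the stock test
  set.seed(3)
  dl <- rnorm(40, 0.2)
  pa <- exact_signed_rank(dl, exact_cutoff = 25)
  expect_equal(pa$method, "normal_approx")
  expect_equal(pa$p, wilcox.test(dl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

make_table <- function(vals, metrics = "C1", patients = 12) {
  # vals: list tissue -> matrix patients x metrics (or vector)
  rows <- list()
  for (tt in names(vals)) {
    v <- matrix(vals[[tt]], patients)
    for (j in seq_along(metrics))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", seq_len(patients)), tissue = tt,
        metric = metrics[j], median = v[, j], n_voxels = 100,
        roi_volume_cm3 = 3.125)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

test_that("pairwise Wilcoxon stage: symmetry, capping, monotonicity", {
  set.seed(19)
  tab <- make_table(list(malignant = rlnorm(12, log(0.32), 0.4),
                         benign = rlnorm(12, log(0.05), 1.5),
                         healthy = rlnorm(12, log(0.08), 1.1)))
  rep1 <- pairwise_wilcoxon_bonferroni(tab, "C1")
  expect_equal(nrow(rep1), 3)
  expect_true(all(rep1$p_adjusted >= rep1$p_raw))
  expect_true(all(rep1$p_adjusted == pmin(1, 3 * rep1$p_raw)))
  # adjusted ordering preserves raw ordering
  expect_equal(order(rep1$p_raw), order(rep1$p_raw + 0))
  expect_false(is.unsorted(rep1$p_adjusted[order(rep1$p_raw)]))
  # two-sidedness: swapping the tissues in a pair leaves p unchanged
  swapped <- tab
  swapped$tissue[swapped$tissue == "benign"] <- "tmp"
  swapped$tissue[swapped$tissue == "healthy"] <- "benign"
  swapped$tissue[swapped$tissue == "tmp"] <- "healthy"
  rep2 <- pairwise_wilcoxon_bonferroni(swapped, "C1")
  expect_equal(rep1$p_raw[3], rep2$p_raw[3], tolerance = 1e-12)
  # p_adjusted capped at 1
  expect_true(all(rep1$p_adjusted <= 1))
  expect_error(pairwise_wilcoxon_bonferroni(tab, "nope"), "not present")
})

test_that("Shapiro-Wilk and Levene wrappers behave like the references", {
  expect_error(rsi_shapiro(rep(1, 10)), "constant")
  expect_error(rsi_shapiro(c(1, 2)), "3 <= n")
  set.seed(9)
  x <- rexp(80)
  rp <- rsi_shapiro(x)
  expect_lt(rp$p_raw, 0.05)                       # exponential is non-normal
  expect_equal(rp$p_raw, shapiro.test(x)$p.value)

  expect_error(rsi_levene(list(rnorm(5))), "two groups")
  set.seed(10)
  a <- rnorm(50); b <- rnorm(50) + 3              # pure location shift
  lv <- rsi_levene(list(a, b))
  expect_gt(lv$p_raw, 0.2)
  lv2 <- rsi_levene(list(a, a * 10))              # scale difference
  expect_lt(lv2$p_raw, 0.05)
  # agrees with car on the same data
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 50)))
  expect_equal(lv$statistic, ref$`F value`[1])
})

test_that("ranked RM-ANOVA is rank-invariant and detects tissue effects", {
  set.seed(42)
  mets <- c("C1", "C2", "C3")
  vals <- list(
    malignant = cbind(rlnorm(12, log(0.32), 0.3), rlnorm(12, log(2.6), 0.3),
                      rlnorm(12, log(0.13), 0.5)),
    benign = cbind(rlnorm(12, log(0.05), 0.5), rlnorm(12, log(1.6), 0.3),
                   rlnorm(12, log(0.34), 0.5)),
    healthy = cbind(rlnorm(12, log(0.08), 0.5), rlnorm(12, log(0.9), 0.3),
                    rlnorm(12, log(0.34), 0.5)))
  tab <- make_table(vals, mets)
  res <- ranked_rm_anova(tab)
  expect_equal(res$comparison, c("tissue", "metric", "tissue:metric"))
  expect_lt(res$p_raw[1], 0.05)

  # invariance under a strictly increasing transform of all values
  tab2 <- tab; tab2$median <- exp(tab2$median)
  res2 <- ranked_rm_anova(tab2)
  expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  expect_equal(res$p_raw, res2$p_raw, tolerance = 1e-12)

  # permutation oracle for the tissue effect: permute tissue labels within
  # patient and compare the observed F to the permutation distribution
  obs_f <- res$statistic[1]
  set.seed(1)
  perm_f <- replicate(200, {
    ptab <- tab
    for (pid in unique(ptab$patient_id)) {
      sel <- ptab$patient_id == pid
      relab <- sample(c("malignant", "benign", "healthy"))
      names(relab) <- c("malignant", "benign", "healthy")
      ptab$tissue[sel] <- relab[ptab$tissue[sel]]
    }
    ranked_rm_anova(ptab)$statistic[1]
  })
  p_perm <- mean(perm_f >= obs_f)
  expect_lt(p_perm, 0.05)

  # degenerate all-equal table gives NA p-values, not an error
  flat <- make_table(list(malignant = rep(1, 12), benign = rep(1, 12),
                          healthy = rep(1, 12)), "C1")
  flat3 <- do.call(rbind, lapply(mets, function(m) {
    f <- flat; f$metric <- m; f
  }))
  class(flat3) <- c("cohort_table", "data.frame")
  expect_true(all(is.na(ranked_rm_anova(flat3)$p_raw)))

  # unbalanced table names the missing cell
  expect_error(ranked_rm_anova(tab[-1, ]), "unbalanced")
})

test_that("marginal one-factor analyses cover every metric and tissue", {
  set.seed(14)
  mets <- c("C1", "C2", "C3")
  vals <- lapply(c(malignant = 1, benign = 2, healthy = 3), function(i)
    matrix(rlnorm(36, log(0.3 * i), 0.4), 12))
  tab <- make_table(vals, mets)
  mg <- marginal_ranked_anova(tab, mets)
  expect_equal(nrow(mg), 3 + 3)   # per-metric tissue tests + per-tissue component tests
  expect_true(all(mg$p_raw >= 0 & mg$p_raw <= 1, na.rm = TRUE))
})

test_that("the full battery runs on a synthetic cohort table", {
  set.seed(23)
  mets <- c("C1", "C2", "C3", "C1C2", "sqrtC1C2", "ADC")
  vals <- lapply(c(malignant = 0.3, benign = 0.1, healthy = 0.12), function(m)
    matrix(rlnorm(72, log(m), 0.5), 12))
  tab <- make_table(vals, mets)
  st <- cohort_stats(tab)
  expect_s3_class(st, "cohort_stats")
  expect_equal(nrow(st$pairwise), 18)          # 6 metrics x 3 pairs
  expect_equal(nrow(st$variance), 6)
  expect_equal(nrow(st$normality), 18)
  expect_true(all(st$pairwise$family == 3))
  expect_output(print(st), "Pairwise Wilcoxon")
})
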