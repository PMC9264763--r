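#' @title Statistical battery for paired tissue comparisons
#' @description Helpers mirroring the analysis battery run on the cohort
#'   table: Shapiro-Wilk normality checks, Levene's homogeneity-of-variance
#'   test, a ranked two-way repeated-measures ANOVA across tissue type and
#'   diffusion component, and post hoc paired Wilcoxon signed-rank tests with
#'   Bonferroni correction at family size 3 (the three tissue pairs within a
#'   metric). Alpha is 0.05 throughout.
#' @name group_stats
NULL

new_test_report <- function(test, comparison, statistic, df = NA_real_,
                            p_raw = NA_real_, p_adjusted = NA_real_,
                            family = NA_integer_) {
  data.frame(test = test, comparison = comparison, statistic = statistic,
             df = df, p_raw = p_raw, p_adjusted = p_adjusted,
             family = family, alpha = 0.05)
}

#' Shapiro-Wilk normality test report
#'
#' @param values numeric sample, 3 <= n <= 5000, not constant.
#' @param label comparison label carried into the report.
#' @return One-row report data.frame with W and p.
#' @export
rsi_shapiro <- function(values, label = "sample") {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) stop("Shapiro-Wilk is undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  new_test_report("shapiro_wilk", label, unname(sw$statistic),
                  p_raw = sw$p.value)
}

#' Levene homogeneity-of-variance test report
#'
#' Brown-Forsythe variant by default (absolute deviations from the group
#' median).
#'
#' @param groups list of numeric vectors, >= 2 groups with n >= 2 each.
#' @param center `"median"` (default) or `"mean"`.
#' @param label comparison label.
#' @return One-row report with the Levene F statistic, dfs and p.
#' @export
rsi_levene <- function(groups, center = c("median", "mean"), label = "groups") {
  center <- match.arg(center)
  if (length(groups) < 2) stop("Levene's test needs at least two groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  lt <- car::leveneTest(y, g, center = get(center))
  rep_ <- new_test_report("levene", label, lt$`F value`[1],
                          df = lt$Df[1], p_raw = lt$`Pr(>F)`[1])
  rep_$df2 <- lt$Df[2]
  rep_
}

# ---- exact Wilcoxon signed-rank -------------------------------------------

# exact null distribution of 2*W+ given (possibly tied) absolute-rank vector;
# returns P(W2 <= w2) and P(W2 >= w2) by generating-function convolution
signed_rank_tails <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)  # f[k+1] = P(W2 = k) * 2^n
  f[1] <- 1
  for (r in ranks2) {
    g <- numeric(total + 1)
    g[(r + 1):(total + 1)] <- f[1:(total + 1 - r)]
    f <- f + g
  }
  f <- f / 2^length(ranks2)
  w2 <- round(w2)
  c(lower = sum(f[seq_len(w2 + 1)]), upper = sum(f[seq(w2 + 1, total + 1)]))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped before ranking (default) or handled by the Pratt method; ties get
#' mid-ranks. For n <= `exact_cutoff` pairs the p-value comes from the exact
#' null distribution of the positive-rank sum conditional on the observed
#' absolute ranks (enumeration over all sign assignments via convolution);
#' above the cutoff a normal approximation with tie correction and continuity
#' correction is used. The two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y paired numeric vectors (or `x` = differences, `y = NULL`).
#' @param zero_policy `"drop"` or `"pratt"`.
#' @param exact_cutoff largest n for the exact distribution (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `n_used`, `p`
#'   and `method`.
#' @export
exact_signed_rank <- function(x, y = NULL, zero_policy = c("drop", "pratt"),
                              exact_cutoff = 25) {
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  nonzero <- d != 0
  if (!any(nonzero)) stop("all paired differences are zero")
  if (zero_policy == "drop") {
    d <- d[nonzero]
    r <- rank(abs(d))
    keep <- rep(TRUE, length(d))
  } else {
    r <- rank(abs(d))       # zeros keep their (smallest) ranks
    keep <- d != 0
    d <- d
  }
  n <- length(d)
  V <- sum(r[keep & d > 0])
  ranks2 <- round(2 * r[keep])
  if (sum(keep) <= exact_cutoff) {
    tails <- signed_rank_tails(ranks2, 2 * V)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- sum(r[keep]) / 2
    sig2 <- sum(r[keep]^2) / 4
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = V, n_used = sum(keep), p = p, method = method)
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Post hoc paired comparisons of the three tissue types for one metric of a
#' cohort table: malignant-benign, malignant-healthy, benign-healthy. Raw
#' two-sided exact p-values are Bonferroni-adjusted with family size `family`
#' (default 3, the pairs within one metric), `p_adj = min(1, family * p)`.
#'
#' @param table a [build_cohort_table()] data.frame.
#' @param metric one of `r toString(rsi_metrics)`.
#' @param family Bonferroni family size.
#' @param zero_policy,exact_cutoff passed to [exact_signed_rank()].
#' @return Report data.frame, one row per tissue pair.
#' @export
pairwise_wilcoxon_bonferroni <- function(table, metric, family = 3,
                                         zero_policy = "drop",
                                         exact_cutoff = 25) {
  sub <- table[table$metric == metric, ]
  if (nrow(sub) == 0) stop(sprintf("metric '%s' not present in the table", metric))
  wide <- stats::reshape(sub[, c("patient_id", "tissue", "median")],
                         idvar = "patient_id", timevar = "tissue",
                         direction = "wide")
  pairs <- list(c("malignant", "benign"), c("malignant", "healthy"),
                c("benign", "healthy"))
  out <- lapply(pairs, function(pr) {
    a <- wide[[paste0("median.", pr[1])]]
    b <- wide[[paste0("median.", pr[2])]]
    ok <- stats::complete.cases(a, b)
    t <- exact_signed_rank(a[ok], b[ok], zero_policy = zero_policy,
                           exact_cutoff = exact_cutoff)
    rp <- new_test_report("wilcoxon_signed_rank",
                          sprintf("%s: %s vs %s", metric, pr[1], pr[2]),
                          t$statistic, p_raw = t$p,
                          p_adjusted = min(1, family * t$p),
                          family = family)
    rp$n <- t$n_used
    rp$method <- t$method
    rp
  })
  do.call(rbind, out)
}

# ---- ranked repeated-measures ANOVA ---------------------------------------

#' Ranked two-way repeated-measures ANOVA
#'
#' Conover-style rank transform followed by a two-way repeated-measures ANOVA:
#' all selected values of the cohort table are ranked jointly once (mid-ranks
#' for ties), then `aov(rank ~ tissue * metric + Error(patient/(tissue *
#' metric)))` is fitted with the patient as the repeated unit. Because only
#' ranks enter, the result is invariant under any strictly increasing
#' transform of the values. The default restricts the metric factor to the
#' three diffusion components C1, C2, C3 (the two factors of interest being
#' tissue type and diffusion component). A table with all values equal yields
#' `NA` p-values rather than an error.
#'
#' @param table a [build_cohort_table()] data.frame, complete and balanced
#'   over patients x tissues x metrics.
#' @param metrics metrics included as the second within factor.
#' @return Report data.frame with rows for the tissue effect, the metric
#'   (component) effect and their interaction.
#' @export
ranked_rm_anova <- function(table, metrics = c("C1", "C2", "C3")) {
  sub <- table[table$metric %in% metrics, ]
  check_balanced(sub, metrics)
  sub$r <- rank(sub$median)
  sub$patient_id <- factor(sub$patient_id)
  sub$tissue <- factor(sub$tissue)
  sub$metric <- factor(sub$metric, levels = metrics)
  if (diff(range(sub$median)) == 0) {
    return(rbind(
      new_test_report("ranked_rm_anova", "tissue", NA_real_),
      new_test_report("ranked_rm_anova", "metric", NA_real_),
      new_test_report("ranked_rm_anova", "tissue:metric", NA_real_)))
  }
  fit <- stats::aov(r ~ tissue * metric +
                      Error(patient_id / (tissue * metric)), data = sub)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[paste0("Error: patient_id:", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    new_test_report("ranked_rm_anova", term,
                    statistic = tab[i, "F value"], df = tab[i, "Df"],
                    p_raw = tab[i, "Pr(>F)"])
  }
  rbind(grab("tissue", "tissue"), grab("metric", "metric"),
        grab("tissue:metric", "tissue:metric"))
}

check_balanced <- function(sub, metrics) {
  tab <- table(sub$patient_id, sub$tissue, sub$metric)
  if (any(tab != 1)) {
    miss <- which(tab != 1, arr.ind = TRUE)
    stop(sprintf("unbalanced cohort table; first problem cell: patient %s, tissue %s, metric %s",
                 dimnames(tab)[[1]][miss[1, 1]], dimnames(tab)[[2]][miss[1, 2]],
                 dimnames(tab)[[3]][miss[1, 3]]))
  }
  invisible(TRUE)
}

#' Marginal one-factor ranked repeated-measures analyses
#'
#' The per-metric tissue-effect analyses (ranked one-way repeated-measures
#' ANOVA of tissue within each metric) and the per-tissue component-effect
#' analyses (across C1, C2, C3 within each tissue), i.e. the marginal row and
#' column analyses accompanying the two-way model.
#'
#' @param table a [build_cohort_table()] data.frame.
#' @param metrics metrics analysed per-metric (default all six).
#' @return Report data.frame, one row per marginal analysis.
#' @export
marginal_ranked_anova <- function(table, metrics = rsi_metrics) {
  one_way <- function(df, factor_name) {
    df$r <- rank(df$median)
    df$patient_id <- factor(df$patient_id)
    df$f <- factor(df[[factor_name]])
    if (diff(range(df$median)) == 0)
      return(list(F = NA_real_, df = NA_real_, p = NA_real_))
    fit <- stats::aov(r ~ f + Error(patient_id / f), data = df)
    tab <- summary(fit)[["Error: patient_id:f"]][[1]]
    list(F = tab[1, "F value"], df = tab[1, "Df"], p = tab[1, "Pr(>F)"])
  }
  rows <- list()
  for (met in intersect(metrics, unique(table$metric))) {
    res <- one_way(table[table$metric == met, ], "tissue")
    rows[[length(rows) + 1]] <-
      new_test_report("ranked_rm_anova_marginal",
                      sprintf("tissue effect | %s", met),
                      res$F, df = res$df, p_raw = res$p)
  }
  comp <- table[table$metric %in% c("C1", "C2", "C3"), ]
  for (tt in unique(comp$tissue)) {
    res <- one_way(comp[comp$tissue == tt, ], "metric")
    rows[[length(rows) + 1]] <-
      new_test_report("ranked_rm_anova_marginal",
                      sprintf("component effect | %s", tt),
                      res$F, df = res$df, p_raw = res$p)
  }
  do.call(rbind, rows)
}

#' Full statistical battery on a cohort table
#'
#' Runs, in order: Shapiro-Wilk normality per tissue x metric cell, Levene's
#' test across tissues per metric, the ranked two-way repeated-measures ANOVA
#' over tissue x diffusion component, the marginal one-factor analyses, and
#' pairwise Wilcoxon signed-rank tests with Bonferroni correction (family 3)
#' for every metric.
#'
#' @param table a [build_cohort_table()] data.frame.
#' @param family Bonferroni family size for the pairwise stage.
#' @return List of class `cohort_stats` with components `normality`,
#'   `variance`, `anova`, `marginal` and `pairwise` (report data.frames).
#' @export
cohort_stats <- function(table, family = 3) {
  norm_rows <- list(); var_rows <- list()
  for (met in unique(table$metric)) {
    sub <- table[table$metric == met, ]
    for (tt in unique(sub$tissue)) {
      v <- sub$median[sub$tissue == tt]
      norm_rows[[length(norm_rows) + 1]] <-
        tryCatch(rsi_shapiro(v, sprintf("%s | %s", tt, met)),
                 error = function(e) new_test_report("shapiro_wilk",
                   sprintf("%s | %s", tt, met), NA_real_))
    }
    var_rows[[length(var_rows) + 1]] <-
      rsi_levene(split(sub$median, sub$tissue), label = met)
  }
  pw <- do.call(rbind, lapply(unique(table$metric), function(met)
    pairwise_wilcoxon_bonferroni(table, met, family = family)))
  structure(list(normality = do.call(rbind, norm_rows),
                 variance = do.call(rbind, var_rows),
                 anova = ranked_rm_anova(table),
                 marginal = marginal_ranked_anova(table),
                 pairwise = pw),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Ranked two-way repeated-measures ANOVA (tissue x component):\n")
  print(x$anova[, c("comparison", "statistic", "df", "p_raw")], row.names = FALSE)
  cat("\nPairwise Wilcoxon signed-rank (Bonferroni-adjusted):\n")
  print(x$pairwise[, c("comparison", "statistic", "p_raw", "p_adjusted")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
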