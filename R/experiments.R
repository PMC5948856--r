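#' Run a batch of replicate simulations
#'
#' Executes `n_reps` independent simulations of the same configuration and
#' strategy, replicate `i` using seed `base_seed + i`, and collects the final
#' metric record of each run. Identical `(config, strategy, base_seed)` give
#' identical batches.
#'
#' @param config A [sim_config()]; its `strategy` and `seed` fields are
#'   overridden per replicate.
#' @param strategy Strategy name (defaults to `config$strategy`).
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer; replicate `i` is seeded with `base_seed + i`.
#' @return A `pest_batch`: a data frame with one row per replicate and columns
#'   `strategy`, `replicate`, `seed`, `power`, `crop_health`, `alive_bugs`,
#'   `pesticide`.
#' @export
run_batch <- function(config, strategy = config$strategy, n_reps = 100L,
                      base_seed = config$seed) {
  stopifnot(n_reps >= 1L)
  seeds <- as.integer(base_seed) + seq_len(n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$strategy <- strategy
    cfg$seed <- seeds[i]
    fin <- run_simulation(cfg)$final
    rows[[i]] <- data.frame(
      strategy = strategy, replicate = i, seed = seeds[i],
      power = fin$avg_power, crop_health = fin$crop_health_pct,
      alive_bugs = fin$alive_bugs_pct, pesticide = fin$pesticide_per_station
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pest_batch", "data.frame")
  attr(out, "config") <- config
  out
}

batch_metrics <- function() c("power", "crop_health", "alive_bugs", "pesticide")

#' Per-metric mean and sample standard deviation of a batch
#'
#' @param batch A `pest_batch` (or any data frame with the four metric
#'   columns).
#' @return Data frame with columns `metric`, `mean`, `sd` (sample SD, `n - 1`
#'   denominator).
#' @export
summarize_batch <- function(batch) {
  if (nrow(batch) < 2L) {
    stop("summarize_batch: at least 2 replicates are needed for the SD",
         call. = FALSE)
  }
  mets <- batch_metrics()
  data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(batch[[m]]), 0),
    sd = vapply(mets, function(m) stats::sd(batch[[m]]), 0),
    row.names = NULL
  )
}

check_groups <- function(groups, min_n = 2L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- vapply(groups, length, 0L)
  if (any(n < min_n)) {
    stop("each group needs at least ", min_n, " observations", call. = FALSE)
  }
  invisible(n)
}

groups_to_long <- function(groups) {
  g <- factor(rep(seq_along(groups), lengths(groups)))
  list(x = unlist(groups, use.names = FALSE), g = g)
}

#' Levene's test of homogeneity of variances
#'
#' Classical Levene procedure: a one-way ANOVA F test on the absolute
#' deviations of each observation from its group centre (the group mean by
#' default; `center = "median"` gives the Brown-Forsythe variant of the
#' variance test).
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @param center `"mean"` (classical) or `"median"`.
#' @return List with `statistic`, `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(groups)
  cfun <- if (center == "mean") mean else stats::median
  devs <- lapply(groups, function(x) abs(x - cfun(x)))
  long <- groups_to_long(devs)
  if (all(long$x == 0)) {
    stop("levene_test: degenerate data (all observations equal their group center)",
         call. = FALSE)
  }
  tab <- stats::anova(stats::lm(long$x ~ long$g))
  list(statistic = tab[["F value"]][1L],
       df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
       p.value = tab[["Pr(>F)"]][1L])
}

#' Welch's heteroscedastic one-way test of equality of means
#'
#' Robust to unequal group variances; asymptotically F distributed. For two
#' groups the statistic equals the squared Welch t statistic and `df2` is the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2 with
#'   positive variance.
#' @return List with `statistic`, `df1`, `df2`, `p.value`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  v <- vapply(groups, stats::var, 0)
  if (any(v <= 0)) {
    stop("welch_anova: every group must have positive variance", call. = FALSE)
  }
  long <- groups_to_long(groups)
  ht <- stats::oneway.test(long$x ~ long$g, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df1 = unname(ht$parameter[["num df"]]),
       df2 = unname(ht$parameter[["denom df"]]),
       p.value = unname(ht$p.value))
}

#' Brown-Forsythe robust test of equality of means
#'
#' The variance-weighted F approximation: the between-group sum of squares is
#' divided by `sum((1 - n_i/N) * s_i^2)`, with Satterthwaite-type denominator
#' degrees of freedom. Robust to unequal variances; asymptotically F
#' distributed, and for equal group variances it approaches the classical
#' one-way F.
#'
#' @inheritParams welch_anova
#' @return List with `statistic`, `df1`, `df2`, `p.value`.
#' @export
brown_forsythe_anova <- function(groups) {
  n <- check_groups(groups)
  v <- vapply(groups, stats::var, 0)
  if (any(v <= 0)) {
    stop("brown_forsythe_anova: every group must have positive variance",
         call. = FALSE)
  }
  k <- length(groups)
  N <- sum(n)
  m <- vapply(groups, mean, 0)
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  wts <- (1 - n / N) * v
  den <- sum(wts)
  stat <- num / den
  ci <- wts / den
  df2 <- 1 / sum(ci^2 / (n - 1))
  list(statistic = stat, df1 = k - 1L, df2 = df2,
       p.value = stats::pf(stat, k - 1L, df2, lower.tail = FALSE))
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_p`, where `s_p` is the pooled standard deviation
#' with `(n - 1)` weights. Magnitudes above 1.3 are conventionally read as
#' "very large" (Rosenthal's interpretation).
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("cohens_d: each sample needs at least 2 observations", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("cohens_d: pooled SD is zero", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

sig_stars <- function(p) {
  ifelse(p <= 0.001, "**", ifelse(p <= 0.01, "*", ""))
}

#' Compare strategy batches
#'
#' Produces the full comparison report: per-strategy summary (mean and SD of
#' each final metric), Levene homogeneity tests, Welch and Brown-Forsythe
#' robust tests over all batches and over each requested pair, and mean
#' differences with Cohen's d effect sizes per pair. Significance stars follow
#' the convention `*` for p <= 0.01 and `**` for p <= 0.001.
#'
#' @param batches Named list of `pest_batch` objects (names are strategy
#'   labels).
#' @param pairs List of length-2 character vectors naming batch pairs for the
#'   two-group tests and effect sizes; effects are computed as
#'   `first - second`. Defaults to `list(c("lowcost_neighbor", "neighbor"))`
#'   when both are present, else all pairs.
#' @return A `pest_comparison`: list with data frames `summary`, `levene`,
#'   `robust` (all-group tests), `pairwise` and `effects`.
#' @export
compare_strategies <- function(batches, pairs = NULL) {
  stopifnot(is.list(batches), length(batches) >= 2L,
            !is.null(names(batches)), all(nzchar(names(batches))))
  mets <- batch_metrics()
  if (is.null(pairs)) {
    pairs <- if (all(c("lowcost_neighbor", "neighbor") %in% names(batches))) {
      list(c("lowcost_neighbor", "neighbor"))
    } else {
      utils::combn(names(batches), 2L, simplify = FALSE)
    }
  }

  summary_df <- do.call(rbind, lapply(names(batches), function(nm) {
    s <- summarize_batch(batches[[nm]])
    cbind(strategy = nm, s)
  }))

  test_table <- function(nms) {
    do.call(rbind, lapply(mets, function(m) {
      grps <- lapply(nms, function(nm) batches[[nm]][[m]])
      w <- welch_anova(grps)
      b <- brown_forsythe_anova(grps)
      data.frame(
        metric = m, test = c("welch", "brown_forsythe"),
        statistic = c(w$statistic, b$statistic),
        df1 = c(w$df1, b$df1), df2 = c(w$df2, b$df2),
        p.value = c(w$p.value, b$p.value),
        sig = sig_stars(c(w$p.value, b$p.value))
      )
    }))
  }

  levene_df <- do.call(rbind, lapply(mets, function(m) {
    grps <- lapply(batches, function(b) b[[m]])
    lv <- levene_test(grps)
    data.frame(metric = m, statistic = lv$statistic, df1 = lv$df1,
               df2 = lv$df2, p.value = lv$p.value, sig = sig_stars(lv$p.value))
  }))

  robust_df <- test_table(names(batches))

  pairwise_df <- do.call(rbind, lapply(pairs, function(pr) {
    cbind(comparison = paste(pr, collapse = " vs "), test_table(pr))
  }))

  effects_df <- do.call(rbind, lapply(pairs, function(pr) {
    a <- batches[[pr[1L]]]; b <- batches[[pr[2L]]]
    do.call(rbind, lapply(mets, function(m) {
      data.frame(comparison = paste(pr, collapse = " - "), metric = m,
                 mean_difference = mean(a[[m]]) - mean(b[[m]]),
                 cohens_d = cohens_d(a[[m]], b[[m]]))
    }))
  }))

  structure(list(summary = summary_df, levene = levene_df, robust = robust_df,
                 pairwise = pairwise_df, effects = effects_df),
            class = "pest_comparison")
}

#' @export
print.pest_comparison <- function(x, ...) {
  cat("<pest_comparison>\n\nPer-strategy final metrics (mean, SD):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("\nLevene homogeneity of variances:\n")
  print(x$levene, row.names = FALSE, digits = 4)
  cat("\nRobust tests of equality of means (all strategies):\n")
  print(x$robust, row.names = FALSE, digits = 4)
  cat("\nPairwise robust tests:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  cat("\nEffect sizes (mean difference, Cohen's d):\n")
  print(x$effects, row.names = FALSE, digits = 4)
  cat("\nSignificance: '*' p <= 0.01, '**' p <= 0.001\n")
  invisible(x)
}
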