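#' Monte-Carlo resampling tests
#'
#' Two one-tailed nonparametric engines used throughout the pipeline, plus
#' an exhaustive-enumeration oracle and a classical one-way ANOVA.
#'
#' @section Permutation test (independent samples):
#' For samples A and B with H0: mean(A) <= mean(B), the statistic is
#' v0 = mean(A) - mean(B).  Each resample pools A and B and randomly splits
#' the pool into two groups of the original sizes, recording the new mean
#' difference.  The resampled statistics are sorted ascending; `location` is
#' the rank of the first value strictly greater than v0 and the p-value is
#' p = 1 - location / n_resamples.  When no resampled value exceeds v0 the
#' rank is undefined and p is taken as its limit, 0 (a conservative
#' alternative floor of 1/(n+1) is available via `floor_p`).
#'
#' @section Paired bootstrap test:
#' For paired samples C and D with H0: mean(C) <= mean(D), the elementwise
#' differences P = C - D are resampled with replacement; each resample's
#' mean is recorded.  After ascending sort, `index` is the rank of the first
#' value strictly greater than zero and p' = index / n_resamples.  When all
#' resampled means exceed zero, index = 1 gives p' = 1/n naturally; when
#' none do, p' = 1.
#'
#' Ties are broken by strict comparison in both engines and in the oracle.
#' All randomness flows from the explicit `seed` argument (NULL = use the
#' caller's RNG stream); there is no hidden global state.
#'
#' @param sampA,sampB independent numeric samples.
#' @param n_resamples number of Monte-Carlo resamples (default 10000).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @param floor_p if TRUE, report 1/(n_resamples+1) instead of 0 when no
#'   resampled value exceeds the observed statistic.
#' @return an object of class `resampling_result`: list with `statistic`
#'   (v0 or the paired-mean analogue), `null_values` (ascending), `p_value`,
#'   `location_or_index`, `n_resamples`, `seed`, `method`.
#' @examples
#' permutation_test_independent(rnorm(10, 1), rnorm(10), seed = 1)
#' @export
permutation_test_independent <- function(sampA, sampB, n_resamples = 10000,
                                         seed = NULL, floor_p = FALSE) {
  if (!length(sampA) || !length(sampB)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nA <- length(sampA); nB <- length(sampB)
  v0 <- mean(sampA) - mean(sampB)
  pool <- c(sampA, sampB)
  n <- nA + nB
  total <- sum(pool)
  nulls <- with_seed(seed, {
    out <- numeric(n_resamples)
    for (k in seq_len(n_resamples)) {
      sa <- sum(pool[sample.int(n, nA)])
      out[k] <- sa / nA - (total - sa) / nB
    }
    out
  })
  finish_greater_rank(v0, nulls, n_resamples, seed, floor_p,
                      method = "permutation_independent")
}

# Shared tail bookkeeping: rank of first sorted null strictly above `v0`,
# p = 1 - location/n (0, or the optional floor, when none exceeds v0).
finish_greater_rank <- function(v0, nulls, n_resamples, seed, floor_p, method) {
  nulls <- sort(nulls)
  n_le <- sum(nulls <= v0)
  if (n_le == length(nulls)) {
    location <- NA_integer_
    p <- if (floor_p) 1 / (length(nulls) + 1) else 0
  } else {
    location <- n_le + 1L
    p <- 1 - location / length(nulls)
  }
  structure(list(statistic = v0, null_values = nulls, p_value = p,
                 location_or_index = location, n_resamples = length(nulls),
                 seed = seed, method = method),
            class = "resampling_result")
}

#' Exhaustive permutation oracle
#'
#' Enumerates every split of the pooled sample into groups of the original
#' sizes and reports p = #(splits with mean difference strictly greater
#' than v0) / #(splits) -- the same strict ordering as the Monte-Carlo
#' engine, so the two converge as `n_resamples` grows.
#'
#' @inheritParams permutation_test_independent
#' @return a `resampling_result` with `method = "exhaustive"`; its
#'   `null_values` hold every enumerated mean difference.
#' @export
permutation_test_exhaustive <- function(sampA, sampB) {
  if (!length(sampA) || !length(sampB)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nA <- length(sampA); nB <- length(sampB)
  if (choose(nA + nB, nA) > 1e6) {
    stop("choose(", nA + nB, ", ", nA, ") exceeds the enumeration bound 1e6",
         call. = FALSE)
  }
  v0 <- mean(sampA) - mean(sampB)
  pool <- c(sampA, sampB)
  total <- sum(pool)
  splits <- utils::combn(nA + nB, nA)
  diffs <- apply(splits, 2L, function(ia) {
    sa <- sum(pool[ia])
    sa / nA - (total - sa) / nB
  })
  diffs <- sort(diffs)
  p <- sum(diffs > v0) / length(diffs)
  structure(list(statistic = v0, null_values = diffs, p_value = p,
                 location_or_index = sum(diffs <= v0) + 1L,
                 n_resamples = length(diffs), seed = NULL,
                 method = "exhaustive"),
            class = "resampling_result")
}

#' Paired bootstrap test
#'
#' @param sampC,sampD paired numeric samples of equal length.
#' @inheritParams permutation_test_independent
#' @return a `resampling_result`; `location_or_index` holds the rank used.
#' @export
bootstrap_paired_test <- function(sampC, sampD, n_resamples = 10000,
                                  seed = NULL) {
  if (length(sampC) != length(sampD)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (!length(sampC)) stop("samples must be non-empty", call. = FALSE)
  p0 <- sampC - sampD
  n <- length(p0)
  nulls <- with_seed(seed, {
    draws <- matrix(p0[sample.int(n, n * n_resamples, replace = TRUE)],
                    nrow = n_resamples)
    rowMeans(draws)
  })
  nulls <- sort(nulls)
  n_le <- sum(nulls <= 0)
  if (n_le == length(nulls)) {
    index <- NA_integer_
    p <- 1
  } else {
    index <- n_le + 1L
    p <- index / length(nulls)
  }
  structure(list(statistic = mean(p0), null_values = nulls, p_value = p,
                 location_or_index = index, n_resamples = length(nulls),
                 seed = seed, method = "bootstrap_paired"),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("<resampling_result> method=", x$method,
      "  statistic=", signif(x$statistic, 5),
      "  p=", signif(x$p_value, 5),
      "  (", x$n_resamples, " resamples)\n", sep = "")
  invisible(x)
}

#' One-way ANOVA with Tukey pairwise comparisons
#'
#' Classical one-way F test on group means plus Tukey HSD pairwise
#' comparisons at level `alpha`.
#'
#' @param groups named (or unnamed) list of numeric vectors, one per group,
#'   each with at least 2 values.
#' @param alpha significance level for the pairwise flags.
#' @return list with `F`, `p`, `df`, and `pairwise` (data frame: pair,
#'   difference, adjusted p, significant flag).
#' @export
anova_one_way <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups)))
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairwise <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] <= alpha,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df = c(between = tab[["Df"]][1L], within = tab[["Df"]][2L]),
       pairwise = pairwise)
}

#' Type-I error calibration of the permutation engine
#'
#' Simulates pairs of standard-normal samples and reports the fraction of
#' simulations rejected at level `alpha` -- the package's statistical
#' self-test.
#'
#' @param n_sims number of simulated null datasets.
#' @param n per-group sample size.
#' @param alpha nominal level.
#' @param n_resamples Monte-Carlo resamples per test.
#' @param seed integer seed.
#' @return list with `rejection_rate`, `n_sims`, `alpha`.
#' @export
permutation_calibration <- function(n_sims = 1000, n = 19, alpha = 0.05,
                                    n_resamples = 1000, seed = 1L) {
  rej <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      a <- stats::rnorm(n); b <- stats::rnorm(n)
      permutation_test_independent(a, b, n_resamples = n_resamples,
                                   seed = NULL)$p_value <= alpha
    }, logical(1))
  })
  list(rejection_rate = mean(rej), n_sims = n_sims, alpha = alpha)
}
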