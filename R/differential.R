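# Moderated differential methylation
#
# Per-probe linear model on beta values with empirical-Bayes variance
# shrinkage: the per-probe residual variance s^2 (d residual df) is shrunk
# toward a prior s0^2 with d0 prior df,
#
#     s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d),
#
# where (d0, s0^2) are estimated from the marginal distribution of the s^2
# by the closed-form method of moments on log s^2 (digamma/trigamma
# inversion). Statistics are moderated t (two groups) or moderated F
# (>= 2 groups) on d + d0 denominator df, followed by Benjamini-Hochberg
# adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the step-up procedure (not a wrapper around
#' `p.adjust`): sorted p-values are scaled by m/rank, a running minimum is
#' taken from the largest down, values are capped at 1, and results are
#' returned in the input order. `NA`s are ignored (they do not count toward
#' m) and returned as `NA`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok], decreasing = TRUE)
  scaled <- p[ok][o] * m / (m:1)
  adj <- pmin(cummin(scaled), 1)
  out[ok][o] <- adj
  out
}

# Newton inversion of the trigamma function (used to solve for d0/2).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate the variance prior (d0, s0^2)
#'
#' Closed-form moment estimator on `log(s^2)`: with `e = log(s^2) -
#' digamma(d/2) + log(d/2)`, the mean and excess variance of `e` identify
#' `s0^2` and `d0`. Probes with zero residual variance are excluded from the
#' estimation (they cannot inform the prior) but still receive shrunken
#' variances downstream. When the observed spread of `e` does not exceed its
#' sampling variance, `d0 = Inf` and every probe collapses onto `s0^2`.
#'
#' @param s2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar or per-probe vector).
#' @return list with `d0` and `s0_2`.
#' @export
estimate_var_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2k <- s2[keep]; dk <- df[keep]
  if (length(s2k) < 2) stop("need >= 2 positive residual variances")
  z <- log(s2k)
  e <- z - digamma(dk / 2) + log(dk / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dk / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread no larger than sampling noise: variances are
    # exchangeable and fully pooled
    d0 <- Inf
    s0_2 <- mean(s2k)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated group comparison of methylation levels
#'
#' Fits per-probe group means, shrinks residual variances with
#' [estimate_var_prior()], and tests for group differences with a moderated
#' t (two groups, `statistic = "t"`) or moderated F (default, any number of
#' groups) on `d + d0` denominator degrees of freedom. Delta beta is the mean
#' difference, comparison minus reference, and is always computed on the
#' beta scale even when `transform = "mvalue"` runs the test on
#' logit2-transformed values.
#'
#' @param beta beta matrix (probes x samples).
#' @param groups named character vector or factor mapping each sample
#'   (column) to a group label, or a sample sheet data.frame.
#' @param comparison character vector of two group labels
#'   `c(reference, comparison)`, or `"all"` for an omnibus F across all
#'   groups present.
#' @param alpha significance level for the BH-adjusted flag (default 0.05).
#' @param statistic `"F"` (default, squared-t for two groups) or `"t"`.
#' @param d0 `"estimate"` (default), or a fixed prior df: `0` gives ordinary
#'   unmoderated statistics, `Inf` fully pools variances.
#' @param transform `"none"` (default: model beta values directly) or
#'   `"mvalue"` (logit2 with a 0.01 offset).
#' @return data.frame with one row per probe: group means, `delta_beta`,
#'   residual and shrunken variances, the moderated statistic, raw and
#'   BH-adjusted p-values, and the significance flag. Probes with all-missing
#'   rows are dropped and counted in the `"dropped_all_missing"` attribute;
#'   the moderation parameters sit in the `"moderation"` attribute.
#' @export
moderated_group_test <- function(beta, groups, comparison = "all",
                                 alpha = 0.05, statistic = c("F", "t"),
                                 d0 = "estimate",
                                 transform = c("none", "mvalue")) {
  statistic <- match.arg(statistic)
  transform <- match.arg(transform)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$sample_id)
  if (is.null(names(groups)))
    stop("groups must be named by sample id")
  groups <- groups[colnames(beta)]
  if (anyNA(groups)) stop("groups missing for some samples of beta")

  if (!identical(comparison, "all")) {
    if (length(comparison) != 2)
      stop("comparison must be 'all' or c(reference, comparison)")
    keep <- groups %in% comparison
    beta <- beta[, keep, drop = FALSE]
    groups <- factor(groups[keep], levels = comparison)
  } else {
    groups <- factor(groups)
  }
  tab <- table(groups)
  if (any(tab < 2))
    stop("group with < 2 samples: ", names(tab)[tab < 2][1])
  g <- nlevels(groups)
  if (statistic == "t" && g != 2)
    stop("moderated t requires exactly two groups")

  all_missing <- rowSums(!is.na(beta)) == 0
  dropped <- sum(all_missing)
  beta <- beta[!all_missing, , drop = FALSE]
  y <- if (transform == "mvalue") {
    b <- pmin(pmax(beta, 0.01), 0.99)
    log2(b / (1 - b))
  } else beta

  lv <- levels(groups)
  means_b <- means_y <- matrix(NA_real_, nrow(beta), g,
                               dimnames = list(rownames(beta), lv))
  counts <- matrix(0L, nrow(beta), g)
  rss <- numeric(nrow(beta))
  for (j in seq_len(g)) {
    cols <- which(groups == lv[j])
    sub <- y[, cols, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    mj <- rowMeans(sub, na.rm = TRUE)
    mj[nobs == 0] <- NA
    means_y[, j] <- mj
    counts[, j] <- nobs
    means_b[, j] <- {
      sb <- beta[, cols, drop = FALSE]
      mb <- rowMeans(sb, na.rm = TRUE)
      mb[rowSums(!is.na(sb)) == 0] <- NA
      mb
    }
    rss <- rss + rowSums((sub - mj)^2, na.rm = TRUE)
  }
  n_obs <- rowSums(counts)
  d <- n_obs - rowSums(counts > 0)
  s2 <- ifelse(d > 0, rss / d, NA_real_)

  if (identical(d0, "estimate")) {
    prior <- estimate_var_prior(s2, d)
  } else {
    stopifnot(is.numeric(d0), length(d0) == 1, d0 >= 0)
    prior <- list(d0 = d0,
                  s0_2 = if (d0 > 0) mean(s2[s2 > 0], na.rm = TRUE) else NA)
  }
  d0v <- prior$d0
  s0_2 <- prior$s0_2
  s2_tilde <- if (is.infinite(d0v)) rep(s0_2, length(s2)) else if (d0v > 0)
    (d0v * s0_2 + d * s2) / (d0v + d) else s2
  # total df never exceeds the pooled residual df of the whole matrix
  df_total <- pmin(d + d0v, sum(d))

  grand <- rowSums(means_y * counts, na.rm = TRUE) / n_obs
  ss_between <- rowSums(counts * (means_y - grand)^2, na.rm = TRUE)
  delta <- if (g == 2) means_b[, 2] - means_b[, 1] else NA_real_

  if (statistic == "t") {
    se2 <- s2_tilde * (1 / counts[, 1] + 1 / counts[, 2])
    stat <- (means_y[, 2] - means_y[, 1]) / sqrt(se2)
    p <- 2 * pt(-abs(stat), df_total)
    df1 <- NA_real_
  } else {
    df1 <- g - 1
    stat <- (ss_between / df1) / s2_tilde
    p <- pf(stat, df1, df_total, lower.tail = FALSE)
  }
  # zero-variance probes without a prior are indeterminate, not infinite
  indet <- s2_tilde == 0 | !is.finite(s2_tilde) | df_total <= 0
  stat[indet] <- NA_real_
  p[indet] <- NA_real_

  p_adj <- bh_adjust(p)
  res <- data.frame(probe_id = rownames(beta), means_b,
                    delta_beta = delta, sigma2 = s2, sigma2_tilde = s2_tilde,
                    statistic = stat, stat_type = statistic, df1 = df1,
                    df_total = df_total, p_value = p, p_adjusted = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(res)[2:(1 + g)] <- paste0("mean_", lv)
  attr(res, "moderation") <- list(d0 = d0v, s0_2 = s0_2,
                                  groups = lv, alpha = alpha)
  attr(res, "dropped_all_missing") <- dropped
  res
}
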