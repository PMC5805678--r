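#' @importFrom stats rnorm runif rbinom rnbinom var cor dist hclust cutree
#'   prcomp pt pf t.test setNames
#' @importFrom utils head tail packageVersion
NULL

# Clamp values into [lo, hi], counting how many were moved.
clamp01 <- function(x, lo = 0, hi = 1) {
  n_clamped <- sum(x < lo | x > hi, na.rm = TRUE)
  x[x < lo] <- lo
  x[x > hi] <- hi
  attr(x, "n_clamped") <- n_clamped
  x
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a root seed; kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(manifest = 11L, cohort = 23L, references = 37L, clock = 53L,
               variants = 71L, pipeline = 97L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare recovered subclass calls with a known partition.
#' 1 means identical partitions (up to label names), 0 is the expected
#' value for independent random labelings.
#'
#' @param a,b vectors of equal length giving the two labelings. `NA` pairs
#'   are dropped.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

# Mean silhouette width of a flat clustering, from a "dist" object.
mean_silhouette <- function(d, labels) {
  dm <- as.matrix(d)
  n <- length(labels)
  if (length(unique(labels)) < 2) return(0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a_i <- if (any(own)) mean(dm[i, own]) else 0
    b_i <- min(vapply(setdiff(unique(labels), labels[i]),
                      function(l) mean(dm[i, labels == l]), numeric(1)))
    s[i] <- if (max(a_i, b_i) > 0) (b_i - a_i) / max(a_i, b_i) else 0
  }
  mean(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
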