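# Methylation age: a pluggable linear clock on beta values with the
# piecewise log-linear age transform. Clock coefficients are never bundled
# with the package (published clocks carry their own provenance); the model
# is supplied as a clock file or built by the synthetic generator.

#' Piecewise log-linear age transform and its inverse
#'
#' Clock models are linear on a transformed age scale that is logarithmic
#' in childhood and linear in adulthood, continuous and differentiable at
#' the pivot `adult_age`:
#' `f(a) = log(a + 1) - log(adult_age + 1)` for `a <= adult_age`, and
#' `f(a) = (a - adult_age) / (adult_age + 1)` above it.
#'
#' @param age age in years; must be > -1.
#' @param adult_age pivot in years (default 20).
#' @return transformed score (`age_transform`) or years
#'   (`age_transform_inverse`).
#' @export
age_transform <- function(age, adult_age = 20) {
  if (any(age <= -1)) stop("age must be > -1")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @param score transformed score.
#' @export
age_transform_inverse <- function(score, adult_age = 20) {
  ifelse(score <= 0,
         (adult_age + 1) * exp(score) - 1,
         (adult_age + 1) * score + adult_age)
}

#' Predict methylation age
#'
#' Per sample, the linear score `intercept + sum(weight * beta)` over the
#' clock's probes is mapped back to years with [age_transform_inverse()].
#' Clock probes missing from the matrix are dropped from every sample (their
#' terms are omitted, which biases the score if many are absent — hence the
#' report); a sample with more than 20% missing clock-probe measurements is
#' flagged low-confidence.
#'
#' @param beta beta matrix.
#' @param clock a `clock_model` ([read_clock()], [generate_clock()]).
#' @return data.frame: `sample_id`, `score`, `predicted_age`,
#'   `n_missing_clock_probes`, `low_confidence`. The number of clock probes
#'   absent from the matrix altogether is in the `"missing_clock_probes"`
#'   attribute.
#' @export
predict_age <- function(beta, clock) {
  stopifnot(inherits(clock, "clock_model"))
  present <- intersect(names(clock$weights), rownames(beta))
  if (length(present) == 0)
    stop("none of the clock's probes are present in the beta matrix")
  absent <- setdiff(names(clock$weights), present)
  w <- clock$weights[present]
  sub <- beta[present, , drop = FALSE]
  n_clock <- length(clock$weights)
  score <- numeric(ncol(sub))
  n_missing <- integer(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    x <- sub[, j]
    obs <- !is.na(x)
    score[j] <- clock$intercept + sum(w[obs] * x[obs])
    n_missing[j] <- length(absent) + sum(!obs)
  }
  out <- data.frame(sample_id = colnames(sub), score = score,
                    predicted_age = age_transform_inverse(score,
                                                          clock$adult_age),
                    n_missing_clock_probes = n_missing,
                    low_confidence = n_missing / n_clock > 0.2,
                    stringsAsFactors = FALSE)
  attr(out, "missing_clock_probes") <- length(absent)
  out
}

#' Methylation-age gap by group
#'
#' Gap = predicted minus chronological age, so a negative gap means a
#' "younger" methylome than the patient. Samples without a chronological age
#' are excluded from group means and counted in the report.
#'
#' @param predicted result of [predict_age()].
#' @param samples sample sheet with `chronological_age`.
#' @return list with `per_sample` (sample_id, group, chronological age,
#'   predicted age, gap) and `per_group` (group, n, mean_gap,
#'   n_missing_age).
#' @export
age_gap <- function(predicted, samples) {
  df <- merge(predicted, samples[, c("sample_id", "group",
                                     "chronological_age")],
              by = "sample_id", sort = FALSE)
  df$gap <- df$predicted_age - df$chronological_age
  per_group <- do.call(rbind, lapply(split(df, df$group), function(d) {
    ok <- !is.na(d$gap)
    data.frame(group = d$group[1], n = sum(ok),
               mean_gap = if (any(ok)) mean(d$gap[ok]) else NA_real_,
               n_missing_age = sum(!ok), stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_sample = df[, c("sample_id", "group", "chronological_age",
                           "predicted_age", "gap")],
       per_group = per_group)
}
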