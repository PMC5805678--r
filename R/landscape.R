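# Cancer-methylome landscape statistics: substructure shifts and their
# hyper/hypo fractions, region-set (LAD) shifts, and the non-CpG channel.
#
# Sign convention everywhere: delta beta = mean(group_b) - mean(group_a),
# with group_a the reference (healthy). The across-probe t-tests treat
# probes as independent units; since neighbouring probes are correlated,
# the resulting p-values are descriptive summaries of effect consistency,
# not calibrated genome-wide inference.

group_mean_delta <- function(beta, samples, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (!any(samples$group == g)) stop("group not present: ", g)
  cols_a <- samples$sample_id[samples$group == group_a]
  cols_b <- samples$sample_id[samples$group == group_b]
  rowMeans(beta[, cols_b, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, cols_a, drop = FALSE], na.rm = TRUE)
}

one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(list(t = NA_real_, p = NA_real_))
  ht <- t.test(x)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Methylation shift per epigenomic substructure
#'
#' For each of island / shore / shelf / open sea, computes the per-probe
#' group-mean difference (`group_b - group_a`) over CpG-context probes and
#' summarizes it by its mean and a two-sided one-sample t-test against zero
#' across probes.
#'
#' @param beta beta matrix.
#' @param manifest probe manifest.
#' @param samples sample sheet.
#' @param group_a reference group (e.g. `"healthy"`).
#' @param group_b comparison group (e.g. `"AK"`).
#' @return data.frame with one row per substructure: `n_probes`,
#'   `mean_delta`, `t_stat`, `p_value`. Empty classes are reported with
#'   `n_probes = 0` and `NA` statistics. The per-probe delta vectors are in
#'   the `"delta_by_class"` attribute.
#' @export
substructure_shift <- function(beta, manifest, samples, group_a, group_b) {
  m <- manifest[match(rownames(beta), manifest$probe_id), ]
  delta <- group_mean_delta(beta, samples, group_a, group_b)
  res <- vector("list", length(SUBSTRUCTURES))
  deltas <- list()
  for (i in seq_along(SUBSTRUCTURES)) {
    cls <- SUBSTRUCTURES[i]
    sel <- !is.na(m$substructure) & m$substructure == cls &
      m$context == "CpG"
    dx <- delta[sel]
    deltas[[cls]] <- dx
    ht <- one_sample_t(dx)
    res[[i]] <- data.frame(substructure = cls, n_probes = sum(sel),
                           mean_delta = if (sum(sel)) mean(dx, na.rm = TRUE)
                                        else NA_real_,
                           t_stat = ht$t, p_value = ht$p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "delta_by_class") <- deltas
  attr(out, "comparison") <- c(reference = group_a, comparison = group_b)
  out
}

#' Fractions of hyper-/hypo-methylated probes per substructure
#'
#' Classifies each CpG probe of a differential result as hypermethylated
#' (significant with `delta_beta > 0`), hypomethylated (significant with
#' `delta_beta < 0`) or unchanged (everything else; a significant probe with
#' `delta_beta` exactly 0 counts as unchanged). Fractions sum to 1 within
#' each substructure.
#'
#' @param diff a [moderated_group_test()] result (two-group).
#' @param manifest probe manifest.
#' @return data.frame: substructure, `n_probes`, `frac_hyper`, `frac_hypo`,
#'   `frac_unchanged`.
#' @export
shift_fractions <- function(diff, manifest) {
  m <- manifest[match(diff$probe_id, manifest$probe_id), ]
  cpg <- m$context == "CpG"
  hyper <- diff$significant & !is.na(diff$delta_beta) & diff$delta_beta > 0
  hypo <- diff$significant & !is.na(diff$delta_beta) & diff$delta_beta < 0
  res <- lapply(SUBSTRUCTURES, function(cls) {
    sel <- cpg & m$substructure == cls
    n <- sum(sel)
    data.frame(substructure = cls, n_probes = n,
               frac_hyper = if (n) sum(hyper[sel]) / n else NA_real_,
               frac_hypo = if (n) sum(hypo[sel]) / n else NA_real_,
               frac_unchanged = if (n) 1 - (sum(hyper[sel]) +
                                              sum(hypo[sel])) / n
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Methylation shift over a region set
#'
#' Mean group difference over all probes that fall in any interval of the
#' region set (LADs, typically), with a two-sided one-sample t-test across
#' member probes. Membership uses [probes_in_regions()].
#'
#' @inheritParams substructure_shift
#' @param regions region set from [read_regions_bed()].
#' @return one-row data.frame: `region_set`, `n_probes`, `mean_delta`,
#'   `t_stat`, `p_value`; per-probe deltas in the `"delta"` attribute.
#' @export
region_shift <- function(beta, manifest, regions, samples,
                         group_a, group_b) {
  members <- unique(unlist(probes_in_regions(manifest, regions)))
  members <- intersect(members, rownames(beta))
  if (length(members) == 0)
    stop("region set '", attr(regions, "name") %||% "?",
         "' covers no probes of the beta matrix")
  delta <- group_mean_delta(beta[members, , drop = FALSE], samples,
                            group_a, group_b)
  ht <- one_sample_t(delta)
  out <- data.frame(region_set = attr(regions, "name") %||% NA_character_,
                    n_probes = length(members),
                    mean_delta = mean(delta, na.rm = TRUE),
                    t_stat = ht$t, p_value = ht$p, stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  out
}

#' Differential non-CpG (CH) methylation
#'
#' Runs the moderated group test restricted to CH-context probes, returning
#' both the significant CH probe list and per-sample average beta over that
#' list (box-plot-style summary of the non-CpG methylation gain).
#'
#' @inheritParams substructure_shift
#' @param alpha BH significance level (default 0.05).
#' @param ... passed on to [moderated_group_test()].
#' @return list with `result` (the differential table), `significant_probes`,
#'   and `sample_means` (named per-sample mean beta over the significant CH
#'   probes; `NA`s if none are significant).
#' @export
noncpg_analysis <- function(beta, manifest, samples, group_a, group_b,
                            alpha = 0.05, ...) {
  m <- manifest[match(rownames(beta), manifest$probe_id), ]
  ch <- rownames(beta)[m$context == "CH"]
  if (length(ch) == 0) stop("no CH probes in the supplied manifest/matrix")
  sub <- beta[ch, , drop = FALSE]
  keep <- samples$group %in% c(group_a, group_b)
  res <- moderated_group_test(sub[, samples$sample_id[keep], drop = FALSE],
                              samples[keep, ],
                              comparison = c(group_a, group_b),
                              alpha = alpha, ...)
  sig <- res$probe_id[res$significant]
  sm <- if (length(sig))
    colMeans(sub[sig, samples$sample_id[keep], drop = FALSE], na.rm = TRUE)
  else setNames(rep(NA_real_, sum(keep)), samples$sample_id[keep])
  list(result = res, significant_probes = sig, sample_means = sm)
}
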