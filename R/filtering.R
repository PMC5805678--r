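#' Probe-level quality filtering
#'
#' Removes probes that are unreliable or confounded before any analysis:
#' probes whose detection p-value exceeds `p_threshold` in *any* sample (the
#' strictest reading; only applied when a detection table is supplied),
#' probes on sex chromosomes, SNP-affected probes, and self-hybridizing
#' probes. Rules are applied and attributed in that fixed order, so a probe
#' failing several rules is counted once, under the first.
#'
#' Array normalization is out of scope: inputs are assumed normalized, and
#' this function marks the position in the pipeline where a normalization
#' stage would sit.
#'
#' @param beta beta matrix (probes x samples).
#' @param manifest probe manifest covering all rows of `beta`.
#' @param detection_p optional matrix of per-probe per-sample detection
#'   p-values with the same dimnames as `beta`.
#' @param p_threshold detection p-value cutoff; probes with `p > threshold`
#'   anywhere are removed (default 0.01).
#' @return the filtered beta matrix, with an `"exclusion_report"` attribute:
#'   a data.frame of per-rule removal counts (first-rule attribution) plus
#'   the retained count.
#' @export
filter_probes <- function(beta, manifest, detection_p = NULL,
                          p_threshold = 0.01) {
  probes <- rownames(beta)
  missing_m <- setdiff(probes, manifest$probe_id)
  if (length(missing_m))
    stop("manifest does not cover probe(s): ", missing_m[1])
  m <- manifest[match(probes, manifest$probe_id), ]

  rule <- rep(NA_character_, length(probes))
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)) ||
        !identical(colnames(detection_p), colnames(beta)) ||
        !identical(rownames(detection_p), rownames(beta)))
      stop("detection_p must match the beta matrix's probes and samples")
    fail <- apply(detection_p > p_threshold, 1, any, na.rm = TRUE)
    rule[fail] <- "detection"
  }
  hit <- function(flag, name) {
    sel <- is.na(rule) & flag
    rule[sel] <<- name
  }
  hit(m$sex, "sex_chromosome")
  hit(m$snp, "snp_affected")
  hit(m$selfhyb, "self_hybridizing")

  keep <- is.na(rule)
  report <- data.frame(
    rule = c("detection", "sex_chromosome", "snp_affected",
             "self_hybridizing", "retained"),
    n = c(sum(rule == "detection", na.rm = TRUE),
          sum(rule == "sex_chromosome", na.rm = TRUE),
          sum(rule == "snp_affected", na.rm = TRUE),
          sum(rule == "self_hybridizing", na.rm = TRUE),
          sum(keep)),
    stringsAsFactors = FALSE)
  out <- beta[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  attr(out, "dropped_probes") <- NULL
  out
}
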