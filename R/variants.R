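# Whole-exome artifact filtering: the confidence score and the
# population-frequency exclusion cascade.

OVERLAP_FLAGS <- c("repeats", "duke_excluded", "dac_blacklist",
                   "self_chain", "segmental_duplication")

#' Confidence score of annotated variants
#'
#' Every variant starts at 10. One deduction (default 1 point, configurable)
#' is taken per overlapping artifact category — repeats, DUKE-excluded
#' regions, DAC-blacklisted regions, self-chain regions, segmental
#' duplication records (`merge_repeat_duke = TRUE` collapses the first two
#' into one category) — and, for indels only, one further deduction per set
#' Platypus filter among alleleBias, badReads, MQ, SC, GOF, QD, strandBias.
#' The score never exceeds 10; at deduction 1 its minimum is
#' `10 - (5 + 7) = -2`.
#'
#' @param variants variant table ([read_variants()] layout). Missing (NA)
#'   overlap flags are an error, never assumed `FALSE`.
#' @param deduction points deducted per category (non-negative integer,
#'   default 1).
#' @param merge_repeat_duke treat repeats + DUKE-excluded as a single
#'   category.
#' @return integer vector of scores, one per variant.
#' @export
confidence_score <- function(variants, deduction = 1L,
                             merge_repeat_duke = FALSE) {
  if (deduction < 0) stop("deduction must be non-negative")
  validate_variants(variants)
  flags <- as.matrix(variants[, OVERLAP_FLAGS])
  if (anyNA(flags))
    stop("missing overlap flag(s); annotate fully before scoring")
  if (merge_repeat_duke) {
    merged <- flags[, "repeats"] | flags[, "duke_excluded"]
    flags <- cbind(merged, flags[, c("dac_blacklist", "self_chain",
                                     "segmental_duplication"), drop = FALSE])
  }
  n_overlap <- rowSums(flags)
  n_platypus <- ifelse(
    variants$kind == "indel",
    lengths(lapply(strsplit(variants$platypus_filters, ","),
                   function(x) x[nzchar(x)])),
    0L)
  as.integer(10 - deduction * (n_overlap + n_platypus))
}

#' Filter a variant table
#'
#' Applies the exclusion cascade in a fixed, documented order, attributing
#' each excluded variant to the first rule it fails:
#' confidence score `< min_score` (strict) -> sequencing depth outside
#' `depth_bounds` or improperly mapped reads -> dbSNP-common (unless rescued
#' by an OMIM record) -> ExAC frequency `> exac_max` -> EVS frequency
#' `> evs_max` -> in-house frequency `> inhouse_max` -> non-coding. Any rule
#' can be disabled by passing `NULL`; with everything disabled the input
#' passes through unchanged.
#'
#' @param variants variant table.
#' @param min_score retention requires `score >= min_score` (default 8, the
#'   printed `< 8` exclusion). `NULL` disables.
#' @param depth_bounds length-2 numeric `c(low, high)`; depth must satisfy
#'   `low <= depth <= high`. No default — bounds are study-specific and must
#'   be chosen explicitly. `NULL` disables.
#' @param exac_max,evs_max,inhouse_max population-frequency ceilings
#'   (strict `>` excludes); defaults 0.001, 0.01, 0.02. `NULL` disables.
#' @param exclude_dbsnp_common drop dbSNP-common variants lacking an OMIM
#'   record (default `TRUE`).
#' @param coding_only keep coding variants only (default `TRUE`).
#' @param require_properly_mapped couple the mapping flag to the depth rule
#'   (default `TRUE` when `depth_bounds` given, else unused unless set).
#' @param deduction,merge_repeat_duke passed to [confidence_score()].
#' @return list with `retained`, `excluded` (with an `excluded_by` column)
#'   and `report` (first-rule exclusion counts). Both tables carry a
#'   `confidence_score` column.
#' @export
filter_variants <- function(variants, min_score = 8, depth_bounds = NULL,
                            exac_max = 0.001, evs_max = 0.01,
                            inhouse_max = 0.02,
                            exclude_dbsnp_common = TRUE, coding_only = TRUE,
                            require_properly_mapped = !is.null(depth_bounds),
                            deduction = 1L, merge_repeat_duke = FALSE) {
  validate_variants(variants)
  v <- variants
  v$confidence_score <- confidence_score(v, deduction = deduction,
                                         merge_repeat_duke =
                                           merge_repeat_duke)
  rule <- rep(NA_character_, nrow(v))
  hit <- function(fail, name) {
    sel <- is.na(rule) & fail
    rule[sel] <<- name
  }
  if (!is.null(min_score))
    hit(v$confidence_score < min_score, "low_confidence_score")
  if (!is.null(depth_bounds)) {
    stopifnot(length(depth_bounds) == 2, depth_bounds[1] <= depth_bounds[2])
    hit(v$depth < depth_bounds[1] | v$depth > depth_bounds[2], "depth")
  }
  if (isTRUE(require_properly_mapped))
    hit(!v$properly_mapped, "improper_mapping")
  if (isTRUE(exclude_dbsnp_common)) {
    if (anyNA(v$dbsnp_common) || anyNA(v$omim_record))
      stop("missing dbsnp_common/omim_record annotation")
    hit(v$dbsnp_common & !v$omim_record, "dbsnp_common")
  }
  pop_rule <- function(col, max, name) {
    if (is.null(max)) return(invisible())
    if (anyNA(v[[col]])) stop("missing ", col, " annotation")
    hit(v[[col]] > max, name)
  }
  pop_rule("exac_af", exac_max, "exac_frequency")
  pop_rule("evs_af", evs_max, "evs_frequency")
  pop_rule("inhouse_af", inhouse_max, "inhouse_frequency")
  if (isTRUE(coding_only)) hit(!v$coding, "noncoding")

  keep <- is.na(rule)
  excluded <- v[!keep, , drop = FALSE]
  excluded$excluded_by <- rule[!keep]
  rules <- c("low_confidence_score", "depth", "improper_mapping",
             "dbsnp_common", "exac_frequency", "evs_frequency",
             "inhouse_frequency", "noncoding")
  report <- data.frame(rule = c(rules, "retained"),
                       n = c(vapply(rules, function(r)
                         sum(rule == r, na.rm = TRUE), integer(1)),
                         sum(keep)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(retained = v[keep, , drop = FALSE], excluded = excluded,
       report = report)
}
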