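#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom data.table fread fwrite data.table as.data.table setDF
NULL

MANIFEST_COLS <- c("probe_id", "chrom", "pos", "context", "substructure",
                   "genes", "gene_region", "sex", "snp", "selfhyb")
SUBSTRUCTURES <- c("island", "shore", "shelf", "open_sea")
SAMPLE_GROUPS <- c("healthy", "AK", "cSCC", "reference_ESC",
                   "reference_keratinocyte", "reference_EpSC",
                   "reference_diffKC", "pan_cancer")
SUBCLASSES <- c("EpSC_like", "keratinocyte_like")

# Normalize chromosome names to the "chr"-prefixed dialect.
# A mix of prefixed and bare names is an error, never silently patched.
normalize_chroms <- function(x, what = "input") {
  x <- as.character(x)
  pref <- grepl("^chr", x)
  if (all(pref)) return(x)
  if (!any(pref)) return(paste0("chr", x))
  stop("mixed chromosome naming dialects in ", what,
       " ('chr1' and '1' style); normalize upstream", call. = FALSE)
}

validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  missing_cols <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("duplicate probe_id in manifest")
  if (!all(manifest$context %in% c("CpG", "CH")))
    stop("manifest context must be 'CpG' or 'CH'")
  if (!all(manifest$substructure %in% SUBSTRUCTURES))
    stop("manifest substructure must be one of: ",
         paste(SUBSTRUCTURES, collapse = ", "))
  if (any(manifest$pos < 1)) stop("manifest positions are 1-based (>= 1)")
  invisible(manifest)
}

#' Read a probe manifest table
#'
#' The manifest carries per-probe genomic and functional metadata: 1-based
#' position, cytosine context (`CpG` or `CH`), epigenomic substructure
#' (`island`, `shore`, `shelf`, `open_sea`), comma-separated gene symbols with
#' matching `gene_region` labels (`promoter`/`body`/`other`), and the three
#' quality flags used by [filter_probes()] (`sex`, `snp`, `selfhyb`).
#' Chromosome names are normalized to the `chr` prefix on load; mixing
#' dialects within one file is an error.
#'
#' @param path tab-separated file with columns
#'   `probe_id, chrom, pos, context, substructure, genes, gene_region, sex,
#'   snp, selfhyb`.
#' @return a `data.frame`, one row per probe.
#' @export
read_manifest <- function(path) {
  m <- setDF(fread(path, sep = "\t", header = TRUE,
                   colClasses = list(character = c("probe_id", "chrom",
                                                   "genes", "gene_region")),
                   na.strings = "NA"))
  m$chrom <- normalize_chroms(m$chrom, what = path)
  m$pos <- as.integer(m$pos)
  for (fl in c("sex", "snp", "selfhyb")) m[[fl]] <- as.logical(m[[fl]])
  m$genes[is.na(m$genes)] <- ""
  m$gene_region[is.na(m$gene_region)] <- ""
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  fwrite(manifest[, MANIFEST_COLS], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a beta-value matrix
#'
#' Beta values are per-probe, per-sample methylation fractions in \[0, 1\];
#' missing measurements are encoded as `NA`. Probes absent from the supplied
#' manifest are dropped with a message, and the number dropped is recorded in
#' the `"dropped_probes"` attribute.
#'
#' @param path tab-separated table; first column `probe_id`, remaining columns
#'   one per sample, header row holds sample ids.
#' @param manifest probe manifest as returned by [read_manifest()]; used to
#'   restrict the matrix to known probes.
#' @return numeric matrix (probes x samples) with `dimnames`, values in
#'   \[0, 1\] or `NA`.
#' @export
read_beta_matrix <- function(path, manifest = NULL) {
  raw <- setDF(fread(path, sep = "\t", header = TRUE, colClasses = "character",
                     na.strings = "NA"))
  if (ncol(raw) < 2) stop("beta matrix needs a probe_id column plus samples")
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe_id in beta matrix: ",
         probe_ids[duplicated(probe_ids)][1])
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header")
  vals <- matrix(NA_real_, nrow = length(probe_ids), ncol = length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col_chr <- raw[[j + 1]]
    suppressWarnings(col_num <- as.numeric(col_chr))
    bad <- which(!is.na(col_chr) & is.na(col_num))
    if (length(bad))
      stop(sprintf("malformed numeric cell at probe '%s', sample '%s': '%s'",
                   probe_ids[bad[1]], sample_ids[j], col_chr[bad[1]]))
    out <- which(!is.na(col_num) & (col_num < 0 | col_num > 1))
    if (length(out))
      stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %s",
                   probe_ids[out[1]], sample_ids[j], col_chr[out[1]]))
    vals[, j] <- col_num
  }
  dropped <- 0L
  if (!is.null(manifest)) {
    keep <- probe_ids %in% manifest$probe_id
    dropped <- sum(!keep)
    if (dropped > 0)
      message(dropped, " probe(s) absent from manifest dropped from beta matrix")
    vals <- vals[keep, , drop = FALSE]
  }
  attr(vals, "dropped_probes") <- dropped
  vals
}

#' @rdname read_beta_matrix
#' @param beta numeric matrix with probe rownames and sample colnames.
#' @details `write_beta_matrix()` prints 17 significant digits so that a
#'   write/read round trip reproduces every double bit-exactly.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  out <- data.table(probe_id = rownames(beta))
  for (s in colnames(beta)) {
    v <- beta[, s]
    out[[s]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Columns: `sample_id`, `group` (one of healthy, AK, cSCC, the four
#' `reference_*` groups, or `pan_cancer`), optional `chronological_age` in
#' years, and optional `latent_subclass` — the synthetic generator's ground
#' truth, present only for simulated AK/cSCC samples and never consumed by
#' any analysis routine.
#'
#' @param path tab-separated sample sheet.
#' @return `data.frame` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  s <- setDF(fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                   colClasses = list(character = "sample_id")))
  validate_sample_sheet(s)
  s
}

validate_sample_sheet <- function(s) {
  stopifnot(all(c("sample_id", "group") %in% names(s)))
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(s$group), SAMPLE_GROUPS)
  if (length(bad)) stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  if (!"chronological_age" %in% names(s)) s$chronological_age <- NA_real_
  if (!"latent_subclass" %in% names(s)) s$latent_subclass <- NA_character_
  ok <- is.na(s$latent_subclass) | s$latent_subclass %in% SUBCLASSES
  if (!all(ok)) stop("latent_subclass must be EpSC_like/keratinocyte_like/NA")
  invisible(s)
}

#' @rdname read_sample_sheet
#' @param samples sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_sample_sheet(samples)
  cols <- intersect(c("sample_id", "group", "chronological_age",
                      "latent_subclass"), names(samples))
  fwrite(samples[, cols], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a BED interval file into a region set
#'
#' Intervals are kept verbatim in BED's native 0-based half-open convention;
#' overlapping intervals are never merged. The fourth column, when present,
#' provides `region_id`; otherwise ids are generated as `chrom:start-end`.
#'
#' @param path BED3/BED4 file (no header). An empty file yields a region set
#'   with zero intervals.
#' @param name label for the set (e.g. `"LAD"`, `"ESC_enhancer"`).
#' @return `data.frame` with columns `chrom, start, end, region_id` and
#'   attributes `name` and (optionally) `gene_map`.
#' @export
read_regions_bed <- function(path, name) {
  if (file.size(path) == 0) {
    r <- data.frame(chrom = character(), start = integer(), end = integer(),
                    region_id = character(), stringsAsFactors = FALSE)
    attr(r, "name") <- name
    return(r)
  }
  # hand-rolled line parse: BED rows may mix 3 and 4 columns
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) > 0]
  if (any(lengths(fields) < 3)) stop("BED file needs at least 3 columns")
  out <- data.frame(
    chrom = normalize_chroms(vapply(fields, `[`, "", 1), what = path),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
    stringsAsFactors = FALSE)
  r <- data.frame(V4 = vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, ""),
    stringsAsFactors = FALSE)
  if (all(is.na(r$V4))) r$V4 <- NULL
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("non-integer BED coordinates in ", path)
  if (any(out$start >= out$end))
    stop("BED interval with start >= end at line ",
         which(out$start >= out$end)[1])
  auto_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out$region_id <- if (!is.null(r$V4)) {
    ifelse(is.na(r$V4) | !nzchar(r$V4), auto_id, r$V4)
  } else auto_id
  if (anyDuplicated(out$region_id)) stop("duplicate region_id in ", path)
  attr(out, "name") <- name
  out
}

#' @rdname read_regions_bed
#' @param regions region set `data.frame`.
#' @export
write_regions_bed <- function(regions, path) {
  fwrite(regions[, c("chrom", "start", "end", "region_id")], path,
         sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve probe membership in a region set
#'
#' Manifest positions are 1-based cytosine sites; regions are 0-based
#' half-open. A probe at 1-based position `p` belongs to `(start, end)` iff
#' `start < p <= end` — equivalently its 0-based coordinate `p - 1` lies in
#' `[start, end)`. This function is the package's single coordinate-convention
#' conversion point.
#'
#' @param manifest probe manifest.
#' @param regions region set from [read_regions_bed()].
#' @return named list mapping `region_id` to a character vector of probe ids
#'   (possibly empty); the ids of probe-free regions are repeated in the
#'   `"empty_regions"` attribute.
#' @export
probes_in_regions <- function(manifest, regions) {
  chroms <- c(unique(manifest$chrom), unique(regions$chrom))
  pref <- grepl("^chr", chroms)
  if (any(pref) && !all(pref))
    stop("chromosome naming mismatch between manifest and regions ",
         "('chr1' vs '1'); refusing a silent empty join")
  out <- setNames(vector("list", nrow(regions)), regions$region_id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(regions) > 0 && nrow(manifest) > 0) {
    probe_gr <- GenomicRanges::GRanges(manifest$chrom,
                                       IRanges(manifest$pos, manifest$pos))
    region_gr <- GenomicRanges::GRanges(regions$chrom,
                                        IRanges(regions$start + 1L,
                                                regions$end))
    # disjoint chromosome sets between manifest and regions are legitimate
    # (e.g. a LAD set restricted to one chromosome); silence the seqlevel
    # chatter, the dialect check above already caught real mismatches
    hits <- suppressWarnings(GenomicRanges::findOverlaps(probe_gr,
                                                         region_gr))
    if (length(hits)) {
      sp <- split(manifest$probe_id[S4Vectors::queryHits(hits)],
                  regions$region_id[S4Vectors::subjectHits(hits)])
      out[names(sp)] <- sp
    }
  }
  attr(out, "empty_regions") <- names(out)[lengths(out) == 0]
  out
}

#' Read / write a methylation clock model
#'
#' The file format is two comment-style header lines `#intercept<TAB>x` and
#' `#adult_age<TAB>y`, followed by a `probe_id<TAB>weight` table.
#'
#' @param path clock TSV.
#' @return list with `intercept`, `adult_age` and a named numeric `weights`
#'   vector, class `"clock_model"`.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), hdr, value = TRUE)
    if (length(ln) != 1) stop("clock file missing #", key, " header")
    as.numeric(strsplit(ln, "\t")[[1]][2])
  }
  intercept <- get_hdr("intercept")
  adult_age <- get_hdr("adult_age")
  tab <- fread(text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE)
  w <- setNames(as.numeric(tab$weight), tab$probe_id)
  clock_model(intercept, w, adult_age)
}

#' @rdname read_clock
#' @param intercept linear-model intercept on the transformed-age scale.
#' @param weights named numeric vector of per-probe weights.
#' @param adult_age pivot (years) of the piecewise age transform; must be > 0.
#' @export
clock_model <- function(intercept, weights, adult_age = 20) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(weights), !is.null(names(weights)), adult_age > 0)
  structure(list(intercept = intercept, weights = weights,
                 adult_age = adult_age), class = "clock_model")
}

#' @rdname read_clock
#' @param clock a `clock_model`.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#intercept\t%.17g", clock$intercept),
               sprintf("#adult_age\t%.17g", clock$adult_age),
               "probe_id\tweight",
               sprintf("%s\t%.17g", names(clock$weights), clock$weights)),
             con)
  invisible(path)
}

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "kind", "repeats",
                  "duke_excluded", "dac_blacklist", "self_chain",
                  "segmental_duplication", "platypus_filters", "depth",
                  "properly_mapped", "dbsnp_common", "omim_record",
                  "exac_af", "evs_af", "inhouse_af", "coding")
PLATYPUS_FLAGS <- c("alleleBias", "badReads", "MQ", "SC", "GOF", "QD",
                    "strandBias")

validate_variants <- function(v) {
  missing_cols <- setdiff(VARIANT_COLS, names(v))
  if (length(missing_cols))
    stop("variant table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(v$kind %in% c("SNV", "indel"))) stop("kind must be SNV or indel")
  for (col in c("exac_af", "evs_af", "inhouse_af")) {
    x <- v[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      stop(col, " must lie in [0,1]")
  }
  flags <- setdiff(unlist(strsplit(v$platypus_filters[
    !is.na(v$platypus_filters) & nzchar(v$platypus_filters)], ",")),
    PLATYPUS_FLAGS)
  if (length(flags))
    stop("unknown Platypus filter(s): ", paste(unique(flags), collapse = ", "))
  invisible(v)
}

#' Read / write an annotated variant table
#'
#' A deliberately simple TSV stand-in for a fully annotated VCF: one row per
#' somatic call with blacklist-overlap booleans, Platypus filter flags
#' (comma-separated), depth, mapping status and population-frequency
#' annotations — everything [confidence_score()] and [filter_variants()]
#' consume.
#'
#' @param path variant TSV.
#' @return `data.frame` with the columns listed in the details.
#' @export
read_variants <- function(path) {
  v <- setDF(fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                   colClasses = list(character = c("chrom", "ref", "alt",
                                                   "kind",
                                                   "platypus_filters"))))
  v$platypus_filters[is.na(v$platypus_filters)] <- ""
  validate_variants(v)
  v
}

#' @rdname read_variants
#' @param variants variant `data.frame`.
#' @export
write_variants <- function(variants, path) {
  cols <- intersect(c(VARIANT_COLS, "confidence_score"), names(variants))
  fwrite(variants[, cols], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# Expand the comma-separated genes/gene_region manifest columns into a long
# probe-gene table. A probe linked to several genes yields several rows.
probe_gene_map <- function(manifest) {
  has <- nzchar(manifest$genes)
  if (!any(has))
    return(data.frame(probe_id = character(), gene = character(),
                      gene_region = character(), stringsAsFactors = FALSE))
  genes <- strsplit(manifest$genes[has], ",")
  regs <- strsplit(manifest$gene_region[has], ",")
  n <- lengths(genes)
  bad <- lengths(regs) != n
  if (any(bad)) stop("genes/gene_region length mismatch for probe ",
                     manifest$probe_id[has][bad][1])
  data.frame(probe_id = rep(manifest$probe_id[has], n),
             gene = unlist(genes), gene_region = unlist(regs),
             stringsAsFactors = FALSE)
}
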