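# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (brute force / closed form) and never call
# the package code paths they are used to check.

# O(n*m) interval membership scan: probe (1-based) p in region iff
# start < p <= end.
brute_force_membership <- function(manifest, regions) {
  out <- setNames(vector("list", nrow(regions)), regions$region_id)
  for (i in seq_len(nrow(regions))) {
    hits <- character(0)
    for (j in seq_len(nrow(manifest))) {
      if (manifest$chrom[j] == regions$chrom[i] &&
          manifest$pos[j] > regions$start[i] &&
          manifest$pos[j] <= regions$end[i])
        hits <- c(hits, manifest$probe_id[j])
    }
    out[[i]] <- hits
  }
  out
}

# Definitionally independent BH step-up: for each p_i, the minimum over all
# p_j >= p_i of min(1, m * p_j / rank_j).
brute_force_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Naive O(n^3) agglomerative clustering over a distance matrix, average or
# complete linkage, recomputing all inter-cluster distances from scratch at
# every step. Returns the sequence of merge heights.
naive_agglomeration_heights <- function(dmat, linkage = "average") {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  link <- function(a, b) {
    d <- dmat[a, b, drop = FALSE]
    if (linkage == "average") mean(d) else max(d)
  }
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- link(clusters[[i]], clusters[[j]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Tiny hand-built manifest: probes laid out explicitly.
tiny_manifest <- function() {
  data.frame(
    probe_id = sprintf("p%02d", 1:8),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
              "chr2"),
    pos = c(100L, 101L, 150L, 250L, 50L, 120L, 180L, 500L),
    context = c(rep("CpG", 6), "CH", "CH"),
    substructure = c("island", "island", "shore", "open_sea", "shelf",
                     "shore", "open_sea", "open_sea"),
    genes = c("GATA3", "GATA3,TP63", "", "", "", "KRT5", "", ""),
    gene_region = c("promoter", "promoter,body", "", "", "", "promoter",
                    "", ""),
    sex = FALSE, snp = FALSE, selfhyb = FALSE,
    stringsAsFactors = FALSE)
}

tiny_beta <- function(manifest = tiny_manifest(), n_samples = 4,
                      seed = 42) {
  set.seed(seed)
  b <- matrix(round(runif(nrow(manifest) * n_samples), 4),
              nrow = nrow(manifest),
              dimnames = list(manifest$probe_id,
                              sprintf("S%02d", seq_len(n_samples))))
  b
}

# Small synthetic world, cached per seed so several tests can share it.
.world_cache <- new.env(parent = emptyenv())
small_world <- function(seed = 7, ...) {
  key <- paste0("w", seed, "_", paste(c(...), collapse = "_"))
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- cohort_config(n_probes = 6000, n_enhancers = 40, n_gained = 12,
                       n_lost = 20, n_keratin_genes = 10, n_lads = 4,
                       seed = seed, ...)
  bundle <- generate_manifest(cfg)
  clock <- generate_clock(bundle$manifest, seed = seed)
  cohort <- generate_cohort(bundle, cfg, clock = clock)
  refs <- generate_references(bundle, cfg)
  w <- list(cfg = cfg, bundle = bundle, clock = clock, cohort = cohort,
            refs = refs)
  .world_cache[[key]] <- w
  w
}

latent_truth <- function(world, ids) {
  world$cohort$samples$latent_subclass[
    match(ids, world$cohort$samples$sample_id)]
}

tmpfile <- function(name) file.path(tempdir(), name)

# Full default-scale world (20,000 probes, 12/16/18 samples) shared by the
# acceptance criteria; built once per test run.
default_world <- function(seed = 1, ...) {
  key <- paste0("full", seed, "_", paste(c(...), collapse = "_"))
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- cohort_config(seed = seed, ...)
  bundle <- generate_manifest(cfg)
  clock <- generate_clock(bundle$manifest, seed = seed)
  cohort <- generate_cohort(bundle, cfg, clock = clock)
  w <- list(cfg = cfg, bundle = bundle, clock = clock, cohort = cohort)
  .world_cache[[key]] <- w
  w
}
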