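small_cfg <- function(...) {
  cohort_config(n_probes = 6000, n_enhancers = 40, n_gained = 12,
                n_lost = 20, n_keratin_genes = 10, n_lads = 4, ...)
}

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- small_cfg(seed = 5)
  expect_identical(generate_manifest(cfg), generate_manifest(cfg))
  b <- generate_manifest(cfg)
  expect_identical(generate_cohort(b, cfg), generate_cohort(b, cfg))
  expect_identical(generate_references(b, cfg), generate_references(b, cfg))
  expect_identical(generate_variants(100, cfg, seed = 5),
                   generate_variants(100, cfg, seed = 5))
  expect_identical(generate_clock(b$manifest, seed = 5),
                   generate_clock(b$manifest, seed = 5))
})

test_that("config validation rejects infeasible settings", {
  expect_error(cohort_config(n_probes = 50), "n_probes")
  expect_error(cohort_config(frac_island = 0.9), "sum to 1")
  expect_error(cohort_config(island_hyper = 0.9), "effect sizes")
  expect_error(cohort_config(nonsense = 1), "unknown")
  # shore fraction too small to host all enhancer/keratin probes
  expect_error(generate_manifest(cohort_config(n_probes = 1000)),
               "infeasible")
})

test_that("manifest structure matches the configured world", {
  w <- small_world(7)
  m <- w$bundle$manifest
  cfg <- w$cfg
  expect_equal(nrow(m), cfg$n_probes)
  expect_false(anyDuplicated(m$probe_id) > 0)
  expect_equal(sum(m$context == "CH"), round(cfg$frac_ch * cfg$n_probes))
  expect_equal(sum(m$sex), round(cfg$frac_sex * cfg$n_probes))
  expect_true(all(m$chrom[m$sex] == "chrX"))
  # every keratin gene has at least one probe
  kg <- keratin_genes(m)
  expect_length(kg, cfg$n_keratin_genes)
  pg <- epidermeth:::probe_gene_map(m)
  expect_true(all(table(pg$gene[grepl("^KRT", pg$gene)]) >= 1))
})

test_that("ESC and KC enhancer sets share about a quarter of regions", {
  w <- small_world(7)
  esc <- w$bundle$regions$ESC_enhancer
  kc <- w$bundle$regions$KC_enhancer
  key <- function(r) paste(r$chrom, r$start, r$end)
  shared <- length(intersect(key(esc), key(kc)))
  expect_equal(shared / nrow(esc), 0.25, tolerance = 0.05 / 0.25)
  expect_equal(shared / nrow(kc), 0.25, tolerance = 0.05 / 0.25)
})

test_that("zero CH fraction emits no CH probes", {
  cfg <- small_cfg(frac_ch = 0, seed = 3)
  b <- generate_manifest(cfg)
  expect_equal(sum(b$manifest$context == "CH"), 0)
})

test_that("planted island shift is recovered by the generator's own draw", {
  w <- small_world(7)
  m <- w$bundle$manifest
  co <- w$cohort
  island <- m$probe_id[m$substructure == "island" & m$context == "CpG"]
  ak <- co$samples$sample_id[co$samples$group == "AK"]
  h <- co$samples$sample_id[co$samples$group == "healthy"]
  d <- mean(co$beta[island, ak]) - mean(co$beta[island, h])
  expect_equal(d, w$cfg$island_hyper, tolerance = 0.02 / 0.15)
})

test_that("noiseless generation reproduces baselines plus effects exactly", {
  cfg <- small_cfg(noise_sd = 0, baseline_jitter_sd = 0, seed = 2)
  b <- generate_manifest(cfg)
  co <- generate_cohort(b, cfg)
  m <- b$manifest
  h <- co$samples$sample_id[co$samples$group == "healthy"][1]
  ak <- co$samples$sample_id[co$samples$group == "AK" &
                               co$samples$latent_subclass ==
                                 "keratinocyte_like"][1]
  island <- m$probe_id[m$substructure == "island" & m$context == "CpG"][1]
  expect_equal(unname(co$beta[island, h]), 0.15)
  expect_equal(unname(co$beta[island, ak]), 0.15 + cfg$island_hyper)
  open_sea <- m$probe_id[m$substructure == "open_sea" & m$chrom == "chr4" &
                           m$context == "CpG"][1]
  expect_equal(unname(co$beta[open_sea, h]), 0.75)
  expect_equal(unname(co$beta[open_sea, ak]), 0.75 + cfg$open_sea_hypo)
  expect_equal(co$n_clamped, 0)
})

test_that("beta stays in [0,1] and clamp events are counted", {
  w <- small_world(7)
  expect_true(all(w$cohort$beta >= 0 & w$cohort$beta <= 1))
  expect_true(w$cohort$n_clamped >= 0)
  # latent truth lives in the sample sheet only, never in the beta matrix
  expect_named(w$cohort$truth, c("ch_responsive", "target_age"))
})

test_that("reference profiles differ by the configured margin", {
  w <- small_world(7)
  m <- w$bundle$manifest
  esc_probes <- unique(unlist(probes_in_regions(m,
    w$bundle$regions$ESC_enhancer)))
  kc_probes <- unique(unlist(probes_in_regions(m,
    w$bundle$regions$KC_enhancer)))
  esc_only <- setdiff(esc_probes, kc_probes)
  d <- mean(w$refs$beta[esc_only, "ref_KC"]) -
    mean(w$refs$beta[esc_only, "ref_ESC"])
  expect_equal(d, w$cfg$reference_margin, tolerance = 0.02)
})

test_that("zero reference margin makes references indistinguishable", {
  cfg <- small_cfg(reference_margin = 0, reference_noise_sd = 0, seed = 4)
  b <- generate_manifest(cfg)
  r <- generate_references(b, cfg)
  expect_equal(max(apply(r$beta, 1, function(x) diff(range(x)))), 0)
})

test_that("clock embedding inverts exactly and survives permutation", {
  w <- small_world(7)
  ck <- w$clock
  for (age in c(5, 20, 50, 80)) {
    beta <- matrix(clock_embed_beta(ck, age), ncol = 1,
                   dimnames = list(names(ck$weights), "s"))
    expect_equal(predict_age(beta, ck)$predicted_age, age,
                 tolerance = 1e-6)
  }
  # the pivot age has linear score zero
  beta20 <- matrix(clock_embed_beta(ck, ck$adult_age), ncol = 1,
                   dimnames = list(names(ck$weights), "s"))
  expect_equal(predict_age(beta20, ck)$score, 0, tolerance = 1e-12)
  # consistent reordering of probes and weights leaves predictions unchanged
  perm <- sample(length(ck$weights))
  ck2 <- clock_model(ck$intercept, ck$weights[perm], ck$adult_age)
  beta <- matrix(clock_embed_beta(ck, 63), ncol = 1,
                 dimnames = list(names(ck$weights), "s"))
  expect_equal(predict_age(beta, ck2)$predicted_age,
               predict_age(beta, ck)$predicted_age, tolerance = 1e-10)
})

test_that("variant generator hits its marginal rates and edge cases", {
  cfg <- cohort_config()
  v <- generate_variants(2000, cfg, seed = 9)
  rate <- mean(v$dbsnp_common[seq_len(nrow(v) - 3)])
  p <- cfg$variant_rates$dbsnp_common
  band <- 1.96 * sqrt(p * (1 - p) / (nrow(v) - 3))
  expect_lt(abs(rate - p), band + 1e-9)

  clean <- cohort_config(variant_rates = list(
    repeats = 0, duke_excluded = 0, dac_blacklist = 0, self_chain = 0,
    segmental_duplication = 0, platypus = 0))
  v0 <- generate_variants(100, clean, seed = 9)
  scores <- confidence_score(v0[seq_len(97), ])
  expect_true(all(scores == 10))

  edge <- tail(v, 3)
  expect_true(edge$dbsnp_common[1] && edge$omim_record[1])
  expect_equal(confidence_score(edge), c(10L, 8L, 7L))
})
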