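test_that("gene aggregation is a per-gene mean with multi-mapping", {
  m <- tiny_manifest()
  b <- matrix(0, nrow(m), 2, dimnames = list(m$probe_id, c("A", "B")))
  b["p01", ] <- c(0.2, 0.2); b["p02", ] <- c(0.4, 0.6)
  b["p06", ] <- c(0.9, 0.1)
  g <- aggregate_gene_beta(b, m, c("GATA3", "TP63", "KRT5", "NOPE"))
  expect_equal(g["GATA3", "A"], 0.3)        # two-probe mean
  expect_equal(g["TP63", "B"], 0.6)         # single probe: identity
  expect_equal(g["KRT5", ], c(A = 0.9, B = 0.1))
  expect_equal(attr(g, "genes_without_probes"), "NOPE")
  expect_error(aggregate_gene_beta(b, m, character(0)), "empty gene set")
  # p02 contributes to both GATA3 and TP63
  expect_equal(g["TP63", "A"], unname(b["p02", "A"]))
})

test_that("region aggregation mirrors gene aggregation", {
  m <- tiny_manifest()
  b <- matrix(seq(0.1, 0.8, 0.1), nrow(m), 2,
              dimnames = list(m$probe_id, c("A", "B")))
  r <- data.frame(chrom = c("chr1", "chr1", "chr9"),
                  start = c(99L, 140L, 0L), end = c(100L, 160L, 10L),
                  region_id = c("r1", "r2", "r_empty"),
                  stringsAsFactors = FALSE)
  attr(r, "name") <- "test"
  ag <- aggregate_region_beta(b, m, r)
  expect_equal(ag["r1", "A"], unname(b["p01", "A"]))  # single member
  expect_equal(ag["r2", "A"], unname(b["p03", "A"]))
  expect_equal(attr(ag, "empty_regions"), "r_empty")
  # splitting a region and recombining probe-weighted recovers the mean
  r2 <- data.frame(chrom = "chr1", start = c(99L, 100L),
                   end = c(100L, 160L), region_id = c("a", "b"),
                   stringsAsFactors = FALSE)
  attr(r2, "name") <- "split"
  ag2 <- aggregate_region_beta(b, m, r2)
  n_a <- 1; n_b <- 2  # p01 | p02, p03
  expect_equal((n_a * ag2["a", "A"] + n_b * ag2["b", "A"]) / 3,
               mean(b[c("p01", "p02", "p03"), "A"]))
})

test_that("platform harmonization joins on shared features and reports", {
  a <- matrix(1:6 / 10, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                              c("A1", "A2")))
  b <- matrix(1:4 / 10, 2, 2, dimnames = list(c("g2", "g3"), c("B1", "B2")))
  j <- harmonize_platforms(a, b, "epic", "tcga450k")
  expect_equal(rownames(j), c("g2", "g3"))
  expect_equal(ncol(j), 4)
  expect_equal(attr(j, "dropped_features")$only_a, "g1")
  expect_equal(unname(attr(j, "origin")), c("epic", "epic", "tcga450k",
                                            "tcga450k"))
  # identical feature sets: plain column concatenation
  j2 <- harmonize_platforms(a, a)
  expect_equal(j2, cbind(a, a), ignore_attr = TRUE)
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(5)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
  pc <- pca_embed(x, n_components = 4)
  ev <- eigen(cov(t(x)))
  for (j in 1:4) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pc$loadings[, j]), v, tolerance = 1e-8)
  }
  expect_equal(pc$explained_variance[1:4],
               (ev$values / sum(ev$values))[1:4], tolerance = 1e-8)
  # duplicated samples get identical coordinates
  x2 <- cbind(x, dup = x[, 1])
  pc2 <- pca_embed(x2)
  expect_equal(unname(pc2$scores["s1", ]), unname(pc2$scores["dup", ]),
               tolerance = 1e-10)
  expect_error(pca_embed(matrix(0.5, 3, 4)), "constant")
})

test_that("a one-feature signal lands entirely on PC1", {
  x <- rbind(sig = rep(c(0, 1), each = 10), flat = rnorm(20, 0, 1e-3))
  colnames(x) <- paste0("s", 1:20)
  pc <- pca_embed(x)
  expect_gt(pc$explained_variance[1], 0.999)
  side <- pc$scores[, 1] > 0
  expect_true(all(side[1:10] != side[11:20]))
})

test_that("dendrogram merge heights match a naive O(n^3) oracle", {
  set.seed(8)
  x <- matrix(rnorm(30 * 5), 5, 30,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:30)))
  for (lk in c("average", "complete")) {
    cd <- cluster_dendrogram(x, linkage = lk)
    oracle <- naive_agglomeration_heights(as.matrix(dist(t(x))), lk)
    expect_equal(cd$hclust$height, oracle, tolerance = 1e-10)
  }
  expect_error(cluster_dendrogram(x, k = 31), "k exceeds")
  # two well-separated blobs split perfectly at k = 2
  y <- cbind(matrix(rnorm(50, 0, 0.1), 5), matrix(rnorm(50, 5, 0.1), 5))
  colnames(y) <- paste0("s", 1:20)
  cl <- cluster_dendrogram(y, k = 2)$clusters
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[11])
  # newick export is parseable
  expect_s3_class(ape::read.tree(text = cluster_dendrogram(y)$newick),
                  "phylo")
})

test_that("three equidistant points cluster deterministically", {
  x <- rbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  colnames(x) <- c("a", "b", "c")
  c1 <- cluster_dendrogram(x, k = 2)
  c2 <- cluster_dendrogram(x, k = 2)
  expect_identical(c1$clusters, c2$clusters)
  expect_identical(c1$newick, c2$newick)
})

test_that("subclasses are recovered perfectly on both channels", {
  w <- small_world(7)
  m <- w$bundle$manifest
  co <- w$cohort
  gm <- aggregate_gene_beta(co$beta, m, keratin_genes(m))
  ker <- call_subclasses(gm, co$samples, method = "keratin")
  expect_false(attr(ker, "no_structure"))
  expect_equal(adjusted_rand_index(ker$subclass,
                                   latent_truth(w, ker$sample_id)), 1)
  # the labels themselves match the planted identity, via the healthy anchor
  expect_equal(ker$subclass, latent_truth(w, ker$sample_id))

  ef <- rbind(aggregate_region_beta(co$beta, m, w$bundle$regions$ESC_enhancer),
              aggregate_region_beta(co$beta, m, w$bundle$regions$KC_enhancer))
  enh <- call_subclasses(ef, co$samples, method = "enhancer")
  expect_equal(adjusted_rand_index(enh$subclass,
                                   latent_truth(w, enh$sample_id)), 1)
  # cross-method agreement
  agree <- mean(ker$subclass ==
                  enh$subclass[match(ker$sample_id, enh$sample_id)])
  expect_gte(agree, 0.95)
})

test_that("subclass calling is invariant under sample permutation", {
  w <- small_world(7)
  m <- w$bundle$manifest
  gm <- aggregate_gene_beta(w$cohort$beta, m, keratin_genes(m))
  ker <- call_subclasses(gm, w$cohort$samples, method = "keratin")
  set.seed(3)
  perm <- sample(ncol(gm))
  ker2 <- call_subclasses(gm[, perm], w$cohort$samples, method = "keratin")
  joined <- merge(as.data.frame(ker)[, c("sample_id", "subclass")],
                  as.data.frame(ker2)[, c("sample_id", "subclass")],
                  by = "sample_id")
  expect_equal(joined$subclass.x, joined$subclass.y)
})

test_that("null separation yields a no-structure report, not forced calls", {
  w0 <- small_world(21, subclass_separation = 0)
  m <- w0$bundle$manifest
  gm <- aggregate_gene_beta(w0$cohort$beta, m, keratin_genes(m))
  ker <- call_subclasses(gm, w0$cohort$samples, method = "keratin")
  expect_true(attr(ker, "no_structure"))
  expect_true(all(is.na(ker$subclass)))
})

test_that("EpSC-like samples sit nearer the ESC reference than healthy do", {
  w <- small_world(7)
  m <- w$bundle$manifest
  feats <- rbind(
    aggregate_region_beta(w$cohort$beta, m, w$bundle$regions$ESC_enhancer),
    aggregate_region_beta(w$cohort$beta, m, w$bundle$regions$KC_enhancer))
  ref <- rbind(
    aggregate_region_beta(w$refs$beta, m, w$bundle$regions$ESC_enhancer),
    aggregate_region_beta(w$refs$beta, m, w$bundle$regions$KC_enhancer))
  esc_ref <- ref[rownames(feats), "ref_ESC"]
  truth <- latent_truth(w, colnames(feats))
  d_esc <- sqrt(colSums((feats - esc_ref)^2))
  expect_lt(mean(d_esc[!is.na(truth) & truth == "EpSC_like"]),
            mean(d_esc[!is.na(truth) & truth == "keratinocyte_like"]))
})

test_that("delta versus healthy centers healthy columns exactly", {
  w <- small_world(7)
  m <- w$bundle$manifest
  gained <- aggregate_region_beta(w$cohort$beta, m,
                                  w$bundle$regions$EpSC_gained)
  dm <- delta_vs_healthy(gained, w$cohort$samples)
  healthy <- w$cohort$samples$sample_id[w$cohort$samples$group == "healthy"]
  expect_equal(max(abs(rowMeans(dm[, healthy]))), 0, tolerance = 1e-12)
  # a constant planted shift shows up as a constant column
  g2 <- gained; g2[, "AK01"] <- rowMeans(gained[, healthy]) + 0.2
  dm2 <- delta_vs_healthy(g2, w$cohort$samples)
  expect_equal(unname(dm2[, "AK01"]), rep(0.2, nrow(g2)), tolerance = 1e-12)
})

test_that("hypermethylated-gene selection applies a strict threshold", {
  dm <- matrix(c(0.25, 0.15, 0.20), 3, 2,
               dimnames = list(c("rA", "rB", "rC"), c("S1", "S2")))
  gmap <- data.frame(region_id = c("rA", "rA", "rB", "rC"),
                     gene = c("G2", "G1", "G3", "G4"),
                     stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = c("S1", "S2"), method = "enhancer",
                      subclass = "EpSC_like", stringsAsFactors = FALSE)
  genes <- select_hypermethylated_genes(dm, gmap, calls, threshold = 0.2)
  expect_equal(as.character(genes), c("G1", "G2"))  # sorted, deduplicated
  expect_equal(attr(genes, "regions"), "rA")  # 0.15 and exactly 0.20 fail
  calls$subclass <- "keratinocyte_like"
  expect_warning(g0 <- select_hypermethylated_genes(dm, gmap, calls),
                 "no EpSC-like")
  expect_length(g0, 0)
})

test_that("a dedifferentiated pan-cancer cohort joins and separates", {
  w <- small_world(7)
  m <- w$bundle$manifest
  kg <- keratin_genes(m)
  gm <- aggregate_gene_beta(w$cohort$beta, m, kg)
  # synthetic pan-cancer cohort: keratin profile shifted away from healthy
  set.seed(44)
  pan <- gm[, 1:8] + 0.25
  colnames(pan) <- paste0("TCGA", 1:8)
  pan <- pmin(pan + rnorm(length(pan), 0, 0.02), 1)
  joint <- harmonize_platforms(gm, pan, "epidermis", "pan_cancer")
  pc <- pca_embed(joint)
  origin <- attr(joint, "origin")
  s1 <- pc$scores[, 1]
  healthy <- w$cohort$samples$sample_id[w$cohort$samples$group == "healthy"]
  gap <- abs(mean(s1[names(origin)[origin == "pan_cancer"]]) -
               mean(s1[healthy]))
  spread <- stats::sd(s1[healthy])
  expect_gt(gap, 3 * spread)
})
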