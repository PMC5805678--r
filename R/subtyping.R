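# Two-subclass discovery from aggregated methylation profiles.
#
# Features are gene- or enhancer-level mean beta values; samples are
# clustered hierarchically at k = 2 (the subclass count is fixed by design,
# not estimated) and the two clusters are labeled by proximity to a
# healthy / keratinocyte anchor profile: the nearer cluster is
# keratinocyte_like, the other EpSC_like. A silhouette floor guards against
# forcing subclass structure onto null data.

#' Aggregate probe beta values per gene
#'
#' Per gene and sample, the mean beta over the gene's probes (missing values
#' skipped). A probe linked to several genes contributes to each of them.
#' Requested genes with no probes in the manifest are excluded and reported
#' via the `"genes_without_probes"` attribute.
#'
#' @param beta beta matrix.
#' @param manifest probe manifest with gene links.
#' @param gene_symbols character vector of genes to aggregate (non-empty).
#' @return genes x samples matrix.
#' @export
aggregate_gene_beta <- function(beta, manifest, gene_symbols) {
  if (length(gene_symbols) == 0) stop("empty gene set")
  pg <- probe_gene_map(manifest)
  pg <- pg[pg$gene %in% gene_symbols & pg$probe_id %in% rownames(beta), ]
  found <- unique(pg$gene)
  missing <- setdiff(gene_symbols, found)
  if (length(found) == 0) stop("no probes found for any requested gene")
  out <- matrix(NA_real_, length(found), ncol(beta),
                dimnames = list(sort(found), colnames(beta)))
  for (g in rownames(out)) {
    probes <- pg$probe_id[pg$gene == g]
    out[g, ] <- colMeans(beta[probes, , drop = FALSE], na.rm = TRUE)
  }
  attr(out, "genes_without_probes") <- missing
  out
}

#' Keratin genes present in a manifest
#'
#' Convenience accessor: all gene symbols in the manifest matching `^KRT`.
#'
#' @param manifest probe manifest.
#' @return character vector of keratin gene symbols.
#' @export
keratin_genes <- function(manifest) {
  sort(unique(grep("^KRT", probe_gene_map(manifest)$gene, value = TRUE)))
}

#' Aggregate probe beta values per region
#'
#' As [aggregate_gene_beta()], with membership resolved by
#' [probes_in_regions()]. Regions without probes are dropped and counted.
#'
#' @param beta beta matrix.
#' @param manifest probe manifest.
#' @param regions region set.
#' @return regions x samples matrix with an `"empty_regions"` attribute.
#' @export
aggregate_region_beta <- function(beta, manifest, regions) {
  membership <- probes_in_regions(manifest, regions)
  membership <- lapply(membership, intersect, rownames(beta))
  keep <- names(membership)[lengths(membership) > 0]
  if (length(keep) == 0) stop("no region of '",
                              attr(regions, "name") %||% "?",
                              "' covers any probe")
  out <- matrix(NA_real_, length(keep), ncol(beta),
                dimnames = list(keep, colnames(beta)))
  for (r in keep)
    out[r, ] <- colMeans(beta[membership[[r]], , drop = FALSE], na.rm = TRUE)
  attr(out, "empty_regions") <- setdiff(names(membership), keep)
  out
}

#' Join two cohorts' aggregated matrices on shared features
#'
#' Each cohort is aggregated over its own probe basis first (e.g. 850k vs
#' 450k platforms); the joint matrix keeps only features present in both,
#' reporting what was dropped. Column origin labels are kept in the
#' `"origin"` attribute.
#'
#' @param matrix_a,matrix_b feature x sample matrices.
#' @param label_a,label_b cohort labels.
#' @return joint feature x sample matrix on the shared features.
#' @export
harmonize_platforms <- function(matrix_a, matrix_b,
                                label_a = "cohort_a", label_b = "cohort_b") {
  shared <- intersect(rownames(matrix_a), rownames(matrix_b))
  if (length(shared) == 0) stop("no shared features between cohorts")
  out <- cbind(matrix_a[shared, , drop = FALSE],
               matrix_b[shared, , drop = FALSE])
  attr(out, "origin") <- setNames(c(rep(label_a, ncol(matrix_a)),
                                    rep(label_b, ncol(matrix_b))),
                                  colnames(out))
  attr(out, "dropped_features") <-
    list(only_a = setdiff(rownames(matrix_a), shared),
         only_b = setdiff(rownames(matrix_b), shared))
  out
}

#' Principal component embedding of samples
#'
#' PCA on centered (by default unscaled — beta values are already bounded
#' and commensurate) features, samples as observations. Component signs are
#' fixed by convention: the loading of largest absolute value on each
#' component is made positive, so results are fully deterministic.
#'
#' @param feature_matrix features x samples matrix (>= 2 of each).
#' @param n_components number of components to keep.
#' @param scale. scale features to unit variance first (default `FALSE`).
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` (proportions).
#' @export
pca_embed <- function(feature_matrix, n_components = 2, scale. = FALSE) {
  x <- t(feature_matrix)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 samples and >= 2 features")
  v <- apply(x, 2, var)
  if (all(v < .Machine$double.eps))
    stop("constant feature matrix: no variance to decompose")
  if (scale. && any(v < .Machine$double.eps))
    stop("cannot scale zero-variance features")
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Hierarchical clustering of samples with dendrogram export
#'
#' Agglomerative clustering of the sample columns under euclidean or
#' correlation (`1 - r`) distance and average, complete or Ward linkage.
#' The tree can be cut into `k` flat clusters and exported as a Newick
#' string (via \pkg{ape}) for unrooted dendrogram drawing.
#'
#' @param feature_matrix features x samples matrix.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @param k optional number of flat clusters (`k <=` number of samples).
#' @return list with `hclust`, `clusters` (named integer vector or `NULL`),
#'   `newick` (character scalar).
#' @export
cluster_dendrogram <- function(feature_matrix,
                               distance = c("euclidean", "correlation"),
                               linkage = c("average", "complete", "ward"),
                               k = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  n <- ncol(feature_matrix)
  if (!is.null(k) && k > n) stop("k exceeds the number of samples")
  d <- if (distance == "euclidean") dist(t(feature_matrix))
       else stats::as.dist(1 - cor(feature_matrix))
  hc <- hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  clusters <- if (!is.null(k)) cutree(hc, k = k) else NULL
  list(hclust = hc, clusters = clusters,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Call the two AK/cSCC subclasses
#'
#' Clusters the AK/cSCC samples of a feature matrix at `k = 2` and labels
#' the clusters by anchor proximity: the cluster whose centroid is nearer
#' the healthy-sample centroid (or, failing that, a supplied keratinocyte /
#' reference anchor profile) is `keratinocyte_like`; the other is
#' `EpSC_like`. Without any anchor, an `epsc_score` per sample (e.g. mean
#' methylation over EpSC-gained regions) labels the higher-scoring cluster
#' `EpSC_like`. If the 2-cluster cut's mean silhouette falls below
#' `silhouette_floor` the result reports *no subclass structure* instead of
#' forcing a call; the default floor 0.25 follows the usual silhouette
#' guideline below which no substantial structure should be claimed.
#'
#' @param feature_matrix features x samples; may include healthy samples
#'   and/or reference columns, which are used as anchors, not clustered.
#' @param samples sample sheet covering the columns.
#' @param method label recorded in the calls (`"keratin"`, `"enhancer"`...).
#' @param anchors optional named list of anchor profiles (numeric vectors on
#'   the feature space), e.g. `list(keratinocyte = ...)`; used when no
#'   healthy samples are present.
#' @param epsc_score optional named per-sample score for anchor-free
#'   labeling.
#' @param distance,linkage passed to [cluster_dendrogram()].
#' @param silhouette_floor minimum mean silhouette for a valid 2-cluster
#'   call.
#' @return data.frame of class `"subtype_call"`: `sample_id`, `method`,
#'   `subclass`, `cluster_id`, `dist_to_anchor`; attributes `no_structure`,
#'   `silhouette`, `anchor`, `distance`, `linkage`, `newick`.
#' @export
call_subclasses <- function(feature_matrix, samples, method = "keratin",
                            anchors = NULL, epsc_score = NULL,
                            distance = "euclidean", linkage = "average",
                            silhouette_floor = 0.25) {
  sheet <- samples[match(colnames(feature_matrix), samples$sample_id), ]
  target_ids <- sheet$sample_id[sheet$group %in% c("AK", "cSCC")]
  if (length(target_ids) < 2) stop("need >= 2 AK/cSCC samples to subtype")
  healthy_ids <- sheet$sample_id[sheet$group == "healthy"]
  x <- feature_matrix[, target_ids, drop = FALSE]

  cd <- cluster_dendrogram(x, distance = distance, linkage = linkage, k = 2)
  cl <- cd$clusters
  d <- if (distance == "euclidean") dist(t(x))
       else stats::as.dist(1 - cor(x))
  sil <- mean_silhouette(d, cl)

  base <- data.frame(sample_id = target_ids, method = method,
                     subclass = NA_character_, cluster_id = unname(cl),
                     dist_to_anchor = NA_real_, stringsAsFactors = FALSE)
  finish <- function(df, no_structure, anchor_used) {
    attr(df, "no_structure") <- no_structure
    attr(df, "silhouette") <- sil
    attr(df, "anchor") <- anchor_used
    attr(df, "distance") <- distance
    attr(df, "linkage") <- linkage
    attr(df, "newick") <- cd$newick
    class(df) <- c("subtype_call", "data.frame")
    df
  }
  if (length(unique(cl)) < 2 || sil < silhouette_floor)
    return(finish(base, TRUE, NA_character_))

  anchor <- NULL
  anchor_used <- NA_character_
  if (length(healthy_ids) > 0) {
    anchor <- rowMeans(feature_matrix[, healthy_ids, drop = FALSE],
                       na.rm = TRUE)
    anchor_used <- "healthy_centroid"
  } else if (!is.null(anchors) && length(anchors) > 0) {
    anchor <- anchors[[1]]
    anchor_used <- paste0("anchor:", names(anchors)[1] %||% "1")
  }

  if (!is.null(anchor)) {
    cent <- vapply(1:2, function(g) rowMeans(x[, cl == g, drop = FALSE],
                                             na.rm = TRUE),
                   numeric(nrow(x)))
    d_anchor <- sqrt(colSums((cent - anchor)^2))
    kc_cluster <- which.min(d_anchor)
    base$subclass <- ifelse(cl == kc_cluster, "keratinocyte_like",
                            "EpSC_like")
    base$dist_to_anchor <- sqrt(colSums((x - anchor)^2))
  } else if (!is.null(epsc_score)) {
    sc <- epsc_score[target_ids]
    hi <- which.max(vapply(1:2, function(g) mean(sc[cl == g], na.rm = TRUE),
                           numeric(1)))
    base$subclass <- ifelse(cl == hi, "EpSC_like", "keratinocyte_like")
    anchor_used <- "epsc_score"
  } else {
    stop("no labeling information: supply healthy samples, an anchor ",
         "profile, or an epsc_score")
  }
  finish(base, FALSE, anchor_used)
}

#' Normalized delta-beta matrix versus healthy epidermis
#'
#' Subtracts, per feature (region or gene), the healthy-group mean from
#' every sample's value; healthy columns therefore average to exactly zero
#' per feature.
#'
#' @param feature_matrix features x samples matrix.
#' @param samples sample sheet; must contain healthy samples among the
#'   columns.
#' @return matrix of the same shape.
#' @export
delta_vs_healthy <- function(feature_matrix, samples) {
  sheet <- samples[match(colnames(feature_matrix), samples$sample_id), ]
  healthy <- sheet$sample_id[!is.na(sheet$group) & sheet$group == "healthy"]
  if (length(healthy) == 0) stop("no healthy samples among the columns")
  ref <- rowMeans(feature_matrix[, healthy, drop = FALSE], na.rm = TRUE)
  sweep(feature_matrix, 1, ref, "-")
}

#' Select genes from hypermethylated EpSC-specific regions
#'
#' Regions whose mean normalized delta beta across the EpSC-like samples
#' strictly exceeds `threshold` are selected, and their genes (from the
#' region-to-gene map) are returned deduplicated and sorted. A delta of
#' exactly the threshold is *not* selected.
#'
#' @param delta_matrix regions x samples normalized delta-beta matrix (from
#'   [delta_vs_healthy()] over the EpSC-gained regions).
#' @param gene_map data.frame with columns `region_id`, `gene`.
#' @param calls a `subtype_call` data.frame identifying EpSC-like samples.
#' @param threshold strict lower bound on the region mean (default 0.2).
#' @return sorted character vector of gene symbols; selected region ids in
#'   the `"regions"` attribute.
#' @export
select_hypermethylated_genes <- function(delta_matrix, gene_map, calls,
                                         threshold = 0.2) {
  epsc <- calls$sample_id[!is.na(calls$subclass) &
                            calls$subclass == "EpSC_like"]
  epsc <- intersect(epsc, colnames(delta_matrix))
  if (length(epsc) == 0) {
    warning("no EpSC-like samples: returning an empty gene list")
    out <- character(0)
    attr(out, "regions") <- character(0)
    return(out)
  }
  region_means <- rowMeans(delta_matrix[, epsc, drop = FALSE], na.rm = TRUE)
  sel <- names(region_means)[region_means > threshold]
  genes <- sort(unique(gene_map$gene[gene_map$region_id %in% sel]))
  attr(genes, "regions") <- sel
  genes
}
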