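# End-to-end orchestration: synthesize (optional) -> filter -> differential
# -> landscape -> methylation age -> subtyping -> variant filter, with one
# root seed, per-stage logging to stderr, and a run manifest that makes the
# bundle re-derivable.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
    else if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
    else stop("config must be a .yaml/.yml/.json file or a list")
  }
  stopifnot(is.list(config))
  if (is.null(config$synthetic) && is.null(config$inputs))
    stop("config needs either a 'synthetic:' or an 'inputs:' block")
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config
}

stage_log <- function(stage, code) {
  t0 <- Sys.time()
  message("[", stage, "] start")
  out <- tryCatch(force(code), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done (%.1fs)", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either synthetic data (a `synthetic:` config
#' block of [cohort_config()] overrides) or user-supplied files (an
#' `inputs:` block of paths: `beta`, `manifest`, `samplesheet`, and
#' optionally `lads`, `esc_enhancers`, `kc_enhancers`, `epsc_gained`,
#' `epsc_lost`, `clock`, `variants`). Differential methylation runs the
#' healthy:AK, healthy:cSCC and AK:cSCC contrasts; subtyping runs in keratin
#' mode and — when enhancer regions are available — enhancer mode, with a
#' cross-method agreement summary. Identical config + seed yields
#' byte-identical numeric outputs (the run manifest records the config hash,
#' seed and package version, and no timestamps).
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param out_dir output directory (created); overrides `config$out_dir`.
#' @return (invisibly) a list with every stage result plus `run_manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- cfg$alpha
  results <- list()

  if (!is.null(cfg$synthetic)) {
    sy <- stage_log("synthesize", {
      syn_cfg <- do.call(cohort_config,
                         c(cfg$synthetic[setdiff(names(cfg$synthetic),
                                                 c("variants",
                                                   "n_variants"))],
                           list(seed = cfg$seed)))
      bundle <- generate_manifest(syn_cfg)
      clock <- generate_clock(bundle$manifest, seed = cfg$seed)
      cohort <- generate_cohort(bundle, syn_cfg, clock = clock)
      refs <- generate_references(bundle, syn_cfg)
      variants <- if (isTRUE(cfg$synthetic$variants %||% TRUE))
        generate_variants(cfg$synthetic$n_variants %||% 500L, syn_cfg,
                          seed = cfg$seed) else NULL
      list(bundle = bundle, clock = clock, cohort = cohort, refs = refs,
           variants = variants, config = syn_cfg)
    })
    manifest <- sy$bundle$manifest
    regions <- sy$bundle$regions
    beta <- sy$cohort$beta
    samples <- sy$cohort$samples
    clock <- sy$clock
    refs <- sy$refs
    variants <- sy$variants
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write_sample_sheet(samples, file.path(out_dir, "samplesheet.tsv"))
    for (nm in names(regions))
      write_regions_bed(regions[[nm]],
                        file.path(out_dir, paste0(tolower(nm), ".bed")))
    results$synthetic_truth <- sy$cohort$truth
  } else {
    inp <- cfg$inputs
    manifest <- stage_log("read", read_manifest(inp$manifest))
    beta <- read_beta_matrix(inp$beta, manifest)
    samples <- read_sample_sheet(inp$samplesheet)
    read_opt <- function(path, name)
      if (!is.null(path)) read_regions_bed(path, name) else NULL
    regions <- list(LAD = read_opt(inp$lads, "LAD"),
                    ESC_enhancer = read_opt(inp$esc_enhancers,
                                            "ESC_enhancer"),
                    KC_enhancer = read_opt(inp$kc_enhancers, "KC_enhancer"),
                    EpSC_gained = read_opt(inp$epsc_gained, "EpSC_gained"),
                    EpSC_lost = read_opt(inp$epsc_lost, "EpSC_lost"))
    clock <- if (!is.null(inp$clock)) read_clock(inp$clock) else NULL
    refs <- NULL
    variants <- if (!is.null(inp$variants)) read_variants(inp$variants)
                else NULL
  }

  beta_f <- stage_log("filter", filter_probes(beta, manifest))
  write_tsv(attr(beta_f, "exclusion_report"),
            file.path(out_dir, "filter_report.tsv"))

  contrasts <- list(c("healthy", "AK"), c("healthy", "cSCC"),
                    c("AK", "cSCC"))
  diffs <- stage_log("differential", lapply(contrasts, function(cmp) {
    res <- moderated_group_test(beta_f, samples, comparison = cmp,
                                alpha = alpha)
    write_tsv(res, file.path(out_dir, sprintf("differential_%s_vs_%s.tsv",
                                              cmp[1], cmp[2])))
    res
  }))
  names(diffs) <- vapply(contrasts, paste, "", collapse = "_vs_")
  results$differential <- diffs

  results$landscape <- stage_log("landscape", {
    out <- list()
    for (cmp in list(c("healthy", "AK"), c("healthy", "cSCC"))) {
      key <- paste(cmp, collapse = "_vs_")
      out[[key]] <- list(
        substructure = substructure_shift(beta_f, manifest, samples,
                                          cmp[1], cmp[2]),
        fractions = shift_fractions(diffs[[key]], manifest))
      if (!is.null(regions$LAD) && nrow(regions$LAD) > 0)
        out[[key]]$lad <- region_shift(beta_f, manifest, regions$LAD,
                                       samples, cmp[1], cmp[2])
      write_tsv(out[[key]]$substructure,
                file.path(out_dir, paste0("substructure_", key, ".tsv")))
      write_tsv(out[[key]]$fractions,
                file.path(out_dir, paste0("fractions_", key, ".tsv")))
    }
    ch <- tryCatch(noncpg_analysis(beta_f, manifest, samples, "healthy",
                                   "AK", alpha = alpha),
                   error = function(e) {
                     message("  non-CpG analysis skipped: ",
                             conditionMessage(e))
                     NULL
                   })
    out$noncpg_healthy_vs_AK <- ch
    out
  })

  if (!is.null(clock)) {
    results$age <- stage_log("age", {
      pred <- predict_age(beta_f, clock)
      gap <- age_gap(pred, samples)
      write_tsv(gap$per_sample, file.path(out_dir, "age_per_sample.tsv"))
      write_tsv(gap$per_group, file.path(out_dir, "age_per_group.tsv"))
      gap
    })
  }

  results$subtypes <- stage_log("subtyping", {
    calls <- list()
    kg <- keratin_genes(manifest)
    if (length(kg) > 0) {
      gm <- aggregate_gene_beta(beta_f, manifest, kg)
      calls$keratin <- call_subclasses(gm, samples, method = "keratin",
                                       silhouette_floor =
                                         cfg$subtyping$silhouette_floor %||%
                                         0.25)
      pca <- pca_embed(gm)
      write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(out_dir, "keratin_pca.tsv"))
      write_tsv(as.data.frame(calls$keratin),
                file.path(out_dir, "subtypes_keratin.tsv"))
      writeLines(attr(calls$keratin, "newick"),
                 file.path(out_dir, "keratin_dendrogram.nwk"))
    } else message("  no keratin genes in manifest; keratin mode skipped")

    has_enh <- !is.null(regions$ESC_enhancer) &&
      nrow(regions$ESC_enhancer %||% data.frame()) > 0 &&
      !is.null(regions$KC_enhancer)
    if (has_enh) {
      enh_feat <- rbind(
        aggregate_region_beta(beta_f, manifest, regions$ESC_enhancer),
        aggregate_region_beta(beta_f, manifest, regions$KC_enhancer))
      anchors <- if (!is.null(refs)) {
        ref_enh <- rbind(
          aggregate_region_beta(refs$beta, manifest,
                                regions$ESC_enhancer),
          aggregate_region_beta(refs$beta, manifest, regions$KC_enhancer))
        list(keratinocyte = ref_enh[rownames(enh_feat), "ref_KC"])
      } else NULL
      calls$enhancer <- call_subclasses(enh_feat, samples,
                                        method = "enhancer",
                                        anchors = anchors,
                                        silhouette_floor =
                                          cfg$subtyping$silhouette_floor %||%
                                          0.25)
      write_tsv(as.data.frame(calls$enhancer),
                file.path(out_dir, "subtypes_enhancer.tsv"))
      writeLines(attr(calls$enhancer, "newick"),
                 file.path(out_dir, "enhancer_dendrogram.nwk"))
      if (!is.null(regions$EpSC_gained) &&
          nrow(regions$EpSC_gained %||% data.frame()) > 0) {
        gained_feat <- aggregate_region_beta(beta_f, manifest,
                                             regions$EpSC_gained)
        dm <- delta_vs_healthy(gained_feat, samples)
        write_tsv(data.frame(region_id = rownames(dm), dm),
                  file.path(out_dir, "epsc_gained_delta.tsv"))
        gmap <- attr(regions$EpSC_gained, "gene_map")
        if (!is.null(gmap) && !is.null(calls$enhancer)) {
          genes <- select_hypermethylated_genes(dm, gmap, calls$enhancer)
          writeLines(genes, file.path(out_dir, "hypermethylated_genes.txt"))
          calls$hypermethylated_genes <- genes
        }
      }
    } else message("  enhancer regions not configured; enhancer mode skipped")

    if (!is.null(calls$keratin) && !is.null(calls$enhancer)) {
      a <- calls$keratin$subclass[match(calls$enhancer$sample_id,
                                        calls$keratin$sample_id)]
      b <- calls$enhancer$subclass
      ok <- !is.na(a) & !is.na(b)
      calls$agreement <- if (any(ok)) mean(a[ok] == b[ok]) else NA_real_
      jsonlite::write_json(list(cross_method_agreement = calls$agreement),
                           file.path(out_dir, "subtype_agreement.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    calls
  })

  if (!is.null(variants)) {
    results$variants <- stage_log("variant_filter", {
      vf_cfg <- cfg$variant_filter %||% list()
      vf <- filter_variants(
        variants,
        min_score = vf_cfg$min_score %||% 8,
        depth_bounds = vf_cfg$depth_bounds,
        exac_max = vf_cfg$exac_max %||% 0.001,
        evs_max = vf_cfg$evs_max %||% 0.01,
        inhouse_max = vf_cfg$inhouse_max %||% 0.02)
      write_variants(vf$retained, file.path(out_dir,
                                            "variants_retained.tsv"))
      write_tsv(vf$report, file.path(out_dir, "variant_filter_report.tsv"))
      vf
    })
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  run_manifest <- list(
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("epidermeth")))
  unlink(tmp)
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  results$run_manifest <- run_manifest
  invisible(results)
}
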