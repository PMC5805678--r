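# Synthetic-data generator
#
# Emulates the statistical structure of an epidermis methylation study:
# a probe manifest with epigenomic substructures and region sets (LADs,
# ESC/keratinocyte enhancers, enhancers gained/lost during epidermal
# stem-cell differentiation), a three-group cohort (healthy / AK / cSCC)
# whose lesion samples carry classical cancer-methylome shifts plus a
# two-subclass signature planted in three independent channels
# (ESC-enhancer + EpSC-gained methylation, keratin promoter methylation,
# clock-probe age signal), reference methylomes, a synthetic clock, and an
# annotated somatic-variant table.

KERATIN_GENES_CHR12 <- c("KRT1", "KRT2", "KRT3", "KRT4", "KRT5", "KRT6A",
                         "KRT7", "KRT8", "KRT76", "KRT80")
KERATIN_GENES_CHR17 <- c("KRT9", "KRT10", "KRT14", "KRT15", "KRT16", "KRT17",
                         "KRT19", "KRT20", "KRT31", "KRT33A")

SUBSTRUCTURE_BASELINES <- c(island = 0.15, shore = 0.40, shelf = 0.60,
                            open_sea = 0.75)
CH_BASELINE <- 0.05

#' Configuration of the synthetic cohort
#'
#' Returns the default "stated world" of the generator, optionally overridden
#' field by field. Group sizes default to 12 healthy / 16 AK / 18 cSCC.
#' Effect sizes are signed mean-beta shifts applied to lesion (AK/cSCC)
#' samples: CpG-island hypermethylation `+0.15`, open-sea hypomethylation
#' `-0.15`, LAD hypomethylation `-0.10` (replacing the substructure effect for
#' LAD-resident probes), non-CpG gain `+0.10` on a responsive half of CH
#' probes, and a subclass-separation shift of `0.30` defining the latent
#' EpSC-like subclass in half of the lesion samples. Per-measurement noise is
#' Gaussian with sd `0.05`, clamped into \[0, 1\] (clamp events are counted).
#'
#' @param ... named overrides of any default listed below.
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_probes = 20000L,
    frac_island = 0.20, frac_shore = 0.25, frac_shelf = 0.15,
    frac_open_sea = 0.40,
    frac_ch = 0.05,
    frac_sex = 0.02, frac_snp = 0.02, frac_selfhyb = 0.01,
    n_healthy = 12L, n_ak = 16L, n_cscc = 18L,
    island_hyper = 0.15, open_sea_hypo = -0.15, lad_hypo = -0.10,
    ch_gain = 0.10, subclass_separation = 0.30,
    subclass_fraction = 0.5,
    noise_sd = 0.05, baseline_jitter_sd = 0.02,
    n_keratin_genes = 20L, probes_per_keratin = 6L,
    n_enhancers = 120L, enhancer_shared_frac = 0.25,
    probes_per_enhancer = 3L,
    n_gained = 30L, n_lost = 60L,
    n_lads = 8L, lad_cover_frac = 0.6,
    age_shift = 15, epsc_extra_age_shift = 10,
    reference_margin = 0.30, reference_noise_sd = 0.01,
    variant_rates = list(repeats = 0.10, duke_excluded = 0.05,
                         dac_blacklist = 0.05, self_chain = 0.08,
                         segmental_duplication = 0.07, platypus = 0.08,
                         indel_fraction = 0.20, dbsnp_common = 0.05,
                         omim_given_common = 0.30, rare_pop = 0.05,
                         noncoding = 0.30, improper_map = 0.02),
    depth_mean = 180, depth_size = 10,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown cohort_config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (nm == "variant_rates") {
      cfg$variant_rates[names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  fr <- c(cfg$frac_island, cfg$frac_shore, cfg$frac_shelf, cfg$frac_open_sea)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-6)
    stop("substructure fractions must lie in [0,1] and sum to 1")
  probs <- c(cfg$frac_ch, cfg$frac_sex, cfg$frac_snp, cfg$frac_selfhyb,
             cfg$subclass_fraction, cfg$enhancer_shared_frac,
             cfg$lad_cover_frac, unlist(cfg$variant_rates))
  if (any(probs < 0 | probs > 1)) stop("all fractions must lie in [0,1]")
  if (cfg$n_probes < 100) stop("n_probes must be >= 100")
  effs <- c(cfg$island_hyper, cfg$open_sea_hypo, cfg$lad_hypo, cfg$ch_gain,
            cfg$subclass_separation)
  if (any(abs(effs) > 0.5))
    stop("effect sizes must stay within +/-0.5 so beta remains clampable")
  invisible(cfg)
}

#' Generate a synthetic probe manifest and region sets
#'
#' Lays probes out deterministically on a toy genome: CpG islands on chr1,
#' "shore" territory on chr2 (hosting all enhancer-type intervals), shelves
#' on chr3 (hosting the LAD intervals), open sea on chr4, keratin-gene probes
#' on chr12/chr17, and sex-flagged probes on chrX. ESC and keratinocyte
#' enhancer sets share a configurable fraction (default 25%) of their
#' regions. Each EpSC-gained region carries a region-to-gene map (attribute
#' `gene_map` of that region set).
#'
#' @param config a [cohort_config()].
#' @return list with elements `manifest` (data.frame) and `regions`
#'   (named list of region sets: `LAD`, `ESC_enhancer`, `KC_enhancer`,
#'   `EpSC_gained`, `EpSC_lost`).
#' @export
generate_manifest <- function(config = cohort_config()) {
  cfg <- config
  with_seed(stage_seed(cfg$seed, "manifest"), {
    n <- cfg$n_probes
    n_island <- round(cfg$frac_island * n)
    n_shore <- round(cfg$frac_shore * n)
    n_shelf <- round(cfg$frac_shelf * n)
    n_open <- n - n_island - n_shore - n_shelf

    keratin_genes <- c(head(KERATIN_GENES_CHR12,
                            ceiling(cfg$n_keratin_genes / 2)),
                       head(KERATIN_GENES_CHR17,
                            floor(cfg$n_keratin_genes / 2)))
    if (length(keratin_genes) < cfg$n_keratin_genes)
      stop("at most ", length(KERATIN_GENES_CHR12) +
             length(KERATIN_GENES_CHR17), " keratin genes supported")
    n_keratin_probes <- cfg$n_keratin_genes * cfg$probes_per_keratin

    n_shared <- round(cfg$enhancer_shared_frac * cfg$n_enhancers)
    n_esc_only <- cfg$n_enhancers - n_shared
    n_kc_only <- cfg$n_enhancers - n_shared
    n_enh_regions <- n_esc_only + n_shared + n_kc_only +
      cfg$n_gained + cfg$n_lost
    n_enh_probes <- n_enh_regions * cfg$probes_per_enhancer
    n_shore_plain <- n_shore - n_keratin_probes - n_enh_probes
    if (n_shore_plain < 0)
      stop("infeasible config: shore fraction too small for ",
           n_keratin_probes + n_enh_probes, " keratin/enhancer probes")

    n_sex <- round(cfg$frac_sex * n)
    n_open_auto <- n_open - n_sex
    if (n_open_auto < 0) stop("infeasible config: frac_sex too large")

    rows <- list()
    probe_row <- function(chrom, pos, substructure, genes = "",
                          gene_region = "") {
      data.frame(chrom = chrom, pos = as.integer(pos),
                 context = "CpG", substructure = substructure,
                 genes = genes, gene_region = gene_region,
                 sex = FALSE, snp = FALSE, selfhyb = FALSE,
                 stringsAsFactors = FALSE)
    }
    spacing <- 200L

    # chr1: islands
    rows$island <- probe_row("chr1", 10000L + spacing * seq_len(n_island),
                             "island")

    # chr2: shore plain probes, then enhancer-type intervals with probes
    shore_pos <- 10000L + spacing * seq_len(n_shore_plain)
    rows$shore <- probe_row("chr2", shore_pos, "shore")
    cursor <- max(c(shore_pos, 10000L)) + 5000L
    k <- cfg$probes_per_enhancer
    region_width <- 180L * k + 160L
    enh_labels <- c(rep("esc_only", n_esc_only), rep("shared", n_shared),
                    rep("kc_only", n_kc_only), rep("gained", cfg$n_gained),
                    rep("lost", cfg$n_lost))
    enh_start <- integer(n_enh_regions)
    enh_probe_rows <- vector("list", n_enh_regions)
    for (i in seq_len(n_enh_regions)) {
      st <- cursor
      pos <- st + 150L + 180L * (seq_len(k) - 1L)
      enh_start[i] <- st
      enh_probe_rows[[i]] <- probe_row("chr2", pos, "shore")
      cursor <- st + region_width + 400L
    }
    rows$enhancer <- do.call(rbind, enh_probe_rows)

    # chr12 / chr17: keratin genes, 'shore' probes split promoter/body
    ker_rows <- list()
    for (gi in seq_along(keratin_genes)) {
      g <- keratin_genes[gi]
      chrom <- if (g %in% KERATIN_GENES_CHR12) "chr12" else "chr17"
      base <- 100000L + 10000L * gi
      ppk <- cfg$probes_per_keratin
      n_prom <- ceiling(ppk / 2)
      reg <- c(rep("promoter", n_prom), rep("body", ppk - n_prom))
      ker_rows[[gi]] <- probe_row(chrom, base + spacing * seq_len(ppk),
                                  "shore", genes = g, gene_region = reg)
    }
    rows$keratin <- do.call(rbind, ker_rows)

    # chr3: shelves; LADs cover the leading lad_cover_frac as contiguous runs
    shelf_pos <- 10000L + spacing * seq_len(n_shelf)
    rows$shelf <- probe_row("chr3", shelf_pos, "shelf")
    n_lad_probes <- round(cfg$lad_cover_frac * n_shelf)
    lad <- NULL
    if (n_lad_probes > 0 && cfg$n_lads > 0) {
      run_len <- floor(n_lad_probes / cfg$n_lads)
      starts <- ends <- integer(cfg$n_lads)
      for (li in seq_len(cfg$n_lads)) {
        idx <- ((li - 1) * run_len + 1):(li * run_len)
        starts[li] <- shelf_pos[idx[1]] - 100L
        ends[li] <- shelf_pos[idx[length(idx)]] + 100L
      }
      lad <- data.frame(chrom = "chr3", start = starts, end = ends,
                        region_id = sprintf("LAD_%03d", seq_len(cfg$n_lads)),
                        stringsAsFactors = FALSE)
    } else {
      lad <- data.frame(chrom = character(), start = integer(),
                        end = integer(), region_id = character(),
                        stringsAsFactors = FALSE)
    }
    attr(lad, "name") <- "LAD"

    # chr4 open sea + chrX sex-flagged open sea
    rows$open <- probe_row("chr4", 10000L + spacing * seq_len(n_open_auto),
                           "open_sea")
    if (n_sex > 0) {
      sx <- probe_row("chrX", 10000L + spacing * seq_len(n_sex), "open_sea")
      sx$sex <- TRUE
      rows$sex <- sx
    }

    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    manifest <- cbind(probe_id = sprintf("cg%08d", seq_len(nrow(manifest))),
                      manifest, stringsAsFactors = FALSE)

    # CH context: drawn from plain island / autosomal open-sea probes so the
    # non-CpG channel never collides with gene, enhancer or LAD territory.
    plain_pool <- which(manifest$chrom %in% c("chr1", "chr4") &
                          !nzchar(manifest$genes))
    n_ch <- round(cfg$frac_ch * n)
    if (n_ch > length(plain_pool))
      stop("infeasible config: frac_ch exceeds available plain probes")
    ch_idx <- sort(sample(plain_pool, n_ch))
    manifest$context[ch_idx] <- "CH"

    # snp / self-hybridization flags on plain CpG probes only
    flag_pool <- setdiff(which(manifest$chrom %in% c("chr1", "chr3", "chr4") &
                                 manifest$context == "CpG"), ch_idx)
    n_snp <- round(cfg$frac_snp * n)
    n_shy <- round(cfg$frac_selfhyb * n)
    flagged <- sample(flag_pool, min(n_snp + n_shy, length(flag_pool)))
    manifest$snp[flagged[seq_len(n_snp)]] <- TRUE
    manifest$selfhyb[flagged[n_snp + seq_len(n_shy)]] <- TRUE

    region_df <- function(sel, prefix) {
      idx <- which(enh_labels %in% sel)
      r <- data.frame(chrom = "chr2", start = enh_start[idx],
                      end = enh_start[idx] + region_width,
                      region_id = sprintf("%s_%04d", prefix,
                                          seq_along(idx)),
                      stringsAsFactors = FALSE)
      r
    }
    esc <- region_df(c("esc_only", "shared"), "ESC")
    attr(esc, "name") <- "ESC_enhancer"
    kc <- region_df(c("shared", "kc_only"), "KC")
    attr(kc, "name") <- "KC_enhancer"
    gained <- region_df("gained", "EPSCG")
    attr(gained, "name") <- "EpSC_gained"
    lost <- region_df("lost", "EPSCL")
    attr(lost, "name") <- "EpSC_lost"

    # region -> gene map for the gained set (1-3 synthetic genes each)
    if (nrow(gained) > 0) {
      gene_pool <- sprintf("EPG%04d", seq_len(max(2 * cfg$n_gained, 4)))
      maps <- lapply(seq_len(nrow(gained)), function(i) {
        data.frame(region_id = gained$region_id[i],
                   gene = sample(gene_pool, sample(1:3, 1)),
                   stringsAsFactors = FALSE)
      })
      attr(gained, "gene_map") <- do.call(rbind, maps)
    }

    list(manifest = manifest,
         regions = list(LAD = lad, ESC_enhancer = esc, KC_enhancer = kc,
                        EpSC_gained = gained, EpSC_lost = lost))
  })
}

# Per-probe baseline means: substructure-typical levels plus a per-probe
# jitter shared across samples, kept away from the clamping boundaries.
probe_baselines <- function(manifest, cfg) {
  base <- SUBSTRUCTURE_BASELINES[manifest$substructure]
  base[manifest$context == "CH"] <- CH_BASELINE
  jit <- rnorm(nrow(manifest), 0, cfg$baseline_jitter_sd)
  pmin(pmax(base + jit, 0.02), 0.98)
}

# Signed lesion effect per probe (applied to every AK/cSCC sample).
# LAD-resident probes take the LAD effect in place of their substructure
# effect; CH probes take only the non-CpG channel (responsive half).
lesion_effects <- function(manifest, lad_probes, ch_responsive, cfg) {
  eff <- numeric(nrow(manifest))
  cpg <- manifest$context == "CpG"
  eff[cpg & manifest$substructure == "island"] <- cfg$island_hyper
  eff[cpg & manifest$substructure == "open_sea"] <- cfg$open_sea_hypo
  eff[cpg & manifest$probe_id %in% lad_probes] <- cfg$lad_hypo
  eff[manifest$probe_id %in% ch_responsive] <- cfg$ch_gain
  eff
}

#' Generate a synthetic cohort
#'
#' Healthy samples are drawn around substructure-typical baselines. Lesion
#' (AK/cSCC) samples receive the configured island/open-sea/LAD/non-CpG
#' shifts; a fixed fraction (default half) of lesion samples in each group is
#' additionally assigned the latent EpSC-like subclass, which is planted in
#' three independent channels: hypomethylated ESC-specific enhancer probes,
#' hypermethylated EpSC-gained enhancer probes, and hypomethylated keratin
#' promoter probes — plus, when a clock is supplied, an extra shift of the
#' clock-probe signal toward a younger predicted age. All lesion samples get
#' the baseline clock youthening (`age_shift`, default 15 years). The ground
#' truth (latent subclass, responsive CH probes, per-sample clock target age)
#' is returned separately and is never an input to any analysis routine.
#'
#' @param bundle result of [generate_manifest()].
#' @param config the same [cohort_config()].
#' @param clock optional `clock_model` from [generate_clock()]; when given,
#'   clock-probe rows are overwritten with an exact age embedding before
#'   noise is added.
#' @return list with `beta` (matrix), `samples` (sample sheet including
#'   `latent_subclass` truth), `truth` (list: `ch_responsive`, `target_age`),
#'   and `n_clamped` (count of values clamped into \[0, 1\]).
#' @export
generate_cohort <- function(bundle, config = cohort_config(), clock = NULL) {
  cfg <- config
  manifest <- bundle$manifest
  regions <- bundle$regions
  with_seed(stage_seed(cfg$seed, "cohort"), {
    lad_probes <- unique(unlist(probes_in_regions(manifest, regions$LAD)))
    esc_probes <- unique(unlist(probes_in_regions(manifest,
                                                  regions$ESC_enhancer)))
    kc_probes <- unique(unlist(probes_in_regions(manifest,
                                                 regions$KC_enhancer)))
    esc_only <- setdiff(esc_probes, kc_probes)
    gained_probes <- unique(unlist(probes_in_regions(manifest,
                                                     regions$EpSC_gained)))
    pg <- probe_gene_map(manifest)
    ker_prom <- pg$probe_id[grepl("^KRT", pg$gene) &
                              pg$gene_region == "promoter"]

    ch_all <- manifest$probe_id[manifest$context == "CH"]
    ch_responsive <- sort(sample(ch_all, round(length(ch_all) / 2)))

    ids <- c(sprintf("H%02d", seq_len(cfg$n_healthy)),
             sprintf("AK%02d", seq_len(cfg$n_ak)),
             sprintf("SCC%02d", seq_len(cfg$n_cscc)))
    grp <- c(rep("healthy", cfg$n_healthy), rep("AK", cfg$n_ak),
             rep("cSCC", cfg$n_cscc))
    age <- c(round(runif(cfg$n_healthy, 40, 70)),
             round(runif(cfg$n_ak + cfg$n_cscc, 60, 85)))
    subclass <- rep(NA_character_, length(ids))
    for (g in c("AK", "cSCC")) {
      idx <- which(grp == g)
      n_epsc <- round(cfg$subclass_fraction * length(idx))
      epsc <- sample(idx, n_epsc)
      subclass[idx] <- "keratinocyte_like"
      subclass[epsc] <- "EpSC_like"
    }
    samples <- data.frame(sample_id = ids, group = grp,
                          chronological_age = age,
                          latent_subclass = subclass,
                          stringsAsFactors = FALSE)

    base <- probe_baselines(manifest, cfg)
    eff <- lesion_effects(manifest, lad_probes, ch_responsive, cfg)
    mu <- matrix(base, nrow = nrow(manifest), ncol = length(ids),
                 dimnames = list(manifest$probe_id, ids))
    lesion <- grp %in% c("AK", "cSCC")
    mu[, lesion] <- mu[, lesion] + eff

    sep <- cfg$subclass_separation
    epsc_cols <- which(!is.na(subclass) & subclass == "EpSC_like")
    if (length(epsc_cols)) {
      mu[esc_only, epsc_cols] <- mu[esc_only, epsc_cols] - sep
      mu[gained_probes, epsc_cols] <- mu[gained_probes, epsc_cols] + sep
      mu[ker_prom, epsc_cols] <- mu[ker_prom, epsc_cols] - sep
    }

    target_age <- age
    target_age[lesion] <- target_age[lesion] - cfg$age_shift
    target_age[epsc_cols] <- target_age[epsc_cols] - cfg$epsc_extra_age_shift
    if (!is.null(clock)) {
      cp <- names(clock$weights)
      missing_cp <- setdiff(cp, manifest$probe_id)
      if (length(missing_cp))
        stop("clock probes absent from manifest: ", missing_cp[1])
      for (j in seq_along(ids))
        mu[cp, j] <- clock_embed_beta(clock, target_age[j])
    }

    noise <- if (cfg$noise_sd > 0)
      matrix(rnorm(length(mu), 0, cfg$noise_sd), nrow = nrow(mu)) else 0
    beta <- clamp01(mu + noise)
    n_clamped <- attr(beta, "n_clamped")
    attr(beta, "n_clamped") <- NULL
    dimnames(beta) <- dimnames(mu)

    list(beta = beta, samples = samples,
         truth = list(ch_responsive = ch_responsive,
                      target_age = setNames(target_age, ids)),
         n_clamped = n_clamped)
  })
}

#' Generate reference methylomes
#'
#' Four single-sample reference profiles: an embryonic stem cell (ESC)
#' profile hypomethylated at ESC enhancers, a keratinocyte profile
#' hypomethylated at keratinocyte enhancers, and epidermal stem cell (EpSC) /
#' differentiated keratinocyte profiles that differ at the EpSC-gained and
#' EpSC-lost enhancer sets, by the configured `reference_margin`.
#'
#' @inheritParams generate_cohort
#' @return list with `beta` (probes x 4 matrix) and `samples` (sheet with
#'   `reference_*` groups).
#' @export
generate_references <- function(bundle, config = cohort_config()) {
  cfg <- config
  manifest <- bundle$manifest
  regions <- bundle$regions
  with_seed(stage_seed(cfg$seed, "references"), {
    esc_probes <- unique(unlist(probes_in_regions(manifest,
                                                  regions$ESC_enhancer)))
    kc_probes <- unique(unlist(probes_in_regions(manifest,
                                                 regions$KC_enhancer)))
    gained_probes <- unique(unlist(probes_in_regions(manifest,
                                                     regions$EpSC_gained)))
    lost_probes <- unique(unlist(probes_in_regions(manifest,
                                                   regions$EpSC_lost)))
    base <- SUBSTRUCTURE_BASELINES[manifest$substructure]
    base[manifest$context == "CH"] <- CH_BASELINE
    m <- cfg$reference_margin
    ids <- c("ref_ESC", "ref_KC", "ref_EpSC", "ref_diffKC")
    mu <- matrix(base, nrow = nrow(manifest), ncol = 4,
                 dimnames = list(manifest$probe_id, ids))
    set_low <- function(col, probes) {
      mu[probes, col] <<- mu[probes, col] - m
    }
    set_low("ref_ESC", esc_probes)
    set_low("ref_KC", kc_probes)
    set_low("ref_EpSC", gained_probes)
    set_low("ref_diffKC", lost_probes)
    noise <- if (cfg$reference_noise_sd > 0)
      matrix(rnorm(length(mu), 0, cfg$reference_noise_sd),
             nrow = nrow(mu)) else 0
    beta <- clamp01(mu + noise)
    n_clamped <- attr(beta, "n_clamped")
    attr(beta, "n_clamped") <- NULL
    dimnames(beta) <- dimnames(mu)
    samples <- data.frame(
      sample_id = ids,
      group = c("reference_ESC", "reference_keratinocyte",
                "reference_EpSC", "reference_diffKC"),
      chronological_age = NA_real_, latent_subclass = NA_character_,
      stringsAsFactors = FALSE)
    list(beta = beta, samples = samples, n_clamped = n_clamped)
  })
}

#' Generate a synthetic methylation clock
#'
#' Draws sparse uniform weights over autosomal open-sea CpG probes carrying
#' no gene links, with the intercept chosen so that the all-`0.5` methylation
#' pattern scores exactly the transform pivot (predicted age =
#' `adult_age`). [clock_embed_beta()] can then produce, for any requested
#' age, a beta pattern whose linear score equals the transformed age exactly.
#'
#' @param manifest probe manifest (from [generate_manifest()]).
#' @param n_clock_probes number of clock probes (default 50).
#' @param adult_age transform pivot in years.
#' @param seed RNG seed.
#' @return a `clock_model`.
#' @export
generate_clock <- function(manifest, n_clock_probes = 50, adult_age = 20,
                           seed = 1L) {
  with_seed(stage_seed(seed, "clock"), {
    pool <- manifest$probe_id[manifest$chrom == "chr4" &
                                manifest$context == "CpG" &
                                !nzchar(manifest$genes) &
                                !(manifest$snp | manifest$selfhyb)]
    if (length(pool) < n_clock_probes)
      stop("not enough eligible open-sea probes for a ", n_clock_probes,
           "-probe clock")
    probes <- sort(sample(pool, n_clock_probes))
    w <- runif(n_clock_probes, -1, 1)
    # keep the embedding's per-probe excursions small
    while (sum(w^2) < n_clock_probes / 10) w <- runif(n_clock_probes, -1, 1)
    intercept <- -sum(w * 0.5)
    clock_model(intercept, setNames(w, probes), adult_age)
  })
}

#' Exact-age beta embedding for a clock
#'
#' Returns a beta pattern over the clock's probes whose linear score
#' `intercept + sum(w * beta)` equals `age_transform(age)` exactly: the
#' minimal-norm correction of the flat `0.5` profile along the weight vector.
#'
#' @param clock a `clock_model`.
#' @param age target age in years (> -1).
#' @return named numeric vector over the clock probes.
#' @export
clock_embed_beta <- function(clock, age) {
  w <- clock$weights
  s <- age_transform(age, clock$adult_age)
  alpha <- s - clock$intercept - sum(w * 0.5)
  beta <- 0.5 + alpha * w / sum(w^2)
  if (any(beta < 0 | beta > 1))
    warning("clock embedding left [0,1] for age ", age, "; clamped")
  out <- pmin(pmax(beta, 0), 1)
  setNames(out, names(w))
}

#' Generate an annotated somatic-variant table
#'
#' Marginal rates for blacklist-overlap flags, Platypus filters, depth and
#' population frequencies come from `config$variant_rates`. The last three
#' rows are deterministic edge cases: a dbSNP-common variant rescued by an
#' OMIM record, an SNV with exactly two deductible categories (score 8, the
#' retention boundary), and an indel with three Platypus filters (score 7,
#' just excluded).
#'
#' @param n number of variants (>= 3).
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return variant `data.frame` in [read_variants()] layout.
#' @export
generate_variants <- function(n, config = cohort_config(), seed = 1L) {
  stopifnot(n >= 3)
  r <- config$variant_rates
  with_seed(stage_seed(seed, "variants"), {
    m <- n - 3L
    draw <- function(p) as.logical(rbinom(m, 1, p))
    kind <- ifelse(runif(m) < r$indel_fraction, "indel", "SNV")
    platypus <- vapply(seq_len(m), function(i) {
      if (kind[i] != "indel") return("")
      set <- PLATYPUS_FLAGS[runif(length(PLATYPUS_FLAGS)) < r$platypus]
      paste(set, collapse = ",")
    }, character(1))
    common <- draw(r$dbsnp_common)
    omim <- common & as.logical(rbinom(m, 1, r$omim_given_common))
    rare_af <- function() ifelse(runif(m) < r$rare_pop, runif(m, 0, 0.05), 0)
    v <- data.frame(
      chrom = paste0("chr", sample(1:22, m, replace = TRUE)),
      pos = sample.int(5e7, m),
      ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      kind = kind,
      repeats = draw(r$repeats),
      duke_excluded = draw(r$duke_excluded),
      dac_blacklist = draw(r$dac_blacklist),
      self_chain = draw(r$self_chain),
      segmental_duplication = draw(r$segmental_duplication),
      platypus_filters = platypus,
      depth = rnbinom(m, size = config$depth_size, mu = config$depth_mean),
      properly_mapped = !draw(r$improper_map),
      dbsnp_common = common,
      omim_record = omim,
      exac_af = rare_af(), evs_af = rare_af(), inhouse_af = rare_af(),
      coding = !draw(r$noncoding),
      stringsAsFactors = FALSE)
    edge <- data.frame(
      chrom = rep("chr1", 3), pos = c(1001L, 1002L, 1003L),
      ref = c("A", "C", "G"), alt = c("T", "G", "GA"),
      kind = c("SNV", "SNV", "indel"),
      repeats = c(FALSE, TRUE, FALSE),
      duke_excluded = FALSE,
      dac_blacklist = c(FALSE, TRUE, FALSE),
      self_chain = FALSE, segmental_duplication = FALSE,
      platypus_filters = c("", "", "alleleBias,MQ,strandBias"),
      depth = c(180L, 180L, 180L), properly_mapped = TRUE,
      dbsnp_common = c(TRUE, FALSE, FALSE),
      omim_record = c(TRUE, FALSE, FALSE),
      exac_af = 0, evs_af = 0, inhouse_af = 0, coding = TRUE,
      stringsAsFactors = FALSE)
    out <- rbind(v, edge)
    rownames(out) <- NULL
    validate_variants(out)
    out
  })
}
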