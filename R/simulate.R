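# Synthetic microcosm and environmental-series generators with known
# ground truth. The microcosm emulates the study design the pipeline
# targets: 3 treatments x 3 replicate flasks x days 0-7, a background
# community of roughly constant density (total ~1e6 cells/mL), planted
# treatment responders following logistic growth from day 1 that saturates
# by the end of the middle phase, viral particle bursts lagging host growth
# by 0-2 days with burst-size-scaled amplitude, and compositional
# (multinomial) read sampling at realistic depths.

#' Configuration of the synthetic generators
#'
#' @param n_background_asvs Background ASVs (near-constant density).
#' @param n_responders Named integer vector: planted responders per class
#'   (`CIF`, `HIF`, `both`, `all`).
#' @param background_total Total background density, cells/mL.
#' @param background_sdlog Spread (sdlog) of background densities.
#' @param responder_baseline Day-0 density of each responder, cells/mL.
#' @param responder_enrichment Carrying capacity as a multiple of the
#'   baseline (default 10).
#' @param growth_rate Logistic growth rate, 1/day.
#' @param lag_day Day growth starts; the default 0 makes responders grow
#'   within the first day and saturate by the end of the middle phase.
#' @param noise_sdlog Lognormal multiplicative noise on latent densities.
#' @param depth_amplicon Amplicon reads per sample (multinomial draws).
#' @param depth_virome Virome reads per sample.
#' @param n_background_votus Background vOTUs (near-constant density).
#' @param background_viral_total Total background vOTU density,
#'   particles/mL.
#' @param votus_per_responder Planted vOTUs per responder host.
#' @param votu_baseline Day-0 density of planted vOTUs, particles/mL.
#' @param burst_size Particles released per lysed host cell; burst
#'   amplitude is `burst_size` times the host density increment (marine
#'   phages average 50-185 particles per cell, ~100 used here).
#' @param burst_lag_max Maximum lag (days) of the viral burst behind host
#'   growth; lags are drawn uniformly from 0..`burst_lag_max`.
#' @param lysogenic_per_treatment Planted lysogenic vOTUs per treatment
#'   class; these track host density with no burst.
#' @param noncatalog_viral Density of assembled >1 kb viral scaffolds
#'   outside the >10 kb vOTU catalogue, particles/mL.
#' @param uncatalogued_viral Density of viral particles whose reads map to
#'   no assembled scaffold (potential virus-derived reads), particles/mL.
#' @param virome_days Days with virome sampling.
#' @param measurement_sdlog Lognormal measurement noise on FPKM/cytometry.
#' @param n_timepoints Environmental time points (monthly).
#' @param n_env_pairs Planted correlated host-virus pairs in the
#'   environmental series.
#' @param env_strength Latent association strength of planted pairs
#'   (Pearson scale of the Gaussian copula, approximately the Spearman r).
#' @param n_env_null Uncorrelated environmental ASVs and vOTUs (each).
#' @return Named list classed `sim_config`.
#' @export
sim_config <- function(n_background_asvs = 80L,
                       n_responders = c(CIF = 5L, HIF = 8L, both = 2L, all = 3L),
                       background_total = 1e6,
                       background_sdlog = 1.2,
                       responder_baseline = 5e3,
                       responder_enrichment = 10,
                       growth_rate = 3,
                       lag_day = 0,
                       noise_sdlog = 0.2,
                       depth_amplicon = 20000L,
                       depth_virome = 2e6,
                       n_background_votus = 40L,
                       background_viral_total = 1.4e6,
                       votus_per_responder = 2L,
                       votu_baseline = 4.5e3,
                       burst_size = 100,
                       burst_lag_max = 2L,
                       lysogenic_per_treatment = 1L,
                       noncatalog_viral = 2e5,
                       uncatalogued_viral = 4e5,
                       virome_days = c(0L, 1L, 3L, 5L, 7L),
                       measurement_sdlog = 0.05,
                       n_timepoints = 17L,
                       n_env_pairs = 5L,
                       env_strength = 0.9,
                       n_env_null = 10L) {
  cfg <- as.list(environment())
  for (f in c("n_background_asvs", "background_total", "depth_amplicon",
              "depth_virome", "n_background_votus")) {
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] < 1) {
      bt_stop("sim config field '", f, "' must be >= 1")
    }
  }
  if (cfg$n_timepoints < 5L) bt_stop("n_timepoints must be >= 5")
  for (cl in c("CIF", "HIF", "both", "all")) {
    if (is.na(cfg$n_responders[cl])) cfg$n_responders[cl] <- 0L
  }
  structure(cfg, class = "sim_config")
}

#' Deterministic logistic growth curve
#' @noRd
logistic_density <- function(day, n0, k, rate, lag) {
  ifelse(day <= lag, n0, k / (1 + ((k - n0) / n0) * exp(-rate * (day - lag))))
}

#' Treatments in which a responder class grows
#' @noRd
class_treatments <- function(class) {
  switch(class,
         CIF = "CIF", HIF = "HIF",
         both = c("CIF", "HIF"),
         all = c("control", "CIF", "HIF"),
         character(0))
}

#' Simulate a full microcosm experiment with known ground truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with `dataset` (a validated [bloom_dataset()]) and `truth`
#'   (responder/vOTU ground truth plus the latent density arrays before
#'   read sampling).
#' @export
simulate_microcosm <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  with_seed(seed, {
    days <- 0:7
    grid <- expand.grid(replicate = REPLICATES, treatment = TREATMENTS,
                        day = days, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[order(match(grid$treatment, TREATMENTS),
                       match(grid$replicate, REPLICATES), grid$day), ]
    grid$sample_id <- sprintf("%s_%s_d%d", grid$treatment, grid$replicate, grid$day)

    # --- planted ASV truth ---------------------------------------------
    classes <- rep(names(cfg$n_responders), cfg$n_responders)
    n_resp <- length(classes)
    resp_ids <- sprintf("ASV_resp_%s_%02d", classes, seq_len(n_resp))
    bg_ids <- sprintf("ASV_bg_%03d", seq_len(cfg$n_background_asvs))
    bg_base <- stats::rlnorm(cfg$n_background_asvs, sdlog = cfg$background_sdlog)
    bg_base <- bg_base / sum(bg_base) * cfg$background_total
    names(bg_base) <- bg_ids
    truth_asv <- data.frame(
      feature_id = resp_ids, responder_class = classes,
      baseline = rep(cfg$responder_baseline, n_resp),
      carrying_capacity = rep(cfg$responder_baseline * cfg$responder_enrichment,
                              n_resp),
      growth_rate = rep(cfg$growth_rate, n_resp),
      lag_day = rep(cfg$lag_day, n_resp),
      stringsAsFactors = FALSE)

    asv_ids <- c(bg_ids, resp_ids)
    latent <- matrix(0, nrow = length(asv_ids), ncol = nrow(grid),
                     dimnames = list(asv_ids, grid$sample_id))
    for (s in seq_len(nrow(grid))) {
      tr <- grid$treatment[s]; d <- grid$day[s]
      dens <- c(bg_base, vapply(seq_len(n_resp), function(j) {
        if (tr %in% class_treatments(classes[j])) {
          logistic_density(d, cfg$responder_baseline,
                           cfg$responder_baseline * cfg$responder_enrichment,
                           cfg$growth_rate, cfg$lag_day)
        } else cfg$responder_baseline
      }, numeric(1)))
      latent[, s] <- dens * stats::rlnorm(length(dens), sdlog = cfg$noise_sdlog)
    }

    counts <- matrix(0, nrow = length(asv_ids), ncol = nrow(grid),
                     dimnames = list(asv_ids, grid$sample_id))
    for (s in seq_len(nrow(grid))) {
      counts[, s] <- stats::rmultinom(1L, cfg$depth_amplicon,
                                      latent[, s] / sum(latent[, s]))
    }

    # --- planted vOTU truth --------------------------------------------
    host_pool <- truth_asv$feature_id
    votu_rows <- list()
    k <- 0L
    for (j in seq_along(host_pool)) {
      for (v in seq_len(cfg$votus_per_responder)) {
        k <- k + 1L
        votu_rows[[k]] <- data.frame(
          votu_id = sprintf("vOTU_resp_%03d", k),
          host_asv = host_pool[j], responder_class = classes[j],
          burst_lag = sample.int(cfg$burst_lag_max + 1L, 1L) - 1L,
          lysogenic = FALSE, stringsAsFactors = FALSE)
      }
    }
    # lysogenic planted vOTUs track their host with no burst
    for (cl in c("CIF", "HIF")) {
      hosts_cl <- host_pool[classes == cl]
      if (cfg$lysogenic_per_treatment > 0L && length(hosts_cl)) {
        for (l in seq_len(cfg$lysogenic_per_treatment)) {
          k <- k + 1L
          votu_rows[[k]] <- data.frame(
            votu_id = sprintf("vOTU_lyso_%03d", k),
            host_asv = hosts_cl[1L + (l - 1L) %% length(hosts_cl)],
            responder_class = cl, burst_lag = NA_integer_,
            lysogenic = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    truth_votu <- if (k > 0L) do.call(rbind, votu_rows) else
      data.frame(votu_id = character(0), host_asv = character(0),
                 responder_class = character(0), burst_lag = integer(0),
                 lysogenic = logical(0), stringsAsFactors = FALSE)
    bgv_ids <- sprintf("vOTU_bg_%03d", seq_len(cfg$n_background_votus))
    bgv_base <- stats::rlnorm(cfg$n_background_votus, sdlog = cfg$background_sdlog)
    bgv_base <- bgv_base / sum(bgv_base) * cfg$background_viral_total
    names(bgv_base) <- bgv_ids
    votu_ids <- c(bgv_ids, truth_votu$votu_id)

    latent_v <- matrix(0, nrow = length(votu_ids), ncol = nrow(grid),
                       dimnames = list(votu_ids, grid$sample_id))
    for (s in seq_len(nrow(grid))) {
      tr <- grid$treatment[s]; d <- grid$day[s]
      dens <- c(bgv_base, vapply(seq_len(nrow(truth_votu)), function(m) {
        host_grows <- tr %in% class_treatments(truth_votu$responder_class[m])
        n0 <- cfg$responder_baseline
        k_cap <- cfg$responder_baseline * cfg$responder_enrichment
        if (truth_votu$lysogenic[m]) {
          host <- if (host_grows) {
            logistic_density(d, n0, k_cap, cfg$growth_rate, cfg$lag_day)
          } else n0
          0.1 * host
        } else if (host_grows) {
          dd <- d - truth_votu$burst_lag[m]
          inc <- if (dd >= 0) {
            logistic_density(dd, n0, k_cap, cfg$growth_rate, cfg$lag_day) - n0
          } else 0
          cfg$votu_baseline + cfg$burst_size * inc
        } else cfg$votu_baseline
      }, numeric(1)))
      latent_v[, s] <- dens * stats::rlnorm(length(dens), sdlog = cfg$noise_sdlog)
    }

    # --- cytometry totals ----------------------------------------------
    cyt <- grid[, c("treatment", "replicate", "day")]
    cyt$cells_per_ml <- colSums(latent)
    cyt$particles_per_ml <- colSums(latent_v) + cfg$noncatalog_viral +
      cfg$uncatalogued_viral

    # --- virome quantification (subset of days) ------------------------
    vs <- grid$day %in% cfg$virome_days
    vcols <- grid$sample_id[vs]
    measured <- latent_v[, vcols, drop = FALSE] *
      stats::rlnorm(length(latent_v[, vcols]), sdlog = cfg$measurement_sdlog)
    f_scale <- 1e-3
    fpkm_mat <- measured * f_scale
    c_tot <- colSums(measured)
    si <- data.frame(
      sample_id = vcols,
      fpkm_viral_total = (c_tot + cfg$noncatalog_viral) * f_scale,
      r_viral = round(cfg$depth_virome * (c_tot + cfg$noncatalog_viral) /
                        (c_tot + cfg$noncatalog_viral + cfg$uncatalogued_viral)),
      stringsAsFactors = FALSE)
    si$r_potential <- cfg$depth_virome - si$r_viral
    lengths_bp <- stats::setNames(
      10000L + 500L * (seq_along(votu_ids) %% 50L), votu_ids)

    # --- taxonomy and host predictions ---------------------------------
    phyla <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes")
    tax <- data.frame(
      feature_id = asv_ids,
      domain = "Bacteria",
      phylum = phyla[1L + (seq_along(asv_ids) %% length(phyla))],
      class = "", order = "", family = "", genus = "",
      confidence = 0.95, stringsAsFactors = FALSE)
    # each responder gets its own genus so host prediction can single it out
    is_resp <- tax$feature_id %in% resp_ids
    tax$class[is_resp] <- paste0("Class_", tax$feature_id[is_resp])
    tax$order[is_resp] <- paste0("Order_", tax$feature_id[is_resp])
    tax$family[is_resp] <- paste0("Family_", tax$feature_id[is_resp])
    tax$genus[is_resp] <- paste0("Genus_", tax$feature_id[is_resp])
    host <- data.frame(
      votu_id = votu_ids,
      host_rank = c(rep("", length(bgv_ids)),
                    rep("genus", nrow(truth_votu))),
      host_taxon = c(rep("", length(bgv_ids)),
                     paste0("Genus_", truth_votu$host_asv, recycle0 = TRUE)),
      gotu = sprintf("g%03d", 1L + (seq_along(votu_ids) %% 20L)),
      lysogenic = c(rep(FALSE, length(bgv_ids)), truth_votu$lysogenic),
      stringsAsFactors = FALSE)

    metadata <- sample_metadata(grid[, c("sample_id", "treatment", "replicate", "day")])
    ds <- bloom_dataset(
      counts = feature_table(counts),
      metadata = metadata,
      taxonomy = taxonomy_table(tax),
      cytometry = cytometry_counts(cyt),
      votu = votu_quant(fpkm_mat, lengths_bp, si),
      host = host_prediction(host))
    attr(ds, "seed") <- seed
    truth <- list(asv = truth_asv, votu = truth_votu,
                  latent_cells = latent, latent_particles = latent_v,
                  seed = seed)
    list(dataset = ds, truth = truth)
  })
}

#' Simulate an environmental monthly series with planted correlated pairs
#'
#' Planted pairs share a standardized seasonal latent signal through a
#' Gaussian copula: with strength `a`, both members load `sqrt(a)` on the
#' shared signal and `sqrt(1-a)` on independent noise, so their latent
#' Pearson correlation is `a` (and the Spearman correlation close to it).
#' The latent variables are mapped through exponential (monotone)
#' transforms to relative-abundance and FPKM scales, which leaves Spearman
#' correlations untouched. Null features are independent.
#'
#' @param config A [sim_config()] (uses `n_timepoints`, `n_env_pairs`,
#'   `env_strength`, `n_env_null`).
#' @param seed Integer seed.
#' @param asv_ids,votu_ids Optional feature ids to build the series for
#'   (e.g. the features of a simulated microcosm). When omitted, generic
#'   `envASV_pair_*` / `envASV_null_*` ids are generated from
#'   `n_env_pairs` and `n_env_null`.
#' @param pairs Optional data frame with columns `asv_id` and `votu_id`
#'   naming which of the supplied features form correlated pairs (an ASV
#'   may host several vOTUs; they then share its seasonal signal). Only
#'   used together with `asv_ids`/`votu_ids`.
#' @return List with `env` (an [env_series()]) and `truth` (data frame of
#'   planted pairs with their strengths; null features have no row).
#' @export
simulate_environment <- function(config = sim_config(), seed = 1L,
                                 asv_ids = NULL, votu_ids = NULL,
                                 pairs = NULL) {
  cfg <- config
  if (cfg$n_timepoints < 5L) bt_stop("n_timepoints must be >= 5")
  if (is.null(asv_ids) != is.null(votu_ids)) {
    bt_stop("supply asv_ids and votu_ids together")
  }
  if (is.null(asv_ids)) {
    asv_ids <- c(sprintf("envASV_pair_%02d", seq_len(cfg$n_env_pairs)),
                 sprintf("envASV_null_%02d", seq_len(cfg$n_env_null)))
    votu_ids <- c(sprintf("envvOTU_pair_%02d", seq_len(cfg$n_env_pairs)),
                  sprintf("envvOTU_null_%02d", seq_len(cfg$n_env_null)))
    pairs <- data.frame(asv_id = asv_ids[seq_len(cfg$n_env_pairs)],
                        votu_id = votu_ids[seq_len(cfg$n_env_pairs)],
                        stringsAsFactors = FALSE)
  } else if (is.null(pairs)) {
    pairs <- data.frame(asv_id = character(0), votu_id = character(0),
                        stringsAsFactors = FALSE)
  }
  bad <- !(pairs$asv_id %in% asv_ids) | !(pairs$votu_id %in% votu_ids)
  if (any(bad)) bt_stop("pairs reference unknown feature ids")
  with_seed(seed, {
    nt <- cfg$n_timepoints
    tp <- sprintf("t%02d", seq_len(nt))
    a <- cfg$env_strength
    season <- sin(2 * pi * seq_len(nt) / 12)
    mk_latent <- function() {
      z <- season + 0.5 * stats::rnorm(nt)
      (z - mean(z)) / stats::sd(z)
    }
    # one shared seasonal signal per host ASV that appears in any pair
    paired_asvs <- unique(pairs$asv_id)
    signal <- lapply(stats::setNames(paired_asvs, paired_asvs),
                     function(id) mk_latent())
    load_on <- function(z) {
      if (a >= 1) z else sqrt(a) * z + sqrt(1 - a) * stats::rnorm(nt)
    }
    asv <- t(vapply(asv_ids, function(id) {
      x <- if (id %in% paired_asvs) load_on(signal[[id]]) else stats::rnorm(nt)
      exp(-4.6 + x)
    }, numeric(nt)))
    host_of <- stats::setNames(pairs$asv_id, pairs$votu_id)
    votu <- t(vapply(votu_ids, function(id) {
      y <- if (id %in% names(host_of)) load_on(signal[[host_of[[id]]]])
      else stats::rnorm(nt)
      exp(log(10) + y)
    }, numeric(nt)))
    colnames(asv) <- colnames(votu) <- tp
    truth <- pairs
    truth$strength <- rep(a, nrow(pairs))
    truth$seed <- rep(seed, nrow(pairs))
    list(env = env_series(asv, votu), truth = truth)
  })
}
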