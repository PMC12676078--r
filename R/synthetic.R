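#' Community-effect specification for the count-table generator
#'
#' Bundles the effect magnitudes and noise model of the simulated amplicon
#' experiment. Counts are Dirichlet-multinomial: per-sample expected
#' composition logits are taxon baseline + genotype loading + environmental
#' response + block shift; `dispersion` scales the Dirichlet concentration
#' (smaller = more overdispersed replicates).
#'
#' @param n_taxa Number of taxa the marker observes.
#' @param genotype_sd SD of per-genotype taxon log-loadings (the host
#'   genotype effect). The default was fixed by [calibrate_genotype_sd()]
#'   so that the genotype term explains 21-31% of Bray-Curtis variation at
#'   the default design (40 genotypes x 5 replicates).
#' @param env_responders Fraction of taxa whose abundance responds to
#'   historic soil nitrogen.
#' @param env_beta Log-abundance slope per standardized soil-nitrogen unit
#'   for responder taxa (random sign per taxon). Default fixed by
#'   [calibrate_env_beta()] against a ~1-3% conditioned-dbRDA share.
#' @param block_sd SD of per-block taxon log-shifts (glasshouse rack
#'   effects).
#' @param depth Sequencing depth (library size) per sample.
#' @param dispersion Dirichlet concentration total; concentration =
#'   `dispersion` x expected proportions.
#' @param baseline_sd SD of taxon baseline logits (abundance skew).
#' @param richness_gradient Length-2 numeric `(rich_lowN, rich_highN)`:
#'   expected number of occupied flagged diazotroph taxa at the historic
#'   soil-nitrogen extremes, interpolated linearly in between; `NULL`
#'   disables occupancy thinning.
#' @param group_ra_gradient Length-2 numeric `(ra_lowN, ra_highN)` in
#'   (0,1): expected summed relative abundance of flagged ammonia-oxidizer
#'   taxa at the soil-nitrogen extremes; `NULL` disables.
#' @return A list of class `community_effect_spec`.
#' @export
community_effect_spec <- function(n_taxa = 400,
                                  genotype_sd = 0.14,
                                  env_responders = 0.3,
                                  env_beta = 0.315,
                                  block_sd = 0.15,
                                  depth = 2000,
                                  dispersion = 300,
                                  baseline_sd = 1.2,
                                  richness_gradient = NULL,
                                  group_ra_gradient = NULL) {
  assert_scalar_number(n_taxa, "n_taxa", lower = 2)
  assert_scalar_number(env_responders, "env_responders", 0, 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(dispersion, "dispersion", lower = 1e-8)
  for (nm in c("genotype_sd", "env_beta", "block_sd", "baseline_sd")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  if (!is.null(richness_gradient)) {
    stopifnot(length(richness_gradient) == 2, all(richness_gradient > 0))
  }
  if (!is.null(group_ra_gradient)) {
    stopifnot(length(group_ra_gradient) == 2,
              all(group_ra_gradient > 0), all(group_ra_gradient < 1))
  }
  structure(list(n_taxa = as.integer(n_taxa), genotype_sd = genotype_sd,
                 env_responders = env_responders, env_beta = env_beta,
                 block_sd = block_sd, depth = as.integer(depth),
                 dispersion = dispersion, baseline_sd = baseline_sd,
                 richness_gradient = richness_gradient,
                 group_ra_gradient = group_ra_gradient),
            class = "community_effect_spec")
}

#' Trait-effect specification for the factorial nitrogen-by-microbe
#' experiment generator
#'
#' Trait values are `baseline * (1 + nitrogen_effect * highN) *
#' (1 + ME(g, e) * live) + baseline * (genotype + block + residual noise)`,
#' where the expected microbial effect for genotype `g` under glasshouse
#' nitrogen level `e` is `microbe_effect + me_slope_e * soil_nitrogen_z(g)`.
#' SD parameters are relative (coefficients of variation on the baseline).
#'
#' @param baseline Named numeric: expected low-N sterile trait values
#'   (`height` in cm, `biomass` in g).
#' @param nitrogen_effect Proportional trait increase under high glasshouse
#'   nitrogen.
#' @param microbe_effect Baseline microbial effect (response-ratio units).
#' @param me_slope_low,me_slope_high Slope of the expected microbial effect
#'   on standardized historic soil nitrogen within the low- and high-N
#'   glasshouse treatments.
#' @param genotype_sd,block_sd,residual_sd Relative SDs of genotype random
#'   intercepts, block random intercepts, and plant-level noise.
#' @param tiller_logit_coefs Named numeric logit coefficients
#'   (`intercept`, `nitrogen`, `microbe`) for tillering status.
#' @return A list of class `trait_effect_spec`.
#' @export
trait_effect_spec <- function(baseline = c(height = 20, biomass = 0.8),
                              nitrogen_effect = 0.5,
                              microbe_effect = 0.2,
                              me_slope_low = -0.15,
                              me_slope_high = 0.15,
                              genotype_sd = 0.06,
                              block_sd = 0.04,
                              residual_sd = 0.12,
                              tiller_logit_coefs = c(intercept = -0.5,
                                                     nitrogen = 1.2,
                                                     microbe = 0.6)) {
  stopifnot(all(baseline > 0), residual_sd > 0)
  structure(list(baseline = baseline, nitrogen_effect = nitrogen_effect,
                 microbe_effect = microbe_effect,
                 me_slope_low = me_slope_low, me_slope_high = me_slope_high,
                 genotype_sd = genotype_sd, block_sd = block_sd,
                 residual_sd = residual_sd,
                 tiller_logit_coefs = tiller_logit_coefs),
            class = "trait_effect_spec")
}

#' Default cross-correlation of the historic-environment variables
#'
#' Soil variables correlate moderately with each other, precipitation
#' variables strongly with each other, and temperature weakly negatively
#' with precipitation, mimicking gridded climate/soil products.
#'
#' @return A 9 x 9 positive-definite correlation matrix over the
#'   environment variables.
#' @export
default_env_corr <- function() {
  v <- env_vars
  m <- diag(length(v))
  dimnames(m) <- list(v, v)
  soil <- c("soil_nitrogen", "soil_phosphorus", "cec", "ph")
  prec <- c("precip_spring", "precip_summer", "precip_fall",
            "mean_annual_precip")
  m[soil, soil] <- 0.3
  m[prec, prec] <- 0.6
  m["mean_annual_temp", prec] <- -0.2
  m[prec, "mean_annual_temp"] <- -0.2
  diag(m) <- 1
  m
}

# n x k matrix of standard-normal fields with exponential spatial
# covariance exp(-d / range_km) over the supplied coordinates, plus a
# nugget fraction of white noise (each column has unit variance).
spatial_fields <- function(lon, lat, k, range_km, nugget = 0.5) {
  n <- length(lon)
  if (range_km <= 0) return(matrix(rnorm(n * k), n, k))
  d <- haversine_dist(lon, lat)
  kern <- exp(-d / range_km) + diag(1e-8, n)
  L <- t(chol(kern))
  gp <- L %*% matrix(rnorm(n * k), n, k)
  sqrt(1 - nugget) * gp + sqrt(nugget) * matrix(rnorm(n * k), n, k)
}

#' Generate a genotype panel with spatially structured historic
#' environments
#'
#' Coordinates are uniform over a Turkey-like bounding box (lon 26-45,
#' lat 36-42). Environment variables are spatially autocorrelated Gaussian
#' fields (exponential kernel) plus independent noise, cross-correlated by
#' `env_corr` and mapped onto plausible scales. A standardized copy of
#' soil nitrogen (`soil_nitrogen_z`) is retained as the downstream
#' predictor.
#'
#' @param n_genotypes Number of genotypes (>= 3).
#' @param spatial_range_km Range of the exponential spatial kernel; 0
#'   yields spatially uncorrelated environments.
#' @param env_corr Positive-semidefinite correlation matrix over the nine
#'   environment variables (see [default_env_corr()]).
#' @param nugget Fraction of spatially unstructured variance in each
#'   environment variable.
#' @param seed Integer seed.
#' @return A tibble, one row per genotype.
#' @export
gen_panel <- function(n_genotypes = 40, spatial_range_km = 200,
                      env_corr = default_env_corr(), nugget = 0.5,
                      seed = NULL) {
  stopifnot(n_genotypes >= 3)
  ev <- eigen(env_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("`env_corr` must be positive semidefinite.")
  local_seed_eval(seed, {
    lon <- runif(n_genotypes, 26, 45)
    lat <- runif(n_genotypes, 36, 42)
    z <- spatial_fields(lon, lat, ncol(env_corr), spatial_range_km, nugget)
    y <- z %*% chol(env_corr + diag(1e-10, ncol(env_corr)))
    colnames(y) <- env_vars
    elev_field <- spatial_fields(lon, lat, 1, spatial_range_km, nugget)
    panel <- tibble::tibble(
      genotype = sprintf("G%02d", seq_len(n_genotypes)),
      lon = lon, lat = lat,
      elevation = round(pmax(0, 700 + 350 * elev_field[, 1])),
      soil_nitrogen = exp(0.6 + 0.5 * y[, "soil_nitrogen"]),
      soil_phosphorus = exp(2.6 + 0.4 * y[, "soil_phosphorus"]),
      cec = 18 + 5 * y[, "cec"],
      ph = 7.2 + 0.45 * y[, "ph"],
      mean_annual_temp = 14 + 3 * y[, "mean_annual_temp"],
      precip_spring = exp(4.9 + 0.35 * y[, "precip_spring"]),
      precip_summer = exp(3.7 + 0.4 * y[, "precip_summer"]),
      precip_fall = exp(4.6 + 0.35 * y[, "precip_fall"]),
      mean_annual_precip = exp(6.2 + 0.3 * y[, "mean_annual_precip"]))
    panel$soil_nitrogen_z <- zscore(panel$soil_nitrogen)
    panel
  })
}

#' Generate an SSR marker matrix with isolation by distance
#'
#' Each locus is a discretized spatial Gaussian field: nearby genotypes
#' fall into the same allele bin more often, so expected pairwise Hamming
#' distance increases with geographic distance at a rate controlled by
#' `ibd_strength` (0 = no spatial signal).
#'
#' @param panel A genotype panel from [gen_panel()] (uses `lon`, `lat`).
#' @param n_loci Number of SSR loci.
#' @param ibd_strength Fraction (0-1) of per-locus variance that is
#'   spatially structured.
#' @param n_alleles Number of allele states per locus.
#' @param range_km Spatial range of the allele fields.
#' @param missing_rate Fraction of calls set missing at random.
#' @param seed Integer seed.
#' @return A tibble: `genotype` plus one integer column per locus.
#' @export
gen_ssr <- function(panel, n_loci = 20, ibd_strength = 0.6, n_alleles = 4,
                    range_km = 300, missing_rate = 0.02, seed = NULL) {
  stopifnot(n_loci >= 1, ibd_strength >= 0, ibd_strength <= 1)
  local_seed_eval(seed, {
    n <- nrow(panel)
    fields <- spatial_fields(panel$lon, panel$lat, n_loci, range_km,
                             nugget = 1 - ibd_strength)
    alleles <- apply(fields, 2, function(g) {
      as.integer(cut(g, breaks = quantile(g, probs = seq(0, 1, length.out = n_alleles + 1)),
                     include.lowest = TRUE, labels = FALSE))
    })
    alleles <- matrix(alleles, nrow = n)
    if (missing_rate > 0) {
      alleles[matrix(runif(length(alleles)) < missing_rate,
                     nrow = n)] <- NA_integer_
    }
    colnames(alleles) <- sprintf("locus%02d", seq_len(n_loci))
    dplyr::bind_cols(tibble::tibble(genotype = panel$genotype),
                     tibble::as_tibble(alleles))
  })
}

#' Generate a random rooted phylogeny over the given taxa
#'
#' A random coalescent tree (via [ape::rcoal]) with positive branch
#' lengths whose leaf set is exactly `taxon_ids`.
#'
#' @param taxon_ids Character vector of unique taxon ids (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] object.
#' @export
gen_tree <- function(taxon_ids, seed = NULL) {
  if (length(taxon_ids) < 2) abort("Need at least 2 taxa for a tree.")
  if (anyDuplicated(taxon_ids)) abort("Duplicate taxon ids.")
  local_seed_eval(seed, ape::rcoal(length(taxon_ids),
                                   tip.label = as.character(taxon_ids)))
}

#' Generate a taxonomy table with functional-group flags
#'
#' Taxa receive rank labels drawn from a small pool of lineages (a
#' fraction are left unclassified at order/genus level) and functional
#' flags: the first `n_ammonia_oxidizer` taxa are flagged as ammonia
#' oxidizers, `n_diazotroph` as diazotrophs, `n_glomeromycota` as
#' Glomeromycota.
#'
#' @param n_taxa Number of taxa.
#' @param n_ammonia_oxidizer,n_diazotroph,n_glomeromycota Flagged counts.
#' @param prefix Taxon-id prefix.
#' @param seed Integer seed.
#' @return A taxonomy tibble compatible with [read_taxonomy()].
#' @export
gen_taxonomy <- function(n_taxa, n_ammonia_oxidizer = 0, n_diazotroph = 0,
                         n_glomeromycota = 0, prefix = "ASV", seed = NULL) {
  stopifnot(n_ammonia_oxidizer + n_diazotroph + n_glomeromycota <= n_taxa)
  local_seed_eval(seed, {
    ids <- sprintf("%s%04d", prefix, seq_len(n_taxa))
    orders <- sprintf("order_%02d", sample.int(max(3, n_taxa %/% 20),
                                               n_taxa, replace = TRUE))
    genera <- sprintf("genus_%03d", sample.int(max(5, n_taxa %/% 6),
                                               n_taxa, replace = TRUE))
    orders[runif(n_taxa) < 0.05] <- NA_character_
    pos <- 0L
    take <- function(k) {
      if (k == 0) return(logical(n_taxa))
      out <- logical(n_taxa)
      out[pos + seq_len(k)] <- TRUE
      pos <<- pos + as.integer(k)
      out
    }
    tibble::tibble(taxon_id = ids,
                   domain = "Bacteria",
                   phylum = sprintf("phylum_%d", 1 + (seq_len(n_taxa) %% 6)),
                   order = orders,
                   genus = genera,
                   ammonia_oxidizer = take(n_ammonia_oxidizer),
                   diazotroph = take(n_diazotroph),
                   glomeromycota = take(n_glomeromycota))
  })
}

#' Generate a community count table for the common-garden design
#'
#' Emulates the rhizosphere experiment: each genotype is grown once per
#' glasshouse block; per-sample expected composition logits are taxon
#' baseline + genotype loading + environmental response (responder taxa
#' only, slope on standardized historic soil nitrogen) + block shift.
#' Occupancy of flagged diazotroph taxa is thinned per genotype so the
#' expected occupied richness interpolates `spec$richness_gradient`
#' across the soil-nitrogen range; the expected summed relative abundance
#' of flagged ammonia-oxidizer taxa is rescaled to interpolate
#' `spec$group_ra_gradient`. Counts are Dirichlet-multinomial at the
#' configured depth.
#'
#' @param panel Genotype panel (needs `genotype`, `soil_nitrogen_z`).
#' @param taxonomy Taxonomy table defining the taxa and flags.
#' @param spec A [community_effect_spec()].
#' @param n_replicates Replicates per genotype (>= 2).
#' @param n_blocks Number of glasshouse blocks; replicate r sits in block
#'   `((r - 1) %% n_blocks) + 1`.
#' @param seed Integer seed.
#' @return A list with elements `table` (a [feature_table()]), `metadata`
#'   (tibble: sample_id, genotype, block) and `truth` (planted
#'   per-genotype expectations).
#' @export
gen_feature_table <- function(panel, taxonomy, spec = community_effect_spec(),
                              n_replicates = 5, n_blocks = n_replicates,
                              seed = NULL) {
  stopifnot(n_replicates >= 2)
  if (nrow(taxonomy) < 2) abort("Need at least two taxa.")
  local_seed_eval(seed, {
    taxa <- taxonomy$taxon_id
    K <- length(taxa)
    G <- nrow(panel)
    z <- panel$soil_nitrogen_z
    u <- (z - min(z)) / (max(z) - min(z))

    base <- rnorm(K, 0, spec$baseline_sd)
    loadings <- matrix(rnorm(G * K, 0, spec$genotype_sd), G, K)
    beta <- numeric(K)
    n_resp <- round(spec$env_responders * K)
    if (n_resp > 0 && spec$env_beta > 0) {
      resp <- sample.int(K, n_resp)
      beta[resp] <- spec$env_beta * sample(c(-1, 1), n_resp, replace = TRUE)
    }
    shifts <- matrix(rnorm(n_blocks * K, 0, spec$block_sd), n_blocks, K)

    dia <- which(taxonomy$diazotroph)
    occ <- NULL
    rich_target <- NULL
    if (!is.null(spec$richness_gradient) && length(dia)) {
      rg <- spec$richness_gradient
      rich_target <- rg[1] + (rg[2] - rg[1]) * u
      p_occ <- pmin(1, rich_target / length(dia))
      occ <- matrix(rbinom(G * length(dia), 1, rep(p_occ, length(dia))),
                    G, length(dia))
    }
    ao <- which(taxonomy$ammonia_oxidizer)
    ra_target <- NULL
    if (!is.null(spec$group_ra_gradient) && length(ao)) {
      gr <- spec$group_ra_gradient
      ra_target <- gr[1] + (gr[2] - gr[1]) * u
    }

    n_samples <- G * n_replicates
    counts <- matrix(0L, n_samples, K)
    sample_id <- character(n_samples)
    meta_g <- character(n_samples)
    meta_b <- character(n_samples)
    i <- 0L
    for (g in seq_len(G)) {
      for (r in seq_len(n_replicates)) {
        i <- i + 1L
        b <- ((r - 1L) %% n_blocks) + 1L
        lg <- base + loadings[g, ] + beta * z[g] + shifts[b, ]
        w <- exp(lg)
        if (!is.null(occ)) w[dia][occ[g, ] == 0] <- 0
        if (!is.null(ra_target) && sum(w[ao]) > 0) {
          q <- ra_target[g]
          w[ao] <- w[ao] * (q / (1 - q)) * sum(w[-ao]) / sum(w[ao])
        }
        conc <- spec$dispersion * w / sum(w)
        p <- rgamma(K, shape = conc, rate = 1)
        p[conc == 0] <- 0
        if (sum(p) == 0) p[which.max(conc)] <- 1
        counts[i, ] <- rmultinom(1, spec$depth, p / sum(p))[, 1]
        sample_id[i] <- sprintf("%s_r%d", panel$genotype[g], r)
        meta_g[i] <- panel$genotype[g]
        meta_b[i] <- sprintf("B%d", b)
      }
    }
    dimnames(counts) <- list(sample_id, taxa)
    list(table = feature_table(counts),
         metadata = tibble::tibble(sample_id = sample_id,
                                   genotype = meta_g, block = meta_b),
         truth = list(beta = setNames(beta, taxa),
                      richness_target = rich_target,
                      group_ra_target = ra_target))
  })
}

#' Generate the crossed nitrogen-by-microbe trait experiment
#'
#' Emulates the nitrogen-response glasshouse experiment: a genotype subset
#' spanning the historic soil-nitrogen range, grown under 2 glasshouse
#' nitrogen x 2 microbe (live/sterile) treatments in randomized blocks,
#' with germination failure thinning pots completely at random.
#'
#' @param panel Genotype panel.
#' @param spec A [trait_effect_spec()].
#' @param genotypes Character vector of genotypes to use; default picks
#'   `n_genotypes` evenly across the soil-nitrogen range.
#' @param n_genotypes Number of genotypes when `genotypes` is `NULL`.
#' @param n_replicates Pots per genotype x nitrogen x microbe cell; each
#'   replicate is one glasshouse block.
#' @param failure_rate Fraction of pots lost to germination failure
#'   (missing completely at random).
#' @param seed Integer seed.
#' @return A tibble trait table (one row per surviving plant) carrying the
#'   genotype's standardized historic soil nitrogen as `soil_nitrogen_z`,
#'   with the planted expectations in `attr(, "truth")`.
#' @export
gen_experiment2_traits <- function(panel, spec = trait_effect_spec(),
                                   genotypes = NULL, n_genotypes = 10,
                                   n_replicates = 10, failure_rate = 0.25,
                                   seed = NULL) {
  stopifnot(n_replicates >= 3)
  if (is.null(genotypes)) {
    ord <- order(panel$soil_nitrogen_z)
    genotypes <- panel$genotype[ord][round(seq(1, nrow(panel),
                                               length.out = n_genotypes))]
  }
  if (length(genotypes) < 2) abort("Need at least 2 genotypes.")
  sub <- panel[match(genotypes, panel$genotype), ]
  if (anyNA(sub$genotype)) abort("Unknown genotype(s) requested.")
  local_seed_eval(seed, {
    design <- tidyr::expand_grid(genotype = sub$genotype,
                                 nitrogen = c("low", "high"),
                                 microbe = c("live", "sterile"),
                                 rep = seq_len(n_replicates))
    design$block <- sprintf("B%02d", design$rep)
    design$soil_nitrogen_z <- sub$soil_nitrogen_z[match(design$genotype,
                                                        sub$genotype)]
    slope <- ifelse(design$nitrogen == "high", spec$me_slope_high,
                    spec$me_slope_low)
    me <- spec$microbe_effect + slope * design$soil_nitrogen_z
    mult <- (1 + spec$nitrogen_effect * (design$nitrogen == "high")) *
      (1 + me * (design$microbe == "live"))

    g_int <- setNames(rnorm(length(genotypes), 0, spec$genotype_sd),
                      sub$genotype)
    b_lab <- unique(design$block)
    b_int <- setNames(rnorm(length(b_lab), 0, spec$block_sd), b_lab)
    n <- nrow(design)
    noise_shift <- unname(g_int[design$genotype] + b_int[design$block])

    out <- design
    for (tr in names(spec$baseline)) {
      b0 <- spec$baseline[[tr]]
      val <- b0 * mult + b0 * (noise_shift + rnorm(n, 0, spec$residual_sd))
      out[[tr]] <- pmax(val, 0.01 * b0)
    }
    tc <- spec$tiller_logit_coefs
    eta <- tc[["intercept"]] + tc[["nitrogen"]] * (design$nitrogen == "high") +
      tc[["microbe"]] * (design$microbe == "live") + noise_shift
    out$tillering <- rbinom(n, 1, stats::plogis(eta))
    out$plant_id <- sprintf("%s_N%s_M%s_r%02d", out$genotype,
                            substr(out$nitrogen, 1, 2),
                            substr(out$microbe, 1, 2), out$rep)
    keep <- runif(n) >= failure_rate
    out <- dplyr::select(out[keep, ], "plant_id", "genotype", "block",
                         "nitrogen", "microbe", "soil_nitrogen_z",
                         dplyr::all_of(names(spec$baseline)), "tillering")
    attr(out, "truth") <- list(me_slope_low = spec$me_slope_low,
                               me_slope_high = spec$me_slope_high,
                               microbe_effect = spec$microbe_effect,
                               nitrogen_effect = spec$nitrogen_effect)
    out
  })
}

#' Simulate the full two-experiment study
#'
#' Generates the genotype panel, SSR markers, the universal bacterial
#' (ammonia-oxidizer-flagged) and diazotroph marker tables with their
#' trees and taxonomies, and the factorial trait experiment.
#'
#' @param seed Integer seed driving all generators.
#' @param n_genotypes,n_replicates Common-garden design size.
#' @param spec_16s,spec_nifh Community specs for the universal bacterial
#'   and diazotroph markers; defaults carry the calibrated effect sizes,
#'   the ammonia-oxidizer relative-abundance gradient (0.85% to 1.12%)
#'   and the diazotroph richness gradient (25 to 12 occupied taxa).
#' @param trait_spec A [trait_effect_spec()].
#' @param n_trait_genotypes,n_trait_replicates Factorial-experiment size.
#' @return A named list bundle.
#' @export
simulate_study <- function(seed = 1, n_genotypes = 40, n_replicates = 5,
                           spec_16s = community_effect_spec(
                             group_ra_gradient = c(0.0085, 0.0112)),
                           spec_nifh = community_effect_spec(
                             n_taxa = 60, depth = 1000, dispersion = 200,
                             baseline_sd = 0.6,
                             richness_gradient = c(25, 12)),
                           trait_spec = trait_effect_spec(),
                           n_trait_genotypes = 10,
                           n_trait_replicates = 10) {
  panel <- gen_panel(n_genotypes, seed = child_seed(seed, 1))
  ssr <- gen_ssr(panel, seed = child_seed(seed, 2))
  tax_16s <- gen_taxonomy(spec_16s$n_taxa,
                          n_ammonia_oxidizer = max(2L, round(0.03 * spec_16s$n_taxa)),
                          prefix = "B", seed = child_seed(seed, 3))
  tax_nifh <- gen_taxonomy(spec_nifh$n_taxa, n_diazotroph = spec_nifh$n_taxa,
                           prefix = "N", seed = child_seed(seed, 4))
  comm_16s <- gen_feature_table(panel, tax_16s, spec_16s, n_replicates,
                                seed = child_seed(seed, 5))
  comm_nifh <- gen_feature_table(panel, tax_nifh, spec_nifh, n_replicates,
                                 seed = child_seed(seed, 6))
  tree_16s <- gen_tree(tax_16s$taxon_id, seed = child_seed(seed, 7))
  traits <- gen_experiment2_traits(panel, trait_spec,
                                   n_genotypes = n_trait_genotypes,
                                   n_replicates = n_trait_replicates,
                                   seed = child_seed(seed, 8))
  list(seed = as.integer(seed), panel = panel, ssr = ssr,
       taxonomy_16s = tax_16s, taxonomy_nifh = tax_nifh,
       table_16s = comm_16s$table, metadata = comm_16s$metadata,
       truth_16s = comm_16s$truth,
       table_nifh = comm_nifh$table, metadata_nifh = comm_nifh$metadata,
       truth_nifh = comm_nifh$truth,
       tree_16s = tree_16s, traits = traits)
}

#' Calibrate the genotype effect size against a PERMANOVA R-squared band
#'
#' Bisection on `genotype_sd`: at each step, community tables are
#' simulated at the study design and the mean sequential PERMANOVA
#' R-squared of the genotype term (Bray-Curtis) is compared with the
#' centre of `target`.
#'
#' @param target Length-2 band for the genotype R-squared proportion.
#' @param spec Base [community_effect_spec()]; `genotype_sd` is varied.
#' @param n_genotypes,n_replicates Study design.
#' @param n_seeds Monte-Carlo seeds per evaluation.
#' @param bounds Search interval for `genotype_sd`.
#' @param tol Stop when the band half-width criterion (2 percentage
#'   points) is met or the interval is narrower than `tol`.
#' @param seed Base seed.
#' @return The calibrated `genotype_sd` with the evaluation trace as
#'   `attr(, "trace")`.
#' @export
calibrate_genotype_sd <- function(target = c(0.21, 0.31),
                                  spec = community_effect_spec(),
                                  n_genotypes = 40, n_replicates = 5,
                                  n_seeds = 3, bounds = c(0.05, 1.5),
                                  tol = 0.02, seed = 1) {
  mid_target <- mean(target)
  eval_r2 <- function(sd_val) {
    sp <- spec
    sp$genotype_sd <- sd_val
    mean(vapply(seq_len(n_seeds), function(i) {
      pan <- gen_panel(n_genotypes, seed = child_seed(seed, 100 + i))
      tax <- gen_taxonomy(sp$n_taxa, seed = child_seed(seed, 200 + i))
      sim <- gen_feature_table(pan, tax, sp, n_replicates,
                               seed = child_seed(seed, 300 + i))
      d <- bray_curtis(sim$table)
      design_r2(d, sim$metadata, c("genotype", "block"))[["genotype"]]
    }, numeric(1)))
  }
  lo <- bounds[1]; hi <- bounds[2]
  trace <- list()
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    r2 <- eval_r2(mid)
    trace[[it]] <- c(genotype_sd = mid, r2 = r2)
    if (abs(r2 - mid_target) < tol || (hi - lo) < 1e-3) break
    if (r2 < mid_target) lo <- mid else hi <- mid
  }
  structure(mid, trace = do.call(rbind, trace))
}

#' Calibrate the environmental effect size against a conditioned-dbRDA
#' share
#'
#' Bisection on `env_beta`: the objective is the proportion of Bray-Curtis
#' inertia explained by standardized historic soil nitrogen after
#' conditioning on the geographic and SSR Moran-eigenvector bases.
#'
#' @param target Length-2 band for the conditioned constrained proportion.
#' @inheritParams calibrate_genotype_sd
#' @return The calibrated `env_beta` with the trace as `attr(, "trace")`.
#' @export
calibrate_env_beta <- function(target = c(0.01, 0.03),
                               spec = community_effect_spec(),
                               n_genotypes = 40, n_replicates = 5,
                               n_seeds = 3, bounds = c(0.02, 1.2),
                               tol = 0.004, seed = 1) {
  mid_target <- mean(target)
  eval_share <- function(beta_val) {
    sp <- spec
    sp$env_beta <- beta_val
    mean(vapply(seq_len(n_seeds), function(i) {
      pan <- gen_panel(n_genotypes, seed = child_seed(seed, 100 + i))
      ssr <- gen_ssr(pan, seed = child_seed(seed, 150 + i))
      tax <- gen_taxonomy(sp$n_taxa, seed = child_seed(seed, 200 + i))
      sim <- gen_feature_table(pan, tax, sp, n_replicates,
                               seed = child_seed(seed, 300 + i))
      d <- bray_curtis(sim$table)
      cond <- condition_basis(pan, ssr, sim$metadata)
      preds <- data.frame(soil_nitrogen = pan$soil_nitrogen_z[
        match(sim$metadata$genotype, pan$genotype)])
      fit <- dbrda(d, preds, condition = cond)
      fit$constrained / fit$total
    }, numeric(1)))
  }
  lo <- bounds[1]; hi <- bounds[2]
  trace <- list()
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    share <- eval_share(mid)
    trace[[it]] <- c(env_beta = mid, share = share)
    if (abs(share - mid_target) < tol || (hi - lo) < 1e-3) break
    if (share < mid_target) lo <- mid else hi <- mid
  }
  structure(mid, trace = do.call(rbind, trace))
}
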