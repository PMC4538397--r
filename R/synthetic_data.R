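# Multi-site synthetic forest-stand generator. Emulates the structural
# features the largest-tree analyses rely on: truncated power-law stem
# diameters (the metabolic-scaling size structure), dominance-skewed species
# abundances with among-site turnover, species-level wood densities, noisy
# power height-diameter allometry, lognormal site effects on stem density and
# stature, and optional near-monodominant sites. AGB is computed through the
# allometry module, never drawn directly, so the full pipeline is exercised.

#' Configuration of the synthetic stand generator
#'
#' Defaults describe a Central-African-like network: 8 sites of 20 one-ha
#' plots, about 450 stems/ha at or above 10 cm DBH, a truncated Pareto DBH
#' distribution with exponent 2 on 10-250 cm, a 300-species regional pool
#' with a log-series-like rank-abundance, species wood densities around
#' 0.6 g/cm3, a power height-diameter law near H = 2.8 D^0.57 with 10%
#' lognormal scatter, and one near-monodominant site.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @param n_sites number of sites.
#' @param plots_per_site 1-ha plots per site.
#' @param stems_per_ha mean stem density (Poisson per plot).
#' @param dbh_exponent power-law slope of the DBH density (> 1).
#' @param dbh_range truncation bounds in cm (lower bound is the census
#'   threshold).
#' @param sad `"logseries"` (rank-abundance p_i proportional to x^i / i) or
#'   `"geometric"` (p_i proportional to (1 - k)^(i-1)).
#' @param sad_shape shape parameter: x in (0,1) for logseries, k in (0,1)
#'   for geometric.
#' @param species_pool regional species richness.
#' @param wd_mean,wd_sd mean and sd of species-level wood density (g/cm3);
#'   draws are clamped to 0.15-1.3.
#' @param hd_a,hd_b,hd_sd amplitude, exponent and lognormal residual sd of
#'   the height-diameter power law.
#' @param monodominant_sites number of sites (taken first) given a
#'   near-monodominant structure.
#' @param dominant_share probability that a stem of a monodominant site
#'   belongs to the dominant species, in (0, 1).
#' @param dominant_min_dbh DBH (cm) above which the dominant share applies
#'   (default 10 = all stems).
#' @param site_density_sd lognormal sd of the site effect on stem density.
#' @param site_agb_sd lognormal sd of the site effect on stature (applied to
#'   the height-diameter amplitude, hence multiplicatively to AGB).
#' @param site_species_sd lognormal sd of per-site species-weight turnover.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_sites = 8, plots_per_site = 20,
                             stems_per_ha = 450, dbh_exponent = 2,
                             dbh_range = c(10, 250),
                             sad = c("logseries", "geometric"),
                             sad_shape = 0.99, species_pool = 300,
                             wd_mean = 0.6, wd_sd = 0.15,
                             hd_a = 2.8, hd_b = 0.57, hd_sd = 0.1,
                             monodominant_sites = 1, dominant_share = 0.6,
                             dominant_min_dbh = 10,
                             site_density_sd = 0.1, site_agb_sd = 0.1,
                             site_species_sd = 0.5) {
  sad <- match.arg(sad)
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              plots_per_site = plots_per_site, stems_per_ha = stems_per_ha,
              dbh_exponent = dbh_exponent, dbh_range = dbh_range, sad = sad,
              sad_shape = sad_shape, species_pool = species_pool,
              wd_mean = wd_mean, wd_sd = wd_sd, hd_a = hd_a, hd_b = hd_b,
              hd_sd = hd_sd, monodominant_sites = monodominant_sites,
              dominant_share = dominant_share,
              dominant_min_dbh = dominant_min_dbh,
              site_density_sd = site_density_sd, site_agb_sd = site_agb_sd,
              site_species_sd = site_species_sd)
  check_pos <- c("n_sites", "plots_per_site", "stems_per_ha", "sad_shape",
                 "species_pool", "wd_mean", "wd_sd", "hd_a", "hd_b")
  bad <- character()
  for (f in check_pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
    bad <- c(bad, f)
  }
  if (cfg$dbh_exponent <= 1) bad <- c(bad, "dbh_exponent (needs > 1)")
  if (length(cfg$dbh_range) != 2 || cfg$dbh_range[1] <= 0 ||
      diff(cfg$dbh_range) <= 0) bad <- c(bad, "dbh_range")
  if (cfg$sad_shape >= 1) bad <- c(bad, "sad_shape (needs < 1)")
  if (cfg$hd_sd < 0 || cfg$site_density_sd < 0 || cfg$site_agb_sd < 0 ||
      cfg$site_species_sd < 0) bad <- c(bad, "negative sd field")
  if (cfg$monodominant_sites < 0 || cfg$monodominant_sites > cfg$n_sites) {
    bad <- c(bad, "monodominant_sites")
  }
  if (cfg$dominant_share <= 0 || cfg$dominant_share >= 1) {
    bad <- c(bad, "dominant_share (needs (0,1))")
  }
  if (length(bad)) {
    stop("invalid synthetic_config field(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Truncated power-law (Pareto) diameter distribution
#'
#' Density proportional to \eqn{D^{-a}} on `[lower, upper]`.
#'
#' @param n number of draws.
#' @param exponent power-law slope a (> 1).
#' @param lower,upper truncation bounds (cm).
#' @return `rtrunc_pareto`: draws; `ptrunc_pareto`: the closed-form CDF.
#' @export
rtrunc_pareto <- function(n, exponent, lower = 10, upper = 250) {
  qtrunc_pareto(stats::runif(n), exponent, lower, upper)
}

#' @rdname rtrunc_pareto
#' @param q quantiles.
#' @export
ptrunc_pareto <- function(q, exponent, lower = 10, upper = 250) {
  a1 <- 1 - exponent
  p <- (lower^a1 - pmin(pmax(q, lower), upper)^a1) / (lower^a1 - upper^a1)
  p[q < lower] <- 0
  p[q > upper] <- 1
  p
}

qtrunc_pareto <- function(p, exponent, lower = 10, upper = 250) {
  a1 <- 1 - exponent
  (lower^a1 - p * (lower^a1 - upper^a1))^(1 / a1)
}

sad_probs <- function(cfg) {
  i <- seq_len(cfg$species_pool)
  p <- switch(cfg$sad,
    logseries = cfg$sad_shape^i / i,
    geometric = (1 - cfg$sad_shape)^(i - 1))
  p / sum(p)
}

species_pool_table <- function(cfg) {
  i <- seq_len(cfg$species_pool)
  genus <- ceiling(i / 3)
  data.frame(species = sprintf("Species %03d", i),
             genus = sprintf("Genus%03d", genus),
             family = sprintf("Family%02d", ceiling(genus / 3)),
             wd = pmin(pmax(stats::rnorm(cfg$species_pool, cfg$wd_mean,
                                         cfg$wd_sd), 0.15), 1.3))
}

#' Generate a synthetic multi-site inventory region
#'
#' Draws the full network described by the config, computes heights from the
#' site-specific height-diameter law and tree AGB through the allometry
#' module after wood-density assignment, and returns the inventory together
#' with the generating truth (for parameter-recovery tests) and the
#' wood-density reference table.
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given, writes `inventory.csv`,
#'   `wood_density.csv` and `truth.json` there.
#' @return list with `inventory` (a `forest_inventory` with `wd` and
#'   `agb_kg` filled), `wd_table` (the [wood_density_table()]), `species`
#'   (the species truth table) and `truth` (config + per-site effects).
#' @export
generate_region <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pool <- species_pool_table(config)
  base_p <- sad_probs(config)
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  site_fx <- data.frame(
    site = sites,
    density_mult = exp(stats::rnorm(config$n_sites, 0,
                                    config$site_density_sd)),
    hd_a_mult = exp(stats::rnorm(config$n_sites, 0, config$site_agb_sd)),
    monodominant = seq_len(config$n_sites) <= config$monodominant_sites)
  blocks <- lapply(seq_len(config$n_sites), function(si) {
    w <- base_p * exp(stats::rnorm(config$species_pool, 0,
                                   config$site_species_sd))
    w <- w / sum(w)
    generate_site_block(config, site_fx[si, ], w, pool)
  })
  inv <- do.call(rbind, blocks)
  inv <- forest_inventory(inv, dbh_min = config$dbh_range[1])
  wdt <- wood_density_table(pool)
  inv <- assign_wood_density(inv, wdt)
  inv <- compute_agb(inv, mode = "with_height")
  truth <- list(config = unclass(config), site_effects = site_fx,
                dominant_species = pool$species[1])
  out <- list(inventory = inv, wd_table = wdt, species = pool, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_inventory(inv, file.path(dir, "inventory.csv"))
    utils::write.csv(pool, file.path(dir, "wood_density.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

generate_site_block <- function(cfg, fx, weights, pool) {
  plots <- lapply(seq_len(cfg$plots_per_site), function(pi) {
    n <- max(1L, stats::rpois(1, cfg$stems_per_ha * fx$density_mult))
    dbh <- rtrunc_pareto(n, cfg$dbh_exponent, cfg$dbh_range[1],
                         cfg$dbh_range[2])
    sp <- sample.int(cfg$species_pool, n, replace = TRUE, prob = weights)
    if (fx$monodominant) {
      take <- dbh >= cfg$dominant_min_dbh &
        stats::runif(n) < cfg$dominant_share
      sp[take] <- 1L  # the regional rank-1 species dominates
    }
    height <- cfg$hd_a * fx$hd_a_mult * dbh^cfg$hd_b *
      exp(stats::rnorm(n, 0, cfg$hd_sd))
    data.frame(site = fx$site, plot = sprintf("P%02d", pi),
               stem = sprintf("t%05d", seq_len(n)),
               family = pool$family[sp], genus = pool$genus[sp],
               species = pool$species[sp], dbh_cm = dbh, height_m = height,
               wd = NA_real_, agb_kg = NA_real_)
  })
  do.call(rbind, plots)
}

#' Generate a single near-monodominant site
#'
#' Convenience wrapper producing one site in which the dominant species holds
#' a configured share of the stems (hence, size being species-independent by
#' default, of basal area and AGB in expectation).
#'
#' @param config a [synthetic_config()]; `dominant_share` supplies the share.
#' @return As [generate_region()], restricted to one monodominant site.
#' @export
generate_monodominant_site <- function(config) {
  cfg <- config
  cfg$n_sites <- 1
  cfg$monodominant_sites <- 1
  class(cfg) <- "synthetic_config"
  generate_region(cfg)
}

#' Monte-Carlo estimate of the top-N power law implied by the generator
#'
#' Simulates replicate regions under the config (seeds derived from
#' `config$seed`), fits the intercept-free power model at the requested N in
#' each, and returns the across-replicate mean and standard error of alpha
#' and beta — the recovery target for parameter-recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param n number of largest trees (default 20).
#' @param n_rep number of replicate regions (default 5).
#' @return list with `alpha_mean`, `alpha_se`, `beta_mean`, `beta_se` and
#'   the per-replicate `replicates` data.frame.
#' @export
true_agb_law <- function(config, n = 20, n_rep = 5) {
  reps <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * r
    class(cfg) <- "synthetic_config"
    region <- generate_region(cfg)
    tab <- plot_topn_table(region$inventory, n)
    fit <- fit_power_model(tab$agb_topn, tab$agb_tot, n = n)
    data.frame(rep = r, alpha = fit$alpha, beta = fit$beta, r2 = fit$r2)
  })
  reps <- do.call(rbind, reps)
  list(alpha_mean = mean(reps$alpha),
       alpha_se = stats::sd(reps$alpha) / sqrt(n_rep),
       beta_mean = mean(reps$beta),
       beta_se = stats::sd(reps$beta) / sqrt(n_rep),
       replicates = reps)
}
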