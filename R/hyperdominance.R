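# Site-standardized species biomass contributions, regional biomass
# hyperdominance and local dominance.

#' Per-species AGB at each site, standardized to t/ha
#'
#' Species totals at a site are divided by the site's inventoried area
#' (number of 1-ha plots) and converted from kg to t, so sites of different
#' plot counts are comparable and, downstream, contribute equally to the
#' regional pool.
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @return data.frame with `site`, `species`, `family`, `agb_t_ha`.
#' @export
site_species_agb <- function(inv) {
  if (!nrow(inv)) stop("empty inventory", call. = FALSE)
  if (anyNA(inv$agb_kg)) stop("agb_kg must be filled", call. = FALSE)
  area <- tapply(inv$plot, inv$site, function(p) length(unique(p)))
  key <- paste(inv$site, inv$species, sep = "\r")
  tot <- tapply(inv$agb_kg, key, sum)
  parts <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
  fam <- tapply(inv$family, key, function(f) f[1])
  out <- data.frame(site = parts[, 1], species = parts[, 2],
                    family = unname(fam[names(tot)]),
                    agb_t_ha = unname(tot) / unname(area[parts[, 1]]) / 1000)
  out <- out[order(out$site, -out$agb_t_ha, out$species), ]
  rownames(out) <- NULL
  out
}

#' Ranked regional species contributions with equal site weighting
#'
#' The regional contribution of a species is the unweighted mean over sites
#' of its site-standardized AGB (t/ha; absent at a site counts as 0), so each
#' site contributes equally regardless of its plot count. Species are ranked
#' by decreasing contribution (ties broken alphabetically) with percentages
#' and cumulated percentages against the regional total. Unidentified stems
#' (`"indet"`) are kept in the table and in the total (they hold biomass) but
#' are flagged ineligible for dominance.
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @return A `species_contrib` data.frame: `rank`, `species`, `family`,
#'   `agb_t_ha`, `pct`, `pct_cum`, `n_sites`, `eligible`. Attribute
#'   `n_sites` holds the number of sites pooled.
#' @export
regional_contributions <- function(inv) {
  per_site <- site_species_agb(inv)
  n_sites <- length(unique(per_site$site))
  agb <- tapply(per_site$agb_t_ha, per_site$species, sum) / n_sites
  fam <- tapply(per_site$family, per_site$species, function(f) f[1])
  n_occ <- tapply(per_site$site, per_site$species,
                  function(s) length(unique(s)))
  df <- data.frame(species = names(agb), family = unname(fam[names(agb)]),
                   agb_t_ha = unname(agb), n_sites = unname(n_occ[names(agb)]))
  df <- df[order(-df$agb_t_ha, df$species), ]
  df$pct <- 100 * df$agb_t_ha / sum(df$agb_t_ha)
  df$pct_cum <- cumulate_pct(df$pct)
  df$rank <- seq_len(nrow(df))
  df$eligible <- df$species != INDET
  df <- df[, c("rank", "species", "family", "agb_t_ha", "pct", "pct_cum",
               "n_sites", "eligible")]
  rownames(df) <- NULL
  attr(df, "n_sites") <- n_sites
  class(df) <- c("species_contrib", "data.frame")
  df
}

#' Cumulate a percentage column
#'
#' The cumulation operator applied to ranked per-species percentage
#' contributions: a running sum down the ranking.
#'
#' @param pct numeric vector of percentages in ranked order.
#' @return Cumulated percentages, same length.
#' @export
cumulate_pct <- function(pct) cumsum(pct)

#' Minimal set of top-ranked species cumulating a biomass threshold
#'
#' The biomass-hyperdominant set: the smallest k such that the k top-ranked
#' eligible species cumulate at least `threshold` of the total AGB
#' (inclusive: a prefix reaching exactly the threshold stops). Ineligible
#' rows (the `"indet"` pool) stay in the denominator but cannot be selected.
#'
#' @param contrib a `species_contrib` (or any data.frame with `species`,
#'   `pct` ranked by decreasing contribution; `eligible` optional).
#' @param threshold cumulated fraction of total AGB, in (0, 1]; default 0.5.
#' @return Character vector of the selected species, in rank order.
#' @export
hyperdominant_set <- function(contrib, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  elig <- if (!is.null(contrib$eligible)) contrib$eligible else
    rep(TRUE, nrow(contrib))
  pool <- contrib[elig, , drop = FALSE]
  cum <- cumulate_pct(pool$pct)
  k <- match(TRUE, cum >= 100 * threshold - 1e-9)
  if (is.na(k)) k <- nrow(pool)  # eligible species cannot reach the threshold
  pool$species[seq_len(k)]
}

#' Locally dominant species of each site
#'
#' The site-level analogue of [hyperdominant_set()]: per site, the minimal
#' set of top-ranked species cumulating `threshold` of the site's AGB.
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @param threshold cumulated fraction, default 0.5.
#' @return Named list (by site) of character vectors of species.
#' @export
local_dominants <- function(inv, threshold = 0.5) {
  per_site <- site_species_agb(inv)
  lapply(split(per_site, per_site$site), function(df) {
    df <- df[order(-df$agb_t_ha, df$species), ]
    df$pct <- 100 * df$agb_t_ha / sum(df$agb_t_ha)
    df$eligible <- df$species != INDET
    hyperdominant_set(df, threshold)
  })
}

#' Classify each site's local dominants by regional hyperdominance
#'
#' Partitions every site's locally dominant species into those that are also
#' regional hyperdominants and those that are local-only; the two counts sum
#' to the local set size.
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @param threshold cumulated fraction used for both scales, default 0.5.
#' @return list with `by_site` data.frame (`site`, `n_local`,
#'   `n_local_and_regional`, `n_local_only`), the `regional` species set and
#'   the `local` sets.
#' @export
classify_overlap <- function(inv, threshold = 0.5) {
  regional <- hyperdominant_set(regional_contributions(inv), threshold)
  local <- local_dominants(inv, threshold)
  by_site <- do.call(rbind, lapply(names(local), function(s) {
    both <- sum(local[[s]] %in% regional)
    data.frame(site = s, n_local = length(local[[s]]),
               n_local_and_regional = both,
               n_local_only = length(local[[s]]) - both)
  }))
  rownames(by_site) <- NULL
  list(by_site = by_site, regional = regional, local = local)
}

# ---- packaged regional reference table ------------------------------------

#' Published regional biomass-hyperdominant reference table
#'
#' The packaged transcription of a published compilation of the biomass
#' hyperdominant species of Central African moist forests: the species
#' cumulating half of the regional AGB across an 8-site, 175-plot network,
#' with their site-standardized regional contributions (t/ha), percentage
#' and cumulated-percentage columns, and site occupancy. Used as a fixture
#' to check the package's ranking and cumulation arithmetic against printed
#' values.
#'
#' @return data.frame with `species`, `family`, `agb_t_ha`, `pct`,
#'   `pct_cum`, `n_sites`, `local_sites`; attribute `n_recorded_species`
#'   gives the total number of species recorded across the source network.
#' @export
regional_reference_table <- function() {
  path <- system.file("extdata", "central_africa_bhd_table.csv",
                      package = "largetrees", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(system.file("extdata",
                                          "regional_survey_meta.json",
                                          package = "largetrees",
                                          mustWork = TRUE))
  attr(out, "n_recorded_species") <- meta$n_recorded_species
  attr(out, "n_sites") <- meta$n_sites
  attr(out, "n_plots") <- meta$n_plots
  out
}
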