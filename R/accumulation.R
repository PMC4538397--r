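# Within-plot accumulation of AGB and species richness over trees ranked by
# decreasing biomass.

#' Rank the trees of a plot by decreasing AGB
#'
#' Deterministic ordering: decreasing `agb_kg`, ties broken by larger
#' `dbh_cm`, then lexicographic `stem` id, so the ranking does not depend on
#' input order.
#'
#' @param plot_df data.frame of one plot's stems with `agb_kg` set.
#' @return The same rows, reordered.
#' @export
rank_trees <- function(plot_df) {
  if (anyNA(plot_df$agb_kg)) {
    stop("all trees must have agb_kg before ranking", call. = FALSE)
  }
  ord <- order(-plot_df$agb_kg, -plot_df$dbh_cm, plot_df$stem,
               method = "radix")
  out <- plot_df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accumulation curve of AGB and species richness for one plot
#'
#' Trees are ranked by decreasing AGB; for each N = 1..stems the curve gives
#' the cumulative AGB of the N largest trees, its fraction of the plot total
#' (AGB_TOT), and the number of distinct species among those N trees with its
#' fraction of the plot's total species richness (species_TOT). Unidentified
#' stems (`"indet"`) count towards AGB but never towards richness.
#'
#' @param plot_df data.frame of one plot's stems with `agb_kg` set.
#' @return An `accumulation_curve` data.frame with columns `n`, `topn_agb_kg`,
#'   `agb_fraction`, `richness`, `richness_fraction`, plus attributes
#'   `agb_tot` (kg) and `species_tot`.
#' @export
cumulative_curve <- function(plot_df) {
  if (!nrow(plot_df)) stop("empty plot", call. = FALSE)
  ranked <- rank_trees(plot_df)
  cum_agb <- cumsum(ranked$agb_kg)
  agb_tot <- cum_agb[length(cum_agb)]
  known <- ranked$species != INDET
  new_species <- known & !duplicated(ranked$species) # first occurrence
  richness <- cumsum(new_species)
  species_tot <- richness[length(richness)]
  out <- data.frame(
    n = seq_len(nrow(ranked)),
    topn_agb_kg = cum_agb,
    agb_fraction = cum_agb / agb_tot,
    richness = richness,
    richness_fraction = if (species_tot > 0) richness / species_tot else
      rep(NA_real_, length(richness)))
  attr(out, "agb_tot") <- agb_tot
  attr(out, "species_tot") <- species_tot
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Long-format accumulation table for a whole inventory
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @param n_max optional cap on reported N (default: every plot reported over
#'   its full 1..stems range).
#' @return data.frame with `site`, `plot`, `n`, `topn_agb_kg`,
#'   `agb_fraction`, `richness`, `richness_fraction`.
#' @export
accumulation_table <- function(inv, n_max = NULL) {
  plots <- split_plots(inv)
  rows <- lapply(plots, function(p) {
    cur <- cumulative_curve(p)
    if (!is.null(n_max)) cur <- cur[cur$n <= n_max, , drop = FALSE]
    data.frame(site = p$site[1], plot = p$plot[1], as.data.frame(cur))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site mean and sd of accumulation fractions over an N grid
#'
#' For each site and each N in `n_grid`, the across-plot mean and standard
#' deviation of the AGB fraction and richness fraction held by the N largest
#' trees. For plots with fewer than N stems the curve is flat at its terminal
#' value (the whole plot is already included), i.e. N is capped at the plot's
#' stem count. With a single plot, sd is reported as 0 and flagged.
#'
#' @param inv a `forest_inventory` with `agb_kg` filled (may hold several
#'   sites; summaries are per site).
#' @param n_grid integer vector of N values (default 1..100).
#' @return data.frame with `site`, `n`, `n_plots`, `agb_fraction_mean`,
#'   `agb_fraction_sd`, `richness_fraction_mean`, `richness_fraction_sd`,
#'   `sd_degenerate` (TRUE where only one plot contributed).
#' @export
site_summary <- function(inv, n_grid = 1:100) {
  if (!nrow(inv)) stop("empty inventory", call. = FALSE)
  n_grid <- sort(unique(as.integer(n_grid)))
  plots <- split_plots(inv)
  per_plot <- lapply(plots, function(p) {
    cur <- cumulative_curve(p)
    idx <- pmin(n_grid, nrow(cur))   # cap N at the plot's stem count
    data.frame(site = p$site[1], n = n_grid,
               agb_fraction = cur$agb_fraction[idx],
               richness_fraction = cur$richness_fraction[idx])
  })
  long <- do.call(rbind, per_plot)
  agg <- function(v, f) tapply(v, list(long$site, long$n), f)
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  m_agb <- agg(long$agb_fraction, mean)
  s_agb <- agg(long$agb_fraction, sd0)
  m_ric <- agg(long$richness_fraction, function(v) mean(v, na.rm = TRUE))
  s_ric <- agg(long$richness_fraction,
               function(v) sd0(v[!is.na(v)]))
  counts <- agg(long$agb_fraction, length)
  out <- data.frame(
    site = rep(rownames(m_agb), times = ncol(m_agb)),
    n = rep(as.integer(colnames(m_agb)), each = nrow(m_agb)),
    n_plots = as.vector(counts),
    agb_fraction_mean = as.vector(m_agb),
    agb_fraction_sd = as.vector(s_agb),
    richness_fraction_mean = as.vector(m_ric),
    richness_fraction_sd = as.vector(s_ric))
  out$sd_degenerate <- out$n_plots < 2
  out <- out[order(out$site, out$n), ]
  rownames(out) <- NULL
  out
}
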