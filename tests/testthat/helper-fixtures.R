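# In-code fixtures shared across test files.

# A tiny hand-built inventory: known AGB values, two sites.
toy_inventory <- function() {
  forest_inventory(data.frame(
    site = c("A", "A", "A", "A", "B", "B"),
    plot = c("p1", "p1", "p1", "p2", "p1", "p1"),
    stem = c("s1", "s2", "s3", "s1", "s1", "s2"),
    family = "Fam1",
    genus = c("Gen1", "Gen1", "Gen2", "Gen1", "Gen2", "Gen2"),
    species = c("Gen1 one", "Gen1 one", "Gen2 two", "Gen1 one",
                "Gen2 two", "Gen2 three"),
    dbh_cm = c(50, 30, 20, 40, 60, 25),
    agb_kg = c(5000, 1500, 500, 3000, 8000, 900)))
}

# A plot data.frame with chosen AGB values (single plot, one site).
plot_with_agb <- function(agb, species = NULL, dbh = NULL,
                          site = "S", plot = "p1") {
  n <- length(agb)
  if (n == 0) {
    return(plot_with_agb(1, site = site, plot = plot)[0, ])
  }
  if (is.null(species)) species <- sprintf("Sp %02d", seq_len(n))
  if (is.null(dbh)) dbh <- 10 + seq_len(n)
  data.frame(site = site, plot = plot, stem = sprintf("s%03d", seq_len(n)),
             family = "F", genus = "G", species = species,
             dbh_cm = dbh, height_m = NA_real_, wd = NA_real_, agb_kg = agb)
}

# Inventory of several sites obeying agb_tot = alpha * agb_topn^beta exactly
# is easiest built directly as a plot-level table.
exact_law_table <- function(alpha = 1.4, beta = 0.96, n_sites = 5,
                            plots_per_site = 10, n = 20) {
  topn <- as.vector(outer(seq(2e5, 6e5, length.out = plots_per_site),
                          seq(0.9, 1.1, length.out = n_sites)))
  data.frame(site = rep(sprintf("S%02d", seq_len(n_sites)),
                        each = plots_per_site),
             plot = rep(sprintf("p%02d", seq_len(plots_per_site)), n_sites),
             n = n, agb_topn = topn, agb_tot = alpha * topn^beta)
}

# Fast random plot generator for property checks (no allometry involved).
random_plot <- function(n_stems, n_species = 12, seed_species = FALSE) {
  plot_with_agb(exp(stats::rnorm(n_stems, 6, 1)),
                species = sample(sprintf("Sp %02d", seq_len(n_species)),
                                 n_stems, replace = TRUE),
                dbh = stats::runif(n_stems, 10, 120))
}

small_config <- function(seed = 99, ...) {
  synthetic_config(seed = seed, n_sites = 3, plots_per_site = 4,
                   stems_per_ha = 120, species_pool = 60, ...)
}
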