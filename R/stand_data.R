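#' @keywords internal
"_PACKAGE"

# Sentinel taxon for unidentified stems. They carry biomass but are excluded
# from species-richness counts and from dominance candidacy.
INDET <- "indet"

# Valid wood-density range (g/cm3) for sanity checks.
WD_RANGE <- c(0.05, 1.5)

#' Canonical inventory columns
#'
#' A forest inventory is a data.frame with one row per measured stem and the
#' columns below. `height_m`, `wd` and `agb_kg` may be `NA` until filled by
#' the height-diameter and allometry steps.
#'
#' @return Character vector of canonical column names.
#' @export
inventory_columns <- function() {
  c("site", "plot", "stem", "family", "genus", "species",
    "dbh_cm", "height_m", "wd", "agb_kg")
}

#' Build a validated forest inventory
#'
#' Coerces a data.frame of stem records into a `forest_inventory`, applying
#' the census protocol: stems below the minimum diameter (default 10 cm DBH)
#' are dropped with a warning, or rejected outright in strict mode. Blank or
#' missing species labels are pooled under the sentinel taxon `"indet"`.
#'
#' @param x data.frame with at least `site`, `plot`, `species`, `dbh_cm`.
#'   Missing optional columns (`stem`, `family`, `genus`, `height_m`, `wd`,
#'   `agb_kg`) are added.
#' @param dbh_min minimum DBH (cm) retained, default 10.
#' @param on_small `"drop"` (default: drop with a warning) or `"error"`.
#' @return A `forest_inventory`: the canonical data.frame with attribute
#'   `n_dropped` (stems removed by the diameter rule).
#' @export
forest_inventory <- function(x, dbh_min = 10, on_small = c("drop", "error")) {
  on_small <- match.arg(on_small)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("site", "plot", "species", "dbh_cm")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("inventory is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(x)) {
    out <- empty_inventory()
    return(out)
  }
  if (!is.numeric(x$dbh_cm)) {
    stop("dbh_cm must be numeric", call. = FALSE)
  }
  for (col in c("stem", "family", "genus")) {
    if (is.null(x[[col]])) x[[col]] <- NA_character_
  }
  for (col in c("height_m", "wd", "agb_kg")) {
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  }
  x$site <- as.character(x$site)
  x$plot <- as.character(x$plot)
  x$species <- trimws(as.character(x$species))
  x$genus <- trimws(as.character(x$genus))
  x$family <- trimws(as.character(x$family))
  x$stem <- as.character(x$stem)
  if (anyNA(x$dbh_cm)) {
    stop("dbh_cm contains missing values on row(s): ",
         paste(which(is.na(x$dbh_cm)), collapse = ", "), call. = FALSE)
  }
  if (any(x$dbh_cm <= 0)) {
    stop("dbh_cm must be > 0", call. = FALSE)
  }

  # default stem ids: running index within plot
  no_id <- is.na(x$stem) | x$stem == ""
  if (any(no_id)) {
    idx <- stats::ave(seq_len(nrow(x)), x$site, x$plot, FUN = seq_along)
    x$stem[no_id] <- sprintf("s%04d", idx[no_id])
  }
  blank <- is.na(x$species) | x$species == ""
  x$species[blank] <- INDET
  x$genus[is.na(x$genus)] <- ""
  x$family[is.na(x$family)] <- ""

  small <- x$dbh_cm < dbh_min
  if (any(small)) {
    if (on_small == "error") {
      stop(sum(small), " stem(s) below the ", dbh_min,
           " cm DBH census threshold", call. = FALSE)
    }
    warning(sum(small), " stem(s) below ", dbh_min,
            " cm DBH dropped", call. = FALSE)
    x <- x[!small, , drop = FALSE]
  }
  bad_wd <- !is.na(x$wd) & (x$wd <= WD_RANGE[1] | x$wd >= WD_RANGE[2])
  if (any(bad_wd)) {
    stop("wood density outside (", WD_RANGE[1], ", ", WD_RANGE[2],
         ") g/cm3 on row(s): ", paste(which(bad_wd), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$agb_kg) & x$agb_kg <= 0)) {
    stop("agb_kg must be > 0 where set", call. = FALSE)
  }
  x <- x[, inventory_columns()]
  rownames(x) <- NULL
  class(x) <- c("forest_inventory", "data.frame")
  attr(x, "n_dropped") <- sum(small)
  x
}

empty_inventory <- function() {
  out <- data.frame(site = character(), plot = character(), stem = character(),
                    family = character(), genus = character(),
                    species = character(), dbh_cm = numeric(),
                    height_m = numeric(), wd = numeric(), agb_kg = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("forest_inventory", "data.frame")
  attr(out, "n_dropped") <- 0L
  out
}

#' @export
print.forest_inventory <- function(x, ...) {
  cat("forest_inventory: ", nrow(x), " stems, ",
      length(unique(paste(x$site, x$plot, sep = "/"))), " plot(s), ",
      length(unique(x$site)), " site(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Read a stem inventory from delimited text
#'
#' Expects a header naming at least the site, plot, taxon and DBH columns;
#' other canonical columns are optional. Column names can be remapped through
#' `col_map` so files from other databases can be ingested unchanged.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param col_map named character vector mapping canonical names
#'   (`site`, `plot`, `stem`, `family`, `genus`, `species`, `dbh_cm`,
#'   `height_m`, `wd`) to the file's column names, e.g.
#'   `c(dbh_cm = "DBH", species = "taxon")`.
#' @param dbh_min,on_small passed to [forest_inventory()].
#' @return A `forest_inventory`.
#' @export
read_inventory <- function(path, delim = ",", col_map = NULL,
                           dbh_min = 10, on_small = "drop") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("col_map names absent column '", src, "'", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("site", "plot", "species", "dbh_cm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("dbh_cm", "height_m", "wd", "agb_kg")) {
    if (col %in% names(raw)) {
      val <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(val)
      if (any(bad)) {
        stop("non-numeric ", col, " in ", path, " on data row(s): ",
             paste(which(bad), collapse = ", "), call. = FALSE)
      }
      raw[[col]] <- val
    }
  }
  forest_inventory(raw, dbh_min = dbh_min, on_small = on_small)
}

#' Write a stem inventory to delimited text
#'
#' Output is re-readable by [read_inventory()]; numeric fields keep full
#' precision (15 significant digits).
#'
#' @param inv a `forest_inventory` (or coercible data.frame).
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path, delim = ",") {
  cols <- intersect(inventory_columns(), names(inv))
  out <- as.data.frame(inv)[, cols, drop = FALSE]
  for (col in c("dbh_cm", "height_m", "wd", "agb_kg")) {
    if (col %in% names(out)) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           formatC(out[[col]], digits = 15, format = "g"))
    }
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split an inventory into per-plot data.frames
#'
#' @param inv a `forest_inventory`.
#' @return Named list of data.frames, one per (site, plot), names
#'   `"site/plot"`. Plots are 1 ha by construction.
#' @export
split_plots <- function(inv) {
  key <- paste(inv$site, inv$plot, sep = "/")
  split(as.data.frame(inv), factor(key, levels = unique(key)))
}

# ---- wood specific gravity ------------------------------------------------

#' Build a wood-density lookup table with taxonomic fallback levels
#'
#' From a species-level reference (one row per species with family, genus and
#' wood specific gravity in g/cm3) derives genus and family means and a global
#' mean, the fallback chain used when species-level information is missing.
#'
#' @param ref data.frame with columns `family`, `genus`, `species`, `wd`
#'   (names remappable via `col_map`, as for the public wood-density
#'   repositories whose layouts differ).
#' @param col_map optional named character vector mapping canonical names to
#'   `ref`'s column names.
#' @return A `wood_density_table`: list with named numeric vectors `species`,
#'   `genus`, `family` and scalar `global`.
#' @export
wood_density_table <- function(ref, col_map = NULL) {
  ref <- as.data.frame(ref, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(ref)[names(ref) == col_map[[canon]]] <- canon
    }
  }
  need <- c("family", "genus", "species", "wd")
  if (!all(need %in% names(ref))) {
    stop("wood-density reference needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ref$wd <- as.numeric(ref$wd)
  ref <- ref[!is.na(ref$wd), , drop = FALSE]
  if (!nrow(ref)) stop("empty wood-density reference", call. = FALSE)
  if (any(ref$wd <= WD_RANGE[1] | ref$wd >= WD_RANGE[2])) {
    stop("reference wood densities must lie in (", WD_RANGE[1], ", ",
         WD_RANGE[2], ") g/cm3", call. = FALSE)
  }
  sp <- tapply(ref$wd, ref$species, mean)
  ge <- tapply(ref$wd, ref$genus, mean)
  fa <- tapply(ref$wd, ref$family, mean)
  drop_blank <- function(v) v[names(v) != "" & !is.na(names(v))]
  out <- list(species = drop_blank(c(sp)), genus = drop_blank(c(ge)),
              family = drop_blank(c(fa)), global = mean(ref$wd))
  class(out) <- "wood_density_table"
  out
}

#' @export
print.wood_density_table <- function(x, ...) {
  cat("wood_density_table: ", length(x$species), " species, ",
      length(x$genus), " genera, ", length(x$family), " families; global mean ",
      round(x$global, 3), " g/cm3\n", sep = "")
  invisible(x)
}

#' Assign wood specific gravity with species -> genus -> family -> global fallback
#'
#' Each stem receives the species mean where available, otherwise the genus
#' mean, otherwise the family mean, otherwise the dataset-wide mean, and the
#' provenance level is recorded in a `wd_level` column. Stems that already
#' carry a measured `wd` keep it (`wd_level = "measured"`).
#'
#' @param inv a `forest_inventory`.
#' @param table a [wood_density_table()].
#' @return The inventory with `wd` filled and a `wd_level` column.
#' @export
assign_wood_density <- function(inv, table) {
  if (!inherits(table, "wood_density_table")) {
    stop("table must be a wood_density_table", call. = FALSE)
  }
  wd <- inv$wd
  level <- ifelse(!is.na(wd), "measured", NA_character_)
  todo <- is.na(wd)

  hit <- todo & inv$species %in% names(table$species)
  wd[hit] <- table$species[inv$species[hit]]
  level[hit] <- "species"
  todo <- is.na(wd)

  hit <- todo & inv$genus %in% names(table$genus)
  wd[hit] <- table$genus[inv$genus[hit]]
  level[hit] <- "genus"
  todo <- is.na(wd)

  hit <- todo & inv$family %in% names(table$family)
  wd[hit] <- table$family[inv$family[hit]]
  level[hit] <- "family"
  todo <- is.na(wd)

  wd[todo] <- table$global
  level[todo] <- "global"

  inv$wd <- unname(wd)
  inv$wd_level <- level
  inv
}
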