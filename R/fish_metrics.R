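# Fish metrics: areal abundance, Fulton-type condition factor, and
# hatchery-origin accounting for stocked salmonids.

#' Fulton-type condition factor
#'
#' `CF = 1000 * weight / fork_length^3` with weight in g and fork length in
#' cm; a body-condition index for individual fish, sensitive to
#' population-level consequences of contamination.
#'
#' @param weight Body weight, g (> 0).
#' @param fork_length Fork length, cm (> 0).
#' @return Dimensionless condition factor.
#' @examples
#' condition_factor(20, 12)
#' @export
condition_factor <- function(weight, fork_length) {
  if (!is.numeric(weight) || !is.numeric(fork_length))
    stop("weight (g) and fork_length (cm) must be numeric")
  if (any(weight <= 0, na.rm = TRUE) || any(fork_length <= 0, na.rm = TRUE))
    stop("weight and fork length must be positive")
  1000 * weight / fork_length^3
}

#' Tally captures into a complete site x area x species grid
#'
#' Counts individual capture records per sampling area and species,
#' zero-filling areas and species with no captures so downstream abundance
#' summaries see true zeros.
#'
#' @param captures Data frame of individual fish: columns `site`, `area`,
#'   `species` (other columns ignored).
#' @param sites Sites to include; default those present in `captures`.
#' @param areas_per_site Number of sampling areas per site (areas are
#'   labelled `1:areas_per_site`); ignored if `captures$area` contains other
#'   labels, which are then used as the area set.
#' @param species Species to include; default those present in `captures`.
#' @return Data frame: `site`, `area`, `species`, `count`.
#' @export
fish_area_counts <- function(captures, sites = NULL, areas_per_site = 5,
                             species = NULL) {
  stopifnot(all(c("site", "area", "species") %in% names(captures)))
  if (is.null(sites)) sites <- unique(captures$site)
  if (is.null(species)) species <- sort(unique(captures$species))
  areas <- sort(unique(c(seq_len(areas_per_site), captures$area)))
  grid <- expand.grid(site = sites, area = areas, species = species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(s, a, sp) paste(s, a, sp, sep = "\r")
  tab <- table(key(captures$site, captures$area, captures$species))
  grid$count <- as.numeric(tab[key(grid$site, grid$area, grid$species)])
  grid$count[is.na(grid$count)] <- 0
  grid[order(grid$species, grid$site, grid$area), ]
}

#' Site summary of fish abundance
#'
#' Per-area counts are standardized to a nominal sampling area (50 m^2 by
#' default), log10(x + 1)-transformed, and averaged over the replicate areas
#' of each site.
#'
#' @param area_counts Data frame from [fish_area_counts()]; an optional
#'   `area_m2` column gives the measured area of each sampling plot.
#' @param species Species to summarize; default all in `area_counts`.
#' @param standard_m2 Reporting area, m^2.
#' @return Data frame: `species`, `site`, `mean`, `se`, `n`, `transform`.
#' @export
abundance_summary <- function(area_counts, species = NULL, standard_m2 = 50) {
  stopifnot(all(c("site", "area", "species", "count") %in% names(area_counts)))
  if (is.null(species)) species <- unique(area_counts$species)
  am2 <- if ("area_m2" %in% names(area_counts)) area_counts$area_m2 else standard_m2
  scaled <- area_counts$count * standard_m2 / am2
  out <- do.call(rbind, lapply(species, function(sp) {
    sub <- area_counts$species == sp
    cbind(species = sp,
          summarize_by_site(data.frame(site = area_counts$site[sub],
                                       value = scaled[sub]), "log10p1"))
  }))
  rownames(out) <- NULL
  out
}

#' Hatchery-origin proportion from an otolith-mark subsample
#'
#' Estimates the proportion of hatchery fish at a site from the otolith
#' marks of a subsample of captures, either from a vector of marks or from
#' the two counts directly.
#'
#' @param marks Character vector of `"wild"` / `"hatchery"` marks, or `NULL`
#'   when the counts are given.
#' @param n_hatchery,n_checked Counts, used when `marks` is `NULL`.
#' @return List: `proportion`, `n_hatchery`, `n_checked`. An empty
#'   subsample yields `proportion = NA` with a warning.
#' @examples
#' hatchery_proportion(n_hatchery = 13, n_checked = 27)
#' @export
hatchery_proportion <- function(marks = NULL, n_hatchery = NULL,
                                n_checked = NULL) {
  if (!is.null(marks)) {
    bad <- setdiff(unique(marks), c("wild", "hatchery"))
    if (length(bad)) stop("marks must be 'wild' or 'hatchery'; got: ",
                          paste(bad, collapse = ", "))
    n_checked <- length(marks)
    n_hatchery <- sum(marks == "hatchery")
  }
  if (is.null(n_checked) || n_checked == 0) {
    warning("empty otolith subsample; proportion undefined")
    return(list(proportion = NA_real_, n_hatchery = 0L, n_checked = 0L))
  }
  if (n_hatchery < 0 || n_hatchery > n_checked)
    stop("n_hatchery must lie in [0, n_checked]")
  list(proportion = n_hatchery / n_checked,
       n_hatchery = as.integer(n_hatchery), n_checked = as.integer(n_checked))
}

#' Wild (natural-origin) abundance from hatchery proportions
#'
#' Scales per-area counts by `1 - proportion` of hatchery fish. The
#' adjustment is applied to every capture of the species at the site,
#' including fish outside the otolith subsample, i.e. unknown-origin fish
#' are apportioned at the site's subsample proportion. Adjusted counts are
#' real-valued; the downstream log10(x + 1) transform operates on reals.
#'
#' @param counts Numeric per-area counts.
#' @param proportion Hatchery proportion in \[0, 1\].
#' @return Adjusted counts, same length as `counts`.
#' @export
wild_abundance <- function(counts, proportion) {
  if (any(proportion < 0 | proportion > 1, na.rm = TRUE))
    stop("proportion must lie in [0, 1]")
  counts * (1 - proportion)
}

#' Apply site-specific hatchery adjustments to an area-count table
#'
#' Joins per-site otolith subsample results to the area counts of one
#' species and returns the table with wild-adjusted counts. Sites with no
#' subsample keep their raw counts (proportion 0).
#'
#' @param area_counts Data frame from [fish_area_counts()].
#' @param otolith Data frame: `site`, `n_checked`, `n_hatchery`.
#' @param species Species to adjust.
#' @return `area_counts` restricted to `species`, with `count` replaced by
#'   the wild-adjusted value and a `hatchery_proportion` column appended.
#' @export
wild_adjusted_counts <- function(area_counts, otolith, species) {
  stopifnot(all(c("site", "n_checked", "n_hatchery") %in% names(otolith)))
  sub <- area_counts[area_counts$species == species, ]
  p <- otolith$n_hatchery / otolith$n_checked
  prop <- p[match(sub$site, otolith$site)]
  prop[is.na(prop)] <- 0
  sub$count <- wild_abundance(sub$count, prop)
  sub$hatchery_proportion <- prop
  sub
}

#' Drop species with too few captures for analysis
#'
#' Species whose total capture count across all sites is at or below
#' `min_total` are removed (with a message); sparse catches support neither
#' an abundance contrast nor a condition-factor comparison.
#'
#' @param captures Individual capture records with a `species` column.
#' @param min_total Exclusion floor; a species is kept only if its total
#'   captures exceed this.
#' @return `captures` without the rare species.
#' @export
exclude_rare_species <- function(captures, min_total = 5) {
  tot <- table(captures$species)
  drop <- names(tot)[tot <= min_total]
  if (length(drop)) {
    message("excluding species with <= ", min_total, " captures: ",
            paste(drop, collapse = ", "))
    captures <- captures[!captures$species %in% drop, ]
  }
  captures
}
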