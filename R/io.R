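# Delimited-text readers with schema validation. All tables are plain
# UTF-8 CSV (comma separator, dot decimal); censored concentrations are
# written as "<loq" tokens (e.g. "<0.005") and parsed to censored values.

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

.parse_conc <- function(x, metal, loqs) {
  x <- trimws(as.character(x))
  cen <- grepl("^<", x)
  val <- rep(NA_real_, length(x))
  suppressWarnings(val[!cen] <- as.numeric(x[!cen]))
  if (any(is.na(val) & !cen & x != "" & !is.na(x)))
    stop("non-numeric concentration value(s): ",
         paste(unique(x[is.na(val) & !cen & x != ""]), collapse = ", "))
  tok <- suppressWarnings(as.numeric(sub("^<", "", x)))
  loq <- ifelse(cen & is.finite(tok), tok, unname(loqs[metal]))
  list(value = val, censored = cen, loq = loq)
}

#' Read a water-sample table
#'
#' Accepts either a long table (`site`, `metal`, `value`, optional
#' `replicate`) or a wide table (`site` plus one column per metal among Cu,
#' Zn, Cd, Pb). Values may be numeric or censored tokens such as `"<0.005"`;
#' a bare `"<"`-token without a number takes the default LOQ of the metal.
#'
#' @param path CSV file path.
#' @param loqs Named LOQ fallback, ug/L.
#' @return Long data frame: `site`, `replicate`, `metal`, `value`,
#'   `censored`, `loq`.
#' @export
read_water_samples <- function(path, loqs = default_loqs()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_cols(df, "site", "water table")
  metals <- intersect(names(loqs), names(df))
  if ("metal" %in% names(df)) {                     # long form
    .require_cols(df, c("metal", "value"), "water table")
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    p <- .parse_conc(df$value, df$metal, loqs)
    out <- data.frame(site = df$site, replicate = df$replicate,
                      metal = df$metal, value = p$value, censored = p$censored,
                      loq = p$loq, stringsAsFactors = FALSE)
  } else if (length(metals)) {                      # wide form
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    out <- do.call(rbind, lapply(metals, function(m) {
      p <- .parse_conc(df[[m]], rep(m, nrow(df)), loqs)
      data.frame(site = df$site, replicate = df$replicate, metal = m,
                 value = p$value, censored = p$censored, loq = p$loq,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("water table: need either a 'metal' column (long form) or metal ",
         "columns among ", paste(names(loqs), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Read a taxonomy table
#'
#' @param path CSV with columns `taxon`, `family`, `order`.
#' @return Validated data frame.
#' @export
read_taxonomy <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("taxon", "family", "order"), "taxonomy")
  if (anyDuplicated(df$taxon))
    stop("taxonomy: duplicated taxon: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  df
}

#' Read a stone x taxon count matrix
#'
#' Wide CSV with identifier columns `site` and `stone`, optional stone
#' covariates (`depth_cm`, `velocity_cm_s`, `surface_area_cm2`), and one
#' column per taxon holding non-negative integer counts.
#'
#' @param path CSV file path.
#' @return Long count table: `site`, `stone`, `taxon`, `count` (explicit
#'   zeros kept).
#' @export
read_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_cols(df, c("site", "stone"), "count matrix")
  key <- paste(df$site, df$stone)
  if (anyDuplicated(key))
    stop("count matrix: duplicated site/stone row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  covars <- c("site", "stone", "depth_cm", "velocity_cm_s", "surface_area_cm2")
  taxa <- setdiff(names(df), covars)
  if (!length(taxa)) stop("count matrix: no taxon columns found")
  for (tx in taxa) {
    v <- df[[tx]]
    if (!is.numeric(v) || any(!is.finite(v) | v < 0 | v != round(v)))
      stop("count matrix: non-integer or negative counts in column '", tx, "'")
  }
  out <- do.call(rbind, lapply(taxa, function(tx) {
    data.frame(site = df$site, stone = df$stone, taxon = tx,
               count = df[[tx]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read individual fish capture records
#'
#' Columns `site`, `area`, `species`, one of `fork_length_mm` /
#' `fork_length_cm`, `weight_g`, optional `origin`
#' (`wild`/`hatchery`/`unknown`). Fork lengths given in mm are converted to
#' cm at 0.1 cm resolution.
#'
#' @param path CSV file path.
#' @return Data frame with `fork_length_cm` standardized.
#' @export
read_fish_captures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("site", "area", "species", "weight_g"), "fish captures")
  if ("fork_length_mm" %in% names(df)) {
    df$fork_length_cm <- round(df$fork_length_mm / 10, 1)
  } else {
    .require_cols(df, "fork_length_cm", "fish captures")
  }
  if (any(df$fork_length_cm <= 0 | df$weight_g <= 0, na.rm = TRUE))
    stop("fish captures: non-positive length or weight")
  if (!"origin" %in% names(df)) df$origin <- "unknown"
  bad <- setdiff(unique(df$origin), c("wild", "hatchery", "unknown"))
  if (length(bad))
    stop("fish captures: invalid origin value(s): ", paste(bad, collapse = ", "))
  df
}

#' Read otolith subsample counts
#'
#' @param path CSV with columns `site`, `n_checked`, `n_hatchery`.
#' @return Validated data frame.
#' @export
read_otolith <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("site", "n_checked", "n_hatchery"), "otolith table")
  if (any(df$n_hatchery < 0 | df$n_hatchery > df$n_checked))
    stop("otolith table: n_hatchery must lie in [0, n_checked]")
  df
}

#' Read and validate a site-design table
#'
#' @param path CSV with columns `site`, `status`, `reference`, optional
#'   `elevation`.
#' @return Validated data frame (every contaminated site paired to an
#'   existing reference site).
#' @export
read_site_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("site", "status", "reference"), "site design")
  if (anyDuplicated(df$site))
    stop("site design: duplicated site id")
  df$reference[df$reference %in% c("", "NA")] <- NA
  .check_design(df)
  df
}

#' Write the tables of a synthetic scenario as CSV files
#'
#' Emits the same CSV dialects the readers consume, so a generated survey
#' can be round-tripped through the file-based interface.
#'
#' @param scenario A list from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- scenario$water
  w$value <- ifelse(w$censored, paste0("<", w$loq), as.character(w$value))
  # counts wide
  cw <- scenario$counts
  taxa <- unique(cw$taxon)
  key <- paste(cw$site, cw$stone, sep = "\r")
  stones <- !duplicated(key)
  wide <- data.frame(site = cw$site[stones], stone = cw$stone[stones])
  for (tx in taxa)
    wide[[tx]] <- cw$count[cw$taxon == tx][match(key[stones], key[cw$taxon == tx])]
  paths <- c(water = file.path(dir, "water.csv"),
             counts = file.path(dir, "counts.csv"),
             taxonomy = file.path(dir, "taxonomy.csv"),
             captures = file.path(dir, "fish_captures.csv"),
             otolith = file.path(dir, "otolith.csv"),
             design = file.path(dir, "design.csv"))
  write.csv(w[, c("site", "replicate", "metal", "value")], paths["water"],
            row.names = FALSE, quote = FALSE)
  write.csv(wide, paths["counts"], row.names = FALSE, quote = FALSE)
  write.csv(scenario$taxonomy, paths["taxonomy"], row.names = FALSE, quote = FALSE)
  write.csv(scenario$captures, paths["captures"], row.names = FALSE, quote = FALSE)
  write.csv(scenario$otolith, paths["otolith"], row.names = FALSE, quote = FALSE)
  write.csv(scenario$design, paths["design"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
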