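# End-to-end orchestration: water chemistry -> biological metrics ->
# effect classification -> report files.

#' Build replicate-level fish metric values for assessment
#'
#' Turns capture records into the long metric table [assess_impacts()]
#' consumes: per-species areal abundance (counts per `standard_m2`,
#' replicate = sampling area) and per-species condition factor (replicate =
#' individual fish, pooled within site).
#'
#' @param captures Individual capture records (`site`, `area`, `species`,
#'   `fork_length_cm`, `weight_g`).
#' @param sites All sites of the design (so sites with no captures get
#'   explicit zero counts).
#' @param areas_per_site,standard_m2 See [fish_area_counts()] and
#'   [abundance_summary()].
#' @return Long data frame: `site`, `metric`, `value`, `type`.
#' @export
fish_metric_values <- function(captures, sites, areas_per_site = 5,
                               standard_m2 = 50) {
  ac <- fish_area_counts(captures, sites = sites,
                         areas_per_site = areas_per_site)
  am2 <- if ("area_m2" %in% names(ac)) ac$area_m2 else standard_m2
  ab <- data.frame(site = ac$site,
                   metric = paste0(ac$species, "_abundance"),
                   value = ac$count * standard_m2 / am2,
                   type = "abundance", stringsAsFactors = FALSE)
  cf <- data.frame(site = captures$site,
                   metric = paste0(captures$species, "_condition_factor"),
                   value = condition_factor(captures$weight_g,
                                            captures$fork_length_cm),
                   type = "condition", stringsAsFactors = FALSE)
  rbind(ab, cf)
}

#' Run the full assessment pipeline
#'
#' Orchestrates the whole analysis: CCU table from water chemistry,
#' community metrics and dominant-family abundances from stone counts, fish
#' abundance and condition factor from captures, and the two-gate effect
#' classification for every metric. Inputs not supplied are generated from
#' `config` with `seed`, so the default call runs a fully synthetic survey
#' end to end. With `out_dir` set, all result tables are written as CSV
#' together with a plain-text log (package version, seed, options,
#' warnings).
#'
#' To re-analyse a real survey, point the path arguments at CSV files in
#' the documented dialects (see [read_water_samples()], [read_counts()],
#' [read_taxonomy()], [read_fish_captures()], [read_otolith()],
#' [read_site_design()]).
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed RNG seed for any generated inputs.
#' @param config Scenario used for generated inputs ([scenario_config()]).
#' @param water,counts,taxonomy,captures,otolith,design Either data frames,
#'   paths to CSV files, or `NULL` (generate synthetically).
#' @param hardness Water hardness (mg/L CaCO3) at which criteria are
#'   evaluated.
#' @param policy Censoring policy for the CCU (see [compute_ccu()]).
#' @param alpha_range,alpha_test Error rates of the two gates.
#' @param min_fish_total Exclusion floor for rarely captured species.
#' @param wild_adjust Also re-run the masu-salmon abundance assessment with
#'   hatchery-origin fish removed via the otolith proportions.
#' @return List: `ccu`, `community_summary`, `fish_summary`, `assessment`
#'   (the [assess_impacts()] fit), `wild_assessment` (or `NULL`),
#'   `dominant_families`, `log` (character vector), invisibly also written
#'   to `out_dir`.
#' @export
run_pipeline <- function(out_dir = NULL, seed = 1, config = scenario_config(),
                         water = NULL, counts = NULL, taxonomy = NULL,
                         captures = NULL, otolith = NULL, design = NULL,
                         hardness = 10, policy = "zero",
                         alpha_range = 0.10, alpha_test = 0.05,
                         min_fish_total = 5, wild_adjust = TRUE) {
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  as_table <- function(x, reader) if (is.character(x)) reader(x) else x

  gen_needed <- is.null(water) || is.null(counts) || is.null(taxonomy) ||
    is.null(captures) || is.null(design)
  if (gen_needed) {
    scn <- generate_scenario(config, seed)
    note("generated synthetic inputs (seed ", seed, ")")
    if (is.null(water)) water <- scn$water
    if (is.null(counts)) counts <- scn$counts
    if (is.null(taxonomy)) taxonomy <- scn$taxonomy
    if (is.null(captures)) captures <- scn$captures
    if (is.null(otolith)) otolith <- scn$otolith
    if (is.null(design)) design <- scn$design
  }
  water <- as_table(water, read_water_samples)
  counts <- as_table(counts, read_counts)
  taxonomy <- as_table(taxonomy, read_taxonomy)
  captures <- as_table(captures, read_fish_captures)
  otolith <- as_table(otolith, read_otolith)
  design <- as_table(design, read_site_design)
  .check_design(design)

  # --- exposure ---------------------------------------------------------
  criteria <- withCallingHandlers(
    criterion_set(hardness = hardness),
    warning = function(w) {
      log <<- c(log, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  ccu <- ccu_table(water, criteria, policy)
  note("CCU computed for ", nrow(ccu), " sites (policy ", policy,
       ", hardness ", hardness, " mg/L)")

  # --- macroinvertebrates ----------------------------------------------
  doms <- dominant_families(counts, taxonomy)
  note("dominant families: ", paste(doms, collapse = ", "))
  benthos_vals <- rbind(
    stone_metrics(counts, taxonomy)[, c("site", "metric", "value", "type")],
    family_abundances(counts, taxonomy, doms)[, c("site", "metric", "value", "type")]
  )
  community_summary <- site_summary(benthos_vals)

  # --- fishes -----------------------------------------------------------
  captures <- withCallingHandlers(
    exclude_rare_species(captures, min_fish_total),
    message = function(m) {
      log <<- c(log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  fish_vals <- fish_metric_values(captures, sites = design$site,
                                  areas_per_site = config$areas,
                                  standard_m2 = config$area_m2)
  fish_summary <- site_summary(fish_vals)

  # --- classification ---------------------------------------------------
  assessment <- withCallingHandlers(
    assess_impacts(rbind(benthos_vals, fish_vals), design,
                   alpha_range = alpha_range, alpha_test = alpha_test),
    warning = function(w) {
      log <<- c(log, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  nlab <- table(assessment$classification$label)
  note("classification: ",
       paste(names(nlab), as.integer(nlab), collapse = ", "))

  wild_assessment <- NULL
  if (wild_adjust && !is.null(otolith) &&
      "masu_salmon" %in% captures$species) {
    ac <- fish_area_counts(captures, sites = design$site,
                           areas_per_site = config$areas)
    wac <- wild_adjusted_counts(ac, otolith, "masu_salmon")
    wvals <- data.frame(site = wac$site, metric = "masu_salmon_wild_abundance",
                        value = wac$count, type = "abundance",
                        stringsAsFactors = FALSE)
    wild_assessment <- assess_impacts(wvals, design,
                                      alpha_range = alpha_range,
                                      alpha_test = alpha_test)
    note("wild masu salmon re-analysis: ",
         paste(wild_assessment$classification$label, collapse = ", "))
  }

  res <- list(ccu = ccu, community_summary = community_summary,
              fish_summary = fish_summary, assessment = assessment,
              wild_assessment = wild_assessment, dominant_families = doms,
              log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ccu, file.path(out_dir, "ccu.csv"), row.names = FALSE)
    write.csv(community_summary, file.path(out_dir, "community_metrics.csv"),
              row.names = FALSE)
    write.csv(fish_summary, file.path(out_dir, "fish_metrics.csv"),
              row.names = FALSE)
    write.csv(assessment$classification,
              file.path(out_dir, "classification.csv"), row.names = FALSE)
    if (!is.null(wild_assessment))
      write.csv(wild_assessment$classification,
                file.path(out_dir, "classification_wild_masu.csv"),
                row.names = FALSE)
    writeLines(c(
      paste("streamimpact", as.character(utils::packageVersion("streamimpact"))),
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      paste("seed", seed), paste("policy", policy),
      paste("hardness", hardness),
      paste("alpha_range", alpha_range), paste("alpha_test", alpha_test),
      log), file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}
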