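#' Water hardness from dissolved calcium and magnesium
#'
#' Converts dissolved Ca and Mg concentrations (mg/L) to water hardness
#' expressed as mg/L CaCO3, using the standard equivalence
#' `2.497 * Ca + 4.118 * Mg`.
#'
#' @param ca Dissolved calcium, mg/L. Non-negative numeric vector.
#' @param mg Dissolved magnesium, mg/L. Non-negative numeric vector.
#' @return Hardness, mg/L as CaCO3.
#' @examples
#' compute_hardness(2.5, 0.9)
#' @export
compute_hardness <- function(ca, mg) {
  if (!is.numeric(ca) || !is.numeric(mg))
    stop("`ca` and `mg` must be numeric (mg/L)")
  if (any(ca < 0, na.rm = TRUE) || any(mg < 0, na.rm = TRUE))
    stop("negative Ca or Mg concentration")
  2.497 * ca + 4.118 * mg
}

#' Hardness-equation constants for U.S. EPA chronic criteria
#'
#' Constants of the U.S. EPA freshwater chronic (criterion continuous
#' concentration) hardness equations for dissolved Cu, Zn, Cd, and Pb, from
#' the 2006 national recommended water-quality criteria tables. The chronic
#' criterion at hardness `H` (mg/L CaCO3) is
#' `exp(mA * ln(H) + bA) * CF`, where the conversion factor `CF` from total
#' to dissolved metal is a constant for Cu and Zn and hardness-dependent
#' (`cf_a - ln(H) * cf_b`) for Cd and Pb.
#'
#' `digits` is the number of decimals at which each criterion is customarily
#' reported (used by [criterion_set()] when `rounded = TRUE`). Users may edit
#' this table (e.g. for updated criteria) and pass it through the
#' `constants` argument of the criterion functions.
#'
#' @return A data frame with one row per metal: `metal`, `mA`, `bA`, `cf`,
#'   `cf_a`, `cf_b`, `digits`.
#' @export
wqc_constants <- function() {
  data.frame(
    metal = c("Cu", "Zn", "Cd", "Pb"),
    mA = c(0.8545, 0.8473, 0.7409, 1.273),
    bA = c(-1.702, 0.884, -4.719, -4.705),
    cf = c(0.960, 0.986, NA, NA),
    cf_a = c(NA, NA, 1.101672, 1.46203),
    cf_b = c(NA, NA, 0.041838, 0.145712),
    digits = c(1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Hardness-adjusted chronic water-quality criterion
#'
#' Evaluates the U.S. EPA freshwater chronic criterion for a dissolved metal
#' at a given water hardness. Criteria were calibrated with toxicity data at
#' hardness >= 20 mg/L; at softer water the equation is still evaluated but a
#' warning is issued, since extrapolation below the calibration floor needs
#' cautious interpretation.
#'
#' @param metal Character vector of metal names among `"Cu"`, `"Zn"`,
#'   `"Cd"`, `"Pb"`.
#' @param hardness Water hardness, mg/L as CaCO3 (positive scalar or vector
#'   recycled against `metal`).
#' @param constants Constants table, see [wqc_constants()].
#' @param warn Warn when `hardness < 20` mg/L.
#' @return Criterion concentration(s), ug/L dissolved metal.
#' @examples
#' hardness_adjusted_criterion("Zn", 10)
#' @export
hardness_adjusted_criterion <- function(metal, hardness,
                                        constants = wqc_constants(),
                                        warn = TRUE) {
  if (!is.numeric(hardness) || any(!is.finite(hardness)) || any(hardness <= 0))
    stop("`hardness` must be positive and finite (mg/L as CaCO3)")
  n <- max(length(metal), length(hardness))
  metal <- rep_len(metal, n)
  hardness <- rep_len(hardness, n)
  idx <- match(metal, constants$metal)
  if (anyNA(idx))
    stop("no criterion constants for metal(s): ",
         paste(unique(metal[is.na(idx)]), collapse = ", "))
  if (warn && any(hardness < 20))
    warning("hardness below the 20 mg/L floor of the criteria calibration ",
            "range; interpret criteria and CCU with caution", call. = FALSE)
  lh <- log(hardness)
  cf <- constants$cf[idx]
  hd <- is.na(cf)
  cf[hd] <- constants$cf_a[idx[hd]] - lh[hd] * constants$cf_b[idx[hd]]
  exp(constants$mA[idx] * lh + constants$bA[idx]) * cf
}

#' Criteria table for a CCU calculation
#'
#' Builds the per-metal chronic criteria (`c_i`) used as denominators of the
#' cumulative criterion unit. By default criteria are rounded to the
#' precision at which they are conventionally reported (1 decimal for Cu and
#' Zn, 2 for Cd and Pb), which is also the precision used when published CCU
#' tables are recomputed from printed concentrations; set `rounded = FALSE`
#' to keep full precision. The unrounded value is always retained in
#' `criterion_full`.
#'
#' @param hardness Water hardness, mg/L as CaCO3.
#' @param metals Metals to include.
#' @param rounded Round each criterion to its reporting precision.
#' @param constants Constants table, see [wqc_constants()].
#' @param warn Warn when `hardness < 20` mg/L.
#' @return Data frame with columns `metal`, `hardness`, `criterion`,
#'   `criterion_full`.
#' @examples
#' criterion_set(hardness = 10, warn = FALSE)
#' @export
criterion_set <- function(hardness = 10, metals = c("Cu", "Zn", "Cd", "Pb"),
                          rounded = TRUE, constants = wqc_constants(),
                          warn = TRUE) {
  full <- hardness_adjusted_criterion(metals, hardness, constants, warn = warn)
  digs <- constants$digits[match(metals, constants$metal)]
  crit <- if (rounded) round(full, digs) else full
  data.frame(metal = metals, hardness = hardness,
             criterion = crit, criterion_full = full,
             stringsAsFactors = FALSE)
}

.censoring_policies <- c("zero", "half_loq", "loq")

#' Cumulative criterion unit for one water sample
#'
#' Sums the ratios of measured dissolved metal concentrations to their
#' chronic criteria, `CCU = sum(m_i / c_i)`. A CCU above 1 flags potential
#' ecological risk from the measured metals alone. Concentrations flagged as
#' censored (below the limit of quantification) are substituted according to
#' `policy` before the ratios are formed: `"zero"` (default, most
#' conservative downward), `"half_loq"`, or `"loq"`.
#'
#' @param sample Data frame with one row per metal: columns `metal`, `value`
#'   (ug/L dissolved; may be `NA` when censored), and optionally `censored`
#'   (logical) and `loq` (ug/L, required when any value is censored).
#' @param criteria Criteria table from [criterion_set()] (columns `metal`,
#'   `criterion`).
#' @param policy Censoring substitution policy.
#' @return An object of class `"ccu_result"`: list with `ratios` (named
#'   per-metal ratios), `ccu`, `policy`, `n_censored`.
#' @examples
#' s1a <- data.frame(metal = c("Cu", "Cd", "Pb", "Zn"),
#'                   value = c(1.0, 0.13, 0.69, 24.0))
#' compute_ccu(s1a, criterion_set(10, warn = FALSE))
#' @export
compute_ccu <- function(sample, criteria, policy = c("zero", "half_loq", "loq")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(sample), all(c("metal", "value") %in% names(sample)))
  if (anyDuplicated(sample$metal))
    stop("`sample` must have one row per metal; average replicates first ",
         "(see ccu_table())")
  cen <- if ("censored" %in% names(sample)) isTRUE_vec(sample$censored) else
    rep(FALSE, nrow(sample))
  val <- as.numeric(sample$value)
  if (any(cen)) {
    if (!"loq" %in% names(sample) || any(!is.finite(sample$loq[cen]) | sample$loq[cen] <= 0))
      stop("censored values need a positive `loq` column")
    val[cen] <- switch(policy,
                       zero = 0,
                       half_loq = sample$loq[cen] / 2,
                       loq = sample$loq[cen])
  }
  if (any(!is.finite(val) | val < 0))
    stop("metal concentrations must be finite and non-negative")
  ci <- criteria$criterion[match(sample$metal, criteria$metal)]
  if (anyNA(ci))
    stop("no criterion for metal(s): ",
         paste(sample$metal[is.na(ci)], collapse = ", "))
  ratios <- setNames(val / ci, sample$metal)
  structure(list(ratios = ratios, ccu = sum(ratios), policy = policy,
                 n_censored = sum(cen)),
            class = "ccu_result")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x else as.logical(x) %in% TRUE
}

#' @export
print.ccu_result <- function(x, ...) {
  cat("CCU =", format(x$ccu, digits = 4), " (policy:", x$policy, ")\n")
  print(round(x$ratios, 4))
  invisible(x)
}

#' Per-site CCU report table
#'
#' Computes the cumulative criterion unit for every site in a long water
#' table. Replicate samples are first substituted per the censoring policy
#' and then averaged per site and metal, so a metal appears censored in the
#' report only if all its replicates were censored.
#'
#' @param water Long data frame: columns `site`, `metal`, `value`, optional
#'   `replicate`, `censored`, `loq`.
#' @param criteria Criteria table from [criterion_set()].
#' @param policy Censoring substitution policy (see [compute_ccu()]).
#' @return Data frame with one row per site: per-metal ratio columns
#'   (`ratio_<metal>`), `ccu`, `n_censored`, `policy`. Full precision; round
#'   for display (published tables use 1 decimal).
#' @export
ccu_table <- function(water, criteria = criterion_set(warn = FALSE),
                      policy = c("zero", "half_loq", "loq")) {
  policy <- match.arg(policy)
  stopifnot(all(c("site", "metal", "value") %in% names(water)))
  cen <- if ("censored" %in% names(water)) isTRUE_vec(water$censored) else
    rep(FALSE, nrow(water))
  val <- as.numeric(water$value)
  if (any(cen)) {
    if (!"loq" %in% names(water))
      stop("censored values need a `loq` column")
    val[cen] <- switch(policy,
                       zero = 0,
                       half_loq = water$loq[cen] / 2,
                       loq = water$loq[cen])
  }
  agg <- aggregate(cbind(value = val, censored = as.numeric(cen)),
                   by = list(site = water$site, metal = water$metal),
                   FUN = mean)
  sites <- unique(water$site)
  metals <- criteria$metal[criteria$metal %in% unique(water$metal)]
  out <- do.call(rbind, lapply(sites, function(s) {
    rows <- agg[agg$site == s, ]
    samp <- data.frame(metal = rows$metal, value = rows$value)
    res <- compute_ccu(samp, criteria, policy)
    rat <- setNames(as.list(res$ratios[metals]), paste0("ratio_", metals))
    cbind(data.frame(site = s, stringsAsFactors = FALSE),
          as.data.frame(rat),
          data.frame(ccu = res$ccu,
                     n_censored = sum(rows$censored == 1),
                     policy = policy))
  }))
  rownames(out) <- NULL
  out
}

#' Default limits of quantification for dissolved metals
#'
#' LOQs (ug/L) of the ICP-MS protocol assumed by the readers when a censored
#' token (`"<LOQ"` or `"<"` with no number) carries no explicit limit:
#' Cu 0.001, Zn 0.06, Cd 0.005, Pb 0.005.
#'
#' @return Named numeric vector of LOQs, ug/L.
#' @export
default_loqs <- function() {
  c(Cu = 0.001, Zn = 0.06, Cd = 0.005, Pb = 0.005)
}
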