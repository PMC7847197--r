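# Stone-level macroinvertebrate community metrics.
#
# Counts are kept long (site, stone, taxon, count); readers convert the
# wide stones-x-taxa matrix. A stone exists iff it has at least one row,
# so zero-filled tables must carry explicit zero rows (the readers and the
# generator both do).

.insect_orders <- c(mayfly = "Ephemeroptera",
                    caddisfly = "Trichoptera",
                    dipteran = "Diptera")

.stone_id <- function(counts) {
  factor(paste(counts$site, counts$stone, sep = "\r"),
         levels = unique(paste(counts$site, counts$stone, sep = "\r")))
}

.check_counts <- function(counts, taxonomy) {
  stopifnot(all(c("site", "stone", "taxon", "count") %in% names(counts)),
            all(c("taxon", "family", "order") %in% names(taxonomy)))
  if (any(!is.finite(counts$count) | counts$count < 0))
    stop("counts must be finite and non-negative")
  unknown <- setdiff(unique(counts$taxon), taxonomy$taxon)
  if (length(unknown))
    stop("taxa missing from the taxonomy table: ",
         paste(unknown, collapse = ", "))
  ord <- taxonomy$order[match(counts$taxon, taxonomy$taxon)]
  bad <- unique(counts$taxon[is.na(ord) | ord == ""])
  if (length(bad))
    stop("taxa with no order assignment: ", paste(bad, collapse = ", "))
  ord
}

#' Per-stone community metrics
#'
#' Computes the eight community metrics from stone-level taxon counts: total
#' abundance (individuals per stone), total taxon richness (taxa with count
#' > 0 per stone), and the abundance and richness of the three major aquatic
#' insect orders, Ephemeroptera (mayflies), Trichoptera (caddisflies), and
#' Diptera (true flies). Abundances are returned as raw counts; the
#' log10(x + 1) transform is applied later, at site aggregation or
#' assessment ([site_summary()], [assess_impacts()]).
#'
#' @param counts Long count table: columns `site`, `stone`, `taxon`, `count`.
#' @param taxonomy Data frame mapping `taxon` to `family` and `order`. Every
#'   taxon in `counts` must resolve to an order; unresolved taxa are an
#'   error listing the offenders.
#' @return Long data frame: `site`, `stone`, `metric`, `value`, `type`
#'   (`"abundance"` or `"richness"`). Metrics: `total_abundance`,
#'   `total_richness`, and `<group>_{abundance,richness}` for `mayfly`,
#'   `caddisfly`, `dipteran`.
#' @export
stone_metrics <- function(counts, taxonomy) {
  ord <- .check_counts(counts, taxonomy)
  f <- .stone_id(counts)
  first <- !duplicated(f)
  base <- data.frame(site = counts$site[first], stone = counts$stone[first],
                     stringsAsFactors = FALSE)
  pres <- as.numeric(counts$count > 0)
  cols <- list(
    total_abundance = rowsum(counts$count, f)[, 1],
    total_richness  = rowsum(pres, f)[, 1]
  )
  for (g in names(.insect_orders)) {
    m <- as.numeric(ord == .insect_orders[[g]])
    cols[[paste0(g, "_abundance")]] <- rowsum(counts$count * m, f)[, 1]
    cols[[paste0(g, "_richness")]] <- rowsum(pres * m, f)[, 1]
  }
  out <- do.call(rbind, lapply(names(cols), function(nm) {
    data.frame(base, metric = nm, value = unname(cols[[nm]]),
               type = if (grepl("abundance$", nm)) "abundance" else "richness",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-stone abundance of selected families
#'
#' Tallies counts per stone for each requested family. Taxa identified above
#' family level (empty or `NA` family) contribute to order-level metrics but
#' are excluded here.
#'
#' @param counts,taxonomy As in [stone_metrics()].
#' @param families Character vector of families; default all families
#'   occurring in `counts`. Typically [dominant_families()].
#' @return Long data frame: `site`, `stone`, `metric`
#'   (`"<family>_abundance"`), `value`, `type = "abundance"`.
#' @export
family_abundances <- function(counts, taxonomy, families = NULL) {
  .check_counts(counts, taxonomy)
  fam <- taxonomy$family[match(counts$taxon, taxonomy$taxon)]
  fam[is.na(fam) | fam == ""] <- NA
  if (is.null(families))
    families <- sort(unique(fam[!is.na(fam) & counts$count > 0]))
  f <- .stone_id(counts)
  first <- !duplicated(f)
  base <- data.frame(site = counts$site[first], stone = counts$stone[first],
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(families, function(fm) {
    v <- rowsum(counts$count * as.numeric(!is.na(fam) & fam == fm), f)[, 1]
    data.frame(base, metric = paste0(fm, "_abundance"), value = unname(v),
               type = "abundance", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dominant families of the benthic community
#'
#' A family is dominant when (a) it accounts for strictly more than
#' `share_threshold` of the total abundance on a stone — on at least one
#' stone under the default `share_rule = "any_stone"`, on every stone under
#' `"all_stones"` — and (b) it is collected (count > 0) on strictly more
#' than `ceiling(occupancy_threshold * n_stones)` of all stones pooled
#' across sites. With the reference design of 45 stones and a 30% threshold
#' this requires presence on more than 14 stones.
#'
#' @param counts,taxonomy As in [stone_metrics()].
#' @param share_threshold Per-stone share of total abundance, in (0, 1).
#' @param occupancy_threshold Fraction of all stones, in (0, 1).
#' @param share_rule Whether the share condition must hold on any one stone
#'   or on all stones.
#' @return Sorted character vector of qualifying families.
#' @export
dominant_families <- function(counts, taxonomy, share_threshold = 0.05,
                              occupancy_threshold = 0.30,
                              share_rule = c("any_stone", "all_stones")) {
  share_rule <- match.arg(share_rule)
  if (share_threshold <= 0 || share_threshold >= 1 ||
      occupancy_threshold <= 0 || occupancy_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  .check_counts(counts, taxonomy)
  fam <- taxonomy$family[match(counts$taxon, taxonomy$taxon)]
  keep <- !is.na(fam) & fam != ""
  f <- .stone_id(counts)
  n_stones <- nlevels(f)
  stone_tot <- rowsum(counts$count, f)[, 1]
  occ_floor <- ceiling(occupancy_threshold * n_stones)
  res <- vapply(sort(unique(fam[keep])), function(fm) {
    cnt <- rowsum(counts$count * as.numeric(keep & fam == fm), f)[, 1]
    share <- ifelse(stone_tot > 0, cnt / stone_tot, 0)
    share_ok <- if (share_rule == "any_stone") any(share > share_threshold)
                else all(share > share_threshold)
    share_ok && sum(cnt > 0) > occ_floor
  }, logical(1))
  names(res)[res]
}

#' Site means and standard errors of a per-sample metric
#'
#' Aggregates replicate-level values (stones, fish-sampling areas) to site
#' mean and standard error, optionally after a per-replicate log10(x + 1)
#' transform — the transform is applied to each replicate before averaging,
#' never to the site mean. `se = sd / sqrt(n)`; with a single replicate the
#' mean is returned and `se` is `NA`.
#'
#' @param values Data frame with columns `site` and `value`.
#' @param transform `"none"` or `"log10p1"`.
#' @return Data frame: `site`, `mean`, `se`, `n`, `transform`.
#' @examples
#' summarize_by_site(data.frame(site = "A", value = c(9, 99)), "log10p1")
#' @export
summarize_by_site <- function(values, transform = c("none", "log10p1")) {
  transform <- match.arg(transform)
  stopifnot(all(c("site", "value") %in% names(values)))
  v <- as.numeric(values$value)
  if (transform == "log10p1") {
    if (any(v < 0, na.rm = TRUE)) stop("log10(x + 1) needs non-negative values")
    v <- log10(v + 1)
  }
  s <- factor(values$site, levels = unique(values$site))
  n <- as.integer(table(s))
  mean_ <- as.numeric(tapply(v, s, mean))
  sd_ <- as.numeric(tapply(v, s, sd))
  data.frame(site = levels(s), mean = mean_,
             se = ifelse(n > 1, sd_ / sqrt(n), NA_real_),
             n = n, transform = transform, stringsAsFactors = FALSE)
}

#' Site summary of a long metric table
#'
#' Applies [summarize_by_site()] metric by metric, log10(x + 1)-transforming
#' abundance metrics and leaving richness and condition metrics untouched.
#'
#' @param metric_values Long data frame: `site`, `metric`, `value`, `type`
#'   (as produced by [stone_metrics()], [family_abundances()], or the fish
#'   metric builders).
#' @return Data frame: `site`, `metric`, `type`, `mean`, `se`, `n`,
#'   `transform`.
#' @export
site_summary <- function(metric_values) {
  stopifnot(all(c("site", "metric", "value", "type") %in% names(metric_values)))
  out <- do.call(rbind, lapply(unique(metric_values$metric), function(m) {
    sub <- metric_values[metric_values$metric == m, ]
    tr <- if (sub$type[1] == "abundance") "log10p1" else "none"
    cbind(metric = m, type = sub$type[1],
          summarize_by_site(sub, tr))
  }))
  rownames(out) <- NULL
  out[, c("site", "metric", "type", "mean", "se", "n", "transform")]
}
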