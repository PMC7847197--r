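# Effect classification engine: prediction-interval reference ranges,
# single-step (max-|t|) adjusted paired contrasts after one-way ANOVA, and
# the two-gate three-way label.

#' Reference range (90% prediction interval of reference-site means)
#'
#' The reference range for a metric is the prediction interval for a new
#' reference-site mean, obtained from an intercept-only linear model fitted
#' to the observed reference-site means. Its closed form is
#' `mean(x) +/- t(1 - alpha/2, n - 1) * sd(x) * sqrt(1 + 1/n)`.
#' Site means at contaminated sites falling outside this range trigger the
#' first gate of the effect classification.
#'
#' @param means Numeric vector of reference-site means.
#' @param alpha Two-sided error rate; 0.10 gives the 90% interval.
#' @return Object of class `"reference_range"`: list with `mean`, `lower`,
#'   `upper`, `n`, `alpha`, `defined`. With fewer than two finite means the
#'   interval is undefined (`defined = FALSE`, `lower`/`upper` `NA`), the
#'   case of a species captured at a single reference site.
#' @examples
#' reference_range(c(1, 2, 3, 4))
#' @export
reference_range <- function(means, alpha = 0.10) {
  stopifnot(is.numeric(means), alpha > 0, alpha < 1)
  x <- means[is.finite(means)]
  n <- length(x)
  if (n < 2) {
    return(structure(list(mean = if (n) mean(x) else NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          n = n, alpha = alpha, defined = FALSE),
                     class = "reference_range"))
  }
  m <- mean(x)
  half <- qt(1 - alpha / 2, n - 1) * sd(x) * sqrt(1 + 1 / n)
  structure(list(mean = m, lower = m - half, upper = m + half,
                 n = n, alpha = alpha, defined = TRUE),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  if (x$defined)
    cat(sprintf("%.0f%% reference range: [%.4g, %.4g] (mean %.4g, n = %d)\n",
                100 * (1 - x$alpha), x$lower, x$upper, x$mean, x$n))
  else
    cat("reference range undefined (fewer than 2 reference means)\n")
  invisible(x)
}

# Evaluate pmvt under a locally fixed RNG seed, restoring the caller's
# random state so assessment calls do not perturb simulations around them.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Paired site contrasts with single-step max-|t| adjustment
#'
#' Fits a homogeneous-variance one-way fixed-effects model over all sites
#' (pooled within-site variance) and tests each contaminated site against
#' its elevation-matched reference site. Familywise error over the set of
#' contrasts is controlled by the single-step adjustment: the adjusted
#' p-value of contrast `i` is `1 - P(max_j |T_j| <= |t_i|)` under the joint
#' central multivariate t distribution of all contrast statistics (residual
#' degrees of freedom, correlation induced by shared sites and the pooled
#' variance). The joint probability is evaluated by quasi-random
#' integration (`mvtnorm::pmvt`, Genz-Bretz) under a fixed internal seed so
#' results are reproducible to the integration tolerance.
#'
#' @param data Replicate-level data frame: columns `site`, `value`, already
#'   on the analysis scale (log10(x + 1) for abundances, raw for richness,
#'   individual fish for condition factor).
#' @param design Site-design data frame: columns `site`,
#'   `status` (`"contaminated"`/`"reference"`), `reference` (the paired
#'   reference site for contaminated rows). Many-to-one pairing is allowed.
#' @param tol Absolute error tolerance of the multivariate-t integration.
#' @param seed Integration seed.
#' @return Data frame of class `"paired_contrasts"`: one row per contrast
#'   with `site`, `reference`, `estimate` (contaminated minus reference),
#'   `se`, `t`, `df`, `p_raw`, `p_adj`, `direction` (`"lower"`, `"higher"`,
#'   `"none"`). The contrast correlation matrix is attached as attribute
#'   `"corr"`, and `attr(, "degenerate")` flags a model with zero residual
#'   variance (p-values `NA`).
#' @export
paired_contrasts <- function(data, design, tol = 1e-4, seed = 20180626) {
  stopifnot(all(c("site", "value") %in% names(data)),
            all(c("site", "status", "reference") %in% names(design)))
  data <- data[is.finite(data$value), ]
  s <- factor(data$site)
  n_g <- as.integer(table(s))
  g <- levels(s)
  if (any(n_g < 2))
    warning("site(s) with a single replicate included in the ANOVA: ",
            paste(g[n_g < 2], collapse = ", "))
  means <- as.numeric(tapply(data$value, s, mean))
  names(means) <- g
  N <- nrow(data); k <- length(g); df <- N - k
  if (df < 1) stop("no residual degrees of freedom for the pooled ANOVA")
  ss <- sum((data$value - means[as.integer(s)])^2)
  sigma2 <- ss / df
  degenerate <- !is.finite(sigma2) || sigma2 <= 0

  pairs <- design[design$status == "contaminated" &
                    design$site %in% g & design$reference %in% g,
                  c("site", "reference")]
  if (!nrow(pairs)) stop("no testable contaminated/reference pair")
  m <- nrow(pairs)
  C <- matrix(0, m, k, dimnames = list(NULL, g))
  for (i in seq_len(m)) {
    C[i, pairs$site[i]] <- 1
    C[i, pairs$reference[i]] <- -1
  }
  V <- C %*% diag(1 / n_g, k) %*% t(C)      # covariance / sigma2
  est <- as.numeric(C %*% means)
  se <- sqrt(sigma2 * diag(V))
  tstat <- est / se
  corr <- V / sqrt(tcrossprod(diag(V)))

  if (degenerate) {
    warning("zero residual variance: contrasts are degenerate, p-values NA")
    p_raw <- p_adj <- rep(NA_real_, m)
  } else {
    p_raw <- 2 * pt(-abs(tstat), df)
    if (m == 1L) {
      p_adj <- p_raw
    } else {
      p_adj <- vapply(abs(tstat), function(a) {
        if (!is.finite(a)) return(0)
        pr <- .with_seed(seed, mvtnorm::pmvt(
          lower = rep(-a, m), upper = rep(a, m), delta = rep(0, m),
          df = as.integer(df), corr = corr,
          algorithm = mvtnorm::GenzBretz(abseps = tol, maxpts = 50000L)))
        min(max(1 - as.numeric(pr), 0), 1)
      }, numeric(1))
      p_adj <- pmax(p_adj, p_raw)   # adjusted p can never undercut raw p
    }
  }
  out <- data.frame(site = pairs$site, reference = pairs$reference,
                    estimate = est, se = se, t = tstat, df = df,
                    p_raw = p_raw, p_adj = p_adj,
                    direction = ifelse(est < 0, "lower",
                                       ifelse(est > 0, "higher", "none")),
                    stringsAsFactors = FALSE)
  attr(out, "corr") <- corr
  attr(out, "degenerate") <- degenerate
  class(out) <- c("paired_contrasts", "data.frame")
  out
}

#' Two-gate effect label
#'
#' Combines the two gates of the classification: `"adverse"` when the site
#' mean lies outside the reference range *and* the multiplicity-adjusted
#' contrast is significant; `"some_concern"` when exactly one gate fires;
#' `"no_concern"` when neither does.
#'
#' @param outside_range Logical; `NA` (undefined range) is treated as
#'   not-triggered.
#' @param significant Logical; `NA` (degenerate test) is treated as
#'   not-triggered.
#' @return Character vector of labels.
#' @export
effect_label <- function(outside_range, significant) {
  o <- !is.na(outside_range) & outside_range
  s <- !is.na(significant) & significant
  ifelse(o & s, "adverse", ifelse(o | s, "some_concern", "no_concern"))
}

#' Percent difference from the paired reference site
#'
#' Reports how much lower (positive) or higher (negative) a contaminated
#' site's metric is than its reference site's,
#' `100 * (ref - cont) / ref`. For abundance metrics analysed on the
#' log10(x + 1) scale the comparison is made on back-transformed mean
#' abundances (`10^mean - 1`) by default; `scale = "raw_mean"` compares the
#' analysis-scale means directly.
#'
#' @param cont_mean,ref_mean Site means on the analysis scale.
#' @param scale `"backtransformed"` or `"raw_mean"`.
#' @return Percent difference; `NA` when the reference value is not
#'   positive.
#' @export
percent_difference <- function(cont_mean, ref_mean,
                               scale = c("backtransformed", "raw_mean")) {
  scale <- match.arg(scale)
  if (scale == "backtransformed") {
    a <- 10^cont_mean - 1
    b <- 10^ref_mean - 1
  } else {
    a <- cont_mean
    b <- ref_mean
  }
  ifelse(is.finite(b) & b > 0, 100 * (b - a) / b, NA_real_)
}

#' Assess metal-contamination effects at contaminated sites
#'
#' The central fit of the package. For every metric in a replicate-level
#' table it (1) computes site means on the analysis scale (abundances
#' log10(x + 1)-transformed per replicate, richness and condition raw),
#' (2) derives the reference range — the `1 - alpha_range` prediction
#' interval of the reference-site means, (3) tests each contaminated site
#' against its paired reference site with the single-step max-|t|
#' adjustment after a one-way ANOVA over all sites, and (4) labels every
#' metric x contaminated site combination `adverse`, `some_concern`, or
#' `no_concern` by the two-gate rule.
#'
#' For abundance metrics the reference range is computed only when the taxon
#' or species is present (positive site mean) at `min_reference_presence`
#' or more reference sites; otherwise the range gate is skipped and flagged,
#' mirroring the treatment of species captured at a single reference site.
#'
#' @param values Replicate-level long table: columns `site`, `metric`,
#'   `value`, `type` (`"abundance"`, `"richness"`, or `"condition"`).
#'   Replicates are stones, fish-sampling areas, or individual fish
#'   (condition factor is pooled per site, not averaged per area).
#' @param design Site-design data frame: `site`, `status`, `reference`.
#' @param alpha_range Error rate of the reference range (0.10 = 90%
#'   prediction interval).
#' @param alpha_test Significance level for the adjusted contrasts.
#' @param percent_scale Scale for the reported percent difference of
#'   abundance metrics, see [percent_difference()].
#' @param min_reference_presence Minimum number of reference sites at which
#'   an abundance metric must be present for a defined reference range.
#' @param tol,seed Multivariate-t integration control, see
#'   [paired_contrasts()].
#' @return Object of class `"impact_assessment"`; see
#'   [print.impact_assessment()], [summary.impact_assessment()],
#'   [plot.impact_assessment()], and `as.data.frame()` which returns the
#'   classification table (`metric`, `site`, `label`, gates, adjusted p,
#'   percent difference, ...).
#' @examples
#' scn <- scenario_config(beta = 0)
#' counts <- generate_benthos(scn, seed = 1)
#' vals <- stone_metrics(counts, scenario_taxonomy(scn))
#' fit <- assess_impacts(vals, scn$design)
#' fit
#' @export
assess_impacts <- function(values, design,
                           alpha_range = 0.10, alpha_test = 0.05,
                           percent_scale = c("backtransformed", "raw_mean"),
                           min_reference_presence = 2,
                           tol = 1e-4, seed = 20180626) {
  percent_scale <- match.arg(percent_scale)
  stopifnot(all(c("site", "metric", "value", "type") %in% names(values)),
            all(c("site", "status", "reference") %in% names(design)))
  .check_design(design)
  ref_sites <- design$site[design$status == "reference"]
  metrics <- unique(values$metric)
  ranges <- list(); contrasts <- list(); cls <- list(); means_l <- list()

  for (mt in metrics) {
    sub <- values[values$metric == mt, ]
    ty <- sub$type[1]
    av <- sub$value
    if (ty == "abundance") av <- log10(av + 1)
    dat <- data.frame(site = sub$site, value = av)
    sm <- summarize_by_site(dat, "none")
    means_l[[mt]] <- cbind(metric = mt, type = ty, sm)

    ref_means <- sm$mean[match(ref_sites, sm$site)]
    n_present <- sum(is.finite(ref_means) & ref_means > 0)
    range_skipped <- ty == "abundance" && n_present < min_reference_presence
    rr <- if (range_skipped) reference_range(numeric(0), alpha_range)
          else reference_range(ref_means, alpha_range)
    ranges[[mt]] <- data.frame(metric = mt, mean = rr$mean, lower = rr$lower,
                               upper = rr$upper, n_ref = rr$n,
                               alpha = alpha_range, defined = rr$defined,
                               stringsAsFactors = FALSE)

    ct <- paired_contrasts(dat, design, tol = tol, seed = seed)
    contrasts[[mt]] <- cbind(metric = mt, as.data.frame(ct))

    site_mean <- sm$mean[match(ct$site, sm$site)]
    ref_mean <- sm$mean[match(ct$reference, sm$site)]
    outside <- if (rr$defined)
      site_mean < rr$lower | site_mean > rr$upper else NA
    range_dir <- if (rr$defined)
      ifelse(site_mean < rr$lower, "lower",
             ifelse(site_mean > rr$upper, "higher", "none")) else "undefined"
    signif <- !is.na(ct$p_adj) & ct$p_adj < alpha_test
    pd <- percent_difference(site_mean, ref_mean,
                             if (ty == "abundance") percent_scale else "raw_mean")
    cls[[mt]] <- data.frame(
      metric = mt, type = ty, site = ct$site, reference = ct$reference,
      site_mean = site_mean, ref_mean = ref_mean,
      outside_range = outside, range_direction = range_dir,
      range_defined = rr$defined,
      p_adj = ct$p_adj, significant = signif, direction = ct$direction,
      percent_lower = pd,
      label = effect_label(outside, signif),
      stringsAsFactors = FALSE)
  }
  res <- list(classification = do.call(rbind, c(cls, make.row.names = FALSE)),
              ranges = do.call(rbind, c(ranges, make.row.names = FALSE)),
              contrasts = do.call(rbind, c(contrasts, make.row.names = FALSE)),
              site_means = do.call(rbind, c(means_l, make.row.names = FALSE)),
              design = design, alpha_range = alpha_range,
              alpha_test = alpha_test, percent_scale = percent_scale,
              call = match.call())
  class(res) <- "impact_assessment"
  res
}

.check_design <- function(design) {
  if (!all(design$status %in% c("contaminated", "reference")))
    stop("design status must be 'contaminated' or 'reference'")
  cont <- design[design$status == "contaminated", ]
  missing_ref <- is.na(cont$reference) |
    !cont$reference %in% design$site[design$status == "reference"]
  if (any(missing_ref))
    stop("contaminated site(s) without a valid paired reference site: ",
         paste(cont$site[missing_ref], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.impact_assessment <- function(x, ...) {
  cl <- x$classification
  cat("Impact assessment:", length(unique(cl$metric)), "metrics x",
      length(unique(cl$site)), "contaminated sites\n")
  cat(sprintf("  reference range: %.0f%% prediction interval; contrast alpha = %.2f (single-step adjusted)\n",
              100 * (1 - x$alpha_range), x$alpha_test))
  tab <- table(factor(cl$label, levels = c("adverse", "some_concern", "no_concern")))
  cat("  labels: adverse", tab[["adverse"]],
      "| some_concern", tab[["some_concern"]],
      "| no_concern", tab[["no_concern"]], "\n")
  adv <- cl[cl$label == "adverse", ]
  if (nrow(adv)) {
    cat("  adverse effects:\n")
    for (i in seq_len(nrow(adv)))
      cat(sprintf("    %s at %s (%s than %s, adj. p = %.3g%s)\n",
                  adv$metric[i], adv$site[i], adv$direction[i],
                  adv$reference[i], adv$p_adj[i],
                  if (is.finite(adv$percent_lower[i]))
                    sprintf(", %.0f%% lower", adv$percent_lower[i]) else ""))
  }
  invisible(x)
}

#' @rdname print.impact_assessment
#' @param object,x An `impact_assessment` fit.
#' @param ... Unused.
#' @export
summary.impact_assessment <- function(object, ...) {
  cl <- object$classification
  cl$p_adj <- signif(cl$p_adj, 3)
  cl$site_mean <- signif(cl$site_mean, 4)
  cl$ref_mean <- signif(cl$ref_mean, 4)
  cl$percent_lower <- round(cl$percent_lower)
  print(cl[, c("metric", "site", "label", "range_direction", "p_adj",
               "direction", "percent_lower")], row.names = FALSE)
  invisible(cl)
}

#' @export
as.data.frame.impact_assessment <- function(x, ...) x$classification

#' Plot site means against the reference range
#'
#' Draws, for one metric, the site means with +/- 1 SE bars, the reference
#' band (shaded) with the reference mean (dashed), and an asterisk above
#' contaminated sites whose adjusted contrast is significant — the
#' conventional presentation of paired-design bioassessment results.
#'
#' @param x An `impact_assessment` fit.
#' @param metric Metric name; default the first.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.impact_assessment <- function(x, metric = NULL, ...) {
  if (is.null(metric)) metric <- x$classification$metric[1]
  sm <- x$site_means[x$site_means$metric == metric, ]
  rg <- x$ranges[x$ranges$metric == metric, ]
  cl <- x$classification[x$classification$metric == metric, ]
  ord <- order(match(sm$site, x$design$site))
  sm <- sm[ord, ]
  ylim <- range(c(sm$mean - sm$se, sm$mean + sm$se, rg$lower, rg$upper),
                na.rm = TRUE)
  n <- nrow(sm)
  plot(seq_len(n), sm$mean, xaxt = "n", xlab = "", ylab = metric,
       ylim = ylim + c(-0.05, 0.1) * diff(ylim), pch = 19, ...)
  axis(1, at = seq_len(n), labels = sm$site, las = 2)
  if (isTRUE(rg$defined)) {
    graphics::rect(0.5, rg$lower, n + 0.5, rg$upper,
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
    graphics::abline(h = rg$mean, lty = 2)
  }
  graphics::segments(seq_len(n), sm$mean - sm$se, seq_len(n), sm$mean + sm$se)
  graphics::points(seq_len(n), sm$mean, pch = 19)
  sig <- cl$site[cl$significant]
  if (length(sig)) {
    i <- match(sig, sm$site)
    graphics::text(i, (sm$mean + sm$se)[i] + 0.04 * diff(ylim), "*", cex = 1.5)
  }
  invisible(x)
}
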