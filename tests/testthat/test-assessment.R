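test_that("reference range matches the closed form and handles degeneracy", {
  rr <- reference_range(c(1, 2, 3, 4), alpha = 0.10)
  expect_equal(rr$mean, 2.5)
  # frozen from an independent t-table evaluation of the closed form
  expect_equal(rr$upper - rr$mean, 3.3968, tolerance = 1e-4)
  expect_equal(rr$lower, -0.897, tolerance = 1e-3)
  expect_equal(rr$upper, 5.897, tolerance = 1e-3)
  # identical means collapse to zero width
  rr0 <- reference_range(c(3, 3, 3))
  expect_equal(rr0$lower, 3)
  expect_equal(rr0$upper, 3)
  # fewer than two means: undefined, flagged
  rr1 <- reference_range(5)
  expect_false(rr1$defined)
  expect_true(is.na(rr1$lower))
})

test_that("reference range equals the lm prediction-interval oracle", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    y <- rnorm(n, 10, 3)
    rr <- reference_range(y, alpha = 0.10)
    fit <- lm(y ~ 1)
    pi <- predict(fit, newdata = data.frame(x = 1), interval = "prediction",
                  level = 0.90)
    expect_equal(rr$lower, unname(pi[1, "lwr"]))
    expect_equal(rr$upper, unname(pi[1, "upr"]))
  }
})

test_that("a single contrast reduces to the pooled two-sample t-test", {
  set.seed(4)
  d <- data.frame(site = rep(c("S", "R"), each = 6),
                  value = c(rnorm(6, 9), rnorm(6, 10)))
  design <- data.frame(site = c("S", "R"),
                       status = c("contaminated", "reference"),
                       reference = c("R", NA))
  ct <- paired_contrasts(d, design)
  tt <- t.test(value ~ site, data = d, var.equal = TRUE)
  # t.test orders groups R, S: estimate is R - S
  expect_equal(abs(ct$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(ct$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(ct$p_raw, ct$p_adj)
})

test_that("a null contrast has adjusted p of 1", {
  d <- data.frame(site = rep(c("S", "R"), each = 3),
                  value = c(1, 2, 3, 3, 2, 1))
  design <- data.frame(site = c("S", "R"),
                       status = c("contaminated", "reference"),
                       reference = c("R", NA))
  ct <- paired_contrasts(d, design)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p_adj, 1)
  expect_equal(ct$direction, "none")
})

test_that("single-step adjusted p agrees with the multcomp oracle", {
  library(multcomp)
  d <- balanced_site_data(seed = 12, effects = c(S1a = -2, S2 = -1))
  design <- default_design()
  ct <- paired_contrasts(d, design, tol = 1e-5)
  fit <- lm(value ~ 0 + site, data = d)
  K <- matrix(0, nrow(ct), nlevels(factor(d$site)),
              dimnames = list(NULL, paste0("site", levels(factor(d$site)))))
  for (i in seq_len(nrow(ct))) {
    K[i, paste0("site", ct$site[i])] <- 1
    K[i, paste0("site", ct$reference[i])] <- -1
  }
  gl <- summary(glht(fit, linfct = K))
  expect_equal(unname(ct$estimate), unname(gl$test$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(ct$t), unname(gl$test$tstat), tolerance = 1e-10)
  expect_equal(unname(ct$p_adj), unname(as.numeric(gl$test$pvalues)),
               tolerance = 2e-3)
})

test_that("adjusted p is monotone in |t| and at least the raw p", {
  d <- balanced_site_data(seed = 21, effects = c(S1a = -3, S1b = -1, S3 = 2))
  ct <- paired_contrasts(d, default_design())
  ord <- order(abs(ct$t), decreasing = TRUE)
  expect_true(all(diff(ct$p_adj[ord]) >= -1e-9))
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12))
  expect_true(all(ct$p_adj <= 1 & ct$p_adj >= 0))
})

test_that("adjusted p is invariant to contrast relabelling", {
  d <- balanced_site_data(seed = 31, effects = c(S2 = -2))
  design <- default_design()
  ct1 <- paired_contrasts(d, design)
  perm <- design[c(5:1, 6:9), ]   # reorder the contaminated rows
  ct2 <- paired_contrasts(d, perm)
  m <- match(ct1$site, ct2$site)
  expect_equal(ct1$p_adj, ct2$p_adj[m], tolerance = 1e-3)
})

test_that("degenerate zero-variance data are flagged", {
  d <- data.frame(site = rep(c("S", "R"), each = 3), value = 5)
  design <- data.frame(site = c("S", "R"),
                       status = c("contaminated", "reference"),
                       reference = c("R", NA))
  expect_warning(ct <- paired_contrasts(d, design), "degenerate")
  expect_true(is.na(ct$p_adj))
  expect_true(attr(ct, "degenerate"))
})

test_that("the two-gate rule labels all four gate combinations", {
  expect_equal(effect_label(TRUE, TRUE), "adverse")
  expect_equal(effect_label(FALSE, TRUE), "some_concern")
  expect_equal(effect_label(TRUE, FALSE), "some_concern")
  expect_equal(effect_label(FALSE, FALSE), "no_concern")
  # undefined gates are treated as not triggered
  expect_equal(effect_label(NA, TRUE), "some_concern")
  expect_equal(effect_label(NA, FALSE), "no_concern")
})

test_that("percent difference reports reductions on the requested scale", {
  expect_equal(percent_difference(5, 10, "raw_mean"), 50)
  expect_equal(percent_difference(10, 10, "raw_mean"), 0)
  expect_equal(percent_difference(2.5, 10, "raw_mean"), 75)
  expect_true(is.na(percent_difference(1, 0, "raw_mean")))
  # back-transformed: log10 means 1 and 2 are abundances 9 and 99
  expect_equal(percent_difference(1, 2), 100 * (99 - 9) / 99)
})

test_that("assess_impacts classifies a clear effect as adverse end to end", {
  set.seed(7)
  design <- default_design()
  mu <- setNames(rep(50, 9), design$site)
  mu[c("S1a", "S1b")] <- 3   # strong depletion upstream
  vals <- do.call(rbind, lapply(design$site, function(s) {
    data.frame(site = s, metric = "demo_abundance",
               value = rpois(5, mu[[s]]), type = "abundance")
  }))
  fit <- assess_impacts(vals, design)
  cl <- fit$classification
  expect_s3_class(fit, "impact_assessment")
  expect_equal(cl$label[cl$site %in% c("S1a", "S1b")],
               c("adverse", "adverse"))
  expect_equal(cl$range_direction[cl$site == "S1a"], "lower")
  expect_false(any(cl$label[cl$site %in% c("S3", "S4")] == "adverse"))
  expect_output(print(fit), "adverse")
})

test_that("abundance metrics absent from the reference sites skip the range gate", {
  design <- default_design()
  set.seed(15)
  vals <- do.call(rbind, lapply(design$site, function(s) {
    lambda <- if (s == "R1") 10 else if (s %in% c("S1a", "S1b")) 8 else 0
    data.frame(site = s, metric = "char_abundance",
               value = rpois(5, lambda), type = "abundance")
  }))
  fit <- assess_impacts(vals, design)
  expect_false(fit$ranges$defined[1])
  expect_equal(unique(fit$classification$range_direction), "undefined")
  # without the range gate the label can never be adverse
  expect_false(any(fit$classification$label == "adverse"))
})

test_that("the design validator rejects broken pairings", {
  bad <- data.frame(site = c("S1", "R1"),
                    status = c("contaminated", "reference"),
                    reference = c("R9", NA))
  d <- data.frame(site = rep(c("S1", "R1"), each = 3), value = rnorm(6),
                  metric = "m", type = "richness")
  expect_error(assess_impacts(d, bad), "S1")
})
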