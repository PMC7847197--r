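test_that("stone metrics tally abundance and richness by order", {
  m <- rbind(c(10, 5, 0, 0, 0))
  colnames(m) <- c("Baetis", "Hydropsyche", "Chironomus", "Epeorus", "Tubifex")
  cnt <- counts_from_matrix(m, sites = "A", stones = 1)
  sm <- stone_metrics(cnt, tiny_taxonomy())
  v <- setNames(sm$value, sm$metric)
  expect_equal(v[["total_abundance"]], 15)
  expect_equal(v[["total_richness"]], 2)
  expect_equal(v[["mayfly_abundance"]], 10)
  expect_equal(v[["mayfly_richness"]], 1)
  expect_equal(v[["caddisfly_abundance"]], 5)
  expect_equal(v[["caddisfly_richness"]], 1)
  expect_equal(v[["dipteran_abundance"]], 0)
  expect_equal(v[["dipteran_richness"]], 0)
})

test_that("an empty stone yields all-zero metrics", {
  cnt <- data.frame(site = "A", stone = 1,
                    taxon = c("Baetis", "Chironomus"), count = 0)
  sm <- stone_metrics(cnt, tiny_taxonomy())
  expect_true(all(sm$value == 0))
})

test_that("unknown taxa are an error listing the offenders", {
  cnt <- data.frame(site = "A", stone = 1,
                    taxon = c("Baetis", "Mysterium"), count = 1)
  expect_error(stone_metrics(cnt, tiny_taxonomy()), "Mysterium")
})

test_that("stone metrics agree with a brute-force tally on a 45-stone table", {
  scn <- scenario_config()
  counts <- generate_benthos(scn, seed = 11)
  tax <- scenario_taxonomy(scn)
  sm <- stone_metrics(counts, tax)
  orders <- c(mayfly = "Ephemeroptera", caddisfly = "Trichoptera",
              dipteran = "Diptera")
  for (s in unique(counts$site)) for (st in unique(counts$stone)) {
    rows <- counts[counts$site == s & counts$stone == st, ]
    ord <- tax$order[match(rows$taxon, tax$taxon)]
    pick <- function(metric) {
      sm$value[sm$site == s & sm$stone == st & sm$metric == metric]
    }
    expect_equal(pick("total_abundance"), sum(rows$count))
    expect_equal(pick("total_richness"), sum(rows$count > 0))
    for (g in names(orders)) {
      expect_equal(pick(paste0(g, "_abundance")),
                   sum(rows$count[ord == orders[[g]]]))
      expect_equal(pick(paste0(g, "_richness")),
                   sum(rows$count[ord == orders[[g]]] > 0))
    }
  }
})

test_that("order-level metrics never exceed the totals", {
  scn <- scenario_config()
  counts <- generate_benthos(scn, seed = 3)
  sm <- stone_metrics(counts, scenario_taxonomy(scn))
  key <- paste(sm$site, sm$stone)
  for (k in unique(key)) {
    v <- setNames(sm$value[key == k], sm$metric[key == k])
    expect_lte(v[["mayfly_abundance"]] + v[["caddisfly_abundance"]] +
                 v[["dipteran_abundance"]], v[["total_abundance"]])
    expect_lte(v[["mayfly_richness"]] + v[["caddisfly_richness"]] +
                 v[["dipteran_richness"]], v[["total_richness"]])
  }
})

test_that("dominant-family occupancy boundary excludes exactly-30% presence", {
  # 45 stones; family Fb present on exactly 14 (excluded), then 15 (included)
  sites <- rep(paste0("s", 1:9), each = 5)
  stones <- rep(1:5, 9)
  tax <- data.frame(taxon = c("A1", "B1"), family = c("Fa", "Fb"),
                    order = "Ephemeroptera", stringsAsFactors = FALSE)
  for (n_present in c(14, 15)) {
    cnt <- rbind(
      data.frame(site = sites, stone = stones, taxon = "A1", count = 100),
      data.frame(site = sites, stone = stones, taxon = "B1",
                 count = rep(c(50, 0), c(n_present, 45 - n_present))))
    doms <- dominant_families(cnt, tax)
    if (n_present == 14) expect_false("Fb" %in% doms)
    else expect_true("Fb" %in% doms)
    expect_true("Fa" %in% doms)  # 100% share on every stone
  }
})

test_that("dominant families are monotone in both thresholds", {
  scn <- scenario_config()
  counts <- generate_benthos(scn, seed = 5)
  tax <- scenario_taxonomy(scn)
  base <- dominant_families(counts, tax, 0.05, 0.30)
  for (st in c(0.10, 0.20)) {
    expect_true(all(dominant_families(counts, tax, st, 0.30) %in% base))
  }
  for (ot in c(0.50, 0.80)) {
    expect_true(all(dominant_families(counts, tax, 0.05, ot) %in% base))
  }
  expect_error(dominant_families(counts, tax, 0, 0.3), "thresholds")
})

test_that("family abundances exclude taxa unresolved below order level", {
  cnt <- data.frame(site = "A", stone = 1,
                    taxon = c("Baetis", "Tubifex"), count = c(3, 7))
  fa <- family_abundances(cnt, tiny_taxonomy())
  expect_equal(fa$metric, "Baetidae_abundance")
  expect_equal(fa$value, 3)
})

test_that("site summaries transform per replicate before averaging", {
  s <- summarize_by_site(data.frame(site = "A", value = c(9, 99)), "log10p1")
  expect_equal(s$mean, 1.5)
  expect_equal(s$se, 0.5)
  expect_equal(s$n, 2L)
  # identical stones: zero standard error
  s0 <- summarize_by_site(data.frame(site = "A", value = c(7, 7, 7)), "log10p1")
  expect_equal(s0$se, 0)
  # no transform leaves richness integers unchanged
  sr <- summarize_by_site(data.frame(site = "A", value = c(3, 5)), "none")
  expect_equal(sr$mean, 4)
  # single replicate: mean defined, se flagged NA
  s1 <- summarize_by_site(data.frame(site = "A", value = 9), "log10p1")
  expect_equal(s1$mean, 1)
  expect_true(is.na(s1$se))
})

test_that("site_summary equals the element-wise oracle at full precision", {
  scn <- scenario_config()
  counts <- generate_benthos(scn, seed = 8)
  sm <- stone_metrics(counts, scenario_taxonomy(scn))
  ss <- site_summary(sm[, c("site", "metric", "value", "type")])
  sub <- sm[sm$metric == "total_abundance", ]
  for (s in unique(sub$site)) {
    oracle <- mean(log10(sub$value[sub$site == s] + 1))
    expect_equal(ss$mean[ss$site == s & ss$metric == "total_abundance"], oracle)
  }
  # richness is untransformed
  sub <- sm[sm$metric == "total_richness", ]
  s1 <- unique(sub$site)[1]
  expect_equal(ss$mean[ss$site == s1 & ss$metric == "total_richness"],
               mean(sub$value[sub$site == s1]))
})
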