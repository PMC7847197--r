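# Small in-code fixtures shared across test files.

tiny_taxonomy <- function() {
  data.frame(
    taxon = c("Baetis", "Hydropsyche", "Chironomus", "Epeorus", "Tubifex"),
    family = c("Baetidae", "Hydropsychidae", "Chironomidae",
               "Heptageniidae", NA),
    order = c("Ephemeroptera", "Trichoptera", "Diptera", "Ephemeroptera",
              "Tubificida"),
    stringsAsFactors = FALSE
  )
}

# long count table from a stones x taxa matrix
counts_from_matrix <- function(m, sites, stones) {
  stopifnot(nrow(m) == length(sites), length(sites) == length(stones))
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    data.frame(site = sites, stone = stones, taxon = colnames(m)[j],
               count = m[, j], stringsAsFactors = FALSE)
  }))
}

table2_water <- function() {
  read_water_samples(system.file("extdata", "tokushibetsu_water_table2.csv",
                                 package = "streamimpact"))
}

table2_printed_ccu <- function() {
  # sites whose printed CCU is recomputable from the printed inputs
  c(S1a = 8.4, S1b = 9.4, R1 = 2.1, R2 = 0.1, R3 = 0.3, R4 = 0.3)
}

# balanced replicate-level data for the 9-site design
balanced_site_data <- function(seed = 1, n = 5, effects = NULL) {
  design <- default_design()
  set.seed(seed)
  mu <- setNames(rep(10, nrow(design)), design$site)
  if (!is.null(effects)) mu[names(effects)] <- mu[names(effects)] + effects
  data.frame(site = rep(design$site, each = n),
             value = rnorm(n * nrow(design), rep(mu, each = n), 1),
             stringsAsFactors = FALSE)
}
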