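# Shared fixtures and independent oracles for the suite.
# `.fixture_cache` persists across test files within one run, so expensive
# simulations are performed once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_network <- function() cached("network", tf_pathway_network())

nominal_composition <- function() {
  plasma_composition("nominal", "control",
                     fII = 100, fV = 100, fVII = 100, fVIII = 100,
                     fIX = 100, fX = 100, AT = 100, TFPI = 100)
}

nominal_trajectory <- function() {
  cached("nominal_traj", simulate_subject(nominal_composition()))
}

fixture_trajectory <- function(name) {
  cached(paste0("traj_", name),
         simulate_subject(fixture_compositions()[[name]]))
}

# Draw a composition uniformly within the published control ranges.
random_composition <- function(id = "rand") {
  spec <- cohort_spec()$factors$control
  lv <- vapply(spec, function(p) stats::runif(1, p$min, p$max), numeric(1))
  plasma_composition(id, "control",
                     fII = lv[["fII"]], fV = lv[["fV"]], fVII = lv[["fVII"]],
                     fVIII = lv[["fVIII"]], fIX = lv[["fIX"]],
                     fX = lv[["fX"]], AT = lv[["AT"]], TFPI = lv[["TFPI"]])
}

# Independent brute-force mass-action derivative: walks the reaction strings
# one reaction at a time, accumulating flux into reactant/product species.
# Deliberately naive; shares no code with network_derivative() or the
# compiled engine.
brute_force_derivative <- function(state, network) {
  d <- setNames(numeric(length(network$species)), network$species)
  for (j in seq_len(nrow(network$reactions))) {
    re <- strsplit(network$reactions$reactants[j], "+", fixed = TRUE)[[1]]
    pr <- strsplit(network$reactions$products[j], "+", fixed = TRUE)[[1]]
    flux <- network$reactions$k[j]
    for (sp in re) flux <- flux * state[[sp]]
    for (sp in re) d[sp] <- d[sp] - flux
    for (sp in pr) d[sp] <- d[sp] + flux
  }
  d
}

# Independent metric recomputation from a trajectory file on disk: re-reads
# the TSV and recomputes the five parameters with plain arithmetic.
file_level_fxa_metrics <- function(path) {
  tab <- read.delim(path)
  s <- tab$Xa + tab$Xa_Va + tab$Xa_Va_II
  step <- tab$time[2] - tab$time[1]
  rate <- (s[-1] - s[-length(s)]) / step
  list(MaxL = max(s) * 1e9,
       TMaxL = tab$time[which(s == max(s))[1]],
       MaxR = max(rate) * 1e12,
       TMaxR = tab$time[-1][which(rate == max(rate))[1]],
       AUC = sum(s) * step * 1e6)
}
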