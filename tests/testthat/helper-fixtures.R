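# Shared fixture builders: minimal templates with known truth.

simple_template <- function(levels = c(2, 4, 8),
                            proportions = c(0.5, 0.3, 0.2),
                            base = 100, ratios = c(1.9, 1.9),
                            cv = 0.05, debris = 0, chain = 0,
                            interference = "none", name = "test") {
  tissue_template(name, class_levels = levels,
                  class_proportions = proportions,
                  base_2cx_intensity = base, under_replication = ratios,
                  peak_cv = cv, debris_fraction = debris,
                  chain_fraction = chain, interference = interference)
}

single_class_events <- function(n = 5000, centre = 100, cv = 0.05,
                                seed = 1) {
  tpl <- tissue_template("one", class_levels = 2, class_proportions = 1,
                         base_2cx_intensity = centre,
                         under_replication = numeric(), peak_cv = cv)
  generate_sample(tpl, n, seed = seed)
}

# raw triple realising a given (mean, se) exactly at n = 3
raw_triple <- function(m, se) m + se * sqrt(3) * c(-1, 0, 1)
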