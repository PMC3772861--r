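# Fixtures are built in code: no data files.

# long-format egg-cohort counts for a single assay from a vector of adult
# counts at days 0, 2, ..., 12 (no deaths shown in the juvenile columns)
make_egg_counts <- function(adults, initial = 10, assay_id = "X-E1",
                            colony_id = "X", cultivar = "Zinfandel") {
  days <- seq(0, by = 2, length.out = length(adults))
  eggs <- ifelse(days < 2, initial, 0)
  data.frame(assay_id = assay_id, colony_id = colony_id, cultivar = cultivar,
             cohort_type = "egg", day = days, eggs = eggs,
             immatures = pmax(initial - eggs - adults, 0), adults = adults,
             stringsAsFactors = FALSE)
}

# interval-censored toy dataset: two colonies (one per cultivar), two assays
# each, over a 3-interval grid
toy_intervals <- function() {
  data.frame(
    assay_id = rep(c("A1", "A2", "B1", "B2"), each = 3),
    colony_id = rep(c("A", "A", "B", "B"), each = 3),
    cultivar = rep(c("Zinfandel", "Zinfandel", "Chardonnay", "Chardonnay"),
                   each = 3),
    lower = rep(c(0, 2, 4), 4), upper = rep(c(2, 4, 6), 4),
    matured = c(2, 4, 3, 1, 5, 2, 3, 3, 2, 0, 4, 4),
    right_censored = rep(c(1, 2, 2, 2), each = 3),
    stringsAsFactors = FALSE)
}

# small design for fast simulation-based tests
small_design <- function(n_z = 2, n_c = 2, ...) {
  experiment_design(colonies = data.frame(
    colony_id = c(sprintf("Z%d", seq_len(n_z)), sprintf("C%d", seq_len(n_c))),
    cultivar = rep(c("Zinfandel", "Chardonnay"), c(n_z, n_c))), ...)
}

# independent Weibull survival (direct pweibull), used by oracles
surv_oracle <- function(t, shape, rate) {
  stats::pweibull(t, shape = shape, scale = 1 / rate, lower.tail = FALSE)
}
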