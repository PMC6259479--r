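# Shared fixtures, built in code. The bundled extdata tables carry the
# printed reference values (seven-workshop survey); helpers here produce
# small record sets and oracle implementations independent of the package
# internals.

fixture_path <- function(file) ps_example(file)

tissue_summaries <- function() load_summary_table(fixture_path("tissue_summaries.csv"))
soil_summaries <- function() load_summary_table(fixture_path("soil_summaries.csv"))

# printed per-site contamination factors, wide: one named vector per site
cf_matrix <- function() {
  cf <- readr::read_csv(fixture_path("contamination_factors.csv"),
                        show_col_types = FALSE)
  split(setNames(cf$cf, cf$parameter), cf$site_id)
}

# small clean record set: 2 sites x 2 replicates x soil Pb + root Pb
make_records <- function() {
  concentration_records(
    site_id = rep(c("S1", "control"), each = 4),
    plot_class = rep(c("test", "control"), each = 4),
    medium = rep(c("soil", "soil", "tissue", "tissue"), 2),
    tissue = rep(c("none", "none", "root", "root"), 2),
    parameter = "Pb",
    replicate = rep(c(1L, 2L), 4),
    value = c(70, 77, 50, 53, 20, 24, 15, 18)
  )
}

# random valid record set for round-trip / permutation properties
random_records <- function(n, seed) {
  set.seed(seed)
  medium <- sample(c("soil", "tissue"), n, replace = TRUE)
  concentration_records(
    site_id = sample(paste0("S", 1:4), n, replace = TRUE),
    plot_class = sample(c("test", "control"), n, replace = TRUE),
    medium = medium,
    tissue = ifelse(medium == "soil", "none",
                    sample(c("root", "leaf", "fruit", "stem"), n, replace = TRUE)),
    parameter = sample(c("Pb", "Hg", "Cd", "Cu", "Zn", "EC"), n, replace = TRUE),
    replicate = seq_len(n),  # unique keys by construction
    value = round(stats::runif(n, 0, 100), 3)
  )
}

# independent two-pass mean/SD oracle
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- if (length(x) >= 2) sqrt(sum((x - m)^2) / (length(x) - 1)) else NA_real_
  list(mean = m, sd = s)
}

# hand-formula paired t oracle (independent of stats::t.test)
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# brute-force covariance/variance Pearson oracle
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
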