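# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# mid-size default-structure bundle used across modules
default_bundle <- function() {
  memo("default_bundle", simulate_dataset(sim_config(n_probes = 400, seed = 101)))
}

# hand-built 3-family cohort for unit tests
tiny_cohort <- function() {
  twin_cohort(data.frame(
    individual_id = c("m1a", "m1b", "d1a", "d1b", "s1"),
    family_id = c("fm1", "fm1", "fd1", "fd1", "fs1"),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "singleton"),
    age = c(40, 40, 55, 55, 62),
    sex = "F",
    chip_id = "c1",
    chip_position = 1:5,
    batch_id = "batch1"))
}

# simulate a single-probe twin response with known variance components
sim_twin_response <- function(cohort, s2f = 0, s2z = 0, s2e = 1,
                              beta_age = 0) {
  co <- data.table::as.data.table(cohort)
  n <- nrow(co)
  y <- rnorm(n, 0, sqrt(s2e))
  for (members in split(seq_len(n), co$family_id)) {
    y[members] <- y[members] + rnorm(1, 0, sqrt(s2f))
    if (co$zygosity[members[1]] == "MZ" && length(members) == 2L)
      y[members] <- y[members] + rnorm(1, 0, sqrt(s2z))
  }
  y <- y + beta_age * (co$age - mean(co$age))
  names(y) <- co$individual_id
  y
}

# a larger pair-only cohort for variance-component recovery
pairs_cohort <- function(n_mz = 200, n_dz = 200) {
  k <- n_mz + n_dz
  twin_cohort(data.frame(
    individual_id = paste0("i", rep(seq_len(k), each = 2), c("a", "b")),
    family_id = paste0("f", rep(seq_len(k), each = 2)),
    zygosity = rep(c(rep("MZ", n_mz), rep("DZ", n_dz)), each = 2),
    age = rep(runif(k, 30, 80), each = 2),
    sex = "F",
    chip_id = paste0("c", rep(ceiling(seq_len(k) / 6), each = 2)),
    chip_position = rep_len(1:12, 2 * k),
    batch_id = "batch1"))
}
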