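# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture_table <- function() {
  if (is.null(.fixtures$table)) .fixtures$table <- default_remap_table()
  .fixtures$table
}

# Default synthetic training set (class counts 150/81/149/146) remapped to
# conductivity features.
fixture_training_data <- function() {
  if (is.null(.fixtures$train)) {
    ds <- generate_dataset(seed = 42)
    dm <- dataset_matrix(ds)
    sigma <- remap_matrix(dm$z, fixture_table())$sigma
    .fixtures$train <- list(dataset = ds, z = dm$z, sigma = sigma,
                            labels = dm$labels)
  }
  .fixtures$train
}

# One full default training run (2,000 epochs), shared by the bnn and
# acceptance tests to stay inside the time budget.
fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    td <- fixture_training_data()
    .fixtures$fit <- train_bnn(td$sigma, td$labels, bnn_config(seed = 7))
  }
  .fixtures$fit
}

# Fresh synthetic test set from a disjoint seed.
fixture_test_data <- function() {
  if (is.null(.fixtures$test)) {
    ds <- generate_dataset(seed = 4242)
    dm <- dataset_matrix(ds)
    sigma <- remap_matrix(dm$z, fixture_table())$sigma
    .fixtures$test <- list(z = dm$z, sigma = sigma, labels = dm$labels)
  }
  .fixtures$test
}

# Independent brute-force interpolation oracle: explicit two-point line
# formula per segment, clamped at the ends. Never calls remap_*.
oracle_interp <- function(z_query, nodes_desc, cond_asc) {
  k <- length(nodes_desc)
  vapply(z_query, function(z) {
    if (z >= nodes_desc[1]) return(cond_asc[1])
    if (z <= nodes_desc[k]) return(cond_asc[k])
    j <- max(which(nodes_desc >= z))
    if (nodes_desc[j] == z) return(cond_asc[j])
    cond_asc[j] + (cond_asc[j + 1] - cond_asc[j]) *
      (z - nodes_desc[j]) / (nodes_desc[j + 1] - nodes_desc[j])
  }, numeric(1))
}

# Numeric-quadrature oracle for KL(N(mu, s^2) || N(0, 1)).
kl_quadrature <- function(mu, s) {
  f <- function(x) {
    stats::dnorm(x, mu, s) *
      (stats::dnorm(x, mu, s, log = TRUE) - stats::dnorm(x, log = TRUE))
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}
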