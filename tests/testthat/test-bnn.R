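test_that("KL divergence matches closed forms and numeric quadrature", {
  cfg <- bnn_config(layer_sizes = c(1L, 1L), seed = 1)
  # single weight + single bias; set both to the prior -> KL = 0
  params <- list(list(W_mu = matrix(0), W_rho = matrix(inv_softplus(1)),
                      b_mu = 0, b_rho = inv_softplus(1)))
  expect_equal(kl_to_prior(params), 0, tolerance = 1e-12)

  # N(mu, 1) vs N(0, 1) -> mu^2 / 2 (bias held at the prior)
  for (mu in c(-1.5, 0.3, 2)) {
    p <- params
    p[[1]]$W_mu <- matrix(mu)
    expect_equal(kl_to_prior(p), mu^2 / 2, tolerance = 1e-10)
    expect_equal(kl_to_prior(p), kl_quadrature(mu, 1), tolerance = 1e-7)
  }
  # N(0, s^2) vs N(0, 1) -> (s^2 - 1 - ln s^2) / 2
  for (s in c(0.2, 0.9, 3)) {
    p <- params
    p[[1]]$W_rho <- matrix(inv_softplus(s))
    expect_equal(kl_to_prior(p), (s^2 - 1 - log(s^2)) / 2, tolerance = 1e-10)
    expect_equal(kl_to_prior(p), kl_quadrature(0, s), tolerance = 1e-7)
  }
})

test_that("KL is non-negative and zero only at the prior", {
  set.seed(5)
  for (i in 1:20) {
    params <- list(list(W_mu = matrix(rnorm(6, sd = 2), 2, 3),
                        W_rho = matrix(rnorm(6), 2, 3),
                        b_mu = rnorm(3), b_rho = rnorm(3)))
    kl <- kl_to_prior(params)
    expect_gte(kl, 0)
    expect_gt(kl, 1e-6)   # random parameters are never exactly the prior
  }
})

test_that("loss decomposes into CE plus weighted KL", {
  td <- fixture_training_data()
  cfg <- bnn_config(seed = 3)
  set.seed(3)
  params <- init_bnn_params(cfg)
  n <- nrow(td$sigma)
  full <- bnn_loss(params, td$sigma, td$labels, cfg, seed = 9)
  ce <- bnn_loss(params, td$sigma, td$labels, cfg, seed = 9,
                 include_kl = FALSE)
  expect_equal(full, ce + kl_to_prior(params) / n, tolerance = 1e-10)
  # full-batch KL multiplier is 1/526 for the default class counts
  expect_identical(n, 526L)
  expect_error(bnn_loss(params, td$sigma[0, , drop = FALSE], character(0),
                        cfg), "empty batch")
})

test_that("near-deterministic perfect separation drives CE towards zero", {
  # linearly separable toy set; tiny spreads make sampling near-deterministic
  set.seed(8)
  X <- rbind(matrix(exp(rnorm(60, log(10), 0.05)), 30, 2),
             matrix(exp(rnorm(60, log(1000), 0.05)), 30, 2))
  y <- rep(c("skin", "fat"), each = 30)
  cfg <- bnn_config(layer_sizes = c(2L, 8L, 8L, 2L), epochs = 400,
                    init_spread = 1e-3, kl_weight = 0, seed = 2)
  fit <- train_bnn(X, y, cfg, classes = c("skin", "fat"))
  # deterministic limit: clamp every spread to ~0 before evaluating
  fit$params <- lapply(fit$params, function(l) {
    l$W_rho[] <- inv_softplus(1e-9); l$b_rho[] <- inv_softplus(1e-9); l
  })
  ce <- bnn_loss(fit, X, y, seed = 1, include_kl = FALSE)
  expect_lt(ce, 0.05)
})

test_that("well-separated two-class blobs reach >= 0.95 held-out accuracy", {
  set.seed(13)
  gen <- function(n) {
    X <- rbind(matrix(exp(rnorm(2 * n, log(50), 0.2)), n, 2),
               matrix(exp(rnorm(2 * n, log(2000), 0.2)), n, 2))
    list(X = X, y = rep(c("skin", "fat"), each = n))
  }
  tr <- gen(100); te <- gen(100)
  cfg <- bnn_config(layer_sizes = c(2L, 8L, 8L, 2L), epochs = 200, seed = 4)
  fit <- train_bnn(tr$X, tr$y, cfg, classes = c("skin", "fat"))
  pred <- predict(fit, te$X, n_samples = 30, seed = 5)
  expect_gte(mean(pred$class_label == te$y), 0.95)
})

test_that("training and prediction are deterministic under a fixed seed", {
  td <- fixture_training_data()
  cfg <- bnn_config(epochs = 50, seed = 77)
  f1 <- train_bnn(td$sigma, td$labels, cfg)
  f2 <- train_bnn(td$sigma, td$labels, cfg)
  expect_identical(f1$cost_trace, f2$cost_trace)
  expect_identical(f1$params, f2$params)
  p1 <- predict(f1, td$sigma[1:5, ], n_samples = 10, seed = 3)
  p2 <- predict(f2, td$sigma[1:5, ], n_samples = 10, seed = 3)
  expect_identical(p1$mean_probs, p2$mean_probs)
})

test_that("mean probabilities are normalised for arbitrary models and inputs", {
  set.seed(19)
  td <- fixture_training_data()
  cfg <- bnn_config(epochs = 5, seed = 23)
  fit <- train_bnn(td$sigma, td$labels, cfg)   # barely trained, near-random
  X <- matrix(exp(runif(20 * 15, log(300), log(3e5))), 20, 15)
  pred <- predict(fit, X, n_samples = 7, seed = 29)
  expect_equal(rowSums(pred$mean_probs), rep(1, 20), tolerance = 1e-6)
  expect_true(all(pred$spread_of_max >= 0))
})

test_that("degenerate posterior with one sample equals the mean forward pass", {
  td <- fixture_training_data()
  cfg <- bnn_config(epochs = 30, init_spread = 1e-9, kl_weight = 0, seed = 31)
  fit <- train_bnn(td$sigma, td$labels, cfg)
  x <- td$sigma[3, , drop = FALSE]
  sampled <- predict(fit, x, n_samples = 1, seed = 1)
  det <- predict(fit, x, posterior = FALSE)
  expect_equal(sampled$mean_probs, det$mean_probs, tolerance = 1e-5)
  expect_identical(sampled$spread_of_max, 0)
})

test_that("trained classifier recovers the synthetic classes", {
  fit <- fixture_fit()
  te <- fixture_test_data()
  cm <- confusion_matrix(fit, te$sigma, te$labels, seed = 3)
  expect_identical(rownames(cm), tissue_classes())
  expect_identical(as.integer(rowSums(cm)), c(150L, 81L, 149L, 146L))
  expect_gte(sum(diag(cm)) / sum(cm), 0.9)
  # a CSF-template spectrum is classified as CSF
  csf_z <- exp(default_templates()$CSF$log_z_mean)
  csf_sig <- remap_spectrum(impedance_spectrum(csf_z), fixture_table())
  expect_identical(predict(fit, csf_sig, seed = 2)$class_label, "CSF")
})

test_that("confusion matrix of degenerate predictors has the right shape", {
  fit <- fixture_fit()
  td <- fixture_training_data()
  # perfect predictions -> diagonal with the class counts
  y <- factor(td$labels, levels = fit$classes)
  cm_perfect <- table(true = y, predicted = y)
  expect_identical(as.integer(diag(cm_perfect)), c(150L, 81L, 149L, 146L))
  expect_identical(sum(cm_perfect) - sum(diag(cm_perfect)), 0L)
  # all-one-class predictor -> single nonzero column
  p <- factor(rep("fat", length(y)), levels = fit$classes)
  cm_const <- table(true = y, predicted = p)
  expect_identical(as.integer(colSums(cm_const) > 0), c(0L, 1L, 0L, 0L))
})

test_that("strong KL weight shrinks weights attached to noise features", {
  set.seed(37)
  n <- 120
  # features 1-3 carry the class signal; 4-10 are pure noise
  signal <- rep(c(log(30), log(3000)), each = n / 2)
  X <- exp(cbind(matrix(rnorm(3 * n, signal, 0.2), n, 3),
                 matrix(rnorm(7 * n, log(300), 0.2), n, 7)))
  y <- rep(c("skin", "fat"), each = n / 2)
  cfg <- bnn_config(layer_sizes = c(10L, 8L, 8L, 2L), epochs = 600,
                    kl_weight = 0.05, seed = 41)
  fit <- train_bnn(X, y, cfg, classes = c("skin", "fat"))
  W1 <- abs(fit$params[[1]]$W_mu)
  expect_gt(mean(W1[1:3, ]), mean(W1[4:10, ]))
})

test_that("training rejects degenerate input and diverging costs are named", {
  td <- fixture_training_data()
  expect_error(train_bnn(td$sigma, rep("skin", nrow(td$sigma))),
               ">= 2 classes")
  bad <- td$sigma; bad[1, 1] <- NaN
  expect_error(train_bnn(bad, td$labels), "finite")
  expect_error(train_bnn(td$sigma[, 1:4], td$labels), "feature count")
  # an absurd learning rate drives the cost non-finite; the epoch is named
  expect_error(
    train_bnn(td$sigma, td$labels, bnn_config(epochs = 60, lr = 1e6,
                                              seed = 1)),
    "epoch")
})
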