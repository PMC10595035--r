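#' Tissue class labels
#'
#' Fixed class ordering used throughout the package for one-hot encoding
#' and confusion matrices.
#'
#' @return Character vector `c("skin", "fat", "ligament", "CSF")`.
#' @export
tissue_classes <- function() c("skin", "fat", "ligament", "CSF")

#' Configuration for the Bayesian neural-network classifier
#'
#' The classifier is a fully connected network whose weights carry
#' independent Gaussian variational posteriors N(mu, s^2) regularised
#' towards a N(prior_mean, prior_sd^2) prior. Training minimises
#' cross-entropy plus `kl_weight * KL(posterior || prior)`; by default the
#' KL weight is 1/batch_size with the whole dataset as a single batch.
#'
#' @param layer_sizes integer vector of layer widths, input first. Default
#'   15 features -> 10 -> 10 -> 4 classes.
#' @param prior_mean,prior_sd Gaussian prior on every weight and bias.
#' @param epochs number of full-batch training iterations.
#' @param lr Adam learning rate.
#' @param init_spread initial posterior standard deviation (softplus
#'   parameterised); small values stabilise early training.
#' @param mc_samples_predict posterior draws averaged at prediction time.
#' @param kl_weight KL multiplier; `NULL` means 1/batch_size (full batch).
#' @param seed RNG seed controlling initialisation and weight sampling.
#' @return A `bnn_config` list.
#' @export
bnn_config <- function(layer_sizes = c(15L, 10L, 10L, 4L),
                       prior_mean = 0, prior_sd = 1,
                       epochs = 2000L, lr = 0.01,
                       init_spread = 0.1,
                       mc_samples_predict = 30L,
                       kl_weight = NULL,
                       seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop("layer_sizes must be >= 2 positive widths", call. = FALSE)
  }
  if (prior_sd <= 0) stop("prior_sd must be > 0", call. = FALSE)
  if (init_spread <= 0) stop("init_spread must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(layer_sizes = layer_sizes, prior_mean = prior_mean,
                 prior_sd = prior_sd, epochs = as.integer(epochs), lr = lr,
                 init_spread = init_spread,
                 mc_samples_predict = as.integer(mc_samples_predict),
                 kl_weight = kl_weight, seed = as.integer(seed)),
            class = "bnn_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

# Initialise variational parameters: means ~ N(0, 1/sqrt(fan_in)),
# spreads at config$init_spread. Consumes the active RNG stream.
init_bnn_params <- function(config) {
  sizes <- config$layer_sizes
  rho0 <- inv_softplus(config$init_spread)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    list(W_mu = matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)),
                       n_in, n_out),
         W_rho = matrix(rho0, n_in, n_out),
         b_mu = numeric(n_out),
         b_rho = rep(rho0, n_out))
  })
}

#' KL divergence of the weight posterior from the prior
#'
#' Closed-form sum over every weight and bias of
#' KL(N(mu, s^2) || N(m0, s0^2)) where s = softplus(rho):
#' 0.5 * (log(s0^2/s^2) + (s^2 + (mu - m0)^2)/s0^2 - 1).
#'
#' @param model a `bnn_fit` (or its `$params` list).
#' @param prior_mean,prior_sd prior Gaussian; defaults standard normal.
#' @return Non-negative scalar; 0 iff the posterior equals the prior.
#' @export
kl_to_prior <- function(model, prior_mean = 0, prior_sd = 1) {
  params <- if (inherits(model, "bnn_fit")) model$params else model
  if (prior_sd <= 0) stop("prior_sd must be > 0", call. = FALSE)
  total <- 0
  for (layer in params) {
    for (nm in c("W", "b")) {
      mu <- layer[[paste0(nm, "_mu")]]
      s <- softplus(layer[[paste0(nm, "_rho")]])
      if (any(s <= 0)) stop("posterior spread must be > 0", call. = FALSE)
      total <- total + sum(0.5 * (2 * log(prior_sd / s) +
                                  (s^2 + (mu - prior_mean)^2) / prior_sd^2 - 1))
    }
  }
  total
}

# Draw one weight sample per parameter via the reparameterisation trick.
# Returns sampled weights plus the noise used (needed for gradients).
sample_weights <- function(params) {
  lapply(params, function(layer) {
    sW <- softplus(layer$W_rho); sb <- softplus(layer$b_rho)
    epsW <- matrix(stats::rnorm(length(layer$W_mu)),
                   nrow(layer$W_mu), ncol(layer$W_mu))
    epsb <- stats::rnorm(length(layer$b_mu))
    list(W = layer$W_mu + sW * epsW, b = layer$b_mu + sb * epsb,
         epsW = epsW, epsb = epsb, sW = sW, sb = sb)
  })
}

mean_weights <- function(params) {
  lapply(params, function(layer) list(W = layer$W_mu, b = layer$b_mu))
}

# Forward pass with ReLU hidden layers and softmax output.
# Returns per-class probabilities and the activations needed for backprop.
forward_pass <- function(weights, X) {
  A <- list(X)
  Zs <- list()
  L <- length(weights)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% weights[[l]]$W +
      matrix(weights[[l]]$b, nrow(A[[l]]), length(weights[[l]]$b),
             byrow = TRUE)
    Zs[[l]] <- Z
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  logits <- A[[L + 1L]]
  m <- apply(logits, 1, max)
  el <- exp(logits - m)
  P <- el / rowSums(el)
  list(P = P, A = A, Zs = Zs, logits = logits)
}

softmax_ce <- function(P, Y) {
  # mean over rows of -log p at the true class; P already normalised
  -mean(log(pmax(rowSums(P * Y), 1e-300)))
}

#' Variational loss (cross-entropy + weighted KL)
#'
#' Evaluates the training objective on a labelled batch using one
#' posterior weight sample (reparameterised, seeded). The KL term uses the
#' analytic Gaussian-Gaussian form, scaled by the configured KL weight
#' (1/batch_size by default).
#'
#' @param model a `bnn_fit` or a raw parameter list.
#' @param X numeric matrix (n x n_features) of conductivity features.
#' @param y factor or character vector of class labels.
#' @param config a `bnn_config`; defaults to the model's own.
#' @param seed RNG seed for the weight sample.
#' @param include_kl set `FALSE` to return the plain cross-entropy.
#' @return scalar loss.
#' @export
bnn_loss <- function(model, X, y, config = NULL, seed = 1L,
                     include_kl = TRUE) {
  params <- if (inherits(model, "bnn_fit")) model$params else model
  if (is.null(config) && inherits(model, "bnn_fit")) config <- model$config
  if (is.null(config)) config <- bnn_config()
  classes <- if (inherits(model, "bnn_fit")) model$classes else tissue_classes()
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty batch", call. = FALSE)
  # a fitted model carries its own feature standardisation
  if (inherits(model, "bnn_fit")) X <- scale_features(model, X)
  Y <- one_hot(y, classes)
  set.seed(seed)
  w <- sample_weights(params)
  fw <- forward_pass(w, X)
  ce <- softmax_ce(fw$P, Y)
  if (!include_kl) return(ce)
  lam <- if (is.null(config$kl_weight)) 1 / nrow(X) else config$kl_weight
  ce + lam * kl_to_prior(params, config$prior_mean, config$prior_sd)
}

one_hot <- function(y, classes) {
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad)) {
    stop("labels outside class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

#' Train the Bayesian neural-network tissue classifier
#'
#' Full-batch variational training: each epoch draws one posterior weight
#' sample, backpropagates the cross-entropy through the reparameterisation,
#' adds the analytic KL gradient scaled by 1/batch_size, and applies an
#' Adam update. Training is deterministic given `config$seed`.
#'
#' @param X numeric matrix (n x n_features) of conductivity features
#'   (uS/cm), one row per labelled spectrum.
#' @param y class labels (character or factor); at least two distinct
#'   classes required.
#' @param config a [bnn_config()].
#' @param classes class ordering; defaults to [tissue_classes()] when the
#'   labels are a subset of it, otherwise `sort(unique(y))`.
#' @return A `bnn_fit` with elements `params` (posterior means/spreads),
#'   `config`, `classes`, `cost_trace` (per-epoch objective) and
#'   `feature_scale` (centre/scale used to standardise inputs).
#' @export
train_bnn <- function(X, y, config = bnn_config(), classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  if (length(unique(y)) < 2) stop("need >= 2 classes", call. = FALSE)
  if (is.null(classes)) {
    classes <- if (all(y %in% tissue_classes())) tissue_classes()
               else sort(unique(y))
  }
  classes <- classes[classes %in% c(y, classes)]
  if (ncol(X) != config$layer_sizes[1]) {
    stop("feature count ", ncol(X), " does not match input width ",
         config$layer_sizes[1], call. = FALSE)
  }
  if (utils::tail(config$layer_sizes, 1) != length(classes)) {
    stop("output width does not match number of classes", call. = FALSE)
  }

  # standardise features (log scale: conductivities span decades)
  Xl <- log(pmax(X, 1e-12))
  ctr <- colMeans(Xl)
  scl <- pmax(apply(Xl, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(Xl, 2, ctr), 2, scl, "/")

  Y <- one_hot(y, classes)
  n <- nrow(Xs)
  lam <- if (is.null(config$kl_weight)) 1 / n else config$kl_weight

  set.seed(config$seed)
  params <- init_bnn_params(config)
  opt <- adam_init(params, config$lr)
  cost_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    w <- sample_weights(params)
    fw <- forward_pass(w, Xs)
    ce <- softmax_ce(fw$P, Y)
    # a spread underflowing to zero is a divergence, not an API error
    kl <- tryCatch(kl_to_prior(params, config$prior_mean, config$prior_sd),
                   error = function(e) Inf)
    cost <- ce + lam * kl
    if (!is.finite(cost)) {
      stop("training diverged (non-finite cost) at epoch ", epoch,
           call. = FALSE)
    }
    cost_trace[epoch] <- cost

    grads <- backprop(params, w, fw, Y, lam, config)
    opt <- adam_step(opt, params, grads)
    params <- opt$params
  }

  structure(list(params = params, config = config, classes = classes,
                 cost_trace = cost_trace,
                 feature_scale = list(center = ctr, scale = scl)),
            class = "bnn_fit")
}

# Gradients of CE + lam*KL w.r.t. every mu and rho.
# Chain rule through the reparameterisation: w = mu + softplus(rho)*eps,
# so dL/dmu = dL/dw and dL/drho = dL/dw * eps * sigmoid(rho).
backprop <- function(params, w, fw, Y, lam, config) {
  L <- length(params)
  n <- nrow(Y)
  delta <- (fw$P - Y) / n              # dCE/dlogits, mean-CE scaling
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW <- crossprod(fw$A[[l]], delta)
    gb <- colSums(delta)
    sigW <- stats::plogis(params[[l]]$W_rho)
    sigb <- stats::plogis(params[[l]]$b_rho)
    sW <- w[[l]]$sW; sb <- w[[l]]$sb
    m0 <- config$prior_mean; v0 <- config$prior_sd^2
    grads[[l]] <- list(
      W_mu = gW + lam * (params[[l]]$W_mu - m0) / v0,
      W_rho = gW * w[[l]]$epsW * sigW + lam * (sW / v0 - 1 / sW) * sigW,
      b_mu = gb + lam * (params[[l]]$b_mu - m0) / v0,
      b_rho = gb * w[[l]]$epsb * sigb + lam * (sb / v0 - 1 / sb) * sigb)
    if (l > 1L) {
      delta <- (delta %*% t(w[[l]]$W)) * (fw$Zs[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(params, lr) {
  zeros <- lapply(params, function(layer) {
    lapply(layer, function(p) p * 0)
  })
  list(params = params, m = zeros, v = zeros, t = 0L, lr = lr,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      g <- grads[[l]][[nm]]
      opt$m[[l]][[nm]] <- b1 * opt$m[[l]][[nm]] + (1 - b1) * g
      opt$v[[l]][[nm]] <- b2 * opt$v[[l]][[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[l]][[nm]] / bc1
      vhat <- opt$v[[l]][[nm]] / bc2
      params[[l]][[nm]] <- params[[l]][[nm]] -
        opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  opt$params <- params
  opt
}

scale_features <- function(fit, X) {
  Xl <- log(pmax(as.matrix(X), 1e-12))
  sweep(sweep(Xl, 2, fit$feature_scale$center), 2, fit$feature_scale$scale, "/")
}

#' Predict tissue class from conductivity features
#'
#' Averages the softmax output over `n_samples` posterior weight draws.
#' The predicted label is the argmax of the mean probabilities; the
#' standard deviation of that class's probability across draws
#' (`spread_of_max`) serves as the confidence indicator — small spread
#' means a confident posterior.
#'
#' @param object a `bnn_fit`.
#' @param newdata a `conductivity_spectrum`, numeric feature vector, or
#'   matrix (n x n_features) of conductivities in uS/cm.
#' @param n_samples posterior draws (>= 1); defaults to the config value.
#' @param seed optional seed; `NULL` continues the active RNG stream.
#' @param posterior set `FALSE` for a deterministic forward pass using the
#'   posterior means (no sampling).
#' @param ... unused.
#' @return For a single spectrum, a `bnn_prediction` list with
#'   `class_label`, `mean_probs`, `spread_of_max`, `n_posterior_samples`.
#'   For a matrix, a list with vectors `class_label`, `spread_of_max` and
#'   matrix `mean_probs`.
#' @export
predict.bnn_fit <- function(object, newdata,
                            n_samples = object$config$mc_samples_predict,
                            seed = NULL, posterior = TRUE, ...) {
  single <- FALSE
  if (inherits(newdata, "conductivity_spectrum")) {
    newdata <- newdata$sigma_us_cm
  }
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1)
    single <- TRUE
  }
  X <- as.matrix(newdata)
  if (ncol(X) != object$config$layer_sizes[1]) {
    stop("expected ", object$config$layer_sizes[1], " features, got ",
         ncol(X), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Xs <- scale_features(object, X)
  if (!posterior) {
    P <- forward_pass(mean_weights(object$params), Xs)$P
    draws <- array(P, c(nrow(X), ncol(P), 1L))
  } else {
    if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
    draws <- array(NA_real_, c(nrow(X), length(object$classes), n_samples))
    for (s in seq_len(n_samples)) {
      draws[, , s] <- forward_pass(sample_weights(object$params), Xs)$P
    }
  }
  mean_probs <- apply(draws, c(1, 2), mean)
  idx <- max.col(mean_probs, ties.method = "first")
  spread <- vapply(seq_len(nrow(X)), function(i) {
    if (dim(draws)[3] < 2) 0 else stats::sd(draws[i, idx[i], ])
  }, numeric(1))
  labels <- object$classes[idx]
  if (single) {
    structure(list(class_label = labels[1],
                   mean_probs = stats::setNames(mean_probs[1, ],
                                                object$classes),
                   spread_of_max = spread[1],
                   n_posterior_samples = dim(draws)[3]),
              class = "bnn_prediction")
  } else {
    colnames(mean_probs) <- object$classes
    list(class_label = labels, mean_probs = mean_probs,
         spread_of_max = spread, n_posterior_samples = dim(draws)[3])
  }
}

#' @export
print.bnn_prediction <- function(x, ...) {
  cat("Predicted tissue:", x$class_label,
      sprintf("(p = %.3f, spread = %.4f, %d posterior samples)\n",
              max(x$mean_probs), x$spread_of_max, x$n_posterior_samples))
  invisible(x)
}

#' @export
print.bnn_fit <- function(x, ...) {
  cat("Bayesian neural-network tissue classifier\n")
  cat("  architecture:", paste(x$config$layer_sizes, collapse = "-"), "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  trained", x$config$epochs, "epochs; final cost",
      signif(utils::tail(x$cost_trace, 1), 5), "\n")
  invisible(x)
}

#' Confusion matrix of a fitted classifier
#'
#' @param fit a `bnn_fit`.
#' @param X feature matrix (n x n_features), conductivities in uS/cm.
#' @param y true labels.
#' @param n_samples posterior draws per prediction.
#' @param seed RNG seed for the posterior draws.
#' @return Square count matrix, rows = true class, columns = predicted;
#'   row sums equal the per-class sample counts.
#' @export
confusion_matrix <- function(fit, X, y, n_samples = fit$config$mc_samples_predict,
                             seed = 1L) {
  pred <- predict(fit, as.matrix(X), n_samples = n_samples, seed = seed)
  y <- factor(as.character(y), levels = fit$classes)
  p <- factor(pred$class_label, levels = fit$classes)
  table(true = y, predicted = p)
}
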