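#' Stepper-motor configuration
#'
#' @param step_mm linear distance travelled per motor step (Hs). The
#'   driver supports 0.08 to 0.22 mm; 0.08 mm is the finest mode and the
#'   default.
#' @return A `motor_config` list.
#' @export
motor_config <- function(step_mm = 0.08) {
  if (!is.numeric(step_mm) || length(step_mm) != 1 ||
      step_mm < 0.08 - 1e-12 || step_mm > 0.22 + 1e-12) {
    stop("step_mm must be within the motor driver range [0.08, 0.22] mm",
         call. = FALSE)
  }
  structure(list(step_mm = step_mm), class = "motor_config")
}

#' Net step count from an impulse sequence
#'
#' The depth counter increases by 1 for each forward impulse and
#' decreases by 1 for each backward impulse, so equal numbers of forward
#' and backward impulses home the needle exactly.
#'
#' @param impulses integer vector of +1 (forward) / -1 (backward).
#' @return Integer net step count.
#' @export
count_steps <- function(impulses) {
  impulses <- as.integer(impulses)
  if (any(!impulses %in% c(-1L, 1L))) {
    stop("impulses must be +1 or -1", call. = FALSE)
  }
  sum(impulses)
}

#' Comfortable travel distance (CTD) from step counts
#'
#' With the zero position reached after N1 steps and the terminal
#' (stopped) position after N2 steps, depths are H1 = N1 * Hs and
#' H2 = N2 * Hs, and the CTD is their difference
#' Delta = H2 - H1 = (N2 - N1) * Hs. Step counts may be fractional means
#' over repeated trials.
#'
#' @param n1 step count at the zero position (first contact), >= 0.
#' @param n2 step count at the terminal position, >= n1.
#' @param hs mm per motor step, inside the driver range.
#' @return A `ctd_report` list with `N1`, `N2`, `Hs`, `H1`, `H2`,
#'   `delta_mm`.
#' @export
compute_ctd <- function(n1, n2, hs = 0.08) {
  motor_config(hs)   # range check
  if (n1 < 0) stop("N1 must be >= 0", call. = FALSE)
  if (n2 < n1) stop("N2 must be >= N1", call. = FALSE)
  structure(list(N1 = n1, N2 = n2, Hs = hs,
                 H1 = n1 * hs, H2 = n2 * hs,
                 delta_mm = (n2 - n1) * hs),
            class = "ctd_report")
}

#' @export
print.ctd_report <- function(x, ...) {
  cat(sprintf(
    "CTD report: N1 = %s, N2 = %s, Hs = %g mm -> Delta = %.4g mm\n",
    format(x$N1), format(x$N2), x$Hs, x$delta_mm))
  invisible(x)
}

#' Stop policy for the closed-loop insertion
#'
#' The needle stops once the target tissue has been predicted for
#' `consecutive_hits` consecutive steps while the policy is armed and the
#' prediction confidence passes the gate. Arming implements the "skip
#' shallow look-alikes" delay needed for epidural injection: target
#' detections are ignored until the needle is deeper than `min_depth_mm`
#' and, if `arm_after` is set, until that tissue has been predicted at
#' least once (e.g. arm on ligament so subcutaneous fat cannot trigger a
#' stop intended for epidural fat).
#'
#' @param target tissue label to stop in.
#' @param consecutive_hits required consecutive target predictions
#'   (>= 1); default 2 debounces single-step flips near boundaries.
#' @param min_depth_mm detections above this depth are ignored.
#' @param arm_after optional tissue label that must be predicted once
#'   before target detections count.
#' @param max_spread confidence gate: predictions with
#'   `spread_of_max` above this do not count as hits.
#' @return A `stop_policy` list.
#' @export
stop_policy <- function(target, consecutive_hits = 2L, min_depth_mm = 0,
                        arm_after = NULL, max_spread = Inf) {
  if (consecutive_hits < 1) stop("consecutive_hits must be >= 1", call. = FALSE)
  if (min_depth_mm < 0) stop("min_depth_mm must be >= 0", call. = FALSE)
  structure(list(target = as.character(target),
                 consecutive_hits = as.integer(consecutive_hits),
                 min_depth_mm = min_depth_mm,
                 arm_after = if (is.null(arm_after)) NULL
                             else as.character(arm_after),
                 max_spread = max_spread),
            class = "stop_policy")
}

#' Oracle classifier
#'
#' A reference classifier that returns the phantom's true label with zero
#' spread — used to test stop-policy geometry independently of the
#' learned model.
#'
#' @return An object of class `oracle_classifier`.
#' @export
oracle_classifier <- function() {
  structure(list(), class = "oracle_classifier")
}

classify_step <- function(classifier, sigma, true_label, n_samples) {
  if (inherits(classifier, "oracle_classifier")) {
    list(label = true_label, spread = 0)
  } else if (inherits(classifier, "bnn_fit")) {
    p <- predict(classifier, sigma, n_samples = n_samples, seed = NULL)
    list(label = p$class_label, spread = p$spread_of_max)
  } else {
    stop("classifier must be a bnn_fit or oracle_classifier", call. = FALSE)
  }
}

#' Run a closed-loop simulated needle insertion
#'
#' State machine replicating the robot's advance-measure-classify loop:
#' from depth 0 the needle advances one motor step per cycle; at each step
#' the phantom emits an impedance spectrum at the tip depth, the spectrum
#' is remapped to conductivity and classified, and the stop policy is
#' evaluated. The run ends with stop reason `"target"` when the policy is
#' satisfied, or `"not found"` when the stack bottom is reached (reported
#' in the trace, not an error).
#'
#' @param stack a `phantom_stack`.
#' @param classifier a `bnn_fit` or [oracle_classifier()].
#' @param table a `remap_table`.
#' @param policy a `stop_policy` whose target occurs in the stack.
#' @param motor a `motor_config`.
#' @param templates tissue templates for the phantom.
#' @param seed RNG seed for the whole run (phantom noise and posterior
#'   draws share one stream).
#' @param n_samples posterior draws per prediction.
#' @return An `insertion_trace`: `steps` data.frame (step, depth_mm,
#'   true_label, pred_label, conf_spread), matrices `z` and `sigma`,
#'   `stop_step`, `stop_depth_mm`, `stop_reason`, plus the policy and
#'   motor used.
#' @export
run_insertion <- function(stack, classifier, table = default_remap_table(),
                          policy = stop_policy("CSF"),
                          motor = motor_config(),
                          templates = default_templates(),
                          seed = 1L, n_samples = 30L) {
  stopifnot(inherits(stack, "phantom_stack"), inherits(policy, "stop_policy"),
            inherits(motor, "motor_config"))
  if (!policy$target %in% stack$layers$tissue) {
    stop("policy target '", policy$target, "' not present in stack",
         call. = FALSE)
  }
  set.seed(seed)
  hs <- motor$step_mm
  max_steps <- floor(stack$total_depth_mm / hs)
  k <- length(table$freqs_khz)
  depth_v <- numeric(max_steps); true_v <- character(max_steps)
  pred_v <- character(max_steps); spread_v <- numeric(max_steps)
  Z <- matrix(NA_real_, max_steps, k); S <- matrix(NA_real_, max_steps, k)

  hits <- 0L
  armed_tissue_seen <- is.null(policy$arm_after)
  stop_step <- NA_integer_; stop_reason <- "not found"

  n_rec <- 0L
  for (n in seq_len(max_steps)) {
    depth <- n * hs
    obs <- spectrum_at_depth(stack, depth, templates, seed = NULL)
    sig <- remap_matrix(matrix(obs$z, nrow = 1), table)$sigma[1, ]
    cls <- classify_step(classifier, sig, obs$true_label, n_samples)

    n_rec <- n
    depth_v[n] <- depth; true_v[n] <- obs$true_label
    pred_v[n] <- cls$label; spread_v[n] <- cls$spread
    Z[n, ] <- obs$z; S[n, ] <- sig

    if (!armed_tissue_seen && identical(cls$label, policy$arm_after)) {
      armed_tissue_seen <- TRUE
    }
    armed <- armed_tissue_seen && depth >= policy$min_depth_mm
    if (armed && identical(cls$label, policy$target) &&
        cls$spread <= policy$max_spread) {
      hits <- hits + 1L
    } else {
      hits <- 0L
    }
    if (hits >= policy$consecutive_hits) {
      stop_step <- n; stop_reason <- "target"
      break
    }
  }

  idx <- seq_len(n_rec)
  structure(list(
    steps = data.frame(step = idx, depth_mm = depth_v[idx],
                       true_label = true_v[idx], pred_label = pred_v[idx],
                       conf_spread = spread_v[idx],
                       stringsAsFactors = FALSE),
    z = Z[idx, , drop = FALSE], sigma = S[idx, , drop = FALSE],
    freqs_khz = table$freqs_khz,
    stop_step = stop_step,
    stop_depth_mm = if (is.na(stop_step)) NA_real_ else stop_step * hs,
    stop_reason = stop_reason,
    policy = policy, motor = motor, stack = stack),
    class = "insertion_trace")
}

#' @export
print.insertion_trace <- function(x, ...) {
  cat("Insertion trace:", nrow(x$steps), "steps of", x$motor$step_mm, "mm\n")
  if (x$stop_reason == "target") {
    cat(sprintf("  stopped at step %d (%.2f mm) in '%s' (target '%s')\n",
                x$stop_step, x$stop_depth_mm,
                x$steps$true_label[x$stop_step], x$policy$target))
  } else {
    cat("  target not found before stack bottom\n")
  }
  invisible(x)
}

#' Evaluate an insertion trace against the true stack geometry
#'
#' @param trace an `insertion_trace`.
#' @param stack the phantom stack the trace was run on (defaults to the
#'   one recorded in the trace).
#' @return list with `stopped`, `stop_depth_mm`, `stop_layer`,
#'   `false_stop` (stopped in a non-target layer), `overshoot_mm` (stop
#'   depth minus entry depth of the target layer; `NA` if no stop) and
#'   `step_accuracy` (fraction of steps whose prediction matched the true
#'   label).
#' @export
evaluate_trace <- function(trace, stack = trace$stack) {
  stopifnot(inherits(trace, "insertion_trace"))
  entry <- layer_entry_depths(stack)
  acc <- mean(trace$steps$pred_label == trace$steps$true_label)
  if (is.na(trace$stop_step)) {
    return(list(stopped = FALSE, stop_depth_mm = NA_real_,
                stop_layer = NA_integer_, false_stop = NA,
                overshoot_mm = NA_real_, step_accuracy = acc))
  }
  d <- trace$stop_depth_mm
  stop_layer <- layer_at_depth(stack, min(d, stack$total_depth_mm))
  target <- trace$policy$target
  false_stop <- stack$layers$tissue[stop_layer] != target
  ref_layer <- if (!false_stop) stop_layer else {
    which(stack$layers$tissue == target)[1]
  }
  list(stopped = TRUE, stop_depth_mm = d, stop_layer = stop_layer,
       false_stop = false_stop,
       overshoot_mm = d - entry[ref_layer],
       step_accuracy = acc)
}

#' Write a machine-parseable detection log
#'
#' CSV log of (step, depth, predicted label, confidence spread), echoing
#' the robot's real-time detection log; floats at 6 significant digits.
#'
#' @param trace an `insertion_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detection_log <- function(trace, path) {
  df <- trace$steps
  out <- data.frame(step = df$step,
                    depth_mm = signif(df$depth_mm, 6),
                    predicted = df$pred_label,
                    conf_spread = signif(df$conf_spread, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
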