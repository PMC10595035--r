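#' Tissue spectrum template
#'
#' Log-normal generative model of a tissue's impedance spectrum:
#' per-frequency |Z| = exp(N(log_z_mean, log_z_sd^2)). Multiplicative
#' sensor noise keeps impedances positive and matches the decade-spanning
#' range of bioimpedance data.
#'
#' @param tissue class label.
#' @param log_z_mean numeric vector of 15 per-frequency log-impedance
#'   means (log ohm).
#' @param log_z_sd per-frequency dispersions (>= 0); a scalar is recycled.
#' @param freqs_khz frequency grid.
#' @return An object of class `tissue_template`.
#' @export
tissue_template <- function(tissue, log_z_mean, log_z_sd,
                            freqs_khz = eis_frequencies()) {
  validate_grid(freqs_khz)
  log_z_mean <- as.numeric(log_z_mean)
  log_z_sd <- rep_len(as.numeric(log_z_sd), length(freqs_khz))
  if (length(log_z_mean) != length(freqs_khz)) {
    stop("log_z_mean length must match frequency grid", call. = FALSE)
  }
  if (any(!is.finite(log_z_mean))) stop("means must be finite", call. = FALSE)
  if (any(log_z_sd < 0) || any(!is.finite(log_z_sd))) {
    stop("dispersions must be finite and >= 0", call. = FALSE)
  }
  structure(list(tissue = as.character(tissue), log_z_mean = log_z_mean,
                 log_z_sd = log_z_sd, freqs_khz = as.numeric(freqs_khz)),
            class = "tissue_template")
}

#' Default tissue templates
#'
#' Synthetic stand-ins for ex vivo tissue spectra, anchored to the
#' calibration table:
#' * CSF: the 0.9 % saline column exactly (CSF conductivity approximates
#'   physiological saline, ~16,000 uS/cm), with small dispersion — a
#'   homogeneous fluid varies far less than heterogeneous tissue.
#' * fat: a 0.6/0.4 geometric mix of the 0.01 % and 0.1 % columns —
#'   the least conductive, most resistive class, kept far enough below
#'   the distilled-water column that +/- 3 sd draws stay interpolable at
#'   every frequency.
#' * skin: geometric mean of the 0.1 % and 0.2 % columns.
#' * ligament: geometric mean of the 0.3 % and 0.4 % columns.
#'
#' Because CSF sits exactly on the most-conductive calibration node, about
#' half of its noisy draws fall just beyond the table and clamp (flagged)
#' to 16,000 uS/cm — the physically correct value at that boundary.
#'
#' @param table calibration table anchoring the templates.
#' @return Named list of `tissue_template` objects in
#'   [tissue_classes()] order.
#' @export
default_templates <- function(table = default_remap_table()) {
  z <- table$node_impedance_ohm
  lz <- log(z)
  list(
    skin = tissue_template("skin", (lz[, 3] + lz[, 4]) / 2, 0.08,
                           table$freqs_khz),
    fat = tissue_template("fat", 0.6 * lz[, 2] + 0.4 * lz[, 3], 0.08,
                          table$freqs_khz),
    ligament = tissue_template("ligament", (lz[, 5] + lz[, 6]) / 2, 0.08,
                               table$freqs_khz),
    CSF = tissue_template("CSF", lz[, 8], 0.03, table$freqs_khz)
  )
}

#' Draw impedance spectra from a tissue template
#'
#' @param template a `tissue_template`.
#' @param n number of spectra.
#' @param seed optional RNG seed; `NULL` continues the active stream.
#' @return Numeric matrix (n x 15) of |Z| in ohm.
#' @export
sample_spectrum <- function(template, n = 1L, seed = NULL) {
  stopifnot(inherits(template, "tissue_template"))
  if (!is.null(seed)) set.seed(seed)
  k <- length(template$log_z_mean)
  noise <- matrix(stats::rnorm(n * k), n, k)
  exp(sweep(sweep(noise, 2, template$log_z_sd, "*"),
            2, template$log_z_mean, "+"))
}

#' Generate a labelled synthetic dataset
#'
#' Emulates the soft-tissue training set: the default per-class counts are
#' skin 150, fat 81, ligament 149, CSF 146 (526 spectra total). Rows are
#' shuffled under the seed.
#'
#' @param templates named list of `tissue_template`s.
#' @param counts named integer vector of per-class sample counts; names
#'   must exist in `templates`.
#' @param seed RNG seed.
#' @return data.frame with columns `id`, `label` and `z_<freq>kHz` for the
#'   15 grid frequencies (impedance in ohm).
#' @export
generate_dataset <- function(templates = default_templates(),
                             counts = c(skin = 150L, fat = 81L,
                                        ligament = 149L, CSF = 146L),
                             seed = 1L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by class", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(templates))
  if (length(unknown)) {
    stop("unknown class in counts: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 1)) stop("counts must be >= 1", call. = FALSE)
  set.seed(seed)
  blocks <- lapply(names(counts), function(cl) {
    sample_spectrum(templates[[cl]], n = counts[[cl]])
  })
  Z <- do.call(rbind, blocks)
  labels <- rep(names(counts), counts)
  ord <- sample.int(nrow(Z))
  Z <- Z[ord, , drop = FALSE]
  labels <- labels[ord]
  freqs <- templates[[1]]$freqs_khz
  df <- data.frame(id = seq_len(nrow(Z)), label = labels,
                   Z, stringsAsFactors = FALSE)
  names(df) <- c("id", "label", paste0("z_", freqs, "kHz"))
  df
}

#' Extract the feature matrix and labels from a wide dataset
#'
#' @param dataset data.frame as produced by [generate_dataset()].
#' @return list with `z` (impedance matrix), `labels` and `freqs_khz`.
#' @export
dataset_matrix <- function(dataset) {
  zcols <- grep("^z_", names(dataset), value = TRUE)
  if (length(zcols) == 0) stop("no z_<freq>kHz columns found", call. = FALSE)
  freqs <- as.numeric(sub("^z_([0-9.]+)kHz$", "\\1", zcols))
  z <- as.matrix(dataset[, zcols, drop = FALSE])
  list(z = z, labels = dataset$label, freqs_khz = freqs)
}

#' Layered phantom stack
#'
#' Ordered tissue layers with thicknesses, mimicking the puncture path:
#' skin, subcutaneous fat, ligament, epidural fat, then the CSF-filled
#' subarachnoid space. Subcutaneous and epidural fat share one template
#' and label; they differ only by position.
#'
#' @param layers data.frame with columns `tissue` and `thickness_mm`
#'   (all > 0).
#' @param boundary_blend_mm half-width of the transition zone at each
#'   interface over which adjacent templates are log-linearly mixed.
#' @return An object of class `phantom_stack`.
#' @export
phantom_stack <- function(layers, boundary_blend_mm = 0.3) {
  layers <- as.data.frame(layers)
  if (!all(c("tissue", "thickness_mm") %in% names(layers))) {
    stop("layers needs columns tissue, thickness_mm", call. = FALSE)
  }
  if (nrow(layers) < 1 || any(layers$thickness_mm <= 0)) {
    stop("layer thicknesses must be > 0", call. = FALSE)
  }
  if (boundary_blend_mm < 0) stop("blend width must be >= 0", call. = FALSE)
  structure(list(layers = layers,
                 boundary_blend_mm = boundary_blend_mm,
                 total_depth_mm = sum(layers$thickness_mm)),
            class = "phantom_stack")
}

#' Default five-layer lumbar phantom stack
#'
#' Skin 3 mm, subcutaneous fat 10 mm, ligament 15 mm, epidural fat 4 mm,
#' CSF 3 mm (the dorsal CSF layer is 2-3 mm wide in adults). Total depth
#' 35 mm; CSF entry at 32 mm.
#'
#' @param boundary_blend_mm interface transition half-width (default
#'   0.3 mm).
#' @return A `phantom_stack`.
#' @export
default_stack <- function(boundary_blend_mm = 0.3) {
  phantom_stack(data.frame(
    tissue = c("skin", "fat", "ligament", "fat", "CSF"),
    thickness_mm = c(3, 10, 15, 4, 3)), boundary_blend_mm)
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat("Layered phantom stack (", x$total_depth_mm, " mm, blend ",
      x$boundary_blend_mm, " mm):\n", sep = "")
  entry <- cumsum(c(0, x$layers$thickness_mm[-nrow(x$layers)]))
  for (i in seq_len(nrow(x$layers))) {
    cat(sprintf("  %-10s %5.1f-%5.1f mm\n", x$layers$tissue[i],
                entry[i], entry[i] + x$layers$thickness_mm[i]))
  }
  invisible(x)
}

# Layer index containing a depth; label switches exactly at cumulative
# thickness boundaries (depth == boundary belongs to the deeper layer).
layer_at_depth <- function(stack, depth_mm) {
  bounds <- cumsum(stack$layers$thickness_mm)
  idx <- findInterval(depth_mm, c(0, bounds[-length(bounds)]))
  min(max(idx, 1L), nrow(stack$layers))
}

#' Layer entry depths of a stack
#'
#' @param stack a `phantom_stack`.
#' @return Numeric vector: depth (mm) at which each layer begins.
#' @export
layer_entry_depths <- function(stack) {
  cumsum(c(0, stack$layers$thickness_mm[-nrow(stack$layers)]))
}

#' Virtual needle-tip measurement at a given depth
#'
#' Returns one impedance spectrum as sensed at `depth_mm` inside the
#' stack. Away from interfaces the spectrum is a draw from the local
#' layer's template. Within `boundary_blend_mm` of an interface the two
#' adjacent templates are mixed log-linearly, weighted by the penetration
#' fraction through the transition zone (50/50 exactly at the interface) —
#' emulating the electrode sensing both tissues at once.
#'
#' @param stack a `phantom_stack`.
#' @param depth_mm needle-tip depth, 0 <= depth <= total depth.
#' @param templates named list of `tissue_template`s covering the stack's
#'   tissues.
#' @param seed optional RNG seed; `NULL` continues the active stream.
#' @return list with `z` (15 impedances, ohm), `true_label` (layer
#'   containing the depth) and `layer_index`.
#' @export
spectrum_at_depth <- function(stack, depth_mm, templates = default_templates(),
                              seed = NULL) {
  stopifnot(inherits(stack, "phantom_stack"))
  if (depth_mm < 0 || depth_mm > stack$total_depth_mm) {
    stop("depth ", depth_mm, " mm outside stack [0, ",
         stack$total_depth_mm, "]", call. = FALSE)
  }
  missing_t <- setdiff(stack$layers$tissue, names(templates))
  if (length(missing_t)) {
    stop("no template for: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- layer_at_depth(stack, depth_mm)
  blend <- stack$boundary_blend_mm
  bounds <- cumsum(stack$layers$thickness_mm)
  tmpl <- templates[[stack$layers$tissue[idx]]]
  mu <- tmpl$log_z_mean; sd <- tmpl$log_z_sd
  if (blend > 0) {
    # interior interfaces only
    for (j in seq_len(nrow(stack$layers) - 1L)) {
      if (abs(depth_mm - bounds[j]) < blend) {
        t1 <- templates[[stack$layers$tissue[j]]]
        t2 <- templates[[stack$layers$tissue[j + 1L]]]
        w <- (depth_mm - (bounds[j] - blend)) / (2 * blend)
        mu <- (1 - w) * t1$log_z_mean + w * t2$log_z_mean
        sd <- (1 - w) * t1$log_z_sd + w * t2$log_z_sd
        break
      }
    }
  }
  k <- length(mu)
  z <- exp(mu + sd * stats::rnorm(k))
  list(z = z, true_label = stack$layers$tissue[idx], layer_index = idx)
}

#' Bayes-optimal template classifier
#'
#' Likelihood-ratio classifier using the true generative templates:
#' assigns the class maximising the log-normal likelihood of the observed
#' impedance spectrum. On template-generated data this is the Bayes rule
#' (uniform prior) and upper-bounds any learned classifier's accuracy —
#' used to certify that the synthetic task is learnable.
#'
#' @param z impedance vector (15) or matrix (n x 15), ohm.
#' @param templates named list of `tissue_template`s.
#' @return Character vector of predicted labels.
#' @export
bayes_classify <- function(z, templates = default_templates()) {
  if (is.null(dim(z))) z <- matrix(as.numeric(z), nrow = 1)
  lz <- log(as.matrix(z))
  ll <- vapply(templates, function(t) {
    sd <- pmax(t$log_z_sd, 1e-9)
    rowSums(sweep(lz, 2, t$log_z_mean)^2 / (-2 * rep(sd^2, each = nrow(lz))) -
              rep(log(sd), each = nrow(lz)))
  }, numeric(nrow(lz)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  names(templates)[max.col(ll, ties.method = "first")]
}
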