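#' Read a remapping table from CSV
#'
#' Format: first line `COND,<8 conductivities>`, then one line per
#' frequency `freq_khz,z1,...,z8` with impedances ordered by increasing
#' conductivity. Parse errors report the offending line number.
#'
#' @param path CSV file.
#' @return A `remap_table`.
#' @export
read_remap_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("remap table file too short", call. = FALSE)
  head_f <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (toupper(trimws(head_f[1])) != "COND") {
    stop("line 1: expected 'COND' header row", call. = FALSE)
  }
  cond <- suppressWarnings(as.numeric(head_f[-1]))
  if (any(is.na(cond))) stop("line 1: non-numeric conductivity", call. = FALSE)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i + 1], ",",
                                              fixed = TRUE)[[1]]))
    if (any(is.na(f))) {
      stop("line ", i + 1, ": non-numeric value", call. = FALSE)
    }
    if (length(f) != length(cond) + 1) {
      stop("line ", i + 1, ": expected ", length(cond) + 1, " fields, got ",
           length(f), call. = FALSE)
    }
    f
  })
  m <- do.call(rbind, rows)
  freqs <- m[, 1]
  z <- m[, -1, drop = FALSE]
  # row-level monotonicity with a line-numbered message
  bad <- which(apply(z, 1, function(r) any(diff(r) >= 0)))
  if (length(bad)) {
    stop("line ", bad[1] + 1, ": impedances not strictly decreasing at ",
         freqs[bad[1]], " kHz", call. = FALSE)
  }
  remap_table(cond, z, freqs)
}

#' Write a remapping table to CSV
#'
#' Deterministic inverse of [read_remap_table()]: stable field order,
#' locale-independent formatting, full precision.
#'
#' @param table a `remap_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_remap_table <- function(table, path) {
  stopifnot(inherits(table, "remap_table"))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste(c("COND", fmt(table$conductivities_us_cm)), collapse = ","),
    vapply(seq_along(table$freqs_khz), function(i) {
      paste(c(fmt(table$freqs_khz[i]), fmt(table$node_impedance_ohm[i, ])),
            collapse = ",")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled spectrum dataset (wide CSV)
#'
#' Columns: `id`, `label`, then `z_<freq>kHz` impedance columns. Rejects
#' empty datasets, non-finite features and labels outside the class set.
#'
#' @param path CSV file.
#' @param classes allowed labels; `NULL` skips the label check.
#' @return data.frame in the [generate_dataset()] layout.
#' @export
read_dataset <- function(path, classes = tissue_classes()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no samples in dataset: ", path, call. = FALSE)
  if (!all(c("label") %in% names(df))) {
    stop("dataset needs a 'label' column", call. = FALSE)
  }
  zcols <- grep("^z_", names(df), value = TRUE)
  if (!length(zcols)) stop("dataset has no z_<freq>kHz columns", call. = FALSE)
  z <- as.matrix(df[, zcols])
  if (any(!is.finite(z))) stop("non-finite feature values", call. = FALSE)
  if (!is.null(classes)) {
    bad <- setdiff(unique(df$label), classes)
    if (length(bad)) {
      stop("labels outside class set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  df
}

#' Write a labelled spectrum dataset (wide CSV)
#'
#' @param dataset data.frame in the [generate_dataset()] layout.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

MODEL_FORMAT <- "needleEIS_bnn"
MODEL_VERSION <- 1L

# %.17g round-trips IEEE doubles exactly; jsonlite's numeric output does not
num17 <- function(x) sprintf("%.17g", as.numeric(x))

#' Serialise a fitted classifier to a JSON archive
#'
#' Versioned single-file archive storing the config, class order, feature
#' scaling and full-precision posterior means/spreads. Round-trips
#' exactly: a reloaded model produces identical predictions.
#'
#' @param fit a `bnn_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "bnn_fit"))
  obj <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    config = fit$config[c("layer_sizes", "prior_mean", "prior_sd", "epochs",
                          "lr", "init_spread", "mc_samples_predict",
                          "kl_weight", "seed")],
    classes = fit$classes,
    feature_scale = list(center = num17(fit$feature_scale$center),
                         scale = num17(fit$feature_scale$scale)),
    cost_trace = fit$cost_trace,
    params = lapply(fit$params, function(l) {
      list(W_mu = num17(l$W_mu), W_rho = num17(l$W_rho),
           dim = dim(l$W_mu), b_mu = num17(l$b_mu), b_rho = num17(l$b_rho))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a classifier archive written by [write_model()]
#'
#' Refuses archives with an unknown format tag or version.
#'
#' @param path JSON archive.
#' @return A `bnn_fit`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT) ||
      !identical(as.integer(obj$version), MODEL_VERSION)) {
    stop("unsupported model archive (format '", obj$format, "' version ",
         obj$version, ")", call. = FALSE)
  }
  cfg <- obj$config
  config <- bnn_config(layer_sizes = cfg$layer_sizes,
                       prior_mean = cfg$prior_mean, prior_sd = cfg$prior_sd,
                       epochs = cfg$epochs, lr = cfg$lr,
                       init_spread = cfg$init_spread,
                       mc_samples_predict = cfg$mc_samples_predict,
                       kl_weight = cfg$kl_weight, seed = cfg$seed)
  params <- lapply(seq_len(nrow_or_len(obj$params)), function(i) {
    l <- if (is.data.frame(obj$params)) lapply(obj$params, `[[`, i)
         else obj$params[[i]]
    d <- as.integer(unlist(l$dim))
    list(W_mu = matrix(as.numeric(unlist(l$W_mu)), d[1], d[2]),
         W_rho = matrix(as.numeric(unlist(l$W_rho)), d[1], d[2]),
         b_mu = as.numeric(unlist(l$b_mu)),
         b_rho = as.numeric(unlist(l$b_rho)))
  })
  structure(list(params = params, config = config,
                 classes = as.character(obj$classes),
                 cost_trace = as.numeric(obj$cost_trace),
                 feature_scale = list(
                   center = as.numeric(obj$feature_scale$center),
                   scale = as.numeric(obj$feature_scale$scale))),
            class = "bnn_fit")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Write tissue templates to JSON
#'
#' @param templates named list of `tissue_template`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  obj <- lapply(templates, function(t) {
    list(tissue = t$tissue, log_z_mean = t$log_z_mean,
         log_z_sd = t$log_z_sd, freqs_khz = t$freqs_khz)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read tissue templates from JSON
#'
#' @param path JSON file written by [write_templates()].
#' @return Named list of `tissue_template`s.
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(obj), function(nm) {
    t <- obj[[nm]]
    tissue_template(t$tissue, as.numeric(t$log_z_mean),
                    as.numeric(t$log_z_sd), as.numeric(t$freqs_khz))
  })
  stats::setNames(out, names(obj))
}

#' Read a phantom stack from JSON
#'
#' Schema: `{"layers": [{"tissue": ..., "thickness_mm": ...}, ...],
#' "boundary_blend_mm": ...}`.
#'
#' @param path JSON file.
#' @return A `phantom_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$layers)) stop("stack config needs 'layers'", call. = FALSE)
  blend <- if (is.null(obj$boundary_blend_mm)) 0.3 else obj$boundary_blend_mm
  phantom_stack(as.data.frame(obj$layers), blend)
}

#' Write a phantom stack to JSON
#'
#' @param stack a `phantom_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "phantom_stack"))
  jsonlite::write_json(list(layers = stack$layers,
                            boundary_blend_mm = stack$boundary_blend_mm),
                       path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read a single impedance spectrum from CSV
#'
#' Long format with header `freq_khz,z_ohm`, one row per frequency.
#'
#' @param path CSV file.
#' @return An `impedance_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("freq_khz", "z_ohm") %in% names(df))) {
    stop("spectrum file needs columns freq_khz, z_ohm", call. = FALSE)
  }
  df <- df[order(df$freq_khz), ]
  impedance_spectrum(df$z_ohm, df$freq_khz)
}

#' Write a single impedance spectrum to CSV
#'
#' @param spec an `impedance_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  utils::write.csv(data.frame(freq_khz = spec$freqs_khz,
                              z_ohm = spec$z_ohm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
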