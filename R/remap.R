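#' Default excitation-frequency grid
#'
#' The 15 excitation frequencies (kHz) at which impedance magnitude is
#' sampled, spanning 1 to 349 kHz on an approximately logarithmic grid.
#'
#' @return Numeric vector of 15 strictly increasing frequencies in kHz.
#' @export
eis_frequencies <- function() {
  c(1, 2, 3, 7, 11, 17, 23, 31, 43, 61, 89, 127, 179, 251, 349)
}

N_FREQ <- 15L
N_CONC <- 8L

validate_grid <- function(freqs_khz) {
  if (!is.numeric(freqs_khz) || length(freqs_khz) != N_FREQ) {
    stop("frequency grid must have exactly ", N_FREQ, " entries", call. = FALSE)
  }
  if (any(!is.finite(freqs_khz)) || any(diff(freqs_khz) <= 0)) {
    stop("frequency grid must be finite and strictly increasing", call. = FALSE)
  }
  invisible(as.numeric(freqs_khz))
}

#' Impedance spectrum
#'
#' A single sensor observation: impedance magnitude |Z| (ohm) at each
#' frequency of the grid.
#'
#' @param z_ohm numeric vector of 15 impedance magnitudes in ohm, all
#'   finite and positive.
#' @param freqs_khz frequency grid; defaults to [eis_frequencies()].
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(z_ohm, freqs_khz = eis_frequencies()) {
  validate_grid(freqs_khz)
  z_ohm <- as.numeric(z_ohm)
  if (length(z_ohm) != length(freqs_khz)) {
    stop("impedance spectrum length does not match frequency grid", call. = FALSE)
  }
  if (any(!is.finite(z_ohm)) || any(z_ohm <= 0)) {
    stop("impedance magnitudes must be finite and > 0", call. = FALSE)
  }
  structure(list(freqs_khz = as.numeric(freqs_khz), z_ohm = z_ohm),
            class = "impedance_spectrum")
}

#' Construct a remapping (calibration) table
#'
#' Pairs, per frequency, the known conductivities of a set of saline
#' calibration solutions with the impedance magnitudes the probe measured
#' in them. Conductivity of saline depends only on concentration (not on
#' excitation frequency), so the table has one conductivity per solution
#' and one impedance node per (frequency, solution) pair.
#'
#' @param conductivities_us_cm conductivities of the calibration solutions
#'   in microsiemens/cm, strictly increasing.
#' @param node_impedance_ohm 15 x n matrix of measured |Z| (ohm), rows =
#'   frequencies, columns = solutions in the same order as
#'   `conductivities_us_cm`. Each row must be strictly decreasing (higher
#'   conductivity, lower impedance).
#' @param freqs_khz frequency grid.
#' @return An object of class `remap_table`.
#' @export
remap_table <- function(conductivities_us_cm, node_impedance_ohm,
                        freqs_khz = eis_frequencies()) {
  validate_grid(freqs_khz)
  cond <- as.numeric(conductivities_us_cm)
  if (any(!is.finite(cond)) || any(cond <= 0)) {
    stop("conductivities must be finite and positive", call. = FALSE)
  }
  if (length(cond) < 2 || any(diff(cond) <= 0)) {
    stop("conductivities must be strictly increasing (>= 2 solutions)",
         call. = FALSE)
  }
  z <- as.matrix(node_impedance_ohm)
  if (nrow(z) != length(freqs_khz) || ncol(z) != length(cond)) {
    stop("node impedance matrix must be ", length(freqs_khz), " x ",
         length(cond), call. = FALSE)
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("node impedances must be finite and > 0", call. = FALSE)
  }
  bad <- which(apply(z, 1, function(row) any(diff(row) >= 0)))
  if (length(bad)) {
    stop("calibration failure: node impedances not strictly decreasing at ",
         paste(freqs_khz[bad], collapse = ", "), " kHz", call. = FALSE)
  }
  dimnames(z) <- NULL
  structure(list(freqs_khz = as.numeric(freqs_khz),
                 conductivities_us_cm = cond,
                 node_impedance_ohm = z),
            class = "remap_table")
}

#' @export
print.remap_table <- function(x, ...) {
  cat("Impedance-to-conductivity remapping table\n")
  cat("  ", length(x$freqs_khz), " frequencies: ", x$freqs_khz[1], "-",
      x$freqs_khz[length(x$freqs_khz)], " kHz\n", sep = "")
  cat("  ", length(x$conductivities_us_cm), " calibration solutions: ",
      min(x$conductivities_us_cm), "-", max(x$conductivities_us_cm),
      " uS/cm\n", sep = "")
  invisible(x)
}

#' The shipped default calibration table
#'
#' Eight saline solutions (distilled water through 0.9 % physiological
#' saline, 5 to 16,000 uS/cm) measured at the 15 grid frequencies; each
#' node is the median of repeated probe measurements.
#'
#' @return A `remap_table`.
#' @export
default_remap_table <- function() {
  path <- system.file("extdata", "remap_table_default.csv",
                      package = "needleEIS", mustWork = TRUE)
  read_remap_table(path)
}

#' Build a remapping table from raw saline measurements
#'
#' For each calibration solution the per-frequency node impedance is the
#' median of all measured spectra in that solution (robust against sensor
#' outliers). Monotonicity across solutions is enforced: non-monotone
#' medians indicate a corrupted calibration run and raise an error naming
#' the offending frequency.
#'
#' @param saline_measurements list with one element per solution, ordered by
#'   increasing conductivity; each element a numeric matrix (samples x 15)
#'   of |Z| in ohm, or a single `impedance_spectrum`.
#' @param conductivities_us_cm conductivity of each solution, strictly
#'   increasing.
#' @param freqs_khz frequency grid shared by all measurements.
#' @return A `remap_table`.
#' @export
build_remap_table <- function(saline_measurements, conductivities_us_cm,
                              freqs_khz = eis_frequencies()) {
  validate_grid(freqs_khz)
  if (!is.list(saline_measurements) ||
      length(saline_measurements) != length(conductivities_us_cm)) {
    stop("need one measurement set per conductivity", call. = FALSE)
  }
  nodes <- vapply(saline_measurements, function(m) {
    if (inherits(m, "impedance_spectrum")) {
      if (!isTRUE(all.equal(m$freqs_khz, as.numeric(freqs_khz)))) {
        stop("spectrum frequency grid does not match table grid", call. = FALSE)
      }
      m <- matrix(m$z_ohm, nrow = 1)
    }
    m <- as.matrix(m)
    if (ncol(m) != length(freqs_khz)) {
      stop("measurement matrix must have ", length(freqs_khz), " columns",
           call. = FALSE)
    }
    if (nrow(m) < 1) stop("need >= 1 spectrum per solution", call. = FALSE)
    apply(m, 2, stats::median)
  }, numeric(length(freqs_khz)))
  remap_table(conductivities_us_cm, nodes, freqs_khz)
}

#' Remap an impedance spectrum to a conductivity spectrum
#'
#' Per frequency, conductivity is obtained by piecewise-linear
#' interpolation of the calibration nodes (|Z| on the x-axis, conductivity
#' on the y-axis; a monotone non-increasing function). Queries more
#' resistive than the most dilute solution clamp to its conductivity;
#' queries more conductive than the strongest solution clamp likewise.
#' Clamped frequencies are marked in the `out_of_range` field rather than
#' silently altered.
#'
#' @param spec an `impedance_spectrum`, or a bare numeric vector of 15
#'   impedances on the table's grid.
#' @param table a `remap_table`.
#' @return An object of class `conductivity_spectrum` with fields
#'   `freqs_khz`, `sigma_us_cm` (15 conductivities, uS/cm) and
#'   `out_of_range` (logical, per frequency).
#' @export
remap_spectrum <- function(spec, table) {
  stopifnot(inherits(table, "remap_table"))
  if (inherits(spec, "impedance_spectrum")) {
    if (!isTRUE(all.equal(spec$freqs_khz, table$freqs_khz))) {
      stop("spectrum and table frequency grids differ", call. = FALSE)
    }
    z <- spec$z_ohm
  } else {
    z <- as.numeric(spec)
    if (length(z) != length(table$freqs_khz)) {
      stop("expected ", length(table$freqs_khz), " impedance values",
           call. = FALSE)
    }
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("impedance magnitudes must be finite and > 0", call. = FALSE)
  }
  out <- remap_matrix(matrix(z, nrow = 1), table)
  structure(list(freqs_khz = table$freqs_khz,
                 sigma_us_cm = as.numeric(out$sigma[1, ]),
                 out_of_range = as.logical(out$out_of_range[1, ])),
            class = "conductivity_spectrum")
}

#' Remap a matrix of impedance spectra
#'
#' Vectorised form of [remap_spectrum()] for datasets: rows are spectra,
#' columns the 15 grid frequencies.
#'
#' @param z numeric matrix (n x 15) of |Z| in ohm.
#' @param table a `remap_table`.
#' @return list with `sigma` (n x 15 conductivities, uS/cm) and
#'   `out_of_range` (n x 15 logical).
#' @export
remap_matrix <- function(z, table) {
  stopifnot(inherits(table, "remap_table"))
  z <- as.matrix(z)
  if (ncol(z) != length(table$freqs_khz)) {
    stop("expected ", length(table$freqs_khz), " columns", call. = FALSE)
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("impedance magnitudes must be finite and > 0", call. = FALSE)
  }
  sigma <- matrix(NA_real_, nrow(z), ncol(z))
  oor <- matrix(FALSE, nrow(z), ncol(z))
  cond <- table$conductivities_us_cm
  for (f in seq_len(ncol(z))) {
    nodes <- table$node_impedance_ohm[f, ]   # strictly decreasing
    # approx() needs increasing x; reverse the pairing
    sigma[, f] <- stats::approx(x = rev(nodes), y = rev(cond),
                                xout = z[, f], rule = 2)$y
    oor[, f] <- z[, f] > nodes[1] | z[, f] < nodes[length(nodes)]
  }
  list(sigma = sigma, out_of_range = oor)
}

#' @export
print.conductivity_spectrum <- function(x, ...) {
  cat("Conductivity spectrum (uS/cm):\n")
  print(stats::setNames(signif(x$sigma_us_cm, 6),
                        paste0(x$freqs_khz, "kHz")))
  if (any(x$out_of_range)) {
    cat("out-of-range (clamped) at:",
        paste0(x$freqs_khz[x$out_of_range], "kHz", collapse = " "), "\n")
  }
  invisible(x)
}
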