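test_that("sample_spectrum follows the log-normal template model", {
  tmpl <- tissue_template("skin", log(seq(1000, 2400, by = 100)), 0)
  # zero dispersion -> exactly exp(mean)
  z <- sample_spectrum(tmpl, n = 3, seed = 1)
  expect_equal(z, matrix(rep(seq(1000, 2400, by = 100), each = 3), 3, 15),
               tolerance = 1e-12)
  # seed reproducibility
  tmpl2 <- tissue_template("skin", rep(log(1000), 15), 0.2)
  expect_identical(sample_spectrum(tmpl2, n = 5, seed = 9),
                   sample_spectrum(tmpl2, n = 5, seed = 9))
  # law of large numbers: sample log-mean within 3 SE of the template mean
  n <- 10000
  z <- sample_spectrum(tmpl2, n = n, seed = 17)
  se <- 0.2 / sqrt(n)
  expect_true(all(abs(colMeans(log(z)) - log(1000)) < 3 * se))
  expect_true(all(z > 0))
})

test_that("generate_dataset honours the requested class balance", {
  ds <- generate_dataset(seed = 3)
  expect_identical(nrow(ds), 526L)
  counts <- table(ds$label)
  expect_identical(as.integer(counts[tissue_classes()]),
                   c(150L, 81L, 149L, 146L))
  # single-row request
  one <- generate_dataset(counts = c(CSF = 1L), seed = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$label, "CSF")
  # disjoint seeds: identical counts, different spectra
  a <- generate_dataset(seed = 1); b <- generate_dataset(seed = 2)
  expect_identical(table(a$label), table(b$label))
  expect_false(isTRUE(all.equal(dataset_matrix(a)$z, dataset_matrix(b)$z)))
  expect_error(generate_dataset(counts = c(bone = 5L)), "unknown class")
  expect_error(generate_dataset(counts = c(CSF = 0L)), ">= 1")
})

test_that("default templates are anchored and ordered as expected", {
  tab <- fixture_table()
  tmpl <- default_templates(tab)
  expect_identical(names(tmpl), tissue_classes())
  # CSF template mean is the 0.9 % saline column: remaps to 16,000 uS/cm
  csf_sig <- remap_spectrum(impedance_spectrum(exp(tmpl$CSF$log_z_mean)), tab)
  expect_equal(csf_sig$sigma_us_cm, rep(16000, 15))
  # conductivity ordering at every frequency: CSF > skin,ligament > fat
  sig_of <- function(t) {
    remap_spectrum(impedance_spectrum(exp(t$log_z_mean)), tab)$sigma_us_cm
  }
  s <- lapply(tmpl, sig_of)
  expect_true(all(s$CSF > s$skin & s$CSF > s$ligament))
  expect_true(all(s$skin > s$fat & s$ligament > s$fat))
})

test_that("non-CSF templates stay in calibration range at +/- 3 sd", {
  tab <- fixture_table()
  tmpl <- default_templates(tab)
  for (cl in c("skin", "fat", "ligament")) {
    t <- tmpl[[cl]]
    for (sgn in c(-3, 3)) {
      z <- exp(t$log_z_mean + sgn * t$log_z_sd)
      sig <- remap_spectrum(impedance_spectrum(z), tab)
      expect_false(any(sig$out_of_range),
                   info = paste(cl, "at", sgn, "sd"))
    }
  }
  # CSF sits exactly on the most-conductive node: draws beyond it clamp
  # to 16,000 uS/cm (flagged), which is the physically correct value
  t <- tmpl$CSF
  low <- remap_spectrum(impedance_spectrum(exp(t$log_z_mean - 3 * t$log_z_sd)),
                        tab)
  expect_equal(low$sigma_us_cm, rep(16000, 15))
})

test_that("remapped class medians are separated from within-class spread", {
  tab <- fixture_table()
  tmpl <- default_templates(tab)
  set.seed(7)
  sig <- lapply(tmpl, function(t) {
    remap_matrix(sample_spectrum(t, n = 200), tab)$sigma
  })
  med <- sapply(sig, function(m) apply(m, 2, stats::median))
  spr <- sapply(sig, function(m) apply(m, 2, stats::sd))
  pairs <- utils::combn(tissue_classes(), 2)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sep <- abs(med[, a] - med[, b]) >= 2 * pmax(spr[, a], spr[, b])
    expect_gte(sum(sep), 8)
  }
})

test_that("generated datasets remap end-to-end; only CSF touches the boundary", {
  tab <- fixture_table()
  ds <- generate_dataset(seed = 13)
  dm <- dataset_matrix(ds)
  out <- remap_matrix(dm$z, tab)
  expect_true(all(is.finite(out$sigma)))
  non_csf <- dm$labels != "CSF"
  expect_false(any(out$out_of_range[non_csf, ]))
  # CSF flags are exclusively clamps to the 16,000 uS/cm node
  flagged <- out$out_of_range & !non_csf
  expect_true(all(out$sigma[flagged] == 16000))
})

test_that("Bayes-optimal template classifier certifies learnability", {
  td <- fixture_test_data()
  pred <- bayes_classify(td$z, default_templates())
  expect_gte(mean(pred == td$labels), 0.98)
})

test_that("spectrum_at_depth is piecewise with blend 0 and mixes at interfaces", {
  stack0 <- default_stack(boundary_blend_mm = 0)
  tmpl <- default_templates()
  # label switches exactly at cumulative thickness boundaries
  expect_identical(spectrum_at_depth(stack0, 2.999, tmpl, seed = 1)$true_label,
                   "skin")
  expect_identical(spectrum_at_depth(stack0, 3, tmpl, seed = 1)$true_label,
                   "fat")
  expect_identical(spectrum_at_depth(stack0, 32, tmpl, seed = 1)$true_label,
                   "CSF")
  expect_identical(spectrum_at_depth(stack0, 33.5, tmpl, seed = 1)$layer_index,
                   5L)
  # noiseless templates: interface midpoint is the 50/50 log-mix
  det <- lapply(tmpl, function(t) {
    tissue_template(t$tissue, t$log_z_mean, 0, t$freqs_khz)
  })
  stack <- default_stack(boundary_blend_mm = 0.5)
  at_if <- spectrum_at_depth(stack, 3, det, seed = 1)
  want <- exp((det$skin$log_z_mean + det$fat$log_z_mean) / 2)
  expect_equal(at_if$z, want, tolerance = 1e-12)
  # centre of a layer is unaffected by blending
  mid <- spectrum_at_depth(stack, 20, det, seed = 1)
  expect_equal(mid$z, exp(det$ligament$log_z_mean), tolerance = 1e-12)
  expect_error(spectrum_at_depth(stack, 99, det), "outside")
  expect_error(spectrum_at_depth(stack, -1, det), "outside")
})

test_that("template and stack constructors validate their inputs", {
  expect_error(tissue_template("x", rep(0, 14), 0.1), "length")
  expect_error(tissue_template("x", rep(0, 15), -1), ">= 0")
  expect_error(phantom_stack(data.frame(tissue = "skin", thickness_mm = 0)),
               "> 0")
  expect_error(phantom_stack(data.frame(a = 1)), "columns")
})
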