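test_that("qrs_score ranks ECG above artifact signals", {
  ecg <- gen_ecg(fs = 360, duration = 10, seed = 1)
  bw <- gen_baseline_wander(fs = 360, duration = 10, seed = 1)
  ma <- gen_muscle_artifact(fs = 360, duration = 10, seed = 1)
  expect_gt(qrs_score(ecg, 360), qrs_score(bw, 360))
  expect_gt(qrs_score(ecg, 360), qrs_score(ma, 360))
})

test_that("denoise recovers the ECG component from a noisy mixture", {
  src <- ivaecg:::synth_cell_sources(4003, 360, 72, seed = 2, guard = 3)
  A <- random_mixing_matrix(4, 52)
  X <- mix_sources(src, A, snr_db = 20, seed = 62)
  dn <- denoise(recording_bundle(X, fs = 360), algorithm = "iva_g")
  expect_s3_class(dn, "denoise_result")
  s <- src$signals[match("ECG", src$labels), seq_along(dn$cleaned)]
  # the selected component is the one most correlated with the true ECG
  cors <- abs(stats::cor(s, t(dn$result$Y[[1]])))
  expect_equal(dn$component, which.max(cors))
  # cleaning improves on the best raw channel
  ls_crmse <- function(y) {
    a <- sum(s * y) / sum(y * y)
    crmse(s, a * y)
  }
  best_raw <- min(apply(X[, seq_along(dn$cleaned)], 1, ls_crmse))
  expect_lt(ls_crmse(dn$cleaned), best_raw)
  expect_lt(ls_crmse(dn$cleaned), 0.75)
  # report covers all components and flags the selection
  expect_identical(nrow(dn$report), 4L)
  expect_identical(sum(dn$report$selected), 1L)
})

test_that("denoise passes through an already clean duplicated ECG", {
  ecg <- gen_ecg(fs = 360, duration = 8, seed = 4)
  X <- rbind(ecg, 0.9 * ecg, 1.1 * ecg, ecg)
  set.seed(7)
  X <- X + matrix(rnorm(length(X), sd = 0.01), nrow(X))
  dn <- denoise(X, algorithm = "iva_g", fs = 360)
  expect_gt(abs(stats::cor(dn$cleaned, ecg[seq_along(dn$cleaned)])), 0.99)
})

test_that("denoise rejects single-channel input", {
  expect_error(denoise(matrix(rnorm(1000), 1), fs = 360), "channels")
})

test_that("run_grid produces a deterministic tidy grid", {
  cfg <- grid_config(algorithms = "iva_g", L = 100, snr_db = 20, reps = 2,
                     seed = 31)
  g1 <- run_grid(cfg)
  expect_identical(nrow(g1), 2L)
  expect_true(all(is.finite(g1$isi_com)))
  expect_true(all(is.finite(g1$crmse)))
  expect_true(all(g1$isi_com >= 0 & g1$isi_com <= 1))
  expect_named(g1, c("algorithm", "ecg_source_id", "L", "snr_db", "replicate",
                     "seed", "isi_com", "u_wa", "crmse", "n_iterations",
                     "converged"))
  g2 <- run_grid(cfg)
  expect_identical(g1, g2)
  # CSV side effect
  path <- withr::local_tempfile(fileext = ".csv")
  run_grid(cfg, out = path)
  expect_identical(nrow(readr::read_csv(path, show_col_types = FALSE)), 2L)
})

test_that("grid configuration validates algorithm names and wfdb records", {
  expect_error(grid_config(algorithms = "pca"), "valid names")
  expect_error(grid_config(data_source = "wfdb"), "nstdb")
})

test_that("grid configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(algorithms = list("iva_g", "cca"), L = list(100, 500),
                        snr_db = 20, reps = 3, seed = 11,
                        opts = list(max_iterations = 64)), path)
  cfg <- read_grid_config(path)
  expect_s3_class(cfg, "grid_config")
  expect_identical(cfg$algorithms, c("iva_g", "cca"))
  expect_identical(cfg$L, c(100L, 500L))
  expect_identical(cfg$opts$max_iterations, 64L)
})

test_that("reproduce_table returns the published table layouts", {
  fast <- iva_options(max_iterations = 48)
  t2 <- reproduce_table(2, reps = 2, L = 200, seed = 5, opts = fast)
  expect_s3_class(t2, "benchmark_table")
  expect_identical(t2$source_label, "surrogate")
  # 4 SNR rows x 3 algorithm columns
  expect_identical(nrow(t2$wide), 4L)
  expect_identical(sort(t2$wide$snr_db), c(0, 5, 10, 20))
  expect_true(all(c("iva_l", "iva_g", "iva_ggd") %in% names(t2$wide)))
  vals <- unlist(t2$wide[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(reproduce_table(4), "table_id")
})

test_that("tidiers and plots summarize results", {
  coll <- make_test_collection(seed = 12, L = 500)
  r <- iva_g(coll, iva_options(max_iterations = 64))
  td <- tidy(r)
  expect_identical(nrow(td), 4L * 500L * 4L)  # D x L x K
  gl <- glance(r)
  expect_identical(gl$algorithm, "iva_g")
  expect_identical(gl$K, 4L)
  expect_s3_class(autoplot(r), "ggplot")
  src <- gen_standard_sources(duration = 5, seed = 1)
  expect_s3_class(autoplot(src), "ggplot")
  expect_identical(nrow(tidy(src)), 4L * 1800L)
  cfg <- grid_config(algorithms = c("iva_g", "cca"), L = c(100, 200),
                     snr_db = 20, reps = 2, seed = 3,
                     opts = iva_options(max_iterations = 32))
  g <- run_grid(cfg)
  expect_s3_class(plot_grid_summary(g), "ggplot")
  summ <- summarize_grid(g)
  expect_identical(nrow(summ), 4L)
  expect_true(all(summ$n == 2))
})

test_that("the command-line interface runs a simulate round trip", {
  cli <- system.file("cli", "ivaecg.R", package = "ivaecg")
  expect_true(nzchar(cli))
  out <- withr::local_tempfile(fileext = ".csv")
  res <- system2("Rscript", c(cli, "simulate", "--duration", "3",
                              "--seed", "4", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  b <- read_csv_matrix(out, fs = 360)
  expect_identical(nrow(b$channels), 4L)
})
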