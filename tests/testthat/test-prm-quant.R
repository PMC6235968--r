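# XIC extraction, integration, scoring, q-values, quantification.

make_run <- function(panel = mini_panel(), cfg = noise_free_config(),
                     stage = "MG", seed = 9, truth_seed = 5) {
  truth <- make_ground_truth(panel, cfg, seed = truth_seed)
  list(run = simulate_run(panel, truth, cfg, stage, seed = seed),
       truth = truth)
}

test_that("XIC extraction honours the m/z tolerance and RT window", {
  x <- make_run()
  run <- x$run
  pep <- "ISPNSPVAR"
  tn <- names(x$truth$fractions[[pep]])[1]
  full <- extract_xic(run, pep, "light", tn)
  expect_gt(length(full$time_s), 0)
  # a 0.6 Da offset exceeds the 0.5 Da product tolerance -> empty, not error
  off <- extract_xic(run, pep, "light", tn, mz_tolerance = 0.5,
                     target_mz = full$mz + 0.6)
  expect_length(off$time_s, 0)
  expect_equal(integrate_auc(off), 0)
  # +/- 5 min window around the scheduled 13.25 min
  win <- extract_xic(run, pep, "light", tn, rt_window = 5)
  expect_true(all(win$time_s / 60 >= 8.25 & win$time_s / 60 <= 18.25))
  expect_error(extract_xic(run, "NOSUCHPEP", "light", tn), "no such")
})

test_that("trapezoidal integration matches closed forms", {
  rect <- list(time_s = 0:10, intensity = rep(1, 11))
  expect_equal(integrate_auc(rect), 10)
  t <- seq(-20, 20, by = 0.1)
  gauss <- list(time_s = t, intensity = 1000 * exp(-t^2 / (2 * 2^2)))
  expect_equal(integrate_auc(gauss), 1000 * 2 * sqrt(2 * pi),
               tolerance = 1e-3)
  expect_equal(integrate_auc(list(time_s = numeric(), intensity = numeric())),
               0)
  expect_equal(integrate_auc(gauss, boundaries = c(-2, 2)),
               1000 * 2 * sqrt(2 * pi) * (2 * pnorm(1) - 1), tolerance = 1e-3)
  expect_error(integrate_auc(rect, boundaries = c(5, 5)), "precede")
})

test_that("ppm arithmetic reproduces the gate examples", {
  expect_equal(mass_error_ppm(470.7665, 470.7642), 4.9, tolerance = 0.02)
  expect_lt(mass_error_ppm(470.7665, 470.7642), 5)
  expect_gt(mass_error_ppm(470.80, 470.7642), 5)  # 76 ppm
  expect_equal(mass_error_ppm(470.80, 470.7642), 76, tolerance = 0.1)
})

test_that("transition-group scoring rewards a clean noise-free group", {
  x <- make_run()
  run <- x$run
  pep <- "ISPNSPVAR"
  tns <- names(x$truth$fractions[[pep]])
  lx <- lapply(tns, function(tn) extract_xic(run, pep, "light", tn))
  hx <- lapply(tns, function(tn) extract_xic(run, pep, "heavy", tn))
  sc <- score_transition_group(lx, hx)
  expect_equal(sc$coelution_r, 1, tolerance = 1e-9)
  expect_equal(sc$intensity_dotp, 1, tolerance = 1e-9)
  expect_lt(sc$mass_error_ppm, 0.01)
  expect_true(sc$passes_ppm_gate)
  # apex interpolation is quadratic, not exact on a Gaussian: ~1e-5 slack
  expect_equal(sc$composite, 1, tolerance = 1e-4)
  expect_error(score_transition_group(lx[1], hx), "at least 2")
})

test_that("all-zero traces score with flagged zero coelution", {
  zero <- function(tn) structure(
    list(peptide = "P", isotope = "light", transition = tn,
         time_s = 0:10, intensity = rep(0, 11), mz = 500, query_mz = 500,
         theoretical_mz = 500, precursor_mz = 500,
         precursor_theoretical_mz = 500, scheduled_rt_min = NA_real_),
    class = "xic")
  sc <- score_transition_group(list(zero("a"), zero("b")),
                               list(zero("a"), zero("b")))
  expect_equal(sc$coelution_r, 0)
  expect_equal(sc$intensity_dotp, 0)
  expect_true(sc$flagged_zero_traces)
})

test_that("q-value estimator matches its definition and brute force", {
  expect_equal(estimate_q_values(rep(10, 5), rep(0, 5)), rep(0, 5))
  expect_equal(estimate_q_values(c(10, 1, 1, 1), c(5, 5, 5, 5))[1], 0)
  # identically distributed targets and decoys -> median q near 1
  set.seed(21)
  t <- rnorm(2000); d <- rnorm(2000)
  expect_gt(median(estimate_q_values(t, d)), 0.85)
  # brute force: q_i = min over thresholds at scores <= s_i of FDR
  for (rep in 1:10) {
    ts <- round(rnorm(sample(5:50, 1)), 1)  # ties on purpose
    ds <- round(rnorm(sample(5:50, 1)), 1)
    q <- estimate_q_values(ts, ds)
    brute <- vapply(ts, function(s) {
      thr <- ts[ts <= s]
      min(vapply(thr, function(x)
        min(1, sum(ds >= x) / max(1, sum(ts >= x))), numeric(1)))
    }, numeric(1))
    expect_equal(q, brute)
    # monotone non-increasing in score
    o <- order(ts, decreasing = TRUE)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
  expect_error(estimate_q_values(numeric(), 1), "no target")
  expect_error(estimate_q_values(1, numeric()), "decoys")
})

test_that("q-value gates map to keep/flag/remove", {
  d <- apply_q_filter(c(0.004, 0.03, 0.07))
  expect_equal(as.character(d), c("kept", "flagged", "removed"))
  s <- apply_q_filter(c(0.004, 0.03, 0.07), strict = TRUE)
  expect_equal(as.character(s), c("kept", "removed", "removed"))
})

test_that("single-point calibration is plain ratio arithmetic", {
  expect_equal(quantify_single_point(100, 100, 10), 10)
  expect_equal(quantify_single_point(100, 50, 50), 100)
  expect_equal(quantify_single_point(100, 100, 10, injected_ug = 2), 5)
  expect_warning(out <- quantify_single_point(100, 0, 10),
                 "quantification failure")
  expect_true(is.na(out))
  expect_error(quantify_single_point(1, 1, 0), "spike")
})

test_that("quantification is invariant to a global intensity scale", {
  x <- make_run()
  run <- x$run
  q1 <- quantify_run(run, mini_panel(), seed = 4)
  run$traces$intensity <- run$traces$intensity * 7.3
  q2 <- quantify_run(run, mini_panel(), seed = 4)
  expect_equal(q2$fmol_per_ug, q1$fmol_per_ug, tolerance = 1e-9)
})

test_that("noise-free quantification recovers the hidden truth", {
  panel <- mini_panel()
  x <- make_run(panel)
  q <- quantify_run(x$run, panel, seed = 4)
  truth <- x$run$truth_fmol_per_ug[q$peptide]
  expect_true(all(abs(q$fmol_per_ug - truth) / truth < 0.02))
  expect_true(all(q$decision == "kept"))
})

test_that("dilution linearity is perfect on a noise-free series", {
  panel <- mini_panel()
  cfg <- noise_free_config()
  series <- simulate_spike_series(panel, endogenous_fmol = 10, cfg, seed = 2)
  p1 <- panel; p1$protein_id <- p1$peptide
  sdf <- do.call(rbind, lapply(series, function(r) {
    q <- quantify_run(r, p1, seed = 1)
    data.frame(level = r$spike_level,
               auc_heavy = q$auc_heavy[q$peptide == "ISPNSPVAR"],
               auc_light = q$auc_light[q$peptide == "ISPNSPVAR"])
  }))
  fit <- evaluate_dilution_linearity(sdf)
  expect_gte(fit$r_squared, 0.999)
  expect_equal(fit$n_used, 5)  # level 0 excluded
  # flat responses: no dependence on level
  flat <- data.frame(level = c(1, 5, 10, 100), auc_heavy = 4, auc_light = 2)
  ffit <- evaluate_dilution_linearity(flat)
  expect_equal(ffit$slope, 0, tolerance = 1e-12)
  expect_equal(ffit$r_squared, 0, tolerance = 1e-9)
  # zero endogenous signal excludes the run with a warning
  bad <- rbind(sdf, data.frame(level = 400, auc_heavy = 1, auc_light = 0))
  expect_warning(bfit <- evaluate_dilution_linearity(bad), "excluded")
  expect_equal(bfit$n_used, 5)
  expect_error(evaluate_dilution_linearity(sdf[1:2, ]), "at least 3")
})

test_that("spike-level choice matches on the log scale with low tie", {
  series <- data.frame(level = c(0, 1, 5, 10, 100, 200),
                       auc_heavy = c(0, 10, 50, 100, 1000, 2000))
  expect_equal(choose_spike_level(series, 100), 10)
  expect_equal(choose_spike_level(series, 1900), 200)
  # exact log-scale tie between two adjacent levels goes to the lower one
  two <- data.frame(level = c(5, 100), auc_heavy = c(50, 1000))
  expect_equal(choose_spike_level(two, sqrt(50 * 1000)), 5)
  expect_error(choose_spike_level(series, 0), "positive")
})

test_that("accepted identifications co-elute within the jitter", {
  panel <- mini_panel()
  cfg <- sim_config(noise_sd = 20, rt_jitter_sd = 2)
  truth <- make_ground_truth(panel, cfg, seed = 5)
  run <- simulate_run(panel, truth, cfg, "MG", seed = 13)
  q <- quantify_run(run, panel, seed = 13)
  for (pep in q$peptide[q$decision == "kept"]) {
    tns <- names(truth$fractions[[pep]])
    l <- extract_xic(run, pep, "light", tns[1])
    h <- extract_xic(run, pep, "heavy", tns[1])
    dt <- abs(l$time_s[which.max(l$intensity)] -
                h$time_s[which.max(h$intensity)])
    expect_lte(dt, max(2 * cfg$rt_jitter_sd, 2 * cfg$sampling_interval))
  }
})
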