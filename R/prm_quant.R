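# XIC extraction, area integration, transition-group scoring, decoy-based
# q-values, q-value gating, single-point-calibration quantification and
# dilution-series linearity.

#' Extract an ion chromatogram from a run
#'
#' Pulls the trace of one (peptide, isotope, transition) out of a run,
#' optionally restricted to a retention-time window around the scheduled RT
#' and gated on the m/z match tolerance: if the requested target m/z is
#' further than `mz_tolerance` from the trace's reported m/z, an empty
#' (zero-length) trace is returned rather than an error.
#'
#' @param run A `prm_run`.
#' @param peptide,isotope,transition Trace key; `isotope` is `"light"` or
#'   `"heavy"`.
#' @param mz_tolerance Ion match tolerance in Da (default 0.5, the product
#'   tolerance; use 1.0 for the 2 m/z precursor selection window).
#' @param rt_window Half-width (minutes) of the window around the scheduled
#'   RT; `NULL` keeps the whole trace. The acquisition default is 5 min.
#' @param target_mz Optional m/z to match against the reported trace m/z.
#' @return An `xic` list: `peptide`, `isotope`, `transition`, `time_s`,
#'   `intensity`, `mz` (reported), `theoretical_mz`, `scheduled_rt_min`.
#' @export
extract_xic <- function(run, peptide, isotope, transition,
                        mz_tolerance = 0.5, rt_window = NULL,
                        target_mz = NULL) {
  if (mz_tolerance <= 0) stop("mz_tolerance must be positive")
  meta <- run$transitions
  sel <- meta$peptide == peptide & meta$isotope == isotope &
    meta$transition == transition
  if (!any(sel))
    stop("no such transition in run: ", peptide, "/", isotope, "/", transition)
  meta <- meta[which(sel)[1L], ]
  tr <- run$traces
  keep <- tr$peptide == peptide & tr$isotope == isotope &
    tr$transition == transition
  time_s <- tr$time_s[keep]
  intensity <- tr$intensity[keep]
  if (!is.null(target_mz) &&
      abs(meta$observed_mz - target_mz) > mz_tolerance) {
    time_s <- numeric(); intensity <- numeric()
  }
  if (!is.null(rt_window) && length(time_s) &&
      !is.na(meta$scheduled_rt_min)) {
    inside <- abs(time_s / 60 - meta$scheduled_rt_min) <= rt_window
    time_s <- time_s[inside]; intensity <- intensity[inside]
  }
  structure(list(peptide = peptide, isotope = isotope,
                 transition = transition, time_s = time_s,
                 intensity = intensity, mz = meta$observed_mz,
                 query_mz = target_mz %||% meta$theoretical_mz,
                 theoretical_mz = meta$theoretical_mz,
                 precursor_mz = meta$precursor_observed_mz,
                 precursor_theoretical_mz = meta$precursor_theoretical_mz,
                 scheduled_rt_min = meta$scheduled_rt_min),
            class = "xic")
}

#' Mass error in parts per million
#'
#' @param observed,theoretical Observed and theoretical m/z.
#' @return `1e6 * |observed - theoretical| / theoretical`.
#' @examples
#' mass_error_ppm(470.7665, 470.7642)  # 4.9 ppm, inside the 5 ppm gate
#' @export
mass_error_ppm <- function(observed, theoretical) {
  1e6 * abs(observed - theoretical) / theoretical
}

#' Trapezoidal area under an ion chromatogram
#'
#' @param xic An `xic` (or any list with `time_s` and `intensity`).
#' @param boundaries Optional `c(start, end)` integration boundaries in
#'   seconds; default integrates the whole trace. Zero-length traces give 0.
#' @return The area (intensity * seconds).
#' @export
integrate_auc <- function(xic, boundaries = NULL) {
  t <- xic$time_s; y <- xic$intensity
  if (length(t) < 2L) return(0)
  if (!is.null(boundaries)) {
    if (boundaries[1L] >= boundaries[2L])
      stop("integration start must precede end")
    keep <- t >= boundaries[1L] & t <= boundaries[2L]
    t <- t[keep]; y <- y[keep]
    if (length(t) < 2L) return(0)
  }
  sum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

.apex_time <- function(xics) {
  xics <- xics[vapply(xics, function(x) length(x$time_s) > 0L, logical(1))]
  if (!length(xics)) return(NA_real_)
  n <- vapply(xics, function(x) length(x$time_s), integer(1))
  xics <- xics[n == max(n)]  # ignore truncated traces
  total <- Reduce(`+`, lapply(xics, `[[`, "intensity"))
  t <- xics[[1L]]$time_s
  i <- which.max(total)
  if (!length(i) || is.na(i)) return(NA_real_)
  # quadratic interpolation of the apex over the three points around it
  if (i > 1L && i < length(total)) {
    y1 <- total[i - 1L]; y2 <- total[i]; y3 <- total[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      return(t[i] + delta * (t[2L] - t[1L]))
    }
  }
  t[i]
}

#' Score a transition group
#'
#' Combines the identification evidence the workflow relies on: closeness
#' of the observed apex to the scheduled retention time, precursor mass
#' error in ppm (the identification gate is < 5 ppm), co-elution of the
#' transition traces (mean pairwise Pearson correlation), and agreement of
#' the relative transition intensities with a reference pattern (normalized
#' dot product; the heavy traces serve as the reference when none is given,
#' mirroring the comparison of endogenous against synthetic-peptide XICs).
#'
#' @param light_xics,heavy_xics Lists of `xic` objects (>= 2 transitions
#'   each) for the endogenous and labeled form.
#' @param reference_fractions Optional named reference relative intensities;
#'   default: heavy-trace area fractions.
#' @param weights Composite-score weights for the four sub-scores
#'   (`rt`, `ppm`, `coelution`, `dotp`).
#' @param rt_tolerance_min RT deviation (minutes) at which the RT sub-score
#'   reaches zero.
#' @param ppm_gate Mass-error gate in ppm (default 5).
#' @return A `transition_group_score` list: `rt_delta_min`,
#'   `mass_error_ppm`, `coelution_r`, `intensity_dotp`, `composite`,
#'   `passes_ppm_gate`, `flagged_zero_traces`.
#' @export
score_transition_group <- function(light_xics, heavy_xics,
                                   reference_fractions = NULL,
                                   weights = c(rt = 0.2, ppm = 0.3,
                                               coelution = 0.3, dotp = 0.2),
                                   rt_tolerance_min = 1, ppm_gate = 5) {
  if (length(light_xics) < 2L || length(heavy_xics) < 2L)
    stop("need at least 2 transitions per isotope")
  flagged <- FALSE
  # retention time of the summed light trace vs schedule
  sched <- light_xics[[1L]]$scheduled_rt_min
  apex <- .apex_time(light_xics)
  rt_delta <- if (is.na(sched) || is.na(apex)) NA_real_
  else abs(apex / 60 - sched)
  # mass error: reported trace m/z against the m/z each XIC was queried at
  # (the theoretical fragment m/z for genuine assays; decoy m/z for decoys)
  ppm <- mean(vapply(light_xics, function(x)
    mass_error_ppm(x$mz, x$query_mz %||% x$theoretical_mz), numeric(1)))
  # co-elution: mean pairwise Pearson of light transition traces
  pairs <- utils::combn(length(light_xics), 2L)
  rs <- apply(pairs, 2L, function(ix) {
    a <- light_xics[[ix[1L]]]$intensity; b <- light_xics[[ix[2L]]]$intensity
    if (length(a) < 3L || length(a) != length(b) ||
        stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  })
  if (all(is.na(rs))) { coelution_r <- 0; flagged <- TRUE }
  else coelution_r <- mean(rs, na.rm = TRUE)
  # intensity pattern agreement
  la <- vapply(light_xics, integrate_auc, numeric(1))
  if (is.null(reference_fractions))
    reference_fractions <- vapply(heavy_xics, integrate_auc, numeric(1))
  ref <- as.numeric(reference_fractions)
  if (sum(la) == 0 || sum(ref) == 0) { dotp <- 0; flagged <- TRUE }
  else dotp <- sum(la * ref) / sqrt(sum(la^2) * sum(ref^2))
  s_rt <- if (is.na(rt_delta)) 0 else max(0, 1 - rt_delta / rt_tolerance_min)
  s_ppm <- max(0, 1 - ppm / ppm_gate)
  s_co <- max(0, coelution_r)
  composite <- unname(weights["rt"] * s_rt + weights["ppm"] * s_ppm +
                        weights["coelution"] * s_co + weights["dotp"] * dotp)
  structure(list(rt_delta_min = rt_delta, mass_error_ppm = ppm,
                 coelution_r = coelution_r, intensity_dotp = dotp,
                 composite = composite, passes_ppm_gate = ppm < ppm_gate,
                 flagged_zero_traces = flagged),
            class = "transition_group_score")
}

#' Decoy-based q-value estimation
#'
#' Simplified target-decoy FDR in place of full semi-supervised mProphet
#' rescoring: at each target score `s`, `FDR(s) = #\{decoys >= s\} /
#' max(1, #\{targets >= s\})`, and the q-value is the running minimum of the
#' FDR over decreasing score. Decoys come from shuffled-sequence transition
#' groups (see [decoy_scores()]).
#'
#' @param target_scores,decoy_scores Numeric composite scores.
#' @return Numeric q-values aligned with `target_scores`, each in \[0, 1\]
#'   and monotone non-increasing in the score.
#' @export
estimate_q_values <- function(target_scores, decoy_scores) {
  if (!length(target_scores)) stop("no target scores")
  if (!length(decoy_scores))
    stop("no decoy scores: generate decoys first ",
         "(e.g. shuffled-sequence transition groups via decoy_scores())")
  ord <- order(target_scores, decreasing = TRUE)
  s <- target_scores[ord]
  n_dec <- vapply(s, function(x) sum(decoy_scores >= x), numeric(1))
  n_tar <- vapply(s, function(x) sum(target_scores >= x), numeric(1))
  fdr <- pmin(1, n_dec / pmax(1, n_tar))
  q_sorted <- rev(cummin(rev(fdr)))  # running min over decreasing score
  q <- numeric(length(s))
  q[ord] <- q_sorted
  q
}

#' Score shuffled-sequence decoy transition groups against a run
#'
#' For every panel peptide, shuffles the internal residues (keeping the
#' C-terminal K/R so the label arithmetic stays valid), computes the decoy
#' fragment m/z, and scores the XICs extracted at those m/z. Since decoy
#' fragments rarely match real traces within the product tolerance, decoy
#' traces are mostly empty and their composite scores populate the null.
#'
#' @param run A `prm_run`.
#' @param panel The `assay_panel` the run was acquired with.
#' @param seed Integer seed for the shuffle.
#' @param mz_tolerance Product ion match tolerance in Da.
#' @return Numeric vector of decoy composite scores (one per panel row).
#' @export
decoy_scores <- function(run, panel, seed = 1L, mz_tolerance = 0.5) {
  set.seed(seed)
  vapply(seq_len(nrow(panel)), function(i) {
    pep <- panel$peptide[i]
    n <- nchar(pep)
    core <- strsplit(substr(pep, 1L, n - 1L), "")[[1L]]
    decoy <- paste0(paste(sample(core), collapse = ""), substr(pep, n, n))
    ions <- parse_product_ions(panel$product_ions[i])
    ions <- ions[ions$ion_type %in% c("y", "b") & ions$ordinal < n, ,
                 drop = FALSE]
    if (nrow(ions) < 2L) return(0)
    trans <- paste0(ions$ion_type, ions$ordinal, strrep("+", ions$charge))
    get <- function(iso, heavy) lapply(seq_len(nrow(ions)), function(j) {
      dm <- fragment_mz(decoy, ions$ion_type[j], ions$ordinal[j],
                        ions$charge[j], heavy = heavy)
      extract_xic(run, pep, iso, trans[j], mz_tolerance = mz_tolerance,
                  target_mz = dm)
    })
    sc <- score_transition_group(get("light", FALSE), get("heavy", TRUE))
    sc$composite
  }, numeric(1))
}

#' Apply the q-value gates
#'
#' Identifications with q < 0.01 are kept; 0.01 <= q <= 0.05 are flagged
#' for manual review (kept by default, removed under `strict`); q > 0.05
#' are removed outright.
#'
#' @param q_values Numeric q-values.
#' @param strict Remove flagged groups as well.
#' @return Factor with levels `kept`, `flagged`, `removed` (under `strict`
#'   flagged groups are reported as `removed`).
#' @export
apply_q_filter <- function(q_values, strict = FALSE) {
  out <- ifelse(q_values < 0.01, "kept",
                ifelse(q_values <= 0.05, "flagged", "removed"))
  if (strict) out[out == "flagged"] <- "removed"
  factor(out, levels = c("kept", "flagged", "removed"))
}

#' Single-point-calibration absolute quantification
#'
#' The ratio of the summed endogenous transition areas to the summed
#' heavy-labeled transition areas, multiplied by the known spiked amount,
#' gives the absolute amount; dividing by the injected protein mass yields
#' fmol per microgram.
#'
#' @param auc_light,auc_heavy Summed quantifier-transition areas.
#' @param spike Spiked heavy amount (fmol), > 0.
#' @param injected_ug Injected protein amount (micrograms, default 1).
#' @return Abundance in fmol per microgram; `NA` with a warning when the
#'   heavy area is zero (quantification failure, reported rather than
#'   silently dropped).
#' @export
quantify_single_point <- function(auc_light, auc_heavy, spike,
                                  injected_ug = 1) {
  if (any(spike <= 0)) stop("spike must be positive")
  if (any(injected_ug <= 0)) stop("injected_ug must be positive")
  bad <- auc_heavy <= 0
  if (any(bad))
    warning(sum(bad), " quantification failure(s): zero heavy-label signal")
  ifelse(bad, NA_real_, (auc_light / auc_heavy) * spike / injected_ug)
}

#' Quantify every panel peptide in a run
#'
#' End-to-end per-run quantification: extracts the quantifier-transition
#' XICs of both isotopes, integrates them, scores the transition group,
#' estimates q-values against shuffled-sequence decoys, applies the q
#' gates, and computes the single-point-calibration abundance for every
#' group that survives.
#'
#' @param run A `prm_run`.
#' @param panel The `assay_panel`.
#' @param strict Remove flagged (0.01 <= q <= 0.05) groups.
#' @param rt_window RT extraction half-window in minutes.
#' @param seed Seed for the decoy shuffle.
#' @return Data frame: `sample_id`, `stage`, `protein`, `peptide`,
#'   `auc_light`, `auc_heavy`, `ratio`, `spike_fmol`, `fmol_per_ug`,
#'   `composite_score`, `mass_error_ppm`, `q_value`, `decision`.
#' @export
quantify_run <- function(run, panel, strict = FALSE, rt_window = 5,
                         seed = 1L) {
  scores <- numeric(nrow(panel))
  rows <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    pep <- panel$peptide[i]
    trans <- .transition_names(panel$product_ions[i])
    lx <- lapply(trans, function(tn)
      extract_xic(run, pep, "light", tn, rt_window = rt_window))
    hx <- lapply(trans, function(tn)
      extract_xic(run, pep, "heavy", tn, rt_window = rt_window))
    sc <- score_transition_group(lx, hx)
    scores[i] <- sc$composite
    auc_l <- sum(vapply(lx, integrate_auc, numeric(1)))
    auc_h <- sum(vapply(hx, integrate_auc, numeric(1)))
    spike <- unname(run$spiked[pep])
    rows[[i]] <- data.frame(
      sample_id = run$run_id, stage = run$stage,
      protein = panel$protein_id[i], peptide = pep,
      auc_light = auc_l, auc_heavy = auc_h,
      ratio = if (auc_h > 0) auc_l / auc_h else NA_real_,
      spike_fmol = spike,
      composite_score = sc$composite, mass_error_ppm = sc$mass_error_ppm,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  dec <- decoy_scores(run, panel, seed = seed)
  out$q_value <- estimate_q_values(scores, dec)
  out$decision <- apply_q_filter(out$q_value, strict = strict)
  out$fmol_per_ug <- NA_real_
  usable <- out$decision != "removed" & out$spike_fmol > 0
  out$fmol_per_ug[usable] <- suppressWarnings(quantify_single_point(
    out$auc_light[usable], out$auc_heavy[usable], out$spike_fmol[usable],
    run$injected_ug))
  out
}

#' Dilution-series linearity
#'
#' For each non-zero spike level the run-to-run-corrected response is the
#' heavy summed area divided by the endogenous summed area (the endogenous
#' signal acts as the internal normalizer across injections). An ordinary
#' least-squares fit of the corrected response on the level gives slope,
#' intercept and R-squared.
#'
#' @param series Data frame with columns `level`, `auc_heavy`, `auc_light`
#'   (one row per spike run).
#' @return A `dilution_fit` list: `levels`, `corrected_responses`, `slope`,
#'   `intercept`, `r_squared`, `n_used`.
#' @export
evaluate_dilution_linearity <- function(series) {
  zero_light <- series$auc_light <= 0
  if (any(zero_light)) {
    warning(sum(zero_light),
            " run(s) excluded: zero endogenous (normalizer) signal")
    series <- series[!zero_light, , drop = FALSE]
  }
  series <- series[series$level > 0, , drop = FALSE]
  if (nrow(series) < 3L) stop("need at least 3 non-zero spike levels")
  resp <- series$auc_heavy / series$auc_light
  fit <- stats::lm(resp ~ series$level)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((resp - mean(resp))^2)
  r2 <- if (ss_tot <= 0) 0 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(levels = series$level, corrected_responses = resp,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_used = nrow(series)),
            class = "dilution_fit")
}

#' Choose the spike level matching the endogenous signal
#'
#' Returns the tested spike level whose heavy summed area is closest, on
#' the log scale, to the endogenous summed area (spiking aims at a heavy
#' signal similar in intensity to the endogenous one). Ties go to the lower
#' level.
#'
#' @param series Data frame with columns `level` and `auc_heavy`.
#' @param endogenous_auc Endogenous summed area to match.
#' @return The chosen level (fmol).
#' @export
choose_spike_level <- function(series, endogenous_auc) {
  ok <- series$level > 0 & series$auc_heavy > 0
  s <- series[ok, , drop = FALSE]
  if (!nrow(s)) stop("no usable spike runs")
  if (endogenous_auc <= 0) stop("endogenous_auc must be positive")
  d <- abs(log(s$auc_heavy) - log(endogenous_auc))
  best <- which(d <= min(d) + 1e-12)
  min(s$level[best])
}
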