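# Seeded simulator of PRM acquisitions, spike dilution series, qPCR plates
# and paired mean/SE stage profiles, each carrying its hidden ground truth.
# Stands in for the instrument and the fruit so every downstream stage can
# be tested against known quantities.

#' Simulation configuration
#'
#' @param stages Ordered ripening-stage labels; default mature green,
#'   breaker, orange, red.
#' @param replicates_per_stage Biological replicates per stage (default 6).
#' @param rt_sigma Gaussian elution-peak width (sd, seconds). The default
#'   2.55 s corresponds to a 6 s full width at half maximum on a 60-min
#'   gradient.
#' @param rt_jitter_sd Run-to-run retention-time jitter (sd, seconds),
#'   shared by all traces of one peptide (isotopologues co-elute).
#' @param noise_sd Additive Gaussian intensity noise (arbitrary units),
#'   truncated at zero.
#' @param mz_error_ppm_sd Mass-measurement error (sd, ppm) applied to the
#'   reported trace m/z.
#' @param response_factor Summed transition area (intensity * s) generated
#'   per fmol of peptide on column.
#' @param sampling_interval Chromatogram sampling interval (seconds).
#' @param injected_ug Protein amount analyzed per injection (micrograms).
#' @return A `sim_config` list.
#' @export
sim_config <- function(stages = c("MG", "BR", "OR", "R"),
                       replicates_per_stage = 6L,
                       rt_sigma = 2.55, rt_jitter_sd = 2,
                       noise_sd = 50, mz_error_ppm_sd = 1.5,
                       response_factor = 1e5, sampling_interval = 1,
                       injected_ug = 1) {
  stopifnot(replicates_per_stage >= 1L, rt_sigma >= 0, rt_jitter_sd >= 0,
            noise_sd >= 0, mz_error_ppm_sd >= 0, response_factor > 0,
            sampling_interval > 0, injected_ug > 0)
  structure(list(stages = stages,
                 replicates_per_stage = as.integer(replicates_per_stage),
                 rt_sigma = rt_sigma, rt_jitter_sd = rt_jitter_sd,
                 noise_sd = noise_sd, mz_error_ppm_sd = mz_error_ppm_sd,
                 response_factor = response_factor,
                 sampling_interval = sampling_interval,
                 injected_ug = injected_ug),
            class = "sim_config")
}

#' Ground truth for a simulated experiment
#'
#' Draws protein abundance trajectories over the ripening stages (a mix of
#' climacteric, declining, late-drop and flat shapes, matching the patterns
#' reported for ethylene-signaling proteins), per-peptide digestion-yield
#' factors and per-transition relative intensity fractions (one Dirichlet
#' draw per peptide, shared by the light and heavy form).
#'
#' @param panel An `assay_panel`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param abundance_range Range (fmol per microgram) from which per-protein
#'   base abundances are drawn log-uniformly; default 1-20, the order of
#'   magnitude of receptor abundances in ripening tomato pericarp.
#' @param yield_preset `"uniform"` (all digestion yields 1) or
#'   `"discordant"` (yields cycle through 1, 0.5, 0.25 across the peptides
#'   of a protein, emulating position-dependent trypsin digestion
#'   efficiency).
#' @return A `ground_truth` list with `protein_abundance` (matrix, proteins
#'   x stages, fmol/ug), `yield` (named by peptide) and `fractions` (named
#'   list of per-transition fractions summing to 1).
#' @export
make_ground_truth <- function(panel, config, seed = 1L,
                              abundance_range = c(1, 20),
                              yield_preset = c("uniform", "discordant")) {
  yield_preset <- match.arg(yield_preset)
  set.seed(seed)
  proteins <- unique(panel$protein_id)
  stages <- config$stages
  k <- length(stages)
  shape_bank <- list(
    climacteric = function(k) {
      pk <- sample(2:max(2, k - 1), 1)
      z <- -abs(seq_len(k) - pk); 0.4 + 0.6 * (z - min(z)) / max(1e-9, diff(range(z)))
    },
    declining = function(k) seq(1, 0.3, length.out = k),
    late_drop = function(k) c(rep(1, k - 1), 0.45),
    flat = function(k) rep(1, k)
  )
  ab <- t(vapply(proteins, function(p) {
    base <- exp(stats::runif(1, log(abundance_range[1]), log(abundance_range[2])))
    shape <- shape_bank[[sample(length(shape_bank), 1)]](k)
    base * shape
  }, numeric(k)))
  colnames(ab) <- stages
  yield <- rep(1, nrow(panel))
  if (yield_preset == "discordant") {
    for (p in proteins) {
      i <- which(panel$protein_id == p)
      yield[i] <- rep(c(1, 0.5, 0.25), length.out = length(i))
    }
  }
  names(yield) <- panel$peptide
  fractions <- lapply(seq_len(nrow(panel)), function(i) {
    ions <- parse_product_ions(panel$product_ions[i])
    g <- stats::rgamma(nrow(ions), shape = 2)
    f <- g / sum(g)
    names(f) <- paste0(ions$ion_type, ifelse(is.na(ions$ordinal), "", ions$ordinal),
                       strrep("+", ions$charge))
    f
  })
  names(fractions) <- panel$peptide
  structure(list(protein_abundance = ab, yield = yield, fractions = fractions),
            class = "ground_truth")
}

.transition_names <- function(product_ions) {
  ions <- parse_product_ions(product_ions)
  paste0(ions$ion_type, ifelse(is.na(ions$ordinal), "", ions$ordinal),
         strrep("+", ions$charge))
}

.transition_theoretical_mz <- function(peptide, product_ions, heavy,
                                       precursor) {
  ions <- parse_product_ions(product_ions)
  vapply(seq_len(nrow(ions)), function(j) {
    if (ions$ion_type[j] == "p") return(precursor)
    fragment_mz(peptide, ions$ion_type[j], ions$ordinal[j], ions$charge[j],
                heavy = heavy)
  }, numeric(1))
}

#' Simulate one PRM acquisition
#'
#' Generates co-eluting Gaussian light/heavy transition-group chromatograms
#' for every panel peptide. Per transition, the trace is
#' `A * f_i * exp(-(t - apex)^2 / (2 * rt_sigma^2))` plus truncated Gaussian
#' noise, where the summed area `A * rt_sigma * sqrt(2*pi)` equals
#' `response_factor` times the fmol on column (true abundance times
#' digestion yield for the light form; the spiked amount for the heavy
#' form). Light and heavy share one retention-time jitter per peptide.
#'
#' @param panel An `assay_panel`.
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param config A `sim_config`.
#' @param stage Stage label (must be a column of the truth abundances).
#' @param replicate Replicate index, used only to build the run id.
#' @param spike Named numeric vector of heavy spike amounts (fmol);
#'   defaults to the panel `spike_fmol` column. All spikes must be >= 0.
#' @param seed Integer seed.
#' @return A `prm_run` list: `run_id`, `stage`, `replicate`, `traces` (long
#'   data frame: peptide, isotope, transition, time_s, intensity),
#'   `transitions` (per-trace theoretical and reported m/z, including
#'   precursor m/z), `spiked`, `injected_ug`, and the hidden ground truth
#'   `truth_fmol_per_ug` (named by peptide; the light amount divided by
#'   yield recovers the protein-level truth).
#' @export
simulate_run <- function(panel, truth, config, stage, replicate = 1L,
                         spike = NULL, seed = 1L) {
  if (!stage %in% colnames(truth$protein_abundance))
    stop("unknown stage: ", stage)
  if (is.null(spike)) {
    spike <- panel$spike_fmol
    names(spike) <- panel$peptide
  }
  if (any(spike < 0)) stop("spike amounts must be non-negative")
  set.seed(seed)
  traces <- list(); meta <- list()
  for (i in seq_len(nrow(panel))) {
    pep <- panel$peptide[i]
    rt_s <- (if (is.na(panel$rt_min[i])) 20 else panel$rt_min[i]) * 60
    jitter <- stats::rnorm(1, 0, config$rt_jitter_sd)
    apex <- rt_s + jitter
    half <- max(8 * config$rt_sigma, 20)
    tgrid <- seq(rt_s - half, rt_s + half, by = config$sampling_interval)
    f <- truth$fractions[[pep]]
    trans <- names(f)
    abundance <- truth$protein_abundance[panel$protein_id[i], stage]
    light_fmol <- abundance * truth$yield[[pep]] * config$injected_ug
    heavy_fmol <- unname(spike[pep])
    if (is.na(heavy_fmol)) heavy_fmol <- 0
    gauss <- exp(-(tgrid - apex)^2 / (2 * config$rt_sigma^2))
    denom <- config$rt_sigma * sqrt(2 * pi)
    for (iso in c("light", "heavy")) {
      fmol <- if (iso == "light") light_fmol else heavy_fmol
      ppm_err <- stats::rnorm(1, 0, config$mz_error_ppm_sd)
      prec_theo <- if (iso == "light") panel$light_mz[i] else panel$heavy_mz[i]
      theo <- .transition_theoretical_mz(pep, panel$product_ions[i],
                                         iso == "heavy", prec_theo)
      for (j in seq_along(trans)) {
        amp <- config$response_factor * fmol * f[[j]] / denom
        y <- amp * gauss
        if (config$noise_sd > 0)
          y <- pmax(0, y + stats::rnorm(length(y), 0, config$noise_sd))
        traces[[length(traces) + 1L]] <- data.frame(
          peptide = pep, isotope = iso, transition = trans[j],
          time_s = tgrid, intensity = y, stringsAsFactors = FALSE)
        meta[[length(meta) + 1L]] <- data.frame(
          peptide = pep, isotope = iso, transition = trans[j],
          theoretical_mz = theo[j],
          observed_mz = theo[j] * (1 + ppm_err * 1e-6),
          precursor_theoretical_mz = prec_theo,
          precursor_observed_mz = prec_theo * (1 + ppm_err * 1e-6),
          scheduled_rt_min = panel$rt_min[i], stringsAsFactors = FALSE)
      }
    }
  }
  tf <- truth$protein_abundance[panel$protein_id, stage] * truth$yield[panel$peptide]
  names(tf) <- panel$peptide
  structure(list(
    run_id = sprintf("%s_rep%d", stage, as.integer(replicate)),
    stage = stage, replicate = as.integer(replicate),
    traces = do.call(rbind, traces), transitions = do.call(rbind, meta),
    spiked = spike, injected_ug = config$injected_ug,
    truth_fmol_per_ug = tf), class = "prm_run")
}

#' Simulate a full stage-by-replicate experiment
#'
#' @inheritParams simulate_run
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @return List of `prm_run` objects, one per stage x replicate.
#' @export
simulate_experiment <- function(panel, truth, config, seed = 1L) {
  runs <- list()
  counter <- 0L
  for (stage in config$stages) {
    for (rep in seq_len(config$replicates_per_stage)) {
      counter <- counter + 1L
      runs[[length(runs) + 1L]] <- simulate_run(
        panel, truth, config, stage, rep,
        seed = (seed * 1009L + counter * 7919L) %% 2147483647L)
    }
  }
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  runs
}

#' Simulate a heavy-peptide spike dilution series
#'
#' One run per spike level, each with identical endogenous amounts and the
#' heavy amount set to the level. The default levels are the series used
#' for assay calibration: 0, 1, 5, 10, 100 and 200 fmol.
#'
#' @param panel An `assay_panel`.
#' @param endogenous_fmol Named vector of endogenous fmol per peptide (one
#'   number recycles to all peptides).
#' @param config A `sim_config`.
#' @param levels Spike levels in fmol (non-negative).
#' @param seed Integer seed.
#' @return Named list of `prm_run` objects, one per level.
#' @export
simulate_spike_series <- function(panel, endogenous_fmol, config,
                                  levels = c(0, 1, 5, 10, 100, 200),
                                  seed = 1L) {
  if (any(levels < 0)) stop("spike levels must be non-negative")
  if (is.null(names(endogenous_fmol)))
    endogenous_fmol <- stats::setNames(rep(endogenous_fmol,
                                           length.out = nrow(panel)),
                                       panel$peptide)
  stages <- "series"
  ab <- matrix(endogenous_fmol[panel$peptide] /
                 pmax(1e-12, config$injected_ug),
               ncol = 1, dimnames = list(panel$peptide, stages))
  # one pseudo-protein per peptide so each peptide keeps its own amount
  panel2 <- panel
  panel2$protein_id <- panel$peptide
  rownames(ab) <- panel2$protein_id
  set.seed(seed)
  fractions <- lapply(seq_len(nrow(panel)), function(i) {
    ions <- parse_product_ions(panel$product_ions[i])
    g <- stats::rgamma(nrow(ions), shape = 2)
    f <- g / sum(g)
    names(f) <- .transition_names(panel$product_ions[i])
    f
  })
  names(fractions) <- panel$peptide
  truth <- structure(list(protein_abundance = ab,
                          yield = stats::setNames(rep(1, nrow(panel)),
                                                  panel$peptide),
                          fractions = fractions), class = "ground_truth")
  runs <- lapply(seq_along(levels), function(j) {
    spike <- stats::setNames(rep(levels[j], nrow(panel)), panel$peptide)
    r <- simulate_run(panel2, truth, config, stages, replicate = j,
                      spike = spike,
                      seed = (seed * 1013L + j * 104729L) %% 2147483647L)
    r$run_id <- sprintf("spike_%gfmol", levels[j])
    r$spike_level <- levels[j]
    r
  })
  names(runs) <- sprintf("spike_%g", levels)
  runs
}

#' Ground truth for a simulated qPCR experiment
#'
#' @param genes Target gene labels.
#' @param stages Stage labels.
#' @param reference_genes Labels of the three reference genes; their true
#'   expression is constant across stages.
#' @param seed Integer seed.
#' @param efficiency_range Range of true amplification efficiencies (fold
#'   per cycle); default 1.85-2.0, typical of validated primer pairs.
#' @param ct_noise_sd Technical Ct noise (cycles).
#' @return A `qpcr_truth` list: `expression` (matrix genes x stages),
#'   `efficiency`, `ct0`, `reference_genes`, `ct_noise_sd`.
#' @export
make_qpcr_truth <- function(genes, stages = c("MG", "BR", "OR", "R"),
                            reference_genes = c("ACT", "EF1", "GAPDH"),
                            seed = 1L, efficiency_range = c(1.85, 2),
                            ct_noise_sd = 0.15) {
  set.seed(seed)
  all_genes <- c(genes, reference_genes)
  k <- length(stages)
  expr <- t(vapply(all_genes, function(g) {
    if (g %in% reference_genes) return(rep(1, k))
    base <- exp(stats::runif(1, log(0.05), log(1)))
    base * exp(stats::rnorm(k, 0, 0.8))
  }, numeric(k)))
  colnames(expr) <- stages
  structure(list(
    expression = expr,
    efficiency = stats::setNames(
      stats::runif(length(all_genes), efficiency_range[1], efficiency_range[2]),
      all_genes),
    ct0 = stats::setNames(stats::runif(length(all_genes), 22, 30), all_genes),
    reference_genes = reference_genes, ct_noise_sd = ct_noise_sd),
    class = "qpcr_truth")
}

#' Simulate qPCR Ct tables
#'
#' Generates per-sample Ct values, `Ct = Ct0 - log_E(quantity) + noise`, and
#' a pooled-cDNA standard dilution series per gene for efficiency
#' estimation, mirroring a plate that carries a standard curve in every run.
#'
#' @param qtruth A `qpcr_truth` from [make_qpcr_truth()].
#' @param replicates Biological replicates per stage.
#' @param seed Integer seed.
#' @param dilutions Standard-curve relative input amounts (default five
#'   10-fold dilutions of the pooled cDNA).
#' @param biological_sd Log-scale sd of the between-replicate biological
#'   variation in true quantity (default 0.1; set 0 for noise-free plates).
#' @return Data frame with columns `run`, `gene`, `sample`, `stage`, `ct`,
#'   `is_standard`, `dilution`.
#' @export
simulate_qpcr <- function(qtruth, replicates = 6L, seed = 1L,
                          dilutions = 10^(0:-4), biological_sd = 0.1) {
  if (any(qtruth$efficiency <= 1)) stop("amplification efficiency must be > 1")
  set.seed(seed)
  stages <- colnames(qtruth$expression)
  genes <- rownames(qtruth$expression)
  out <- list()
  for (g in genes) {
    E <- qtruth$efficiency[[g]]
    ct0 <- qtruth$ct0[[g]]
    for (st in stages) {
      q_true <- qtruth$expression[g, st]
      for (r in seq_len(replicates)) {
        q <- q_true * exp(stats::rnorm(1, 0, biological_sd))
        out[[length(out) + 1L]] <- data.frame(
          run = 1L, gene = g, sample = sprintf("%s_%d", st, r), stage = st,
          ct = ct0 - log(q, base = E) +
            stats::rnorm(1, 0, qtruth$ct_noise_sd),
          is_standard = FALSE, dilution = NA_real_, stringsAsFactors = FALSE)
      }
    }
    pooled <- mean(qtruth$expression[g, ])
    for (d in dilutions) {
      out[[length(out) + 1L]] <- data.frame(
        run = 1L, gene = g, sample = sprintf("std_%g", d), stage = NA_character_,
        ct = ct0 - log(pooled * d, base = E) +
          stats::rnorm(1, 0, qtruth$ct_noise_sd),
        is_standard = TRUE, dilution = d, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a pair of mean/SE stage profiles with known correlation
#'
#' Builds two latent stage profiles whose empirical Pearson correlation is
#' exactly `true_r`, then reports noisy observed means (one Gaussian
#' measurement error of sd `se_scale` per stage) together with standard
#' errors equal to `se_scale`. This is the test harness for the Monte-Carlo
#' correlation procedure.
#'
#' @param true_r Target correlation of the latent profiles, in \[-1, 1\].
#' @param n_stages Number of stages (default 4). With 2 stages any sample
#'   correlation is degenerate (+/-1); a warning is issued.
#' @param se_scale Standard error of each stage mean (also the sd of the
#'   measurement noise added to the latent means).
#' @param seed Integer seed.
#' @param amplitude Spread of the latent profiles around `center`.
#' @param center Baseline level of both profiles.
#' @param n_per_stage Replicate count reported per stage (default 6).
#' @return List with data frames `a` and `b` (columns `stage`, `mean`,
#'   `se`, `n`) and the latent `true_r`.
#' @export
simulate_profiles <- function(true_r, n_stages = 4L, se_scale = 0.1,
                              seed = 1L, amplitude = 1, center = 3,
                              n_per_stage = 6L) {
  if (abs(true_r) > 1) stop("true_r must be in [-1, 1]")
  if (n_stages < 3L)
    warning("correlation of ", n_stages,
            " points is degenerate (always +/-1)")
  set.seed(seed)
  n <- n_stages
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  x0 <- as.numeric(scale(x))
  e <- e - mean(e)
  e <- e - sum(e * x0) / sum(x0^2) * x0
  e0 <- if (sqrt(sum(e^2)) < 1e-12) rep(0, n) else as.numeric(e / stats::sd(e))
  y0 <- true_r * x0 + sqrt(max(0, 1 - true_r^2)) * e0
  mk <- function(z) {
    m <- center + amplitude * z +
      if (se_scale > 0) stats::rnorm(n, 0, se_scale) else 0
    data.frame(stage = paste0("S", seq_len(n)), mean = m,
               se = rep(se_scale, n), n = n_per_stage,
               stringsAsFactors = FALSE)
  }
  list(a = mk(x0), b = mk(y0), true_r = true_r)
}

#' Write / read simulated run traces
#'
#' Serializes a `prm_run` as a long trace CSV plus a JSON sidecar holding
#' the transition metadata, spike amounts and hidden ground truth.
#'
#' @param run A `prm_run`.
#' @param dir Output directory (created if needed).
#' @return For `write_run`, the paths written (invisibly); for `read_run`,
#'   the reconstructed `prm_run`.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trace_path <- file.path(dir, paste0(run$run_id, "_traces.csv"))
  side_path <- file.path(dir, paste0(run$run_id, "_meta.json"))
  df <- run$traces
  df$run_id <- run$run_id
  utils::write.csv(df, trace_path, row.names = FALSE)
  jsonlite::write_json(
    list(run_id = run$run_id, stage = run$stage, replicate = run$replicate,
         transitions = run$transitions, spiked = as.list(run$spiked),
         injected_ug = run$injected_ug,
         truth_fmol_per_ug = as.list(run$truth_fmol_per_ug)),
    side_path, auto_unbox = TRUE, digits = NA)
  invisible(c(trace_path, side_path))
}

#' @rdname write_run
#' @param run_id Run identifier used when the files were written.
#' @export
read_run <- function(dir, run_id) {
  traces <- utils::read.csv(file.path(dir, paste0(run_id, "_traces.csv")),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(run_id, "_meta.json")),
                              simplifyVector = TRUE)
  traces$run_id <- NULL
  structure(list(run_id = meta$run_id, stage = meta$stage,
                 replicate = meta$replicate, traces = traces,
                 transitions = meta$transitions,
                 spiked = unlist(meta$spiked),
                 injected_ug = meta$injected_ug,
                 truth_fmol_per_ug = unlist(meta$truth_fmol_per_ug)),
            class = "prm_run")
}
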