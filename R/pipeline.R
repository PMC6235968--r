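# End-to-end orchestration: simulate -> quantify -> roll up -> qPCR ->
# correlate, with a deterministic manifest. Also the bundled demo fixtures.

#' The bundled ethylene-signaling assay panel
#'
#' Loads the packaged transcription of the published PRM panel: 21
#' endogenous peptides and their heavy twins across 11 target proteins
#' (7 ethylene receptors, 3 CTR-like kinases, EIN2), with precursor m/z,
#' charge states, quantifier product ions, scheduled retention times and
#' spike amounts.
#'
#' @return An `assay_panel` data frame.
#' @export
demo_panel <- function() {
  read_panel(system.file("extdata", "table1_panel.csv", package = "prmquant"))
}

#' Synthetic target proteins embedding the panel peptides
#'
#' Builds one synthetic protein sequence per panel protein by
#' concatenating its panel peptides between tryptic junctions, so that a
#' zero-missed-cleavage digest releases exactly those peptides. These are
#' stand-ins for the real receptor sequences (which are not shipped), good
#' enough to exercise digestion, uniqueness screening and panel
#' construction end to end.
#'
#' @param panel An `assay_panel` (default: the bundled panel).
#' @return Data frame with `accession`, `sequence`, `description`.
#' @export
demo_targets <- function(panel = demo_panel()) {
  proteins <- unique(panel$protein_id)
  seqs <- vapply(proteins, function(p) {
    peps <- panel$peptide[panel$protein_id == p]
    paste0("MK", paste(peps, collapse = ""), "AAGGAAGK")
  }, character(1))
  data.frame(accession = proteins, sequence = unname(seqs),
             description = paste("synthetic stand-in for", proteins),
             stringsAsFactors = FALSE)
}

#' Synthetic background proteome
#'
#' The targets plus seeded random decoy entries, used for the uniqueness
#' screen in tests and demos.
#'
#' @param targets Data frame of target proteins.
#' @param n_decoys Number of random background entries.
#' @param seed Integer seed.
#' @return Data frame with `accession`, `sequence`, `description`.
#' @export
demo_proteome <- function(targets = demo_targets(), n_decoys = 20L,
                          seed = 42L) {
  set.seed(seed)
  res <- names(AA_MONO_MASS)
  decoys <- data.frame(
    accession = sprintf("BG%03d", seq_len(n_decoys)),
    sequence = vapply(seq_len(n_decoys), function(i)
      paste(sample(res, sample(120:400, 1), replace = TRUE), collapse = ""),
      character(1)),
    description = "synthetic background protein",
    stringsAsFactors = FALSE)
  rbind(targets, decoys)
}

#' Run the full workflow on synthetic data
#'
#' Orchestrates the whole pipeline: loads (or builds) the assay panel,
#' simulates a PRM acquisition per stage and replicate, quantifies every
#' run with q-value gating, rolls peptide quantities up to protein stage
#' profiles, simulates and analyzes the matching qPCR experiment, and runs
#' the Monte-Carlo protein-mRNA correlation for every protein. All outputs
#' are CSV files under `out_dir`, listed with checksums in
#' `manifest.json`; completed stages stay on disk if a later stage fails.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param config A `sim_config`.
#' @param panel An `assay_panel` (default: the bundled panel).
#' @param strict Remove flagged (0.01 <= q <= 0.05) identifications.
#' @param n_datasets Monte-Carlo datasets per correlation (default 1500).
#' @param alpha Significance level for Tukey letters.
#' @param verbose Log progress to stderr as well as to the log file.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(),
                         panel = demo_panel(), strict = FALSE,
                         n_datasets = 1500L, alpha = 0.05,
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  cat("", file = log_path)
  logf("prmquant %s | seed=%d | q gates 0.01/0.05 | ppm gate 5 | alpha=%g",
       as.character(utils::packageVersion("prmquant")), seed, alpha)

  paths <- character()
  add <- function(name, path) { paths[[name]] <<- path; path }

  write_panel(panel, add("panel", file.path(out_dir, "panel.csv")))
  logf("panel: %d peptides, %d proteins", nrow(panel),
       length(unique(panel$protein_id)))

  truth <- make_ground_truth(panel, config, seed = seed)
  runs <- simulate_experiment(panel, truth, config, seed = seed)
  logf("simulated %d runs (%d stages x %d replicates)", length(runs),
       length(config$stages), config$replicates_per_stage)

  quant <- do.call(rbind, lapply(runs, function(r)
    quantify_run(r, panel, strict = strict, seed = seed)))
  rownames(quant) <- NULL
  utils::write.csv(quant, add("quant", file.path(out_dir, "quant.csv")),
                   row.names = FALSE)
  logf("quantified %d transition groups: %d kept, %d flagged, %d removed",
       nrow(quant), sum(quant$decision == "kept"),
       sum(quant$decision == "flagged"), sum(quant$decision == "removed"))

  profiles <- do.call(rbind, lapply(unique(panel$protein_id), function(p) {
    qp <- quant[quant$protein == p, , drop = FALSE]
    if (all(is.na(qp$fmol_per_ug))) {
      logf("protein %s could not be quantified (no usable signal)", p)
      return(NULL)
    }
    fit_protein_model(qp, protein = p, alpha = alpha)
  }))
  utils::write.csv(profiles,
                   add("profiles", file.path(out_dir, "profiles.csv")),
                   row.names = FALSE)

  genes <- unique(panel$protein_id)
  qtruth <- make_qpcr_truth(genes, stages = config$stages,
                            seed = seed + 1L)
  cts <- simulate_qpcr(qtruth, replicates = config$replicates_per_stage,
                       seed = seed + 2L)
  utils::write.csv(cts, add("cts", file.path(out_dir, "cts.csv")),
                   row.names = FALSE)
  expr <- qpcr_expression(cts, reference_genes = qtruth$reference_genes)
  eprof <- expression_profile(expr$expression, alpha = alpha)
  utils::write.csv(eprof, add("expression",
                              file.path(out_dir, "expression.csv")),
                   row.names = FALSE)

  corr <- do.call(rbind, lapply(unique(profiles$protein), function(p) {
    pp <- profiles[profiles$protein == p, , drop = FALSE]
    ep <- eprof[eprof$gene == p, , drop = FALSE]
    ep <- ep[match(pp$stage, ep$stage), , drop = FALSE]
    if (nrow(pp) < 3L || any(is.na(ep$mean))) return(NULL)
    a <- data.frame(stage = pp$stage, mean = pp$estimate, se = pp$se)
    b <- data.frame(stage = ep$stage, mean = ep$mean, se = ep$se)
    res <- monte_carlo_correlation(a, b, n_datasets = n_datasets,
                                   seed = seed + 3L)
    data.frame(pair = p, r_point = res$r_point, ci_low = res$ci_low,
               ci_high = res$ci_high, significant = res$significant,
               n_datasets = res$n_datasets, seed = res$seed,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(corr, add("correlation",
                             file.path(out_dir, "correlation.csv")),
                   row.names = FALSE)
  logf("correlation: %d/%d pairs significant", sum(corr$significant),
       nrow(corr))

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("prmquant")),
    seed = seed, strict = strict, alpha = alpha,
    thresholds = list(q_keep = 0.01, q_flag = 0.05, ppm_gate = 5),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("wrote %d artifacts + manifest", length(paths))
  invisible(manifest)
}
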