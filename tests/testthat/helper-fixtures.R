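# Shared fixtures: everything is built in code at test time.

fixture_panel <- function() demo_panel()

# three-peptide mini panel for fast simulation-heavy tests
mini_panel <- function() {
  p <- demo_panel()[c(1, 3, 9), ]
  rownames(p) <- NULL
  p
}

# toy proteome: two ETR4-like entries plus fillers, with known shared and
# unique peptides
toy_proteome <- function() {
  data.frame(
    accession = c("T1", "T2", "T3"),
    sequence = c(
      "MKDSSFNSAYNLPIPRVLPESVSRK",      # holds DSSFNSAYNLPIPR + VLPESVSR
      "MKAAAGGKVLPESVSRDDDK",           # shares VLPESVSR with T1
      "MKISPNSPVARGGAAAK"               # holds ISPNSPVAR uniquely
                                        # (tail GGAAAK < 7 aa, never kept)
    ),
    description = "toy",
    stringsAsFactors = FALSE)
}

noise_free_config <- function(...) {
  sim_config(noise_sd = 0, rt_jitter_sd = 0, mz_error_ppm_sd = 0, ...)
}

# peptide quantity table with known stage means, one or more peptides
make_quantities <- function(stage_means = c(MG = 10, BR = 20, OR = 15, R = 5),
                            peptide_offsets = 0, sd = 1, n_rep = 6,
                            seed = 1) {
  set.seed(seed)
  stages <- rep(names(stage_means), each = n_rep)
  samples <- paste0(stages, "_", seq_len(n_rep))
  do.call(rbind, lapply(seq_along(peptide_offsets), function(i)
    data.frame(stage = stages, peptide = paste0("P", i),
               sample_id = samples,
               fmol_per_ug = stats::rnorm(length(stages),
                                          stage_means[stages] +
                                            peptide_offsets[i], sd),
               stringsAsFactors = FALSE)))
}
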