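# qPCR analysis: standard-curve amplification efficiency, efficiency-
# corrected relative expression normalized to three reference genes, and
# stage ANOVA with Tukey letters.

#' Fit a qPCR standard curve
#'
#' Least squares of Ct on log10 of the relative input amount over a pooled
#' cDNA dilution series. The amplification efficiency is
#' `E = 10^(-1 / slope)` (fold amplification per cycle); a 10-fold series
#' with 3.3219-cycle spacing gives E = 2.
#'
#' @param dilutions Relative input amounts (positive; e.g. `10^(0:-4)`).
#' @param cts Mean Ct per dilution.
#' @return A `standard_curve` list: `slope` (cycles per log10 input),
#'   `intercept`, `efficiency`, `r_squared`, `n`.
#' @export
fit_standard_curve <- function(dilutions, cts) {
  if (length(dilutions) < 3L) stop("need at least 3 dilution points")
  if (any(dilutions <= 0)) stop("dilutions must be positive")
  fit <- stats::lm(cts ~ log10(dilutions))
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("invalid standard curve: non-negative slope (Ct must decrease ",
         "with input)")
  E <- 10^(-1 / slope)
  if (E > 2.2 || E <= 1)
    warning("estimated efficiency ", signif(E, 4),
            " outside the plausibility band (1, 2.2]")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  r2 <- if (ss_tot <= 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 efficiency = E, r_squared = r2, n = length(dilutions)),
            class = "standard_curve")
}

#' Efficiency-corrected relative quantity
#'
#' The modified-Ct relative quantity of one well:
#' `Q = E^(ct_min - ct)`, with `ct_min` the minimum observed Ct of that
#' gene across all samples (the per-gene calibrator). The sample with the
#' lowest Ct has Q = 1; one extra cycle at E = 2 halves Q.
#'
#' @param ct Observed Ct value(s).
#' @param efficiency Amplification efficiency in (1, 2.2].
#' @param ct_min Calibrator Ct (per-gene minimum).
#' @return Relative quantity (>= 0).
#' @export
relative_quantity <- function(ct, efficiency, ct_min) {
  if (any(efficiency <= 1) || any(efficiency > 2.2))
    stop("efficiency must be in (1, 2.2]")
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  efficiency^(ct_min - ct)
}

#' Normalized relative expression for one sample
#'
#' Divides the target's relative quantity by the average of the three
#' reference-gene quantities.
#'
#' @param ct_target,e_target Target Ct and efficiency.
#' @param ct_refs,e_refs Reference-gene Cts and efficiencies (same length).
#' @param ct_min_target,ct_min_refs Per-gene calibrator (minimum) Cts.
#' @param ref_mean `"arithmetic"` (default) or `"geometric"` averaging of
#'   the reference quantities.
#' @return Normalized relative expression.
#' @export
relative_expression <- function(ct_target, e_target, ct_refs, e_refs,
                                ct_min_target = ct_target,
                                ct_min_refs = ct_refs,
                                ref_mean = c("arithmetic", "geometric")) {
  ref_mean <- match.arg(ref_mean)
  q_t <- relative_quantity(ct_target, e_target, ct_min_target)
  q_r <- mapply(relative_quantity, ct_refs, e_refs, ct_min_refs)
  denom <- if (ref_mean == "arithmetic") mean(q_r)
  else exp(mean(log(q_r)))
  q_t / denom
}

#' Gene-by-stage normalized expression from a Ct table
#'
#' Full qPCR pipeline over a long Ct table: fits a standard curve per gene
#' from the `is_standard` rows, converts each sample Ct to an
#' efficiency-corrected relative quantity against the per-gene minimum Ct,
#' and normalizes every target by the average reference-gene quantity of
#' the same sample. Samples missing any reference measurement are dropped
#' with a warning.
#'
#' @param ct_table Data frame with columns `gene`, `sample`, `stage`, `ct`,
#'   `is_standard`, `dilution`.
#' @param reference_genes Three reference-gene labels.
#' @param ref_mean Reference averaging mode, see [relative_expression()].
#' @return List with `expression` (data frame `gene`, `sample`, `stage`,
#'   `expression`) and `curves` (named list of `standard_curve`).
#' @export
qpcr_expression <- function(ct_table,
                            reference_genes = c("ACT", "EF1", "GAPDH"),
                            ref_mean = c("arithmetic", "geometric")) {
  ref_mean <- match.arg(ref_mean)
  std <- ct_table[ct_table$is_standard, , drop = FALSE]
  samp <- ct_table[!ct_table$is_standard, , drop = FALSE]
  genes <- unique(ct_table$gene)
  missing_refs <- setdiff(reference_genes, genes)
  if (length(missing_refs))
    stop("reference gene(s) absent from Ct table: ",
         paste(missing_refs, collapse = ", "))
  curves <- lapply(stats::setNames(genes, genes), function(g) {
    s <- std[std$gene == g, , drop = FALSE]
    fit_standard_curve(s$dilution, s$ct)
  })
  eff <- vapply(curves, `[[`, numeric(1), "efficiency")
  ct_min <- vapply(stats::setNames(genes, genes), function(g)
    min(samp$ct[samp$gene == g]), numeric(1))
  samp$q <- relative_quantity(samp$ct, eff[samp$gene], ct_min[samp$gene])
  targets <- setdiff(genes, reference_genes)
  out <- list()
  for (sid in unique(samp$sample)) {
    block <- samp[samp$sample == sid, , drop = FALSE]
    q_refs <- block$q[match(reference_genes, block$gene)]
    if (any(is.na(q_refs))) {
      warning("sample ", sid, " dropped: missing reference gene Ct")
      next
    }
    denom <- if (ref_mean == "arithmetic") mean(q_refs)
    else exp(mean(log(q_refs)))
    tb <- block[block$gene %in% targets, , drop = FALSE]
    if (!nrow(tb)) next
    out[[length(out) + 1L]] <- data.frame(
      gene = tb$gene, sample = sid, stage = tb$stage,
      expression = tb$q / denom, stringsAsFactors = FALSE)
  }
  list(expression = do.call(rbind, out), curves = curves)
}

#' One-way stage ANOVA with Tukey letters
#'
#' @param values Numeric response values.
#' @param stages Stage labels aligned with `values`.
#' @param alpha Significance level.
#' @return List with `p_value` (ANOVA F test), `letters` (named by stage,
#'   in order of first appearance) and the per-stage `means`.
#' @export
stage_anova <- function(values, stages, alpha = 0.05) {
  lev <- unique(stages)
  if (length(lev) < 2L) stop("need at least 2 stages")
  f <- factor(stages, levels = lev)
  if (min(table(f)) < 2L) stop("need at least 2 replicates per stage")
  fit <- stats::lm(values ~ 0 + f)
  an <- stats::anova(stats::lm(values ~ f))
  est <- stats::setNames(stats::coef(fit), lev)
  lt <- tukey_letters(est, stats::vcov(fit), stats::df.residual(fit),
                      alpha = alpha)
  list(p_value = an[["Pr(>F)"]][1L],
       letters = stats::setNames(lt, lev), means = est)
}

#' Stage-level expression profile with Tukey letters
#'
#' @param expression Data frame from [qpcr_expression()] (`gene`, `sample`,
#'   `stage`, `expression`).
#' @param alpha Significance level.
#' @return Data frame `gene`, `stage`, `mean`, `se`, `n`, `letter`.
#' @export
expression_profile <- function(expression, alpha = 0.05) {
  out <- list()
  for (g in unique(expression$gene)) {
    e <- expression[expression$gene == g, , drop = FALSE]
    an <- stage_anova(e$expression, e$stage, alpha = alpha)
    for (st in names(an$letters)) {
      v <- e$expression[e$stage == st]
      out[[length(out) + 1L]] <- data.frame(
        gene = g, stage = st, mean = mean(v),
        se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v), letter = unname(an$letters[st]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
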