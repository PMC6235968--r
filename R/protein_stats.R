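# Peptide-to-protein roll-up: mixed model over stages with peptide as a
# random factor and sample as the repeated structure, one-way ANOVA for
# single-peptide proteins, Tukey HSD compact letter display, and plain
# mean/SE stage summaries.

#' Compact letter display from pairwise Tukey tests
#'
#' All-pairs comparisons with the studentized-range distribution: for
#' groups i, j the statistic is `q = |m_i - m_j| / (SE_diff / sqrt(2))`
#' compared against `ptukey` with `k` means and `df` degrees of freedom.
#' Letters are assigned by insert-and-absorb so that two groups share a
#' letter if and only if they are not significantly different.
#'
#' @param estimates Named (or ordered) group estimates.
#' @param covariance Covariance matrix of the estimates (a single number is
#'   recycled as a common variance with zero covariances).
#' @param df Degrees of freedom for the studentized range.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letter strings, one per group, in input
#'   order. With zero standard errors, unequal means get distinct letters.
#' @export
tukey_letters <- function(estimates, covariance, df, alpha = 0.05) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 groups")
  if (length(covariance) == 1L) covariance <- diag(rep(covariance, k))
  nonsig <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    diff <- abs(estimates[i] - estimates[j])
    v <- covariance[i, i] + covariance[j, j] - 2 * covariance[i, j]
    if (v <= 0) {
      sig <- diff > 1e-10  # zero variance: any real difference is significant
    } else {
      q <- diff / sqrt(v / 2)
      sig <- stats::ptukey(q, k, max(1, df), lower.tail = FALSE) < alpha
    }
    nonsig[i, j] <- nonsig[j, i] <- !sig
  }
  # insert-and-absorb
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (nonsig[i, j]) next
    touched <- FALSE
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        touched <- TRUE
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    if (touched) {
      new_sets <- new_sets[lengths(new_sets) > 0L]
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
        if (a != b && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) ||
             (length(new_sets[[a]]) == length(new_sets[[b]]) && a > b)))
          keep[a] <- FALSE
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    for (g in sets[[s]])
      letters_out[g] <- paste0(letters_out[g], letters[s])
  }
  letters_out
}

#' Per-stage mean and standard error of a peptide-quantity table
#'
#' Biological-replicate summary: peptide values are first averaged within
#' each (stage, sample) so that every fruit contributes once, then the
#' stage mean and `SE = sd / sqrt(n)` are computed over samples. A single
#' replicate yields a missing SE.
#'
#' @param quantities Data frame with columns `stage`, `sample_id`,
#'   `fmol_per_ug` (and optionally `peptide`).
#' @return Data frame `stage`, `mean`, `se`, `n` in the order of first
#'   appearance of the stages.
#' @export
summarize_profile <- function(quantities) {
  q <- quantities[!is.na(quantities$fmol_per_ug), , drop = FALSE]
  per_sample <- stats::aggregate(fmol_per_ug ~ stage + sample_id, data = q,
                                 FUN = mean)
  stages <- unique(quantities$stage)
  out <- do.call(rbind, lapply(stages, function(st) {
    v <- per_sample$fmol_per_ug[per_sample$stage == st]
    data.frame(stage = st, mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.anova_profile <- function(values, stages_f) {
  fit <- stats::lm(values ~ 0 + stages_f)
  est <- stats::coef(fit)
  names(est) <- levels(stages_f)
  list(estimates = est, covariance = stats::vcov(fit),
       df = stats::df.residual(fit))
}

#' Roll peptide quantities up to a protein stage profile
#'
#' Proteins represented by several peptides are analyzed with a linear
#' mixed model: ripening stage as a fixed categorical factor, peptide as a
#' random factor, and a random sample (fruit) intercept inducing a
#' compound-symmetric repeated structure among peptides measured on the
#' same fruit. Fitting is by REML; stage estimates are the model-based
#' marginal means. Proteins with a single peptide are analyzed by classical
#' one-way ANOVA, to which the mixed model reduces. Non-convergence falls
#' back to an ANOVA on peptide-averaged samples.
#'
#' Degrees of freedom for the mixed-model Tukey comparisons use a
#' containment-style approximation (observations minus estimated fixed,
#' peptide and sample levels); exact software-specific denominator df may
#' differ.
#'
#' @param quantities Data frame with columns `stage`, `peptide`,
#'   `sample_id`, `fmol_per_ug`. Missing values (quantification failures)
#'   are dropped per (sample, peptide) pair.
#' @param protein Optional protein label stored in the result.
#' @param alpha Significance level for the Tukey letters.
#' @return A `protein_profile` data frame: `protein`, `stage`, `estimate`,
#'   `se`, `letter`, `model_used`, plus the per-stage replicate `n`.
#' @export
fit_protein_model <- function(quantities, protein = NA_character_,
                              alpha = 0.05) {
  q <- quantities[!is.na(quantities$fmol_per_ug), , drop = FALSE]
  stages <- unique(quantities$stage)
  if (length(stages) < 2L) stop("need at least 2 stages")
  q$stage_f <- factor(q$stage, levels = stages)
  n_pep <- length(unique(q$peptide))
  model_used <- NULL
  if (n_pep <= 1L) {
    res <- .anova_profile(q$fmol_per_ug, q$stage_f)
    model_used <- "anova"
  } else {
    res <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(fmol_per_ug ~ 0 + stage_f + (1 | peptide) + (1 | sample_id),
                   data = q, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
        stop("optimizer did not converge")  # caught below -> ANOVA fallback
      est <- lme4::fixef(fit)
      names(est) <- levels(q$stage_f)
      n_samp <- length(unique(q$sample_id))
      df <- max(2, nrow(q) - length(est) - (n_pep - 1) - (n_samp - 1))
      model_used <- "mixed"
      list(estimates = est, covariance = as.matrix(stats::vcov(fit)), df = df)
    }, error = function(e) {
      avg <- stats::aggregate(fmol_per_ug ~ stage_f + sample_id, data = q,
                              FUN = mean)
      model_used <<- "anova-fallback"
      .anova_profile(avg$fmol_per_ug, avg$stage_f)
    })
  }
  letter <- tukey_letters(res$estimates, res$covariance, res$df, alpha = alpha)
  summ <- summarize_profile(q)
  out <- data.frame(
    protein = protein, stage = names(res$estimates),
    estimate = unname(res$estimates),
    se = sqrt(pmax(0, diag(res$covariance))),
    letter = letter, model_used = model_used,
    n = summ$n[match(names(res$estimates), summ$stage)],
    stringsAsFactors = FALSE)
  class(out) <- c("protein_profile", "data.frame")
  out
}
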