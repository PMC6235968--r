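# Assay design: in-silico tryptic digestion, proteotypic peptide filtering,
# uniqueness screening against a proteome, light/heavy mass arithmetic and
# construction of the PRM assay panel.

#' Read a protein FASTA file
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a data frame of
#' protein entries. The accession is the first whitespace-delimited token of
#' the header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">"))
    stop("not a FASTA file: ", path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  acc <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                 character(1))
  if (length(seqs) != length(acc)) stop("FASTA record without sequence")
  data.frame(accession = acc, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write protein entries to FASTA
#'
#' @param proteome Data frame with `accession`, `sequence` (and optionally
#'   `description`) columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  desc <- proteome$description %||% rep("", nrow(proteome))
  hdr <- ifelse(nzchar(desc), paste(proteome$accession, desc),
                proteome$accession)
  body <- vapply(proteome$sequence, function(s)
    paste(strsplit(gsub("(.{60})", "\\1\n", s), "\n")[[1L]], collapse = "\n"),
    character(1))
  writeLines(paste0(">", hdr, "\n", body), path)
  invisible(path)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  bad <- setdiff(strsplit(sequence, "")[[1L]], names(AA_MONO_MASS))
  if (length(bad))
    stop("non-canonical residue letter(s): ", paste(unique(bad), collapse = ", "))
  invisible(sequence)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal of every lysine or arginine except
#' when the following residue is proline (the classical trypsin rule), and
#' enumerates peptides with up to `missed_cleavages` internal missed
#' cleavage sites.
#'
#' @param entry A protein entry: either a single sequence string or a
#'   list/one-row data frame with `accession` and `sequence` fields.
#' @param missed_cleavages Maximum number of missed cleavage sites per
#'   peptide (default 0, as used for target selection).
#' @return A data frame of peptide candidates with columns `sequence`,
#'   `parent_accession`, `start`, `end` (1-based inclusive),
#'   `missed_cleavages` and `monoisotopic_mass`. Zero-missed-cleavage
#'   peptides tile the input sequence exactly.
#' @examples
#' digest_protein("MKDSSFNSAYNLPIPRVLPESVSRK")$sequence
#' @export
digest_protein <- function(entry, missed_cleavages = 0L) {
  if (is.list(entry)) {
    accession <- entry$accession %||% "protein"
    sequence <- entry$sequence
  } else {
    accession <- "protein"
    sequence <- entry
  }
  .check_sequence(sequence)
  if (missed_cleavages < 0L) stop("missed_cleavages must be >= 0")
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  # cleavage after position i when residue i is K/R and i+1 is not P
  cut_after <- which(res %in% c("K", "R") & c(res[-1L], "") != "P" &
                       seq_len(n) < n)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  out <- list()
  for (mc in 0:min(missed_cleavages, k - 1L)) {
    i <- seq_len(k - mc)
    s <- starts[i]
    e <- ends[i + mc]
    out[[mc + 1L]] <- data.frame(
      sequence = substring(sequence, s, e),
      parent_accession = accession,
      start = s, end = e, missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  out$monoisotopic_mass <- vapply(out$sequence, peptide_mass, numeric(1))
  rownames(out) <- NULL
  out
}

#' Check peptide uniqueness against a proteome
#'
#' Scans every proteome entry for the peptide as an exact substring. A
#' peptide is proteotypic when it occurs in exactly one entry. Absent
#' peptides (0 matches) are reported as non-unique but are distinguishable
#' from shared peptides by the empty `matches` vector.
#'
#' @param peptide Peptide sequence.
#' @param proteome Data frame with `accession` and `sequence` columns.
#' @param collapse_il Treat isoleucine and leucine as indistinguishable
#'   (they are isobaric); off by default.
#' @return List with `unique` (logical) and `matches` (accessions containing
#'   the peptide).
#' @export
check_uniqueness <- function(peptide, proteome, collapse_il = FALSE) {
  if (!is.character(peptide) || nchar(peptide) < 1L)
    stop("peptide must have at least 1 residue")
  seqs <- proteome$sequence
  pat <- peptide
  if (collapse_il) {
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
    pat <- gsub("I", "L", pat, fixed = TRUE)
  }
  hit <- grepl(pat, seqs, fixed = TRUE)
  list(unique = sum(hit) == 1L, matches = proteome$accession[hit])
}

#' Filter digestion candidates into a proteotypic target list
#'
#' Applies the target-selection criteria: peptide length between `min_length`
#' and `max_length` residues, no missed cleavages, absence of methionine,
#' cysteine and histidine, and uniqueness within the proteome. Every
#' rejected peptide is annotated with all the rules it violates.
#'
#' @param candidates Data frame from [digest_protein()].
#' @param proteome Data frame with `accession` and `sequence` columns used
#'   for the uniqueness screen.
#' @param min_length,max_length Length bounds in residues (default 7 and 25).
#' @param excluded_residues Residues whose presence disqualifies a peptide
#'   (default M, C, H: oxidisable, alkylated or poorly behaved).
#' @param collapse_il Passed to [check_uniqueness()].
#' @return List with data frames `kept` and `rejected`; `rejected` carries a
#'   `rejection_reasons` column (semicolon-separated rule ids). Both carry
#'   `is_unique`.
#' @export
filter_candidates <- function(candidates, proteome,
                              min_length = 7L, max_length = 25L,
                              excluded_residues = c("M", "C", "H"),
                              collapse_il = FALSE) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    empty <- candidates
    return(list(kept = empty, rejected = empty))
  }
  if (is.null(proteome) || nrow(proteome) == 0L)
    stop("proteome must be non-empty")
  len <- nchar(candidates$sequence)
  reasons <- vector("list", nrow(candidates))
  add <- function(which, tag) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  add(which(len < min_length), sprintf("length<%d", min_length))
  add(which(len > max_length), sprintf("length>%d", max_length))
  add(which(candidates$missed_cleavages > 0L), "missed-cleavage")
  for (res in excluded_residues)
    add(which(grepl(res, candidates$sequence, fixed = TRUE)),
        paste0("contains-", res))
  uni <- vapply(candidates$sequence, function(p)
    check_uniqueness(p, proteome, collapse_il = collapse_il)$unique,
    logical(1))
  add(which(!uni), "not-unique")
  candidates$is_unique <- uni
  candidates$rejection_reasons <-
    vapply(reasons, function(r) paste(r, collapse = ";"), character(1))
  keep <- !nzchar(candidates$rejection_reasons)
  list(kept = candidates[keep, , drop = FALSE],
       rejected = candidates[!keep, , drop = FALSE])
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any modification deltas, plus
#' the heavy-label delta when `heavy = TRUE` (the label sits on a C-terminal
#' K or R).
#'
#' @param sequence Peptide sequence (canonical residues only).
#' @param modifications Character vector of modification names drawn from
#'   [MOD_DELTA] (repeat a name to apply it more than once; at most 3 total).
#' @param heavy Apply the stable-isotope label of the C-terminal residue.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("ISPNSPVAR")          # 939.5138
#' peptide_mass("EGNVSISAFVAK", heavy = TRUE) -
#'   peptide_mass("EGNVSISAFVAK")     # +8.0142
#' @export
peptide_mass <- function(sequence, modifications = character(), heavy = FALSE) {
  .check_sequence(sequence)
  if (length(modifications) > MAX_MODS_PER_PEPTIDE)
    stop("at most ", MAX_MODS_PER_PEPTIDE, " modifications per peptide")
  unknown <- setdiff(modifications, names(MOD_DELTA))
  if (length(unknown))
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  mass <- sum(AA_MONO_MASS[strsplit(sequence, "")[[1L]]]) + WATER_MONO +
    sum(MOD_DELTA[modifications])
  if (isTRUE(heavy)) {
    cterm <- substr(sequence, nchar(sequence), nchar(sequence))
    if (!cterm %in% names(HEAVY_LABEL_DELTA))
      stop("heavy label requires a C-terminal K or R, found ", cterm)
    mass <- mass + HEAVY_LABEL_DELTA[[cterm]]
  }
  unname(mass)
}

#' Precursor m/z from neutral mass
#'
#' @param monoisotopic_mass Neutral monoisotopic mass in Da.
#' @param charge Precursor charge state (the assays use 2 or 3).
#' @return m/z `(mass + charge * proton) / charge`, rounded half away from
#'   zero to 4 decimals, matching the panel's print precision.
#' @examples
#' precursor_mz(peptide_mass("ISPNSPVAR"), 2)  # 470.7642
#' @export
precursor_mz <- function(monoisotopic_mass, charge) {
  if (any(charge <= 0)) stop("charge must be positive")
  if (any(monoisotopic_mass < 0)) stop("mass must be >= 0")
  round_half_up((monoisotopic_mass + charge * PROTON_MASS) / charge, 4L)
}

#' Fragment-ion m/z
#'
#' y ions comprise the `ordinal` C-terminal residues plus water; b ions the
#' `ordinal` N-terminal residues. The heavy label is C-terminal, so it
#' shifts y ions (by delta / charge) and leaves b ions untouched.
#'
#' @param sequence Peptide sequence.
#' @param ion_type `"y"` or `"b"`.
#' @param ordinal Fragment index, `1 <= ordinal <= nchar(sequence) - 1`.
#' @param charge Product-ion charge, 1 or 2.
#' @param heavy Whether the precursor carries the C-terminal heavy label.
#' @return Fragment m/z rounded to 4 decimals.
#' @export
fragment_mz <- function(sequence, ion_type = c("y", "b"), ordinal,
                        charge = 1L, heavy = FALSE) {
  ion_type <- match.arg(ion_type)
  .check_sequence(sequence)
  n <- nchar(sequence)
  if (ordinal < 1L || ordinal > n - 1L)
    stop("ordinal must be in [1, ", n - 1L, "] for ", sequence)
  res <- strsplit(sequence, "")[[1L]]
  if (ion_type == "y") {
    frag <- res[(n - ordinal + 1L):n]
    neutral <- sum(AA_MONO_MASS[frag]) + WATER_MONO
    if (isTRUE(heavy)) {
      cterm <- res[n]
      if (!cterm %in% names(HEAVY_LABEL_DELTA))
        stop("heavy label requires a C-terminal K or R")
      neutral <- neutral + HEAVY_LABEL_DELTA[[cterm]]
    }
  } else {
    frag <- res[seq_len(ordinal)]
    neutral <- sum(AA_MONO_MASS[frag])  # b ion: no water
  }
  round_half_up((neutral + charge * PROTON_MASS) / charge, 4L)
}

#' Parse a product-ion list string
#'
#' Turns the compact panel notation (e.g. `"y7+;y6+;b2+;y8++"`) into a
#' transition table. `p` denotes the precursor itself and has no ordinal.
#'
#' @param x Product-ion string; entries separated by `;`.
#' @return Data frame with `ion_type`, `ordinal` (NA for `p`) and `charge`.
#' @export
parse_product_ions <- function(x) {
  parts <- trimws(strsplit(tolower(x), ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([ybp])([0-9]*)(\\+{0,2})$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable product ion(s): ",
                     paste(parts[bad], collapse = ", "))
  data.frame(
    ion_type = vapply(m, `[`, character(1), 2L),
    ordinal = as.integer(vapply(m, function(g)
      if (nzchar(g[3L])) g[3L] else NA_character_, character(1))),
    charge = pmax(1L, vapply(m, function(g) nchar(g[4L]), integer(1))),
    stringsAsFactors = FALSE
  )
}

#' Heavy-twin display string
#'
#' @param peptide Light peptide sequence ending in K or R.
#' @return The labeled-peptide notation, e.g. `"ISPNSPVA[Heavy R]"`.
#' @keywords internal
heavy_twin_label <- function(peptide) {
  n <- nchar(peptide)
  cterm <- substr(peptide, n, n)
  if (!cterm %in% names(HEAVY_LABEL_DELTA))
    stop("peptide does not end in K or R: ", peptide)
  paste0(substr(peptide, 1L, n - 1L), "[Heavy ", cterm, "]")
}

#' Default panel settings
#' @keywords internal
panel_settings <- function() {
  list(precursor_charges = c(2L, 3L), ion_charges = c(1L, 2L),
       ion_match_tolerance = 0.5, product_ions_picked = 10L,
       charge3_mz_threshold = 1000)
}

# auto-pick product ions: singly charged y ions, preferring (up to 3) ions
# with m/z above the precursor, then filling downwards by ordinal
.autopick_ions <- function(peptide, prec_mz, n_pick = 10L) {
  n <- nchar(peptide)
  ords <- rev(seq(2L, n - 1L))
  mzs <- vapply(ords, function(o) fragment_mz(peptide, "y", o, 1L), numeric(1))
  above <- ords[mzs > prec_mz]
  picked <- c(utils::head(above, 3L), setdiff(ords, utils::head(above, 3L)))
  picked <- utils::head(picked, n_pick)
  paste0("y", picked, "+", collapse = ";")
}

#' Build a PRM assay panel
#'
#' Digests the target proteins, applies the proteotypic filters, merges in
#' any explicitly supplied extra peptides (e.g. peptides carried over from a
#' shotgun experiment that violate the strict filters), and computes light
#' and heavy precursor m/z. Precursor charge defaults to 2 and switches to
#' 3 when the doubly charged m/z would exceed the settings threshold.
#'
#' @param targets Data frame of target proteins (`accession`, `sequence`).
#' @param proteome Data frame used for the uniqueness screen (should contain
#'   the targets).
#' @param spike_amounts Named numeric vector, fmol of heavy peptide spiked
#'   per peptide sequence. Peptides without an entry get `default_spike`.
#' @param extra_peptides Character vector of peptides exempt from the
#'   residue/length filters (still must map to a target).
#' @param scheduled_rt Named numeric vector of scheduled retention times
#'   (minutes) per peptide; missing entries are left NA.
#' @param default_spike Default spike amount (fmol), used when a peptide has
#'   no entry in `spike_amounts`.
#' @param settings Panel settings list; see `panel_settings()`.
#' @return An `assay_panel` data frame with one row per peptide: columns
#'   `protein_id`, `peptide`, `labeled_peptide`, `light_mz`, `heavy_mz`,
#'   `charge`, `product_ions`, `rt_min`, `spike_fmol`.
#' @export
build_assay_panel <- function(targets, proteome, spike_amounts = numeric(),
                              extra_peptides = character(),
                              scheduled_rt = numeric(),
                              default_spike = 50,
                              settings = panel_settings()) {
  if (any(spike_amounts <= 0)) stop("spike amounts must be positive")
  if (is.null(targets) || nrow(targets) == 0L)
    return(empty_panel(settings))
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    cand <- digest_protein(targets[i, ], missed_cleavages = 0L)
    kept <- filter_candidates(cand, proteome)$kept
    peps <- kept$sequence
    extra_here <- extra_peptides[
      vapply(extra_peptides, function(p)
        grepl(p, targets$sequence[i], fixed = TRUE), logical(1))]
    peps <- unique(c(peps, extra_here))
    peps <- peps[substr(peps, nchar(peps), nchar(peps)) %in% c("K", "R")]
    if (!length(peps)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = targets$accession[i], peptide = peps,
      stringsAsFactors = FALSE)
  }
  unmapped <- setdiff(extra_peptides,
                      unlist(lapply(rows, function(r) r$peptide)))
  if (length(unmapped))
    stop("peptide(s) not found in any target: ",
         paste(unmapped, collapse = ", "))
  if (!length(rows)) return(empty_panel(settings))
  panel <- do.call(rbind, rows)
  mass <- vapply(panel$peptide, peptide_mass, numeric(1))
  charge <- ifelse(precursor_mz(mass, 2L) > settings$charge3_mz_threshold,
                   3L, 2L)
  hmass <- vapply(panel$peptide, peptide_mass, numeric(1), heavy = TRUE)
  panel$labeled_peptide <- vapply(panel$peptide, heavy_twin_label, character(1))
  panel$light_mz <- precursor_mz(mass, charge)
  panel$heavy_mz <- precursor_mz(hmass, charge)
  panel$charge <- charge
  panel$product_ions <- mapply(.autopick_ions, panel$peptide, panel$light_mz,
                               MoreArgs = list(n_pick = settings$product_ions_picked))
  panel$rt_min <- unname(scheduled_rt[panel$peptide])
  panel$spike_fmol <- ifelse(panel$peptide %in% names(spike_amounts),
                             unname(spike_amounts[panel$peptide]),
                             default_spike)
  rownames(panel) <- NULL
  structure(panel, settings = settings,
            class = c("assay_panel", "data.frame"))
}

empty_panel <- function(settings = panel_settings()) {
  structure(
    data.frame(protein_id = character(), peptide = character(),
               labeled_peptide = character(), light_mz = numeric(),
               heavy_mz = numeric(), charge = integer(),
               product_ions = character(), rt_min = numeric(),
               spike_fmol = numeric(), stringsAsFactors = FALSE),
    settings = settings, class = c("assay_panel", "data.frame"))
}

#' Read / write an assay panel CSV
#'
#' The panel CSV dialect has one row per peptide with columns `protein_id`,
#' `peptide`, `labeled_peptide`, `light_mz`, `heavy_mz`, `charge`,
#' `product_ions` (semicolon list such as `"y7+;y6+;y5+"`), `rt_min`,
#' `spike_fmol`. A transcription of the published tomato ethylene-signaling
#' panel ships with the package (`system.file("extdata", "table1_panel.csv",
#' package = "prmquant")`).
#'
#' @param path CSV path.
#' @return For `read_panel`, an `assay_panel` data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide", "labeled_peptide", "light_mz",
            "heavy_mz", "charge", "product_ions", "rt_min", "spike_fmol")
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  structure(panel[need], settings = panel_settings(),
            class = c("assay_panel", "data.frame"))
}

#' @rdname read_panel
#' @param panel An `assay_panel` data frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Export a Skyline-style transition list
#'
#' One row per (precursor, product ion) pair, for both the light and heavy
#' form of each panel peptide.
#'
#' @param panel An `assay_panel`.
#' @param path Optional CSV output path.
#' @return The transition-list data frame (invisibly if `path` is given).
#' @export
export_transition_list <- function(panel, path = NULL) {
  out <- list()
  for (i in seq_len(nrow(panel))) {
    ions <- parse_product_ions(panel$product_ions[i])
    for (iso in c("light", "heavy")) {
      heavy <- iso == "heavy"
      pm <- if (heavy) panel$heavy_mz[i] else panel$light_mz[i]
      prod <- vapply(seq_len(nrow(ions)), function(j) {
        if (ions$ion_type[j] == "p") return(pm)
        fragment_mz(panel$peptide[i], ions$ion_type[j], ions$ordinal[j],
                    ions$charge[j], heavy = heavy)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        protein = panel$protein_id[i], peptide = panel$peptide[i],
        isotope = iso, precursor_mz = pm, precursor_charge = panel$charge[i],
        fragment = ifelse(ions$ion_type == "p", "p",
                          paste0(ions$ion_type, ions$ordinal)),
        product_mz = prod, product_charge = ions$charge,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Recompute panel precursor m/z from sequence
#'
#' Round-trip validation helper: recomputes light and heavy precursor m/z of
#' every panel row from the peptide sequence and compares with the stored
#' values.
#'
#' @param panel An `assay_panel`.
#' @return Data frame with recomputed m/z and the absolute deviations
#'   `dev_light`, `dev_heavy`.
#' @export
validate_panel_mz <- function(panel) {
  light <- vapply(seq_len(nrow(panel)), function(i)
    precursor_mz(peptide_mass(panel$peptide[i]), panel$charge[i]), numeric(1))
  heavy <- vapply(seq_len(nrow(panel)), function(i)
    precursor_mz(peptide_mass(panel$peptide[i], heavy = TRUE),
                 panel$charge[i]), numeric(1))
  data.frame(peptide = panel$peptide,
             light_mz = light, heavy_mz = heavy,
             dev_light = abs(light - panel$light_mz),
             dev_heavy = abs(heavy - panel$heavy_mz))
}
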