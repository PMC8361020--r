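# Synonymous codon alternatives (excluding the codon itself).
synonymous_codons <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  setdiff(names(gc)[gc == gc[[codon]]], codon)
}

# Try to change the 2-base core at 0-based position pos0 by synonymous codon
# replacement. Prefers one edit over two; among equals, the replacement
# codon(s) with the highest summed usage frequency. Returns NULL when the
# core is pinned by the genetic code (e.g. Met/Trp context).
try_destroy_core <- function(seq, pos0, table) {
  n <- nchar(seq)
  if (pos0 < 0L || pos0 + 2L > n) stop("core position out of range")
  lo <- pos0 + 1L; hi <- pos0 + 2L        # 1-based core span
  core <- substr(seq, lo, hi)
  ci <- unique(c(pos0 %/% 3L, (pos0 + 1L) %/% 3L))  # 0-based codon indices
  codons <- codon_split(seq)
  apply_edit <- function(idx, alt) {
    cs <- codons
    cs[idx + 1L] <- alt
    paste(cs, collapse = "")
  }
  best <- NULL
  consider <- function(new_seq, edits, freq) {
    if (substr(new_seq, lo, hi) == core) return()
    if (is.null(best) ||
        nrow(edits) < nrow(best$edits) ||
        (nrow(edits) == nrow(best$edits) && freq > best$freq)) {
      best <<- list(seq = new_seq, edits = edits, freq = freq)
    }
  }
  for (i in ci) {
    for (alt in synonymous_codons(codons[i + 1L])) {
      consider(apply_edit(i, alt),
               data.frame(codon_index = i, from = codons[i + 1L], to = alt,
                          stringsAsFactors = FALSE),
               usage_freq(table, alt))
    }
  }
  if (is.null(best) && length(ci) == 2L) {
    alts1 <- synonymous_codons(codons[ci[1L] + 1L])
    alts2 <- synonymous_codons(codons[ci[2L] + 1L])
    for (a1 in alts1) for (a2 in alts2) {
      cs <- codons
      cs[ci + 1L] <- c(a1, a2)
      consider(paste(cs, collapse = ""),
               data.frame(codon_index = ci, from = codons[ci + 1L],
                          to = c(a1, a2), stringsAsFactors = FALSE),
               usage_freq(table, a1) + usage_freq(table, a2))
    }
  }
  best
}

#' Synonymously ablate cryptic splice motifs in a CDS
#'
#' For each candidate intron, attempts to destroy the donor core (the GT
#' dinucleotide opening the intron, falling back to the exonic AG context
#' when the GT is pinned by Met/Trp codons) and the acceptor core (the AG
#' closing it) by synonymous codon replacement, so the protein sequence is
#' untouched. Among the possible edits, the fewest-edit solution wins; ties
#' go to the replacement codon with the highest usage frequency in `table`.
#' Candidates whose cores admit no synonymous edit are reported as
#' unresolvable, never silently dropped.
#'
#' @param record a [cds_record()] or nucleotide string (length divisible
#'   by 3).
#' @param candidates a `cryptic_introns` data.frame (columns `donor_pos`,
#'   `acceptor_pos`, 0-based junction offsets).
#' @param table a [codon_usage_table()] used to rank synonymous
#'   alternatives (codons absent from a partial table rank as frequency 0).
#' @return List of class `ablation_result`: `record` (edited
#'   [cds_record()]), `report` (per-candidate data.frame: `donor_pos`,
#'   `acceptor_pos`, `donor_resolved`, `acceptor_resolved`, `resolved`,
#'   `n_edits`), `edits` (data.frame of codon replacements).
#' @export
ablate_splice_motifs <- function(record, candidates, table) {
  record <- as_cds_record(record)
  seq <- record$seq
  if (nchar(seq) %% 3L != 0L) stop("CDS length not divisible by 3")
  report <- data.frame(donor_pos = integer(), acceptor_pos = integer(),
                       donor_resolved = logical(), acceptor_resolved = logical(),
                       resolved = logical(), n_edits = integer(),
                       stringsAsFactors = FALSE)
  all_edits <- data.frame(codon_index = integer(), from = character(),
                          to = character(), stringsAsFactors = FALSE)
  if (!is.null(candidates) && NROW(candidates)) {
    for (i in seq_len(NROW(candidates))) {
      d <- as.integer(candidates[["donor_pos"]][i])
      a <- as.integer(candidates[["acceptor_pos"]][i])
      if (d < 0L || a > nchar(seq) || a <= d) stop("candidate out of range")
      n_edits <- 0L

      # donor: kill the intronic GT at [d, d+1]; fall back to the exonic AG
      donor_resolved <- substr(seq, d + 1L, d + 2L) != "GT"
      if (!donor_resolved) {
        fix <- try_destroy_core(seq, d, table)
        if (is.null(fix) && d >= 2L && substr(seq, d - 1L, d) == "AG") {
          fix <- try_destroy_core(seq, d - 2L, table)
        }
        if (!is.null(fix)) {
          seq <- fix$seq
          all_edits <- rbind(all_edits, fix$edits)
          n_edits <- n_edits + nrow(fix$edits)
          donor_resolved <- TRUE
        }
      }

      # acceptor: kill the intronic AG at [a-2, a-1]
      acceptor_resolved <- substr(seq, a - 1L, a) != "AG"
      if (!acceptor_resolved) {
        fix <- try_destroy_core(seq, a - 2L, table)
        if (!is.null(fix)) {
          seq <- fix$seq
          all_edits <- rbind(all_edits, fix$edits)
          n_edits <- n_edits + nrow(fix$edits)
          acceptor_resolved <- TRUE
        }
      }

      report <- rbind(report, data.frame(
        donor_pos = d, acceptor_pos = a,
        donor_resolved = donor_resolved, acceptor_resolved = acceptor_resolved,
        resolved = donor_resolved || acceptor_resolved,
        n_edits = n_edits, stringsAsFactors = FALSE))
    }
  }
  stopifnot(translate_cds(seq) == translate_cds(record$seq))
  structure(list(record = cds_record(seq, id = record$id),
                 report = report, edits = all_edits),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("Ablation: %d candidate(s), %d resolved, %d edit(s)\n",
              nrow(x$report), sum(x$report$resolved), nrow(x$edits)))
  if (any(!x$report$resolved)) {
    cat("  unresolvable candidate(s) at donor position(s):",
        paste(x$report$donor_pos[!x$report$resolved], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Harden a CDS against heterosplicing
#'
#' The full prevention recipe: scan the CDS against genome-derived splice
#' PWMs, synonymously ablate the cores of every candidate cryptic intron,
#' then apply whole-CDS codon optimization (raising GC content), and rescan
#' to report residual candidates.
#'
#' @param record a [cds_record()] or nucleotide string.
#' @param table a [codon_usage_table()] (drives both ablation ranking and
#'   the substitution map).
#' @param donor_pwm,acceptor_pwm [build_pwm()] matrices.
#' @param min_score PWM score threshold in bits (default: consensus - 6).
#' @param min_len minimum intron length for enumeration (default 50).
#' @param aa_set amino acids for the substitution map (default: the eight
#'   two-fold degenerate ones).
#' @return List of class `hardening_result`: `record` (hardened CDS),
#'   `ablation`, `optimization` (its report), `residual`
#'   (`cryptic_introns` remaining above threshold after hardening).
#' @export
harden_cds <- function(record, table, donor_pwm, acceptor_pwm,
                       min_score = NULL, min_len = 50L,
                       aa_set = DEFAULT_AA_SET) {
  record <- as_cds_record(record)
  cand <- scan_candidates(record, donor_pwm, acceptor_pwm, min_score)
  introns <- enumerate_cryptic_introns(record, cand, min_len = min_len)
  abl <- ablate_splice_motifs(record, introns, table)
  opt <- optimize_cds(abl$record, derive_substitution_map(table, aa_set))
  rescan <- scan_candidates(opt$record, donor_pwm, acceptor_pwm, min_score)
  residual <- enumerate_cryptic_introns(opt$record, rescan, min_len = min_len)
  stopifnot(translate_cds(opt$record$seq) == translate_cds(record$seq))
  structure(list(record = opt$record, ablation = abl,
                 optimization = opt$report, residual = residual),
            class = "hardening_result")
}

#' @export
print.hardening_result <- function(x, ...) {
  cat("CDS hardening\n")
  print(x$ablation)
  print(x$optimization)
  cat(sprintf("  residual candidate intron(s): %d\n", nrow(x$residual)))
  invisible(x)
}
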