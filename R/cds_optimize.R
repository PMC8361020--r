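#' Coding sequence records
#'
#' @param seq nucleotide string over A, C, G, T, N (case-insensitive;
#'   upper-cased on construction).
#' @param id record identifier.
#' @return An object of class `cds_record`.
#' @export
cds_record <- function(seq, id = "cds") {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  structure(list(id = id, seq = seq), class = "cds_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat("CDS record '", x$id, "': ", nchar(x$seq), " nt\n", sep = "")
  invisible(x)
}

as_cds_record <- function(x, id = "cds") {
  if (inherits(x, "cds_record")) x else cds_record(x, id = id)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file.
#' @return List of [cds_record()]s.
#' @export
read_cds_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  mapply(function(s, n) cds_record(s, id = n),
         as.character(ss), names(ss), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write coding sequences to FASTA (60-column wrap)
#'
#' @param records list of [cds_record()]s (or a single record).
#' @param path output file.
#' @export
write_cds_fasta <- function(records, path) {
  if (inherits(records, "cds_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(ss) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Translate a coding sequence under the standard genetic code
#'
#' Codons containing N translate to `X`. Translation does not stop at stop
#' codons (they appear as `*`); see [characterize_variant()] for
#' stop-truncated products.
#'
#' @param seq nucleotide string, length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3L != 0L) stop("length not divisible by 3")
  codons <- codon_split(seq)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Structural validation of a CDS
#'
#' Checks length divisibility by 3, an ATG start, a terminal stop codon and
#' internal (premature) stop codons. All failures are reported as warnings in
#' the returned report, never as errors: irregular but readable sequences are
#' still processed downstream.
#'
#' @param record a [cds_record()] or nucleotide string.
#' @return List of class `cds_validation`: `length_ok`, `start_ok`,
#'   `stop_ok`, `internal_stop_codons` (0-based codon indices, final codon
#'   excluded), `warnings`.
#' @examples
#' validate_cds("ATGAAATAG")
#' @export
validate_cds <- function(record) {
  record <- as_cds_record(record)
  seq <- record$seq
  n <- nchar(seq)
  warnings <- character()
  length_ok <- n %% 3L == 0L
  if (!length_ok) warnings <- c(warnings, sprintf("length %d not divisible by 3", n))
  start_ok <- n >= 3L && substr(seq, 1L, 3L) == "ATG"
  if (!start_ok) warnings <- c(warnings, "sequence does not start with ATG")
  stops <- c("TAA", "TAG", "TGA")
  internal <- integer()
  stop_ok <- FALSE
  if (length_ok && n >= 3L) {
    codons <- codon_split(seq)
    k <- length(codons)
    stop_ok <- codons[k] %in% stops
    internal <- which(codons[-k] %in% stops) - 1L
  }
  if (!stop_ok) warnings <- c(warnings, "sequence does not end with a stop codon")
  if (length(internal)) {
    warnings <- c(warnings, sprintf("internal stop codon(s) at codon index %s",
                                    paste(internal, collapse = ", ")))
  }
  structure(list(length_ok = length_ok, start_ok = start_ok, stop_ok = stop_ok,
                 internal_stop_codons = internal, warnings = warnings),
            class = "cds_validation")
}

#' @export
print.cds_validation <- function(x, ...) {
  cat("CDS validation: length_ok=", x$length_ok, " start_ok=", x$start_ok,
      " stop_ok=", x$stop_ok, "\n", sep = "")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' GC content of a nucleotide sequence
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq nucleotide string.
#' @return Fraction of G+C among A/C/G/T bases, in `[0, 1]`.
#' @examples
#' gc_content("GGCC") # 1
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  counts <- table(factor(strsplit(seq, "")[[1L]], levels = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no A/C/G/T bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Synonymous codon optimization of a CDS
#'
#' Inspects a coding sequence codon by codon and replaces each codon found in
#' the substitution map with its target. The protein sequence is unchanged by
#' construction; with the default usage-derived maps, every rule swaps a
#' third-position T for C or A for G, so the GC content never decreases.
#' Codons containing N are skipped with a warning.
#'
#' @param record a [cds_record()] or nucleotide string; length must be
#'   divisible by 3.
#' @param map a [substitution_map()].
#' @return List with `record` (optimized [cds_record()]) and `report` (class
#'   `optimization_report`): `n_codons`, `n_changed`, `changed_positions`
#'   (0-based codon indices), `gc_before`, `gc_after`.
#' @examples
#' map <- derive_substitution_map(usage_table_fixture("ppatens"))
#' optimize_cds("ATGTGTGAATAA", map)$record$seq # "ATGTGCGAGTAA"
#' @export
optimize_cds <- function(record, map) {
  record <- as_cds_record(record)
  stopifnot(inherits(map, "substitution_map"))
  if (nchar(record$seq) %% 3L != 0L) {
    stop("cannot optimize: length not divisible by 3")
  }
  codons <- codon_split(record$seq)
  has_n <- grepl("N", codons, fixed = TRUE)
  if (any(has_n)) {
    warning(sum(has_n), " codon(s) containing N skipped", call. = FALSE)
  }
  targets <- unname(unclass(map)[codons])
  change <- !is.na(targets) & !has_n
  out <- codons
  out[change] <- targets[change]
  new_seq <- paste(out, collapse = "")
  report <- structure(list(
    n_codons = length(codons),
    n_changed = sum(change),
    changed_positions = which(change) - 1L,
    gc_before = gc_content(record$seq),
    gc_after = gc_content(new_seq)
  ), class = "optimization_report")
  list(record = cds_record(new_seq, id = record$id), report = report)
}

#' @export
print.optimization_report <- function(x, ...) {
  cat(sprintf("Optimization: %d of %d codons changed; GC %.1f%% -> %.1f%%\n",
              x$n_changed, x$n_codons, 100 * x$gc_before, 100 * x$gc_after))
  invisible(x)
}
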