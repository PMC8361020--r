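#' Codon usage tables
#'
#' A codon usage table stores, for one species, the frequency of each codon
#' per thousand codons (the scale used by the Kazusa Codon Usage Database).
#' Tables parsed from full Kazusa-style dumps carry all 64 codons; the
#' packaged reference tables carry only the codons of the eight two-fold
#' degenerate amino acids they document.
#'
#' @param freq named numeric vector, codon (DNA alphabet) -> frequency per
#'   thousand; RNA (U) codons are accepted and normalized to T.
#' @param species_label character scalar naming the species.
#' @param complete logical; if `TRUE` (the default for [parse_usage_table()])
#'   require all 64 codons.
#' @return An object of class `codon_usage_table`.
#' @export
codon_usage_table <- function(freq, species_label = "unknown", complete = FALSE) {
  if (is.null(names(freq)) || any(!nzchar(names(freq)))) {
    stop("frequencies must be a named vector keyed by codon")
  }
  codons <- toupper(chartr("Uu", "Tt", names(freq)))
  if (any(!grepl("^[ACGT]{3}$", codons))) {
    bad <- codons[!grepl("^[ACGT]{3}$", codons)]
    stop("invalid codon key(s): ", paste(bad, collapse = ", "))
  }
  dup <- codons[duplicated(codons)]
  if (length(dup)) stop("duplicated codon(s): ", paste(unique(dup), collapse = ", "))
  freq <- as.numeric(freq)
  if (any(!is.finite(freq)) || any(freq < 0)) stop("frequencies must be finite and >= 0")
  names(freq) <- codons
  if (complete && length(freq) != 64L) {
    missing <- setdiff(names(Biostrings::GENETIC_CODE), codons)
    stop("missing codon(s): ", paste(missing, collapse = ", "))
  }
  structure(list(species_label = species_label, freq = freq),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table:", x$species_label, "\n")
  cat(" ", length(x$freq), "codons; frequencies per thousand\n")
  invisible(x)
}

# Frequency lookup with 0 default for codons absent from partial tables.
usage_freq <- function(table, codon) {
  f <- unname(table$freq[codon])
  f[is.na(f)] <- 0
  f
}

#' Parse a Kazusa-style codon usage table
#'
#' Accepts both the Codon Usage Database layout (several
#' `codon frequency (count)` fields per line) and plain two-column
#' `codon frequency` text. RNA codons (U) are normalized to the DNA alphabet.
#' All 64 codons must be present exactly once.
#'
#' @param text character vector of lines, or a single string (possibly
#'   containing newlines), or a file path when `file = TRUE`.
#' @param species_label species name to attach to the table.
#' @param file logical; treat `text` as a path to read.
#' @return A [codon_usage_table()] with 64 DNA-alphabet codons.
#' @examples
#' lines <- paste(names(Biostrings::GENETIC_CODE), 15.6)
#' tab <- parse_usage_table(lines)
#' @export
parse_usage_table <- function(text, species_label = "unknown", file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  text <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  text <- text[!grepl("^\\s*(#|$)", text)]
  pat <- "([ACGUTacgut]{3})\\s+([0-9]+\\.?[0-9]*)(\\s*\\(\\s*[0-9]+\\s*\\))?"
  hits <- regmatches(text, gregexpr(pat, text))
  fields <- unlist(hits)
  if (!length(fields)) stop("no codon/frequency pairs found")
  m <- regmatches(fields, regexec(pat, fields))
  codons <- toupper(chartr("Uu", "Tt", vapply(m, `[`, "", 2L)))
  freqs <- as.numeric(vapply(m, `[`, "", 3L))
  dup <- unique(codons[duplicated(codons)])
  if (length(dup)) stop("duplicated codon(s): ", paste(dup, collapse = ", "))
  missing <- setdiff(names(Biostrings::GENETIC_CODE), codons)
  if (length(missing)) stop("missing codon(s): ", paste(missing, collapse = ", "))
  names(freqs) <- codons
  codon_usage_table(freqs, species_label = species_label, complete = TRUE)
}

#' Write a codon usage table as two-column text
#'
#' @param table a [codon_usage_table()].
#' @param path file path to write (`codon<TAB>frequency` lines).
#' @export
write_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  writeLines(sprintf("%s\t%g", names(table$freq), table$freq), path)
  invisible(path)
}

#' Packaged reference codon usage tables
#'
#' The package ships the documented per-thousand frequencies of the codons of
#' eight two-fold degenerate amino acids (Cys, Glu, Phe, His, Lys, Asn, Gln,
#' Tyr) for six production-host species, as reported by the Kazusa Codon
#' Usage Database.
#'
#' @param species one of `ppatens`, `sfrugiperda`, `hsapiens`, `cgriseus`,
#'   `osativa`, `ntabacum`; with no argument, the available labels.
#' @return A (partial, 16-codon) [codon_usage_table()], or a character vector
#'   of available species labels.
#' @export
usage_table_fixture <- function(species) {
  dir <- system.file("extdata", "codon_usage", package = "hskit")
  avail <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
  if (missing(species)) return(avail)
  species <- match.arg(species, avail)
  d <- utils::read.delim(file.path(dir, paste0(species, ".tsv")),
                         stringsAsFactors = FALSE)
  codon_usage_table(stats::setNames(d$freq_per_thousand, d$codon),
                    species_label = species)
}
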