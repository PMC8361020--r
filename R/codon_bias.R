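#' Two-fold degenerate amino acids and codon bias
#'
#' For an amino acid encoded by exactly two synonymous codons (differing at
#' the third position), a usage table defines an under- and an
#' over-represented codon. Eight such amino acids (C, E, F, H, K, N, Q, Y)
#' drive the synonymous optimization rules; Asp (D) is also two-fold
#' degenerate and is accepted on request.
#'
#' @name two_codon_bias
NULL

DEFAULT_AA_SET <- c("C", "E", "F", "H", "K", "N", "Q", "Y")

# amino acid -> its two codons, for every two-fold degenerate amino acid
two_codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), gc)
  fam <- fam[vapply(fam, length, 0L) == 2L]
  fam[names(fam) != "*"]
}

#' Classify under- and over-represented codons for two-fold amino acids
#'
#' @param table a [codon_usage_table()].
#' @param aa_set character vector of 1-letter amino-acid codes; each must be
#'   two-fold degenerate. Default: C, E, F, H, K, N, Q, Y.
#' @return A data.frame with one row per amino acid whose two codon
#'   frequencies differ: `aa`, `under_codon`, `over_codon`, `under_freq`,
#'   `over_freq`. Amino acids with tied frequencies are omitted with a
#'   warning (a tie carries no usage-bias signal).
#' @examples
#' classify_two_codon_bias(usage_table_fixture("ppatens"))
#' @export
classify_two_codon_bias <- function(table, aa_set = DEFAULT_AA_SET) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam <- two_codon_families()
  aa_set <- toupper(aa_set)
  bad <- setdiff(aa_set, names(fam))
  if (length(bad)) {
    stop("not two-fold degenerate amino acid(s): ", paste(bad, collapse = ", "))
  }
  rows <- lapply(aa_set, function(aa) {
    codons <- fam[[aa]]
    f <- table$freq[codons]
    if (any(is.na(f))) {
      stop("table '", table$species_label, "' lacks codon(s) ",
           paste(codons[is.na(f)], collapse = ", "), " for amino acid ", aa)
    }
    if (f[1L] == f[2L]) {
      warning("tied frequencies for ", aa, " (", codons[1L], " == ",
              codons[2L], "); no bias recorded", call. = FALSE)
      return(NULL)
    }
    o <- order(f)
    data.frame(aa = aa,
               under_codon = codons[o[1L]], over_codon = codons[o[2L]],
               under_freq = unname(f[o[1L]]), over_freq = unname(f[o[2L]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(aa = character(), under_codon = character(),
                      over_codon = character(), under_freq = numeric(),
                      over_freq = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Derive a synonymous substitution map from codon usage
#'
#' Maps each amino acid's under-represented codon to its over-represented
#' one. Every rule is synonymous, touches only the third codon position, and
#' no rule's target is itself a source, so applying the map twice equals
#' applying it once.
#'
#' @inheritParams classify_two_codon_bias
#' @return An object of class `substitution_map`: a named character vector
#'   of `source -> target` rules with an `origin_species` attribute.
#' @examples
#' derive_substitution_map(usage_table_fixture("ppatens"))
#' @export
derive_substitution_map <- function(table, aa_set = DEFAULT_AA_SET) {
  bias <- classify_two_codon_bias(table, aa_set)
  rules <- stats::setNames(bias$over_codon, bias$under_codon)
  substitution_map(rules, origin_species = table$species_label)
}

#' Construct and validate a substitution map
#'
#' @param rules named character vector, source codon -> target codon.
#' @param origin_species label of the usage table the rules derive from.
#' @export
substitution_map <- function(rules, origin_species = "unknown") {
  rules <- stats::setNames(toupper(chartr("Uu", "Tt", as.character(rules))),
                           toupper(chartr("Uu", "Tt", names(rules) %||% character())))
  gc <- Biostrings::GENETIC_CODE
  if (length(rules)) {
    stopifnot(all(grepl("^[ACGT]{3}$", names(rules))),
              all(grepl("^[ACGT]{3}$", rules)))
    syn <- gc[names(rules)] == gc[rules]
    if (any(!syn)) {
      stop("non-synonymous rule(s): ",
           paste(names(rules)[!syn], "->", rules[!syn], collapse = ", "))
    }
    if (any(gc[names(rules)] == "*")) stop("stop codons may not be substituted")
    circular <- intersect(rules, names(rules))
    if (length(circular)) {
      stop("target codon(s) also used as source: ",
           paste(circular, collapse = ", "))
    }
  }
  structure(rules, class = "substitution_map", origin_species = origin_species)
}

#' @export
print.substitution_map <- function(x, ...) {
  cat("Substitution map (", attr(x, "origin_species"), "): ",
      length(x), " rule(s)\n", sep = "")
  if (length(x)) cat(" ", paste(names(x), "->", unname(x), collapse = "  "), "\n")
  invisible(x)
}

#' Write a substitution map as JSON
#'
#' @param map a [substitution_map()].
#' @param path output file.
#' @export
write_substitution_map <- function(map, path) {
  jsonlite::write_json(as.list(stats::setNames(unname(unclass(map)), names(map))),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Compare synonymous codon preference across species
#'
#' For each species, counts the amino acids (of `aa_set`) whose
#' over-represented codon agrees with the reference species' choice.
#'
#' @param reference a [codon_usage_table()] used as the baseline.
#' @param others list of [codon_usage_table()]s to compare.
#' @inheritParams classify_two_codon_bias
#' @return data.frame: `species`, `n_agree`, `n_total`, `agree_aa`
#'   (comma-separated amino acids in agreement).
#' @examples
#' compare_bias_across_species(usage_table_fixture("ppatens"),
#'                             list(usage_table_fixture("osativa")))
#' @export
compare_bias_across_species <- function(reference, others, aa_set = DEFAULT_AA_SET) {
  ref <- classify_two_codon_bias(reference, aa_set)
  if (inherits(others, "codon_usage_table")) others <- list(others)
  rows <- lapply(others, function(tab) {
    b <- classify_two_codon_bias(tab, aa_set)
    merged <- merge(ref[, c("aa", "over_codon")], b[, c("aa", "over_codon")],
                    by = "aa", suffixes = c("_ref", "_other"))
    agree <- merged$aa[merged$over_codon_ref == merged$over_codon_other]
    data.frame(species = tab$species_label,
               n_agree = length(agree), n_total = length(aa_set),
               agree_aa = paste(sort(agree), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
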