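# Average (not monoisotopic) residue masses in Daltons, ExPASy values;
# a peptide mass is the residue sum plus one water.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153

#' Average molecular mass of a protein
#'
#' @param protein amino-acid string (standard 20 residues).
#' @return Mass in Daltons: sum of average residue masses plus one water
#'   (18.02 Da).
#' @examples
#' protein_mass("G") # 75.07
#' @export
protein_mass <- function(protein) {
  protein <- toupper(as.character(protein))
  if (!nzchar(protein)) stop("empty protein")
  aa <- strsplit(protein, "")[[1L]]
  bad <- setdiff(aa, names(AVERAGE_RESIDUE_MASS))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(AVERAGE_RESIDUE_MASS[aa]) + WATER_MASS
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of lysine (K) or arginine (R) except when the next
#' residue is proline (P). With `missed_cleavages = k`, additionally emits
#' every run of up to `k + 1` consecutive fully-cleaved peptides.
#'
#' @param protein amino-acid string.
#' @param missed_cleavages maximum internal cleavage sites per reported
#'   peptide (default 0).
#' @return Character vector of peptides. The zero-missed-cleavage peptides
#'   concatenate to the input.
#' @examples
#' digest_trypsin("MKRGPR") # "MK" "R" "GPR"
#' @export
digest_trypsin <- function(protein, missed_cleavages = 0L) {
  protein <- toupper(as.character(protein))
  if (!nzchar(protein)) return(character())
  aa <- strsplit(protein, "")[[1L]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  base <- substring(protein, starts, ends)
  if (missed_cleavages <= 0L) return(base)
  out <- base
  for (k in seq_len(missed_cleavages)) {
    if (length(base) <= k) break
    i <- seq_len(length(base) - k)
    out <- c(out, substring(protein, starts[i], ends[i + k]))
  }
  out
}

#' Peptides spanning a splice junction
#'
#' Returns the digestion peptides containing at least one residue from each
#' side of the variant's splice junction - the diagnostic signature of a
#' spliced isoform in mass-spectrometric data. A junction falling exactly on
#' a cleavage boundary is spanned by no peptide.
#'
#' @param variant a [characterize_variant()] result; must be
#'   frame-preserving (after a frameshift the junction is undefined at the
#'   protein level).
#' @param peptides character vector from [digest_trypsin()] applied to the
#'   variant's product; defaults to the zero-missed-cleavage digest.
#' @return Character vector (possibly empty) of junction-spanning peptides.
#' @export
junction_peptides <- function(variant, peptides = NULL) {
  stopifnot(inherits(variant, "splice_variant"))
  if (!variant$frame_preserving) {
    stop("junction peptides are undefined for frameshifted variants")
  }
  if (identical(variant$deleted_aa, 0L) || nchar(variant$variant_seq) == 0L) {
    return(character())
  }
  peptides <- peptides %||% digest_trypsin(variant$product)
  if (variant$deleted_aa == 0L) return(character())
  b <- variant$junction_codon_index       # residues 1..b are 5' of the junction
  prod <- variant$product
  if (b <= 0L || b >= nchar(prod)) return(character())
  straddles <- vapply(unique(peptides), function(p) {
    at <- gregexpr(p, prod, fixed = TRUE)[[1L]]
    if (at[1L] < 0L) return(FALSE)
    any(at <= b & at + nchar(p) - 1L >= b + 1L)
  }, NA)
  unique(peptides)[straddles]
}
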