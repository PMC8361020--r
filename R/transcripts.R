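#' Load transcript models from GFF3 annotation
#'
#' Builds one model per mRNA/transcript feature of a gene, with exons ordered
#' 5'->3' along the transcript (i.e. reversed genomic order on the minus
#' strand). GFF3 coordinates (1-based inclusive) are converted to 0-based
#' half-open intervals at this boundary only.
#'
#' @param annotation path to a GFF3 file.
#' @param genome optional genome as a named [Biostrings::DNAStringSet] or
#'   FASTA path; when supplied, exon chromosome names are checked against it.
#' @return List of `transcript_model` objects: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` (two-column matrix `start`/`end`, 0-based
#'   half-open, transcript order). Features of other biotypes are skipped and
#'   counted in attribute `n_skipped_features`.
#' @export
load_transcript_models <- function(annotation, genome = NULL) {
  check_gff3_lines(annotation)
  gff <- rtracklayer::import(annotation, format = "gff3")
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gff))),
                       names(genome))
    if (length(unknown)) {
      stop("annotation references unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  type <- as.character(gff$type)
  is_tx <- type %in% c("mRNA", "transcript")
  n_skipped <- sum(!type %in% c("gene", "mRNA", "transcript", "exon"))
  tx <- gff[is_tx]
  tx_id <- as.character(tx$ID)
  tx_parent <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  exons <- gff[type == "exon"]
  exon_parent <- vapply(exons$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  if (anyNA(exon_parent)) stop("exon feature without Parent attribute")
  exon_by_tx <- split(seq_along(exons), exon_parent)
  models <- lapply(seq_along(tx), function(i) {
    idx <- exon_by_tx[[tx_id[i]]]
    if (is.null(idx)) return(NULL)
    e <- exons[idx]
    start0 <- BiocGenerics::start(e) - 1L   # to 0-based half-open
    end0 <- BiocGenerics::end(e)
    o <- order(start0)
    start0 <- start0[o]; end0 <- end0[o]
    if (any(start0[-1L] < end0[-length(end0)])) {
      stop("overlapping exons in transcript ", tx_id[i])
    }
    strand <- as.character(BiocGenerics::strand(tx[i]))
    if (!strand %in% c("+", "-")) stop("transcript ", tx_id[i], " lacks a strand")
    ex <- cbind(start = start0, end = end0)
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    structure(list(transcript_id = tx_id[i],
                   gene_id = tx_parent[i],
                   chrom = as.character(GenomeInfoDb::seqnames(tx[i])),
                   strand = strand,
                   exons = ex),
              class = "transcript_model")
  })
  models <- Filter(Negate(is.null), models)
  attr(models, "n_skipped_features") <- n_skipped
  models
}

# Cheap structural pre-check so malformed lines are reported with their
# line number rather than an opaque parser failure.
check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9L]
  if (length(bad)) {
    stop("malformed GFF3 line ", bad[1L], ": expected 9 tab-separated fields")
  }
  invisible(TRUE)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  Biostrings::readDNAStringSet(genome)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript", x$transcript_id, "(", x$gene_id, ")", x$chrom, x$strand,
      "-", nrow(x$exons), "exon(s)\n")
  invisible(x)
}
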