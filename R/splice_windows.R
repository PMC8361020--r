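#' Extract splice-junction windows from transcript models
#'
#' For every intron of every transcript, extracts an 18-base window centred
#' on each junction: 9 exonic + 9 intronic bases for donor sites, 9 intronic
#' + 9 exonic bases for acceptor sites. Windows are always written 5'->3' on
#' the transcript strand (minus-strand windows are reverse-complemented), so
#' positions 10-11 of a donor window read the first two intron bases.
#'
#' @param models list of transcript models from [load_transcript_models()].
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param half_window bases on each side of the junction (default 9).
#' @return data.frame of class `splice_windows`: `kind` (donor/acceptor),
#'   `transcript_id`, `chrom`, `strand`, `intron_start`, `intron_end`
#'   (0-based half-open genomic), `window`, `gtag` (does the intron follow
#'   the GT-AG rule). Junctions too close to a contig edge are skipped with
#'   a warning; the count is kept in attribute `n_skipped`.
#' @export
extract_splice_windows <- function(models, genome, half_window = 9L) {
  genome <- as_genome(genome)
  chrom_str <- stats::setNames(as.character(genome), names(genome))
  half_window <- as.integer(half_window)
  stopifnot(half_window >= 1L)

  rows <- vector("list", length(models))
  for (m in seq_along(models)) {
    mod <- models[[m]]
    ex <- mod$exons
    if (nrow(ex) < 2L) next
    # introns in genomic order regardless of transcript orientation
    g <- ex[order(ex[, "start"]), , drop = FALSE]
    istart <- g[-nrow(g), "end"]       # 0-based intron start (first intron base)
    iend <- g[-1L, "start"]            # 0-based half-open intron end
    if (any(iend - istart < 1L)) {
      stop("zero-length intron in transcript ", mod$transcript_id)
    }
    rows[[m]] <- data.frame(transcript_id = mod$transcript_id,
                            chrom = mod$chrom, strand = mod$strand,
                            intron_start = istart, intron_end = iend,
                            stringsAsFactors = FALSE)
  }
  introns <- do.call(rbind, rows)
  empty <- data.frame(kind = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      window = character(), gtag = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(introns) || !nrow(introns)) {
    out <- structure(empty, class = c("splice_windows", "data.frame"))
    attr(out, "n_skipped") <- 0L
    return(out)
  }

  chrlen <- nchar(chrom_str)[introns$chrom]
  # donor junction: 5' end of intron on the transcript strand
  don_pos <- ifelse(introns$strand == "+", introns$intron_start, introns$intron_end)
  acc_pos <- ifelse(introns$strand == "+", introns$intron_end, introns$intron_start)
  fetch <- function(pos0) {
    lo <- pos0 - half_window   # 0-based window start
    hi <- pos0 + half_window   # 0-based half-open window end
    ok <- lo >= 0L & hi <= chrlen
    w <- rep(NA_character_, length(pos0))
    if (any(ok)) {
      w[ok] <- substring(chrom_str[introns$chrom[ok]], lo[ok] + 1L, hi[ok])
    }
    w
  }
  don_w <- fetch(don_pos)
  acc_w <- fetch(acc_pos)
  neg <- introns$strand == "-"
  if (any(neg)) {
    don_w[neg & !is.na(don_w)] <- reverse_complement(don_w[neg & !is.na(don_w)])
    acc_w[neg & !is.na(acc_w)] <- reverse_complement(acc_w[neg & !is.na(acc_w)])
  }
  first2 <- ifelse(neg,
                   reverse_complement(substring(chrom_str[introns$chrom],
                                                introns$intron_end - 1L,
                                                introns$intron_end)),
                   substring(chrom_str[introns$chrom],
                             introns$intron_start + 1L, introns$intron_start + 2L))
  last2 <- ifelse(neg,
                  reverse_complement(substring(chrom_str[introns$chrom],
                                               introns$intron_start + 1L,
                                               introns$intron_start + 2L)),
                  substring(chrom_str[introns$chrom],
                            introns$intron_end - 1L, introns$intron_end))
  gtag <- first2 == "GT" & last2 == "AG"

  out <- rbind(
    data.frame(kind = "donor", transcript_id = introns$transcript_id,
               chrom = introns$chrom, strand = introns$strand,
               intron_start = introns$intron_start, intron_end = introns$intron_end,
               window = don_w, gtag = gtag, stringsAsFactors = FALSE),
    data.frame(kind = "acceptor", transcript_id = introns$transcript_id,
               chrom = introns$chrom, strand = introns$strand,
               intron_start = introns$intron_start, intron_end = introns$intron_end,
               window = acc_w, gtag = gtag, stringsAsFactors = FALSE)
  )
  n_skipped <- sum(is.na(out$window))
  if (n_skipped) {
    warning(n_skipped, " junction window(s) skipped at contig edges", call. = FALSE)
    out <- out[!is.na(out$window), , drop = FALSE]
  }
  rownames(out) <- NULL
  out <- structure(out, class = c("splice_windows", "data.frame"))
  attr(out, "n_skipped") <- n_skipped
  out
}

window_strings <- function(windows, kind = NULL) {
  if (is.data.frame(windows)) {
    if (!is.null(kind)) windows <- windows[windows$kind == kind, , drop = FALSE]
    windows$window
  } else {
    as.character(windows)
  }
}

#' Build a position frequency matrix from splice windows
#'
#' @param windows a `splice_windows` data.frame or character vector of
#'   equal-length windows (all of one kind).
#' @param kind optional filter (`"donor"` or `"acceptor"`) when `windows` is
#'   a data.frame carrying both kinds.
#' @return Object of class `pfm`: `counts` (4 x width integer matrix, rows
#'   A/C/G/T; each column sums to `n_windows`), `n_windows`, `n_skipped`
#'   (windows containing N, excluded), `kind`.
#' @export
build_pfm <- function(windows, kind = NULL) {
  if (is.data.frame(windows) && is.null(kind) && length(unique(windows$kind)) > 1L) {
    stop("windows contain both kinds; pass kind = 'donor' or 'acceptor'")
  }
  if (is.data.frame(windows) && is.null(kind)) kind <- unique(windows$kind)
  w <- window_strings(windows, kind)
  if (!length(w)) stop("no windows to build a PFM from")
  width <- unique(nchar(w))
  if (length(width) != 1L) stop("windows have unequal lengths")
  has_n <- grepl("N", w, fixed = TRUE)
  n_skipped <- sum(has_n)
  w <- w[!has_n]
  if (!length(w)) stop("all windows contain N")
  chars <- matrix(unlist(strsplit(w, ""), use.names = FALSE),
                  nrow = length(w), byrow = TRUE)
  counts <- vapply(seq_len(width), function(j) {
    tabulate(factor(chars[, j], levels = c("A", "C", "G", "T")), nbins = 4L)
  }, integer(4L))
  dimnames(counts) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(kind = kind %||% "unknown", counts = counts,
                 n_windows = length(w), n_skipped = n_skipped),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix (", x$kind, "): ", ncol(x$counts),
      " positions, ", x$n_windows, " windows\n", sep = "")
  invisible(x)
}

#' Fraction of windows carrying a junction motif
#'
#' The default motif `CAGGT` anchored at -3 asks for `CAG` as the last three
#' bases before the junction and `GT` as the first two after it: for donor
#' windows that is exon-final CAG followed by the intron's GT, for acceptor
#' windows the intron-final CAG followed by the exon's first two bases.
#'
#' @param windows `splice_windows` data.frame or character vector.
#' @param motif motif string (default `"CAGGT"`).
#' @param anchor offset of the motif start relative to the junction point
#'   (default -3).
#' @param kind optional kind filter for data.frame input.
#' @param junction_offset bases before the junction in each window
#'   (default 9).
#' @param gtag_only restrict to windows of GT-AG introns (data.frame input
#'   only).
#' @return Fraction of N-free windows matching the motif at the anchor.
#' @export
junction_motif_fraction <- function(windows, motif = "CAGGT", anchor = -3L,
                                    kind = NULL, junction_offset = 9L,
                                    gtag_only = FALSE) {
  if (is.data.frame(windows) && gtag_only) {
    windows <- windows[windows$gtag, , drop = FALSE]
  }
  w <- window_strings(windows, kind)
  if (!length(w)) stop("no windows")
  width <- unique(nchar(w))
  if (length(width) != 1L) stop("windows have unequal lengths")
  start0 <- junction_offset + anchor           # 0-based motif start
  if (start0 < 0L || start0 + nchar(motif) > width) {
    stop("anchor places motif outside the window")
  }
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (!length(w)) stop("all windows contain N")
  mean(substring(w, start0 + 1L, start0 + nchar(motif)) == motif)
}

#' Information-content (logo) matrix of a PFM
#'
#' Per column, letter height is `p * (2 - H)` bits, where `H` is the Shannon
#' entropy of the column's base distribution; no small-sample correction is
#' applied.
#'
#' @param pfm a [build_pfm()] result.
#' @return 4 x width numeric matrix of letter heights in bits.
#' @export
logo_matrix <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"), pfm$n_windows >= 1L)
  p <- pfm$counts / pfm$n_windows
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)            # 2 - H
  sweep(p, 2L, ic, `*`)
}

#' Log-odds position weight matrix from a PFM
#'
#' Adds `pseudocount` to every cell and scores against a uniform 0.25
#' background, in bits.
#'
#' @param pfm a [build_pfm()] result.
#' @param pseudocount added to each count (default 1).
#' @return Object of class `pwm`: 4 x width matrix of log2 odds, with the
#'   PFM's `kind` attached.
#' @export
build_pwm <- function(pfm, pseudocount = 1) {
  stopifnot(inherits(pfm, "pfm"))
  p <- (pfm$counts + pseudocount) / (pfm$n_windows + 4 * pseudocount)
  m <- log2(p / 0.25)
  structure(m, class = c("pwm", class(m)), kind = pfm$kind)
}

# Best attainable score: per-position maximum.
pwm_consensus_score <- function(pwm) sum(apply(unclass(pwm), 2L, max))

#' Consensus string of a PWM
#'
#' The per-position highest-scoring base; its score is the maximum any
#' window can attain.
#'
#' @param pwm a [build_pwm()] matrix.
#' @return Character string of length `ncol(pwm)`.
#' @export
pwm_consensus_string <- function(pwm) {
  paste(rownames(pwm)[apply(unclass(pwm), 2L, which.max)], collapse = "")
}

#' Genome-wide splice-site profiling
#'
#' Convenience wrapper: load transcript models, extract junction windows,
#' build donor and acceptor PFMs and compute junction-motif fractions.
#'
#' @param annotation GFF3 path.
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param half_window bases each side of the junction (default 9).
#' @param motif junction motif for the fraction report (default `"CAGGT"`).
#' @param dedupe_introns count each genomic intron once rather than once per
#'   transcript in which it appears (default `FALSE`).
#' @param gtag_only restrict fractions to GT-AG introns (default `FALSE`).
#' @return List of class `splice_atlas`: `windows`, `donor_pfm`,
#'   `acceptor_pfm`, `donor_fraction`, `acceptor_fraction`, `n_transcripts`.
#' @export
profile_splice_sites <- function(annotation, genome, half_window = 9L,
                                 motif = "CAGGT", dedupe_introns = FALSE,
                                 gtag_only = FALSE) {
  genome <- as_genome(genome)
  models <- load_transcript_models(annotation, genome)
  windows <- extract_splice_windows(models, genome, half_window)
  if (dedupe_introns) {
    key <- with(windows, paste(kind, chrom, strand, intron_start, intron_end))
    windows <- windows[!duplicated(key), , drop = FALSE]
  }
  don <- windows[windows$kind == "donor", , drop = FALSE]
  acc <- windows[windows$kind == "acceptor", , drop = FALSE]
  structure(list(
    windows = windows,
    donor_pfm = build_pfm(don),
    acceptor_pfm = build_pfm(acc),
    donor_fraction = junction_motif_fraction(don, motif, gtag_only = gtag_only),
    acceptor_fraction = junction_motif_fraction(acc, motif, gtag_only = gtag_only),
    n_transcripts = length(models)
  ), class = "splice_atlas")
}

#' @export
print.splice_atlas <- function(x, ...) {
  cat(sprintf("Splice atlas: %d transcripts, %d donor / %d acceptor windows\n",
              x$n_transcripts, x$donor_pfm$n_windows, x$acceptor_pfm$n_windows))
  cat(sprintf("  junction motif fraction: donor %.1f%%, acceptor %.1f%%\n",
              100 * x$donor_fraction, 100 * x$acceptor_fraction))
  invisible(x)
}
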