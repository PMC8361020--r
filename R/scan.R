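#' Scan a CDS for candidate cryptic splice sites
#'
#' Slides the 18-base donor and acceptor PWMs over the sequence and reports
#' every position whose core dinucleotide holds (GT immediately after a donor
#' junction; AG immediately before an acceptor junction) and whose windowed
#' log-odds score reaches `min_score`. Scores are in bits against a uniform
#' background.
#'
#' @param cds a [cds_record()] or nucleotide string.
#' @param donor_pwm,acceptor_pwm [build_pwm()] matrices (18 positions,
#'   junction between positions 9 and 10).
#' @param min_score minimum score in bits; the default (`NULL`) uses each
#'   PWM's consensus score minus 6 bits.
#' @return data.frame of class `splice_candidates`: `kind`, `junction_pos`
#'   (0-based offset of the exon/intron boundary), `score`, `core` (the
#'   junction-spanning 5-mer, last 3 bases before + first 2 after the
#'   junction). Sorted by position. A CDS shorter than the window yields an
#'   empty result with a warning.
#' @export
scan_candidates <- function(cds, donor_pwm, acceptor_pwm, min_score = NULL) {
  record <- as_cds_record(cds)
  seq <- record$seq
  half <- ncol(donor_pwm) %/% 2L
  stopifnot(ncol(donor_pwm) == ncol(acceptor_pwm))
  empty <- data.frame(kind = character(), junction_pos = integer(),
                      score = numeric(), core = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < ncol(donor_pwm)) {
    warning("sequence shorter than the scoring window; no candidates",
            call. = FALSE)
    return(structure(empty, class = c("splice_candidates", "data.frame")))
  }
  don_min <- min_score %||% (pwm_consensus_score(donor_pwm) - 6)
  acc_min <- min_score %||% (pwm_consensus_score(acceptor_pwm) - 6)

  score_at <- function(pwm, junction_pos) {
    # window is [junction_pos - half, junction_pos + half), 0-based
    vapply(junction_pos, function(j) {
      win <- substr(seq, j - half + 1L, j + half)
      ri <- match(strsplit(win, "")[[1L]], rownames(pwm))
      if (anyNA(ri)) return(-Inf)
      sum(unclass(pwm)[cbind(ri, seq_along(ri))])
    }, 0)
  }
  core_at <- function(junction_pos) {
    substr(rep(seq, length(junction_pos)), junction_pos - 2L, junction_pos + 2L)
  }

  n <- nchar(seq)
  # donor: GT at [j, j+1]; window needs j in [half, n - half]
  gt <- gregexpr("GT", seq, fixed = TRUE)[[1L]]
  don_j <- if (gt[1L] == -1L) integer() else as.integer(gt) - 1L
  don_j <- don_j[don_j >= half & don_j <= n - half]
  don <- empty
  if (length(don_j)) {
    s <- score_at(donor_pwm, don_j)
    keep <- s >= don_min
    if (any(keep)) {
      don <- data.frame(kind = "donor", junction_pos = don_j[keep],
                        score = s[keep], core = core_at(don_j[keep]),
                        stringsAsFactors = FALSE)
    }
  }
  # acceptor: AG at [a-2, a-1]; same window bounds for a
  ag <- gregexpr("AG", seq, fixed = TRUE)[[1L]]
  acc_j <- if (ag[1L] == -1L) integer() else as.integer(ag) + 1L
  acc_j <- acc_j[acc_j >= half & acc_j <= n - half]
  acc <- empty
  if (length(acc_j)) {
    s <- score_at(acceptor_pwm, acc_j)
    keep <- s >= acc_min
    if (any(keep)) {
      acc <- data.frame(kind = "acceptor", junction_pos = acc_j[keep],
                        score = s[keep], core = core_at(acc_j[keep]),
                        stringsAsFactors = FALSE)
    }
  }
  out <- rbind(don, acc)
  out <- out[order(out$junction_pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("splice_candidates", "data.frame"))
}

#' Enumerate candidate cryptic introns from donor/acceptor pairs
#'
#' Pairs every donor with every downstream acceptor, applies length and GC
#' bounds, and ranks by combined score.
#'
#' @param cds a [cds_record()] or nucleotide string.
#' @param candidates a [scan_candidates()] result, or a data.frame with
#'   `kind`, `junction_pos`, `score`.
#' @param min_len minimum intron length in bases (default 50).
#' @param max_len optional maximum length.
#' @param max_gc optional maximum intron GC fraction.
#' @return data.frame of class `cryptic_introns`: `donor_pos`,
#'   `acceptor_pos` (half-open interval `[donor_pos, acceptor_pos)`),
#'   `length`, `gc`, `frame_preserving` (length divisible by 3), `score`
#'   (donor + acceptor bits), sorted by decreasing score.
#' @export
enumerate_cryptic_introns <- function(cds, candidates, min_len = 50L,
                                      max_len = NULL, max_gc = NULL) {
  record <- as_cds_record(cds)
  don <- candidates[candidates$kind == "donor", , drop = FALSE]
  acc <- candidates[candidates$kind == "acceptor", , drop = FALSE]
  out <- data.frame(donor_pos = integer(), acceptor_pos = integer(),
                    length = integer(), gc = numeric(),
                    frame_preserving = logical(), score = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(don) && nrow(acc)) {
    grid <- expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
    dpos <- don$junction_pos[grid$d]
    apos <- acc$junction_pos[grid$a]
    len <- apos - dpos
    keep <- len >= min_len
    if (!is.null(max_len)) keep <- keep & len <= max_len
    if (any(keep)) {
      dpos <- dpos[keep]; apos <- apos[keep]; len <- len[keep]
      gc <- vapply(seq_along(dpos), function(i) {
        gc_content(substr(record$seq, dpos[i] + 1L, apos[i]))
      }, 0)
      score <- don$score[grid$d[keep]] + acc$score[grid$a[keep]]
      out <- data.frame(donor_pos = dpos, acceptor_pos = apos, length = len,
                        gc = gc, frame_preserving = len %% 3L == 0L,
                        score = score, stringsAsFactors = FALSE)
      if (!is.null(max_gc)) out <- out[out$gc <= max_gc, , drop = FALSE]
      out <- out[order(-out$score), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, class = c("cryptic_introns", "data.frame"))
}

#' Remove introns from a sequence (in-silico splicing)
#'
#' @param cds a [cds_record()] or nucleotide string.
#' @param introns a `cryptic_introns` data.frame (rows must be
#'   non-overlapping), or a two-column matrix/data.frame of half-open
#'   `[donor_pos, acceptor_pos)` intervals.
#' @return The spliced nucleotide string; its length is the input length
#'   minus the summed intron lengths.
#' @export
splice_out <- function(cds, introns) {
  record <- as_cds_record(cds)
  if (is.null(introns) || !NROW(introns)) return(record$seq)
  d <- introns[["donor_pos"]] %||% introns[[1L]]
  a <- introns[["acceptor_pos"]] %||% introns[[2L]]
  o <- order(d)
  d <- as.integer(d[o]); a <- as.integer(a[o])
  n <- nchar(record$seq)
  if (any(d < 0L) || any(a > n) || any(a <= d)) stop("intron out of range")
  if (any(d[-1L] < a[-length(a)])) stop("overlapping introns")
  keep_start <- c(0L, a)            # 0-based starts of retained segments
  keep_end <- c(d, n)               # half-open ends
  nonempty <- keep_end > keep_start
  paste(substring(record$seq, keep_start[nonempty] + 1L, keep_end[nonempty]),
        collapse = "")
}

#' Characterize a spliced transcript variant
#'
#' Translates the variant, detects premature termination codons, computes
#' the average molecular mass of the (stop-truncated) protein product and
#' locates the splice junction at codon resolution.
#'
#' @param variant_seq the spliced nucleotide string (from [splice_out()]).
#' @param cds the originating CDS ([cds_record()] or string).
#' @param introns optional `cryptic_introns` rows used to produce the
#'   variant; when omitted, the junction is inferred from the longest common
#'   prefix of variant and CDS.
#' @return List of class `splice_variant`: `variant_seq`, `protein` (full
#'   translation, `*` at stops), `product` (translation truncated at the
#'   first stop), `has_ptc`, `mass_da`, `mass_kda`, `frame_preserving`,
#'   `deleted_aa` (frame-preserving case), `junction_codon_index` (0-based
#'   count of complete codons 5' of the first junction).
#' @export
characterize_variant <- function(variant_seq, cds, introns = NULL) {
  record <- as_cds_record(cds)
  variant_seq <- toupper(as.character(variant_seq))
  if (nchar(variant_seq) < 3L) stop("variant shorter than one codon")
  removed <- nchar(record$seq) - nchar(variant_seq)
  frame_preserving <- removed %% 3L == 0L

  junction_pos <- if (!is.null(introns) && NROW(introns)) {
    min(introns[["donor_pos"]] %||% introns[[1L]])
  } else {
    # longest common prefix with the unspliced CDS
    a <- strsplit(variant_seq, "")[[1L]]
    b <- strsplit(substr(record$seq, 1L, nchar(variant_seq)), "")[[1L]]
    diff <- which(a != b)
    if (length(diff)) diff[1L] - 1L else nchar(variant_seq)
  }

  usable <- nchar(variant_seq) - nchar(variant_seq) %% 3L
  protein <- translate_cds(substr(variant_seq, 1L, usable))
  aa <- strsplit(protein, "")[[1L]]
  stop_idx <- which(aa == "*")
  has_ptc <- length(stop_idx) > 0L && stop_idx[1L] < length(aa)
  product <- if (length(stop_idx)) {
    paste(aa[seq_len(stop_idx[1L] - 1L)], collapse = "")
  } else protein
  mass <- if (nzchar(product)) protein_mass(product) else 0
  structure(list(
    variant_seq = variant_seq,
    protein = protein,
    product = product,
    has_ptc = has_ptc,
    mass_da = mass,
    mass_kda = round(mass / 1000, 1L),
    frame_preserving = frame_preserving,
    deleted_aa = if (frame_preserving) removed %/% 3L else NA_integer_,
    junction_codon_index = junction_pos %/% 3L
  ), class = "splice_variant")
}

#' @export
print.splice_variant <- function(x, ...) {
  cat(sprintf("Splice variant: %d nt, product %d aa, %.1f kDa%s\n",
              nchar(x$variant_seq), nchar(x$product), x$mass_kda,
              if (x$has_ptc) " (premature termination codon)" else ""))
  invisible(x)
}
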