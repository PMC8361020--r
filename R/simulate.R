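# Deterministic synthetic-data generators. Every generator is a pure
# function of its arguments including the mandatory seed, so regeneration
# reproduces byte-identical outputs.

random_bases <- function(n, gc = 0.5) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# n random sense codons (no stops) at roughly the requested GC.
random_codons <- function(n, gc = 0.5) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      c3 <- paste(random_bases(3L, gc), collapse = "")
      if (!c3 %in% STOP_CODONS) break
    }
    out[i] <- c3
  }
  out
}

#' Generate a toy genome with planted splice sites
#'
#' Writes a single-chromosome genome FASTA and matching GFF3 in which every
#' intron follows the GT-AG rule and an exact, chosen fraction of donor
#' junctions carries the CAGGT junction 5-mer (exon-final CAG, intron
#' starting GTAAGT); the remaining donors keep the GT but not the CAG
#' context. All introns end in the canonical ...CAG acceptor. Genes are
#' split between the two strands.
#'
#' @param n_genes number of genes (default 100).
#' @param introns_per_gene introns in each gene (default 4).
#' @param donor_caggt_fraction fraction of donors to plant with CAGGT
#'   (default 0.23).
#' @param seed RNG seed (mandatory).
#' @param out_dir directory for `genome.fa` / `genes.gff3` (created if
#'   needed; default: fresh temporary directory).
#' @param exon_len,intron_len integer ranges to sample lengths from.
#' @param exonic_gc,intronic_gc background GC of exons (0.5) and introns
#'   (0.3).
#' @return List: `genome_fasta`, `gff3` (paths), `truth` (list with
#'   `donors` data.frame - `transcript_id`, `strand`, `intron_start`,
#'   `intron_end`, `planted` -, `n_donors`, `n_planted`, `fraction`,
#'   `seed`).
#' @export
make_toy_genome <- function(n_genes = 100L, introns_per_gene = 4L,
                            donor_caggt_fraction = 0.23, seed = 0L,
                            out_dir = NULL,
                            exon_len = c(60L, 120L), intron_len = c(80L, 200L),
                            exonic_gc = 0.5, intronic_gc = 0.3) {
  stopifnot(donor_caggt_fraction >= 0, donor_caggt_fraction <= 1,
            introns_per_gene >= 1L, n_genes >= 1L)
  if (min(exon_len) < 21L || min(intron_len) < 21L) {
    stop("exons and introns must exceed the junction window flanks")
  }
  out_dir <- out_dir %||% tempfile("toygenome")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(seed, {
    n_donors <- n_genes * introns_per_gene
    n_planted <- round(donor_caggt_fraction * n_donors)
    planted <- rep(FALSE, n_donors)
    planted[sample.int(n_donors, n_planted)] <- TRUE

    spacer_len <- 50L
    chrom_parts <- character()
    gff <- c("##gff-version 3")
    donor_rows <- list()
    offset <- 0L          # 0-based genomic offset of the next segment
    donor_idx <- 0L

    for (g in seq_len(n_genes)) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      n_exons <- introns_per_gene + 1L
      exons <- vapply(seq_len(n_exons), function(i) {
        paste(random_bases(sample(seq(exon_len[1L], exon_len[2L]), 1L),
                           exonic_gc), collapse = "")
      }, "")
      introns <- character(introns_per_gene)
      for (i in seq_len(introns_per_gene)) {
        donor_idx <- donor_idx + 1L
        len <- sample(seq(intron_len[1L], intron_len[2L]), 1L)
        body <- paste(random_bases(len - 12L, intronic_gc), collapse = "")
        intron5 <- if (planted[donor_idx]) "GTAAGT" else {
          paste0("GT", paste(random_bases(4L, intronic_gc), collapse = ""))
        }
        introns[i] <- paste0(intron5, body, "TTTCAG")
        # donor context: exon-final CAG exactly when planted
        ex <- exons[i]
        if (planted[donor_idx]) {
          substr(ex, nchar(ex) - 2L, nchar(ex)) <- "CAG"
        } else while (substr(ex, nchar(ex) - 2L, nchar(ex)) == "CAG") {
          substr(ex, nchar(ex) - 2L, nchar(ex)) <-
            paste(random_bases(3L, exonic_gc), collapse = "")
        }
        exons[i] <- ex
      }
      pieces <- character(0)
      for (i in seq_len(introns_per_gene)) {
        pieces <- c(pieces, exons[i], introns[i])
      }
      pieces <- c(pieces, exons[n_exons])
      tx_seq <- paste(pieces, collapse = "")
      L <- nchar(tx_seq)

      # transcript-coordinate exon intervals (0-based half-open)
      ex_starts <- integer(n_exons); ex_ends <- integer(n_exons)
      pos <- 0L
      for (i in seq_len(n_exons)) {
        ex_starts[i] <- pos
        pos <- pos + nchar(exons[i])
        ex_ends[i] <- pos
        if (i <= introns_per_gene) pos <- pos + nchar(introns[i])
      }

      gene_seq <- if (strand == "+") tx_seq else reverse_complement(tx_seq)
      to_genomic <- function(s, e) {
        if (strand == "+") c(offset + s, offset + e)
        else c(offset + L - e, offset + L - s)
      }
      gid <- sprintf("gene%d", g)
      tid <- sprintf("%s.t1", gid)
      gspan <- to_genomic(0L, L)
      gff <- c(gff,
               sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gspan[1L] + 1L, gspan[2L], strand, gid),
               sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gspan[1L] + 1L, gspan[2L], strand, tid, gid))
      for (i in seq_len(n_exons)) {
        es <- to_genomic(ex_starts[i], ex_ends[i])
        gff <- c(gff,
                 sprintf("chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         es[1L] + 1L, es[2L], strand, tid, i, tid))
      }
      first_planted <- donor_idx - introns_per_gene
      for (i in seq_len(introns_per_gene)) {
        ispan <- to_genomic(ex_ends[i], ex_starts[i + 1L])
        donor_rows[[length(donor_rows) + 1L]] <- data.frame(
          transcript_id = tid, strand = strand,
          intron_start = min(ispan), intron_end = max(ispan),
          planted = planted[first_planted + i], stringsAsFactors = FALSE)
      }
      chrom_parts <- c(chrom_parts, gene_seq,
                       paste(random_bases(spacer_len, 0.5), collapse = ""))
      offset <- offset + L + spacer_len
    }

    genome_fasta <- file.path(out_dir, "genome.fa")
    gff3 <- file.path(out_dir, "genes.gff3")
    chrom <- paste(chrom_parts, collapse = "")
    ss <- Biostrings::DNAStringSet(chrom)
    names(ss) <- "chr1"
    Biostrings::writeXStringSet(ss, genome_fasta, width = 70L)
    writeLines(gff, gff3)
    donors <- do.call(rbind, donor_rows)
    list(genome_fasta = genome_fasta, gff3 = gff3,
         truth = list(donors = donors, n_donors = n_donors,
                      n_planted = n_planted,
                      fraction = n_planted / n_donors, seed = seed))
  })
}

#' Generate a CDS with one planted cryptic intron
#'
#' Builds a valid ORF (ATG start, terminal stop, no internal in-frame stop
#' codons) that contains one GT-AG intron with consensus context: the donor
#' sits at a codon boundary with exon-final CAG and intron-initial GTAAGT,
#' and the intron ends in TTTCAG. Full 18-base junction windows (e.g. the
#' consensus strings of genome-derived PWMs) can be planted instead via
#' `donor_context`/`acceptor_context`; bases of a planted context are only
#' modified when an in-frame stop codon cannot be repaired anywhere else
#' (the GT/AG cores themselves are never touched). The intron body's GC
#' content is adjusted to within 2 percentage points of `intron_gc`.
#'
#' @param cds_len total CDS length in nt including the intron (divisible by
#'   3; default 900).
#' @param intron_len intron length in nt (default 132, frame-preserving).
#' @param intron_gc target GC fraction of the intron (default 0.39).
#' @param seed RNG seed (mandatory).
#' @param exonic_gc GC of the exonic portion (default 0.5).
#' @param donor_context optional 18-base window (9 exonic + 9 intronic,
#'   `GT` at positions 10-11) written around the donor junction.
#' @param acceptor_context optional 18-base window (9 intronic + 9 exonic,
#'   `AG` at positions 8-9) written around the acceptor junction.
#' @return List: `record` (a [cds_record()]), `truth` (list `donor_pos`,
#'   `acceptor_pos` - 0-based junction offsets -, `intron_len`, `intron_gc`
#'   as realized, `frame_preserving`, `seed`).
#' @export
make_cds_with_cryptic_intron <- function(cds_len = 900L, intron_len = 132L,
                                         intron_gc = 0.39, seed = 0L,
                                         exonic_gc = 0.5,
                                         donor_context = NULL,
                                         acceptor_context = NULL) {
  stopifnot(cds_len %% 3L == 0L, intron_len >= 30L)
  if (intron_len >= cds_len - 60L) {
    stop("intron too long for the requested CDS length")
  }
  if (intron_gc < 0.1 || intron_gc > 0.9) stop("infeasible intron GC target")
  check_context <- function(ctx, core, at) {
    if (is.null(ctx)) return(NULL)
    ctx <- toupper(ctx)
    stopifnot(nchar(ctx) == 18L, grepl("^[ACGT]+$", ctx))
    if (substr(ctx, at, at + 1L) != core) {
      stop("context must carry ", core, " at positions ", at, "-", at + 1L)
    }
    ctx
  }
  donor_context <- check_context(donor_context, "GT", 10L)
  acceptor_context <- check_context(acceptor_context, "AG", 8L)

  with_seed(seed, {
    exonic_total <- cds_len - intron_len
    # donor at a codon boundary, roughly the middle of the exonic part
    donor_pos <- (exonic_total %/% 2L) %/% 3L * 3L
    donor_pos <- max(donor_pos, 21L)
    acceptor_pos <- donor_pos + intron_len

    exon1 <- c("ATG", random_codons(donor_pos %/% 3L - 2L, exonic_gc), "CAG")
    # the second exon need not start on a codon boundary (non-frame-
    # preserving introns shift it); build it base-wise with the terminal
    # stop aligned to the global reading frame
    exon2_len <- cds_len - acceptor_pos
    exon2 <- c(random_bases(exon2_len - 3L, exonic_gc), "TAA")

    intron <- paste0("GTAAGT",
                     paste(random_bases(intron_len - 12L, intron_gc),
                           collapse = ""),
                     "TTTCAG")
    seq <- paste0(paste(exon1, collapse = ""), intron,
                  paste(exon2, collapse = ""))
    stopifnot(nchar(seq) == cds_len)
    b <- strsplit(seq, "")[[1L]]

    # plant full junction windows when contexts are supplied
    if (!is.null(donor_context)) {
      b[seq(donor_pos - 8L, donor_pos + 9L)] <- strsplit(donor_context, "")[[1L]]
    }
    if (!is.null(acceptor_context)) {
      b[seq(acceptor_pos - 8L, acceptor_pos + 9L)] <-
        strsplit(acceptor_context, "")[[1L]]
    }

    # the GT/AG cores are inviolable; the rest of a planted context is
    # soft-protected (edited only as a last resort during stop repair)
    hard <- c(donor_pos + 1L, donor_pos + 2L, acceptor_pos - 1L, acceptor_pos)
    soft <- c(seq(donor_pos - 2L, donor_pos + 6L),
              seq(acceptor_pos - 5L, acceptor_pos))
    if (!is.null(donor_context)) {
      soft <- c(soft, seq(donor_pos - 8L, donor_pos + 9L))
    }
    if (!is.null(acceptor_context)) {
      soft <- c(soft, seq(acceptor_pos - 8L, acceptor_pos + 9L))
    }
    soft <- setdiff(unique(soft), hard)
    protected <- c(hard, soft)
    codon_of <- function(p) (p - 1L) %/% 3L + 1L
    makes_stop <- function(p, base) {
      old <- b[p]; b[p] <<- base
      ci <- codon_of(p)
      span <- (3L * (ci - 1L) + 1L):(3L * ci)
      bad <- ci < cds_len %/% 3L &&
        paste(b[span], collapse = "") %in% STOP_CODONS
      if (bad) b[p] <<- old
      bad
    }

    # repair in-frame stop codons introduced by the intron body
    repeat {
      codons <- codon_split(paste(b, collapse = ""))
      bad <- which(codons[-length(codons)] %in% STOP_CODONS)
      if (!length(bad)) break
      fixed_any <- FALSE
      for (ci in bad) {
        span <- (3L * (ci - 1L) + 1L):(3L * ci)
        candidates <- c(setdiff(span, protected), intersect(span, soft))
        done <- FALSE
        for (p in candidates) {
          for (base in c("C", "G", "A", "T")) {
            if (!makes_stop(p, base)) { done <- TRUE; break }
          }
          if (done) break
        }
        if (done) fixed_any <- TRUE
      }
      if (!fixed_any) stop("could not remove in-frame stop codons")
    }

    # nudge the intron's GC to the target without re-creating stops
    intron_pos <- seq(donor_pos + 1L, acceptor_pos)
    free <- setdiff(seq(donor_pos + 7L, acceptor_pos - 6L), protected)
    for (step in seq_len(8L * intron_len)) {
      gc <- mean(b[intron_pos] %in% c("G", "C"))
      if (abs(gc - intron_gc) <= 0.015) break
      if (gc < intron_gc) {
        cand <- free[b[free] %in% c("A", "T")]
        repl <- c("G", "C")
      } else {
        cand <- free[b[free] %in% c("G", "C")]
        repl <- c("A", "T")
      }
      if (!length(cand)) stop("infeasible GC target")
      p <- sample(cand, 1L)
      for (base in sample(repl)) if (!makes_stop(p, base)) break
    }
    realized_gc <- mean(b[intron_pos] %in% c("G", "C"))
    if (abs(realized_gc - intron_gc) > 0.02) stop("infeasible GC target")
    seq <- paste(b, collapse = "")
    list(record = cds_record(seq, id = "synthetic_cds"),
         truth = list(donor_pos = donor_pos, acceptor_pos = acceptor_pos,
                      intron_len = intron_len, intron_gc = realized_gc,
                      frame_preserving = intron_len %% 3L == 0L,
                      seed = seed))
  })
}

#' Generate a synthetic fluorescence voxel stack with known foreground
#'
#' Plants a foreground region (a centred cube, a diffuse blob field, or a
#' thin network of random filaments) of mean intensity `fg_mean` on a dim
#' background, with Gaussian noise and an optional multiplicative intensity
#' gradient along X, and records the ground-truth mask and foreground mean.
#'
#' @param shape stack dimensions (Z, Y, X), default `c(16, 48, 48)`.
#' @param pattern `"cube"`, `"diffuse"` or `"network"`.
#' @param fg_mean mean foreground intensity; must exceed `bg_mean`.
#' @param noise_sd Gaussian background noise SD (default 0.5; 0 for
#'   noise-free).
#' @param fg_noise_sd Gaussian noise SD on foreground voxels (defaults to
#'   `noise_sd`).
#' @param gradient_amp relative amplitude of a linear intensity gradient
#'   along X (default 0).
#' @param seed RNG seed (mandatory).
#' @param bg_mean mean background intensity (default 0.5).
#' @return List: `stack` (a [voxel_stack()]), `truth` (list `mask`,
#'   `fg_mean` as realized, `n_foreground`, `seed`).
#' @export
make_synthetic_stack <- function(shape = c(16L, 48L, 48L),
                                 pattern = c("cube", "diffuse", "network"),
                                 fg_mean = 100, noise_sd = 0.5,
                                 gradient_amp = 0, seed = 0L, bg_mean = 0.5,
                                 fg_noise_sd = noise_sd) {
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), fg_mean > bg_mean)

  with_seed(seed, {
    mask <- array(FALSE, shape)
    if (pattern == "cube") {
      side <- pmax(3L, shape %/% 2L)
      lo <- (shape - side) %/% 2L + 1L
      hi <- lo + side - 1L
      mask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- TRUE
    } else if (pattern == "diffuse") {
      field <- array(stats::runif(prod(shape)), shape)
      field <- box_mean3(field, c(5L, 5L, 5L))
      mask <- field > stats::quantile(field, 0.9)
    } else {
      n_fil <- 6L
      for (f in seq_len(n_fil)) {
        pos <- pmax(2L, pmin(shape - 1L,
                             c(sample(shape[1L], 1L), sample(shape[2L], 1L),
                               sample(shape[3L], 1L))))
        for (s in seq_len(10L * max(shape))) {
          mask[pos[1L], pos[2L], pos[3L]] <- TRUE
          mask[pos[1L], pmin(pos[2L] + 1L, shape[2L]), pos[3L]] <- TRUE
          mask[pos[1L], pos[2L], pmin(pos[3L] + 1L, shape[3L])] <- TRUE
          pos <- pos + sample(c(-1L, 0L, 1L), 3L, replace = TRUE,
                              prob = c(0.3, 0.4, 0.3))
          if (any(pos < 2L) || any(pos > shape - 1L)) break
        }
      }
    }
    values <- array(bg_mean, shape)
    if (noise_sd > 0 || fg_noise_sd > 0) {
      noise <- stats::rnorm(prod(shape))
      values <- values + noise_sd * noise
      values[mask] <- fg_mean + fg_noise_sd * noise[mask]
    } else {
      values[mask] <- fg_mean
    }
    if (gradient_amp != 0) {
      xw <- 1 + gradient_amp * (seq_len(shape[3L]) - (shape[3L] + 1) / 2) /
        shape[3L]
      values <- sweep(values, 3L, xw, `*`)
    }
    values[values < 0] <- 0
    list(stack = voxel_stack(values),
         truth = list(mask = mask, fg_mean = mean(values[mask]),
                      n_foreground = sum(mask), seed = seed))
  })
}
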