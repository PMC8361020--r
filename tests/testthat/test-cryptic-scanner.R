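test_that("scanning finds planted donor/acceptor sites with brute-force scores", {
  pwms <- toy_pwms_fx()
  fx <- consensus_cds_fx()
  cand <- scan_candidates(fx$record, pwms$donor, pwms$acceptor)
  don <- cand[cand$kind == "donor", ]
  acc <- cand[cand$kind == "acceptor", ]
  expect_true(fx$truth$donor_pos %in% don$junction_pos)
  expect_true(fx$truth$acceptor_pos %in% acc$junction_pos)
  expect_identical(don$core[don$junction_pos == fx$truth$donor_pos], "CAGGT")
  # GT/AG core invariants
  seq <- fx$record$seq
  expect_true(all(substr(rep(seq, nrow(don)), don$junction_pos + 1L,
                         don$junction_pos + 2L) == "GT"))
  expect_true(all(substr(rep(seq, nrow(acc)), acc$junction_pos - 1L,
                         acc$junction_pos) == "AG"))

  # brute-force log-odds: sum of log2(p/0.25) from PFM counts + pseudocount
  atlas <- toy_atlas_fx()
  p <- (atlas$donor_pfm$counts + 1) / (atlas$donor_pfm$n_windows + 4)
  j <- fx$truth$donor_pos
  win <- strsplit(substr(seq, j - 8L, j + 9L), "")[[1L]]
  brute <- sum(vapply(seq_along(win),
                      function(k) log2(p[win[k], k] / 0.25), 0))
  expect_equal(don$score[don$junction_pos == j], brute)
})

test_that("sequences without GT or shorter than the window yield no donors", {
  pwms <- toy_pwms_fx()
  expect_warning(res <- scan_candidates("ATGGCA", pwms$donor, pwms$acceptor),
                 regexp = "shorter")
  expect_identical(nrow(res), 0L)
  gc_rich <- paste(rep("GGCACC", 20L), collapse = "")
  cand <- scan_candidates(gc_rich, pwms$donor, pwms$acceptor, min_score = -100)
  expect_false(any(cand$kind == "donor" &
                   substr(rep(gc_rich, nrow(cand)), cand$junction_pos + 1L,
                          cand$junction_pos + 2L) != "GT"))
  no_gt <- paste(rep("CAC", 30L), collapse = "")
  cand2 <- scan_candidates(no_gt, pwms$donor, pwms$acceptor, min_score = -100)
  expect_identical(sum(cand2$kind == "donor"), 0L)
})

test_that("intron enumeration equals brute force over all candidate pairs", {
  cds <- paste(rep("A", 400L), collapse = "")
  cand <- data.frame(
    kind = c("donor", "donor", "acceptor", "acceptor"),
    junction_pos = c(30L, 90L, 200L, 320L),
    score = c(8, 7, 9, 6), core = "NNNNN", stringsAsFactors = FALSE)
  introns <- enumerate_cryptic_introns(cds, cand, min_len = 50L)
  expect_identical(nrow(introns), 4L)   # all 2 x 2 pairings are valid
  brute <- expand.grid(d = c(30L, 90L), a = c(200L, 320L))
  expect_setequal(paste(introns$donor_pos, introns$acceptor_pos),
                  paste(brute$d, brute$a))
  expect_true(all(diff(introns$score) <= 0))   # sorted by combined score

  # acceptor upstream of the donor is excluded
  up <- data.frame(kind = c("donor", "acceptor"),
                   junction_pos = c(200L, 100L), score = 1,
                   core = "NNNNN", stringsAsFactors = FALSE)
  expect_identical(nrow(enumerate_cryptic_introns(cds, up)), 0L)

  # 40-base spacing fails the 50-base minimum
  close <- data.frame(kind = c("donor", "acceptor"),
                      junction_pos = c(100L, 140L), score = 1,
                      core = "NNNNN", stringsAsFactors = FALSE)
  expect_identical(nrow(enumerate_cryptic_introns(cds, close, min_len = 50L)),
                   0L)
  expect_identical(nrow(enumerate_cryptic_introns(cds, close, min_len = 40L)),
                   1L)

  # GC ceiling filters introns
  gc_cds <- paste0(strrep("A", 100L), strrep("GC", 60L), strrep("A", 100L))
  pair <- data.frame(kind = c("donor", "acceptor"),
                     junction_pos = c(100L, 220L), score = 1,
                     core = "NNNNN", stringsAsFactors = FALSE)
  expect_identical(nrow(enumerate_cryptic_introns(gc_cds, pair, max_gc = 0.5)),
                   0L)
})

test_that("in-silico splicing concatenates retained segments exactly", {
  cds <- paste0("ATGCTTCAG", "GTAAGTCCCTTTCAG", "GGATGA")
  expect_identical(splice_out(cds, data.frame(donor_pos = 9L,
                                              acceptor_pos = 24L)),
                   "ATGCTTCAGGGATGA")
  expect_identical(splice_out(cds, NULL), cds)
  expect_identical(splice_out(cds, data.frame(donor_pos = integer(),
                                              acceptor_pos = integer())), cds)
  expect_error(splice_out(cds, data.frame(donor_pos = c(5L, 10L),
                                          acceptor_pos = c(12L, 20L))),
               regexp = "overlapping")
  expect_error(splice_out(cds, data.frame(donor_pos = 9L,
                                          acceptor_pos = 99L)),
               regexp = "range")
})

test_that("splice_out conserves length over random intron sets", {
  set.seed(202)
  for (i in seq_len(1000L)) {
    n <- sample(120:600, 1L)
    cds <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    k <- sample(1:3, 1L)
    cuts <- sort(sample(seq_len(n - 1L), 2L * k))
    introns <- data.frame(donor_pos = cuts[seq(1L, 2L * k, 2L)],
                          acceptor_pos = cuts[seq(2L, 2L * k, 2L)])
    out <- splice_out(cds, introns)
    expect_identical(nchar(out),
                     n - sum(introns$acceptor_pos - introns$donor_pos))
  }
})

test_that("variant characterization translates, truncates and weighs products", {
  v <- characterize_variant("ATGCTTCAGGGATGA", "ATGCTTCAGGTAAGTCCCTTTCAGGGATGA")
  expect_identical(v$product, "MLQG")
  expect_false(v$has_ptc)
  expect_true(v$frame_preserving)
  expect_identical(v$deleted_aa, 5L)

  ptc <- characterize_variant("ATGTAAAAAAAAAAAAAAAAAAAAAAAAAAATAA",
                              paste0("ATGTAAAAAAAAAAAAAAAAAAAAAAAAAAATAA",
                                     "AAA"))
  expect_true(ptc$has_ptc)
  expect_identical(ptc$product, "M")

  expect_error(characterize_variant("AT", "ATGAAATAG"), regexp = "codon")

  # frame classification follows intron length arithmetic
  fx <- planted_cds_fx()
  shift <- splice_out(fx$record$seq,
                      data.frame(donor_pos = fx$truth$donor_pos,
                                 acceptor_pos = fx$truth$acceptor_pos + 2L))
  vs <- characterize_variant(shift, fx$record)
  expect_false(vs$frame_preserving)
})

test_that("average protein mass matches residue bookkeeping", {
  expect_equal(protein_mass("G"), 75.07, tolerance = 1e-4)
  expect_error(protein_mass(""), regexp = "empty")
  expect_error(protein_mass("AZ"), regexp = "non-standard")
  # water bookkeeping: mass(x) + mass(y) == mass(xy) + one water
  set.seed(31)
  aas <- names(hskit:::AVERAGE_RESIDUE_MASS)
  for (i in seq_len(25L)) {
    x <- paste(sample(aas, sample(3:30, 1L), replace = TRUE), collapse = "")
    y <- paste(sample(aas, sample(3:30, 1L), replace = TRUE), collapse = "")
    expect_equal(protein_mass(x) + protein_mass(y),
                 protein_mass(paste0(x, y)) + 18.02, tolerance = 0.01)
  }
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_identical(digest_trypsin("MKRGPR"), c("MK", "R", "GPR"))
  expect_identical(digest_trypsin("AKPR"), "AKPR")
  expect_identical(digest_trypsin(""), character())

  # an AKP context keeps the junction peptide in one piece
  prot <- "MRVVGGEDAKPGEHNIEETEHTEQKRSTV"
  pep <- digest_trypsin(prot)
  expect_true("VVGGEDAKPGEHNIEETEHTEQK" %in% pep)
  pep1 <- digest_trypsin(prot, missed_cleavages = 1L)
  expect_true("VVGGEDAKPGEHNIEETEHTEQKR" %in% pep1)

  # concatenation identity and missed-cleavage bound over random proteins
  set.seed(77)
  aas <- names(hskit:::AVERAGE_RESIDUE_MASS)
  for (i in seq_len(1000L)) {
    prot <- paste(sample(aas, sample(5:80, 1L), replace = TRUE),
                  collapse = "")
    base <- digest_trypsin(prot)
    expect_identical(paste(base, collapse = ""), prot)
    k <- sample(0:2, 1L)
    for (p in digest_trypsin(prot, missed_cleavages = k)) {
      aa <- strsplit(p, "")[[1L]]
      m <- length(aa)
      n_internal <- if (m < 2L) 0L else
        sum(aa[-m] %in% c("K", "R") & aa[-1L] != "P")
      expect_lte(n_internal, k)
    }
  }
})

test_that("junction peptides straddle the splice point or are absent", {
  fx <- planted_cds_fx()
  introns <- data.frame(donor_pos = fx$truth$donor_pos,
                        acceptor_pos = fx$truth$acceptor_pos)
  v <- characterize_variant(splice_out(fx$record$seq, introns),
                            fx$record, introns)
  jp <- junction_peptides(v)
  b <- v$junction_codon_index
  peps <- digest_trypsin(v$product)
  starts <- cumsum(c(1L, head(nchar(peps), -1L)))
  spanning <- peps[starts <= b & starts + nchar(peps) - 1L >= b + 1L]
  expect_setequal(jp, spanning)

  # junction exactly at a cleavage boundary -> no spanning peptide
  cdsK <- paste0("ATGAAG", "GTAAGTCCCTTTCAGTTTCCCAAGTTTCAG", "GGCTGCTGA")
  vK <- characterize_variant(
    splice_out(cdsK, data.frame(donor_pos = 6L, acceptor_pos = 36L)),
    cdsK, data.frame(donor_pos = 6L, acceptor_pos = 36L))
  expect_identical(vK$junction_codon_index, 2L)
  expect_length(junction_peptides(vK), 0L)

  # full-length product has no junction
  full <- characterize_variant(fx$record$seq, fx$record)
  expect_length(junction_peptides(full), 0L)

  # frameshifted variants have no protein-level junction
  shift <- splice_out(fx$record$seq,
                      data.frame(donor_pos = fx$truth$donor_pos,
                                 acceptor_pos = fx$truth$acceptor_pos + 1L))
  vs <- characterize_variant(shift, fx$record)
  expect_error(junction_peptides(vs), regexp = "frameshift")
})

test_that("planted introns are recovered and ranked first by score", {
  pwms <- toy_pwms_fx()
  for (seed in c(3L, 13L, 23L)) {
    fx <- consensus_cds_fx(seed = seed)
    cand <- scan_candidates(fx$record, pwms$donor, pwms$acceptor)
    introns <- enumerate_cryptic_introns(fx$record, cand, min_len = 50L)
    expect_gt(nrow(introns), 0L)
    expect_identical(introns$donor_pos[1L], fx$truth$donor_pos)
    expect_identical(introns$acceptor_pos[1L], fx$truth$acceptor_pos)
    expect_true(all(introns$frame_preserving == (introns$length %% 3L == 0L)))
    # deleting the planted frame-preserving intron removes length/3 residues
    v <- characterize_variant(splice_out(fx$record$seq, introns[1L, ]),
                              fx$record, introns[1L, ])
    expect_identical(v$deleted_aa, 44L)
  }
})
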