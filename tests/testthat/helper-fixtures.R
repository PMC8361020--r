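# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_genome_fx <- function() {
  cached("toy_genome", make_toy_genome(n_genes = 40L, introns_per_gene = 3L,
                                       donor_caggt_fraction = 0.23, seed = 11L))
}

toy_atlas_fx <- function() {
  cached("toy_atlas", {
    g <- toy_genome_fx()
    profile_splice_sites(g$gff3, g$genome_fasta)
  })
}

toy_pwms_fx <- function() {
  cached("toy_pwms", {
    atlas <- toy_atlas_fx()
    list(donor = build_pwm(atlas$donor_pfm),
         acceptor = build_pwm(atlas$acceptor_pfm))
  })
}

planted_cds_fx <- function() {
  cached("planted_cds",
         make_cds_with_cryptic_intron(cds_len = 900L, intron_len = 132L,
                                      intron_gc = 0.39, seed = 3L))
}

# planted intron whose 18-base junction contexts equal the toy genome's
# PWM consensus strings
consensus_cds_fx <- function(seed = 3L) {
  pwms <- toy_pwms_fx()
  make_cds_with_cryptic_intron(
    cds_len = 900L, intron_len = 132L, intron_gc = 0.39, seed = seed,
    donor_context = pwm_consensus_string(pwms$donor),
    acceptor_context = pwm_consensus_string(pwms$acceptor))
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

# Random structurally valid CDS: ATG + sense codons + stop.
random_valid_cds <- function(n_codons) {
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

# A complete synthetic 64-codon usage table with distinct random frequencies.
random_full_table <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  codon_usage_table(stats::setNames(round(stats::runif(64, 1, 40), 1), codons),
                    species_label = "synthetic", complete = TRUE)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
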