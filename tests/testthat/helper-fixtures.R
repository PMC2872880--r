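# In-code fixture builders shared across test files, plus a session cache
# of the full simulated bundle (generated once per test run).

# a single-exon-context genome: one chromosome whose bases are fully
# under our control
toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

toy_exon <- function(chrom = "chr1", strand = "+", start, end,
                     intron_up = 300L, intron_down = 300L, phase = 0L,
                     internal = TRUE, transcript_id = "t1",
                     exon_rank = 2L) {
  data.frame(transcript_id = transcript_id, exon_rank = exon_rank,
             chrom = chrom, strand = strand, start = start, end = end,
             intron_up = intron_up, intron_down = intron_down,
             internal = internal, phase = phase,
             length = end - start + 1L, stringsAsFactors = FALSE)
}

toy_variant <- function(chrom = "chr1", pos, wt, alt, id = "v1") {
  data.frame(chrom = chrom, pos = pos, allele_a = wt, allele_b = alt,
             ancestral = wt, derived = alt, id = id,
             stringsAsFactors = FALSE)
}

# genome with one internal exon at known coordinates; exon sequence and
# flanks caller-controlled
toy_locus <- function(exon_seq, up_intron, down_intron, strand = "+",
                      phase = 0L) {
  pad <- strrep("A", 10)
  if (strand == "+") {
    chrom_seq <- paste0(pad, up_intron, exon_seq, down_intron, pad)
    start <- nchar(pad) + nchar(up_intron) + 1L
  } else {
    chrom_seq <- paste0(pad, o_revcomp(down_intron), o_revcomp(exon_seq),
                        o_revcomp(up_intron), pad)
    start <- nchar(pad) + nchar(down_intron) + 1L
  }
  end <- start + nchar(exon_seq) - 1L
  list(genome = toy_genome(chr1 = chrom_seq),
       exon = toy_exon(strand = strand, start = start, end = end,
                       intron_up = nchar(up_intron),
                       intron_down = nchar(down_intron), phase = phase))
}

# variant context on a toy locus; off0 = 0-based offset in the exon,
# transcript orientation; alt in transcript orientation
toy_ctx <- function(exon_seq, off0, alt, up_intron = strrep("T", 60),
                    down_intron = strrep("T", 60), strand = "+",
                    phase = 0L, flank = 5L, intron_extent = 50L) {
  loc <- toy_locus(exon_seq, up_intron, down_intron, strand, phase)
  pos <- if (strand == "+") loc$exon$start + off0 else loc$exon$end - off0
  wt_tx <- substr(exon_seq, off0 + 1, off0 + 1)
  wt_g <- if (strand == "-") chartr("ACGT", "TGCA", wt_tx) else wt_tx
  alt_g <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
  v <- toy_variant(pos = pos, wt = wt_g, alt = alt_g)
  extract_context(loc$genome, loc$exon, v, flank = flank,
                  intron_extent = intron_extent)
}

# session-cached full fixture bundle (deterministic, seed 202)
.fx_env <- new.env(parent = emptyenv())
fixtures_once <- function() {
  if (!is.null(.fx_env$bundle)) return(.fx_env$bundle)
  dir <- file.path(tempdir(), "savscan-fixtures")
  manifest <- simulate_fixtures(dir, seed = 202L)
  genome <- load_genome(file.path(dir, "genome.fa"))
  exons <- read_exon_models(file.path(dir, "exons.bed"))
  .fx_env$bundle <- list(
    dir = dir, manifest = manifest, genome = genome, exons = exons,
    set = load_motif_set(file.path(dir, "toyESR.tsv"), k = 6),
    set_oct = load_motif_set(file.path(dir, "toyPESX.tsv"), k = 8),
    pwms = load_pwm_set(file.path(dir, "pwm.txt")),
    model = read_splice_model(file.path(dir, "splice_model.txt")),
    maf = read_maf(file.path(dir, "alignments.maf")),
    bias = read_bias(file.path(dir, "bias.tsv")),
    sav = read_variants(file.path(dir, "sav_variants.tsv")),
    ctl = read_variants(file.path(dir, "control_variants.tsv")),
    ect = read_variants(file.path(dir, "ectopic_variants.tsv")))
  .fx_env$bundle
}
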