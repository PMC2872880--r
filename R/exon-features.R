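# Exon-definition features: ESR densities within exons and intron flanks,
# the six-section variant position, natural splice-site strengths, the
# junction occupancy profile, and the exon-length / SNP-probability model.

#' ESR density of a sequence
#'
#' Sliding k-mer windows across the sequence; density per label =
#' (windows carrying that label) / (total windows, `L - k + 1`). Windows
#' never cross the sequence ends.
#'
#' @param set an [esr_motif_set()].
#' @param sequence DNA string of length `>= set$k`.
#' @return named numeric vector with `ese`, `ess` (and `esr` for
#'   unlabeled sets) densities in `[0, 1]`; `NA` with attribute
#'   `unscored` when the sequence is shorter than `k`.
#' @export
esr_density <- function(set, sequence) {
  stopifnot(inherits(set, "esr_motif_set"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  k <- set$k
  if (L < k) {
    out <- c(ese = NA_real_, ess = NA_real_, esr = NA_real_)
    attr(out, "unscored") <- TRUE
    return(out)
  }
  starts <- 1L:(L - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  scorable <- !grepl("[^ACGT]", kmers)
  lab <- rep("NEUTRAL", length(kmers))
  lab[scorable] <- classify_nmer(set, kmers[scorable])
  nw <- length(starts)
  c(ese = sum(lab == "ESE") / nw,
    ess = sum(lab == "ESS") / nw,
    esr = sum(lab == "UNLABELED_ESR") / nw)
}

#' Summed ESEFinder-style PWM density
#'
#' Each matrix's density (threshold-crossing windows / total windows for
#' that width) is computed separately and the four densities are summed.
#'
#' @param pwms a [pwm_set()].
#' @param sequence DNA string.
#' @return the summed density (can exceed 1 across matrices); `NA` when
#'   the sequence is shorter than every matrix.
#' @export
esefinder_density <- function(pwms, sequence) {
  stopifnot(inherits(pwms, "pwm_set"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  total <- 0
  any_scored <- FALSE
  hits <- scan_pwm_hits(pwms, sequence)
  for (m in pwms$matrices) {
    w <- ncol(m$weights)
    if (L < w) next
    any_scored <- TRUE
    nw <- L - w + 1L
    total <- total + sum(hits$motif_name == m$motif_name) / nw
  }
  if (!any_scored) NA_real_ else total
}

#' ESR densities of the 100-bp intron flanks of an exon
#'
#' Densities on intronic positions 3..102 from each junction (the
#' conserved GT/AG splice-site dinucleotides are excluded), transcript
#' orientation. Exons with either flanking intron shorter than 102 bp
#' are excluded.
#'
#' @param set an [esr_motif_set()].
#' @param genome a [load_genome()] result.
#' @param exon one exon-model row.
#' @param flank_bp intronic bases scored per side (default 100).
#' @return list with `excluded` flag and, when scored, `upstream` /
#'   `downstream` density vectors (as [esr_density()]).
#' @export
intron_flank_density <- function(set, genome, exon, flank_bp = 100L) {
  stopifnot(nrow(exon) == 1L)
  need <- flank_bp + 2L  # dinucleotide + flank
  if (is.na(exon$intron_up) || is.na(exon$intron_down) ||
      exon$intron_up < need || exon$intron_down < need)
    return(list(excluded = TRUE, reason = "FLANK_TOO_SHORT"))
  minus <- exon$strand == "-"
  if (!minus) {
    up <- genome_seq(genome, exon$chrom, exon$start - need, exon$start - 3L)
    dn <- genome_seq(genome, exon$chrom, exon$end + 3L, exon$end + need)
  } else {
    up <- revcomp(genome_seq(genome, exon$chrom, exon$end + 3L, exon$end + need))
    dn <- revcomp(genome_seq(genome, exon$chrom, exon$start - need, exon$start - 3L))
  }
  list(excluded = FALSE,
       upstream = esr_density(set, up),
       downstream = esr_density(set, dn))
}

#' Six-section position of a variant within its exon
#'
#' The exon is divided into six equal parts; the section is
#' `floor(6 * offset / length) + 1` (half-open bins, clamped to 6).
#' Sections 1 and 6 are the peripheral sections.
#'
#' @param exon one exon-model row.
#' @param pos genomic position of the variant (1-based, inside the exon).
#' @return list with `section` (1-6) and `peripheral` (logical).
#' @export
exon_position_section <- function(exon, pos) {
  stopifnot(nrow(exon) == 1L)
  if (pos < exon$start || pos > exon$end)
    stop("position ", pos, " outside exon ", exon$start, "-", exon$end)
  offset <- if (exon$strand == "-") exon$end - pos else pos - exon$start
  section <- min(6L, floor(6L * offset / exon$length) + 1L)
  list(section = as.integer(section), peripheral = section %in% c(1L, 6L))
}

#' Expected exon-length distribution of SNP-containing exons
#'
#' `fr(n) = pSNP * obs(n)` per exon length `n`, with `pSNP` the per-base
#' SNP probability and `obs(n)` the observed exon-length histogram.
#' `length_weighted = TRUE` switches to `fr(n) = pSNP * n * obs(n)`,
#' which models the per-exon probability of containing a SNP growing
#' with exon length.
#'
#' @param exon_lengths integer vector of exon lengths.
#' @param p_snp per-base SNP probability (default 0.001).
#' @param range lengths considered (default 20..1000).
#' @param length_weighted use the length-weighted variant.
#' @return data.frame with `length`, `obs`, `fr`.
#' @export
expected_snp_exon_length_dist <- function(exon_lengths, p_snp = 0.001,
                                          range = c(20L, 1000L),
                                          length_weighted = FALSE) {
  if (!length(exon_lengths)) stop("empty exon-length histogram")
  lens <- range[1L]:range[2L]
  obs <- as.integer(table(factor(exon_lengths, levels = lens)))
  fr <- if (length_weighted) p_snp * lens * obs else p_snp * obs
  data.frame(length = lens, obs = obs, fr = fr)
}

#' Exon inclusion filter for exon-level analyses
#'
#' Retains exons between `min_len` and `max_len` bp with canonical GT-AG
#' splice junctions (checked on the genome, transcript orientation).
#'
#' @param genome a [load_genome()] result.
#' @param exons exon-model data.frame.
#' @param min_len,max_len length bounds (defaults 20 and 1000).
#' @return logical keep vector.
#' @export
filter_exons <- function(genome, exons, min_len = 20L, max_len = 1000L) {
  vapply(seq_len(nrow(exons)), function(i) {
    ex <- exons[i, , drop = FALSE]
    if (ex$length < min_len || ex$length > max_len) return(FALSE)
    din <- junction_dinucleotides(genome, ex)
    identical(din$donor, "GT") && identical(din$acceptor, "AG")
  }, logical(1L))
}

# first two bases of the downstream intron (donor side) and last two of
# the upstream intron (acceptor side), transcript orientation
junction_dinucleotides <- function(genome, exon) {
  minus <- exon$strand == "-"
  if ((is.na(exon$intron_down) || exon$intron_down < 2L) ||
      (is.na(exon$intron_up) || exon$intron_up < 2L))
    return(list(donor = NA_character_, acceptor = NA_character_))
  if (!minus) {
    donor <- genome_seq(genome, exon$chrom, exon$end + 1L, exon$end + 2L)
    acceptor <- genome_seq(genome, exon$chrom, exon$start - 2L, exon$start - 1L)
  } else {
    donor <- revcomp(genome_seq(genome, exon$chrom, exon$start - 2L, exon$start - 1L))
    acceptor <- revcomp(genome_seq(genome, exon$chrom, exon$end + 1L, exon$end + 2L))
  }
  list(donor = donor, acceptor = acceptor)
}

#' Natural splice-site strengths of an exon
#'
#' Scores the exon's annotated donor (9-mer: last 3 exonic + first 6
#' intronic bases) and acceptor (23-mer: last 20 intronic + first 3
#' exonic bases) windows with the given backend, and flags non-canonical
#' (non-GT/AG) junctions.
#'
#' @param model a `splice_site_model`.
#' @param genome a [load_genome()] result.
#' @param exon one exon-model row.
#' @return list with `score_5ss`, `score_3ss` (NA when windows are not
#'   extractable) and `noncanonical` flag.
#' @export
splice_site_strengths <- function(model, genome, exon) {
  stopifnot(nrow(exon) == 1L)
  minus <- exon$strand == "-"
  d_ok <- !is.na(exon$intron_down) && exon$intron_down >= 6L &&
    exon$length >= DONOR_EXONIC
  a_ok <- !is.na(exon$intron_up) && exon$intron_up >= 20L &&
    exon$length >= ACCEPTOR_EXONIC
  donor_win <- acceptor_win <- NA_character_
  if (d_ok) {
    donor_win <- if (!minus)
      genome_seq(genome, exon$chrom, exon$end - 2L, exon$end + 6L)
    else revcomp(genome_seq(genome, exon$chrom, exon$start - 6L, exon$start + 2L))
  }
  if (a_ok) {
    acceptor_win <- if (!minus)
      genome_seq(genome, exon$chrom, exon$start - 20L, exon$start + 2L)
    else revcomp(genome_seq(genome, exon$chrom, exon$end - 2L, exon$end + 20L))
  }
  sc <- function(win, side) {
    if (is.na(win) || grepl("[^ACGT]", win)) NA_real_
    else score_splice_site(model, win, side)
  }
  din <- junction_dinucleotides(genome, exon)
  list(score_5ss = sc(donor_win, "5p"), score_3ss = sc(acceptor_win, "3p"),
       noncanonical = !(identical(din$donor, "GT") &&
                          identical(din$acceptor, "AG")))
}

#' Junction occupancy profile of a motif set across an exon cohort
#'
#' For each junction, hexamer (k-mer) start positions slide across the
#' last `intron_bp` bases of the flanking intron and the first/last
#' `exon_bp` bases of the exon; at each start the fraction of exons
#' whose k-mer there is an ESE, and the fraction ESS, is reported.
#' Position 0 is the first exonic base (acceptor side) or first intronic
#' base (donor side); negative positions are intronic (acceptor) or
#' exonic (donor side, counted back from the junction).
#'
#' Exons shorter than `min_exon_len` or with flanking introns shorter
#' than `min_intron_len` are excluded.
#'
#' @param set an [esr_motif_set()].
#' @param genome a [load_genome()] result.
#' @param exons exon-model data.frame.
#' @param exon_bp exonic bases per junction (default 50).
#' @param intron_bp intronic bases per junction (default 100).
#' @param min_exon_len,min_intron_len inclusion bounds (defaults 100 and
#'   200).
#' @return data.frame with `junction` (`acceptor`/`donor`), `position`
#'   (k-mer start relative to the junction), `ese`, `ess` fractions, and
#'   `n_exons` used.
#' @export
junction_occupancy_profile <- function(set, genome, exons, exon_bp = 50L,
                                       intron_bp = 100L,
                                       min_exon_len = 100L,
                                       min_intron_len = 200L) {
  k <- set$k
  keep <- exons$length >= min_exon_len &
    !is.na(exons$intron_up) & exons$intron_up >= min_intron_len &
    !is.na(exons$intron_down) & exons$intron_down >= min_intron_len
  use <- exons[keep, , drop = FALSE]
  if (!nrow(use)) stop("no exons pass the occupancy-profile filters")
  # per-exon junction sequences, transcript orientation
  acc_seqs <- don_seqs <- character(nrow(use))
  for (i in seq_len(nrow(use))) {
    ex <- use[i, , drop = FALSE]
    minus <- ex$strand == "-"
    if (!minus) {
      acc_seqs[i] <- genome_seq(genome, ex$chrom, ex$start - intron_bp,
                                ex$start + exon_bp - 1L)
      don_seqs[i] <- genome_seq(genome, ex$chrom, ex$end - exon_bp + 1L,
                                ex$end + intron_bp)
    } else {
      acc_seqs[i] <- revcomp(genome_seq(genome, ex$chrom,
                                        ex$end - exon_bp + 1L,
                                        ex$end + intron_bp))
      don_seqs[i] <- revcomp(genome_seq(genome, ex$chrom,
                                        ex$start - intron_bp,
                                        ex$start + exon_bp - 1L))
    }
  }
  profile_one <- function(seqs, region_len, origin) {
    nstart <- region_len - k + 1L
    ese <- ess <- numeric(nstart)
    for (s in seq_len(nstart)) {
      kmers <- substr(seqs, s, s + k - 1L)
      scor <- !grepl("[^ACGT]", kmers)
      lab <- rep("NEUTRAL", length(kmers))
      if (any(scor)) lab[scor] <- classify_nmer(set, kmers[scor])
      ese[s] <- mean(lab == "ESE")
      ess[s] <- mean(lab == "ESS")
    }
    data.frame(position = (seq_len(nstart) - 1L) + origin,
               ese = ese, ess = ess)
  }
  acc <- profile_one(acc_seqs, intron_bp + exon_bp, origin = -intron_bp)
  don <- profile_one(don_seqs, exon_bp + intron_bp, origin = -exon_bp)
  out <- rbind(cbind(junction = "acceptor", acc, stringsAsFactors = FALSE),
               cbind(junction = "donor", don, stringsAsFactors = FALSE))
  out$n_exons <- nrow(use)
  out
}

#' Full exon-definition feature profile of one exon
#'
#' @param genome,exon,sets,pwms,model inputs as in the per-feature
#'   functions; `sets` is a list of motif sets.
#' @return one-row data.frame: exon identity, length, splice-site
#'   scores, per-set exon ESE/ESS densities, summed PWM density, and
#'   intron-flank densities (NA when the flank filter excludes the
#'   exon).
#' @export
exon_feature_profile <- function(genome, exon, sets, pwms = NULL,
                                 model = NULL) {
  stopifnot(nrow(exon) == 1L)
  if (inherits(sets, "esr_motif_set")) sets <- list(sets)
  minus <- exon$strand == "-"
  seq <- genome_seq(genome, exon$chrom, exon$start, exon$end)
  if (minus) seq <- revcomp(seq)
  out <- data.frame(transcript_id = exon$transcript_id,
                    exon_rank = exon$exon_rank, chrom = exon$chrom,
                    strand = exon$strand, start = exon$start,
                    end = exon$end, length = exon$length,
                    stringsAsFactors = FALSE)
  if (!is.null(model)) {
    ss <- splice_site_strengths(model, genome, exon)
    out$score_5ss <- ss$score_5ss; out$score_3ss <- ss$score_3ss
    out$noncanonical <- ss$noncanonical
  }
  for (set in sets) {
    d <- esr_density(set, seq)
    out[[paste0(set$name, "_ese_density")]] <- d[["ese"]]
    out[[paste0(set$name, "_ess_density")]] <- d[["ess"]]
    fl <- intron_flank_density(set, genome, exon)
    if (fl$excluded) {
      out[[paste0(set$name, "_up_ese")]] <- NA_real_
      out[[paste0(set$name, "_up_ess")]] <- NA_real_
      out[[paste0(set$name, "_down_ese")]] <- NA_real_
      out[[paste0(set$name, "_down_ess")]] <- NA_real_
    } else {
      out[[paste0(set$name, "_up_ese")]] <- fl$upstream[["ese"]]
      out[[paste0(set$name, "_up_ess")]] <- fl$upstream[["ess"]]
      out[[paste0(set$name, "_down_ese")]] <- fl$downstream[["ese"]]
      out[[paste0(set$name, "_down_ess")]] <- fl$downstream[["ess"]]
    }
  }
  if (!is.null(pwms)) out$pwm_density <- esefinder_density(pwms, seq)
  out
}
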