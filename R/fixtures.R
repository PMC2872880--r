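# Deterministic synthetic fixture generator. Emulates, at toy scale and
# with known planted truth, every input the scoring framework consumes:
# a genome FASTA with multi-exon genes on both strands and consensus
# GT-AG junctions, BED12 exon models, labelled hexamer/octamer motif
# sets, a PWM file, 4-species MAF alignments with codon-position-specific
# conservation rates, polarised variant cohorts (a SAV-like cohort
# enriched for ESE loss / ESS gain near exon edges, an ectopic-like
# cohort that completes donor consensus sites inside exons, and a
# splicing-neutral control cohort), a substitution-bias table and a
# trained splice-site model. Regeneration from (seed, config) is
# byte-identical.

#' Fixture generator configuration
#'
#' Defaults define the simulated study conditions: cohort sizes scaled
#' from the real study (tens of splice-affecting variants against an
#' order-of-magnitude larger neutral pool), exons of 102-240 bp with
#' introns of 250-400 bp (long enough for the 100-bp flank analyses and
#' 23-bp acceptor windows), and third-codon-position conservation far
#' below positions 1-2, lowest in CpG-context codons.
#'
#' @param n_genes genes per chromosome (2 chromosomes).
#' @param exons_per_gene exons per gene (first/last flank the internal
#'   ones).
#' @param n_ese,n_ess labelled hexamers in the toy ESR set.
#' @param n_unlabeled hexamers in the unlabeled (Ast-style) set.
#' @param n_oct_ese,n_oct_ess octamers in the toy PESX-style set.
#' @param n_sav,n_control,n_ectopic cohort sizes.
#' @param min_extent minimum planted combined extent (ESE losses + ESS
#'   gains) per SAV-like variant.
#' @param control_polarizable fraction of control variants with clean
#'   outgroup evidence.
#' @param cons_rates conservation probability per codon position
#'   (positions 1-3).
#' @param cons_rate_cpg3 conservation probability at third positions of
#'   CpG-context codons (TCG/ACG/CCG/GCG).
#' @return named list of parameters.
#' @export
fixture_config <- function(n_genes = 10L, exons_per_gene = 4L,
                           n_ese = 400L, n_ess = 200L, n_unlabeled = 50L,
                           n_oct_ese = 40L, n_oct_ess = 30L,
                           n_sav = 40L, n_control = 400L, n_ectopic = 20L,
                           min_extent = 2L, control_polarizable = 0.95,
                           cons_rates = c(0.95, 0.97, 0.60),
                           cons_rate_cpg3 = 0.30) {
  as.list(environment())
}

rand_seq <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

noisy <- function(consensus, miss_prob = 0.15, protect = integer(0)) {
  b <- strsplit(consensus, "")[[1L]]
  for (i in seq_along(b)) {
    if (i %in% protect) next
    if (stats::runif(1) < miss_prob)
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  }
  paste(b, collapse = "")
}

# direct (non-pipeline) count of ESE losses and ESS gains over all k-mer
# windows containing position `off0` (0-based) of `seq` after mutating
# that base to `alt`; used by the generator to plant effect sizes
.count_changes <- function(seq, off0, alt, motifs, k) {
  n <- nchar(seq)
  starts <- max(0L, off0 - k + 1L):min(n - k, off0)
  if (off0 > n - 1L || !length(starts) || starts[1L] > off0)
    return(c(loss = 0L, gain = 0L))
  der <- paste0(substr(seq, 1L, off0), alt, substr(seq, off0 + 2L, n))
  loss <- gain <- 0L
  for (s in starts) {
    w <- substr(seq, s + 1L, s + k)
    d <- substr(der, s + 1L, s + k)
    lw <- motifs[w]; ld <- motifs[d]
    lw <- ifelse(is.na(lw), "NEUTRAL", lw)
    ld <- ifelse(is.na(ld), "NEUTRAL", ld)
    if (lw == "ESE" && ld != "ESE") loss <- loss + 1L
    if (ld == "ESS" && lw != "ESS") gain <- gain + 1L
  }
  c(loss = loss, gain = gain)
}

#' Generate the synthetic fixture bundle
#'
#' Writes all fixture files into `dir` and returns the bundle manifest
#' (also written as `manifest.json`). See [fixture_config()] for the
#' simulated conditions.
#'
#' @param dir output directory (created if missing).
#' @param config a [fixture_config()].
#' @param seed integer seed; regeneration is byte-identical.
#' @return invisibly, the manifest list (paths, parameters, per-variant
#'   planted truth).
#' @export
simulate_fixtures <- function(dir, config = fixture_config(), seed = 1L) {
  stopifnot(is.list(config), all(c("n_genes", "n_sav") %in% names(config)))
  if (config$n_sav < 1L || config$n_genes < 2L)
    stop("invalid fixture config (need n_genes >= 2, n_sav >= 1)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cfg <- config

  ## motif sets -------------------------------------------------------
  hex <- all_kmers(6L)
  picked <- sample(hex, cfg$n_ese + cfg$n_ess + cfg$n_unlabeled)
  ese <- picked[seq_len(cfg$n_ese)]
  ess <- picked[cfg$n_ese + seq_len(cfg$n_ess)]
  unl <- picked[cfg$n_ese + cfg$n_ess + seq_len(cfg$n_unlabeled)]
  set_main <- esr_motif_set("toyESR", 6L, stats::setNames(
    c(rep("ESE", cfg$n_ese), rep("ESS", cfg$n_ess)), c(ese, ess)),
    source_note = "synthetic")
  set_unl <- esr_motif_set("toyAst", 6L,
    stats::setNames(rep("UNLABELED_ESR", cfg$n_unlabeled), unl),
    source_note = "synthetic")
  oct <- sample(all_kmers(8L), cfg$n_oct_ese + cfg$n_oct_ess)
  set_oct <- esr_motif_set("toyPESX", 8L, stats::setNames(
    c(rep("ESE", cfg$n_oct_ese), rep("ESS", cfg$n_oct_ess)), oct),
    source_note = "synthetic")
  write_motif_set(set_main, file.path(dir, "toyESR.tsv"))
  write_motif_set(set_unl, file.path(dir, "toyAst.tsv"))
  write_motif_set(set_oct, file.path(dir, "toyPESX.tsv"))

  ## PWM set (4 matrices seeded from sampled ESE motifs) --------------
  pwm_list <- lapply(1:4, function(i) {
    L <- c(7L, 7L, 8L, 6L)[i]
    seed_motifs <- vapply(1:6, function(j) rand_seq(L), "")
    counts <- matrix(0.5, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (sm in seed_motifs)
      for (p in seq_len(L))
        counts[substr(sm, p, p), p] <- counts[substr(sm, p, p), p] + 1
    freq <- sweep(counts, 2L, colSums(counts), "/")
    w <- log2(freq / 0.25)
    # threshold midway between a strong hit and the background mean
    strong <- sum(apply(w, 2L, max))
    list(motif_name = paste0("toySR", i), threshold = round(strong * 0.55, 4),
         weights = round(w, 4))
  })
  pwms <- pwm_set("toyPWM", pwm_list)
  write_pwm_set(pwms, file.path(dir, "pwm.txt"))

  ## genome + exon models ---------------------------------------------
  donor_consensus <- "GTAAGT"   # intron first 6
  exon_end3 <- "CAG"            # exon last 3 at the donor
  chroms <- c("chr1", "chr2")
  seqs <- stats::setNames(vector("list", 2L), chroms)
  bed_lines <- character(0)
  exon_rows <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    cursor <- 0L
    parts <- character(0)
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; cursor <<- cursor + nchar(s) }
    add(rand_seq(300L))
    for (g in seq_len(cfg$n_genes)) {
      strand <- if (g %% 2L == 0L) "-" else "+"
      nex <- cfg$exons_per_gene
      ex_len <- c(60L, sample(seq(102L, 240L, by = 3L), nex - 2L, replace = TRUE), 63L)
      in_len <- sample(250L:400L, nex - 1L, replace = TRUE)
      tx_start0 <- cursor  # 0-based
      ex_abs <- integer(0)
      for (e in seq_len(nex)) {
        ex_start0 <- cursor
        body <- rand_seq(ex_len[e])
        # plant donor-side exon consensus (genomic orientation handled below)
        add(body)
        ex_abs <- c(ex_abs, ex_start0)
        if (e < nex) {
          intron <- rand_seq(in_len[e])
          # canonical + consensus junctions in genomic orientation of the
          # transcript strand
          if (strand == "+") {
            intron <- paste0(noisy(donor_consensus, 0.1, protect = 1:2),
                             substr(intron, 7L, in_len[e] - 19L),
                             paste0(noisy(paste(rep("T", 14L), collapse = ""), 0.3),
                                    "TTCAG"))
            substr(parts[[length(parts)]],
                   ex_len[e] - 2L, ex_len[e]) <- noisy(exon_end3, 0.1)
          } else {
            # transcript runs right-to-left: this genomic gap is the intron
            # downstream of the *next* genomic exon in tx orientation
            intron <- paste0(revcomp(paste0(noisy(paste(rep("T", 14L), collapse = ""), 0.3),
                                            "TTCAG")),
                             substr(intron, 20L, in_len[e] - 6L),
                             revcomp(noisy(donor_consensus, 0.1, protect = 1:2)))
          }
          add(intron)
        }
      }
      if (strand == "-") {
        # plant donor-side exon consensus at the tx-orientation exon ends:
        # genomic starts of exons 2..nex
        for (e in 2:nex) {
          idx <- length(parts) - (2L * (nex - e))  # part index of exon e
          substr(parts[[idx]], 1L, 3L) <- revcomp(noisy(exon_end3, 0.1))
        }
      }
      tx_end0 <- cursor
      bs <- ex_abs - tx_start0
      bed_lines <- c(bed_lines, paste(
        chrom, tx_start0, tx_end0, sprintf("tx_%s_%02d", chrom, g), 0, strand,
        tx_start0, tx_end0, "0",
        nex, paste0(paste(ex_len, collapse = ","), ","),
        paste0(paste(bs, collapse = ","), ","), sep = "\t"))
      add(rand_seq(200L))
    }
    seqs[[chrom]] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  writeLines(bed_lines, file.path(dir, "exons.bed"))
  exons <- read_exon_models(file.path(dir, "exons.bed"))
  internal <- exons[exons$internal & !is.na(exons$phase), , drop = FALSE]

  ## ectopic cohort: plant near-consensus donor 9-mers inside exons, one
  ## mismatch each; the variant restores the consensus base. Planted
  ## before alignments / model training / other cohorts so every
  ## downstream artefact sees the final genome.
  donor_consensus9 <- paste0("CAG", donor_consensus)
  ect <- vector("list", cfg$n_ectopic)
  planted_windows <- data.frame(chrom = character(0), lo = integer(0),
                                hi = integer(0))
  i <- 1L
  tries <- 0L
  while (i <= cfg$n_ectopic) {
    tries <- tries + 1L
    if (tries > 2000L) stop("could not place ectopic fixture variants")
    r <- sample.int(nrow(internal), 1L)
    ex <- internal[r, , drop = FALSE]
    len <- ex$length
    if (len < 40L) next
    site0 <- sample((len %/% 2L):(len - 15L), 1L)   # 0-based start, tx orient
    mm <- sample(4:9, 1L)                           # mismatch in intronic part
    planted <- donor_consensus9
    true_b <- substr(donor_consensus9, mm, mm)
    wrong <- sample(setdiff(c("A", "C", "G", "T"), true_b), 1L)
    substr(planted, mm, mm) <- wrong
    off0 <- site0 + mm - 1L
    if (off0 < 4L || off0 > len - 5L) next
    # no stop gain: the planted-then-restored codon must not become a stop
    ref_tx <- genome_seq(genome, ex$chrom, ex$start, ex$end)
    if (ex$strand == "-") ref_tx <- revcomp(ref_tx)
    with_site <- paste0(substr(ref_tx, 1L, site0), planted,
                        substr(ref_tx, site0 + 10L, len))
    codpos <- ((ex$phase + off0) %% 3L) + 1L
    cs <- off0 - (codpos - 1L)
    if (cs >= 0L && cs + 2L <= len - 1L) {
      der_codon <- substr(with_site, cs + 1L, cs + 3L)
      substr(der_codon, codpos, codpos) <- true_b
      if (Biostrings::GENETIC_CODE[[der_codon]] == "*") next
    }
    glo <- if (ex$strand == "+") ex$start + site0 else ex$end - site0 - 8L
    ghi <- glo + 8L
    clash <- planted_windows$chrom == ex$chrom &
      planted_windows$lo <= ghi + 6L & planted_windows$hi >= glo - 6L
    if (any(clash)) next
    if (ex$strand == "+") {
      Biostrings::subseq(genome[[ex$chrom]], glo, ghi) <-
        Biostrings::DNAString(planted)
    } else {
      Biostrings::subseq(genome[[ex$chrom]], glo, ghi) <-
        Biostrings::DNAString(revcomp(planted))
    }
    pos <- if (ex$strand == "-") ex$end - off0 else ex$start + off0
    wt_g <- if (ex$strand == "-") comp_base(wrong) else wrong
    alt_g <- if (ex$strand == "-") comp_base(true_b) else true_b
    planted_windows <- rbind(planted_windows, data.frame(
      chrom = ex$chrom, lo = glo, hi = ghi, stringsAsFactors = FALSE))
    ect[[i]] <- list(chrom = ex$chrom, pos = pos, anc = wt_g, der = alt_g,
                     exon_row = r, offset = off0, loss = NA, gain = NA)
    i <- i + 1L
  }
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"), width = 70L)

  ## SAV-like and control cohorts --------------------------------------
  motifs_lut <- set_main$motifs
  # transcript-orientation exon sequences, cached once on the final genome
  exon_tx <- vapply(seq_len(nrow(internal)), function(r) {
    ex <- internal[r, , drop = FALSE]
    s <- genome_seq(genome, ex$chrom, ex$start, ex$end)
    if (ex$strand == "-") revcomp(s) else s
  }, "")
  pick_variant <- function(kind) {
    for (attempt in 1:2000) {
      r <- sample.int(nrow(internal), 1L)
      ex <- internal[r, , drop = FALSE]
      len <- ex$length
      off0 <- switch(kind,
        sav = { # peripheral sections but > 3 bp from a junction
          edge <- sample(c(TRUE, FALSE), 1L)
          span <- max(5L, len %/% 6L)
          if (edge) sample(4:span, 1L) else (len - 1L) - sample(4:span, 1L)
        },
        sample(4:(len - 5L), 1L))
      pos <- if (ex$strand == "-") ex$end - off0 else ex$start + off0
      clash <- planted_windows$chrom == ex$chrom &
        planted_windows$lo <= pos + 6L & planted_windows$hi >= pos - 6L
      if (any(clash)) next
      ref_tx <- exon_tx[r]
      wt <- substr(ref_tx, off0 + 1L, off0 + 1L)
      alts <- setdiff(c("A", "C", "G", "T"), wt)
      chg <- t(vapply(alts, function(a)
        .count_changes(ref_tx, off0, a, motifs_lut, 6L), integer(2L)))
      ext <- chg[, "loss"] + chg[, "gain"]
      alt <- switch(kind,
        sav = { j <- which.max(ext)
                if (ext[j] < cfg$min_extent) next else alts[j] },
        control = { j <- which.min(ext)
                    if (ext[j] > 0L) next else alts[j] })
      sel <- which(alts == alt)
      # no stop gain (the inclusion filter would reject it)
      codpos <- ((ex$phase + off0) %% 3L) + 1L
      cs <- off0 - (codpos - 1L)
      if (cs >= 0L && cs + 2L <= len - 1L) {
        der_codon <- substr(ref_tx, cs + 1L, cs + 3L)
        substr(der_codon, codpos, codpos) <- alt
        if (Biostrings::GENETIC_CODE[[der_codon]] == "*") next
      }
      wt_g <- if (ex$strand == "-") comp_base(wt) else wt
      alt_g <- if (ex$strand == "-") comp_base(alt) else alt
      return(list(chrom = ex$chrom, pos = pos, anc = wt_g, der = alt_g,
                  exon_row = r, offset = off0,
                  loss = chg[sel, "loss"], gain = chg[sel, "gain"]))
    }
    stop("fixture generation failed to place a ", kind, " variant; ",
         "motif sets too sparse for min_extent = ", cfg$min_extent)
  }
  used <- vapply(ect, function(v) paste(v$chrom, v$pos), "")
  make_cohort <- function(n, kind) {
    out <- vector("list", n)
    i <- 1L
    attempts <- 0L
    while (i <= n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop("fixture generation could not place ", n, " distinct ", kind,
             " variants (placed ", i - 1L, ")")
      v <- pick_variant(kind)
      key <- paste(v$chrom, v$pos)
      if (key %in% used) next
      used <<- c(used, key)
      out[[i]] <- v
      i <- i + 1L
    }
    out
  }
  sav <- make_cohort(cfg$n_sav, "sav")
  ctrl <- make_cohort(cfg$n_control, "control")

  ## MAF alignments over internal exons -------------------------------
  # the 11-bp windows around SAV-like variants are held fully conserved:
  # the SAV cohort models variants falling in regulatorily constrained
  # sequence, so its RC scores sit above the control background
  species <- c("hg", "mm", "rn", "cf")
  sav_offsets <- split(vapply(sav, function(v) v$offset, 0L),
                       vapply(sav, function(v) v$exon_row, 0L))
  blocks <- list()
  for (r in seq_len(nrow(internal))) {
    ex <- internal[r, , drop = FALSE]
    ref_tx <- genome_seq(genome, ex$chrom, ex$start, ex$end)
    if (ex$strand == "-") ref_tx <- revcomp(ref_tx)
    n <- nchar(ref_tx)
    codpos <- ((ex$phase + seq_len(n) - 1L) %% 3L) + 1L
    cstart <- seq_len(n) - (codpos - 1L)
    protected <- rep(FALSE, n)
    for (off in sav_offsets[[as.character(r)]])
      protected[max(1L, off - 4L):min(n, off + 6L)] <- TRUE
    rows_tx <- matrix(rep(strsplit(ref_tx, "")[[1L]], each = 4L), nrow = 4L)
    for (i in seq_len(n)) {
      if (protected[i]) next
      rate <- cfg$cons_rates[codpos[i]]
      if (codpos[i] == 3L && cstart[i] >= 1L && cstart[i] + 2L <= n) {
        codon <- substr(ref_tx, cstart[i], cstart[i] + 2L)
        if (codon %in% c("TCG", "ACG", "CCG", "GCG")) rate <- cfg$cons_rate_cpg3
      }
      if (stats::runif(1) >= rate) {
        sp <- sample(2:4, 1L)
        rows_tx[sp, i] <- sample(setdiff(c("A", "C", "G", "T"), rows_tx[sp, i]), 1L)
      }
    }
    row_strs <- apply(rows_tx, 1L, paste, collapse = "")
    if (ex$strand == "-") row_strs <- vapply(row_strs, revcomp, "", USE.NAMES = FALSE)
    blocks[[r]] <- data.frame(
      src = paste0(species, ".", ex$chrom),
      start = ex$start - 1L, size = n, strand = "+",
      srcSize = length(genome[[ex$chrom]]), text = row_strs,
      stringsAsFactors = FALSE)
  }
  write_maf(blocks, file.path(dir, "alignments.maf"))

  ## splice-site model trained on the planted junctions ---------------
  don_win <- acc_win <- character(0)
  for (r in seq_len(nrow(internal))) {
    ex <- internal[r, , drop = FALSE]
    if (ex$strand == "+") {
      don_win <- c(don_win, genome_seq(genome, ex$chrom, ex$end - 2L, ex$end + 6L))
      acc_win <- c(acc_win, genome_seq(genome, ex$chrom, ex$start - 20L, ex$start + 2L))
    } else {
      don_win <- c(don_win, revcomp(genome_seq(genome, ex$chrom, ex$start - 6L, ex$start + 2L)))
      acc_win <- c(acc_win, revcomp(genome_seq(genome, ex$chrom, ex$end - 2L, ex$end + 20L)))
    }
  }
  model <- train_splice_model(don_win, acc_win)
  write_splice_model(model, file.path(dir, "splice_model.txt"))

  cohort_df <- function(lst, prefix, polarizable = 1) {
    n <- length(lst)
    clean <- stats::runif(n) < polarizable
    data.frame(
      chrom = vapply(lst, `[[`, "", "chrom"),
      pos = vapply(lst, function(v) v$pos, 0),
      allele_a = vapply(lst, `[[`, "", "anc"),
      allele_b = vapply(lst, `[[`, "", "der"),
      id = sprintf("%s%03d", prefix, seq_len(n)),
      out1 = ifelse(clean, vapply(lst, `[[`, "", "anc"), "."),
      out2 = ifelse(clean, vapply(lst, `[[`, "", "anc"), "."),
      stringsAsFactors = FALSE)
  }
  sav_df <- cohort_df(sav, "sav")
  ctrl_df <- cohort_df(ctrl, "ctl", cfg$control_polarizable)
  ect_df <- cohort_df(ect, "ect")
  write_tsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(sav_df, "sav_variants.tsv")
  write_tsv(ctrl_df, "control_variants.tsv")
  write_tsv(ect_df, "ectopic_variants.tsv")

  ## bias table from the polarisable control variants ------------------
  ok <- ctrl_df$out1 != "."
  bias <- substitution_bias(ctrl_df$allele_a[ok], ctrl_df$allele_b[ok])
  write_bias(bias, file.path(dir, "bias.tsv"))

  manifest <- list(
    seed = seed, config = cfg,
    files = list(genome = "genome.fa", exons = "exons.bed",
                 motif_sets = c("toyESR.tsv", "toyAst.tsv", "toyPESX.tsv"),
                 pwm = "pwm.txt", maf = "alignments.maf",
                 splice_model = "splice_model.txt", bias = "bias.tsv",
                 cohorts = c("sav_variants.tsv", "control_variants.tsv",
                             "ectopic_variants.tsv")),
    truth = list(
      sav = data.frame(id = sav_df$id,
                       planted_loss = vapply(sav, function(v) v$loss, 0),
                       planted_gain = vapply(sav, function(v) v$gain, 0),
                       stringsAsFactors = FALSE),
      control = data.frame(id = ctrl_df$id,
                           planted_loss = vapply(ctrl, function(v) v$loss, 0),
                           planted_gain = vapply(ctrl, function(v) v$gain, 0),
                           stringsAsFactors = FALSE),
      ectopic = data.frame(id = ect_df$id, expected_delta_sign = 1,
                           stringsAsFactors = FALSE)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Write synthetic stand-ins for the curated supplementary cohorts
#'
#' Produces four variant TSVs in the [read_variants()] layout at the
#' curated-cohort sizes (87 exon-skipping, 80 splice-neutral, 20
#' inclusion, 54 ectopic). These are synthetic stand-ins for the real
#' curated supplements (which are not redistributed); file names carry
#' the `synthetic_` prefix. Positions are placed on the fixture genome
#' when `fixture_dir` is given, otherwise on nominal coordinates.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return named character vector of the four file paths.
#' @export
write_synthetic_supplements <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sizes <- c(synthetic_sav_skipping = 87L, synthetic_splice_neutral = 80L,
             synthetic_inclusion = 20L, synthetic_ectopic = 54L)
  out <- character(0)
  for (nm in names(sizes)) {
    n <- sizes[[nm]]
    wt <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(wt, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    df <- data.frame(chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
                     pos = sample.int(1e6L, n),
                     allele_a = wt, allele_b = alt,
                     id = sprintf("%s_%03d", nm, seq_len(n)),
                     stringsAsFactors = FALSE)
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out[nm] <- f
  }
  out
}
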