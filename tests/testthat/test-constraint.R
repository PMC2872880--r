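# helper: build a MAF block over an exon with caller-supplied species rows
# (transcript orientation); rows are written genome-orientation, ref first
toy_maf_block <- function(exon, rows_tx, chrom_len = 2000L) {
  rows_g <- if (exon$strand == "-") o_revcomp(rows_tx) else rows_tx
  data.frame(src = paste0(c("hg", "mm", "rn", "cf")[seq_along(rows_g)], ".",
                          exon$chrom),
             start = exon$start - 1L, size = nchar(rows_g[1]), strand = "+",
             srcSize = chrom_len, text = rows_g, stringsAsFactors = FALSE)
}

test_that("MAF files round-trip through the reader", {
  f <- withr::local_tempfile()
  b <- data.frame(src = c("hg.chr1", "mm.chr1", "rn.chr1"),
                  start = c(10L, 5L, 3L), size = 8L, strand = "+",
                  srcSize = 1000L, text = c("ACGTACGT", "ACGTACGA", "ACGAACGT"),
                  stringsAsFactors = FALSE)
  write_maf(list(b), f)
  back <- read_maf(f)
  expect_length(back, 1L)
  expect_identical(back[[1]]$text, b$text)
  expect_identical(back[[1]]$start, b$start)
})

test_that("codon matrix scores are (1 - conserved fraction) x 10", {
  exon_seq <- strrep("GCTACT", 5)   # 30 bp, 10 codons, phase 0
  loc <- toy_locus(exon_seq, strrep("T", 60), strrep("T", 60))
  ex <- loc$exon
  # fully conserved alignment: every observed cell scores 0
  rows <- rep(exon_seq, 4)
  m <- build_codon_matrix(list(toy_maf_block(ex, rows)), ex)
  tab <- m$table
  expect_identical(nrow(tab), 192L)
  obs <- tab[tab$observed > 0, ]
  expect_true(all(obs$score == 0))
  expect_true(all(obs$codon %in% c("GCT", "ACT")))
  # nothing conserved: observed cells score 10
  rows2 <- c(exon_seq, chartr("ACGT", "CATG", exon_seq),
             chartr("ACGT", "GTAC", exon_seq), chartr("ACGT", "TGCA", exon_seq))
  m2 <- build_codon_matrix(list(toy_maf_block(ex, rows2)), ex)
  obs2 <- m2$table[m2$table$observed > 0, ]
  expect_true(all(obs2$score == 10))
  # unobserved cells are flagged undefined and error on use
  expect_true(anyNA(m$table$score))
  expect_error(savscan:::matrix_score(m, "AAA", 1), "no observations")
  # TSV round trip
  f <- withr::local_tempfile()
  write_codon_matrix(m, f)
  expect_equal(read_codon_matrix(f)$table$score, m$table$score)
})

test_that("hypermutable-CpG third positions get the highest matrix scores", {
  b <- fixtures_once()
  internal <- b$exons[b$exons$internal, ]
  m <- build_codon_matrix(b$maf, internal)
  tab <- m$table[!is.na(m$table$score) & m$table$observed >= 10, ]
  cpg3 <- tab$position == 3 & tab$codon %in% c("TCG", "ACG", "CCG", "GCG")
  expect_true(any(cpg3))
  # CpG third positions score above other third positions, which score
  # above positions 1-2 (the planted conservation hierarchy)
  s_cpg3 <- mean(tab$score[cpg3])
  s_pos3 <- mean(tab$score[tab$position == 3 & !(tab$codon %in%
                                                   c("TCG", "ACG", "CCG", "GCG"))])
  s_pos12 <- mean(tab$score[tab$position != 3])
  expect_gt(s_cpg3, s_pos3)
  expect_gt(s_pos3, s_pos12)
})

test_that("rc_score implements the conserved-column weighted mean", {
  # hand example: 11 columns, conserved columns 3 and 7 with weights 8.2
  # and 4.0 -> RC = 12.2 / 11
  tab <- data.frame(codon = rep(savscan:::CODONS, 3),
                    position = rep(1:3, each = 64),
                    observed = 10L, conserved = 5L, pr = 0.5, score = 5)
  # give specific cells the weights we need: codon AAA pos1 = 8.2, pos2 = 4.0
  tab$score[tab$codon == "AAA" & tab$position == 1] <- 8.2
  tab$score[tab$codon == "AAA" & tab$position == 2] <- 4.0
  m <- structure(list(table = tab), class = "codon_constraint_matrix")
  ref <- strrep("GGGGGGGGGGG", 1)
  rows <- c(ref,
            "GGTTGGGTTGG",   # differs except cols 3 and 7? build explicitly
            ref)
  # construct: conserved only at columns 3 and 7
  r2 <- strsplit(ref, "")[[1]]
  r2[setdiff(1:11, c(3, 7))] <- "A"
  rows <- c(ref, paste(r2, collapse = ""), ref)
  codons <- rep("AAA", 11)
  positions <- c(2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)  # col3 -> pos1, col7 -> pos2
  rc <- rc_score(m, rows, codons, positions)
  expect_equal(rc, (8.2 + 4.0) / 11)
  # no conserved columns -> 0; all conserved with weight 10 -> 10
  m10 <- m; m10$table$score <- 10
  expect_equal(rc_score(m10, rows = c(ref, strrep("A", 11), strrep("C", 11)),
                        codons, positions), 0)
  expect_equal(rc_score(m10, rows = rep(ref, 3), codons, positions), 10)
  # guards
  expect_error(rc_score(m, rows[1:2], codons, positions), "two species")
  expect_error(rc_score(m, c(ref, ref, "GG-GGGGGGGG"), codons, positions),
               "ungapped")
})

test_that("RC properties: row-permutation invariance, bounds, monotone growth", {
  tab <- data.frame(codon = rep(savscan:::CODONS, 3),
                    position = rep(1:3, each = 64),
                    observed = 10L, conserved = 5L, pr = 0.5,
                    score = rep(c(1, 2, 9), each = 64))
  m <- structure(list(table = tab), class = "codon_constraint_matrix")
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- sample(6:12, 1)
      ref <- rand_dna(n)
      mk_row <- function() {
        v <- strsplit(ref, "")[[1]]
        flip <- runif(n) < 0.3
        v[flip] <- vapply(v[flip], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
        paste(v, collapse = "")
      }
      rows <- c(ref, mk_row(), mk_row(), mk_row())
      codons <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = ""),
        "")
      positions <- sample(1:3, n, replace = TRUE)
      rc <- rc_score(m, rows, codons, positions)
      expect_gte(rc, 0); expect_lte(rc, 10)
      # independent oracle
      deltas <- vapply(seq_len(n), function(i)
        tab$score[tab$codon == codons[i] & tab$position == positions[i]], 0)
      expect_equal(rc, o_rc(rows, deltas))
      # permuting non-reference rows leaves RC unchanged
      expect_equal(rc_score(m, rows[c(1, 4, 2, 3)], codons, positions), rc)
      # appending a conserved column with weight above the current mean
      # strictly increases RC
      rc2 <- rc_score(m, paste0(rows, "A"), c(codons, "TTT"),
                      c(positions, 3))
      if (rc < 9) expect_gt(rc2, rc)
    }
  })
})

test_that("variant RC windows truncate at junctions and report UNSCORED reasons", {
  exon_seq <- strrep("GCTACT", 8)  # 48 bp
  loc <- toy_locus(exon_seq, strrep("T", 60), strrep("T", 60))
  ex <- loc$exon
  rows <- rep(exon_seq, 4)
  m <- build_codon_matrix(list(toy_maf_block(ex, rows)), ex)
  mk_ctx <- function(off0) {
    wt <- substr(exon_seq, off0 + 1, off0 + 1)
    alt <- setdiff(c("A", "C", "G", "T"), wt)[1]
    toy_ctx(exon_seq, off0, alt)
  }
  # mid-exon: 11 columns
  r <- variant_rc(m, list(toy_maf_block(ex, rows)), mk_ctx(20L))
  expect_true(r$scored)
  expect_identical(r$n_columns, 11L)
  expect_equal(r$rc, 0)  # fully conserved alignment, all-zero scores
  # 3 exonic bases from the start (offset 2): left-truncated window
  r2 <- variant_rc(m, list(toy_maf_block(ex, rows)), mk_ctx(2L))
  expect_identical(r2$n_columns, 8L)
  # gap in the alignment: UNSCORED
  rows_gap <- rows
  substr(rows_gap[2], 5, 5) <- "-"
  rg <- variant_rc(m, list(toy_maf_block(ex, rows_gap)), mk_ctx(20L))
  expect_false(rg$scored)
  expect_identical(rg$reason, "GAPPED")
  # fewer than 3 species: UNSCORED
  r3 <- variant_rc(m, list(toy_maf_block(ex, rows[1:2])), mk_ctx(20L))
  expect_identical(r3$reason, "TOO_FEW_SPECIES")
  # no alignment at all
  r4 <- variant_rc(m, list(), mk_ctx(20L))
  expect_identical(r4$reason, "NO_ALIGNMENT")
})

test_that("exon conservation separates overall and non-synonymous identity", {
  # identical alignment: 100 / 100
  exon_seq <- strrep("GCTACT", 5)
  rows <- rep(exon_seq, 3)
  r <- exon_conservation(rows, phase = 0L)
  expect_equal(r$overall, 100)
  expect_equal(r$nonsynonymous, 100)
  # mutate only 4-fold degenerate third positions (GCN = Ala): overall
  # drops, non-synonymous identity stays 100
  r2rows <- rows
  v <- strsplit(r2rows[2], "")[[1]]
  v[3] <- "G"  # GCT -> GCG, third position of alanine codon
  r2rows[2] <- paste(v, collapse = "")
  r2 <- exon_conservation(r2rows, phase = 0L)
  expect_lt(r2$overall, 100)
  expect_equal(r2$nonsynonymous, 100)
  # random fixtures match a brute-force column classification
  withr::with_seed(19, {
    for (rep in 1:10) {
      n_codons <- sample(4:8, 1)
      ref <- rand_dna(3 * n_codons)
      mk <- function() {
        v <- strsplit(ref, "")[[1]]
        flip <- runif(length(v)) < 0.2
        v[flip] <- vapply(v[flip], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
        paste(v, collapse = "")
      }
      rows <- c(ref, mk(), mk())
      got <- exon_conservation(rows, phase = 0L)
      mat <- do.call(rbind, strsplit(rows, ""))
      conserved <- apply(mat, 2, function(col) length(unique(col)) == 1)
      nonsyn <- logical(ncol(mat))
      gc <- Biostrings::GENETIC_CODE
      for (i in seq_len(ncol(mat))) {
        cp <- ((i - 1) %% 3) + 1
        cod <- substr(ref, i - cp + 1, i - cp + 3)
        alts <- setdiff(c("A", "C", "G", "T"), substr(cod, cp, cp))
        nonsyn[i] <- all(vapply(alts, function(b) {
          mc <- cod; substr(mc, cp, cp) <- b
          gc[[mc]] != gc[[cod]]
        }, NA))
      }
      expect_equal(got$overall, 100 * mean(conserved))
      if (any(nonsyn))
        expect_equal(got$nonsynonymous, 100 * mean(conserved[nonsyn]))
    }
  })
  expect_error(exon_conservation(rows, phase = NA_integer_), "frame")
})

test_that("overlapping constraint windows are deduplicated in coordinate order", {
  v <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  pos = c(100L, 105L, 150L, 100L))
  keep <- nonoverlapping_windows(v)
  expect_identical(keep, c(TRUE, FALSE, TRUE, TRUE))
  # window half-width controls the exclusion radius
  expect_identical(nonoverlapping_windows(v, flank = 2L),
                   rep(TRUE, 4L))
})
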