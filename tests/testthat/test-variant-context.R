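test_that("polarize matches a brute-force truth table over all base combinations", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(a = bases, b = bases, o1 = c(bases, NA),
                      o2 = c(bases, NA), stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, ]
  res <- polarize(grid$a, grid$b, grid$o1, grid$o2)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; o1 <- grid$o1[i]; o2 <- grid$o2[i]
    if (is.na(o1) || is.na(o2)) {
      expect_identical(res$reason[i], "MISSING_ALIGNMENT")
    } else if (o1 != o2) {
      expect_identical(res$reason[i], "OUTGROUP_DISAGREE")
    } else if (!(o1 %in% c(a, b))) {
      expect_identical(res$reason[i], "NO_ALLELE_MATCH")
    } else {
      expect_true(res$accepted[i])
      expect_identical(res$ancestral[i], o1)
      expect_identical(res$derived[i], setdiff(c(a, b), o1))
    }
  }
  # spec examples
  one <- polarize("C", "T", "C", "C")
  expect_identical(one$ancestral, "C"); expect_identical(one$derived, "T")
  expect_identical(polarize("C", "T", "C", "G")$reason, "OUTGROUP_DISAGREE")
  expect_identical(polarize("C", "T", "A", "A")$reason, "NO_ALLELE_MATCH")
})

test_that("BED12 exon models carry intron lengths, internal flags and frame", {
  f <- withr::local_tempfile()
  # two transcripts, one per strand; 3 exons of 9/12/9 bp with 100-bp introns
  writeLines(c(
    paste("chr1", 100, 339, "txA", 0, "+", 100, 339, "0", 3,
          "9,12,9,", "0,109,230,", sep = "\t"),
    paste("chr1", 500, 739, "txB", 0, "-", 500, 739, "0", 3,
          "9,12,9,", "0,109,230,", sep = "\t")), f)
  ex <- read_exon_models(f)
  expect_identical(nrow(ex), 6L)
  a <- ex[ex$transcript_id == "txA", ]
  expect_identical(a$start, c(101L, 210L, 331L))
  expect_identical(a$end, c(109L, 221L, 339L))
  expect_identical(a$internal, c(FALSE, TRUE, FALSE))
  expect_identical(a$intron_up, c(NA_integer_, 100L, 109L))
  expect_identical(a$intron_down, c(100L, 109L, NA_integer_))
  expect_identical(a$phase, c(0L, 0L, 0L))  # 9 and 12 are multiples of 3
  b <- ex[ex$transcript_id == "txB", ]
  # minus strand: transcript order is reversed genomic order
  expect_identical(b$exon_rank, 1:3)
  expect_identical(b$start[1], 731L)  # tx first exon is genomic last
  expect_identical(b$intron_up, c(NA_integer_, 109L, 100L))
  expect_identical(b$internal, c(FALSE, TRUE, FALSE))
})

test_that("context extraction is strand-correct and windows truncate at junctions", {
  withr::with_seed(5, exon_seq <- rand_dna(50))
  off0 <- 10L
  wt <- substr(exon_seq, off0 + 1, off0 + 1)
  alt <- setdiff(c("A", "C", "G", "T"), wt)[1]
  ctx <- toy_ctx(exon_seq, off0, alt)
  # 11-base window centred on the variant
  expect_identical(nchar(ctx$wt_window), 11L)
  expect_identical(ctx$window_var_offset, 5L)
  expect_identical(ctx$wt_window, substr(exon_seq, off0 - 4, off0 + 6))
  # derived differs from wild type at exactly one position
  diffs <- which(strsplit(ctx$wt_window, "")[[1]] !=
                   strsplit(ctx$derived_window, "")[[1]])
  expect_identical(diffs, 6L)

  # minus strand: everything equals the reverse-complement mirror
  ctxm <- toy_ctx(exon_seq, off0, alt, strand = "-")
  expect_identical(ctxm$exon_wt, exon_seq)
  expect_identical(ctxm$wt_window, ctx$wt_window)
  expect_identical(ctxm$derived_window, ctx$derived_window)
  expect_identical(ctxm$dist_3ss, ctx$dist_3ss)
  expect_identical(ctxm$region_wt, ctx$region_wt)

  # variant 2 bases from the exon 3' end: truncated 8-base window
  off_end <- nchar(exon_seq) - 3L   # distance 3 from the end... offset 47
  ctx2 <- toy_ctx(exon_seq, nchar(exon_seq) - 3L,
                  setdiff(c("A", "C", "G", "T"),
                          substr(exon_seq, nchar(exon_seq) - 2,
                                 nchar(exon_seq) - 2))[1])
  expect_identical(nchar(ctx2$wt_window), 5L + 3L)  # 5 left + variant + 2 right

  # reference mismatch is reported with the position
  loc <- toy_locus(exon_seq, strrep("T", 60), strrep("T", 60))
  bad_wt <- setdiff(c("A", "C", "G", "T"), wt)[2]
  v <- toy_variant(pos = loc$exon$start + off0, wt = bad_wt, alt = alt)
  expect_error(extract_context(loc$genome, loc$exon, v),
               "REFERENCE_MISMATCH")
})

test_that("genomic-transcript coordinate mapping round-trips on both strands", {
  withr::with_seed(6, exon_seq <- rand_dna(30))
  for (strand in c("+", "-")) {
    loc <- toy_locus(exon_seq, strrep("C", 40), strrep("G", 40), strand)
    for (off0 in c(0L, 7L, 29L)) {
      pos <- if (strand == "+") loc$exon$start + off0 else loc$exon$end - off0
      wt_tx <- substr(exon_seq, off0 + 1, off0 + 1)
      alt_tx <- setdiff(c("A", "C", "G", "T"), wt_tx)[1]
      wt_g <- if (strand == "-") chartr("ACGT", "TGCA", wt_tx) else wt_tx
      alt_g <- if (strand == "-") chartr("ACGT", "TGCA", alt_tx) else alt_tx
      ctx <- extract_context(loc$genome, loc$exon,
                             toy_variant(pos = pos, wt = wt_g, alt = alt_g))
      expect_identical(ctx$offset, off0)
      expect_identical(ctx$wt_base, wt_tx)
      # round trip back to genomic
      back <- if (strand == "-") loc$exon$end - ctx$offset
        else loc$exon$start + ctx$offset
      expect_identical(back, pos)
    }
  }
})

test_that("consequence classification and the inclusion filters follow the rules", {
  # exon starting at codon position 1: CAA CAA CAA ... (Gln)
  exon_seq <- strrep("CAA", 10)
  # C->T at codon position 1 of an internal codon creates TAA (stop)
  ctx <- toy_ctx(exon_seq, 12L, "T")
  expect_identical(ctx$consequence, "nonsense")
  expect_identical(filter_variant(ctx)$reason, "NONSENSE")
  # A->G at codon position 3 (CAA->CAG): synonymous
  ctx <- toy_ctx(exon_seq, 14L, "G")
  expect_identical(ctx$consequence, "synonymous")
  expect_true(filter_variant(ctx)$keep)
  # A->C at codon position 2 (CAA->CCA): missense
  ctx <- toy_ctx(exon_seq, 13L, "C")
  expect_identical(ctx$consequence, "missense")

  # junction distance rule: the edge base is distance 1; distances 1-3
  # are excluded, distance 4 is kept
  withr::with_seed(7, exon_seq <- rand_dna(60))
  pick_alt <- function(off0) {
    wt <- substr(exon_seq, off0 + 1, off0 + 1)
    # transversion-ish choice that cannot create a premature stop in a
    # random frame is not guaranteed; use filter reason comparison only
    setdiff(c("A", "C", "G", "T"), wt)[1]
  }
  ctx3 <- toy_ctx(exon_seq, 2L, pick_alt(2L))   # distance 3
  expect_identical(ctx3$dist_3ss, 3L)
  expect_identical(filter_variant(ctx3)$reason, "NEAR_JUNCTION")
  ctx4 <- toy_ctx(exon_seq, 3L, pick_alt(3L))   # distance 4
  expect_identical(ctx4$dist_3ss, 4L)
  r4 <- filter_variant(ctx4)
  expect_true(r4$keep || r4$reason == "NONSENSE")

  # non-internal exons are rejected when metadata allows
  loc <- toy_locus(exon_seq, strrep("T", 60), strrep("T", 60))
  loc$exon$internal <- FALSE
  v <- toy_variant(pos = loc$exon$start + 20L,
                   wt = substr(exon_seq, 21, 21), alt = pick_alt(20L))
  ctx <- extract_context(loc$genome, loc$exon, v)
  expect_identical(filter_variant(ctx)$reason,
                   if (ctx$consequence == "nonsense") "NONSENSE"
                   else "NON_INTERNAL")
})

test_that("variant TSV and VCF readers accept SNVs and reject malformed records", {
  f <- withr::local_tempfile()
  writeLines(c("chrom\tpos\tallele_a\tallele_b\tid\tout1\tout2",
               "chr1\t100\tA\tG\trs1\tA\tA",
               "chr2\t200\tc\tt\trs2\t.\t."), f)
  v <- read_variants(f)
  expect_identical(nrow(v), 2L)
  expect_identical(v$allele_a, c("A", "C"))
  writeLines(c("chrom\tpos\tallele_a\tallele_b", "chr1\t100\tA\tA"), f)
  expect_error(read_variants(f), "malformed|non-SNV")

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\trs1\tA\tG\t.\t.\t.",
               "chr1\t150\trs2\tAT\tA\t.\t.\t.",
               "chr1\t180\trs3\tC\tT,G\t.\t.\t."), vcf)
  vv <- read_variants_vcf(vcf)
  expect_identical(nrow(vv), 2L)  # indel dropped
  expect_identical(vv$allele_b, c("G", "T"))
})
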