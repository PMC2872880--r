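test_that("ESR density is the labelled-window fraction", {
  set <- esr_motif_set("t", 6L, c(AAAAAA = "ESS"))
  d <- esr_density(set, strrep("A", 10))
  expect_equal(unname(d["ess"]), 1)   # 5/5 windows
  expect_equal(unname(d["ese"]), 0)
  d0 <- esr_density(set, "ACGTACGTAC")
  expect_equal(unname(d0["ess"]), 0)
  # too short: unscored
  short <- esr_density(set, "ACGT")
  expect_true(all(is.na(short)))
  # oracle on random sequences and sets
  withr::with_seed(17, {
    for (rep in 1:15) {
      map <- setNames(sample(c("ESE", "ESS"), 400, replace = TRUE),
                      sample(savscan:::all_kmers(6), 400))
      s <- esr_motif_set("r", 6L, map)
      seq <- rand_dna(60)
      d <- esr_density(s, seq)
      expect_equal(unname(d["ese"]), o_density(map, seq, 6, "ESE"))
      expect_equal(unname(d["ess"]), o_density(map, seq, 6, "ESS"))
      expect_lte(d["ese"] + d["ess"], 1)
    }
  })
})

test_that("summed PWM density adds per-matrix window fractions", {
  z <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  always <- list(motif_name = "hit", threshold = -1, weights = z)
  never <- list(motif_name = "miss", threshold = Inf, weights = z)
  pw <- pwm_set("p", list(always, never))
  expect_equal(esefinder_density(pw, strrep("A", 30)), 1)
  pw2 <- pwm_set("p2", list(never))
  expect_equal(esefinder_density(pw2, strrep("A", 30)), 0)
  # per-matrix oracle sums on a random fixture
  withr::with_seed(27, {
    mats <- lapply(1:4, function(i) {
      L <- sample(5:8, 1)
      list(motif_name = paste0("m", i), threshold = runif(1, -1, 1),
           weights = matrix(runif(4 * L, -2, 2), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
    })
    pw4 <- pwm_set("p4", mats)
    seq <- rand_dna(50)
  })
  want <- sum(vapply(mats, function(m) {
    L <- ncol(m$weights)
    hits <- sum(vapply(0:(50 - L), function(s)
      o_pwm_score(m$weights, substr(seq, s + 1, s + L)) >= m$threshold, NA))
    hits / (50 - L + 1)
  }, 0))
  expect_equal(esefinder_density(pw4, seq), want)
})

test_that("intron flank densities use positions 3-102 and the 102-bp filter", {
  set <- esr_motif_set("t", 6L, c(TTTTTT = "ESS"))
  exon_seq <- strrep("GCA", 40)
  # flank construction: intron bases 3..102 are all T on both sides
  up <- paste0(strrep("T", 100), "AG")          # acceptor side, tx orientation
  dn <- paste0("GT", strrep("T", 100))          # donor side
  loc <- toy_locus(exon_seq, up, dn)
  r <- intron_flank_density(set, loc$genome, loc$exon)
  expect_false(r$excluded)
  expect_equal(unname(r$upstream["ess"]), 1)
  expect_equal(unname(r$downstream["ess"]), 1)
  # intron of 101 bp: excluded
  loc2 <- toy_locus(exon_seq, substr(up, 1, 101), dn)
  expect_true(intron_flank_density(set, loc2$genome, loc2$exon)$excluded)
  # exactly 102: scored on exactly 100 bases (95 hexamer windows)
  loc3 <- toy_locus(exon_seq, up, dn)
  expect_identical(loc3$exon$intron_up, 102L)
  r3 <- intron_flank_density(set, loc3$genome, loc3$exon)
  expect_false(r3$excluded)
  # minus strand mirrors
  locm <- toy_locus(exon_seq, up, dn, strand = "-")
  rm <- intron_flank_density(set, locm$genome, locm$exon)
  expect_equal(rm$upstream, r$upstream)
})

test_that("six-section binning is half-open, clamped and mirror-symmetric", {
  ex <- toy_exon(start = 101L, end = 700L)  # length 600
  expect_identical(exon_position_section(ex, 101L)$section, 1L)
  expect_true(exon_position_section(ex, 101L)$peripheral)
  expect_identical(exon_position_section(ex, 700L)$section, 6L)
  # offset 300 (0-based) sits at the open edge of bin 4
  expect_identical(exon_position_section(ex, 401L)$section, 4L)
  expect_false(exon_position_section(ex, 401L)$peripheral)
  expect_error(exon_position_section(ex, 60L), "outside")
  # reverse-complement symmetry: section i maps to 7 - i
  exm <- toy_exon(strand = "-", start = 101L, end = 700L)
  withr::with_seed(37, ps <- sample(101:700, 40))
  for (p in ps) {
    s_plus <- exon_position_section(ex, p)$section
    s_minus <- exon_position_section(exm, p)$section
    expect_identical(s_minus, 7L - s_plus)
  }
})

test_that("the exon-length SNP model follows the stated formula", {
  lens <- c(rep(100L, 500), rep(200L, 250))
  d <- expected_snp_exon_length_dist(lens, p_snp = 0.001)
  expect_equal(d$fr[d$length == 100], 0.5)        # 0.001 * 500
  expect_equal(d$fr[d$length == 200], 0.25)
  expect_true(all(expected_snp_exon_length_dist(lens, p_snp = 0)$fr == 0))
  # length-weighted mode reproduces per-base SNP placement frequencies
  withr::with_seed(47, {
    pool <- c(rep(60L, 3000), rep(300L, 1000))
    dw <- expected_snp_exon_length_dist(pool, p_snp = 0.001,
                                        length_weighted = TRUE)
    # simulate SNP placement: each base is a SNP independently; count
    # exons containing >= 1 SNP by length (small p, so ~ p * n * obs)
    hit60 <- sum(stats::rbinom(3000, 60, 0.001) > 0)
    hit300 <- sum(stats::rbinom(1000, 300, 0.001) > 0)
    expect_equal(dw$fr[dw$length == 60], 0.001 * 60 * 3000)
    expect_lt(abs(hit60 - dw$fr[dw$length == 60]) /
                max(dw$fr[dw$length == 60], 1), 0.25)
    expect_lt(abs(hit300 - dw$fr[dw$length == 300]) /
                max(dw$fr[dw$length == 300], 1), 0.25)
  })
})

test_that("junction occupancy recovers planted silencer positions", {
  set <- esr_motif_set("t", 6L, c(CCCCCC = "ESS", GGGGGG = "ESE"))
  # genome with one qualifying exon; ESS hexamer planted at intron
  # positions -10..-5 upstream of the acceptor
  exon_seq <- strrep("ATG", 40)                        # 120 bp
  up <- paste0(strrep("T", 200 - 10), "CCCCCC", "TTAG")  # ESS at -10..-5
  dn <- paste0("GT", strrep("T", 220))
  loc <- toy_locus(exon_seq, up, dn)
  prof <- junction_occupancy_profile(set, loc$genome, loc$exon)
  acc <- prof[prof$junction == "acceptor", ]
  expect_equal(acc$ess[acc$position == -10], 1)
  expect_equal(acc$ess[acc$position == -9], 0)
  expect_true(all(prof$ese >= 0 & prof$ese <= 1))
  expect_true(all(prof$ese + prof$ess <= 1))
  # filters: too-short exon or intron excluded; none qualifying errors
  small <- toy_locus(strrep("A", 60), up, dn)
  expect_error(junction_occupancy_profile(set, small$genome, small$exon),
               "no exons")
})

test_that("natural splice-site strengths flag non-canonical junctions", {
  don <- "CAGGTAAGT"; acc <- paste0(strrep("T", 18), "AG", "GTT")
  model <- train_splice_model(don, acc)
  exon_seq <- paste0("GTT", strrep("ATG", 30), "CAG")
  up <- paste0(strrep("T", 100), "AG")
  dn <- paste0("GTAAGT", strrep("T", 100))
  loc <- toy_locus(exon_seq, up, dn)
  s <- splice_site_strengths(model, loc$genome, loc$exon)
  expect_false(s$noncanonical)
  # identical exon scored twice: identical pair
  s2 <- splice_site_strengths(model, loc$genome, loc$exon)
  expect_identical(s, s2)
  # scores match direct backend invocation on hand-extracted windows
  expect_equal(s$score_5ss, score_splice_site(model, "CAGGTAAGT", "5p"))
  expect_equal(s$score_3ss,
               score_splice_site(model, paste0(strrep("T", 18), "AG", "GTT"),
                                 "3p"))
  # GC donor: flagged
  dn_gc <- paste0("GCAAGT", strrep("T", 100))
  loc_gc <- toy_locus(exon_seq, up, dn_gc)
  expect_true(splice_site_strengths(model, loc_gc$genome,
                                    loc_gc$exon)$noncanonical)
  # exon inclusion filter: length bounds and GT-AG
  exons <- rbind(loc$exon, loc_gc$exon)
  exons$chrom <- c("chr1", "chr1")
  keep <- filter_exons(loc$genome, exons[1, , drop = FALSE])
  expect_true(keep)
  keep_gc <- filter_exons(loc_gc$genome, exons[2, , drop = FALSE])
  expect_false(keep_gc)
  long <- toy_locus(strrep("A", 1200), up, dn)
  expect_false(filter_exons(long$genome, long$exon))
})
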