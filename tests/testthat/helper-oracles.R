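# Independent brute-force oracles, deliberately written with different
# code paths from the package implementation.

o_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

o_mutate <- function(seq, off0, base) {
  v <- strsplit(seq, "")[[1]]
  v[off0 + 1] <- base
  paste(v, collapse = "")
}

# label of a k-mer under a plain named-vector motif map
o_label <- function(map, kmer) {
  l <- map[kmer]
  if (is.na(l)) "NEUTRAL" else unname(l)
}

# all window-level change categories for a variant at 0-based off0 in seq
o_window_changes <- function(seq, off0, alt, map, k) {
  der <- o_mutate(seq, off0, alt)
  n <- nchar(seq)
  out <- character(0)
  for (s in 0:(n - k)) {
    if (off0 < s || off0 > s + k - 1) next
    w <- substr(seq, s + 1, s + k)
    d <- substr(der, s + 1, s + k)
    st <- function(l) switch(l, ESE = "ESE", ESS = "ESS",
                             UNLABELED_ESR = "ESR", "Neutral")
    sw <- st(o_label(map, w)); sd <- st(o_label(map, d))
    out <- c(out, if (sw == sd) paste0(sw, "~", sw) else paste0(sw, "->", sd))
  }
  out
}

o_change_counts <- function(seq, off0, alt, map, k) {
  cats <- o_window_changes(seq, off0, alt, map, k)
  c(ese_loss = sum(cats %in% c("ESE->Neutral", "ESE->ESS")),
    ess_gain = sum(cats %in% c("Neutral->ESS", "ESE->ESS")),
    ese_gain = sum(cats %in% c("Neutral->ESE", "ESS->ESE")),
    ess_loss = sum(cats %in% c("ESS->Neutral", "ESS->ESE")))
}

# density by explicit window loop
o_density <- function(map, seq, k, label) {
  n <- nchar(seq)
  hits <- 0; tot <- 0
  for (s in 1:(n - k + 1)) {
    tot <- tot + 1
    if (o_label(map, substr(seq, s, s + k - 1)) == label) hits <- hits + 1
  }
  hits / tot
}

# PWM window score by explicit loop
o_pwm_score <- function(weights, window) {
  b <- strsplit(window, "")[[1]]
  tot <- 0
  for (j in seq_along(b)) {
    i <- match(b[j], c("A", "C", "G", "T"))
    if (is.na(i)) return(NA_real_)
    tot <- tot + unname(weights[i, j])
  }
  tot
}

# delta-SS by explicit enumeration over all placements, both sides
o_delta_ss <- function(model, reg_wt, reg_der, v0) {
  best <- c(`5p` = -Inf, `3p` = -Inf)
  n <- nchar(reg_wt)
  for (side in c("5p", "3p")) {
    w <- if (side == "5p") 9 else 23
    for (s in 0:(n - w)) {
      if (v0 < s || v0 > s + w - 1) next
      ww <- substr(reg_wt, s + 1, s + w)
      wd <- substr(reg_der, s + 1, s + w)
      if (grepl("[^ACGT]", ww) || grepl("[^ACGT]", wd)) next
      best[side] <- max(best[side],
                        score_splice_site(model, wd, side) -
                          score_splice_site(model, ww, side))
    }
  }
  best
}

# RC by direct formula evaluation
o_rc <- function(rows, deltas) {
  m <- do.call(rbind, strsplit(rows, ""))
  tot <- 0
  for (i in seq_len(ncol(m))) {
    if (length(unique(m[, i])) == 1) tot <- tot + deltas[i]
  }
  tot / ncol(m)
}

# two-sample KS D by empirical-CDF sweep
o_ks_d <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Yates-corrected chi-squared, textbook formula
o_chi2_yates <- function(t) {
  n <- sum(t)
  e <- outer(rowSums(t), colSums(t)) / n
  sum((abs(t - e) - 0.5)^2 / e)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
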