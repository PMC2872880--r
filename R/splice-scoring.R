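# Splice-site strength and the delta-SS ectopic-site metric. Site windows
# are fixed: 9 bp for 5' (donor) sites (3 exonic + 6 intronic) and 23 bp
# for 3' (acceptor) sites (20 intronic + 3 exonic). The scoring backend is
# pluggable: a trainable position log-odds matrix (pseudocount 0.5, log
# base 2) that can also be serialised to / read from a parameter file, so
# externally trained maximum-entropy-style tables can be dropped in.

DONOR_WIDTH <- 9L      # 3 exon + 6 intron
ACCEPTOR_WIDTH <- 23L  # 20 intron + 3 exon
DONOR_EXONIC <- 3L
ACCEPTOR_EXONIC <- 3L

side_width <- function(side) {
  switch(side, "5p" = DONOR_WIDTH, "3p" = ACCEPTOR_WIDTH,
         stop("side must be '5p' or '3p'"))
}

#' Train a log-odds splice-site model
#'
#' Per-position base frequencies of the supplied true junction windows,
#' with pseudocount 0.5 per base, against a background distribution
#' (uniform by default, or base frequencies of supplied background
#' sequences). A window scores as the sum over positions of
#' `log2(f[base, pos] / bg[base])`.
#'
#' @param donor_windows character vector of true 9-mer donor windows.
#' @param acceptor_windows character vector of true 23-mer acceptor
#'   windows.
#' @param background optional character vector of background sequences
#'   used for base composition; uniform 0.25 when omitted.
#' @param pseudocount added per base per position (default 0.5).
#' @return object of class `splice_site_model`.
#' @export
train_splice_model <- function(donor_windows, acceptor_windows,
                               background = NULL, pseudocount = 0.5) {
  bg <- if (is.null(background)) {
    stats::setNames(rep(0.25, 4L), c("A", "C", "G", "T"))
  } else {
    chars <- strsplit(toupper(paste(background, collapse = "")), "")[[1L]]
    chars <- chars[chars %in% c("A", "C", "G", "T")]
    tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
    stats::setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
  }
  fit_one <- function(windows, width, what) {
    windows <- toupper(windows)
    if (any(nchar(windows) != width))
      stop(what, " training windows must all be ", width, " bp")
    if (any(grepl("[^ACGT]", windows)))
      stop(what, " training windows must be ACGT only")
    n <- length(windows)
    counts <- matrix(0, nrow = 4L, ncol = width,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (p in seq_len(width)) {
      tb <- table(factor(substr(windows, p, p), levels = c("A", "C", "G", "T")))
      counts[, p] <- as.numeric(tb)
    }
    freq <- sweep(counts + pseudocount, 2L, n + 4 * pseudocount, "/")
    log2(sweep(freq, 1L, bg, "/"))
  }
  structure(list(backend = "logodds",
                 donor = fit_one(donor_windows, DONOR_WIDTH, "donor"),
                 acceptor = fit_one(acceptor_windows, ACCEPTOR_WIDTH, "acceptor"),
                 background = bg, pseudocount = pseudocount),
            class = "splice_site_model")
}

#' Write / read a splice-site model parameter file
#'
#' Plain-text tables of per-position log-odds weights for the donor
#' (4 x 9) and acceptor (4 x 23) sites, in the [load_pwm_set()] matrix
#' dialect with headers `>donor 0` and `>acceptor 0`. Externally derived
#' weight tables in this layout are accepted as drop-in backends.
#'
#' @param model a `splice_site_model`.
#' @param path file path.
#' @export
write_splice_model <- function(model, path) {
  stopifnot(inherits(model, "splice_site_model"))
  pw <- pwm_set("splice_model", list(
    list(motif_name = "donor", threshold = 0, weights = model$donor),
    list(motif_name = "acceptor", threshold = 0, weights = model$acceptor)))
  write_pwm_set(pw, path)
}

#' @rdname write_splice_model
#' @return for `read_splice_model`, a `splice_site_model`.
#' @export
read_splice_model <- function(path) {
  pw <- load_pwm_set(path)
  if (!all(c("donor", "acceptor") %in% names(pw$matrices)))
    stop("splice model file needs 'donor' and 'acceptor' matrices")
  d <- pw$matrices$donor$weights
  a <- pw$matrices$acceptor$weights
  if (ncol(d) != DONOR_WIDTH || ncol(a) != ACCEPTOR_WIDTH)
    stop("donor must be 4x", DONOR_WIDTH, ", acceptor 4x", ACCEPTOR_WIDTH)
  structure(list(backend = "file", donor = d, acceptor = a,
                 background = NULL, pseudocount = NA_real_),
            class = "splice_site_model")
}

#' Score one splice-site window
#'
#' @param model a `splice_site_model`.
#' @param window DNA string of the side's width (9 for `5p`, 23 for
#'   `3p`), ACGT only.
#' @param side `"5p"` (donor) or `"3p"` (acceptor).
#' @return numeric score (higher = stronger site).
#' @export
score_splice_site <- function(model, window, side) {
  stopifnot(inherits(model, "splice_site_model"))
  width <- side_width(side)
  window <- toupper(window)
  if (nchar(window) != width)
    stop("window for side ", side, " must be ", width, " bp, got ",
         nchar(window))
  if (grepl("[^ACGT]", window))
    stop("window must be ACGT only")
  w <- if (side == "5p") model$donor else model$acceptor
  score_pwm_window(w, window)
}

# score every window of the given width whose 0-based start is in
# `starts` on sequence `seq`; NA for windows with non-ACGT content
score_windows <- function(model, seq, starts, side) {
  width <- side_width(side)
  vapply(starts, function(s) {
    win <- substr(seq, s + 1L, s + width)
    if (grepl("[^ACGT]", win)) NA_real_
    else score_splice_site(model, win, side)
  }, numeric(1L))
}

#' Delta-SS: maximal splice-site score change caused by a variant
#'
#' For each side, every 9-bp (5') or 23-bp (3') window containing the
#' variant is scored for the wild-type and derived alleles, sliding 1 bp
#' at a time and clipping to the available exon+intron sequence;
#' `delta_5ss`/`delta_3ss` are the per-side maxima of (derived - wild)
#' and `delta_ss = max(delta_5ss, delta_3ss)`. Natural-site scores are
#' read at the exon's annotated junctions with the same backend. A side
#' with no scorable window is reported absent (`NA`) and excluded from
#' the max.
#'
#' @param model a `splice_site_model`.
#' @param ctx a [extract_context()] result (built with `intron_extent`
#'   at least 20 for full acceptor windows).
#' @param ectopic_threshold delta-SS at or above which a variant is
#'   flagged ectopic-like (default 1).
#' @return object of class `delta_ss_result`.
#' @export
delta_ss <- function(model, ctx, ectopic_threshold = 1) {
  stopifnot(inherits(ctx, "variant_context"))
  reg_wt <- ctx$region_wt
  reg_der <- ctx$region_derived
  v <- ctx$region_var_offset
  n <- nchar(reg_wt)
  best <- list()
  n_windows <- list()
  for (side in c("5p", "3p")) {
    width <- side_width(side)
    starts <- max(0L, v - width + 1L):min(n - width, v)
    starts <- starts[starts >= 0L]
    if (!length(starts) || n < width) {
      best[[side]] <- list(delta = NA_real_, start = NA_integer_,
                           var_score = NA_real_)
      n_windows[[side]] <- 0L
      next
    }
    sw <- score_windows(model, reg_wt, starts, side)
    sd <- score_windows(model, reg_der, starts, side)
    ok <- !is.na(sw) & !is.na(sd)
    n_windows[[side]] <- sum(ok)
    if (!any(ok)) {
      best[[side]] <- list(delta = NA_real_, start = NA_integer_,
                           var_score = NA_real_)
      next
    }
    d <- sd - sw
    i <- which(ok)[which.max(d[ok])]
    # best ectopic site on this side: the highest-scoring variant-allele
    # window among those the variant improves (variant-generated sites)
    gen <- which(ok & d > 0)
    if (length(gen)) {
      j <- gen[which.max(sd[gen])]
      ect_start <- starts[j]; ect_score <- sd[j]
    } else {
      ect_start <- NA_integer_; ect_score <- NA_real_
    }
    best[[side]] <- list(delta = d[i], start = starts[i],
                         ect_start = ect_start, ect_score = ect_score)
  }
  deltas <- c(`5p` = best$`5p`$delta, `3p` = best$`3p`$delta)
  if (all(is.na(deltas))) {
    dss <- NA_real_
  } else {
    dss <- max(deltas, na.rm = TRUE)
  }
  # best ectopic site overall = strongest variant-generated site
  scores <- c(`5p` = best$`5p`$ect_score, `3p` = best$`3p`$ect_score)
  best_side <- if (all(is.na(scores))) NA_character_
    else names(scores)[which.max(scores)]
  nat <- natural_site_scores(model, ctx)
  ectopic_like <- !is.na(dss) && dss >= ectopic_threshold
  nat_same <- if (!is.na(best_side)) nat[[best_side]] else NA_real_
  ect_ge_nat <- !is.na(best_side) && !is.na(nat_same) &&
    !is.na(best[[best_side]]$ect_score) &&
    best[[best_side]]$ect_score >= nat_same
  structure(list(
    variant_id = ctx$variant$id,
    delta_5ss = best$`5p`$delta, delta_3ss = best$`3p`$delta,
    delta_ss = dss, best_side = best_side,
    best_start = if (!is.na(best_side)) best[[best_side]]$ect_start else NA_integer_,
    best_var_score = if (!is.na(best_side)) best[[best_side]]$ect_score else NA_real_,
    natural_5ss = nat$`5p`, natural_3ss = nat$`3p`,
    n_windows_5p = n_windows$`5p`, n_windows_3p = n_windows$`3p`,
    ectopic_like = ectopic_like, ectopic_ge_natural = ect_ge_nat,
    threshold = ectopic_threshold),
    class = "delta_ss_result")
}

# natural donor/acceptor window scores at the exon's annotated junctions,
# read from the ctx region (transcript orientation); NA when the region
# does not extend far enough into the introns
natural_site_scores <- function(model, ctx) {
  reg <- ctx$region_wt
  n <- nchar(reg)
  es <- ctx$region_exon_start          # 0-based offset of exon base 1
  ee <- es + ctx$exon_len - 1L         # 0-based offset of exon last base
  donor_start <- ee - DONOR_EXONIC + 1L
  acceptor_start <- es - (ACCEPTOR_WIDTH - ACCEPTOR_EXONIC)
  d <- if (donor_start >= 0L && donor_start + DONOR_WIDTH <= n) {
    win <- substr(reg, donor_start + 1L, donor_start + DONOR_WIDTH)
    if (grepl("[^ACGT]", win)) NA_real_ else score_splice_site(model, win, "5p")
  } else NA_real_
  a <- if (acceptor_start >= 0L && acceptor_start + ACCEPTOR_WIDTH <= n) {
    win <- substr(reg, acceptor_start + 1L, acceptor_start + ACCEPTOR_WIDTH)
    if (grepl("[^ACGT]", win)) NA_real_ else score_splice_site(model, win, "3p")
  } else NA_real_
  list(`5p` = d, `3p` = a)
}

#' Ectopic-site assessment of a delta-SS result
#'
#' Flags whether the variant looks ectopic-like (delta-SS at or above the
#' threshold), whether its best variant-allele site is at least as strong
#' as the natural site of the same side, and which exon half the variant
#' sits in relative to that matched natural site (`same-half` when the
#' variant lies in the half of the exon nearest the natural site of the
#' side it mimics, `opposite-half` otherwise — verified ectopic variants
#' sit same-half, ectopic-like neutral SNPs the opposite way).
#'
#' @param result a [delta_ss()] result.
#' @param ctx the matching [extract_context()] result.
#' @return list: `ectopic_like`, `ectopic_ge_natural`, `side`,
#'   `variant_half` (`"5p"`/`"3p"`), `position_class`
#'   (`same-half` / `opposite-half` / `NA`).
#' @export
ectopic_assessment <- function(result, ctx) {
  stopifnot(inherits(result, "delta_ss_result"),
            inherits(ctx, "variant_context"))
  # which half of the exon (donor half = nearer the exon 3' end)
  half <- if (ctx$dist_5ss <= ctx$dist_3ss) "5p" else "3p"
  pos_class <- if (is.na(result$best_side)) NA_character_
    else if (result$best_side == half) "same-half" else "opposite-half"
  list(ectopic_like = result$ectopic_like,
       ectopic_ge_natural = result$ectopic_ge_natural,
       side = result$best_side, variant_half = half,
       position_class = pos_class)
}

#' Select top-n ectopic-like controls from a scored cohort
#'
#' Filters to variants with delta-SS at or above the threshold, ranks by
#' the best ectopic variant-allele site score (descending, ties broken
#' by coordinate), and takes the top `n`. Used to build an ectopic-like
#' control cohort from neutral SNPs.
#'
#' @param scored data.frame with columns `chrom`, `pos`, `delta_ss`,
#'   `best_var_score` (one row per scored variant).
#' @param n number of controls wanted.
#' @param threshold minimum delta-SS (default 1).
#' @return the selected rows; warns when fewer than `n` qualify.
#' @export
select_ectopic_like_controls <- function(scored, n, threshold = 1) {
  stopifnot(all(c("chrom", "pos", "delta_ss", "best_var_score") %in%
                  names(scored)))
  if (n == 0L) return(scored[0L, , drop = FALSE])
  qual <- scored[!is.na(scored$delta_ss) & scored$delta_ss >= threshold, ,
                 drop = FALSE]
  if (!nrow(qual)) {
    warning("no variants reach delta-SS >= ", threshold)
    return(qual)
  }
  qual <- qual[order(-qual$best_var_score, qual$chrom, qual$pos), ,
               drop = FALSE]
  if (nrow(qual) < n)
    warning("only ", nrow(qual), " of the requested ", n,
            " ectopic-like controls qualify")
  utils::head(qual, n)
}

#' Flatten delta-SS results to a per-variant table
#' @param results list of [delta_ss()] results.
#' @return data.frame, one row per variant.
#' @export
delta_ss_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    variant_id = r$variant_id, delta_5ss = r$delta_5ss,
    delta_3ss = r$delta_3ss, delta_ss = r$delta_ss,
    best_side = if (is.na(r$best_side)) NA_character_ else r$best_side,
    best_start = r$best_start, best_var_score = r$best_var_score,
    natural_5ss = r$natural_5ss, natural_3ss = r$natural_3ss,
    ectopic_like = r$ectopic_like,
    ectopic_ge_natural = r$ectopic_ge_natural,
    stringsAsFactors = FALSE)))
}
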