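# ESR change classification: every motif window containing the variant is
# compared between the wild-type and derived alleles and binned into one of
# nine ordered change categories over the states {ESE, NEUTRAL, ESS}.

#' The nine ESR change categories
#'
#' Ordered (wild-type state, derived state) pairs over
#' `{ESE, NEUTRAL, ESS}`. `~` marks an alteration (same state both
#' alleles), `->` a state change; `ESE->ESS` and `ESS->ESE` are the two
#' direct conversions.
#'
#' @return character vector of the nine category names.
#' @export
change_categories <- function() {
  c("ESE~ESE", "ESE->Neutral", "ESE->ESS",
    "Neutral->ESE", "Neutral~Neutral", "Neutral->ESS",
    "ESS->ESE", "ESS->Neutral", "ESS~ESS")
}

# two-state scheme for unlabeled (Ast-ESR-style) sets
change_categories_2state <- function() {
  c("ESR~ESR", "ESR->Neutral", "Neutral->ESR", "Neutral~Neutral")
}

state_of <- function(label) {
  switch(label, ESE = "ESE", ESS = "ESS", UNLABELED_ESR = "ESR", "Neutral")
}

#' Classify the change between a wild-type and derived k-mer
#'
#' @param set an [esr_motif_set()].
#' @param wild_kmer,derived_kmer k-mers of length `set$k`.
#' @return a single category name; nine-category scheme for labelled
#'   sets, four-category `{ESR, Neutral}` scheme for unlabeled sets.
#' @export
classify_change_pair <- function(set, wild_kmer, derived_kmer) {
  sw <- state_of(classify_nmer(set, wild_kmer))
  sd <- state_of(classify_nmer(set, derived_kmer))
  if (sw == sd) paste0(sw, "~", sw) else paste0(sw, "->", sd)
}

#' Enumerate all motif windows containing the variant
#'
#' Sliding k-mer windows over the exon-truncated variant context,
#' 5' to 3'. A mid-exon variant with full flanks yields exactly `k`
#' windows; fewer near junctions.
#'
#' @param ctx a [extract_context()] result (needs `flank >= k - 1`).
#' @param k motif length.
#' @return data.frame with `wild_kmer`, `derived_kmer`,
#'   `offset_of_variant` (1-based position of the variant within the
#'   k-mer, decreasing 5' to 3').
#' @export
variant_windows <- function(ctx, k) {
  stopifnot(inherits(ctx, "variant_context"))
  win <- ctx$wt_window
  der <- ctx$derived_window
  v <- ctx$window_var_offset  # 0-based in window
  n <- nchar(win)
  if (n < k)
    return(data.frame(wild_kmer = character(0), derived_kmer = character(0),
                      offset_of_variant = integer(0)))
  starts <- max(0L, v - k + 1L):min(n - k, v)
  data.frame(
    wild_kmer = substring(win, starts + 1L, starts + k),
    derived_kmer = substring(der, starts + 1L, starts + k),
    offset_of_variant = v - starts + 1L,
    stringsAsFactors = FALSE)
}

#' Per-variant ESR change profile
#'
#' Aggregates [classify_change_pair()] over [variant_windows()] for each
#' motif set, and (optionally) PWM site loss/gain/alteration. A PWM site
#' is lost when a window scores `>= threshold` for the wild type and the
#' corresponding derived window scores below it; gained for the reverse;
#' altered when both score with differing values. For each lost site the
#' 1-based position of the variant within the motif is recorded
#' (per-position loss analysis).
#'
#' @param ctx a [extract_context()] result.
#' @param sets list of [esr_motif_set()] objects.
#' @param pwms optional [pwm_set()].
#' @return object of class `esr_change_profile`: per-set category counts,
#'   `combined_extent` (= ESE losses + ESS gains), and a `pwm` block.
#' @export
change_profile <- function(ctx, sets, pwms = NULL) {
  stopifnot(inherits(ctx, "variant_context"))
  if (inherits(sets, "esr_motif_set")) sets <- list(sets)
  per_set <- list()
  for (set in sets) {
    w <- variant_windows(ctx, set$k)
    cats <- if (nrow(w))
      vapply(seq_len(nrow(w)), function(i)
        classify_change_pair(set, w$wild_kmer[i], w$derived_kmer[i]), "")
    else character(0)
    unlabeled <- any(set$motifs == "UNLABELED_ESR")
    lev <- if (unlabeled) change_categories_2state() else change_categories()
    counts <- table(factor(cats, levels = lev))
    counts <- stats::setNames(as.integer(counts), names(counts))
    # an ESE->ESS direct conversion is simultaneously an ESE loss and an
    # ESS gain, so it contributes to both tallies and twice to the extent
    per_set[[set$name]] <- list(
      counts = counts, n_windows = nrow(w),
      ese_loss = if (unlabeled) NA_integer_ else
        counts[["ESE->Neutral"]] + counts[["ESE->ESS"]],
      ese_gain = if (unlabeled) NA_integer_ else
        counts[["Neutral->ESE"]] + counts[["ESS->ESE"]],
      ese_alteration = if (unlabeled) NA_integer_ else counts[["ESE~ESE"]],
      ess_loss = if (unlabeled) NA_integer_ else
        counts[["ESS->Neutral"]] + counts[["ESS->ESE"]],
      ess_gain = if (unlabeled) NA_integer_ else
        counts[["Neutral->ESS"]] + counts[["ESE->ESS"]],
      ess_alteration = if (unlabeled) NA_integer_ else counts[["ESS~ESS"]],
      ese_to_ess = if (unlabeled) NA_integer_ else counts[["ESE->ESS"]],
      ess_to_ese = if (unlabeled) NA_integer_ else counts[["ESS->ESE"]],
      esr_loss = if (unlabeled) counts[["ESR->Neutral"]] else NA_integer_,
      esr_gain = if (unlabeled) counts[["Neutral->ESR"]] else NA_integer_,
      esr_alteration = if (unlabeled) counts[["ESR~ESR"]] else NA_integer_,
      combined_extent = if (unlabeled) NA_integer_ else
        (counts[["ESE->Neutral"]] + counts[["ESE->ESS"]]) +
        (counts[["Neutral->ESS"]] + counts[["ESE->ESS"]]))
  }
  pwm_block <- NULL
  if (!is.null(pwms)) {
    pwm_block <- pwm_change(ctx, pwms)
  }
  structure(list(variant_id = ctx$variant$id, sets = per_set, pwm = pwm_block),
            class = "esr_change_profile")
}

# PWM site loss/gain/alteration around the variant. Windows are the PWM-
# width windows containing the variant, truncated at exon boundaries.
pwm_change <- function(ctx, pwms) {
  out <- list()
  win <- ctx$wt_window; der <- ctx$derived_window
  v <- ctx$window_var_offset
  n <- nchar(win)
  for (m in pwms$matrices) {
    L <- ncol(m$weights)
    lost <- gained <- altered <- 0L
    lost_positions <- integer(0)
    if (n >= L) {
      starts <- max(0L, v - L + 1L):min(n - L, v)
      for (s in starts) {
        sw <- score_pwm_window(m$weights, substr(win, s + 1L, s + L))
        sd <- score_pwm_window(m$weights, substr(der, s + 1L, s + L))
        if (is.na(sw) || is.na(sd)) next
        hit_w <- sw >= m$threshold; hit_d <- sd >= m$threshold
        if (hit_w && !hit_d) {
          lost <- lost + 1L
          lost_positions <- c(lost_positions, v - s + 1L)
        } else if (!hit_w && hit_d) {
          gained <- gained + 1L
        } else if (hit_w && hit_d && sw != sd) {
          altered <- altered + 1L
        }
      }
    }
    out[[m$motif_name]] <- list(lost = lost, gained = gained,
                                altered = altered,
                                lost_positions = lost_positions)
  }
  out
}

#' Combined-extent bin of an ESR change profile
#'
#' Bins the per-variant combined extent (ESE losses + ESS gains) into
#' `0, 1, 2, 3, >=4`.
#'
#' @param profile an [change_profile()] result.
#' @param set_name which motif set.
#' @return character scalar in `c("0","1","2","3",">=4")`.
#' @export
extent_bin <- function(profile, set_name) {
  stopifnot(inherits(profile, "esr_change_profile"))
  if (!set_name %in% names(profile$sets))
    stop("unknown motif set in profile: ", set_name)
  x <- profile$sets[[set_name]]$combined_extent
  if (is.na(x)) stop("combined extent undefined for unlabeled set ", set_name)
  if (x >= 4L) ">=4" else as.character(x)
}

#' Flatten change profiles to a per-variant table
#'
#' One row per (variant, motif set) with the eight labelled-category
#' counts, combined extent and extent bin; suitable for TSV export.
#'
#' @param profiles list of [change_profile()] results.
#' @return data.frame.
#' @export
profile_table <- function(profiles) {
  rows <- list()
  for (p in profiles) {
    for (sn in names(p$sets)) {
      s <- p$sets[[sn]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = p$variant_id, set = sn, n_windows = s$n_windows,
        ese_loss = s$ese_loss, ese_gain = s$ese_gain,
        ese_alteration = s$ese_alteration,
        ess_loss = s$ess_loss, ess_gain = s$ess_gain,
        ess_alteration = s$ess_alteration,
        ese_to_ess = s$ese_to_ess, ess_to_ese = s$ess_to_ese,
        combined_extent = s$combined_extent,
        extent_bin = if (is.na(s$combined_extent)) NA_character_ else
          (if (s$combined_extent >= 4L) ">=4" else
             as.character(s$combined_extent)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
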