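# End-to-end per-variant scoring: polarisation, context extraction,
# inclusion filters, ESR change profiles, RC score, delta-SS block and
# exon-definition features, with per-variant reason codes on failure.

#' Score a variant cohort for all splice-modulation features
#'
#' One row per input variant. Variants that cannot be scored (no host
#' exon, reference mismatch, failed polarisation or inclusion filter)
#' get a populated `reason` column and NA features; scoring continues
#' for the rest.
#'
#' @param variants data.frame from [read_variants()] (columns `chrom`,
#'   `pos`, `allele_a`, `allele_b`, `id`, optional `out1`/`out2`).
#' @param genome a [load_genome()] result.
#' @param exons exon models from [read_exon_models()].
#' @param sets list of [esr_motif_set()] objects.
#' @param pwms optional [pwm_set()].
#' @param model optional `splice_site_model` for the delta-SS block.
#' @param maf_blocks optional [read_maf()] alignments for RC scoring.
#' @param rc_matrix optional `codon_constraint_matrix`.
#' @param flank exonic motif flank (default 5).
#' @param intron_extent intronic extent for splice windows (default 50).
#' @param apply_filters apply the nonsense / near-junction / internal-
#'   exon inclusion filters (default TRUE).
#' @param polarize_variants polarise with `out1`/`out2` when present
#'   (default TRUE); unpolarised variants treat `allele_a` as wild type.
#' @param max_batch refuse larger cohorts (default 200, the web-tool
#'   batch cap; raise for programmatic use).
#' @return data.frame report, one row per variant.
#' @export
score_variants <- function(variants, genome, exons, sets, pwms = NULL,
                           model = NULL, maf_blocks = NULL,
                           rc_matrix = NULL, flank = 5L,
                           intron_extent = 50L, apply_filters = TRUE,
                           polarize_variants = TRUE, max_batch = 200L) {
  if (inherits(sets, "esr_motif_set")) sets <- list(sets)
  if (nrow(variants) > max_batch)
    stop("cohort of ", nrow(variants), " exceeds max_batch = ", max_batch)
  has_out <- all(c("out1", "out2") %in% names(variants))
  pol <- if (polarize_variants && has_out)
    polarize(variants$allele_a, variants$allele_b,
             variants$out1, variants$out2)
  else data.frame(accepted = rep(TRUE, nrow(variants)),
                  ancestral = variants$allele_a,
                  derived = variants$allele_b, reason = "",
                  stringsAsFactors = FALSE)
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    base <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                       reason = "", stringsAsFactors = FALSE)
    if (!pol$accepted[i]) {
      base$reason <- pol$reason[i]
      rows[[i]] <- base; next
    }
    v$ancestral <- pol$ancestral[i]; v$derived <- pol$derived[i]
    exon <- select_host_exon(exons, v$chrom, v$pos)
    if (is.null(exon)) { base$reason <- "NO_HOST_EXON"; rows[[i]] <- base; next }
    kmax <- max(vapply(sets, function(s) s$k, 0L), 6L)
    ctx <- tryCatch(
      extract_context(genome, exon, v, flank = max(flank, kmax - 1L),
                      intron_extent = intron_extent),
      error = function(e) e)
    if (inherits(ctx, "error")) {
      base$reason <- if (grepl("REFERENCE_MISMATCH", conditionMessage(ctx)))
        "REFERENCE_MISMATCH" else "CONTEXT_ERROR"
      rows[[i]] <- base; next
    }
    if (apply_filters) {
      f <- filter_variant(ctx)
      if (!f$keep) { base$reason <- f$reason; rows[[i]] <- base; next }
    }
    base$transcript_id <- exon$transcript_id
    base$exon_rank <- exon$exon_rank
    base$strand <- exon$strand
    base$exon_length <- exon$length
    base$dist_3ss <- ctx$dist_3ss; base$dist_5ss <- ctx$dist_5ss
    base$min_junction_distance <- min(ctx$dist_3ss, ctx$dist_5ss)
    base$consequence <- ctx$consequence
    sec <- exon_position_section(exon, v$pos)
    base$exon_section <- sec$section
    base$peripheral <- sec$peripheral
    prof <- change_profile(ctx, sets, pwms)
    for (sn in names(prof$sets)) {
      s <- prof$sets[[sn]]
      base[[paste0(sn, "_ese_loss")]] <- s$ese_loss
      base[[paste0(sn, "_ese_gain")]] <- s$ese_gain
      base[[paste0(sn, "_ess_loss")]] <- s$ess_loss
      base[[paste0(sn, "_ess_gain")]] <- s$ess_gain
      base[[paste0(sn, "_ese_to_ess")]] <- s$ese_to_ess
      base[[paste0(sn, "_combined_extent")]] <- s$combined_extent
      base[[paste0(sn, "_extent_bin")]] <-
        if (is.na(s$combined_extent)) NA_character_
        else if (s$combined_extent >= 4L) ">=4"
        else as.character(s$combined_extent)
    }
    if (!is.null(model)) {
      d <- delta_ss(model, ctx)
      base$delta_5ss <- d$delta_5ss; base$delta_3ss <- d$delta_3ss
      base$delta_ss <- d$delta_ss
      base$best_side <- if (is.na(d$best_side)) NA_character_ else d$best_side
      base$best_var_score <- d$best_var_score
      base$natural_5ss <- d$natural_5ss; base$natural_3ss <- d$natural_3ss
      base$ectopic_like <- d$ectopic_like
      base$ectopic_ge_natural <- d$ectopic_ge_natural
    }
    if (!is.null(maf_blocks) && !is.null(rc_matrix)) {
      rc <- variant_rc(rc_matrix, maf_blocks, ctx)
      base$rc_score <- rc$rc
      base$rc_reason <- rc$reason
    }
    rows[[i]] <- base
  }
  if (!length(rows))
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  # rbind with column union
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-variant report as TSV
#' @param report a [score_variants()] result.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
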