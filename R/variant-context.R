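# Variant context construction: strand-normalised sequence around an exonic
# SNV, allele polarisation against two outgroups, and the inclusion filters.
#
# Coordinates are 1-based inclusive in all I/O (VCF convention) and 0-based
# offsets internally (transcript orientation within the exon).

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Read variants from a tab-delimited file
#'
#' Expected columns (header required): `chrom`, `pos` (1-based),
#' `allele_a`, `allele_b`; optional `id`, `out1`, `out2` (outgroup bases
#' for polarisation, `.` or `N` = missing). Only single-base substitutions
#' are accepted.
#'
#' @param path TSV path.
#' @return data.frame of variants.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  need <- c("chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  for (col in c("allele_a", "allele_b"))
    df[[col]] <- toupper(df[[col]])
  bad <- !(df$allele_a %in% BASES) | !(df$allele_b %in% BASES) |
    df$allele_a == df$allele_b
  if (any(bad))
    stop("non-SNV or malformed alleles at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ","))
  if (is.null(df$id)) df$id <- paste0("var", seq_len(nrow(df)))
  df
}

#' Read SNV records from a VCF
#'
#' Thin wrapper over `vcfR`; non-SNV records are dropped. REF becomes
#' `allele_a`, the first ALT `allele_b`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return data.frame in the [read_variants()] layout.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt1 <- vapply(strsplit(fix$ALT, ","), `[[`, "", 1L)
  keep <- nchar(fix$REF) == 1L & nchar(alt1) == 1L &
    toupper(fix$REF) %in% BASES & toupper(alt1) %in% BASES
  data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
             allele_a = toupper(fix$REF[keep]), allele_b = toupper(alt1[keep]),
             id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                         paste0("var", which(keep)), fix$ID[keep]),
             stringsAsFactors = FALSE)
}

#' Polarize a biallelic variant with two outgroup bases
#'
#' A variant is polarised (ancestral/derived assigned) only when both
#' outgroup bases are present, agree with each other, and match one of the
#' two human alleles; that allele becomes ancestral. Rejections are values
#' with reason codes, not errors.
#'
#' @param allele_a,allele_b the two alleles (vectorised).
#' @param out1,out2 outgroup bases; `NA`, `"."`, `"-"` or `"N"` = missing.
#' @return data.frame with columns `accepted`, `ancestral`, `derived`,
#'   `reason` (`MISSING_ALIGNMENT`, `OUTGROUP_DISAGREE`, `NO_ALLELE_MATCH`
#'   or `""`).
#' @export
polarize <- function(allele_a, allele_b, out1, out2) {
  n <- length(allele_a)
  stopifnot(length(allele_b) == n, length(out1) == n, length(out2) == n)
  norm <- function(x) {
    x <- toupper(as.character(x))
    x[is.na(x) | !(x %in% BASES)] <- NA_character_
    x
  }
  a <- norm(allele_a); b <- norm(allele_b)
  o1 <- norm(out1); o2 <- norm(out2)
  anc <- der <- rep(NA_character_, n)
  reason <- rep("", n)
  miss <- is.na(o1) | is.na(o2)
  reason[miss] <- "MISSING_ALIGNMENT"
  disag <- !miss & o1 != o2
  reason[disag] <- "OUTGROUP_DISAGREE"
  open <- !miss & !disag
  hit_a <- open & o1 == a
  hit_b <- open & o1 == b
  anc[hit_a] <- a[hit_a]; der[hit_a] <- b[hit_a]
  anc[hit_b] <- b[hit_b]; der[hit_b] <- a[hit_b]
  nomatch <- open & !hit_a & !hit_b
  reason[nomatch] <- "NO_ALLELE_MATCH"
  data.frame(accepted = reason == "", ancestral = anc, derived = der,
             reason = reason, stringsAsFactors = FALSE)
}

#' Read exon models from BED12
#'
#' Each BED12 line is one transcript; blocks are exons; `thickStart`/
#' `thickEnd` delimit the CDS. Returns one row per exon with transcript-
#' orientation intron lengths, internal-exon status and the CDS frame
#' offset (`phase`: number of CDS bases in earlier exons modulo 3; the
#' exon's first coding base sits at codon position `phase + 1`). Exons not
#' fully coding get `phase = NA`.
#'
#' @param path BED12 file.
#' @return data.frame of exon models (`exon_model` rows): `transcript_id`,
#'   `exon_rank` (transcript order), `chrom`, `strand`, `start`, `end`
#'   (1-based inclusive), `intron_up`, `intron_down` (transcript
#'   orientation; `NA` at transcript ends), `internal`, `phase`, `length`.
#' @export
read_exon_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!("blocks" %in% names(S4Vectors::mcols(gr))))
    stop("BED file ", path, " is not BED12 (no block structure)")
  rows <- list()
  for (ti in seq_along(gr)) {
    tx <- gr[ti]
    txid <- tx$name
    if (is.null(txid) || is.na(txid)) txid <- paste0("tx", ti)
    strand <- as.character(BiocGenerics::strand(tx))
    if (!strand %in% c("+", "-")) strand <- "+"
    bl <- tx$blocks[[1L]]  # rtracklayer: block ranges relative to the
    # feature start (1-based); convert to absolute genomic coordinates
    ex_start <- BiocGenerics::start(tx) + BiocGenerics::start(bl) - 1L
    ex_end <- BiocGenerics::start(tx) + BiocGenerics::end(bl) - 1L
    o <- order(ex_start)
    ex_start <- ex_start[o]; ex_end <- ex_end[o]
    nex <- length(ex_start)
    thick <- tx$thick
    cds_lo <- BiocGenerics::start(thick)[1L]
    cds_hi <- BiocGenerics::end(thick)[1L]
    # transcript order
    tord <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
    cum_cds <- 0L
    out <- vector("list", nex)
    for (r in seq_len(nex)) {
      gi <- tord[r]
      s <- ex_start[gi]; e <- ex_end[gi]
      # intron on transcript-5' side / 3' side
      if (strand == "+") {
        iu <- if (gi > 1L) s - ex_end[gi - 1L] - 1L else NA_integer_
        id <- if (gi < nex) ex_start[gi + 1L] - e - 1L else NA_integer_
      } else {
        iu <- if (gi < nex) ex_start[gi + 1L] - e - 1L else NA_integer_
        id <- if (gi > 1L) s - ex_end[gi - 1L] - 1L else NA_integer_
      }
      cod_lo <- max(s, cds_lo); cod_hi <- min(e, cds_hi)
      fully_coding <- cod_lo == s && cod_hi == e && cod_hi >= cod_lo
      phase <- if (fully_coding) cum_cds %% 3L else NA_integer_
      if (cod_hi >= cod_lo) cum_cds <- cum_cds + (cod_hi - cod_lo + 1L)
      out[[r]] <- data.frame(
        transcript_id = txid, exon_rank = r, chrom = as.character(
          GenomeInfoDb::seqnames(tx)), strand = strand,
        start = s, end = e, intron_up = iu, intron_down = id,
        internal = r > 1L && r < nex, phase = phase,
        length = e - s + 1L, stringsAsFactors = FALSE)
    }
    rows[[ti]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pick the host exon for a genomic position
#'
#' Among all exon models containing the position, the largest exon is
#' used; ties break to the lexicographically lowest transcript id.
#'
#' @param exons exon-model data.frame from [read_exon_models()].
#' @param chrom,pos variant location (1-based).
#' @return single exon-model row, or `NULL` when no exon contains the
#'   position.
#' @export
select_host_exon <- function(exons, chrom, pos) {
  hit <- exons[exons$chrom == chrom & exons$start <= pos & exons$end >= pos, ,
               drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit <- hit[order(-hit$length, hit$transcript_id), , drop = FALSE]
  hit[1L, , drop = FALSE]
}

#' Load a genome FASTA
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet` keyed by sequence name.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  n <- length(genome[[chrom]])
  start <- max(1L, start); end <- min(n, end)
  if (end < start) return("")
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

mutate_at <- function(seq, offset0, base) {
  paste0(substr(seq, 1L, offset0), base,
         substr(seq, offset0 + 2L, nchar(seq)))
}

#' Build the strand-normalised context of a polarised variant
#'
#' All sequences are transcript-orientation (reverse-complemented for
#' minus-strand genes); the wild type carries the ancestral allele and
#' the derived sequence differs at exactly one position. The motif-window
#' context is truncated at the exon boundary (ESRs are exonic); a wider
#' exon+intron region is retained for splice-site windows.
#'
#' Junction distances count the exon edge base as distance 1; the curated-cohort
#' inclusion filter "3 bp or less from either splice junction" therefore
#' excludes distances 1-3.
#'
#' @param genome `DNAStringSet` from [load_genome()].
#' @param exon one exon-model row.
#' @param variant one-row data.frame with `chrom`, `pos`, `id` and either
#'   polarised `ancestral`/`derived` or `allele_a` (wild type) /
#'   `allele_b` columns (genomic-strand bases).
#' @param flank exonic flank either side of the variant for motif windows
#'   (default 5: all hexamers containing the variant, 11 bp total).
#' @param intron_extent intronic bases retained either side for
#'   splice-site windows (default 50).
#' @return object of class `variant_context`.
#' @export
extract_context <- function(genome, exon, variant, flank = 5L,
                            intron_extent = 50L) {
  stopifnot(nrow(variant) == 1L, nrow(exon) == 1L)
  pos <- variant$pos
  if (pos < exon$start || pos > exon$end)
    stop("variant ", variant$id, " not inside exon interval")
  wt_g <- if (!is.null(variant$ancestral) && !is.na(variant$ancestral))
    variant$ancestral else variant$allele_a
  der_g <- if (!is.null(variant$derived) && !is.na(variant$derived))
    variant$derived else variant$allele_b
  ref <- genome_seq(genome, exon$chrom, pos, pos)
  if (!identical(ref, wt_g))
    stop("REFERENCE_MISMATCH at ", exon$chrom, ":", pos,
         " (FASTA ", ref, ", wild-type allele ", wt_g, ")")
  minus <- exon$strand == "-"
  exon_seq_g <- genome_seq(genome, exon$chrom, exon$start, exon$end)
  exon_wt <- if (minus) revcomp(exon_seq_g) else exon_seq_g
  offset <- if (minus) exon$end - pos else pos - exon$start  # 0-based, tx orient
  wt_t <- if (minus) comp_base(wt_g) else wt_g
  der_t <- if (minus) comp_base(der_g) else der_g
  exon_der <- mutate_at(exon_wt, offset, der_t)
  exon_len <- exon$length
  # exon-truncated motif window
  lo <- max(0L, offset - flank)
  hi <- min(exon_len - 1L, offset + flank)
  wt_window <- substr(exon_wt, lo + 1L, hi + 1L)
  derived_window <- substr(exon_der, lo + 1L, hi + 1L)
  # exon + intron region for splice windows (clipped to annotated introns
  # and to the chromosome)
  up_ext <- min(intron_extent, if (is.na(exon$intron_up)) 0L else exon$intron_up)
  dn_ext <- min(intron_extent, if (is.na(exon$intron_down)) 0L else exon$intron_down)
  if (minus) {
    reg_g <- genome_seq(genome, exon$chrom, exon$start - dn_ext, exon$end + up_ext)
    region_wt <- revcomp(reg_g)
  } else {
    region_wt <- genome_seq(genome, exon$chrom, exon$start - up_ext, exon$end + dn_ext)
  }
  region_exon_start <- up_ext  # 0-based offset of exon base 1 in region
  region_var_offset <- region_exon_start + offset
  region_der <- mutate_at(region_wt, region_var_offset, der_t)
  # codon position / consequence
  codon_pos <- NA_integer_; consequence <- NA_character_
  codon_wt <- codon_der <- NA_character_
  if (!is.na(exon$phase)) {
    codon_pos <- ((exon$phase + offset) %% 3L) + 1L
    cstart <- offset - (codon_pos - 1L)
    if (cstart >= 0L && cstart + 2L <= exon_len - 1L) {
      codon_wt <- substr(exon_wt, cstart + 1L, cstart + 3L)
      codon_der <- substr(exon_der, cstart + 1L, cstart + 3L)
      aa_wt <- unname(Biostrings::GENETIC_CODE[codon_wt])
      aa_der <- unname(Biostrings::GENETIC_CODE[codon_der])
      consequence <- if (aa_der == "*" && aa_wt != "*") "nonsense"
        else if (aa_wt == aa_der) "synonymous" else "missense"
    }
  }
  structure(list(
    variant = variant, exon = exon,
    offset = offset, exon_len = exon_len,
    wt_base = wt_t, derived_base = der_t,
    exon_wt = exon_wt, exon_derived = exon_der,
    wt_window = wt_window, derived_window = derived_window,
    window_var_offset = offset - lo,
    region_wt = region_wt, region_derived = region_der,
    region_var_offset = region_var_offset,
    region_exon_start = region_exon_start,
    dist_3ss = offset + 1L,              # exon-start (acceptor) side
    dist_5ss = exon_len - offset,        # exon-end (donor) side
    codon_pos = codon_pos, codon_wt = codon_wt, codon_derived = codon_der,
    consequence = consequence),
    class = "variant_context")
}

#' @export
print.variant_context <- function(x, ...) {
  cat("variant_context ", x$variant$id, " ", x$exon$chrom, ":",
      x$variant$pos, " ", x$wt_base, ">", x$derived_base,
      " exon ", x$exon$transcript_id, "#", x$exon$exon_rank,
      " offset ", x$offset, "/", x$exon_len,
      " d3ss=", x$dist_3ss, " d5ss=", x$dist_5ss,
      " [", x$consequence, "]\n", sep = "")
  invisible(x)
}

#' Apply the variant inclusion filters
#'
#' Rejects nonsense (stop-gain) variants, variants 3 bp or less from
#' either splice junction (edge base = distance 1, so distances 1-3 are
#' excluded and distance 4 is kept), and variants in non-internal
#' (first/last) exons when the exon metadata allows the check.
#'
#' @param ctx a [extract_context()] result.
#' @param max_junction_excl junction distances `<=` this are rejected
#'   (default 3).
#' @param require_internal reject first/last exons (default TRUE).
#' @return list with `keep` (logical) and `reason` (`""`, `NONSENSE`,
#'   `NEAR_JUNCTION`, `NON_INTERNAL`).
#' @export
filter_variant <- function(ctx, max_junction_excl = 3L,
                           require_internal = TRUE) {
  stopifnot(inherits(ctx, "variant_context"))
  if (!is.na(ctx$consequence) && ctx$consequence == "nonsense")
    return(list(keep = FALSE, reason = "NONSENSE"))
  if (min(ctx$dist_3ss, ctx$dist_5ss) <= max_junction_excl)
    return(list(keep = FALSE, reason = "NEAR_JUNCTION"))
  if (require_internal && !isTRUE(ctx$exon$internal))
    return(list(keep = FALSE, reason = "NON_INTERNAL"))
  list(keep = TRUE, reason = "")
}
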