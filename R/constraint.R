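# Regulatory constraint in coding sequence: a 192-entry codon-position
# scoring matrix built from genome-wide alignments (score = (1 - Pr) * 10,
# Pr = proportion of fully conserved columns for that codon position), and
# the RC score of a window: the matrix-weighted sum of fully conserved
# columns, normalised by alignment length.

#' Read a MAF (multiple alignment format) file
#'
#' Minimal reference-anchored reader: `a` lines open blocks, `s` lines
#' carry `src start size strand srcSize text` with 0-based starts (MAF
#' convention). The first `s` row of each block is the reference.
#'
#' @param path MAF path.
#' @return list of blocks; each block is a data.frame with columns
#'   `src`, `start`, `size`, `strand`, `srcSize`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) {
      blocks[[length(blocks) + 1L]] <<- do.call(rbind, cur)
    }
    cur <<- NULL
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) { flush(); cur <- list() }
    else if (grepl("^s ", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 7L) stop("malformed MAF s-line: ", ln)
      cur[[length(cur) + 1L]] <- data.frame(
        src = f[2L], start = as.integer(f[3L]), size = as.integer(f[4L]),
        strand = f[5L], srcSize = as.integer(f[6L]), text = toupper(f[7L]),
        stringsAsFactors = FALSE)
    }
  }
  flush()
  blocks
}

#' Write MAF blocks (inverse of [read_maf()])
#' @param blocks list of block data.frames.
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  out <- c("##maf version=1", "")
  for (b in blocks) {
    out <- c(out, "a score=0")
    for (i in seq_len(nrow(b)))
      out <- c(out, paste("s", b$src[i], b$start[i], b$size[i], b$strand[i],
                          b$srcSize[i], b$text[i]))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Extract the aligned rows covering an exon, transcript orientation.
# Reference row must be the first row of a block, on the + strand, named
# "<genome>.<chrom>" or plain "<chrom>". Returns NULL when no block fully
# covers the exon; list(rows=<named character>, gapped=<logical>) otherwise.
exon_alignment <- function(maf_blocks, exon) {
  for (b in maf_blocks) {
    ref <- b[1L, ]
    chrom <- sub("^[^.]*\\.", "", ref$src)
    if (chrom != exon$chrom || ref$strand != "+") next
    ref_ungapped <- gsub("-", "", ref$text)
    ref_lo <- ref$start + 1L  # 1-based
    ref_hi <- ref$start + nchar(ref_ungapped)
    if (exon$start < ref_lo || exon$end > ref_hi) next
    # map genomic positions to alignment columns
    chars <- strsplit(ref$text, "")[[1L]]
    is_base <- chars != "-"
    gpos <- cumsum(is_base) + ref$start  # genomic 1-based position per column
    cols <- which(is_base & gpos >= exon$start & gpos <= exon$end)
    rows <- vapply(seq_len(nrow(b)), function(i) {
      paste(strsplit(b$text[i], "")[[1L]][cols], collapse = "")
    }, "")
    names(rows) <- b$src
    if (exon$strand == "-") rows <- vapply(rows, revcomp, "")
    gapped <- any(grepl("[-N]", rows))
    return(list(rows = rows, gapped = gapped))
  }
  NULL
}

CODONS <- all_kmers(3L)

#' Build the 192-entry codon-position constraint matrix
#'
#' For every aligned coding column (all species present, no gaps, at
#' least two species besides the reference) the (codon, position) cell's
#' observation and conservation totals are incremented; a column is
#' conserved when identical across all rows. The cell score is
#' `(1 - Pr) * 10` where `Pr` is the conserved fraction, so the least
#' conserved codon positions genome-wide (e.g. third positions of
#' hypermutable CpG codons) receive the highest scores.
#'
#' @param maf_blocks from [read_maf()].
#' @param exons exon-model data.frame; only fully coding exons with known
#'   `phase` contribute.
#' @return object of class `codon_constraint_matrix`: data.frame `table`
#'   with `codon`, `position`, `observed`, `conserved`, `pr`, `score`
#'   (NA where a cell has no observations).
#' @export
build_codon_matrix <- function(maf_blocks, exons) {
  obs <- cons <- matrix(0L, nrow = 64L, ncol = 3L,
                        dimnames = list(CODONS, NULL))
  use <- exons[!is.na(exons$phase), , drop = FALSE]
  for (r in seq_len(nrow(use))) {
    ex <- use[r, , drop = FALSE]
    al <- exon_alignment(maf_blocks, ex)
    if (is.null(al) || length(al$rows) < 3L || al$gapped) next
    mat <- do.call(rbind, strsplit(unname(al$rows), ""))
    n <- ncol(mat)
    refrow <- mat[1L, ]
    codpos <- ((ex$phase + seq_len(n) - 1L) %% 3L) + 1L
    cstart <- seq_len(n) - (codpos - 1L)
    cend <- cstart + 2L
    ok <- cstart >= 1L & cend <= n
    conserved_col <- apply(mat, 2L, function(col) all(col == col[1L]))
    for (i in which(ok)) {
      codon <- paste(refrow[cstart[i]:cend[i]], collapse = "")
      if (!codon %in% CODONS) next
      obs[codon, codpos[i]] <- obs[codon, codpos[i]] + 1L
      if (conserved_col[i]) cons[codon, codpos[i]] <- cons[codon, codpos[i]] + 1L
    }
  }
  tab <- data.frame(
    codon = rep(CODONS, times = 3L),
    position = rep(1:3, each = 64L),
    observed = as.integer(obs), conserved = as.integer(cons),
    stringsAsFactors = FALSE)
  tab$pr <- ifelse(tab$observed > 0, tab$conserved / tab$observed, NA_real_)
  tab$score <- (1 - tab$pr) * 10
  structure(list(table = tab), class = "codon_constraint_matrix")
}

#' @export
print.codon_constraint_matrix <- function(x, ...) {
  ok <- !is.na(x$table$score)
  cat("codon constraint matrix: ", sum(ok), "/192 cells observed, score range [",
      round(min(x$table$score[ok]), 3), ", ",
      round(max(x$table$score[ok]), 3), "]\n", sep = "")
  invisible(x)
}

matrix_score <- function(matrix, codon, position) {
  tab <- matrix$table
  i <- match(paste(codon, position), paste(tab$codon, tab$position))
  if (any(is.na(i))) stop("unknown codon/position key")
  s <- tab$score[i]
  if (any(is.na(s)))
    stop("constraint matrix cell(s) with no observations: ",
         paste(utils::head(paste0(codon, "/", position)[is.na(s)], 3L),
               collapse = ", "))
  s
}

#' Read / write a constraint matrix as 192-row TSV
#' @param path TSV path.
#' @return a `codon_constraint_matrix`.
#' @export
read_codon_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "position", "observed", "conserved", "pr", "score")
  if (!all(need %in% names(tab))) stop("matrix TSV needs columns: ",
                                       paste(need, collapse = ", "))
  structure(list(table = tab[need]), class = "codon_constraint_matrix")
}

#' @rdname read_codon_matrix
#' @param matrix a `codon_constraint_matrix`.
#' @export
write_codon_matrix <- function(matrix, path) {
  utils::write.table(matrix$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' RC score of an alignment window
#'
#' `RC = sum_i S_i * delta_ci / N` over the `N` columns of an ungapped
#' alignment window: `S_i` is 1 when column `i` is identical across all
#' rows, and `delta_ci` is the constraint-matrix weight of the reference
#' codon position at column `i`.
#'
#' @param matrix a `codon_constraint_matrix`.
#' @param rows character vector of aligned row strings, reference first;
#'   at least 3 rows, equal lengths, no gaps.
#' @param codons,positions per-column reference codon (3-mer) and codon
#'   position (1-3).
#' @return the RC score (non-negative real).
#' @export
rc_score <- function(matrix, rows, codons, positions) {
  stopifnot(inherits(matrix, "codon_constraint_matrix"))
  if (length(rows) < 3L) stop("need reference plus at least two species")
  n <- unique(nchar(rows))
  if (length(n) != 1L || n == 0L) stop("rows must be equal, non-zero length")
  if (any(grepl("[-N]", rows))) stop("window must be ungapped (no -/N)")
  if (length(codons) != n || length(positions) != n)
    stop("need one codon key per column")
  m <- do.call(rbind, strsplit(rows, ""))
  s_i <- apply(m, 2L, function(col) as.integer(all(col == col[1L])))
  delta <- matrix_score(matrix, codons, positions)
  sum(s_i * delta) / n
}

#' RC score of the region surrounding a variant
#'
#' Builds the window of up to 5 bp either side of the variant (all
#' hexamers containing it, 11 bp total; truncated at the splice
#' junctions), applies the row and gap filters, and scores it. Columns
#' whose reference codon is not fully inside the exon are dropped from
#' the window. Failures are values, not errors.
#'
#' @param matrix a `codon_constraint_matrix`.
#' @param maf_blocks from [read_maf()].
#' @param ctx a [extract_context()] result (exon must have known phase).
#' @param flank window half-width in exonic bases (default 5).
#' @return list with `scored` (logical), `rc` (score or `NA`), `n_columns`
#'   and `reason` (`""`, `NO_ALIGNMENT`, `GAPPED`, `TOO_FEW_SPECIES`,
#'   `NO_FRAME`, `NO_CODON_COLUMNS`).
#' @export
variant_rc <- function(matrix, maf_blocks, ctx, flank = 5L) {
  stopifnot(inherits(ctx, "variant_context"))
  unscored <- function(reason) list(scored = FALSE, rc = NA_real_,
                                    n_columns = 0L, reason = reason)
  ex <- ctx$exon
  if (is.na(ex$phase)) return(unscored("NO_FRAME"))
  al <- exon_alignment(maf_blocks, ex)
  if (is.null(al)) return(unscored("NO_ALIGNMENT"))
  if (length(al$rows) < 3L) return(unscored("TOO_FEW_SPECIES"))
  if (al$gapped) return(unscored("GAPPED"))
  lo <- max(0L, ctx$offset - flank)
  hi <- min(ctx$exon_len - 1L, ctx$offset + flank)
  cols <- (lo + 1L):(hi + 1L)
  rows <- vapply(al$rows, function(r) substr(r, lo + 1L, hi + 1L), "",
                 USE.NAMES = FALSE)
  codpos <- ((ex$phase + cols - 1L) %% 3L) + 1L
  cstart <- cols - (codpos - 1L)
  keep <- cstart >= 1L & cstart + 2L <= ctx$exon_len
  if (!any(keep)) return(unscored("NO_CODON_COLUMNS"))
  codons <- vapply(which(keep), function(j)
    substr(ctx$exon_wt, cstart[j], cstart[j] + 2L), "")
  sub_rows <- vapply(rows, function(r)
    paste(strsplit(r, "")[[1L]][keep], collapse = ""), "", USE.NAMES = FALSE)
  rc <- rc_score(matrix, sub_rows, codons, codpos[keep])
  list(scored = TRUE, rc = rc, n_columns = sum(keep), reason = "")
}

# is this codon position 0-fold degenerate (any base change is
# non-synonymous)?
is_nonsyn_site <- function(codon, position) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  alts <- setdiff(c("A", "C", "G", "T"), substr(codon, position, position))
  for (b in alts) {
    mut <- codon
    substr(mut, position, position) <- b
    if (Biostrings::GENETIC_CODE[[mut]] == aa) return(FALSE)
  }
  TRUE
}

#' Exon-level conservation: overall and at non-synonymous sites
#'
#' Fraction of fully conserved columns across an ungapped exon alignment,
#' overall and restricted to 0-fold degenerate positions (where any
#' single-base change alters the amino acid).
#'
#' @param rows aligned row strings (reference first, >= 3 rows, ungapped,
#'   transcript orientation).
#' @param phase CDS frame offset of the exon start (0-2).
#' @return list with `overall` and `nonsynonymous` percent identities
#'   (0-100), plus the column counts used.
#' @export
exon_conservation <- function(rows, phase) {
  if (is.na(phase)) stop("exon frame unknown")
  if (length(rows) < 3L) stop("need reference plus at least two species")
  n <- unique(nchar(rows))
  if (length(n) != 1L) stop("ragged alignment")
  if (any(grepl("[-N]", rows))) stop("alignment must be ungapped")
  m <- do.call(rbind, strsplit(rows, ""))
  conserved <- apply(m, 2L, function(col) all(col == col[1L]))
  ref <- rows[1L]
  codpos <- ((phase + seq_len(n) - 1L) %% 3L) + 1L
  cstart <- seq_len(n) - (codpos - 1L)
  in_frame <- cstart >= 1L & cstart + 2L <= n
  nonsyn <- rep(FALSE, n)
  for (i in which(in_frame)) {
    codon <- substr(ref, cstart[i], cstart[i] + 2L)
    nonsyn[i] <- is_nonsyn_site(codon, codpos[i])
  }
  list(overall = 100 * mean(conserved),
       nonsynonymous = if (any(nonsyn))
         100 * mean(conserved[nonsyn]) else NA_real_,
       n_columns = n, n_nonsyn = sum(nonsyn))
}

#' Drop variants whose constraint windows overlap
#'
#' Batch RC statistics use only variants with non-overlapping windows;
#' among an overlapping pair the first in coordinate order is kept.
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param flank window half-width (default 5, the 11-bp window).
#' @return logical vector: keep flags in the input order.
#' @export
nonoverlapping_windows <- function(variants, flank = 5L) {
  keep <- rep(TRUE, nrow(variants))
  o <- order(variants$chrom, variants$pos)
  last_chrom <- ""; last_pos <- -Inf
  for (i in o) {
    if (variants$chrom[i] == last_chrom &&
        variants$pos[i] - last_pos <= 2L * flank) {
      keep[i] <- FALSE
    } else {
      last_chrom <- variants$chrom[i]; last_pos <- variants$pos[i]
    }
  }
  keep
}
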