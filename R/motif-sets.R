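#' @importFrom stats setNames
NULL

ESR_LABELS <- c("ESE", "ESS", "UNLABELED_ESR")

#' Construct an ESR motif set
#'
#' An ESR motif set is a labelled collection of fixed-length DNA k-mers
#' (hexamers for most published collections, octamers for PESX-style sets).
#' Each k-mer carries one label: `ESE` (enhancer), `ESS` (silencer) or
#' `UNLABELED_ESR` for collections whose motifs are not assigned a
#' direction (Ast-ESR-style sets). Any k-mer absent from the set is
#' splicing-neutral.
#'
#' @param name identifier for the set.
#' @param k motif length in bases.
#' @param motifs named character vector: names are uppercase DNA k-mers,
#'   values are labels in `ESE`, `ESS`, `UNLABELED_ESR`.
#' @param source_note free-text provenance note.
#' @return an object of class `esr_motif_set`.
#' @export
esr_motif_set <- function(name, k, motifs = character(0), source_note = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  if (length(motifs)) {
    kmers <- toupper(names(motifs))
    labels <- unname(motifs)
    if (is.null(kmers) || any(!nzchar(kmers)))
      stop("motifs must be a named character vector (names are k-mers)")
    bad <- nchar(kmers) != k | grepl("[^ACGT]", kmers)
    if (any(bad))
      stop("malformed k-mer(s) for k=", k, ": ",
           paste(utils::head(kmers[bad], 5L), collapse = ", "))
    if (any(!labels %in% ESR_LABELS))
      stop("unknown label(s): ", paste(unique(setdiff(labels, ESR_LABELS)), collapse = ", "))
    # collapse duplicates; conflicting labels are an error
    dup <- duplicated(kmers)
    if (any(dup)) {
      for (km in unique(kmers[dup])) {
        if (length(unique(labels[kmers == km])) > 1L)
          stop("conflicting labels for k-mer ", km)
      }
      labels <- labels[!dup]
      kmers <- kmers[!dup]
    }
    motifs <- stats::setNames(labels, kmers)
  } else {
    motifs <- stats::setNames(character(0), character(0))
  }
  structure(list(name = name, k = k, motifs = motifs,
                 source_note = source_note),
            class = "esr_motif_set")
}

#' @export
print.esr_motif_set <- function(x, ...) {
  tab <- table(factor(x$motifs, levels = ESR_LABELS))
  cat("ESR motif set '", x$name, "' (k=", x$k, "): ",
      length(x$motifs), " motifs [",
      paste(names(tab), tab, sep = "=", collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Load an ESR motif set from a plain-text file
#'
#' One motif per line: `KMER` or `KMER<TAB>LABEL`. Lines starting with `#`
#' and blank lines are ignored. Duplicate identical lines collapse;
#' a k-mer listed with two different labels is a validation error.
#'
#' @param path file path.
#' @param k expected motif length.
#' @param default_label label applied to lines that carry no label column.
#' @param name set identifier; defaults to the file base name.
#' @return an [esr_motif_set()].
#' @export
load_motif_set <- function(path, k, default_label = "ESE", name = NULL) {
  if (!file.exists(path)) stop("no such motif file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- trimws(lines[keep])
  if (!length(lines))
    return(esr_motif_set(name, k, character(0), source_note = path))
  parts <- strsplit(lines, "\t| +")
  kmers <- toupper(vapply(parts, `[[`, "", 1L))
  labels <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else default_label, "")
  bad <- which(nchar(kmers) != k | grepl("[^ACGT]", kmers))
  if (length(bad))
    stop("motif file ", path, ": malformed k-mer at line(s) ",
         paste(utils::head(which(keep)[bad], 5L), collapse = ","),
         " (expected ", k, "-mer over ACGT)")
  esr_motif_set(name, k, stats::setNames(labels, kmers), source_note = path)
}

#' Write an ESR motif set in the plain-text dialect read by [load_motif_set()]
#' @param set an [esr_motif_set()].
#' @param path output file path.
#' @export
write_motif_set <- function(set, path) {
  stopifnot(inherits(set, "esr_motif_set"))
  writeLines(paste(names(set$motifs), unname(set$motifs), sep = "\t"), path)
  invisible(path)
}

#' Classify an n-mer against a motif set
#'
#' Membership lookup after uppercasing; k-mers absent from the set are
#' splicing-neutral (`NEUTRAL`).
#'
#' @param set an [esr_motif_set()].
#' @param nmer DNA string of length `set$k` (vectorised).
#' @return character vector of labels in
#'   `ESE`, `ESS`, `UNLABELED_ESR`, `NEUTRAL`.
#' @export
classify_nmer <- function(set, nmer) {
  stopifnot(inherits(set, "esr_motif_set"))
  nmer <- toupper(nmer)
  if (any(nchar(nmer) != set$k))
    stop("n-mer length must equal set k = ", set$k)
  lab <- unname(set$motifs[nmer])
  lab[is.na(lab)] <- "NEUTRAL"
  lab
}

#' Construct a PWM set
#'
#' A collection of position weight matrices with per-matrix score
#' thresholds (ESEFinder-style). A window of width `L` "scores" as a
#' binding site when its additive score is `>= threshold`.
#'
#' @param name identifier.
#' @param matrices list of entries, each a list with `motif_name`,
#'   `threshold`, and `weights` (4 x L numeric matrix, rows A,C,G,T).
#' @return object of class `pwm_set`.
#' @export
pwm_set <- function(name, matrices) {
  stopifnot(is.character(name), is.list(matrices))
  for (m in matrices) {
    if (!all(c("motif_name", "threshold", "weights") %in% names(m)))
      stop("each matrix needs motif_name, threshold, weights")
    if (!is.matrix(m$weights) || nrow(m$weights) != 4L || ncol(m$weights) < 1L)
      stop("weights for ", m$motif_name, " must be a 4 x L matrix")
    if (!is.finite(m$threshold) && !is.infinite(m$threshold))
      stop("threshold for ", m$motif_name, " must be numeric")
    if (any(!is.finite(m$weights)))
      stop("non-finite weight in matrix ", m$motif_name)
  }
  names(matrices) <- vapply(matrices, `[[`, "", "motif_name")
  structure(list(name = name, matrices = matrices), class = "pwm_set")
}

#' @export
print.pwm_set <- function(x, ...) {
  cat("PWM set '", x$name, "': ", length(x$matrices), " matrices (",
      paste(vapply(x$matrices, function(m) {
        paste0(m$motif_name, "[L=", ncol(m$weights), ",t=", signif(m$threshold, 4), "]")
      }, ""), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Load a PWM set from a text file
#'
#' File grammar (one or more matrices):
#' ```
#' >NAME THRESHOLD
#' A: w1 w2 ... wL
#' C: ...
#' G: ...
#' T: ...
#' ```
#' Row order is fixed A,C,G,T; rows must have equal length.
#'
#' @param path file path.
#' @param name set identifier; defaults to the file base name.
#' @return a [pwm_set()].
#' @export
load_pwm_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such PWM file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("PWM file ", path, ": no '>' matrix headers found")
  bounds <- c(heads, length(lines) + 1L)
  matrices <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    block <- lines[heads[i]:(bounds[i + 1L] - 1L)]
    hd <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]]
    if (length(hd) < 2L)
      stop("PWM header needs NAME and THRESHOLD: ", block[1L])
    thr <- suppressWarnings(as.numeric(hd[2L]))
    if (is.na(thr)) stop("missing/invalid threshold in header: ", block[1L])
    rows <- block[-1L]
    if (length(rows) != 4L)
      stop("matrix ", hd[1L], " has ", length(rows), " rows, expected 4 (A,C,G,T)")
    expect <- c("A", "C", "G", "T")
    vals <- vector("list", 4L)
    for (j in 1:4) {
      fields <- strsplit(trimws(rows[j]), "[\\s:]+", perl = TRUE)[[1L]]
      if (toupper(fields[1L]) != expect[j])
        stop("matrix ", hd[1L], ": row ", j, " must start with '", expect[j], ":'")
      v <- suppressWarnings(as.numeric(fields[-1L]))
      if (any(is.na(v)) || !length(v))
        stop("matrix ", hd[1L], ": non-numeric weights in row ", expect[j])
      vals[[j]] <- v
    }
    if (length(unique(lengths(vals))) != 1L)
      stop("matrix ", hd[1L], ": ragged rows")
    w <- do.call(rbind, vals)
    rownames(w) <- expect
    matrices[[i]] <- list(motif_name = hd[1L], threshold = thr, weights = w)
  }
  pwm_set(name, matrices)
}

#' Write a PWM set in the dialect read by [load_pwm_set()]
#' @param pwms a [pwm_set()].
#' @param path output path.
#' @export
write_pwm_set <- function(pwms, path) {
  stopifnot(inherits(pwms, "pwm_set"))
  out <- character(0)
  for (m in pwms$matrices) {
    out <- c(out, paste0(">", m$motif_name, " ", format(m$threshold, digits = 15)))
    for (b in c("A", "C", "G", "T"))
      out <- c(out, paste0(b, ": ", paste(format(m$weights[b, ], digits = 15),
                                          collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

score_pwm_window <- function(weights, window) {
  bases <- strsplit(window, "")[[1L]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(weights[cbind(idx, seq_along(idx))])
}

#' Scan a sequence for PWM threshold-crossing hits
#'
#' Every window of each matrix's width is scored additively; windows with
#' score `>= threshold` are reported. Windows overlapping an `N` (or any
#' non-ACGT base) are unscorable: they are skipped and tallied.
#'
#' @param pwms a [pwm_set()].
#' @param sequence DNA string.
#' @return data.frame with columns `motif_name`, `start` (0-based),
#'   `score`, sorted by start then motif_name; attribute
#'   `skipped_windows` counts windows dropped for non-ACGT content.
#' @export
scan_pwm_hits <- function(pwms, sequence) {
  stopifnot(inherits(pwms, "pwm_set"), is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  hits <- list()
  skipped <- 0L
  for (m in pwms$matrices) {
    L <- ncol(m$weights)
    if (n < L) next
    for (s in 0:(n - L)) {
      sc <- score_pwm_window(m$weights, substr(sequence, s + 1L, s + L))
      if (is.na(sc)) { skipped <- skipped + 1L; next }
      if (sc >= m$threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          motif_name = m$motif_name, start = s, score = sc,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif_name = character(0), start = integer(0), score = numeric(0))
  out <- out[order(out$start, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_windows") <- skipped
  out
}
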