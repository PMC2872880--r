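# Neutral expectation for the nine ESR change categories: permute every
# base of every k-mer to the three remaining bases, view each mutated
# k-mer from all k containing windows, and weight each permutation by an
# empirical base-substitution bias. For hexamers this is the
# 4096 x 3 x 6 = 73,728 permutation enumeration.

SUBSTITUTION_PAIRS <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(from = b, to = b, stringsAsFactors = FALSE)
  p <- p[p$from != p$to, ]
  paste0(p$from, "->", p$to)
}

#' Empirical base-substitution bias from polarised variants
#'
#' Proportion of ancestral-to-derived substitutions for each of the 12
#' ordered base pairs; the neutral model weights permutations by these.
#'
#' @param ancestral,derived vectors of single bases (polarised alleles).
#' @return named numeric vector of 12 proportions summing to 1, class
#'   `substitution_bias`.
#' @export
substitution_bias <- function(ancestral, derived) {
  stopifnot(length(ancestral) == length(derived))
  if (!length(ancestral)) stop("need at least one polarised variant")
  key <- paste0(toupper(ancestral), "->", toupper(derived))
  bad <- !key %in% SUBSTITUTION_PAIRS
  if (any(bad)) stop("invalid substitution(s): ",
                     paste(utils::head(unique(key[bad]), 3L), collapse = ", "))
  tab <- table(factor(key, levels = SUBSTITUTION_PAIRS))
  structure(as.numeric(tab) / sum(tab), names = SUBSTITUTION_PAIRS,
            class = "substitution_bias")
}

#' Uniform substitution bias (all 12 substitutions equally likely)
#' @return a `substitution_bias` with every entry 1/12.
#' @export
uniform_bias <- function() {
  structure(rep(1 / 12, 12L), names = SUBSTITUTION_PAIRS,
            class = "substitution_bias")
}

#' Read / write a substitution-bias table (ordered-pair TSV)
#'
#' Layout: two columns `substitution` (e.g. `A->G`) and `proportion`.
#'
#' @param path TSV path.
#' @return a `substitution_bias`.
#' @export
read_bias <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("substitution", "proportion") %in% names(df)))
    stop("bias TSV needs columns substitution, proportion")
  v <- stats::setNames(as.numeric(df$proportion), df$substitution)
  if (!all(SUBSTITUTION_PAIRS %in% names(v)))
    stop("bias table missing substitutions: ",
         paste(setdiff(SUBSTITUTION_PAIRS, names(v)), collapse = ", "))
  v <- v[SUBSTITUTION_PAIRS]
  if (abs(sum(v) - 1) > 1e-9) stop("bias proportions must sum to 1")
  structure(unname(v), names = SUBSTITUTION_PAIRS, class = "substitution_bias")
}

#' @rdname read_bias
#' @param bias a `substitution_bias`.
#' @export
write_bias <- function(bias, path) {
  utils::write.table(
    data.frame(substitution = names(bias), proportion = as.numeric(bias)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected distribution of the nine ESR change categories under neutrality
#'
#' Every k-mer, every position, every alternative base is enumerated; the
#' (wild, mutant) pair is classified and the bias weight of that
#' substitution accumulated into its category. Each mutated k-mer is seen
#' from all k containing windows; the window factor enters as weight `k`
#' per (k-mer, position, base) triple, which is exact because the window
#' classification does not depend on the window offset. For hexamers the
#' enumeration size is 4096 x 3 x 6 = 73,728.
#'
#' @param set an [esr_motif_set()].
#' @param bias a `substitution_bias` ([substitution_bias()],
#'   [uniform_bias()] or [read_bias()]).
#' @param literal_windows if `TRUE`, run the literal per-window
#'   re-enumeration instead of the weight-k shortcut (identical result,
#'   k-fold slower; used for exactness checks).
#' @return object of class `expected_change_distribution`: category
#'   `proportions` (sum 1), `permutations` (the enumeration count), the
#'   set name and the bias used.
#' @export
expected_change_distribution <- function(set, bias,
                                         literal_windows = FALSE) {
  stopifnot(inherits(set, "esr_motif_set"),
            inherits(bias, "substitution_bias"))
  k <- set$k
  unlabeled <- any(set$motifs == "UNLABELED_ESR")
  lev <- if (unlabeled) change_categories_2state() else change_categories()
  kmers <- all_kmers(k)
  state <- vapply(classify_nmer(set, kmers), state_of, "")
  names(state) <- kmers
  acc <- stats::setNames(numeric(length(lev)), lev)
  nperm <- 0L
  for (pos in seq_len(k)) {
    for (b_from in c("A", "C", "G", "T")) {
      sel <- substr(kmers, pos, pos) == b_from
      for (b_to in setdiff(c("A", "C", "G", "T"), b_from)) {
        w <- bias[[paste0(b_from, "->", b_to)]]
        mut <- kmers[sel]
        substr(mut, pos, pos) <- b_to
        sw <- state[kmers[sel]]
        sd <- state[mut]
        cat_nm <- ifelse(sw == sd, paste0(sw, "~", sw), paste0(sw, "->", sd))
        reps <- if (literal_windows) k else 1L
        wt <- w * (if (literal_windows) 1L else k)
        for (r in seq_len(reps)) {
          t <- tapply(rep(wt, length(cat_nm)), cat_nm, sum)
          acc[names(t)] <- acc[names(t)] + t
        }
        nperm <- nperm + length(mut)  # one (k-mer, position, base) triple each
      }
    }
  }
  props <- acc / sum(acc)
  structure(list(proportions = props, permutations = nperm,
                 set_name = set$name, bias = bias,
                 categories = lev),
            class = "expected_change_distribution")
}

#' @export
print.expected_change_distribution <- function(x, ...) {
  cat("Neutral expectation for '", x$set_name, "' (",
      format(x$permutations, big.mark = ","), " permutations)\n", sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Compare observed category counts to the neutral expectation
#'
#' Per category, a 2x2 chi-squared test with Yates continuity correction
#' of category-vs-rest against the expected proportion, plus the
#' observed/expected ratio. A zero expected proportion with non-zero
#' observed is reported as infinite ratio with an exact binomial P.
#'
#' @param observed named integer vector of nine-category counts (names
#'   must match `expected$categories`).
#' @param expected an [expected_change_distribution()].
#' @return data.frame: `category`, `observed`, `observed_prop`,
#'   `expected_prop`, `ratio`, `chisq`, `p_value`.
#' @export
compare_to_expected <- function(observed, expected) {
  stopifnot(inherits(expected, "expected_change_distribution"))
  lev <- expected$categories
  if (!all(lev %in% names(observed)))
    stop("observed counts missing categories: ",
         paste(setdiff(lev, names(observed)), collapse = ", "))
  observed <- observed[lev]
  n <- sum(observed)
  if (n < 1) stop("need at least one observed window")
  rows <- lapply(lev, function(cat_nm) {
    o <- observed[[cat_nm]]
    pe <- expected$proportions[[cat_nm]]
    op <- o / n
    if (pe == 0) {
      ratio <- if (o > 0) Inf else NA_real_
      pv <- if (o > 0) stats::binom.test(o, n, p = .Machine$double.xmin,
                                         alternative = "greater")$p.value else 1
      chi <- NA_real_
    } else {
      ratio <- op / pe
      tst <- suppressWarnings(
        stats::chisq.test(rbind(c(o, n - o),
                                round(c(pe, 1 - pe) * n)),
                          correct = TRUE))
      # test observed split against the expected split at equal n
      chi <- unname(tst$statistic); pv <- tst$p.value
    }
    data.frame(category = cat_nm, observed = o, observed_prop = op,
               expected_prop = pe, ratio = ratio, chisq = chi,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
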