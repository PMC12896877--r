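#' 2x2 contingency table of two gene sets over a universe
#'
#' Cells are (both, A-only, B-only, neither); the four cells sum to the
#' universe size. Elements outside the universe are an error, not silently
#' dropped.
#'
#' @param setA,setB character vectors of gene ids (duplicates ignored).
#' @param universe character vector, the background gene universe.
#' @return 2x2 integer matrix, rows = in/out of A, cols = in/out of B.
#' @export
contingency <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  out <- setdiff(c(setA, setB), universe)
  if (length(out)) {
    stop("element outside universe: ", out[1L], call. = FALSE)
  }
  both <- length(intersect(setA, setB))
  a_only <- length(setA) - both
  b_only <- length(setB) - both
  neither <- length(universe) - both - a_only - b_only
  matrix(as.integer(c(both, a_only, b_only, neither)), nrow = 2L,
         byrow = TRUE,
         dimnames = list(A = c("in", "out"), B = c("in", "out")))
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the property. Computed with
#' [stats::phyper], which is accurate in log space down to the smallest
#' representable doubles (~1e-300), so extreme enrichment p-values do not
#' underflow to coarse values.
#'
#' @param k observed hits (overlap).
#' @param n draw size (e.g. gene-set size).
#' @param K property size in the universe (e.g. term size).
#' @param N universe size.
#' @return `P(X >= k)`.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) ||
      any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    stop("hypergeometric bounds violated (need 0 <= k <= min(n, K) <= N)",
         call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher's exact test for gene-set overlap
#'
#' Tests whether two gene sets share more members than expected by chance,
#' conditioning on the table margins. The one-sided (enrichment) p-value is
#' the hypergeometric upper tail of the observed overlap given fixed set
#' sizes — target-set overlap is an inherently one-directional question. A
#' two-sided test is available via `alternative = "two.sided"`.
#'
#' @param table 2x2 matrix from [contingency].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return exact p-value in `(0, 1]`. A table with a zero margin carries no
#'   information: p = 1 by convention.
#' @export
fisher_exact_onesided <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  nA <- table[1L, 1L] + table[1L, 2L]
  nB <- table[1L, 1L] + table[2L, 1L]
  N <- sum(table)
  if (nA == 0L || nB == 0L || nA == N || nB == N) {
    message("degenerate margin in overlap table; p = 1 by convention")
    return(1)
  }
  if (alternative == "two.sided") {
    return(stats::fisher.test(table, alternative = "two.sided")$p.value)
  }
  hypergeom_tail(table[1L, 1L], nA, nB, N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via [stats::p.adjust]; adjusted values are elementwise
#' at least the raw values and are capped at 1.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Odds ratio of a 2x2 table (sample OR; Inf when a zero cell makes it so)
#' @noRd
.odds_ratio <- function(tab) {
  num <- as.numeric(tab[1, 1]) * tab[2, 2]
  den <- as.numeric(tab[1, 2]) * tab[2, 1]
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}

#' Evaluate target overlap for candidate mimic pairs
#'
#' For every candidate pair that passed the seed filter, builds the 2x2
#' contingency of the two predicted target sets over the gene universe and
#' computes the one-sided exact overlap p-value; p-values are BH-adjusted
#' across all tested pairs (one multiple-testing family per run) and rows are
#' sorted by p ascending. The universe — all genes with a UTR record — is
#' logged in every row.
#'
#' @param candidates a [screen_catalogue] result (or compatible data.frame
#'   with `query_id`, `hit_id`, `seed_ok`).
#' @param tsets named list from [target_sets] holding a gene set for every
#'   query and hit id among the seed_ok candidates.
#' @param universe character vector of background gene ids.
#' @param alternative passed to [fisher_exact_onesided].
#' @return data.frame of class `overlap_result`: `query_id`, `hit_id`,
#'   `n_overlap`, `n_query`, `n_hit`, `n_universe`, `odds_ratio`, `p`,
#'   `p_adjust`.
#' @export
evaluate_pairs <- function(candidates, tsets, universe,
                           alternative = "greater") {
  cand <- candidates[candidates$seed_ok, , drop = FALSE]
  empty <- data.frame(query_id = character(), hit_id = character(),
                      n_overlap = integer(), n_query = integer(),
                      n_hit = integer(), n_universe = integer(),
                      odds_ratio = numeric(), p = numeric(),
                      p_adjust = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    return(structure(empty, class = c("overlap_result", "data.frame")))
  }
  missing <- setdiff(c(cand$query_id, cand$hit_id), names(tsets))
  if (length(missing)) {
    stop("no target set for: ", paste(head(missing, 3L), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    A <- tsets[[cand$query_id[i]]]
    B <- tsets[[cand$hit_id[i]]]
    tab <- contingency(A, B, universe)
    data.frame(query_id = cand$query_id[i], hit_id = cand$hit_id[i],
               n_overlap = tab[1L, 1L],
               n_query = length(unique(A)), n_hit = length(unique(B)),
               n_universe = length(unique(universe)),
               odds_ratio = .odds_ratio(tab),
               p = fisher_exact_onesided(tab, alternative),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_adjust(out$p)
  out <- out[order(out$p, out$query_id, method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("overlap_result", "data.frame"))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result:", nrow(x), "candidate pairs tested\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Histogram of overlap p-values
#'
#' Under the null (unrelated miRNAs) the overlap p-values are roughly uniform;
#' an excess near zero indicates shared targeting.
#'
#' @param x an `overlap_result`.
#' @param ... passed to [graphics::hist].
#' @export
plot.overlap_result <- function(x, ...) {
  graphics::hist(x$p, breaks = seq(0, 1, by = 0.05),
                 main = "Target-overlap p-values", xlab = "p", ...)
  invisible(x)
}
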