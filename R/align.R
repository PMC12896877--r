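#' Scoring parameters for the mimicry aligner
#'
#' The screen uses a deliberately mismatch-averse scheme: relative to the
#' classical unit NW scoring, the match reward is larger and the mismatch and
#' gap penalties are harsher, so that only near-identical miRNA pairs — in
#' particular pairs with an intact seed — reach high scores. Defaults are
#' match +2, mismatch -3, gap -4 (linear). An affine gap model is available by
#' setting `gap_extend` less harsh than `gap_open`; opening must be at least
#' as costly as extending (`gap_open <= gap_extend`).
#'
#' @param match score for an identical column (> 0).
#' @param mismatch score for a substitution (< 0).
#' @param gap_open score for the first gapped column of a run (< 0).
#' @param gap_extend score for each further gapped column (< 0, >= gap_open).
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(match = 2, mismatch = -3,
                           gap_open = -4, gap_extend = gap_open) {
  stopifnot(length(match) == 1L, length(mismatch) == 1L,
            length(gap_open) == 1L, length(gap_extend) == 1L)
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (mismatch >= 0) stop("mismatch score must be negative", call. = FALSE)
  if (gap_open >= 0 || gap_extend >= 0) {
    stop("gap penalties must be negative", call. = FALSE)
  }
  if (gap_open > gap_extend) {
    stop("gap_open must be at least as costly as gap_extend", call. = FALSE)
  }
  if (abs(mismatch) < match) {
    message("note: |mismatch| < match; the screen is tuned for ",
            "|mismatch| >= match")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf("scoring_params: match %+g, mismatch %+g, gap %+g/%+g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Global alignment of two short RNA sequences
#'
#' Needleman-Wunsch with the mismatch-averse scoring of [scoring_params]
#' (Gotoh recursion when gaps are affine). Ties in the dynamic program are
#' broken deterministically: diagonal over up over left, and gap extension
#' over gap re-opening, so identical inputs always give identical alignments.
#'
#' @param a,b RNA strings over `{A,C,G,U}` (use [normalize_rna] first if
#'   needed), written 5' to 3'. No reverse-complement alignment is done:
#'   mature miRNAs are single-stranded.
#' @param params a [scoring_params] object.
#' @return object of class `rna_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `pos_map`
#'   (alignment column of each ungapped position of `a`).
#' @export
needleman_wunsch <- function(a, b, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  res <- .nw_align(a, b, params$match, params$mismatch,
                   params$gap_open, params$gap_extend)
  cols_a <- strsplit(res$aligned_a, "", fixed = TRUE)[[1L]]
  structure(list(aligned_a = res$aligned_a,
                 aligned_b = res$aligned_b,
                 score = res$score,
                 pos_map = which(cols_a != "-"),
                 params = params),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  ca <- strsplit(x$aligned_a, "")[[1L]]
  cb <- strsplit(x$aligned_b, "")[[1L]]
  midline <- ifelse(ca == cb, "|", ifelse(ca == "-" | cb == "-", " ", "."))
  cat(x$aligned_a, "\n", paste(midline, collapse = ""), "\n",
      x$aligned_b, "\n", sep = "")
  cat("score:", x$score, "\n")
  invisible(x)
}

# Recompute an alignment's score column-by-column; used as an internal
# consistency check (gap runs cost open + (L-1) * extend).
alignment_score <- function(aln, params = aln$params) {
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  gap <- ca == "-" | cb == "-"
  new_run <- gap & !c(FALSE, gap[-length(gap)])
  sum(ifelse(gap, ifelse(new_run, params$gap_open, params$gap_extend),
             ifelse(ca == cb, params$match, params$mismatch)))
}

#' Extract the 6mer seed of a mature miRNA
#'
#' The seed is nucleotides 2-7, 1-based from the 5' end — the primary
#' determinant of target recognition.
#'
#' @param seq RNA string of length >= 8.
#' @return 6-character RNA string.
#' @export
seed_of <- function(seq) {
  if (nchar(seq) < 8L) {
    stop("sequence too short for seed (need >= 8 nt): ", seq, call. = FALSE)
  }
  substr(seq, 2L, 7L)
}

#' Check that the seed aligned properly
#'
#' The mimicry screen keeps a candidate only when the query's seed (positions
#' 2-7) aligned "properly" against the host miRNA: (i) no gap in either row
#' within the alignment columns spanned by query positions 2-7, and (ii) at
#' least `min_matches` identical columns in that span. G:U wobble counts as a
#' mismatch.
#'
#' @param aln an `rna_alignment` whose `a` side is the query miRNA.
#' @param min_matches identities required in the 6-column seed span
#'   (default 6, the strictest reading of a 6mer seed).
#' @return list with `ok` (logical) and `matches` (0-6).
#' @export
seed_aligned_properly <- function(aln, min_matches = 6L) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (length(aln$pos_map) < 7L) {
    stop("query too short for seed (need >= 8 nt)", call. = FALSE)
  }
  cols <- aln$pos_map[2:7]
  span <- seq.int(cols[1L], cols[6L])
  ca <- strsplit(aln$aligned_a, "")[[1L]][span]
  cb <- strsplit(aln$aligned_b, "")[[1L]][span]
  gapless <- length(span) == 6L && !any(ca == "-") && !any(cb == "-")
  matches <- sum(ca == cb & ca != "-")
  list(ok = gapless && matches >= min_matches, matches = as.integer(matches))
}

#' Best host match for one query miRNA
#'
#' Aligns the query against every host miRNA, keeps the maximal score, and
#' applies the seed filter. Score ties are broken by higher seed match count,
#' then lexicographically smallest host id, so the screen is deterministic.
#'
#' @param query one-row data.frame (or list) with `id` and `seq`.
#' @param hosts host catalogue data.frame (`id`, `seq`).
#' @param params a [scoring_params].
#' @param min_seed_matches seed identities required for `seed_ok`.
#' @return one-row data.frame: `query_id`, `hit_id`, `score`,
#'   `aligned_query`, `aligned_hit`, `seed_matches`, `seed_ok`.
#' @export
best_host_match <- function(query, hosts, params = scoring_params(),
                            min_seed_matches = 6L) {
  if (is.null(hosts) || nrow(hosts) == 0L) {
    stop("empty host catalogue", call. = FALSE)
  }
  alns <- lapply(hosts$seq, function(h) needleman_wunsch(query$seq, h, params))
  scores <- vapply(alns, `[[`, 0, "score")
  seeds <- lapply(alns, seed_aligned_properly, min_matches = min_seed_matches)
  sm <- vapply(seeds, `[[`, 0L, "matches")
  ord <- order(-scores, -sm, hosts$id, method = "radix")
  i <- ord[1L]
  data.frame(query_id = query$id, hit_id = hosts$id[i],
             score = scores[i],
             aligned_query = alns[[i]]$aligned_a,
             aligned_hit = alns[[i]]$aligned_b,
             seed_matches = sm[i], seed_ok = seeds[[i]]$ok,
             stringsAsFactors = FALSE)
}

#' Screen a plant miRNA catalogue against a host catalogue for mimicry
#'
#' For each query miRNA, finds its best-scoring host miRNA under the global
#' aligner and flags whether the seed aligned properly. Records failing the
#' seed filter are retained with `seed_ok = FALSE` rather than dropped, so the
#' downstream filter is reproducible and auditable.
#'
#' @param queries plant miRNA catalogue (data.frame with `id`, `seq`).
#' @param hosts host miRNA catalogue.
#' @inheritParams best_host_match
#' @return data.frame of class `mimic_screen`, one row per query, in input
#'   order; columns as in [best_host_match].
#' @export
screen_catalogue <- function(queries, hosts, params = scoring_params(),
                             min_seed_matches = 6L) {
  if (is.null(queries) || nrow(queries) == 0L) {
    warning("empty query catalogue; nothing to screen", call. = FALSE)
    out <- data.frame(query_id = character(), hit_id = character(),
                      score = numeric(), aligned_query = character(),
                      aligned_hit = character(), seed_matches = integer(),
                      seed_ok = logical(), stringsAsFactors = FALSE)
    return(structure(out, class = c("mimic_screen", "data.frame")))
  }
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    best_host_match(queries[i, ], hosts, params, min_seed_matches)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mimic_screen", "data.frame"),
            params = params, min_seed_matches = min_seed_matches)
}

#' @export
print.mimic_screen <- function(x, ...) {
  cat("mimic_screen:", nrow(x), "queries,", sum(x$seed_ok),
      "with properly aligned seed\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
summary.mimic_screen <- function(object, ...) {
  cat("Cross-kingdom mimicry screen\n")
  cat("  queries:          ", nrow(object), "\n")
  cat("  seed_ok:          ", sum(object$seed_ok), "\n")
  if (nrow(object)) {
    cat("  score range:      ", min(object$score), "-", max(object$score), "\n")
    cat("  candidate pairs:\n")
    ok <- object[object$seed_ok, c("query_id", "hit_id", "score", "seed_matches")]
    if (nrow(ok)) print.data.frame(ok, row.names = FALSE)
  }
  invisible(object)
}
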