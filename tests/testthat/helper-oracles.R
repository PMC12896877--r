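# Independent oracles used to check the package's own implementations.
# These deliberately avoid the code paths they verify.

# Exhaustive global-alignment maximum under linear gap scoring: plain
# recursion over the three column types, enumerating every alignment path.
# Exponential; only for sequences of length <= ~8.
bf_align_max <- function(a, b, match = 2, mismatch = -3, gap = -4) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1L, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Exact overlap tail by complete enumeration: over all ways of drawing |A|
# elements from a universe of size N with B fixed, the fraction with
# |A intersect B| >= k. Only for N <= 12.
bf_overlap_tail <- function(k, nA, nB, N) {
  if (nA == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(N, nA)
  hits <- colSums(draws <= nB)  # wlog B = {1..nB}
  mean(hits >= k)
}

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

mirna_row <- function(id, seq) {
  data.frame(id = id, species = "sim", seq = seq, description = "",
             stringsAsFactors = FALSE)
}

utr_row <- function(gene_id, seq) {
  data.frame(gene_id = gene_id, seq = seq, stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}
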