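#' Reverse complement of an RNA string
#' @param x RNA string over `{A,C,G,U}`.
#' @return reverse complement, RNA alphabet.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# all (possibly overlapping) start positions of `pattern` in `subject`
.find_all <- function(pattern, subject) {
  lp <- nchar(pattern); ls <- nchar(subject)
  if (ls < lp) return(integer())
  starts <- seq_len(ls - lp + 1L)
  starts[substring(subject, starts, starts + lp - 1L) == pattern]
}

# length of the full site on the UTR for each class
.site_len <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
.class_weight <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)

#' Scan a 3'UTR for canonical seed-complementary sites
#'
#' Finds every occurrence of the reverse complement of the miRNA seed
#' (nucleotides 2-7) on the UTR (mRNA sense, 5' to 3') and classifies each by
#' the canonical site taxonomy. Because pairing is antiparallel, the UTR base
#' pairing miRNA position 8 sits immediately 5' of the 6mer core on the UTR,
#' and the base opposite miRNA position 1 sits immediately 3' of it:
#' * `7mer-m8`: core plus Watson-Crick match to miRNA nucleotide 8;
#' * `7mer-A1`: core plus an adenosine on the UTR opposite miRNA position 1
#'   (the t1A rule — an A regardless of what miRNA nucleotide 1 is);
#' * `8mer`: both extensions; `6mer`: neither.
#'
#' Reported positions are the 1-based start of the full site on the UTR
#' (so an 8mer site starts one base 5' of its 6mer core).
#'
#' @param mirna one-row data.frame (or list) with `id` and `seq`
#'   (length >= 8 nt).
#' @param utr one-row data.frame (or list) with `gene_id` and `seq`.
#' @param scorer site scoring function; defaults to [score_site]. Any function
#'   with the same signature (class, AU context fraction) can be plugged in.
#' @return data.frame: `mirna_id`, `gene_id`, `position`, `site_class`,
#'   `score`; zero rows if the UTR is shorter than 6 nt or has no site.
#' @export
scan_sites <- function(mirna, utr, scorer = score_site) {
  core <- revcomp_rna(seed_of(mirna$seq))
  L <- nchar(utr$seq)
  starts <- .find_all(core, utr$seq)
  if (length(starts) == 0L) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      position = integer(), site_class = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  m8 <- chartr("ACGU", "UGCA", substr(mirna$seq, 8L, 8L))
  has_m8 <- starts > 1L &
    substring(utr$seq, starts - 1L, starts - 1L) == m8
  has_a1 <- starts + 6L <= L &
    substring(utr$seq, starts + 6L, starts + 6L) == "A"
  cls <- ifelse(has_m8 & has_a1, "8mer",
         ifelse(has_m8, "7mer-m8",
         ifelse(has_a1, "7mer-A1", "6mer")))
  pos <- ifelse(has_m8, starts - 1L, starts)
  au <- vapply(seq_along(starts), function(i) {
    .au_context(utr$seq, pos[i], .site_len[[cls[i]]])
  }, 0)
  data.frame(mirna_id = mirna$id, gene_id = utr$gene_id,
             position = as.integer(pos), site_class = cls,
             score = vapply(seq_along(cls),
                            function(i) scorer(cls[i], au[i]), 0),
             stringsAsFactors = FALSE)
}

# AU fraction of the flanking context: up to `win` nt on each side of the
# site, site itself excluded; 0 when no flanking sequence exists.
.au_context <- function(utr_seq, pos, site_len, win = 30L) {
  L <- nchar(utr_seq)
  left <- substr(utr_seq, max(1L, pos - win), pos - 1L)
  right <- substr(utr_seq, pos + site_len,
                  min(L, pos + site_len + win - 1L))
  ctx <- paste0(left, right)
  n <- nchar(ctx)
  if (n == 0L) return(0)
  (n - nchar(gsub("[AU]", "", ctx))) / n
}

#' Score a target site
#'
#' A transparent, deterministic stand-in for thermodynamic target scoring:
#' a class weight (8mer = 4, 7mer-m8 = 3, 7mer-A1 = 2, 6mer = 1) plus an
#' AU-content bonus of 0.5 times the A/U fraction of the flanking +-30 nt
#' context (AU-rich context correlates with site accessibility). The class
#' weights dominate the bonus, so class ordering is always preserved; the
#' bonus only ranks sites within a class. Downstream statistics depend only
#' on the ranked top-k sets, not on absolute score values, and [scan_sites]
#' accepts any replacement scorer with this signature.
#'
#' @param site_class one of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param au_context A/U fraction of the flanking context, in `[0,1]`.
#' @return numeric score.
#' @export
score_site <- function(site_class, au_context) {
  w <- .class_weight[[site_class]]
  stopifnot(au_context >= 0, au_context <= 1)
  w + 0.5 * au_context
}

#' Keep the best site per UTR
#'
#' When more than one site is predicted on the same 3'UTR only the best one
#' is retained: per gene, the maximum score, ties going to the smallest
#' position (most 5').
#'
#' @param sites data.frame from [scan_sites] (possibly several genes).
#' @return data.frame with at most one row per (`mirna_id`, `gene_id`).
#' @export
best_site_per_utr <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  ord <- order(sites$mirna_id, sites$gene_id, -sites$score, sites$position,
               method = "radix")
  sites <- sites[ord, ]
  keep <- !duplicated(sites[, c("mirna_id", "gene_id")])
  out <- sites[keep, ]
  rownames(out) <- NULL
  out
}

#' Rank target genes and keep the top k
#'
#' Genes are ranked by site score (descending), ties broken by gene id
#' (ascending), and truncated at `k`. The top 100 genes of a miRNA define its
#' putative target set by default.
#'
#' @param per_gene_sites data.frame from [best_site_per_utr] for one miRNA.
#' @param k maximum target-set size (default 100).
#' @return data.frame with columns `mirna_id`, `gene_id`, `rank`, `score`,
#'   `site_class`, `position`.
#' @export
top_k_targets <- function(per_gene_sites, k = 100L) {
  stopifnot(k >= 1L)
  s <- per_gene_sites
  if (nrow(s) == 0L) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      rank = integer(), score = numeric(),
                      site_class = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-s$score, s$gene_id, method = "radix")
  s <- s[ord, ][seq_len(min(k, nrow(s))), ]
  data.frame(mirna_id = s$mirna_id, gene_id = s$gene_id,
             rank = seq_len(nrow(s)), score = s$score,
             site_class = s$site_class, position = s$position,
             stringsAsFactors = FALSE)
}

#' Predict putative targets of each miRNA on a UTR library
#'
#' Full target-prediction stage: scan every UTR for seed-complementary sites,
#' retain the best site per UTR, rank genes and keep the top `k` per miRNA.
#'
#' @param mirnas miRNA catalogue data.frame (`id`, `seq`).
#' @param utrs UTR library data.frame (`gene_id`, `seq`).
#' @param k target-set size per miRNA (default 100).
#' @param scorer plug-in site scorer, see [scan_sites].
#' @return data.frame as in [top_k_targets], rows grouped by miRNA in
#'   catalogue order.
#' @export
predict_targets <- function(mirnas, utrs, k = 100L, scorer = score_site) {
  per_mirna <- lapply(seq_len(nrow(mirnas)), function(i) {
    m <- mirnas[i, ]
    sites <- do.call(rbind, lapply(seq_len(nrow(utrs)), function(j) {
      scan_sites(m, utrs[j, ], scorer)
    }))
    if (is.null(sites)) return(NULL)
    top_k_targets(best_site_per_utr(sites), k)
  })
  out <- do.call(rbind, per_mirna)
  if (is.null(out)) {
    out <- top_k_targets(data.frame(mirna_id = character(),
                                    gene_id = character(),
                                    position = integer(),
                                    site_class = character(),
                                    score = numeric()), k)
  }
  rownames(out) <- NULL
  out
}

#' Split a target table into per-miRNA gene-id sets
#' @param targets data.frame from [predict_targets].
#' @return named list: miRNA id -> character vector of gene ids (rank order).
#' @export
target_sets <- function(targets) {
  lapply(split(targets[order(targets$rank), ], targets$mirna_id[order(targets$rank)]),
         function(d) d$gene_id)
}
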