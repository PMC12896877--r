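#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic study: miRNA catalogue sizes and lengths, how many
#' mimic pairs to plant and how divergent they are outside the seed, the UTR
#' library, optional planted target sites, and a flat annotation with one
#' optionally enriched truth term. Defaults emulate the screening conditions
#' of a small-RNA mimicry study: a handful of top-expressed plant miRNAs
#' screened against a catalogue of 50 host miRNAs of realistic mature lengths
#' (19-24 nt), with planted mimics sharing the 6mer seed exactly and carrying
#' 3 substitutions elsewhere.
#'
#' @param seed integer RNG seed; identical configs give identical outputs.
#' @param n_query,n_host catalogue sizes.
#' @param mirna_len_range inclusive mature-length range, default 19-24 nt.
#' @param n_mimic_pairs mimic pairs to plant (query i paired with host i).
#' @param off_seed_mutations substitutions outside positions 2-7 applied when
#'   planting a mimic (0 = identical pair members).
#' @param n_utrs,utr_len_range UTR library size and length range.
#' @param planted_sites NULL, or data.frame with `mirna_id`, `gene_id`,
#'   `site_class`, `core_position` (1-based start of the 6mer core on the
#'   UTR; both flanks must lie inside the UTR).
#' @param n_terms,term_size_range annotation shape.
#' @param truth_term_size,hit_fraction the planted enriched term: its size,
#'   and the fraction of it forced into the designated gene set (0 disables
#'   planting — the truth term behaves like any null term).
#' @param au_bias probability mass on A+U when drawing background bases
#'   (0.5 = uniform composition). Exposed because the site scorer has an
#'   AU-context term; tests can decouple class weights from the bonus.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_query = 10L, n_host = 50L,
                       mirna_len_range = c(19L, 24L),
                       n_mimic_pairs = 1L, off_seed_mutations = 3L,
                       n_utrs = 300L, utr_len_range = c(200L, 800L),
                       planted_sites = NULL,
                       n_terms = 50L, term_size_range = c(5L, 60L),
                       truth_term_size = 40L, hit_fraction = 0.75,
                       au_bias = 0.5) {
  stopifnot(n_query >= 0, n_host >= 0, n_mimic_pairs >= 0,
            n_mimic_pairs <= min(n_query, n_host),
            off_seed_mutations >= 0,
            mirna_len_range[1] >= 16, mirna_len_range[2] <= 30,
            mirna_len_range[1] <= mirna_len_range[2],
            n_utrs >= 0, utr_len_range[1] >= 10,
            utr_len_range[1] <= utr_len_range[2],
            n_terms >= 0, term_size_range[1] >= 1,
            truth_term_size >= 1, hit_fraction >= 0, hit_fraction <= 1,
            au_bias > 0, au_bias < 1)
  if (off_seed_mutations > mirna_len_range[1] - 6L) {
    stop("off_seed_mutations exceed non-seed positions of shortest miRNA",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_query = as.integer(n_query),
                 n_host = as.integer(n_host),
                 mirna_len_range = as.integer(mirna_len_range),
                 n_mimic_pairs = as.integer(n_mimic_pairs),
                 off_seed_mutations = as.integer(off_seed_mutations),
                 n_utrs = as.integer(n_utrs),
                 utr_len_range = as.integer(utr_len_range),
                 planted_sites = planted_sites,
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 truth_term_size = as.integer(truth_term_size),
                 hit_fraction = hit_fraction, au_bias = au_bias),
            class = "sim_config")
}

# stage-specific RNG seed derived from the config seed, overflow-safe
.derived_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% 2147483647)
}

.base_probs <- function(au_bias) {
  c(A = au_bias / 2, C = (1 - au_bias) / 2,
    G = (1 - au_bias) / 2, U = au_bias / 2)
}

.rand_rna <- function(len, au_bias = 0.5) {
  p <- .base_probs(au_bias)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate synthetic miRNA catalogues with planted mimic pairs
#'
#' Background sequences are i.i.d. draws over the RNA alphabet. Each planted
#' mimic pair shares nucleotides 2-7 exactly (no wobble, matching the strict
#' seed filter) and differs by exactly `off_seed_mutations` substitutions
#' outside the seed; pair members have equal length. The truth table lists the
#' planted pairs, which is sufficient to score recovery exactly downstream.
#'
#' @param cfg a [sim_config]. Sets the RNG state from `cfg$seed`.
#' @return list with `queries`, `hosts` (miRNA data.frames as in
#'   [read_mirna_fasta]) and `truth` (data.frame `query_id`, `host_id`).
#' @export
gen_mirnas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derived_seed(cfg$seed, 0))
  lens_q <- sample(seq(cfg$mirna_len_range[1], cfg$mirna_len_range[2]),
                   cfg$n_query, replace = TRUE)
  lens_h <- sample(seq(cfg$mirna_len_range[1], cfg$mirna_len_range[2]),
                   cfg$n_host, replace = TRUE)
  q_seq <- vapply(lens_q, .rand_rna, "", au_bias = cfg$au_bias)
  h_seq <- vapply(lens_h, .rand_rna, "", au_bias = cfg$au_bias)
  q_id <- sprintf("csi-sim-%03d", seq_len(cfg$n_query))
  h_id <- sprintf("hsa-sim-%03d", seq_len(cfg$n_host))
  truth <- data.frame(query_id = character(), host_id = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_mimic_pairs)) {
    mimic <- strsplit(q_seq[i], "", fixed = TRUE)[[1L]]
    non_seed <- setdiff(seq_along(mimic), 2:7)
    mut_at <- sample(non_seed, cfg$off_seed_mutations)
    for (p in mut_at) {
      mimic[p] <- sample(setdiff(c("A", "C", "G", "U"), mimic[p]), 1L)
    }
    h_seq[i] <- paste(mimic, collapse = "")
    truth <- rbind(truth, data.frame(query_id = q_id[i], host_id = h_id[i],
                                     stringsAsFactors = FALSE))
  }
  list(queries = data.frame(id = q_id, species = "csi", seq = q_seq,
                            description = "", stringsAsFactors = FALSE),
       hosts = data.frame(id = h_id, species = "hsa", seq = h_seq,
                          description = "", stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a synthetic UTR library with optional planted target sites
#'
#' Background bases are i.i.d. draws; each requested site is written as the
#' exact reverse complement of the miRNA's 6mer seed at `core_position`, with
#' the two flanking bases set to satisfy — or deliberately violate — the
#' requested site class (the base pairing miRNA nucleotide 8 on the 5' flank,
#' the t1A adenosine on the 3' flank). Overlapping plants on one UTR are an
#' error. The truth table records the site start position as the scanner
#' reports it (8mer/7mer-m8 sites start one base 5' of the core).
#'
#' @param cfg a [sim_config] (uses `n_utrs`, `utr_len_range`, `au_bias`,
#'   `planted_sites`; RNG state set from `cfg$seed + 1`).
#' @param mirnas miRNA catalogue providing the seeds for planted sites.
#' @return list with `utrs` (data.frame `gene_id`, `seq`) and `truth`
#'   (data.frame `mirna_id`, `gene_id`, `site_class`, `position`).
#' @export
gen_utrs <- function(cfg, mirnas = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derived_seed(cfg$seed, 1))
  lens <- sample(seq(cfg$utr_len_range[1], cfg$utr_len_range[2]),
                 cfg$n_utrs, replace = TRUE)
  seqs <- vapply(lens, .rand_rna, "", au_bias = cfg$au_bias)
  ids <- sprintf("gene%04d", seq_len(cfg$n_utrs))
  truth <- data.frame(mirna_id = character(), gene_id = character(),
                      site_class = character(), position = integer(),
                      stringsAsFactors = FALSE)
  ps <- cfg$planted_sites
  if (!is.null(ps) && nrow(ps)) {
    if (is.null(mirnas)) stop("planted_sites need the miRNA catalogue",
                              call. = FALSE)
    occupied <- list()
    for (r in seq_len(nrow(ps))) {
      g <- match(ps$gene_id[r], ids)
      m <- match(ps$mirna_id[r], mirnas$id)
      if (is.na(g) || is.na(m)) {
        stop("planted site references unknown gene or miRNA", call. = FALSE)
      }
      cls <- ps$site_class[r]
      stopifnot(cls %in% names(.site_len))
      cp <- as.integer(ps$core_position[r])
      L <- nchar(seqs[g])
      if (cp < 2L || cp + 6L > L) {
        stop("planted core position must leave room for both flanks",
             call. = FALSE)
      }
      span <- seq.int(cp - 1L, cp + 6L)
      prev <- occupied[[ids[g]]]
      if (length(prev) && any(span %in% prev)) {
        stop("planted sites overlap on ", ids[g], call. = FALSE)
      }
      occupied[[ids[g]]] <- c(prev, span)
      chars <- strsplit(seqs[g], "", fixed = TRUE)[[1L]]
      core <- strsplit(revcomp_rna(seed_of(mirnas$seq[m])), "",
                       fixed = TRUE)[[1L]]
      chars[cp:(cp + 5L)] <- core
      m8 <- chartr("ACGU", "UGCA", substr(mirnas$seq[m], 8L, 8L))
      want_m8 <- cls %in% c("7mer-m8", "8mer")
      want_a1 <- cls %in% c("7mer-A1", "8mer")
      chars[cp - 1L] <- if (want_m8) m8 else {
        sample(setdiff(c("A", "C", "G", "U"), m8), 1L)
      }
      chars[cp + 6L] <- if (want_a1) "A" else sample(c("C", "G", "U"), 1L)
      seqs[g] <- paste(chars, collapse = "")
      truth <- rbind(truth, data.frame(
        mirna_id = ps$mirna_id[r], gene_id = ps$gene_id[r], site_class = cls,
        position = if (want_m8) cp - 1L else cp, stringsAsFactors = FALSE))
    }
  }
  list(utrs = data.frame(gene_id = ids, seq = seqs, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a synthetic flat annotation with one planted enriched term
#'
#' Terms of random sizes are drawn uniformly from the background. One
#' designated truth term (id `T0001`) is built so that `hit_fraction` of its
#' genes come from `gene_set` (the set whose enrichment is being tested) and
#' the remainder from outside it; with `hit_fraction = 0` it is drawn like
#' any null term.
#'
#' @param cfg a [sim_config] (uses `n_terms`, `term_size_range`,
#'   `truth_term_size`, `hit_fraction`; RNG state set from `cfg$seed + 2`).
#' @param background character vector of background gene ids.
#' @param gene_set character vector, the set the truth term is enriched in
#'   (must be inside `background`).
#' @return list with `annotation` (an [annotation_map]) and `truth_term`
#'   (the planted term id, `"T0001"`).
#' @export
gen_annotation <- function(cfg, background, gene_set = character()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derived_seed(cfg$seed, 2))
  background <- unique(background)
  stopifnot(all(gene_set %in% background),
            cfg$truth_term_size <= length(background))
  ids <- sprintf("T%04d", seq_len(max(cfg$n_terms, 1L)))
  terms <- vector("list", length(ids))
  names(terms) <- ids
  n_hit <- round(cfg$hit_fraction * cfg$truth_term_size)
  n_hit <- min(n_hit, length(gene_set))
  hits <- if (n_hit > 0L) sample(gene_set, n_hit) else character()
  rest_pool <- if (n_hit > 0L) setdiff(background, gene_set) else background
  if (length(rest_pool) < cfg$truth_term_size - n_hit) {
    stop("background too small to fill the truth term", call. = FALSE)
  }
  terms[[1L]] <- c(hits,
                   sample(rest_pool, cfg$truth_term_size - n_hit))
  if (length(ids) > 1L) {
    sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                    length(ids) - 1L, replace = TRUE)
    for (i in seq_along(sizes)) {
      terms[[i + 1L]] <- sample(background, min(sizes[i], length(background)))
    }
  }
  desc <- setNames(sprintf("synthetic term %s", ids), ids)
  desc[ids[1L]] <- "synthetic planted term"
  list(annotation = annotation_map(terms, desc), truth_term = ids[1L])
}

#' Write a full synthetic study to a directory
#'
#' Materializes the generator outputs as the pipeline's file formats:
#' `query.fa`, `host.fa`, `utrs.fa`, `annotation.tsv` plus truth tables
#' (`truth_mimics.tsv`, `truth_sites.tsv`, `truth_term.txt`).
#'
#' @param cfg a [sim_config].
#' @param dir output directory (created if needed).
#' @param enrich_set gene set the truth term is planted in; defaults to the
#'   first `min(100, n_utrs)` gene ids.
#' @return `dir`, invisibly.
#' @export
gen_study <- function(cfg, dir, enrich_set = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mi <- gen_mirnas(cfg)
  ut <- gen_utrs(cfg, rbind(mi$queries, mi$hosts))
  if (is.null(enrich_set)) {
    enrich_set <- head(ut$utrs$gene_id, min(100L, cfg$n_utrs %/% 3L))
  }
  an <- gen_annotation(cfg, ut$utrs$gene_id, enrich_set)
  write_mirna_fasta(mi$queries, file.path(dir, "query.fa"))
  write_mirna_fasta(mi$hosts, file.path(dir, "host.fa"))
  write_utr_fasta(ut$utrs, file.path(dir, "utrs.fa"))
  ann_rows <- do.call(rbind, lapply(names(an$annotation$terms), function(t) {
    data.frame(term_id = t, gene_id = an$annotation$terms[[t]],
               description = an$annotation$descriptions[[t]],
               stringsAsFactors = FALSE)
  }))
  write.table(ann_rows, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(mi$truth, file.path(dir, "truth_mimics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ut$truth, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(an$truth_term, file.path(dir, "truth_term.txt"))
  invisible(dir)
}
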