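#' Configuration for an end-to-end pipeline run
#'
#' @param query_fa plant ("query") mature miRNA FASTA.
#' @param host_fa host ("reference") mature miRNA FASTA.
#' @param utr_fa host 3'UTR FASTA, one record per gene; its gene ids define
#'   the universe for overlap and enrichment.
#' @param annotation_tsv flat term-to-gene TSV (see [read_annotation_tsv]).
#' @param out_dir output directory.
#' @param params a [scoring_params].
#' @param min_seed_matches seed identities required by the mimicry filter.
#' @param top_k target-set size per miRNA (default 100).
#' @param alpha significance level applied to BH-adjusted overlap p-values
#'   when counting significant pairs (default 0.05).
#' @param min_term_size smallest annotation term tested.
#' @return object of class `run_config`.
#' @export
run_config <- function(query_fa, host_fa, utr_fa, annotation_tsv, out_dir,
                       params = scoring_params(), min_seed_matches = 6L,
                       top_k = 100L, alpha = 0.05, min_term_size = 5L) {
  for (p in c(query_fa, host_fa, utr_fa, annotation_tsv)) {
    if (!file.exists(p)) stop("input does not exist: ", p, call. = FALSE)
  }
  stopifnot(inherits(params, "scoring_params"), top_k >= 1L,
            alpha > 0, alpha < 1, min_seed_matches >= 0L)
  structure(list(query_fa = query_fa, host_fa = host_fa, utr_fa = utr_fa,
                 annotation_tsv = annotation_tsv, out_dir = out_dir,
                 params = params,
                 min_seed_matches = as.integer(min_seed_matches),
                 top_k = as.integer(top_k), alpha = alpha,
                 min_term_size = as.integer(min_term_size)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full mimicry pipeline
#'
#' Orchestrates align -> targets -> overlap -> enrichment and writes
#' `candidates.tsv`, `targets.tsv`, `overlap.tsv`, `enrichment.tsv` and
#' `summary.json` to the output directory. Every TSV carries a `# params:`
#' provenance comment; outputs are a pure function of (inputs, config), so
#' repeated runs are byte-identical. Any stage error aborts with a message
#' naming the stage. Target sets are predicted for all query miRNAs and for
#' every host miRNA hit by a seed-passing candidate; enrichment is run on the
#' query target sets against the annotation, with the UTR gene ids as
#' background.
#'
#' @param cfg a [run_config].
#' @return object of class `xkmir_run`: stage counts, parameter echo and
#'   output paths (also serialized as `summary.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  param_echo <- list(match = cfg$params$match, mismatch = cfg$params$mismatch,
                     gap_open = cfg$params$gap_open,
                     gap_extend = cfg$params$gap_extend,
                     min_seed_matches = cfg$min_seed_matches,
                     top_k = cfg$top_k, alpha = cfg$alpha,
                     min_term_size = cfg$min_term_size)

  queries <- .stage("align", read_mirna_fasta(cfg$query_fa, "query"))
  hosts <- .stage("align", read_mirna_fasta(cfg$host_fa, "host"))
  cand <- .stage("align",
                 screen_catalogue(queries, hosts, cfg$params,
                                  cfg$min_seed_matches))
  write_stage_tsv(as.data.frame(cand), file.path(cfg$out_dir, "candidates.tsv"),
                  param_echo)

  utrs <- .stage("targets", read_utr_fasta(cfg$utr_fa))
  hit_hosts <- unique(cand$hit_id[cand$seed_ok])
  need <- rbind(queries[, c("id", "seq")],
                hosts[hosts$id %in% hit_hosts, c("id", "seq")])
  targets <- .stage("targets", predict_targets(need, utrs, cfg$top_k))
  write_stage_tsv(targets, file.path(cfg$out_dir, "targets.tsv"), param_echo)

  universe <- utrs$gene_id
  tsets <- target_sets(targets)
  overlap <- .stage("overlap", evaluate_pairs(cand, tsets, universe))
  write_stage_tsv(as.data.frame(overlap), file.path(cfg$out_dir, "overlap.tsv"),
                  param_echo)

  annotation <- .stage("enrichment", read_annotation_tsv(cfg$annotation_tsv))
  q_sets <- tsets[intersect(names(tsets), queries$id)]
  enr <- .stage("enrichment",
                enrich_all(q_sets, annotation, universe, cfg$min_term_size))
  write_stage_tsv(as.data.frame(enr), file.path(cfg$out_dir, "enrichment.tsv"),
                  param_echo)

  summary <- list(
    counts = list(
      n_queries = nrow(queries), n_hosts = nrow(hosts),
      n_seed_ok = sum(cand$seed_ok),
      n_pairs_tested = nrow(overlap),
      n_pairs_significant = sum(overlap$p_adjust < cfg$alpha),
      n_target_rows = nrow(targets),
      n_enrichment_rows = nrow(enr)),
    params = param_echo,
    outputs = list(candidates = "candidates.tsv", targets = "targets.tsv",
                   overlap = "overlap.tsv", enrichment = "enrichment.tsv"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(c(summary, list(out_dir = cfg$out_dir)), class = "xkmir_run")
}

#' Summarize an existing pipeline output directory
#'
#' Recomputes the stage counts from the TSVs on disk (line counts minus
#' headers, significance at `alpha`), so a run directory can be audited
#' without re-running the pipeline.
#'
#' @param out_dir directory written by [run_pipeline].
#' @param alpha significance level for counting significant pairs.
#' @return list of stage counts.
#' @export
summarize_run <- function(out_dir, alpha = 0.05) {
  cand <- read_stage_tsv(file.path(out_dir, "candidates.tsv"))
  targets <- read_stage_tsv(file.path(out_dir, "targets.tsv"))
  overlap <- read_stage_tsv(file.path(out_dir, "overlap.tsv"))
  enr <- read_stage_tsv(file.path(out_dir, "enrichment.tsv"))
  list(n_queries = nrow(cand), n_seed_ok = sum(cand$seed_ok),
       n_pairs_tested = nrow(overlap),
       n_pairs_significant = if (nrow(overlap)) sum(overlap$p_adjust < alpha) else 0L,
       n_target_rows = nrow(targets), n_enrichment_rows = nrow(enr))
}

#' @export
print.xkmir_run <- function(x, ...) {
  cat("xkmir pipeline run:", x$out_dir, "\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
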