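#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and converts T to U. Both DNA and RNA spellings are accepted on
#' input; internally everything is RNA (`A`, `C`, `G`, `U`). IUPAC ambiguity
#' codes (including `N`) are rejected rather than skipped: a single ambiguous
#' base would silently corrupt seed matching downstream.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. a record id).
#' @return character vector over `{A,C,G,U}`.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("illegal character (non-ACGU after T->U normalization) in ",
         what, ": ", paste(head(which(bad), 3L), collapse = ", "),
         call. = FALSE)
  }
  x
}

.read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path, call. = FALSE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[!nzchar(seqs)][1L], "'", call. = FALSE)
  }
  list(ids = ids, desc = desc, seqs = seqs)
}

#' Read a mature miRNA catalogue from FASTA
#'
#' Headers are parsed miRBase-style: the first whitespace-delimited token is
#' the id, the remainder is kept as a free-text description. Sequences are
#' normalized to RNA ([normalize_rna]); record order is preserved; duplicate
#' ids are an error.
#'
#' @param path FASTA file (multi-line sequences accepted).
#' @param species species tag stored with every record (e.g. `"csi"`, `"hsa"`).
#' @return data.frame with columns `id`, `species`, `seq`, `description`.
#' @export
read_mirna_fasta <- function(path, species = "") {
  rec <- .read_fasta(path)
  if (anyDuplicated(rec$ids)) {
    stop("duplicate miRNA id in ", path, ": ",
         rec$ids[duplicated(rec$ids)][1L], call. = FALSE)
  }
  for (i in seq_along(rec$ids)) {
    rec$seqs[i] <- normalize_rna(rec$seqs[i], paste0("record '", rec$ids[i], "'"))
  }
  n <- nchar(rec$seqs)
  if (any(n < 16L | n > 30L)) {
    warning("miRNA length outside 16-30 nt for: ",
            paste(head(rec$ids[n < 16L | n > 30L], 3L), collapse = ", "),
            call. = FALSE)
  }
  data.frame(id = rec$ids, species = species, seq = rec$seqs,
             description = rec$desc, stringsAsFactors = FALSE)
}

#' Read a 3'UTR library from FASTA
#'
#' One record per gene; the gene id is the first whitespace token of the
#' header. The set of gene ids defines the gene universe used by the overlap
#' and enrichment stages.
#'
#' @param path FASTA file.
#' @return data.frame with columns `gene_id`, `seq`.
#' @export
read_utr_fasta <- function(path) {
  rec <- .read_fasta(path)
  if (anyDuplicated(rec$ids)) {
    stop("duplicate gene id in ", path, ": ",
         rec$ids[duplicated(rec$ids)][1L], call. = FALSE)
  }
  for (i in seq_along(rec$ids)) {
    rec$seqs[i] <- normalize_rna(rec$seqs[i], paste0("record '", rec$ids[i], "'"))
  }
  data.frame(gene_id = rec$ids, seq = rec$seqs, stringsAsFactors = FALSE)
}

#' Read a flat term-to-gene annotation from TSV
#'
#' Two or three tab-separated columns: `term_id`, `gene_id` and an optional
#' `description`. Genes are aggregated per term (duplicates dropped);
#' descriptions merge last-wins. No ontology structure is modeled — any term
#' propagation must be done upstream.
#'
#' @param path TSV file, no header.
#' @return an `annotation_map`: list with `terms` (named list of character
#'   gene-id vectors) and `descriptions` (named character).
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(annotation_map(list(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed annotation line ", which(nf < 2L)[1L],
         " (need term_id<TAB>gene_id): ", path, call. = FALSE)
  }
  term <- vapply(parts, `[`, "", 1L)
  gene <- vapply(parts, `[`, "", 2L)
  desc <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", "")
  terms <- lapply(split(gene, term), unique)
  descriptions <- vapply(split(desc, term), function(d) {
    d <- d[nzchar(d)]
    if (length(d)) d[length(d)] else ""
  }, "")
  annotation_map(terms, descriptions)
}

#' Construct an annotation map
#'
#' @param terms named list: term id -> character vector of gene ids.
#' @param descriptions named character: term id -> human-readable description.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(terms, descriptions = NULL) {
  stopifnot(is.list(terms))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(terms)), names(terms))
  }
  if (any(lengths(terms) == 0L)) stop("empty term gene set", call. = FALSE)
  structure(list(terms = terms,
                 descriptions = descriptions[names(terms)]),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$terms), "terms,",
      length(unique(unlist(x$terms, use.names = FALSE))), "genes\n")
  invisible(x)
}

#' Write a miRNA catalogue to FASTA
#'
#' @param mirnas data.frame as returned by [read_mirna_fasta].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  hdr <- ifelse(nzchar(mirnas$description),
                paste(mirnas$id, mirnas$description), mirnas$id)
  writeLines(paste0(">", hdr, "\n", mirnas$seq), path)
  invisible(path)
}

#' Write a UTR library to FASTA
#' @param utrs data.frame as returned by [read_utr_fasta].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  writeLines(paste0(">", utrs$gene_id, "\n", utrs$seq), path)
  invisible(path)
}

# Stage TSVs carry a "# params:" provenance comment before the header so
# every output row records the parameters that produced it.
write_stage_tsv <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(paste0("# params: ", jsonlite::toJSON(params, auto_unbox = TRUE)),
               con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage TSV
#'
#' Reads back a TSV written by the pipeline, skipping the `# params:`
#' provenance comment, so any stage can be re-run from its upstream file.
#'
#' @param path TSV written by [run_pipeline] or a stage function.
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
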