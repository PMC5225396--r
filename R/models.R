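#' Construct a transcript model
#'
#' A transcript is an ordered set of exons on one chromosome and strand,
#' optionally with CDS intervals (each contained in an exon) and a novelty
#' flag for transcripts assembled from reads rather than taken from a
#' reference annotation.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with `start`, `end` (0-based half-open),
#'   non-overlapping; sorted by `start` on construction.
#' @param cds optional data frame with `start`, `end` of coding intervals.
#' @param biotype transcript biotype string; `""` when unknown.
#' @param novel logical; `TRUE` for newly assembled transcripts.
#'
#' @return An object of class `transcript_model`.
#' @examples
#' transcript_model("tx1", "g1", "chr1", "+",
#'                  exons = data.frame(start = c(0, 200), end = c(100, 300)))
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "", novel = FALSE) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (nrow(exons) == 0) stop("transcript ", transcript_id, " has no exons")
  if (any(exons$start >= exons$end)) {
    stop("transcript ", transcript_id, ": exon with start >= end")
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    cds$start <- as.integer(cds$start)
    cds$end <- as.integer(cds$end)
    rownames(cds) <- NULL
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(ok)) stop("transcript ", transcript_id,
                       ": CDS interval not contained in any exon")
  } else {
    cds <- NULL
  }
  structure(
    list(
      transcript_id = transcript_id, gene_id = gene_id,
      chrom = chrom, strand = strand,
      exons = exons, cds = cds,
      biotype = biotype, novel = isTRUE(novel)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s] %d exon(s)%s%s>\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons),
              if (!is.null(x$cds)) ", coding" else "",
              if (x$novel) ", novel" else ""))
  invisible(x)
}

#' Spliced length of a transcript
#'
#' @param t a `transcript_model`.
#' @return Integer: sum of exon lengths.
#' @examples
#' t <- transcript_model("tx1", "g1", "chr1", "+",
#'                       data.frame(start = 0, end = 100))
#' spliced_length(t)
#' @export
spliced_length <- function(t) sum(t$exons$end - t$exons$start)

#' Construct a gene model
#'
#' Groups transcript models sharing a `gene_id`; the gene span covers all
#' member exons.
#'
#' @param gene_id identifier.
#' @param transcripts list of `transcript_model` objects on one chromosome.
#' @param name,description display metadata.
#'
#' @return An object of class `gene_model` with a `span` interval.
#' @export
gene_model <- function(gene_id, transcripts, name = "", description = "") {
  stopifnot(length(transcripts) > 0)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  if (length(chroms) != 1) stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  starts <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(
      gene_id = gene_id, name = name, description = description,
      chrom = chroms, transcripts = transcripts,
      span = c(start = min(starts), end = max(ends))
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s%s %s:%d-%d, %d transcript(s)>\n",
              x$gene_id, if (nzchar(x$name)) paste0(" (", x$name, ")") else "",
              x$chrom, x$span[["start"]], x$span[["end"]],
              length(x$transcripts)))
  invisible(x)
}

# Flatten a gene list into a named list of transcript models.
all_transcripts <- function(genes) {
  txs <- unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  txs
}

#' Expression matrix with a sample-to-group map
#'
#' @param tpm numeric matrix, features x samples, non-negative TPM.
#' @param group named character vector mapping every sample (column) to
#'   `"case"` or `"control"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, group) {
  stopifnot(is.matrix(tpm), !is.null(colnames(tpm)), !is.null(rownames(tpm)))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  missing <- setdiff(colnames(tpm), names(group))
  if (length(missing)) stop("samples without a group: ", paste(missing, collapse = ", "))
  if (!all(group[colnames(tpm)] %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  structure(list(tpm = tpm, group = group[colnames(tpm)]),
            class = "expression_matrix")
}

# Max TPM for one feature over all samples, or over one group.
max_tpm <- function(expr, feature_id, group = NULL) {
  if (!feature_id %in% rownames(expr$tpm)) {
    stop("no expression row for feature '", feature_id, "'")
  }
  v <- expr$tpm[feature_id, , drop = TRUE]
  if (!is.null(group)) v <- v[expr$group == group]
  if (length(v) == 0) 0 else max(v)
}
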