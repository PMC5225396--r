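# lncRNA classification: expression, length, coding potential (longest
# peptide), biotype exclusion, and the extra structure rule for novel
# transcripts (>= 200 bp and at least one intron).

#' Length of the longest open reading frame, in amino acids
#'
#' Scans the three forward frames for ATG-initiated, stop-terminated open
#' reading frames; the stop codon is required and not counted. Codons
#' containing `N` never match ATG and never terminate. Returns 0 when no
#' complete ORF exists.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return Integer number of amino acids in the longest ORF.
#' @examples
#' longest_peptide_length("ATGAAATAA")  # Met-Lys -> 2
#' @export
longest_peptide_length <- function(seq) {
  n <- nchar(seq)
  if (n < 6) return(0L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    open_at <- NA_integer_  # codon index of current ORF start
    for (k in seq_along(codons)) {
      if (is.na(open_at) && is_start[k]) open_at <- k
      if (!is.na(open_at) && is_stop[k]) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
  }
  as.integer(best)
}

#' Classify one transcript as lncRNA or not
#'
#' A transcript is a lncRNA when it (i) reaches `min_tpm` in at least one
#' sample, (ii) is at least `min_lnc_length` nt long, (iii) has a longest
#' peptide strictly shorter than `max_peptide_aa` amino acids, and (iv)
#' carries no excluded biotype. Novel transcripts must additionally have
#' at least two exons (one intron) and satisfy the length rule; the
#' peptide rule doubles as their coding filter unless an external coding
#' verdict is supplied.
#'
#' @param t a `transcript_model`.
#' @param seq spliced sequence of `t`.
#' @param tpm named numeric vector of per-sample TPM for `t`.
#' @param params a [scoring_params()] object.
#' @param excluded_biotypes character vector; see
#'   [default_excluded_biotypes()].
#' @param coding_verdict optional logical: externally supplied
#'   coding-potential call for novel transcripts (`TRUE` = coding);
#'   overrides the peptide stand-in for the novel-structure rule.
#'
#' @return A list of class `lnc_decision` with fields `transcript_id`,
#'   `is_lncrna`, `failed_criteria`, `longest_peptide_aa`, `max_tpm`.
#' @export
classify_lncrna <- function(t, seq, tpm, params = scoring_params(),
                            excluded_biotypes = default_excluded_biotypes(),
                            coding_verdict = NULL) {
  if (length(tpm) == 0 || all(is.na(tpm))) {
    stop("no expression values for transcript '", t$transcript_id, "'")
  }
  mx <- max(tpm, na.rm = TRUE)
  pep <- longest_peptide_length(seq)
  failed <- character()
  if (mx < params$min_tpm) failed <- c(failed, "expression")
  if (nchar(seq) < params$min_lnc_length) failed <- c(failed, "length")
  if (pep >= params$max_peptide_aa) failed <- c(failed, "peptide")
  if (nzchar(t$biotype) && t$biotype %in% excluded_biotypes) {
    failed <- c(failed, "biotype")
  }
  if (t$novel) {
    coding <- if (is.null(coding_verdict)) pep >= params$max_peptide_aa
              else isTRUE(coding_verdict)
    if (nrow(t$exons) < 2 || nchar(seq) < 200L || coding) {
      failed <- c(failed, "novel_structure")
    }
  }
  structure(
    list(
      transcript_id = t$transcript_id,
      gene_id = t$gene_id,
      is_lncrna = length(failed) == 0,
      failed_criteria = unique(failed),
      longest_peptide_aa = pep,
      max_tpm = mx
    ),
    class = "lnc_decision"
  )
}

#' Build a lncRNA catalog over all transcripts
#'
#' Applies [classify_lncrna()] to every transcript of every gene;
#' decisions are returned in deterministic `transcript_id` order.
#'
#' @param genes list of `gene_model` objects.
#' @param genome named character vector of chromosome sequences.
#' @param expr an [expression_matrix()] with transcript-level rows.
#' @param params a [scoring_params()] object.
#' @param excluded_biotypes see [default_excluded_biotypes()].
#' @param coding_verdicts optional named logical vector of external
#'   coding calls keyed by transcript id.
#'
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `is_lncrna`, `failed_criteria` (comma-joined),
#'   `longest_peptide_aa`, `max_tpm`.
#' @export
build_lnc_catalog <- function(genes, genome, expr,
                              params = scoring_params(),
                              excluded_biotypes = default_excluded_biotypes(),
                              coding_verdicts = NULL) {
  txs <- all_transcripts(genes)
  if (length(txs) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      is_lncrna = logical(), failed_criteria = character(),
                      longest_peptide_aa = integer(), max_tpm = numeric(),
                      stringsAsFactors = FALSE))
  }
  txs <- txs[order(names(txs))]
  rows <- lapply(txs, function(t) {
    if (!t$transcript_id %in% rownames(expr$tpm)) {
      stop("no expression row for transcript '", t$transcript_id, "'")
    }
    d <- classify_lncrna(
      t, spliced_sequence(t, genome),
      expr$tpm[t$transcript_id, , drop = TRUE],
      params, excluded_biotypes,
      coding_verdict = if (!is.null(coding_verdicts) &&
                             t$transcript_id %in% names(coding_verdicts))
        coding_verdicts[[t$transcript_id]] else NULL
    )
    data.frame(
      transcript_id = d$transcript_id, gene_id = d$gene_id,
      is_lncrna = d$is_lncrna,
      failed_criteria = paste(d$failed_criteria, collapse = ","),
      longest_peptide_aa = d$longest_peptide_aa, max_tpm = d$max_tpm,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
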