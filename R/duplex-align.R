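# Duplex discovery: local complementarity alignment of lncRNA sequences
# against candidate target transcripts. The lncRNA is aligned 5'->3'
# against the *reversed* target with a complementarity substitution
# matrix, so paired columns are antiparallel as in a physical duplex;
# target coordinates are reported back in target 5'->3' orientation.

BASES <- c("A", "C", "G", "T", "N")

#' Score one base pair of a duplex column
#'
#' The published complementarity scheme: G:C scores 4, A:T scores 2, the
#' G:U wobble (G:T in DNA alphabet) scores 1; every other combination,
#' including any pair involving `N`, scores the mismatch penalty (-6).
#' Symmetric in its arguments.
#'
#' @param a,b single bases from `{A,C,G,T,N}`.
#' @param params a [scoring_params()] object.
#' @return Integer score.
#' @examples
#' pair_score("G", "C")  # 4
#' pair_score("G", "T")  # 1 (wobble)
#' @export
pair_score <- function(a, b, params = scoring_params()) {
  m <- complementarity_matrix(params)
  if (!a %in% BASES || !b %in% BASES) {
    stop("non-nucleotide symbol: ", a, "/", b)
  }
  m[a, b]
}

#' Complementarity substitution matrix
#'
#' @param params a [scoring_params()] object.
#' @return 5x5 integer matrix over `A,C,G,T,N` with the match scores of
#'   `params` and the mismatch penalty elsewhere.
#' @export
complementarity_matrix <- function(params = scoring_params()) {
  m <- matrix(as.integer(params$mismatch), 5, 5, dimnames = list(BASES, BASES))
  m["G", "C"] <- m["C", "G"] <- as.integer(params$match_gc)
  m["A", "T"] <- m["T", "A"] <- as.integer(params$match_at)
  m["G", "T"] <- m["T", "G"] <- as.integer(params$match_gu)
  m
}

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

new_duplex_alignment <- function(score, lnc_start, lnc_end, target_start,
                                 target_end, pairing,
                                 lnc_aln = NA_character_,
                                 target_aln = NA_character_,
                                 lnc_id = NA_character_,
                                 target_id = NA_character_,
                                 target_space = NA_character_,
                                 genome_blocks = NULL) {
  structure(
    list(
      lnc_id = lnc_id, target_id = target_id, score = score,
      lnc_start = lnc_start, lnc_end = lnc_end,
      target_start = target_start, target_end = target_end,
      pairing = pairing, lnc_aln = lnc_aln, target_aln = target_aln,
      target_space = target_space,
      genome_blocks = genome_blocks
    ),
    class = "duplex_alignment"
  )
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex %s[%d,%d) : %s[%d,%d) score=%d%s>\n",
              if (is.na(x$lnc_id)) "lnc" else x$lnc_id,
              x$lnc_start, x$lnc_end,
              if (is.na(x$target_id)) "target" else x$target_id,
              x$target_start, x$target_end, x$score,
              if (is.na(x$target_space)) "" else paste0(" ", x$target_space)))
  invisible(x)
}

#' Find duplexes between one lncRNA and one target sequence
#'
#' Runs full Smith-Waterman with affine gap costs (a gap of length k
#' costs `|gap_open| + k * |gap_extend|`) of the lncRNA against the
#' reversed target and emits every maximal local alignment scoring at
#' least `params$min_score`. Suboptimal alignments are enumerated
#' Waterman-Eggert style: the matched cells of each reported path are
#' masked and the matrix recomputed until no alignment reaches the
#' threshold. Output is ordered by (score desc, lnc start, target start).
#'
#' @param lnc_seq lncRNA sequence, 5'->3'.
#' @param target_seq target sequence, 5'->3'. `U` is normalized to `T`.
#' @param params a [scoring_params()] object.
#' @param max_hits safety cap on the number of enumerated alignments.
#' @return List of `duplex_alignment` objects; target spans are in target
#'   5'->3' transcript coordinates, 0-based half-open.
#' @export
align_duplex <- function(lnc_seq, target_seq, params = scoring_params(),
                         max_hits = 100L) {
  lnc_seq <- normalize_seq(lnc_seq)
  target_seq <- normalize_seq(target_seq)
  if (!nzchar(lnc_seq) || !nzchar(target_seq)) return(list())
  m <- nchar(target_seq)
  target_rev <- paste(rev(strsplit(target_seq, "", fixed = TRUE)[[1]]),
                      collapse = "")
  raw <- duplex_align_core(
    lnc_seq, target_rev, complementarity_matrix(params),
    abs(params$gap_open), abs(params$gap_extend),
    as.integer(params$min_score), as.integer(max_hits)
  )
  hits <- lapply(raw, function(h) {
    new_duplex_alignment(
      score = h$score,
      lnc_start = h$q_start, lnc_end = h$q_end,
      target_start = m - h$r_end, target_end = m - h$r_start,
      pairing = h$pairing, lnc_aln = h$q_aln, target_aln = h$t_aln
    )
  })
  if (length(hits) > 1) {
    ord <- order(-vapply(hits, `[[`, 0L, "score"),
                 vapply(hits, `[[`, 0L, "lnc_start"),
                 vapply(hits, `[[`, 0L, "target_start"))
    hits <- hits[ord]
  }
  hits
}

#' Recompute an alignment score from its aligned columns
#'
#' Walks the alignment column by column, scoring paired columns with the
#' complementarity matrix and each gap run of length k as
#' `|gap_open| + k * |gap_extend|`. Serves as a consistency check: the
#' result equals the reported alignment score for every emitted
#' alignment.
#'
#' @param aln a `duplex_alignment`.
#' @param params a [scoring_params()] object.
#' @return Integer score.
#' @export
score_from_pairing <- function(aln, params = scoring_params()) {
  qa <- strsplit(aln$lnc_aln, "", fixed = TRUE)[[1]]
  ta <- strsplit(aln$target_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(qa) == length(ta))
  mat <- complementarity_matrix(params)
  score <- 0L
  gap_run <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || ta[k] == "-") {
      gap_run <- gap_run + 1L
      next
    }
    if (gap_run > 0L) {
      score <- score - (abs(params$gap_open) + gap_run * abs(params$gap_extend))
      gap_run <- 0L
    }
    score <- score + mat[qa[k], ta[k]]
  }
  if (gap_run > 0L) {
    score <- score - (abs(params$gap_open) + gap_run * abs(params$gap_extend))
  }
  score
}

#' All-vs-all duplex discovery between lncRNAs and candidate targets
#'
#' Applies [align_duplex()] for every (lncRNA, target) combination,
#' skipping self-pairs and targets not flagged as differentially
#' expressed (the published search was restricted to transcripts with
#' significant up- or downregulation).
#'
#' @param lncs named character vector: lncRNA id -> sequence.
#' @param targets list of target descriptors, each a list with fields
#'   `id`, `seq`, `space` (`"spliced"` or `"premrna"`) and optionally
#'   `de` (logical, default `TRUE`).
#' @param params a [scoring_params()] object.
#' @param max_hits per-pair cap passed to [align_duplex()].
#' @return List of `duplex_alignment` objects with `lnc_id`, `target_id`
#'   and `target_space` filled in, ordered by lnc id, target id, space,
#'   then score.
#' @export
enumerate_interactions <- function(lncs, targets, params = scoring_params(),
                                   max_hits = 100L) {
  out <- list()
  lnc_ids <- sort(names(lncs))
  key <- vapply(targets, function(tg) paste0(tg$id, "|", tg$space), "")
  targets <- targets[order(key)]
  for (lid in lnc_ids) {
    for (tg in targets) {
      if (identical(tg$id, lid)) next
      if (!is.null(tg$de) && !isTRUE(tg$de)) next
      hits <- align_duplex(lncs[[lid]], tg$seq, params, max_hits)
      for (h in hits) {
        h$lnc_id <- lid
        h$target_id <- tg$id
        h$target_space <- tg$space
        out[[length(out) + 1L]] <- h
      }
    }
  }
  out
}

# Data-frame view of a list of duplex alignments.
duplexes_to_df <- function(duplexes) {
  if (length(duplexes) == 0) {
    return(data.frame(lnc_id = character(), target_id = character(),
                      score = integer(), lnc_start = integer(),
                      lnc_end = integer(), target_start = integer(),
                      target_end = integer(), target_space = character(),
                      pairing = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(duplexes, function(d) {
    data.frame(lnc_id = d$lnc_id, target_id = d$target_id, score = d$score,
               lnc_start = d$lnc_start, lnc_end = d$lnc_end,
               target_start = d$target_start, target_end = d$target_end,
               target_space = d$target_space, pairing = d$pairing,
               stringsAsFactors = FALSE)
  }))
}
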