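# Sequence extraction and transcript-space <-> genome-space coordinate
# projection. Transcript space always runs 5'->3' of the transcript; for
# strand "-" that is the genomic reverse.

#' Reverse complement of a DNA string
#'
#' @param x character scalar over `{A,C,G,T,N}`.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_exon_bounds <- function(t, genome) {
  if (!t$chrom %in% names(genome)) {
    stop("chromosome '", t$chrom, "' not present in genome")
  }
  if (max(t$exons$end) > nchar(genome[[t$chrom]])) {
    stop("transcript ", t$transcript_id, ": exon beyond end of ", t$chrom)
  }
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences in transcription order; reverse-complements
#' for strand `-`. Output is uppercase DNA (`A,C,G,T,N`).
#'
#' @param t a `transcript_model`.
#' @param genome named character vector of chromosome sequences.
#' @return Character scalar of length [spliced_length()].
#' @export
spliced_sequence <- function(t, genome) {
  check_exon_bounds(t, genome)
  chrom_seq <- genome[[t$chrom]]
  parts <- substring(chrom_seq, t$exons$start + 1L, t$exons$end)
  s <- toupper(paste(parts, collapse = ""))
  if (t$strand == "-") revcomp(s) else s
}

#' Pre-mRNA sequence with deep-intron masking
#'
#' Returns the unspliced transcript sequence (first exon start to last
#' exon end, 5'->3' of the transcript). Within each intron, positions
#' farther than `margin` bases from both flanking splice sites are
#' replaced by `N`, so introns of length `<= 2 * margin` stay fully
#' unmasked. Single-exon transcripts return the spliced sequence.
#'
#' @param t a `transcript_model`.
#' @param genome named character vector of chromosome sequences.
#' @param margin non-negative integer; default the published 250 nt.
#' @return Character scalar of length `last exon end - first exon start`.
#' @export
premrna_sequence <- function(t, genome, margin = 250L) {
  stopifnot(margin >= 0)
  check_exon_bounds(t, genome)
  region_start <- min(t$exons$start)
  region_end <- max(t$exons$end)
  s <- toupper(substring(genome[[t$chrom]], region_start + 1L, region_end))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_ex <- nrow(t$exons)
  if (n_ex > 1) {
    for (i in seq_len(n_ex - 1)) {
      istart <- t$exons$end[i] - region_start      # local 0-based intron bounds
      iend <- t$exons$start[i + 1] - region_start
      ilen <- iend - istart
      if (ilen > 2 * margin) {
        mask <- (istart + margin + 1L):(iend - margin)  # 1-based char indices
        chars[mask] <- "N"
      }
    }
  }
  s <- paste(chars, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

#' Project a transcript-space interval onto the genome
#'
#' Maps a 0-based half-open interval in spliced or pre-mRNA transcript
#' space to the genomic blocks it covers. In spliced space an interval
#' crossing an exon junction yields one block per exon touched; blocks are
#' reported in genomic orientation (sorted by start) and their lengths sum
#' to `tx_end - tx_start`.
#'
#' @param t a `transcript_model`.
#' @param tx_start,tx_end interval in transcript coordinates (5'->3' of
#'   the transcript).
#' @param space `"spliced"` or `"premrna"`.
#' @return Interval data frame of genomic blocks.
#' @export
transcript_to_genome <- function(t, tx_start, tx_end,
                                 space = c("spliced", "premrna")) {
  space <- match.arg(space)
  tx_start <- as.integer(tx_start); tx_end <- as.integer(tx_end)
  len <- if (space == "spliced") spliced_length(t) else
    max(t$exons$end) - min(t$exons$start)
  if (tx_start < 0 || tx_start >= tx_end || tx_end > len) {
    stop("transcript-space interval [", tx_start, ",", tx_end,
         ") out of range for length ", len)
  }
  if (space == "premrna") {
    rs <- min(t$exons$start); re <- max(t$exons$end)
    blk <- if (t$strand == "+") {
      c(rs + tx_start, rs + tx_end)
    } else {
      c(re - tx_end, re - tx_start)
    }
    return(genomic_intervals(t$chrom, blk[1], blk[2], t$strand))
  }
  ex <- t$exons
  order_tx <- if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  blocks <- list()
  off <- 0L
  for (i in order_tx) {
    elen <- ex$end[i] - ex$start[i]
    s <- max(tx_start, off); e <- min(tx_end, off + elen)
    if (s < e) {
      if (t$strand == "+") {
        gs <- ex$start[i] + (s - off); ge <- ex$start[i] + (e - off)
      } else {
        gs <- ex$end[i] - (e - off); ge <- ex$end[i] - (s - off)
      }
      blocks[[length(blocks) + 1L]] <- c(gs, ge)
    }
    off <- off + elen
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  genomic_intervals(t$chrom, m[, 1], m[, 2], t$strand)
}
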