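#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand` (and any extra columns such as `name`). Coordinates are
#' 0-based half-open throughout the package: `start` is the first base,
#' `end` is one past the last.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` required.
#' @param strand strand per interval, one of `"+"`, `"-"`, `"."`.
#' @param ... additional columns, recycled as in [data.frame()].
#'
#' @return A data frame with at least columns `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = ".", ...) {
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  if (length(strand) == 1L) strand <- rep_len(strand, length(chrom))
  df <- data.frame(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    ...,
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (any(!nzchar(df$chrom))) stop("invalid interval: empty chrom")
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# 0-based half-open data frame <-> GRanges (1-based closed)
intervals_to_granges <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

#' Merge intervals into non-overlapping coordinates
#'
#' Strand-agnostic union per chromosome, the same semantics as
#' `bedtools merge`: overlapping and bookended (touching) intervals are
#' collapsed. Output is sorted by chromosome then start. Used to remove
#' redundancy from annotation tracks (e.g. pooled Argonaute CLIP sites)
#' before intersection.
#'
#' @param intervals interval data frame (see [genomic_intervals()]).
#' @return Sorted, disjoint interval data frame with strand `"."`.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(10, 15), c(20, 25)))
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(empty_intervals())
  pieces <- lapply(split(seq_len(nrow(intervals)), intervals$chrom), function(idx) {
    s <- intervals$start[idx]
    e <- intervals$end[idx]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    run_end <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1] > run_end[-length(e)]))
    data.frame(chrom = intervals$chrom[idx[1]],
               start = as.integer(s[!duplicated(grp)]),
               end = as.integer(tapply(e, grp, max)),
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[sort(names(pieces))])
  rownames(out) <- NULL
  out
}

# Linear sweep over two sorted, disjoint interval lists from the same
# chromosome; emits the common bases.
.sweep_intersect <- function(s1, e1, s2, e2) {
  i <- 1L; j <- 1L
  out_s <- integer(); out_e <- integer()
  while (i <= length(s1) && j <= length(s2)) {
    lo <- max(s1[i], s2[j])
    hi <- min(e1[i], e2[j])
    if (lo < hi) {
      out_s <- c(out_s, lo)
      out_e <- c(out_e, hi)
    }
    if (e1[i] < e2[j]) i <- i + 1L else j <- j + 1L
  }
  list(start = out_s, end = out_e)
}

# Intersection of two interval sets (as position sets); returns disjoint
# intervals covering the common bases, sorted by chrom then start.
# stranded = TRUE requires identical strand labels ("+" with "+", "-"
# with "-", anything else only with itself), matching strand-aware
# range-set semantics; the default ignores strand entirely.
intersect_intervals <- function(x, y, stranded = FALSE) {
  if (nrow(x) == 0 || nrow(y) == 0) return(empty_intervals())
  strand_of <- function(df) {
    if (stranded && "strand" %in% names(df)) {
      s <- df$strand
      s[!s %in% c("+", "-")] <- "."
      s
    } else rep(".", nrow(df))
  }
  sx <- strand_of(x); sy <- strand_of(y)
  out <- list()
  for (st in intersect(unique(sx), unique(sy))) {
    xs <- x[sx == st, , drop = FALSE]
    ys <- y[sy == st, , drop = FALSE]
    for (ch in intersect(unique(xs$chrom), unique(ys$chrom))) {
      mx <- merge_intervals(xs[xs$chrom == ch, , drop = FALSE])
      my <- merge_intervals(ys[ys$chrom == ch, , drop = FALSE])
      z <- .sweep_intersect(mx$start, mx$end, my$start, my$end)
      if (length(z$start)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = z$start, end = z$end,
          strand = if (stranded) st else ".", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Total bases in the union of an interval set.
total_width <- function(x) {
  if (nrow(x) == 0) return(0L)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Number of bases of the union of y covered by the union of x.
overlap_width <- function(x, y, stranded = FALSE) {
  z <- intersect_intervals(x, y, stranded = stranded)
  if (nrow(z) == 0) return(0L)
  sum(z$end - z$start)
}

# TRUE iff every base of x lies within the union of y.
contained_within <- function(x, y, stranded = FALSE) {
  w <- if (nrow(x) == 0) 0L else sum(merge_intervals(x)$end - merge_intervals(x)$start)
  overlap_width(y, x, stranded = stranded) == w && w > 0L
}
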