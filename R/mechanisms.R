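# Mechanism classification: each discovered duplex is tested against four
# candidate regulatory mechanisms (alternative-splicing modulation, miRNA
# target-site masking, A-to-I editing triggering, Staufen-mediated decay)
# and its target region is labelled. The "interaction region" is the
# union of the duplex's genomic blocks.

MECHANISMS <- c("SPLICING", "MIRNA_MASKING", "EDITING", "SMD")

duplex_footprint <- function(d) {
  if (is.null(d$genome_blocks) || nrow(d$genome_blocks) == 0) {
    stop("duplex has no genomic blocks; project it with transcript_to_genome first")
  }
  merge_intervals(d$genome_blocks)
}

# Map a genomic position (0-based) to spliced transcript coordinates.
genome_to_spliced <- function(t, gpos) {
  ex <- t$exons
  order_tx <- if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  off <- 0L
  for (i in order_tx) {
    if (gpos >= ex$start[i] && gpos < ex$end[i]) {
      return(if (t$strand == "+") off + (gpos - ex$start[i])
             else off + (ex$end[i] - 1L - gpos))
    }
    off <- off + ex$end[i] - ex$start[i]
  }
  NA_integer_
}

# Spliced-space [start, end) of the CDS, or NULL for non-coding.
cds_tx_range <- function(t) {
  if (is.null(t$cds)) return(NULL)
  pos <- c(t$cds$start, t$cds$end - 1L)
  tx <- vapply(pos, function(p) genome_to_spliced(t, p), integer(1))
  c(start = min(tx), end = max(tx) + 1L)
}

# Genomic blocks of the 3' UTR (exonic sequence downstream of the CDS).
three_prime_utr_blocks <- function(t) {
  r <- cds_tx_range(t)
  if (is.null(r)) return(empty_intervals())
  txlen <- spliced_length(t)
  if (r[["end"]] >= txlen) return(empty_intervals())
  transcript_to_genome(t, r[["end"]], txlen, space = "spliced")
}

# Genomic CDS blocks of a transcript ("" when non-coding).
cds_blocks <- function(t) {
  if (is.null(t$cds)) return(empty_intervals())
  genomic_intervals(t$chrom, t$cds$start, t$cds$end, t$strand)
}

#' Alternative splice sites of a gene
#'
#' A splice site is an exon boundary adjacent to an intron in at least
#' one isoform. It counts as alternative when at least one isoform whose
#' genomic span contains the position uses it and at least one such
#' isoform does not. Single-isoform genes have no alternative sites.
#'
#' Each site is reported as a 1-base interval: the first intronic base
#' for donor-side boundaries, the last intronic base for acceptor-side
#' boundaries, with the boundary coordinate in column `position`.
#'
#' @param g a `gene_model`.
#' @return Interval data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `position`, `side` (`"exon_end"`/`"exon_start"`).
#' @export
alternative_splice_sites <- function(g) {
  txs <- g$transcripts
  empty <- cbind(empty_intervals(), position = integer(), side = character())
  if (length(txs) < 2) return(empty)
  boundaries <- lapply(txs, function(t) {
    n <- nrow(t$exons)
    if (n < 2) return(data.frame(position = integer(), side = character()))
    rbind(
      data.frame(position = t$exons$end[-n], side = "exon_end",
                 stringsAsFactors = FALSE),
      data.frame(position = t$exons$start[-1], side = "exon_start",
                 stringsAsFactors = FALSE)
    )
  })
  spans <- lapply(txs, function(t) c(min(t$exons$start), max(t$exons$end)))
  all_b <- unique(do.call(rbind, boundaries))
  if (nrow(all_b) == 0) return(empty)
  keep <- vapply(seq_len(nrow(all_b)), function(i) {
    p <- all_b$position[i]; side <- all_b$side[i]
    containing <- vapply(spans, function(sp) sp[1] < p && p < sp[2], logical(1))
    uses <- vapply(boundaries, function(b) {
      any(b$position == p & b$side == side)
    }, logical(1))
    any(containing & uses) && any(containing & !uses)
  }, logical(1))
  alt <- all_b[keep, , drop = FALSE]
  if (nrow(alt) == 0) return(empty)
  start <- ifelse(alt$side == "exon_end", alt$position, alt$position - 1L)
  out <- genomic_intervals(g$chrom, start, start + 1L, ".")
  out$position <- alt$position
  out$side <- alt$side
  out[order(out$start, out$side), , drop = FALSE]
}

#' Splicing-modulation classifier
#'
#' `TRUE` iff the duplex footprint (pre-mRNA space only) contains at
#' least one exon-intron boundary of the target transcript in its
#' interior and overlaps at least one alternative splice site of the
#' gene.
#'
#' @param d a `duplex_alignment` with genomic blocks.
#' @param g the target's `gene_model`.
#' @param target the target `transcript_model` (defaults to the duplex's
#'   `target_id` looked up in `g`).
#' @return Logical.
#' @export
classify_splicing <- function(d, g, target = g$transcripts[[d$target_id]]) {
  if (!identical(d$target_space, "premrna")) {
    stop("splicing calls require pre-mRNA-space alignments")
  }
  if (is.null(target)) stop("target transcript not found in gene model")
  fp <- duplex_footprint(d)
  n <- nrow(target$exons)
  if (n < 2) return(FALSE)
  boundaries <- c(target$exons$end[-n], target$exons$start[-1])
  in_interior <- any(vapply(boundaries, function(b) {
    any(fp$start < b & b < fp$end)
  }, logical(1)))
  if (!in_interior) return(FALSE)
  alt <- alternative_splice_sites(g)
  if (nrow(alt) == 0) return(FALSE)
  overlap_width(fp, alt[, c("chrom", "start", "end", "strand")]) > 0
}

#' Predict miRNA seed-match target sites
#'
#' Reports a site wherever the reverse complement of miRNA positions 2-8
#' (the 7-mer seed) occurs exactly in the target's spliced sequence. The
#' site interval is the seed match extended upstream by the remaining
#' miRNA length (`len - 8` bases before the match), clipped to transcript
#' bounds, and projected to genomic coordinates.
#'
#' @param mirnas named character vector of mature miRNA sequences
#'   (5'->3', 18-26 nt; `U` normalized to `T`).
#' @param target the target `transcript_model`.
#' @param target_seq spliced sequence of `target`.
#' @return Data frame of genomic site blocks with columns `site_id`,
#'   `mirna_id`, `chrom`, `start`, `end`, `strand`, `tx_start`, `tx_end`,
#'   `clip_supported` (initially `FALSE`).
#' @export
predict_seed_sites <- function(mirnas, target, target_seq) {
  target_seq <- normalize_seq(target_seq)
  txlen <- nchar(target_seq)
  out <- list()
  for (mid in sort(names(mirnas))) {
    mir <- normalize_seq(mirnas[[mid]])
    if (nchar(mir) < 8) next
    seed <- substr(mir, 2, 8)
    pat <- revcomp(seed)
    hits <- gregexpr(pat, target_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in as.integer(hits)) {
      s0 <- h - 1L                                   # 0-based seed match start
      tx_start <- max(0L, s0 - (nchar(mir) - 8L))    # full pairing footprint
      tx_end <- min(txlen, s0 + 7L)
      blocks <- transcript_to_genome(target, tx_start, tx_end, "spliced")
      blocks$site_id <- paste0(mid, "@", target$transcript_id, ":", tx_start)
      blocks$mirna_id <- mid
      blocks$tx_start <- tx_start
      blocks$tx_end <- tx_end
      blocks$clip_supported <- FALSE
      out[[length(out) + 1L]] <- blocks
    }
  }
  if (length(out) == 0) {
    return(cbind(empty_intervals(), site_id = character(),
                 mirna_id = character(), tx_start = integer(),
                 tx_end = integer(), clip_supported = logical()))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("site_id", "mirna_id", "chrom", "start", "end", "strand",
         "tx_start", "tx_end", "clip_supported")]
}

#' Retain predicted miRNA sites supported by CLIP evidence
#'
#' Superimposes predicted seed sites with merged Argonaute CLIP
#' intervals; a site is kept iff it overlaps at least one CLIP interval
#' by at least one base, and its interval is truncated to the common
#' part of the two datasets.
#'
#' @param predicted site data frame from [predict_seed_sites()].
#' @param clip interval data frame of CLIP binding sites, already passed
#'   through [merge_intervals()].
#' @param stranded restrict support to same-strand CLIP intervals.
#' @return Site data frame in the same layout, truncated to the CLIP
#'   intersection, with `clip_supported = TRUE`.
#' @export
supported_mirna_sites <- function(predicted, clip, stranded = FALSE) {
  out <- list()
  for (sid in unique(predicted$site_id)) {
    site <- predicted[predicted$site_id == sid, , drop = FALSE]
    common <- intersect_intervals(
      site[, c("chrom", "start", "end", "strand")], clip,
      stranded = stranded
    )
    if (nrow(common) == 0) next
    common$site_id <- sid
    common$mirna_id <- site$mirna_id[1]
    common$strand <- site$strand[1]
    common$tx_start <- site$tx_start[1]
    common$tx_end <- site$tx_end[1]
    common$clip_supported <- TRUE
    out[[length(out) + 1L]] <-
      common[, c("site_id", "mirna_id", "chrom", "start", "end", "strand",
                 "tx_start", "tx_end", "clip_supported")]
  }
  if (length(out) == 0) return(predicted[0, , drop = FALSE])
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' miRNA-masking classifier
#'
#' `TRUE` iff at least half of some miRNA target site (rounded up:
#' `ceiling(half_site_rule * site length)` bases) lies within the duplex
#' footprint.
#'
#' @param d a `duplex_alignment` with genomic blocks.
#' @param sites site data frame (normally CLIP-supported sites from
#'   [supported_mirna_sites()]).
#' @param params a [scoring_params()] object.
#' @param stranded same-strand-only intersection.
#' @return List with `hit` (logical) and `sites` (supporting site ids).
#' @export
classify_mirna_masking <- function(d, sites, params = scoring_params(),
                                   stranded = FALSE) {
  if (nrow(sites) == 0) return(list(hit = FALSE, sites = character()))
  fp <- duplex_footprint(d)
  supporting <- character()
  for (sid in unique(sites$site_id)) {
    blocks <- sites[sites$site_id == sid, , drop = FALSE]
    len <- sum(blocks$end - blocks$start)
    ov <- overlap_width(fp, blocks[, c("chrom", "start", "end", "strand")],
                        stranded = stranded)
    if (ov >= ceiling(params$half_site_rule * len)) {
      supporting <- c(supporting, sid)
    }
  }
  list(hit = length(supporting) > 0, sites = supporting)
}

#' Staufen-mediated decay classifier
#'
#' `TRUE` iff some Alu element lies entirely within the duplex footprint
#' and entirely within the genomic intervals of the target's 3' UTR;
#' always `FALSE` for targets without a CDS (no UTR defined).
#'
#' @param d a `duplex_alignment` with genomic blocks.
#' @param alu interval data frame of Alu elements.
#' @param target the target `transcript_model`.
#' @param stranded same-strand-only containment.
#' @return List with `hit` (logical) and `alus` (supporting interval data
#'   frame).
#' @export
classify_smd <- function(d, alu, target, stranded = FALSE) {
  none <- list(hit = FALSE, alus = empty_intervals())
  if (is.null(target$cds) || nrow(alu) == 0) return(none)
  utr3 <- three_prime_utr_blocks(target)
  if (nrow(utr3) == 0) return(none)
  fp <- duplex_footprint(d)
  keep <- vapply(seq_len(nrow(alu)), function(i) {
    a <- alu[i, , drop = FALSE]
    contained_within(a, fp, stranded = stranded) &&
      contained_within(a, utr3, stranded = stranded)
  }, logical(1))
  list(hit = any(keep), alus = alu[keep, , drop = FALSE])
}

#' A-to-I editing classifier
#'
#' `TRUE` iff at least one known editing position (1-base interval) lies
#' inside the duplex footprint (half-open containment).
#'
#' @param d a `duplex_alignment` with genomic blocks.
#' @param editing interval data frame of editing positions (width 1).
#' @param stranded same-strand-only containment.
#' @return List with `hit` (logical) and `positions` (supporting interval
#'   data frame).
#' @export
classify_editing <- function(d, editing, stranded = FALSE) {
  if (nrow(editing) == 0) return(list(hit = FALSE, positions = empty_intervals()))
  fp <- duplex_footprint(d)
  keep <- vapply(seq_len(nrow(editing)), function(i) {
    overlap_width(fp, editing[i, , drop = FALSE], stranded = stranded) > 0
  }, logical(1))
  list(hit = any(keep), positions = editing[keep, , drop = FALSE])
}

#' Target-region classifier
#'
#' Labels the target region of a duplex: `NONCODING` when the target has
#' no CDS; otherwise `UTR` when the footprint does not touch the CDS,
#' `CDS` when it lies entirely within the CDS, and `UTR_CDS_OVERLAP`
#' otherwise.
#'
#' @param d a `duplex_alignment` with genomic blocks.
#' @param target the target `transcript_model`.
#' @return One of `"UTR"`, `"CDS"`, `"UTR_CDS_OVERLAP"`, `"NONCODING"`.
#' @export
classify_region <- function(d, target) {
  if (is.null(target$cds)) return("NONCODING")
  fp <- duplex_footprint(d)
  cds <- cds_blocks(target)
  if (overlap_width(fp, cds) == 0) return("UTR")
  if (contained_within(fp, cds)) return("CDS")
  "UTR_CDS_OVERLAP"
}

#' Annotate duplexes with mechanisms and region labels
#'
#' Runs all four mechanism classifiers and the region classifier on each
#' duplex. The splicing classifier only applies to pre-mRNA-space
#' duplexes; miRNA sites are predicted per target with
#' [predict_seed_sites()] and filtered for CLIP support (or an external
#' site table can be supplied via `mirna_sites` to bypass the seed-match
#' stand-in). Records with empty mechanism sets are retained.
#'
#' @param duplexes list of `duplex_alignment` objects (ids filled in).
#' @param genes named list of `gene_model` objects.
#' @param genome named character vector of chromosome sequences.
#' @param tracks list with interval data frames `clip`, `alu`, `editing`
#'   (any may be missing or empty).
#' @param mirnas named character vector of mature miRNA sequences.
#' @param params a [scoring_params()] object.
#' @param stranded same-strand-only track intersections.
#' @param mirna_sites optional precomputed site data frame (layout of
#'   [predict_seed_sites()]); replaces seed-match prediction.
#' @return List of `interaction_record` objects.
#' @export
annotate_interactions <- function(duplexes, genes, genome,
                                  tracks = list(), mirnas = character(),
                                  params = scoring_params(),
                                  stranded = FALSE, mirna_sites = NULL) {
  txs <- all_transcripts(genes)
  gene_of <- setNames(
    rep(names(genes), vapply(genes, function(g) length(g$transcripts), 0L)),
    names(txs)
  )
  clip <- if (!is.null(tracks$clip) && nrow(tracks$clip))
    merge_intervals(tracks$clip) else empty_intervals()
  alu <- if (!is.null(tracks$alu)) tracks$alu else empty_intervals()
  editing <- if (!is.null(tracks$editing)) tracks$editing else empty_intervals()

  # CLIP-supported miRNA sites per target transcript, computed lazily
  site_cache <- new.env(parent = emptyenv())
  sites_for <- function(tid) {
    if (!is.null(site_cache[[tid]])) return(site_cache[[tid]])
    t <- txs[[tid]]
    predicted <- if (!is.null(mirna_sites)) {
      mirna_sites[mirna_sites$site_id %in%
                    mirna_sites$site_id[grepl(paste0("@", tid, ":"),
                                              mirna_sites$site_id, fixed = TRUE)] |
                    (if ("target_id" %in% names(mirna_sites))
                      mirna_sites$target_id == tid else FALSE), , drop = FALSE]
    } else if (length(mirnas)) {
      predict_seed_sites(mirnas, t, spliced_sequence(t, genome))
    } else {
      predict_seed_sites(character(), t, "")
    }
    supported <- if (nrow(predicted) && nrow(clip))
      supported_mirna_sites(predicted, clip, stranded = stranded)
    else predicted[0, , drop = FALSE]
    site_cache[[tid]] <- supported
    supported
  }

  records <- lapply(duplexes, function(d) {
    if (!d$target_id %in% names(txs)) {
      stop("duplex references unknown target id '", d$target_id, "'")
    }
    target <- txs[[d$target_id]]
    g <- genes[[gene_of[[d$target_id]]]]
    if (is.null(d$genome_blocks)) {
      d$genome_blocks <- transcript_to_genome(target, d$target_start,
                                              d$target_end, d$target_space)
    }
    mechanisms <- character()
    evidence <- list()
    if (identical(d$target_space, "premrna") && classify_splicing(d, g, target)) {
      mechanisms <- c(mechanisms, "SPLICING")
      evidence$SPLICING <- alternative_splice_sites(g)
    }
    mm <- classify_mirna_masking(d, sites_for(d$target_id), params,
                                 stranded = stranded)
    if (mm$hit) {
      mechanisms <- c(mechanisms, "MIRNA_MASKING")
      evidence$MIRNA_MASKING <- mm$sites
    }
    ed <- classify_editing(d, editing, stranded = stranded)
    if (ed$hit) {
      mechanisms <- c(mechanisms, "EDITING")
      evidence$EDITING <- ed$positions
    }
    smd <- classify_smd(d, alu, target, stranded = stranded)
    if (smd$hit) {
      mechanisms <- c(mechanisms, "SMD")
      evidence$SMD <- smd$alus
    }
    structure(
      list(
        duplex = d,
        mechanisms = mechanisms,
        region = classify_region(d, target),
        gene_id = g$gene_id, gene_name = g$name,
        gene_description = g$description,
        target_biotype = target$biotype,
        evidence = evidence
      ),
      class = "interaction_record"
    )
  })
  records
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction %s : %s [%s] mechanisms={%s} region=%s>\n",
              x$duplex$lnc_id, x$duplex$target_id, x$duplex$target_space,
              paste(x$mechanisms, collapse = ","), x$region))
  invisible(x)
}

#' Tabulate interaction records
#'
#' One row per lncRNA-RNA interaction, in the layout of a search-results
#' table: ids, mechanisms, gene metadata, biotype and region.
#'
#' @param records list of `interaction_record` objects.
#' @return Data frame.
#' @export
interactions_to_df <- function(records) {
  if (length(records) == 0) {
    return(data.frame(lnc_id = character(), target_id = character(),
                      mechanisms = character(), gene_id = character(),
                      gene_name = character(), gene_description = character(),
                      target_biotype = character(), region = character(),
                      target_space = character(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      lnc_id = r$duplex$lnc_id, target_id = r$duplex$target_id,
      mechanisms = paste(sort(r$mechanisms), collapse = ","),
      gene_id = r$gene_id, gene_name = r$gene_name,
      gene_description = r$gene_description,
      target_biotype = r$target_biotype, region = r$region,
      target_space = r$duplex$target_space, score = r$duplex$score,
      stringsAsFactors = FALSE
    )
  }))
}
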