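# Readers and writers for the standard formats the pipeline consumes:
# GTF (Ensembl attribute dialect), FASTA, BED3/BED6, TSV expression and
# differential-expression tables. All interval coordinates are converted
# to 0-based half-open on read.

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read transcript annotations from a GTF file
#'
#' Parses `exon` and `CDS` features, groups them into transcripts and
#' genes, and converts GTF's 1-based inclusive coordinates to the
#' package's 0-based half-open convention. The transcript biotype is read
#' from the `transcript_biotype` (or `transcript_type`) attribute and is
#' `""` when absent; a transcript is flagged novel when it carries a
#' `novel "true"` attribute or its id matches `novel_pattern`.
#'
#' @param path GTF file path.
#' @param novel_pattern optional regex; transcript ids matching it are
#'   flagged novel (e.g. `"^MSTRG"` for StringTie assemblies).
#' @return Named list of `gene_model` objects, ordered by `gene_id`.
#' @export
read_gtf <- function(path, novel_pattern = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("GTF parse error at line ", lineno[which(nf < 9)[1]],
         ": expected 9 tab-separated fields")
  }
  feat <- vapply(fields, `[[`, "", 3)
  use <- feat %in% c("exon", "CDS")
  if (!any(use)) return(list())
  fields <- fields[use]
  lineno <- lineno[use]
  feat <- feat[use]
  chrom <- vapply(fields, `[[`, "", 1)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  strand <- vapply(fields, `[[`, "", 7)
  attrs <- vapply(fields, `[[`, "", 9)
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1 |
                 !strand %in% c("+", "-"))
  if (length(bad)) {
    stop("GTF parse error at line ", lineno[bad[1]],
         ": invalid coordinates or strand")
  }
  tx_id <- gtf_attr(attrs, "transcript_id")
  if (anyNA(tx_id)) {
    stop("GTF parse error at line ", lineno[which(is.na(tx_id))[1]],
         ": feature without transcript_id")
  }
  gene_id <- gtf_attr(attrs, "gene_id")
  if (anyNA(gene_id)) {
    stop("GTF parse error at line ", lineno[which(is.na(gene_id))[1]],
         ": feature without gene_id")
  }
  biotype <- gtf_attr(attrs, "transcript_biotype")
  alt <- gtf_attr(attrs, "transcript_type")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]
  biotype[is.na(biotype)] <- ""
  gene_name <- gtf_attr(attrs, "gene_name")
  gene_desc <- gtf_attr(attrs, "gene_description")
  novel_attr <- tolower(gtf_attr(attrs, "novel")) %in% c("true", "1", "yes")

  df <- data.frame(
    chrom = chrom, start = start1 - 1L, end = end1, strand = strand,
    feat = feat, tx_id = tx_id, gene_id = gene_id, biotype = biotype,
    gene_name = ifelse(is.na(gene_name), "", gene_name),
    gene_desc = ifelse(is.na(gene_desc), "", gene_desc),
    novel = novel_attr, stringsAsFactors = FALSE
  )

  genes <- list()
  for (gid in sort(unique(df$gene_id))) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    txs <- lapply(sort(unique(gdf$tx_id)), function(tid) {
      tdf <- gdf[gdf$tx_id == tid, , drop = FALSE]
      ex <- tdf[tdf$feat == "exon", c("start", "end"), drop = FALSE]
      if (nrow(ex) == 0) return(NULL)  # CDS-only stubs are ignored
      cds <- tdf[tdf$feat == "CDS", c("start", "end"), drop = FALSE]
      novel <- any(tdf$novel) ||
        (!is.null(novel_pattern) && grepl(novel_pattern, tid))
      transcript_model(
        transcript_id = tid, gene_id = gid,
        chrom = tdf$chrom[1], strand = tdf$strand[1],
        exons = ex, cds = if (nrow(cds)) cds else NULL,
        biotype = tdf$biotype[tdf$feat == "exon"][1],
        novel = novel
      )
    })
    txs <- Filter(Negate(is.null), txs)
    if (length(txs) == 0) next
    genes[[gid]] <- gene_model(
      gid, txs,
      name = gdf$gene_name[nzchar(gdf$gene_name)][1] %||% "",
      description = gdf$gene_desc[nzchar(gdf$gene_desc)][1] %||% ""
    )
  }
  genes
}

`%||%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Read a BED track
#'
#' BED3/BED6; coordinates are native 0-based half-open. Extra columns
#' beyond the sixth are ignored.
#'
#' @param path BED file path.
#' @return Interval data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `name`, `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(cbind(empty_intervals(),
                                       name = character(), score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": expected at least 3 columns")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": require 0 <= start < end")
  }
  getcol <- function(i, default) {
    vapply(fields, function(x) if (length(x) >= i) x[i] else default, "")
  }
  strand <- getcol(6, ".")
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = start, end = end, strand = strand,
    name = getcol(4, "."),
    score = suppressWarnings(as.numeric(getcol(5, "0"))),
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED
#'
#' Writes BED6 when any of `name`, `score`, `strand` is informative,
#' otherwise BED3. Round-trips with [read_bed()] on the first six columns.
#'
#' @param intervals interval data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", nrow(intervals))
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0, nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", nrow(intervals))
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome (or any sequence set) from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences; names are
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a TPM expression table with a sample-to-group map
#'
#' The expression file is TSV with a header row of sample ids and a first
#' column of feature ids; the group file is TSV with columns `sample` and
#' `group` (`case`/`control`).
#'
#' @param path expression TSV path.
#' @param group_path group map TSV path.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, group_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tpm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(tpm) <- tab[[1]]
  gm <- read.delim(group_path, stringsAsFactors = FALSE)
  group <- setNames(gm$group, gm$sample)
  expression_matrix(tpm, group)
}

#' Read a differential-expression result table
#'
#' TSV with columns `gene_id`, `fold_change` (linear scale, case over
#' control) and `fdr`. The direction is derived from the fold change.
#'
#' @param path TSV path.
#' @param method label recorded in the result (e.g. the DE package name).
#' @return Data frame with columns `gene_id`, `fold_change`, `fdr`,
#'   `direction`, `method`.
#' @export
read_de_table <- function(path, method = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "fold_change", "fdr") %in% names(tab)))
  if (any(tab$fold_change <= 0)) stop("fold_change must be positive (linear scale)")
  tab$direction <- ifelse(tab$fold_change >= 1, "up", "down")
  tab$method <- method
  tab[, c("gene_id", "fold_change", "fdr", "direction", "method")]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
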