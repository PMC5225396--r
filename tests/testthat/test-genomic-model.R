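test_that("transcript_model validates its exon and CDS structure", {
  ex <- data.frame(start = c(0, 200), end = c(100, 300))
  t <- transcript_model("t1", "g1", "chr1", "+", ex)
  expect_s3_class(t, "transcript_model")
  expect_equal(spliced_length(t), 200L)
  expect_error(transcript_model("t1", "g1", "chr1", "+",
                                data.frame(start = 10, end = 10)),
               "start >= end")
  expect_error(transcript_model("t1", "g1", "chr1", "+",
                                data.frame(start = c(0, 50), end = c(100, 150))),
               "overlapping exons")
  expect_error(transcript_model("t1", "g1", "chr1", "+", ex,
                                cds = data.frame(start = 90, end = 210)),
               "not contained")
  # exons are sorted on construction
  t2 <- transcript_model("t2", "g1", "chr1", "-",
                         data.frame(start = c(200, 0), end = c(300, 100)))
  expect_equal(t2$exons$start, c(0L, 200L))
})

test_that("spliced_sequence concatenates exons in transcription order", {
  genome <- c(chr1 = "AACCGGTTACGTACGTAAAA")
  ex <- data.frame(start = c(2, 8), end = c(6, 12))
  tp <- transcript_model("tp", "g", "chr1", "+", ex)
  tm <- transcript_model("tm", "g", "chr1", "-", ex)
  expect_equal(spliced_sequence(tp, genome), "CCGGACGT")
  expect_equal(spliced_sequence(tm, genome), revcomp("CCGGACGT"))
  expect_error(spliced_sequence(tp, c(chrX = "AAAA")), "not present")
  expect_error(
    spliced_sequence(transcript_model("t", "g", "chr1", "+",
                                      data.frame(start = 0, end = 100)), genome),
    "beyond end")
})

test_that("pre-mRNA masking hides only bases deeper than the margin", {
  set.seed(11)
  margin <- 10L
  intron_lens <- c(2L * margin, 2L * margin + 1L)  # boundary pair
  for (il in intron_lens) {
    chrom <- random_dna(400L)
    ex <- data.frame(start = c(50L, 150L + il), end = c(150L, 250L + il))
    t <- transcript_model("t", "g", "c", "+", ex)
    pm <- premrna_sequence(t, c(c = chrom), margin = margin)
    expect_equal(nchar(pm), 200L + il)
    n_pos <- which(strsplit(pm, "")[[1]] == "N")
    if (il <= 2L * margin) {
      expect_length(n_pos, 0L)
    } else {
      # exactly the deep positions: intron occupies local [100, 100+il)
      expect_equal(n_pos, seq(100L + margin + 1L, 100L + il - margin))
    }
    # unmasked bases equal the raw genomic sequence
    raw <- substring(chrom, ex$start[1] + 1L, ex$end[2])
    keep <- setdiff(seq_len(nchar(pm)), n_pos)
    expect_equal(strsplit(pm, "")[[1]][keep], strsplit(raw, "")[[1]][keep])
  }
})

test_that("pre-mRNA of a minus-strand transcript is the reverse complement", {
  set.seed(12)
  chrom <- random_dna(500L)
  ex <- data.frame(start = c(20L, 400L), end = c(120L, 480L))
  tp <- transcript_model("tp", "g", "c", "+", ex)
  tm <- transcript_model("tm", "g", "c", "-", ex)
  pp <- premrna_sequence(tp, c(c = chrom), margin = 50L)
  pm <- premrna_sequence(tm, c(c = chrom), margin = 50L)
  expect_equal(pm, revcomp(pp))
  # single-exon transcripts have no introns to mask
  t1 <- transcript_model("t1", "g", "c", "+", data.frame(start = 10, end = 110))
  expect_equal(premrna_sequence(t1, c(c = chrom), margin = 0L),
               spliced_sequence(t1, c(c = chrom)))
})

test_that("transcript_to_genome projects spliced intervals exactly", {
  set.seed(13)
  for (rep in 1:30) {
    r <- random_transcript(n_exons = sample(1:4, 1))
    t <- r$t
    L <- spliced_length(t)
    if (L < 3) next
    a <- sample.int(L - 1L, 1) - 1L
    b <- a + sample.int(L - a, 1)
    blocks <- transcript_to_genome(t, a, b, "spliced")
    # widths add up and blocks are genomic-sorted, within exons
    expect_equal(sum(blocks$end - blocks$start), b - a)
    expect_true(!is.unsorted(blocks$start))
    expect_true(all(blocks$strand == t$strand))
    ex_pos <- positions_of(cbind(t$exons, chrom = t$chrom))
    expect_true(all(positions_of(blocks) %in% ex_pos))
    # base-level identity: sequence of the interval equals the sequence
    # assembled from the projected blocks
    seq_tx <- substr(spliced_sequence(t, r$genome), a + 1L, b)
    part <- vapply(seq_len(nrow(blocks)), function(i) {
      substr(r$genome[["chrA"]], blocks$start[i] + 1L, blocks$end[i])
    }, "")
    assembled <- paste(part, collapse = "")
    if (t$strand == "-") assembled <- revcomp(assembled)
    expect_equal(toupper(assembled), seq_tx)
  }
  t <- transcript_model("t", "g", "c", "+", data.frame(start = 0, end = 10))
  expect_error(transcript_to_genome(t, 5, 5), "out of range")
  expect_error(transcript_to_genome(t, -1, 5), "out of range")
  expect_error(transcript_to_genome(t, 0, 11), "out of range")
})

test_that("pre-mRNA-space projection yields one strand-aware block", {
  ex <- data.frame(start = c(100L, 300L), end = c(200L, 400L))
  tp <- transcript_model("tp", "g", "c", "+", ex)
  tm <- transcript_model("tm", "g", "c", "-", ex)
  bp <- transcript_to_genome(tp, 50L, 170L, "premrna")
  expect_equal(c(bp$start, bp$end), c(150L, 270L))
  # minus strand: premrna position p sits at genomic span_end - 1 - p,
  # so [50, 170) maps to [400 - 170, 400 - 50) = [230, 350)
  bm <- transcript_to_genome(tm, 50L, 170L, "premrna")
  expect_equal(c(bm$start, bm$end), c(230L, 350L))
})

test_that("GTF reading converts coordinates and attributes faithfully", {
  gtf <- c(
    "# comment line",
    paste0("chr1\tsrc\texon\t11\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; transcript_biotype "lincRNA"; gene_name "GN1";'),
    paste0("chr1\tsrc\texon\t201\t300\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; transcript_biotype "lincRNA";'),
    paste0("chr1\tsrc\texon\t51\t400\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2"; novel "true";'),
    paste0("chr1\tsrc\tCDS\t101\t200\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2";')
  )
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  genes <- read_gtf(path)
  expect_setequal(names(genes), c("g1", "g2"))
  t1 <- genes$g1$transcripts$t1
  expect_equal(t1$exons$start, c(10L, 200L))  # 1-based -> 0-based
  expect_equal(t1$exons$end, c(100L, 300L))
  expect_equal(t1$biotype, "lincRNA")
  expect_false(t1$novel)
  expect_equal(genes$g1$name, "GN1")
  t2 <- genes$g2$transcripts$t2
  expect_true(t2$novel)
  expect_equal(t2$cds$start, 100L)
  # novel_pattern flags ids without the attribute
  genes2 <- read_gtf(path, novel_pattern = "^t1$")
  expect_true(genes2$g1$transcripts$t1$novel)
})

test_that("GTF parse errors report the offending line", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t10\t.\t+\t.", ""), path)  # 8 fields
  expect_error(read_gtf(path), "line 1.*9 tab-separated")
  writeLines(c("# header",
               "chr1\tsrc\texon\t0\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"),
             path)
  expect_error(read_gtf(path), "line 2.*invalid coordinates")
  writeLines("chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"g\";", path)
  expect_error(read_gtf(path), "line 1.*transcript_id")
})

test_that("BED reading/writing round-trips 0-based half-open intervals", {
  x <- genomic_intervals(c("chr1", "chr2"), c(0L, 50L), c(10L, 99L),
                         c("+", "."), name = c("a", "b"), score = c(1, 2.5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y[, c("chrom", "start", "end", "strand", "name")],
               x[, c("chrom", "start", "end", "strand", "name")])
  expect_equal(y$score, x$score)
  writeLines("chr1\t5\t5", path)
  expect_error(read_bed(path), "line 1.*start < end")
  writeLines(c("track name=x", "chr1\t0\t10"), path)
  expect_equal(nrow(read_bed(path)), 1L)
})

test_that("FASTA round-trips sequences and truncates names at whitespace", {
  seqs <- c(s1 = random_dna(150L), s2 = "ACGTN")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(back, seqs)
  writeLines(c(">name with description", "ACGT"), path)
  expect_equal(names(read_fasta(path)), "name")
})

test_that("expression and DE tables read with groups and directions", {
  ed <- withr::local_tempdir()
  write.table(data.frame(transcript_id = c("t1", "t2"),
                         s1 = c(1.5, 0), s2 = c(0, 3)),
              file.path(ed, "e.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = c("s1", "s2"), group = c("case", "control")),
              file.path(ed, "g.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- read_expression(file.path(ed, "e.tsv"), file.path(ed, "g.tsv"))
  expect_equal(lncduplex:::max_tpm(expr, "t1", "case"), 1.5)
  expect_equal(lncduplex:::max_tpm(expr, "t1", "control"), 0)
  expect_error(lncduplex:::max_tpm(expr, "nope"), "no expression row")

  write.table(data.frame(gene_id = c("g1", "g2"), fold_change = c(2, 0.4),
                         fdr = c(0.001, 0.2)),
              file.path(ed, "de.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  de <- read_de_table(file.path(ed, "de.tsv"), method = "m1")
  expect_equal(de$direction, c("up", "down"))
  expect_equal(de$method, c("m1", "m1"))
})
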