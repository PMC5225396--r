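two_isoform_gene <- function() {
  a <- transcript_model("txA", "g", "c", "+",
                        data.frame(start = c(0L, 200L), end = c(100L, 300L)))
  b <- transcript_model("txB", "g", "c", "+",
                        data.frame(start = c(0L, 250L), end = c(100L, 300L)))
  gene_model("g", list(a, b))
}

test_that("alternative splice sites are boundaries used by some spanning isoforms only", {
  g <- two_isoform_gene()
  alt <- alternative_splice_sites(g)
  # the shared donor at 100 is not alternative; the two acceptors are
  expect_setequal(alt$position, c(200L, 250L))
  expect_true(all(alt$side == "exon_start"))
  # acceptor-side sites are the last intronic base
  expect_equal(alt$start[alt$position == 200L], 199L)
  # single-isoform genes have none
  g1 <- gene_model("g1", list(g$transcripts$txA))
  expect_equal(nrow(alternative_splice_sites(g1)), 0L)
  # identical isoforms have none
  a2 <- transcript_model("txA2", "g2", "c", "+", g$transcripts$txA$exons)
  g2 <- gene_model("g2", list(g$transcripts$txA, a2))
  expect_equal(nrow(alternative_splice_sites(g2)), 0L)
})

test_that("splicing calls need an interior boundary and an alternative site", {
  g <- two_isoform_gene()
  target <- g$transcripts$txA
  fp <- function(s, e) genomic_intervals("c", s, e, "+")
  # spans the txA acceptor (boundary 200) and the alt site [199, 200)
  expect_true(classify_splicing(mk_duplex("txA", "premrna", fp(150L, 220L)), g))
  # boundary exactly at the footprint edge is not interior
  expect_false(classify_splicing(mk_duplex("txA", "premrna", fp(150L, 200L)), g))
  expect_false(classify_splicing(mk_duplex("txA", "premrna", fp(200L, 260L)), g))
  # interior boundary (donor at 100) but no alternative-site overlap
  expect_false(classify_splicing(mk_duplex("txA", "premrna", fp(50L, 150L)), g))
  # spliced-space duplexes are rejected outright
  expect_error(classify_splicing(mk_duplex("txA", "spliced", fp(150L, 220L)), g),
               "pre-mRNA")
  # missing genomic blocks are an error
  expect_error(classify_splicing(mk_duplex("txA", "premrna", NULL), g),
               "no genomic blocks")
})

test_that("seed sites are reverse-complement matches of miRNA positions 2-8", {
  set.seed(41)
  chrom <- random_dna(600L)
  t <- transcript_model("t", "g", "c", "+",
                        data.frame(start = c(50L, 300L), end = c(150L, 500L)))
  genome <- c(c = chrom)
  tseq <- spliced_sequence(t, genome)
  mir <- "TAGCAGCACGTAAATATTGGCG"   # 22 nt
  seed_rc <- revcomp(substr(mir, 2, 8))
  # plant one match inside exon 2 (tx position 150 = genomic 350)
  tseq_planted <- paste0(substr(tseq, 1, 150), seed_rc, substr(tseq, 158, nchar(tseq)))
  sites <- predict_seed_sites(c(m1 = mir), t, tseq_planted)
  expect_true(nrow(sites) >= 1)
  s <- sites[sites$tx_start == 150L - (nchar(mir) - 8L), , drop = FALSE]
  expect_equal(unique(s$tx_end), 157L)
  expect_equal(sum(s$end - s$start), 21L)   # len - 8 upstream + 7 seed
  # genomic projection covers the seed bases (tx 150 -> genomic 350)
  seed_pos <- positions_of(genomic_intervals("c", 350L, 357L))
  expect_true(all(seed_pos %in% positions_of(s)))
  # a site near the transcript start is clipped at zero
  tseq2 <- paste0(seed_rc, substr(tseq, 8, nchar(tseq)))
  s2 <- predict_seed_sites(c(m1 = mir), t, tseq2)
  expect_true(any(s2$tx_start == 0L & s2$tx_end == 7L))
  # miRNAs shorter than 8 nt are skipped; no miRNAs, no sites
  expect_equal(nrow(predict_seed_sites(c(short = "ACGTACG"), t, tseq)), 0L)
  expect_equal(nrow(predict_seed_sites(character(), t, tseq)), 0L)
})

test_that("CLIP support truncates sites to the common bases", {
  site <- data.frame(site_id = "s1", mirna_id = "m1", chrom = "c",
                     start = 100L, end = 121L, strand = "+",
                     tx_start = 0L, tx_end = 21L, clip_supported = FALSE,
                     stringsAsFactors = FALSE)
  clip <- genomic_intervals("c", 110L, 140L)
  out <- supported_mirna_sites(site, clip)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(110L, 121L))
  expect_true(out$clip_supported)
  # no overlap, no support; one-base overlap suffices
  expect_equal(nrow(supported_mirna_sites(site, genomic_intervals("c", 121L, 140L))), 0L)
  expect_equal(nrow(supported_mirna_sites(site, genomic_intervals("c", 120L, 140L))), 1L)
})

test_that("miRNA masking requires at least half the site, rounded up", {
  L <- 19L  # odd length: ceiling(L/2) = 10
  site <- data.frame(site_id = "s1", mirna_id = "m1", chrom = "c",
                     start = 100L, end = 100L + L, strand = "+",
                     tx_start = 0L, tx_end = L, clip_supported = TRUE,
                     stringsAsFactors = FALSE)
  d_at <- function(s, e) mk_duplex("t", "spliced", genomic_intervals("c", s, e, "+"))
  expect_true(classify_mirna_masking(d_at(100L, 110L), site)$hit)    # 10 bases
  expect_false(classify_mirna_masking(d_at(100L, 109L), site)$hit)   # 9 bases
  expect_true(classify_mirna_masking(d_at(90L, 200L), site)$hit)     # full site
  expect_false(classify_mirna_masking(d_at(300L, 400L), site)$hit)
  hit <- classify_mirna_masking(d_at(100L, 119L), site)
  expect_equal(hit$sites, "s1")
  # split sites count their total overlapped bases
  site2 <- rbind(site, site)
  site2$start <- c(100L, 200L); site2$end <- c(110L, 209L)  # L = 19 again
  expect_true(classify_mirna_masking(d_at(100L, 206L), site2)$hit)   # 10 + 6 = 16
  expect_false(classify_mirna_masking(d_at(106L, 205L), site2)$hit)  # 4 + 5 = 9
})

test_that("SMD needs an Alu fully inside both footprint and 3' UTR", {
  t <- transcript_model("t", "g", "c", "+",
                        data.frame(start = 0L, end = 1000L),
                        cds = data.frame(start = 100L, end = 400L))
  d <- mk_duplex("t", "spliced", genomic_intervals("c", 500L, 800L, "+"))
  alu_in <- genomic_intervals("c", 550L, 700L, "+", name = "alu1")
  expect_true(classify_smd(d, alu_in, t)$hit)
  # overhanging the footprint by one base fails
  alu_over <- genomic_intervals("c", 499L, 700L, "+", name = "alu2")
  expect_false(classify_smd(d, alu_over, t)$hit)
  # inside the footprint but overlapping the CDS fails the UTR condition
  d2 <- mk_duplex("t", "spliced", genomic_intervals("c", 300L, 800L, "+"))
  alu_cds <- genomic_intervals("c", 350L, 500L, "+", name = "alu3")
  expect_false(classify_smd(d2, alu_cds, t)$hit)
  # non-coding targets have no 3' UTR
  tnc <- transcript_model("t", "g", "c", "+", data.frame(start = 0L, end = 1000L))
  expect_false(classify_smd(d, alu_in, tnc)$hit)
  # supporting Alu rows are reported
  res <- classify_smd(d, rbind(alu_in, alu_over), t)
  expect_equal(res$alus$name, "alu1")
})

test_that("editing calls need one known position inside the footprint", {
  d <- mk_duplex("t", "spliced", genomic_intervals("c", 100L, 200L, "+"))
  pos <- function(p) genomic_intervals("c", p, p + 1L)
  expect_true(classify_editing(d, pos(100L))$hit)   # first base
  expect_true(classify_editing(d, pos(199L))$hit)   # last base
  expect_false(classify_editing(d, pos(200L))$hit)  # half-open end
  expect_false(classify_editing(d, pos(99L))$hit)
  res <- classify_editing(d, rbind(pos(150L), pos(500L)))
  expect_true(res$hit)
  expect_equal(nrow(res$positions), 1L)
  expect_equal(res$positions$start, 150L)
})

test_that("region labels follow footprint vs CDS set relations", {
  t <- transcript_model("t", "g", "c", "+",
                        data.frame(start = 0L, end = 1000L),
                        cds = data.frame(start = 200L, end = 600L))
  reg <- function(s, e) classify_region(
    mk_duplex("t", "spliced", genomic_intervals("c", s, e, "+")), t)
  expect_equal(reg(650L, 800L), "UTR")
  expect_equal(reg(0L, 150L), "UTR")           # 5' side also counts as UTR
  expect_equal(reg(250L, 500L), "CDS")
  expect_equal(reg(150L, 300L), "UTR_CDS_OVERLAP")
  expect_equal(reg(580L, 650L), "UTR_CDS_OVERLAP")
  tnc <- transcript_model("t", "g", "c", "+", data.frame(start = 0L, end = 1000L))
  expect_equal(classify_region(
    mk_duplex("t", "spliced", genomic_intervals("c", 0L, 100L, "+")), tnc),
    "NONCODING")
})

test_that("3' UTR blocks are the exonic bases downstream of the CDS", {
  t <- transcript_model("t", "g", "c", "+",
                        data.frame(start = c(0L, 200L), end = c(100L, 300L)),
                        cds = data.frame(start = c(50L, 200L), end = c(100L, 230L)))
  utr <- lncduplex:::three_prime_utr_blocks(t)
  expect_equal(c(utr$start, utr$end), c(230L, 300L))
  # minus strand: downstream runs toward lower coordinates
  tm <- transcript_model("t", "g", "c", "-",
                         data.frame(start = c(0L, 200L), end = c(100L, 300L)),
                         cds = data.frame(start = 220L, end = 300L))
  utrm <- lncduplex:::three_prime_utr_blocks(tm)
  expect_setequal(positions_of(utrm),
                  positions_of(genomic_intervals("c", c(0L, 200L), c(100L, 220L))))
  # CDS reaching the transcript end leaves no 3' UTR
  t2 <- transcript_model("t", "g", "c", "+", data.frame(start = 0L, end = 300L),
                         cds = data.frame(start = 100L, end = 300L))
  expect_equal(nrow(lncduplex:::three_prime_utr_blocks(t2)), 0L)
})

test_that("annotate_interactions fills blocks, caches sites and labels records", {
  g <- two_isoform_gene()
  genes <- list(g = g)
  genome <- c(c = random_dna(400L))
  d <- mk_duplex("txA", "premrna", genomic_intervals("c", 150L, 220L, "+"))
  ed_track <- genomic_intervals("c", 160L, 161L)
  recs <- annotate_interactions(list(d), genes, genome,
                                tracks = list(editing = ed_track))
  expect_length(recs, 1L)
  expect_setequal(recs[[1]]$mechanisms, c("SPLICING", "EDITING"))
  expect_equal(recs[[1]]$region, "NONCODING")
  expect_equal(recs[[1]]$gene_id, "g")
  # blocks are projected automatically when absent
  d2 <- mk_duplex("txA", "spliced", NULL)
  d2$target_start <- 10L; d2$target_end <- 30L
  recs2 <- annotate_interactions(list(d2), genes, genome)
  expect_equal(sum(recs2[[1]]$duplex$genome_blocks$end -
                     recs2[[1]]$duplex$genome_blocks$start), 20L)
  expect_error(annotate_interactions(list(mk_duplex("nope", "spliced", NULL)),
                                     genes, genome),
               "unknown target id")
  df <- interactions_to_df(recs)
  expect_equal(df$mechanisms, "EDITING,SPLICING")
})
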