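# Synthetic dataset with planted ground truth for every pipeline stage:
# a toy genome, multi-isoform gene models, reverse-complementary
# lncRNA-target duplex cores strong enough to clear the score threshold,
# mechanism evidence tracks (CLIP/Alu/editing) inside and outside the
# planted footprints, miRNA sequences whose seeds match planted sites,
# group-specific TPM matrices and two differential-expression tables with
# boundary decoys. All randomness goes through R's RNG, so a seed
# reproduces the emitted files byte-identically.

#' Configuration for the synthetic dataset generator
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param samples_per_group samples per group (case and control).
#' @param duplexes_per_mechanism planted duplexes per mechanism.
#' @param decoys_per_failure_mode lncRNA decoy transcripts per failure
#'   mode (expression, length, peptide, biotype, novel structure).
#' @param duplex_length length range of planted duplex cores (nt).
#' @param mutation_rate range of the per-base mutation rate applied to
#'   the lncRNA copy of each planted core.
#' @param case_tpm TPM range for expressed transcripts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_lengths = c(chr1 = 100000L, chr2 = 100000L),
                             samples_per_group = 5L,
                             duplexes_per_mechanism = 2L,
                             decoys_per_failure_mode = 1L,
                             duplex_length = c(130L, 200L),
                             mutation_rate = c(0, 0.05),
                             case_tpm = c(2, 10)) {
  structure(
    list(chrom_lengths = chrom_lengths,
         samples_per_group = as.integer(samples_per_group),
         duplexes_per_mechanism = as.integer(duplexes_per_mechanism),
         decoys_per_failure_mode = as.integer(decoys_per_failure_mode),
         duplex_length = as.integer(duplex_length),
         mutation_rate = mutation_rate,
         case_tpm = case_tpm),
    class = "synthetic_config"
  )
}

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# A sequence whose longest forward ORF is < max_aa, by resampling.
rand_seq_orf_safe <- function(n, max_aa = 100L, gc = 0.5) {
  for (i in 1:50) {
    s <- rand_seq(n, gc)
    if (longest_peptide_length(s) < max_aa) return(s)
  }
  stop("could not sample an ORF-safe sequence of length ", n)
}

#' Generate the synthetic dataset
#'
#' Emits a toy genome (FASTA), annotations (GTF), expression and group
#' tables (TSV), two differential-expression tables (TSV), CLIP, Alu and
#' editing tracks (BED), mature miRNA sequences (FASTA) and a truth
#' manifest (JSON) into `out_dir`. Before emission the generator
#' re-aligns every planted duplex against its target to assert the score
#' threshold is cleared, verifies that the masked intron decoy cannot be
#' found, and checks every decoy track interval violates its classifier's
#' geometric condition.
#'
#' Targets live on chr1, lncRNA genes on chr2. Duplex cores are GC-biased
#' and deterministically reinforced (columns promoted to G:C) until the
#' planted pairing clears the score threshold with margin, since a
#' uniform-composition core of minimal length would not reach it.
#'
#' @param out_dir output directory, created if needed.
#' @param config a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return Invisibly, a list with `dir`, `files` (named paths), `truth`
#'   (the manifest as an R list) and the in-memory `genes`, `genome`,
#'   `expr` objects.
#' @export
generate_dataset <- function(out_dir, config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  params <- scoring_params()
  utr3_len <- 650L
  max_core <- max(config$duplex_length) + 40L
  if (max_core > utr3_len) {
    stop("infeasible config: duplex core (", max_core,
         " nt with margins) longer than the 3' UTR (", utr3_len, " nt)")
  }
  if (params$match_gc * min(config$duplex_length) < params$min_score + 20L) {
    stop("infeasible config: shortest duplex core (",
         min(config$duplex_length), " nt) cannot reach the score threshold")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- lapply(config$chrom_lengths, function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })
  names(genome) <- names(config$chrom_lengths)
  cursor <- setNames(rep(2000L, length(genome)), names(genome))
  place <- function(chrom, width, gap = 1500L) {
    off <- cursor[[chrom]]
    if (off + width + gap > length(genome[[chrom]])) {
      stop("synthetic genome too small for the requested gene count")
    }
    cursor[[chrom]] <<- off + width + gap
    off
  }
  plant <- function(chrom, at, seq_str) {  # at: 0-based genomic start
    chars <- strsplit(seq_str, "", fixed = TRUE)[[1]]
    genome[[chrom]][(at + 1):(at + length(chars))] <<- chars
  }
  fetch <- function(chrom, start, end) {
    paste(genome[[chrom]][(start + 1):end], collapse = "")
  }

  genes <- list()
  gtf_rows <- list()
  add_gtf <- function(chrom, feat, start0, end0, strand, gid, tid, biotype,
                      name = "", desc = "", novel = FALSE) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    if (nzchar(biotype)) attrs <- paste0(attrs, sprintf(' transcript_biotype "%s";', biotype))
    if (nzchar(name)) attrs <- paste0(attrs, sprintf(' gene_name "%s";', name))
    if (nzchar(desc)) attrs <- paste0(attrs, sprintf(' gene_description "%s";', desc))
    if (novel) attrs <- paste0(attrs, ' novel "true";')
    gtf_rows[[length(gtf_rows) + 1L]] <<- sprintf(
      "%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
      chrom, feat, start0 + 1L, end0, strand, attrs
    )
  }
  register_gene <- function(gid, txs, name = "", desc = "") {
    genes[[gid]] <<- gene_model(gid, txs, name = name, description = desc)
    for (t in txs) {
      for (i in seq_len(nrow(t$exons))) {
        add_gtf(t$chrom, "exon", t$exons$start[i], t$exons$end[i], t$strand,
                gid, t$transcript_id, t$biotype, name, desc, t$novel)
      }
      if (!is.null(t$cds)) {
        for (i in seq_len(nrow(t$cds))) {
          add_gtf(t$chrom, "CDS", t$cds$start[i], t$cds$end[i], t$strand,
                  gid, t$transcript_id, t$biotype, name, desc, t$novel)
        }
      }
    }
  }

  mat <- complementarity_matrix(params)
  # Plant a duplex: core written at target genomic position, its reverse
  # complement (mutated, then reinforced to clear the threshold) into the
  # lncRNA locus. Returns the mutation count and final core strings.
  plant_core <- function(chrom_t, core_at, chrom_l, lnc_at, len, rate) {
    core <- strsplit(rand_seq(len, gc = 0.75), "", fixed = TRUE)[[1]]
    lnc <- strsplit(revcomp(paste(core, collapse = "")), "", fixed = TRUE)[[1]]
    n_mut <- rbinom(1, len, rate)
    # Feasibility cap: reinforcement never touches mutated columns, so even
    # with every other column promoted to G:C the score is at most
    # match_gc*(len - n_mut) + mismatch*n_mut. Cap n_mut so the planted
    # duplex can always clear min_score + 20 (short cores near 130 nt have
    # little headroom).
    max_mut <- max(0L, (params$match_gc * len - (params$min_score + 20L)) %/%
                     (params$match_gc - params$mismatch))
    n_mut <- min(n_mut, max_mut)
    mut_pos <- if (n_mut > 0) sample.int(len, n_mut) else integer()
    for (p in mut_pos) {
      lnc[p] <- sample(setdiff(c("A", "C", "G", "T"), lnc[p]), 1)
    }
    col_score <- function() {
      vapply(seq_len(len), function(i) mat[lnc[i], core[len + 1L - i]], 0L)
    }
    s <- col_score()
    boostable <- setdiff(sample.int(len), mut_pos)
    k <- 1L
    while (sum(s) < params$min_score + 20L && k <= length(boostable)) {
      i <- boostable[k]
      j <- len + 1L - i
      # Promote the column to a strong pair, oriented by its current base:
      # a fixed orientation (always lnc = G, core = C) would collapse
      # heavily-reinforced cores toward poly-G lncRNAs and poly-C targets,
      # and two such planted pairs cross-pair above the score threshold.
      # Orienting by the (random) original base keeps cores balanced, so
      # independently planted duplexes stay mutually non-complementary.
      if (core[j] %in% c("A", "C")) {
        lnc[i] <- "G"; core[j] <- "C"
      } else {
        lnc[i] <- "C"; core[j] <- "G"
      }
      s <- col_score()
      k <- k + 1L
    }
    if (sum(s) < params$min_score + 20L) {
      stop("could not reinforce planted duplex to the score threshold")
    }
    plant(chrom_t, core_at, paste(core, collapse = ""))
    plant(chrom_l, lnc_at, paste(lnc, collapse = ""))
    n_mut
  }

  mechs <- c("SPLICING", "MIRNA_MASKING", "EDITING", "SMD")
  clip <- list(); alu <- list(); editing <- list()
  mirnas <- character()
  duplex_truth <- list()
  planted_lnc_ids <- character()
  expr_rows <- list()   # per transcript: list(id, mode) mode in case_only/both/low
  de_rows <- list()     # per gene: list(gene_id, dir, kind)

  add_expr <- function(tid, mode) expr_rows[[length(expr_rows) + 1L]] <<- list(id = tid, mode = mode)
  add_de <- function(gid, dir, kind = "pass") de_rows[[length(de_rows) + 1L]] <<- list(gene_id = gid, dir = dir, kind = kind)

  # ---- planted duplexes --------------------------------------------------
  for (m in mechs) {
    for (k in seq_len(config$duplexes_per_mechanism)) {
      len <- sample(seq(config$duplex_length[1], config$duplex_length[2]), 1)
      rate <- runif(1, config$mutation_rate[1], config$mutation_rate[2])
      cs <- k == 1L  # first duplex per mechanism is condition-specific
      tag <- paste0(tolower(sub("_MASKING", "", m)), k)
      gid_t <- paste0("GT_", tag); tid_t <- paste0("TT_", tag)
      gid_l <- paste0("GL_", tag); tid_l <- paste0("TL_", tag)

      if (m == "SPLICING") {
        off <- place("chr1", 1200L)
        ex_a <- data.frame(start = off + c(0L, 700L), end = off + c(300L, 1200L))
        ex_b <- data.frame(start = off + c(0L, 790L), end = off + c(300L, 1200L))
        cds_a <- data.frame(start = off + c(100L, 700L), end = off + c(300L, 1000L))
        cds_b <- data.frame(start = off + c(100L, 790L), end = off + c(300L, 1000L))
        tx_a <- transcript_model(paste0(tid_t, "A"), gid_t, "chr1", "+", ex_a,
                                 cds = cds_a, biotype = "protein_coding")
        tx_b <- transcript_model(paste0(tid_t, "B"), gid_t, "chr1", "+", ex_b,
                                 cds = cds_b, biotype = "protein_coding")
        register_gene(gid_t, list(tx_a, tx_b), name = paste0("SPL", k),
                      desc = "splicing-regulated synthetic gene")
        core_at <- off + 750L - len       # spans the isoform-A acceptor at off+700
        target_txs <- paste0(tid_t, c("A", "B"))
        expect_mech <- c("SPLICING", "")   # boundary only interior to isoform A
      } else {
        # protein-coding target with the core in the 3' UTR
        if (m == "EDITING") {
          off <- place("chr1", 2100L)
          ex_a <- data.frame(start = off + c(0L, 500L, 900L),
                             end = off + c(300L, 650L, 2100L))
          ex_b <- data.frame(start = off + c(0L, 900L), end = off + c(300L, 2100L))
          cds_a <- data.frame(start = off + c(100L, 500L, 900L),
                              end = off + c(300L, 650L, 1200L))
          cds_b <- data.frame(start = off + c(100L, 900L), end = off + c(300L, 1200L))
          tx_a <- transcript_model(paste0(tid_t, "A"), gid_t, "chr1", "+", ex_a,
                                   cds = cds_a, biotype = "protein_coding")
          tx_b <- transcript_model(paste0(tid_t, "B"), gid_t, "chr1", "+", ex_b,
                                   cds = cds_b, biotype = "protein_coding")
          register_gene(gid_t, list(tx_a, tx_b), name = paste0("EDT", k),
                        desc = "editing-target synthetic gene")
          core_at <- off + 1300L
          target_txs <- paste0(tid_t, c("A", "B"))
          expect_mech <- c("EDITING", "EDITING")
        } else {
          off <- place("chr1", 2000L)
          ex <- data.frame(start = off + c(0L, 700L), end = off + c(300L, 2000L))
          cds <- data.frame(start = off + c(150L, 700L), end = off + c(300L, 1150L))
          # tx: 5'UTR 150, CDS 600, 3'UTR genomic [off+1150, off+2000) (850 nt)
          tx <- transcript_model(tid_t, gid_t, "chr1", "+", ex, cds = cds,
                                 biotype = "protein_coding")
          register_gene(gid_t, list(tx),
                        name = paste0(substr(m, 1, 3), k),
                        desc = paste0(tolower(m), "-target synthetic gene"))
          core_at <- off + 1250L
          target_txs <- tid_t
          expect_mech <- m
        }
      }

      # lncRNA partner on chr2: 2 exons, reverse complement of the core in exon 2
      e2_len <- len + 60L
      offl <- place("chr2", 450L + e2_len)
      ex_l <- data.frame(start = offl + c(0L, 450L), end = offl + c(250L, 450L + e2_len))
      lnc_core_at <- offl + 480L
      novel <- m == "EDITING"
      tx_l <- transcript_model(tid_l, gid_l, "chr2", "+", ex_l,
                               biotype = if (novel) "" else "lincRNA",
                               novel = novel)
      register_gene(gid_l, list(tx_l), name = paste0("LNC_", tag),
                    desc = "synthetic lncRNA gene")
      n_mut <- plant_core("chr1", core_at, "chr2", lnc_core_at, len, rate)

      # keep the lncRNA free of long ORFs (resample non-core exon 1)
      for (try in 1:50) {
        s <- spliced_sequence(genes[[gid_l]]$transcripts[[tid_l]], lapply(genome, paste, collapse = ""))
        if (longest_peptide_length(s) < params$max_peptide_aa) break
        plant("chr2", offl, rand_seq(250L))
      }

      # mechanism evidence inside the core footprint
      if (m == "MIRNA_MASKING") {
        mir <- rand_seq(22L)
        seed7 <- substr(mir, 2, 8)
        site_at <- core_at + 60L          # seed complement inside the core
        plant("chr1", site_at, revcomp(seed7))
        mirnas[paste0("mir-", k)] <- mir
        clip[[length(clip) + 1L]] <- genomic_intervals(
          "chr1", site_at - 24L, site_at + 17L, ".", name = paste0("clip_", tag))
        # planting the seed complement rewrote part of the core: re-plant the
        # lncRNA complement of the final core so the duplex still pairs
        # (this also removes the mutations applied to the lncRNA copy)
        core_final <- fetch("chr1", core_at, core_at + len)
        plant("chr2", lnc_core_at, revcomp(core_final))
        n_mut <- 0L
      }
      if (m == "EDITING") {
        pos <- core_at + c(30L, 70L, 110L)
        editing[[length(editing) + 1L]] <- genomic_intervals(
          "chr1", pos, pos + 1L, ".", name = paste0("edit_", tag, "_", seq_along(pos)))
      }
      if (m == "SMD") {
        alu[[length(alu) + 1L]] <- genomic_intervals(
          "chr1", core_at + 20L, core_at + len - 20L, "+",
          name = paste0("alu_", tag))
      }

      planted_lnc_ids <- c(planted_lnc_ids, tid_l)
      add_expr(tid_l, if (cs) "case_only" else "both")
      for (tt in target_txs) add_expr(tt, if (cs) "case_only" else "both")
      add_de(gid_t, "up"); add_de(gid_l, if (cs) "up" else "down")
      for (i in seq_along(target_txs)) {
        duplex_truth[[length(duplex_truth) + 1L]] <- list(
          lnc_id = tid_l, target_id = target_txs[i], target_gene = gid_t,
          mechanism = expect_mech[i], core_start = core_at,
          core_end = core_at + len, core_len = len, mutations = n_mut,
          condition_specific = cs
        )
      }
    }
  }

  # ---- masked-intron decoy ----------------------------------------------
  off <- place("chr1", 2400L)
  ex <- data.frame(start = off + c(0L, 1600L), end = off + c(300L, 2400L))
  cds <- data.frame(start = off + c(100L, 1600L), end = off + c(300L, 2000L))
  tx <- transcript_model("TT_masked", "GT_masked", "chr1", "+", ex, cds = cds,
                         biotype = "protein_coding")
  register_gene("GT_masked", list(tx), name = "MSK1",
                desc = "deep-intron decoy gene")
  mlen <- 160L
  masked_core_at <- off + 850L   # > 250 nt from both splice sites (300, 1600)
  offl <- place("chr2", 450L + mlen + 60L)
  ex_l <- data.frame(start = offl + c(0L, 450L), end = offl + c(250L, 510L + mlen))
  tx_l <- transcript_model("TL_masked", "GL_masked", "chr2", "+", ex_l,
                           biotype = "lincRNA")
  register_gene("GL_masked", list(tx_l), name = "LNC_masked",
                desc = "partner of the deep-intron decoy")
  plant_core("chr1", masked_core_at, "chr2", offl + 480L, mlen, 0)
  planted_lnc_ids <- c(planted_lnc_ids, "TL_masked")
  add_expr("TL_masked", "both"); add_expr("TT_masked", "both")
  add_de("GT_masked", "up"); add_de("GL_masked", "up")

  # ---- overlapping DE gene pairs ----------------------------------------
  make_host <- function(gid, tid, name) {
    off <- place("chr1", 2300L)
    ex <- data.frame(start = off + c(0L, 1500L), end = off + c(300L, 2300L))
    cds <- data.frame(start = off + c(100L, 1500L), end = off + c(300L, 1900L))
    tx <- transcript_model(tid, gid, "chr1", "+", ex, cds = cds,
                           biotype = "protein_coding")
    register_gene(gid, list(tx), name = name, desc = "overlap host gene")
    off
  }
  offA <- make_host("G_ovA1", "T_ovA1", "OVA1")
  # nested lncRNA gene deep inside the host intron (masked region)
  exn <- data.frame(start = offA + c(600L, 950L), end = offA + c(800L, 1100L))
  txn <- transcript_model("T_ovA2", "G_ovA2", "chr1", "-", exn, biotype = "lincRNA")
  register_gene("G_ovA2", list(txn), name = "OVA2", desc = "nested lncRNA gene")
  offB <- make_host("G_ovB1", "T_ovB1", "OVB1")
  exn <- data.frame(start = offB + c(600L, 900L), end = offB + c(750L, 1100L))
  cdsn <- data.frame(start = offB + c(620L, 900L), end = offB + c(750L, 1000L))
  txn <- transcript_model("T_ovB2", "G_ovB2", "chr1", "-", exn, cds = cdsn,
                          biotype = "protein_coding")
  register_gene("G_ovB2", list(txn), name = "OVB2", desc = "nested coding gene")
  add_expr("T_ovA1", "both"); add_expr("T_ovA2", "both")
  add_expr("T_ovB1", "both"); add_expr("T_ovB2", "both")
  add_de("G_ovA1", "up"); add_de("G_ovA2", "up")
  add_de("G_ovB1", "up"); add_de("G_ovB2", "down")
  planted_lnc_ids <- c(planted_lnc_ids, "T_ovA2")
  overlap_truth <- data.frame(
    gene_a = c("G_ovA1", "G_ovB1"), gene_b = c("G_ovA2", "G_ovB2"),
    concordant = c(TRUE, FALSE), has_lnc_isoform = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )

  # ---- differential-expression boundary decoy genes ---------------------
  make_small_gene <- function(gid, tid, biotype = "protein_coding") {
    off <- place("chr1", 700L)
    ex <- data.frame(start = off + c(0L, 400L), end = off + c(300L, 700L))
    cds <- if (biotype == "protein_coding")
      data.frame(start = off + c(100L, 400L), end = off + c(300L, 600L)) else NULL
    tx <- transcript_model(tid, gid, "chr1", "+", ex, cds = cds, biotype = biotype)
    register_gene(gid, list(tx), name = gid, desc = "boundary decoy gene")
  }
  make_small_gene("G_fc15", "T_fc15"); add_expr("T_fc15", "both")
  add_de("G_fc15", "up", kind = "fc_boundary_pass")
  make_small_gene("G_fc14", "T_fc14"); add_expr("T_fc14", "both")
  add_de("G_fc14", "up", kind = "fc_fail")
  make_small_gene("G_fdr", "T_fdr"); add_expr("T_fdr", "both")
  add_de("G_fdr", "up", kind = "fdr_boundary_fail")
  make_small_gene("G_disc", "T_disc"); add_expr("T_disc", "both")
  add_de("G_disc", "up", kind = "discordant")

  # ---- lncRNA decoy transcripts, one gene per failure mode ---------------
  lnc_decoys <- list()
  for (d in seq_len(config$decoys_per_failure_mode)) {
    sfx <- if (config$decoys_per_failure_mode > 1) paste0("_", d) else ""
    # expression decoy: fine lncRNA, TPM below 1 everywhere
    off <- place("chr2", 500L)
    tx <- transcript_model(paste0("T_dTPM", sfx), paste0("G_dTPM", sfx), "chr2", "+",
                           data.frame(start = off + c(0L, 300L), end = off + c(150L, 450L)),
                           biotype = "lincRNA")
    plant("chr2", off, rand_seq_orf_safe(150L))
    plant("chr2", off + 300L, rand_seq_orf_safe(150L))
    register_gene(paste0("G_dTPM", sfx), list(tx))
    add_expr(paste0("T_dTPM", sfx), "low")
    lnc_decoys[[paste0("T_dTPM", sfx)]] <- "expression"
    # length decoy: 199 nt single exon, minus strand
    off <- place("chr2", 199L)
    tx <- transcript_model(paste0("T_dLEN", sfx), paste0("G_dLEN", sfx), "chr2", "-",
                           data.frame(start = off, end = off + 199L),
                           biotype = "lincRNA")
    register_gene(paste0("G_dLEN", sfx), list(tx))
    add_expr(paste0("T_dLEN", sfx), "both")
    lnc_decoys[[paste0("T_dLEN", sfx)]] <- "length"
    # peptide decoy: longest ORF exactly 100 aa
    off <- place("chr2", 400L)
    orf <- paste0("ATG", paste(rep("GAA", 99L), collapse = ""), "TAA")
    flank1 <- paste(sample(c("C", "T"), 50, replace = TRUE), collapse = "")
    flank2 <- paste(sample(c("C", "T"), 400 - 50 - nchar(orf), replace = TRUE),
                    collapse = "")
    plant("chr2", off, paste0(flank1, orf, flank2))
    tx <- transcript_model(paste0("T_dPEP", sfx), paste0("G_dPEP", sfx), "chr2", "+",
                           data.frame(start = off, end = off + 400L),
                           biotype = "lincRNA")
    register_gene(paste0("G_dPEP", sfx), list(tx))
    add_expr(paste0("T_dPEP", sfx), "both")
    lnc_decoys[[paste0("T_dPEP", sfx)]] <- "peptide"
    # biotype decoy: excluded biotype, everything else fine
    off <- place("chr2", 450L)
    plant("chr2", off, rand_seq_orf_safe(450L))
    tx <- transcript_model(paste0("T_dBIO", sfx), paste0("G_dBIO", sfx), "chr2", "+",
                           data.frame(start = off + c(0L, 250L), end = off + c(200L, 450L)),
                           biotype = "miRNA")
    register_gene(paste0("G_dBIO", sfx), list(tx))
    add_expr(paste0("T_dBIO", sfx), "both")
    lnc_decoys[[paste0("T_dBIO", sfx)]] <- "biotype"
    # novel single-exon decoy
    off <- place("chr2", 300L)
    plant("chr2", off, rand_seq_orf_safe(300L))
    tx <- transcript_model(paste0("T_dNOV", sfx), paste0("G_dNOV", sfx), "chr2", "+",
                           data.frame(start = off, end = off + 300L),
                           biotype = "", novel = TRUE)
    register_gene(paste0("G_dNOV", sfx), list(tx))
    add_expr(paste0("T_dNOV", sfx), "both")
    lnc_decoys[[paste0("T_dNOV", sfx)]] <- "novel_structure"
  }

  # decoy miRNA (no planted site) and decoy track intervals outside any
  # gene (intergenic tail of chr1)
  mirnas[["mir-decoy"]] <- rand_seq(22L)
  tail1 <- length(genome$chr1) - 5000L
  clip[[length(clip) + 1L]] <- genomic_intervals("chr1", tail1, tail1 + 40L, ".",
                                                 name = "clip_decoy")
  editing[[length(editing) + 1L]] <- genomic_intervals("chr1", tail1 + 200L,
                                                       tail1 + 201L, ".",
                                                       name = "edit_decoy")
  # overhanging Alu decoy: starts 1 base before the first SMD core
  smd1 <- Filter(function(d) d$mechanism == "SMD", duplex_truth)[[1]]
  alu[[length(alu) + 1L]] <- genomic_intervals("chr1", smd1$core_start - 1L,
                                               smd1$core_start + 80L, "+",
                                               name = "alu_overhang_decoy")
  # 3' UTR Alu decoy outside any footprint
  alu[[length(alu) + 1L]] <- genomic_intervals("chr1", tail1 + 400L,
                                               tail1 + 700L, "+",
                                               name = "alu_decoy")

  clip <- do.call(rbind, clip); alu <- do.call(rbind, alu)
  editing <- do.call(rbind, editing)

  genome_str <- lapply(genome, paste, collapse = "")

  # ---- expression matrix -------------------------------------------------
  n <- config$samples_per_group
  samples <- c(paste0("case", seq_len(n)), paste0("ctrl", seq_len(n)))
  group <- setNames(rep(c("case", "control"), each = n), samples)
  tpm <- matrix(0, nrow = length(expr_rows), ncol = 2 * n,
                dimnames = list(vapply(expr_rows, `[[`, "", "id"), samples))
  for (r in expr_rows) {
    vals_case <- round(runif(n, config$case_tpm[1], config$case_tpm[2]), 3)
    vals_ctrl <- switch(r$mode,
      case_only = rep(0, n),
      both = round(runif(n, config$case_tpm[1], config$case_tpm[2]), 3),
      low = NULL
    )
    if (r$mode == "low") {
      tpm[r$id, ] <- c(round(runif(n - 1, 0.1, 0.8), 3), 0.9,
                       round(runif(n, 0.1, 0.8), 3))
    } else {
      tpm[r$id, ] <- c(vals_case, vals_ctrl)
    }
  }
  expr <- expression_matrix(tpm, group)

  # ---- differential-expression tables ------------------------------------
  de_tab <- function(method_jitter) {
    rows <- lapply(de_rows, function(r) {
      fc_up <- round(runif(1, 1.6, 4), 3)
      base <- switch(r$kind,
        pass = list(fc = if (r$dir == "up") fc_up else round(1 / fc_up, 4),
                    fdr = signif(runif(1, 1e-6, 1e-3), 3)),
        fc_boundary_pass = list(fc = 1.5, fdr = 1e-4),
        fc_fail = list(fc = 1.4, fdr = 1e-4),
        fdr_boundary_fail = list(fc = 2.0, fdr = 0.01),
        discordant = list(fc = if (method_jitter) 2.0 else 0.5, fdr = 1e-4)
      )
      data.frame(gene_id = r$gene_id, fold_change = base$fc, fdr = base$fdr,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  de1 <- de_tab(TRUE); de2 <- de_tab(FALSE)
  de_expected <- setNames(
    vapply(de_rows, `[[`, "", "dir"),
    vapply(de_rows, `[[`, "", "gene_id")
  )
  de_expected <- de_expected[!vapply(de_rows, `[[`, "", "kind") %in%
                               c("fc_fail", "fdr_boundary_fail", "discordant")]

  # ---- self-validation ---------------------------------------------------
  txs <- all_transcripts(genes)
  for (d in duplex_truth) {
    lnc_seq <- spliced_sequence(txs[[d$lnc_id]], genome_str)
    tseq <- premrna_sequence(txs[[d$target_id]], genome_str, params$intron_margin)
    hits <- align_duplex(lnc_seq, tseq, params, max_hits = 5)
    if (length(hits) == 0) stop("self-validation failed: planted duplex ",
                                d$lnc_id, ":", d$target_id, " not recovered")
  }
  lnc_masked <- spliced_sequence(txs[["TL_masked"]], genome_str)
  pm <- premrna_sequence(txs[["TT_masked"]], genome_str, params$intron_margin)
  if (length(align_duplex(lnc_masked, pm, params)) != 0) {
    stop("self-validation failed: masked decoy recovered despite masking")
  }
  # decoy complementarity check against a decoy target
  relaxed <- scoring_params(min_score = 125L)
  decoy_seq <- spliced_sequence(txs[["T_fc15"]], genome_str)
  for (lid in planted_lnc_ids) {
    if (length(align_duplex(spliced_sequence(txs[[lid]], genome_str),
                            decoy_seq, relaxed)) != 0) {
      stop("self-validation failed: decoy target shares >=125-score complementarity")
    }
  }
  # decoy track geometry
  smd_fp <- genomic_intervals("chr1", smd1$core_start, smd1$core_end, "+")
  stopifnot(!contained_within(alu[alu$name == "alu_overhang_decoy",
                                  c("chrom", "start", "end", "strand")], smd_fp))

  # ---- emit files ---------------------------------------------------------
  f <- function(x) file.path(out_dir, x)
  files <- c(genome = f("genome.fa"), gtf = f("annotation.gtf"),
             expression = f("expression.tsv"), groups = f("groups.tsv"),
             de1 = f("de_method1.tsv"), de2 = f("de_method2.tsv"),
             clip = f("clip.bed"), alu = f("alu.bed"),
             editing = f("editing.bed"), mirnas = f("mirnas.fa"),
             truth = f("truth.json"))
  write_fasta(unlist(genome_str), files[["genome"]])
  writeLines(unlist(gtf_rows), files[["gtf"]])
  expr_out <- data.frame(transcript_id = rownames(tpm), tpm,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_out, files[["expression"]])
  write_tsv(data.frame(sample = samples, group = unname(group[samples])),
            files[["groups"]])
  write_tsv(de1, files[["de1"]]); write_tsv(de2, files[["de2"]])
  write_bed(clip, files[["clip"]]); write_bed(alu, files[["alu"]])
  write_bed(editing, files[["editing"]])
  write_fasta(mirnas, files[["mirnas"]])

  truth <- list(
    seed = seed,
    n_genes = length(genes),
    n_transcripts = length(txs),
    exon_counts = setNames(lapply(txs, function(t) nrow(t$exons)), names(txs)),
    planted_lncrnas = sort(planted_lnc_ids),
    lnc_decoys = lnc_decoys,
    duplexes = duplex_truth,
    masked_decoy = list(lnc_id = "TL_masked", target_id = "TT_masked"),
    de_expected = as.list(de_expected),
    condition_specific_pairs = lapply(
      Filter(function(d) d$condition_specific, duplex_truth),
      function(d) list(lnc_id = d$lnc_id, target_id = d$target_id)),
    overlap_pairs = overlap_truth,
    track_counts = list(clip = nrow(clip), alu = nrow(alu),
                        editing = nrow(editing)),
    mirnas = as.list(mirnas)
  )
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(dir = out_dir, files = files, truth = truth,
                 genes = genes, genome = genome_str, expr = expr,
                 tracks = list(clip = clip, alu = alu, editing = editing),
                 mirnas = mirnas, de_tables = list(de1 = de1, de2 = de2)))
}
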