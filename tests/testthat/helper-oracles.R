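# Independent re-implementations used as test oracles. These deliberately
# avoid the package's algorithms: the alignment oracle uses an explicit
# gap-length recursion (no affine-gap state machine), the tiny-sequence
# oracle enumerates every alignment outright, the ORF oracle scans every
# ATG, and the classifier oracles work on per-base position sets.

rev_str <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# Best local alignment score of q vs t (as given; no reversal) under the
# complementarity matrix, scoring each gap of length k as
# |gap_open| + k * |gap_extend| via explicit maximization over k.
oracle_local_score <- function(q, t, params = scoring_params()) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  mat <- complementarity_matrix(params)
  go <- abs(params$gap_open); ge <- abs(params$gap_extend)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      v <- max(0, H[i, j] + mat[qc[i], tc[j]])
      for (k in seq_len(i)) v <- max(v, H[i + 1 - k, j + 1] - (go + ge * k))
      for (k in seq_len(j)) v <- max(v, H[i + 1, j + 1 - k] - (go + ge * k))
      H[i + 1, j + 1] <- v
    }
  }
  as.integer(max(H))
}

# Exhaustive best local score for very short sequences: enumerate every
# set of aligned column pairs (strictly increasing in both sequences),
# charging each run of unaligned bases between consecutive columns as one
# gap per sequence. Feasible for nchar <= 6.
oracle_exhaustive_score <- function(q, t, params = scoring_params()) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  mat <- complementarity_matrix(params)
  go <- abs(params$gap_open); ge <- abs(params$gap_extend)
  gap_cost <- function(g) sum(ifelse(g > 0, go + ge * g, 0))
  best <- 0L
  for (k in seq_len(min(n, m))) {
    I_sets <- utils::combn(n, k, simplify = FALSE)
    J_sets <- utils::combn(m, k, simplify = FALSE)
    for (I in I_sets) {
      for (J in J_sets) {
        sc <- sum(mat[cbind(qc[I], tc[J])])
        if (k > 1) sc <- sc - gap_cost(diff(I) - 1L) - gap_cost(diff(J) - 1L)
        best <- max(best, sc)
      }
    }
  }
  as.integer(best)
}

# Third, fully independent route: Biostrings' affine-gap local aligner.
biostrings_best_score <- function(q, t, params = scoring_params()) {
  mat <- complementarity_matrix(params)
  as.integer(Biostrings::pairwiseAlignment(
    q, t, type = "local", substitutionMatrix = mat,
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend),
    scoreOnly = TRUE
  ))
}

# Longest ORF in amino acids: start at every ATG, walk codons to the
# first in-frame stop.
oracle_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(s, j, j + 2L) %in% stops) {
        best <- max(best, (j - i) %/% 3L)
        break
      }
      j <- j + 3L
    }
  }
  as.integer(best)
}

# Per-base position set of an interval data frame ("chrom:pos" strings,
# optionally strand-tagged).
positions_of <- function(df, stranded = FALSE) {
  if (is.null(df) || nrow(df) == 0) return(character())
  unlist(lapply(seq_len(nrow(df)), function(i) {
    tag <- if (stranded) {
      s <- df$strand[i]
      if (!s %in% c("+", "-")) s <- "."
      paste0(df$chrom[i], s)
    } else df$chrom[i]
    if (df$end[i] <= df$start[i]) return(character())
    paste0(tag, ":", seq.int(df$start[i], df$end[i] - 1L))
  }))
}

# Random interval set for merge/intersect cross-checks.
random_intervals <- function(n, max_pos = 200L, chroms = c("c1", "c2"),
                             strands = c("+", "-", ".")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(30L, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + width,
                    sample(strands, n, replace = TRUE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random multi-exon transcript on a fresh random chromosome.
random_transcript <- function(n_exons = sample(1:4, 1), strand = sample(c("+", "-"), 1),
                              chrom_len = 3000L, id = "tx", coding = FALSE) {
  genome <- c(chrA = random_dna(chrom_len))
  bounds <- sort(sample(seq(10L, chrom_len - 10L), 2L * n_exons))
  exons <- data.frame(start = bounds[seq(1, 2 * n_exons, 2)],
                      end = bounds[seq(2, 2 * n_exons, 2)])
  exons <- exons[exons$end > exons$start, , drop = FALSE]
  if (nrow(exons) == 0) return(random_transcript(n_exons, strand, chrom_len, id, coding))
  cds <- NULL
  if (coding) {
    i <- sample(nrow(exons), 1)
    w <- exons$end[i] - exons$start[i]
    if (w >= 6) {
      cs <- exons$start[i] + sample.int(w - 3L, 1) - 1L
      cds <- data.frame(start = cs, end = min(exons$end[i], cs + 3L + sample.int(w, 1)))
      if (cds$end <= cds$start) cds <- NULL
    }
  }
  t <- transcript_model(id, paste0(id, "_g"), "chrA", strand, exons, cds = cds)
  list(t = t, genome = genome)
}

# Shared fixtures: synthetic datasets and pipeline runs are expensive, so
# cache them per seed for the whole test session.
.fixture_cache <- new.env(parent = emptyenv())

cached_dataset <- function(seed) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("lncduplex_fixture_ds", seed))
    unlink(dir, recursive = TRUE)
    .fixture_cache[[key]] <- generate_dataset(dir, synthetic_config(), seed = seed)
  }
  .fixture_cache[[key]]
}

# A minimal duplex_alignment carrying only what the classifiers consume.
mk_duplex <- function(target_id, space, blocks, lnc_id = "L1") {
  lncduplex:::new_duplex_alignment(
    score = 600L, lnc_start = 0L, lnc_end = 10L,
    target_start = 0L, target_end = 10L, pairing = "",
    lnc_id = lnc_id, target_id = target_id, target_space = space,
    genome_blocks = blocks
  )
}

# Full planted-truth recovery check for one generated dataset and its
# pipeline result: catalog, interaction pairs (no false positives, no
# masked decoy), exact per-record mechanism labels, and the
# condition-specific filter.
check_planted_recovery <- function(ds, res) {
  expect_setequal(res$lnc_catalog$transcript_id[res$lnc_catalog$is_lncrna],
                  ds$truth$planted_lncrnas)
  pair_of <- function(r) paste(r$duplex$lnc_id, r$duplex$target_id)
  reported <- unique(vapply(res$records, pair_of, ""))
  planted <- unique(vapply(ds$truth$duplexes, function(d) {
    paste(d$lnc_id, d$target_id)
  }, ""))
  expect_setequal(reported, planted)
  expect_false(paste(ds$truth$masked_decoy$lnc_id,
                     ds$truth$masked_decoy$target_id) %in% reported)
  keys <- vapply(res$records, pair_of, "")
  for (d in ds$truth$duplexes) {
    key <- paste(d$lnc_id, d$target_id)
    expected <- setdiff(d$mechanism, "")
    for (i in which(keys == key)) {
      expected_here <- if (identical(expected, "SPLICING") &&
                             res$records[[i]]$duplex$target_space == "spliced")
        character() else expected
      expect_setequal(res$records[[i]]$mechanisms, expected_here)
    }
  }
  cs <- unique(vapply(res$condition_specific, pair_of, ""))
  truth_cs <- unique(vapply(ds$truth$condition_specific_pairs, function(p) {
    paste(p$lnc_id, p$target_id)
  }, ""))
  expect_setequal(cs, truth_cs)
  invisible(TRUE)
}

cached_pipeline <- function(seed) {
  key <- paste0("pl", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- cached_dataset(seed)
    f <- ds$files
    cfg <- pipeline_config(
      gtf = f[["gtf"]], genome = f[["genome"]],
      expression = f[["expression"]], groups = f[["groups"]],
      de_tables = c(f[["de1"]], f[["de2"]]),
      clip = f[["clip"]], alu = f[["alu"]], editing = f[["editing"]],
      mirnas = f[["mirnas"]]
    )
    .fixture_cache[[key]] <- suppressWarnings(run_pipeline(cfg))
  }
  .fixture_cache[[key]]
}
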