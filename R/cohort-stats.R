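# Cohort-level statistics: differential-expression gating, the
# condition-specific interaction filter, overlapping-loci concordance,
# and the interaction summary (unique counts, region fractions and
# mechanism-combination breakdown).

#' Gate genes on differential-expression tables
#'
#' A gene passes one table iff `fdr < fdr_threshold` (strict) and its
#' linear fold change is `>= fc_threshold` or `<= 1/fc_threshold`
#' (inclusive). In `intersection` mode (default) the gene must pass every
#' table with a concordant direction; genes with discordant directions
#' are dropped with a warning. In `union` mode passing any one table
#' suffices (discordant passing calls are still dropped).
#'
#' @param tables list of data frames from [read_de_table()].
#' @param params a [scoring_params()] object.
#' @param mode `"intersection"` or `"union"`.
#' @return Named character vector: gene id -> `"up"`/`"down"`.
#' @export
de_gate <- function(tables, params = scoring_params(),
                    mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 1)
  calls <- lapply(tables, function(tab) {
    pass <- tab$fdr < params$fdr_threshold &
      (tab$fold_change >= params$fc_threshold |
         tab$fold_change <= 1 / params$fc_threshold)
    tab[pass, c("gene_id", "direction"), drop = FALSE]
  })
  all_ids <- sort(unique(unlist(lapply(calls, `[[`, "gene_id"))))
  out <- character()
  dropped <- character()
  for (gid in all_ids) {
    dirs <- unlist(lapply(calls, function(cc) cc$direction[cc$gene_id == gid]))
    n_pass <- length(dirs)
    enough <- if (mode == "intersection") n_pass == length(tables) else n_pass >= 1
    if (!enough) next
    if (length(unique(dirs)) > 1) {
      dropped <- c(dropped, gid)
      next
    }
    out[gid] <- dirs[1]
  }
  if (length(dropped)) {
    warning("dropped gene(s) with discordant DE directions: ",
            paste(dropped, collapse = ", "))
  }
  out
}

#' Keep case-specific interactions
#'
#' Retains an interaction iff both the lncRNA and its target transcript
#' are expressed (max TPM `>= min_tpm`) in case samples and not expressed
#' (max TPM `< min_tpm`) in control samples.
#'
#' @param records list of `interaction_record` objects.
#' @param expr an [expression_matrix()] with transcript-level rows.
#' @param params a [scoring_params()] object.
#' @return Subset of `records`.
#' @export
condition_specific <- function(records, expr, params = scoring_params()) {
  keep <- vapply(records, function(r) {
    ids <- c(r$duplex$lnc_id, r$duplex$target_id)
    all(vapply(ids, function(id) max_tpm(expr, id, "case"), 0) >= params$min_tpm) &&
      all(vapply(ids, function(id) max_tpm(expr, id, "control"), 0) < params$min_tpm)
  }, logical(1))
  records[keep]
}

#' Overlapping-loci direction concordance
#'
#' Among differentially expressed genes, finds genes whose genomic spans
#' overlap another DE gene's span (strand-agnostic) and summarizes (a)
#' the count and fraction of DE genes involved in such overlaps, (b) the
#' fraction of unordered overlapping DE gene pairs with the same
#' direction of change, and (c) the number of pairs containing at least
#' one gene with a lncRNA isoform.
#'
#' @param de named direction vector from [de_gate()].
#' @param genes named list of `gene_model` objects.
#' @param lnc_gene_ids character vector of gene ids with at least one
#'   lncRNA isoform.
#' @return List with `n_de`, `n_overlapping`, `frac_overlapping`,
#'   `n_pairs`, `n_concordant`, `frac_concordant`, `n_lnc_pairs`, and the
#'   pair table `pairs`. Fractions are `NA` when undefined.
#' @export
overlap_concordance <- function(de, genes, lnc_gene_ids = character()) {
  ids <- intersect(names(de), names(genes))
  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      dir_a = character(), dir_b = character(),
                      concordant = logical(), has_lnc_isoform = logical(),
                      stringsAsFactors = FALSE)
  if (length(ids) >= 2) {
    spans <- do.call(rbind, lapply(ids, function(gid) {
      g <- genes[[gid]]
      data.frame(gene_id = gid, chrom = g$chrom,
                 start = g$span[["start"]], end = g$span[["end"]],
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(spans) - 1)) {
      for (j in (i + 1):nrow(spans)) {
        if (spans$chrom[i] != spans$chrom[j]) next
        if (spans$start[i] < spans$end[j] && spans$start[j] < spans$end[i]) {
          a <- spans$gene_id[i]; b <- spans$gene_id[j]
          pairs <- rbind(pairs, data.frame(
            gene_a = a, gene_b = b, dir_a = de[[a]], dir_b = de[[b]],
            concordant = de[[a]] == de[[b]],
            has_lnc_isoform = a %in% lnc_gene_ids || b %in% lnc_gene_ids,
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  overlapping <- unique(c(pairs$gene_a, pairs$gene_b))
  list(
    n_de = length(ids),
    n_overlapping = length(overlapping),
    frac_overlapping = if (length(ids)) length(overlapping) / length(ids) else NA_real_,
    n_pairs = nrow(pairs),
    n_concordant = sum(pairs$concordant),
    frac_concordant = if (nrow(pairs)) mean(pairs$concordant) else NA_real_,
    n_lnc_pairs = sum(pairs$has_lnc_isoform),
    pairs = pairs
  )
}

#' Summarize an interaction set
#'
#' Computes per-mechanism unique-lncRNA counts, unique lncRNA and target
#' totals (deduplicating the isoform-level redundancy of a lncRNA pairing
#' with multiple splice isoforms), region-class fractions over records,
#' and the per-target mechanism-combination breakdown: the fraction of
#' targets (with at least one mechanism) carrying more than one distinct
#' mechanism, and the share of each combination among those
#' multi-mechanism targets.
#'
#' @param records list of `interaction_record` objects.
#' @return List with `n_records`, `n_unique_lncrnas`, `n_unique_targets`,
#'   `mechanism_lnc_counts`, `region_fractions`, `multi_mechanism_fraction`,
#'   `combination_shares`.
#' @export
mechanism_summary <- function(records) {
  if (length(records) == 0) {
    return(list(n_records = 0L, n_unique_lncrnas = 0L, n_unique_targets = 0L,
                mechanism_lnc_counts = setNames(integer(length(MECHANISMS)),
                                                MECHANISMS),
                region_fractions = numeric(),
                multi_mechanism_fraction = NA_real_,
                combination_shares = numeric()))
  }
  lnc <- vapply(records, function(r) r$duplex$lnc_id, "")
  tgt <- vapply(records, function(r) r$duplex$target_id, "")
  region <- vapply(records, `[[`, "", "region")
  mech_lnc <- setNames(vapply(MECHANISMS, function(m) {
    length(unique(lnc[vapply(records, function(r) m %in% r$mechanisms, logical(1))]))
  }, integer(1)), MECHANISMS)
  # mechanism set per unique target transcript (union over its records)
  per_target <- lapply(split(seq_along(records), tgt), function(idx) {
    sort(unique(unlist(lapply(records[idx], `[[`, "mechanisms"))))
  })
  with_mech <- Filter(length, per_target)
  multi <- Filter(function(m) length(m) > 1, with_mech)
  combo_shares <- if (length(multi)) {
    combos <- vapply(multi, paste, "", collapse = "+")
    tab <- table(combos)
    setNames(as.numeric(tab) / length(multi), names(tab))
  } else numeric()
  list(
    n_records = length(records),
    n_unique_lncrnas = length(unique(lnc)),
    n_unique_targets = length(unique(tgt)),
    mechanism_lnc_counts = mech_lnc,
    region_fractions = {
      tab <- table(region)
      setNames(as.numeric(tab) / length(records), names(tab))
    },
    multi_mechanism_fraction = if (length(with_mech))
      length(multi) / length(with_mech) else NA_real_,
    combination_shares = combo_shares
  )
}
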