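# End-to-end orchestration: lncRNA identification -> DE gating -> duplex
# discovery in spliced and masked pre-mRNA spaces -> mechanism annotation
# -> condition-specific filtering -> summaries. Fully deterministic given
# its inputs; no stage uses the RNG.

#' Pipeline configuration
#'
#' Bundles input paths and options for [run_pipeline()]. All referenced
#' paths must exist at construction time.
#'
#' @param gtf,genome,expression,groups input annotation (GTF), genome
#'   (FASTA), TPM matrix (TSV) and sample-group map (TSV).
#' @param de_tables character vector of differential-expression TSV paths
#'   (one per method).
#' @param clip,alu,editing optional BED tracks; `NULL` to skip.
#' @param mirnas optional mature miRNA FASTA; `NULL` to skip seed-site
#'   prediction.
#' @param params a [scoring_params()] object.
#' @param excluded_biotypes see [default_excluded_biotypes()].
#' @param de_mode `"intersection"` or `"union"` for [de_gate()].
#' @param stranded same-strand-only track intersections.
#' @param out_dir optional output directory for the result tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, genome, expression, groups, de_tables,
                            clip = NULL, alu = NULL, editing = NULL,
                            mirnas = NULL, params = scoring_params(),
                            excluded_biotypes = default_excluded_biotypes(),
                            de_mode = "intersection", stranded = FALSE,
                            out_dir = NULL) {
  paths <- c(gtf = gtf, genome = genome, expression = expression,
             groups = groups, de_tables, clip = clip, alu = alu,
             editing = editing, mirnas = mirnas)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(
    list(gtf = gtf, genome = genome, expression = expression,
         groups = groups, de_tables = de_tables, clip = clip, alu = alu,
         editing = editing, mirnas = mirnas, params = params,
         excluded_biotypes = excluded_biotypes, de_mode = de_mode,
         stranded = stranded, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full duplex-discovery and annotation pipeline
#'
#' Stages: (1) classify every transcript with the lncRNA criteria;
#' (2) gate genes on the differential-expression tables; (3) align every
#' accepted lncRNA against the spliced sequence of every DE transcript
#' and, for multi-exon DE transcripts, against the intron-masked pre-mRNA;
#' (4) assign mechanisms and region labels; (5) filter condition-specific
#' interactions; (6) summarize. When `config$out_dir` is set, writes the
#' lncRNA table, the interaction table, the condition-specific table, the
#' overlapping-pair table and a summary JSON.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `lnc_pipeline` with elements `lnc_catalog`,
#'   `de`, `duplexes`, `records`, `condition_specific`, `summary`,
#'   `overlap`, `config` and `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    v <- force(expr)
    timings[[name]] <<- round(tic() - t0, 3)
    v
  }
  params <- config$params

  genome <- stage("read_inputs", {
    read_fasta(config$genome)
  })
  genes <- read_gtf(config$gtf)
  expr <- read_expression(config$expression, config$groups)
  de_tabs <- lapply(config$de_tables, function(p) read_de_table(p))
  tracks <- list(
    clip = if (!is.null(config$clip)) read_bed(config$clip) else NULL,
    alu = if (!is.null(config$alu)) read_bed(config$alu) else NULL,
    editing = if (!is.null(config$editing)) read_bed(config$editing) else NULL
  )
  mirnas <- if (!is.null(config$mirnas)) read_fasta(config$mirnas) else character()

  catalog <- stage("lnc_identify", {
    build_lnc_catalog(genes, genome, expr, params, config$excluded_biotypes)
  })
  lnc_ids <- catalog$transcript_id[catalog$is_lncrna]

  de <- stage("de_gate", de_gate(de_tabs, params, mode = config$de_mode))

  txs <- all_transcripts(genes)
  lncs <- setNames(
    vapply(lnc_ids, function(id) spliced_sequence(txs[[id]], genome), ""),
    lnc_ids
  )
  targets <- stage("target_sequences", {
    out <- list()
    for (tid in sort(names(txs))) {
      t <- txs[[tid]]
      if (!t$gene_id %in% names(de)) next
      out[[length(out) + 1L]] <- list(id = tid,
                                      seq = spliced_sequence(t, genome),
                                      space = "spliced", de = TRUE)
      if (nrow(t$exons) >= 2) {
        out[[length(out) + 1L]] <- list(
          id = tid,
          seq = premrna_sequence(t, genome, params$intron_margin),
          space = "premrna", de = TRUE)
      }
    }
    out
  })

  duplexes <- stage("duplex_align", {
    enumerate_interactions(lncs, targets, params)
  })
  duplexes <- lapply(duplexes, function(d) {
    d$genome_blocks <- transcript_to_genome(txs[[d$target_id]], d$target_start,
                                            d$target_end, d$target_space)
    d
  })

  records <- stage("mechanisms", {
    annotate_interactions(duplexes, genes, genome, tracks, mirnas, params,
                          stranded = config$stranded)
  })
  cs <- stage("condition_specific", condition_specific(records, expr, params))
  summary <- stage("summaries", mechanism_summary(records))
  lnc_gene_ids <- unique(catalog$gene_id[catalog$is_lncrna])
  overlap <- overlap_concordance(de, genes, lnc_gene_ids)

  result <- structure(
    list(lnc_catalog = catalog, de = de, duplexes = duplexes,
         records = records, condition_specific = cs, summary = summary,
         overlap = overlap, config = config, timings = timings),
    class = "lnc_pipeline"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(x) file.path(config$out_dir, x)
    write_tsv(catalog, o("lncrna_catalog.tsv"))
    write_tsv(interactions_to_df(records), o("interactions.tsv"))
    write_tsv(interactions_to_df(cs), o("interactions_condition_specific.tsv"))
    write_tsv(overlap$pairs, o("overlapping_de_pairs.tsv"))
    jsonlite::write_json(
      list(summary = summary,
           overlap = overlap[setdiff(names(overlap), "pairs")],
           n_lncrnas = length(lnc_ids), n_de_genes = length(de)),
      o("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  result
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("lncRNA-RNA duplex pipeline result\n")
  cat(sprintf("  transcripts classified : %d (%d lncRNAs)\n",
              nrow(x$lnc_catalog), sum(x$lnc_catalog$is_lncrna)))
  cat(sprintf("  DE genes               : %d\n", length(x$de)))
  cat(sprintf("  interactions           : %d (%d condition-specific)\n",
              length(x$records), length(x$condition_specific)))
  cat(sprintf("  unique lncRNAs/targets : %d / %d\n",
              x$summary$n_unique_lncrnas, x$summary$n_unique_targets))
  invisible(x)
}

#' @export
summary.lnc_pipeline <- function(object, ...) {
  s <- object$summary
  cat("Interaction summary\n")
  cat("  records:", s$n_records, " unique lncRNAs:", s$n_unique_lncrnas,
      " unique targets:", s$n_unique_targets, "\n")
  cat("  lncRNAs per mechanism:\n")
  for (m in names(s$mechanism_lnc_counts)) {
    cat(sprintf("    %-14s %d\n", m, s$mechanism_lnc_counts[[m]]))
  }
  if (length(s$region_fractions)) {
    cat("  region fractions:\n")
    for (r in names(s$region_fractions)) {
      cat(sprintf("    %-16s %.1f%%\n", r, 100 * s$region_fractions[[r]]))
    }
  }
  if (!is.na(s$multi_mechanism_fraction)) {
    cat(sprintf("  multi-mechanism targets: %.1f%%\n",
                100 * s$multi_mechanism_fraction))
  }
  ov <- object$overlap
  if (!is.na(ov$frac_concordant)) {
    cat(sprintf("  overlapping DE pairs: %d (%.1f%% concordant)\n",
                ov$n_pairs, 100 * ov$frac_concordant))
  }
  invisible(s)
}
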