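#' Scoring and filtering parameters for the duplex pipeline
#'
#' Collects every numeric constant of the procedure in one place. The
#' defaults are the published scheme: complementarity matches G:C, A:T and
#' G:U (G:T in the DNA alphabet) score 4, 2 and 1; mismatches score -6; a
#' gap of length k costs 20 + 8k; alignments below a total score of 500 are
#' discarded; intronic bases farther than 250 nt from both flanking splice
#' sites are masked before pre-mRNA searches; transcripts count as expressed
#' at >= 1 TPM; lncRNA candidates must be >= 200 nt with a longest peptide
#' shorter than 100 amino acids; differential-expression calls require
#' FDR < 0.01 and linear fold change >= 1.5 (or <= 1/1.5); miRNA-site
#' masking requires at least half of the site inside the alignment.
#'
#' @param ... name-value overrides for any of the defaults listed below.
#'
#' @return An object of class `scoring_params`: a named list with fields
#'   `match_gc`, `match_at`, `match_gu`, `mismatch`, `gap_open`,
#'   `gap_extend`, `min_score`, `intron_margin`, `min_tpm`,
#'   `min_lnc_length`, `max_peptide_aa`, `fdr_threshold`, `fc_threshold`,
#'   `half_site_rule`.
#'
#' @examples
#' p <- scoring_params()
#' p$min_score
#' relaxed <- scoring_params(min_score = 100)
#' @export
scoring_params <- function(...) {
  p <- list(
    match_gc = 4L,
    match_at = 2L,
    match_gu = 1L,
    mismatch = -6L,
    gap_open = -20L,
    gap_extend = -8L,
    min_score = 500L,
    intron_margin = 250L,
    min_tpm = 1.0,
    min_lnc_length = 200L,
    max_peptide_aa = 100L,
    fdr_threshold = 0.01,
    fc_threshold = 1.5,
    half_site_rule = 0.5
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown scoring parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
  }
  structure(p, class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Duplex pipeline scoring parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Default Ensembl biotype exclusion groups: 'Protein coding' and
# 'Short non-coding'. Unknown/empty biotypes never match an exclusion.

#' Default excluded transcript biotypes
#'
#' Biotypes belonging to the Ensembl "Protein coding" and "Short
#' non-coding" groups; transcripts carrying one of these are never
#' classified as lncRNAs. The set is configurable wherever it is consumed.
#'
#' @return Character vector of biotype strings.
#' @examples
#' "protein_coding" %in% default_excluded_biotypes()
#' @export
default_excluded_biotypes <- function() {
  c(
    "protein_coding",
    "IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_V_gene",
    "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_V_gene",
    "miRNA", "snRNA", "snoRNA", "rRNA", "tRNA",
    "misc_RNA", "scaRNA", "sRNA", "vault_RNA", "ribozyme"
  )
}
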