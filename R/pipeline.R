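# End-to-end driver: scan -> annotate -> integrate -> report.

.as_spacers <- function(guides) {
  if (inherits(guides, "spacer")) return(list(guides))
  if (is.list(guides) && !is.data.frame(guides) &&
      all(vapply(guides, inherits, logical(1L), "spacer")))
    return(guides)
  stopifnot(is.data.frame(guides),
            all(c("guide_id", "sequence") %in% names(guides)))
  get_col <- function(col, default) {
    if (col %in% names(guides)) guides[[col]] else rep(default, nrow(guides))
  }
  gene <- get_col("intended_gene", NA_character_)
  chrom <- get_col("intended_chrom", NA_character_)
  pos <- get_col("intended_tss_pos", NA_integer_)
  lapply(seq_len(nrow(guides)), function(i)
    spacer(guides$guide_id[i], guides$sequence[i], gene[i], chrom[i],
           pos[i]))
}

#' Run the full guide-specificity pipeline for one comparison
#'
#' Enumerates candidate binding sites for each guide under the flaw
#' budget, pools them, annotates genes proximal to the (non-on-target)
#' sites, calls significant genes from the differential-expression table,
#' cross-references, attributes candidates with the target-matched siRNA
#' control when provided, checks for spreading around the on-target
#' site(s), and computes the global log-expression correlation when TPM
#' columns are present.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param guides A [spacer()], a list of them, or a guide data frame with
#'   columns `guide_id`, `sequence` and optionally `intended_gene`,
#'   `intended_chrom`, `intended_tss_pos`.
#' @param tss TSS table (`gene`, `chrom`, `pos`, optional `strand`).
#' @param de_table Differential-expression table of the comparison.
#' @param sirna_table Optional DE table of the target-matched siRNA
#'   comparison.
#' @param budget A [flaw_budget()].
#' @param pam IUPAC PAM pattern (default `"NGG"`).
#' @param window TSS-proximity window in bp (default 500).
#' @param half_window Spreading-check half-width in bp (default 1e6).
#' @param th A [thresholds()] object.
#' @param comparison Label for the report.
#' @return A `specificity_report` (see [build_report()]) with the pooled
#'   `sites` and `proximal_hits` tables attached.
#' @examples
#' study <- simulate_study(rng_seed = 1, n_genes = 50)
#' rep <- run_specificity_pipeline(study$genome, study$guides, study$tss,
#'                                 study$de, study$sirna_de)
#' rep$possible_offtarget
#' @export
run_specificity_pipeline <- function(genome, guides, tss, de_table,
                                     sirna_table = NULL,
                                     budget = flaw_budget(), pam = "NGG",
                                     window = 500L, half_window = 1e6,
                                     th = thresholds(),
                                     comparison = "treated vs. control") {
  spacers <- .as_spacers(guides)
  sites <- pool_sites(lapply(spacers, function(sp)
    enumerate_sites(genome, sp, budget, pam, on_target_window = window)))
  hits <- annotate_proximal(sites, tss, window = window)
  prox <- proximal_genes(hits)

  intended <- unique(stats::na.omit(
    vapply(spacers, function(s) s$intended_gene, character(1L))))
  on_target <- sites[sites$is_on_target, , drop = FALSE]
  neighborhood <- character()
  if (nrow(on_target) > 0L) {
    for (i in seq_len(nrow(on_target))) {
      neighborhood <- union(
        neighborhood,
        neighborhood_genes(on_target[i, , drop = FALSE], tss,
                           half_window = half_window,
                           exclude_gene = intended))
    }
  } else {
    message("no on-target site found; spreading check skipped")
  }

  report <- build_report(comparison, de_table, prox,
                         sirna_table = sirna_table,
                         neighborhood = sort(neighborhood), th = th,
                         exclude_gene = intended)
  report$sites <- sites
  report$proximal_hits <- hits
  report
}
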