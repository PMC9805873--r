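# Integration of differential-expression results with off-target proximity:
# significance calls, cross-referencing, orthogonal siRNA attribution,
# spreading check, global correlation, and the per-comparison report.

.check_de_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("gene", "log2fc", "pvalue") %in% names(table)))
  if (nrow(table) == 0L) stop("differential-expression table is empty")
  if (anyDuplicated(table$gene)) stop("gene identifiers must be unique")
  if (!"padj" %in% names(table)) table$padj <- NA_real_
  table
}

#' Call significantly differentially expressed genes
#'
#' A gene is significant when its absolute log2 fold change strictly
#' exceeds the threshold and its p-value (adjusted by default) is strictly
#' below alpha. A gene at exactly the fold-change threshold is therefore
#' not significant. Records with non-finite log2 fold change are skipped
#' with a warning; when adjusted p-values are requested but entirely
#' missing, the raw p-value is used instead, with a warning.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `pvalue` and
#'   optionally `padj` (see [read_de_table()]).
#' @param th A [thresholds()] object.
#' @return Sorted character vector of significant gene identifiers.
#' @export
call_significant <- function(table, th = thresholds()) {
  table <- .check_de_table(table)
  stopifnot(inherits(th, "de_thresholds"))
  bad <- !is.finite(table$log2fc)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-finite log2fc skipped")
    table <- table[!bad, , drop = FALSE]
  }
  p <- if (th$use_adjusted) {
    if (all(is.na(table$padj))) {
      warning("adjusted p-values requested but all missing; ",
              "falling back to raw p-values")
      table$pvalue
    } else table$padj
  } else table$pvalue
  sig <- abs(table$log2fc) > th$min_abs_log2fc & !is.na(p) & p < th$alpha
  sort(unique(table$gene[sig]))
}

#' Cross-reference significant genes with proximal genes
#'
#' The genes both significantly differentially expressed and proximal to a
#' potential off-target binding site — the candidates that could reflect
#' off-target guide binding.
#'
#' @param significant,proximal Character vectors of gene identifiers.
#' @return Sorted character vector (set intersection).
#' @export
cross_reference <- function(significant, proximal) {
  sort(intersect(unique(significant), unique(proximal)))
}

#' Attribute candidate off-target genes using the siRNA orthogonal control
#'
#' siRNA knockdown of the same target acts through an orthogonal (RNA-level)
#' mechanism, so a candidate gene that is also differentially expressed in
#' the target-matched siRNA comparison most likely responds to target
#' knockdown itself (a pathway effect) rather than to off-target guide
#' binding. Candidates are split accordingly into a disjoint partition.
#'
#' @param candidates Genes both significant and proximal
#'   (from [cross_reference()]).
#' @param sirna_significant Significant genes of the target-matched siRNA
#'   comparison (from [call_significant()]).
#' @return A list with sorted character vectors `pathway_attributed`
#'   (candidates also significant under siRNA) and `possible_offtarget`
#'   (the remainder).
#' @export
attribute_orthogonal <- function(candidates, sirna_significant) {
  candidates <- unique(candidates)
  list(pathway_attributed = sort(intersect(candidates, sirna_significant)),
       possible_offtarget = sort(setdiff(candidates, sirna_significant)))
}

#' Check for repressive spreading around the on-target locus
#'
#' Intersects the significant genes with the genes neighbouring the
#' on-target site (by default within +/- 1 Mb, see
#' [neighborhood_genes()]). An empty result is the desired "no spreading"
#' outcome: repression confined to the intended target.
#'
#' @param significant Significant genes (from [call_significant()]).
#' @param neighborhood Neighbouring genes (from [neighborhood_genes()]).
#' @return Sorted character vector of flagged genes.
#' @export
spreading_check <- function(significant, neighborhood) {
  sort(intersect(unique(significant), unique(neighborhood)))
}

#' Global specificity correlation of log-transformed expression
#'
#' Pearson's correlation of log2(TPM + 1) between a treated and a control
#' sample across their shared genes, excluding the intended target gene
#' (whose knockdown would otherwise dominate). A pseudocount of one is
#' added before the log transform. High r with the target excluded
#' indicates that the perturbation left the rest of the transcriptome
#' untouched.
#'
#' @param treated_tpm,control_tpm Named numeric vectors of TPM values
#'   (names are gene identifiers).
#' @param exclude Genes to exclude, typically the intended target
#'   (default none).
#' @return Pearson's r in \[-1, 1\], or `NA` with a warning when either
#'   log-expression vector has zero variance.
#' @export
specificity_correlation <- function(treated_tpm, control_tpm,
                                    exclude = character()) {
  stopifnot(is.numeric(treated_tpm), is.numeric(control_tpm),
            !is.null(names(treated_tpm)), !is.null(names(control_tpm)))
  if (any(treated_tpm < 0, na.rm = TRUE) || any(control_tpm < 0, na.rm = TRUE))
    stop("TPM values must be >= 0")
  shared <- setdiff(intersect(names(treated_tpm), names(control_tpm)),
                    exclude)
  if (length(shared) < 3L)
    stop("need at least 3 shared genes after exclusion, have ",
         length(shared))
  x <- log2(treated_tpm[shared] + 1)
  y <- log2(control_tpm[shared] + 1)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in log-expression; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Assemble a specificity report for one comparison
#'
#' Runs the significance call, cross-referencing, orthogonal attribution,
#' spreading check and (when TPM columns are present) the global
#' correlation for a single treated-vs-control comparison, and returns the
#' counts and gene lists of a specificity-table row.
#'
#' @param comparison Label for the comparison (e.g.
#'   `"repressor indiv sgRNA vs. NTC"`).
#' @param de_table Differential-expression table of the comparison, with
#'   optional `tpm_treated`/`tpm_control` columns.
#' @param proximal Genes proximal to potential off-target sites
#'   (from [proximal_genes()]).
#' @param sirna_table DE table of the target-matched siRNA comparison, or
#'   `NULL` when no orthogonal control is available (all candidates then
#'   remain possible off-targets).
#' @param neighborhood Genes neighbouring the on-target site (from
#'   [neighborhood_genes()]); empty to skip the spreading check.
#' @param th A [thresholds()] object.
#' @param exclude_gene Gene(s) excluded from the global correlation,
#'   typically the intended target.
#' @return An object of class `specificity_report`: a list with the
#'   comparison label, counts (`n_significant`, `n_proximal_genes`), gene
#'   lists (`significant`, `candidates`, `pathway_attributed`,
#'   `possible_offtarget`, `neighborhood_flagged`) and `pearson_r`.
#' @seealso [as.data.frame.specificity_report()], [report_to_json()].
#' @export
build_report <- function(comparison, de_table, proximal,
                         sirna_table = NULL, neighborhood = character(),
                         th = thresholds(), exclude_gene = character()) {
  de_table <- .check_de_table(de_table)
  proximal <- unique(as.character(proximal))
  unmeasured <- setdiff(proximal, de_table$gene)
  if (length(unmeasured))
    message(length(unmeasured),
            " proximal gene(s) absent from the DE table; ",
            "operating on the shared gene universe")
  significant <- call_significant(de_table, th)
  candidates <- cross_reference(significant, proximal)
  sirna_significant <- if (is.null(sirna_table)) character()
                       else call_significant(.check_de_table(sirna_table), th)
  att <- attribute_orthogonal(candidates, sirna_significant)
  flagged <- spreading_check(significant, neighborhood)
  pearson_r <- NA_real_
  if (all(c("tpm_treated", "tpm_control") %in% names(de_table))) {
    tr <- setNames(de_table$tpm_treated, de_table$gene)
    ct <- setNames(de_table$tpm_control, de_table$gene)
    pearson_r <- specificity_correlation(tr, ct, exclude = exclude_gene)
  }
  structure(
    list(comparison = comparison,
         n_significant = length(significant),
         n_proximal_genes = length(proximal),
         significant = significant,
         candidates = candidates,
         pathway_attributed = att$pathway_attributed,
         possible_offtarget = att$possible_offtarget,
         neighborhood_flagged = flagged,
         pearson_r = pearson_r),
    class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Specificity report:", x$comparison, "\n")
  cat("  significant DE genes:              ", x$n_significant, "\n")
  cat("  genes proximal to off-target sites:", x$n_proximal_genes, "\n")
  fmt <- function(g) if (length(g)) paste(g, collapse = "; ") else "(none)"
  cat("  significant & proximal candidates: ", fmt(x$candidates), "\n")
  cat("  attributed to pathway (siRNA):     ", fmt(x$pathway_attributed), "\n")
  cat("  possible off-target:               ", fmt(x$possible_offtarget), "\n")
  cat("  significant within +/-1 Mb of target:", fmt(x$neighborhood_flagged),
      "\n")
  if (!is.na(x$pearson_r))
    cat(sprintf("  Pearson r (log2 TPM+1, target excluded): %.4f\n",
                x$pearson_r))
  invisible(x)
}

#' Flatten a specificity report to a one-row data frame
#'
#' @param x A `specificity_report`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return One data frame row with the specificity-table columns; gene
#'   lists are collapsed with `"; "`.
#' @export
as.data.frame.specificity_report <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  collapse <- function(g) paste(g, collapse = "; ")
  data.frame(comparison = x$comparison,
             n_significant = x$n_significant,
             n_proximal_genes = x$n_proximal_genes,
             candidates = collapse(x$candidates),
             pathway_attributed = collapse(x$pathway_attributed),
             possible_offtarget = collapse(x$possible_offtarget),
             neighborhood_flagged = collapse(x$neighborhood_flagged),
             pearson_r = x$pearson_r,
             stringsAsFactors = FALSE)
}

#' Serialize a specificity report (full gene lists) to JSON
#'
#' @param x A `specificity_report`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "specificity_report"))
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
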