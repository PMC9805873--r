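# Readout arithmetic: delta-delta-Cq relative expression from qPCR, and
# control-normalized fluorescence / percent-positive readouts.

#' Relative expression by the delta-delta-Cq method
#'
#' Computes `2^-ddCq` where
#' `ddCq = (cq_target_s - cq_hk_s) - (cq_target_ntc - cq_hk_ntc)`:
#' the target gene's quantification cycle in a sample, normalized to a
#' housekeeping gene (e.g. GAPDH or ACTB) and then to a non-targeting
#' control (NTC) sample. Values below 1 indicate repression relative to
#' the NTC. All arguments are vectorized.
#'
#' @param cq_target_s,cq_hk_s Cq of the target and housekeeping gene in
#'   the sample of interest.
#' @param cq_target_ntc,cq_hk_ntc Cq of the target and housekeeping gene
#'   in the non-targeting control sample.
#' @return Relative expression (positive real).
#' @examples
#' relative_expression(21, 20, 20, 20)  # one extra cycle -> 0.5
#' @export
relative_expression <- function(cq_target_s, cq_hk_s, cq_target_ntc,
                                cq_hk_ntc) {
  args <- list(cq_target_s, cq_hk_s, cq_target_ntc, cq_hk_ntc)
  if (!all(vapply(args, is.numeric, logical(1L))) ||
      any(!is.finite(unlist(args))))
    stop("all Cq values must be finite numbers")
  ddcq <- (cq_target_s - cq_hk_s) - (cq_target_ntc - cq_hk_ntc)
  2^(-ddcq)
}

#' Relative expression from a tidy Cq table
#'
#' Convenience wrapper around [relative_expression()] for a long-format Cq
#' table. Technical replicate wells are averaged on the Cq scale before
#' the delta-delta-Cq formula is applied.
#'
#' @param cq Data frame with columns `sample`, `gene`, `cq`; replicate
#'   rows per (sample, gene) are permitted.
#' @param target_gene Gene whose relative expression is wanted.
#' @param housekeeping_gene Normalization gene (e.g. `"GAPDH"` or
#'   `"ACTB"`).
#' @param ntc_sample Identifier of the non-targeting control sample.
#' @return Data frame with columns `sample` and `relative_expression`
#'   (the NTC row equals 1 by construction).
#' @export
ddcq_table <- function(cq, target_gene, housekeeping_gene, ntc_sample) {
  stopifnot(is.data.frame(cq),
            all(c("sample", "gene", "cq") %in% names(cq)))
  if (any(!is.finite(cq$cq))) stop("all Cq values must be finite")
  mean_cq <- function(s, g) {
    v <- cq$cq[cq$sample == s & cq$gene == g]
    if (length(v) == 0L)
      stop("no Cq record for sample '", s, "', gene '", g, "'")
    mean(v)
  }
  samples <- unique(cq$sample)
  if (!ntc_sample %in% samples) stop("NTC sample '", ntc_sample, "' not found")
  tgt_ntc <- mean_cq(ntc_sample, target_gene)
  hk_ntc <- mean_cq(ntc_sample, housekeeping_gene)
  rel <- vapply(samples, function(s)
    relative_expression(mean_cq(s, target_gene), mean_cq(s, housekeeping_gene),
                        tgt_ntc, hk_ntc), numeric(1L))
  data.frame(sample = samples, relative_expression = unname(rel),
             stringsAsFactors = FALSE)
}

#' Control-normalized readout
#'
#' Divides a readout (fluorescence, percent-positive, ...) by the matched
#' control value, as when reporter fluorescence is normalized to untreated
#' cells or protein signal to a control population. Vectorized.
#'
#' @param value Readout value(s), >= 0.
#' @param control_value Matched control readout(s), > 0.
#' @return `value / control_value`.
#' @export
normalized_readout <- function(value, control_value) {
  stopifnot(is.numeric(value), is.numeric(control_value))
  if (any(!is.finite(value)) || any(!is.finite(control_value)))
    stop("readout values must be finite")
  if (any(value < 0)) stop("value must be >= 0")
  if (any(control_value <= 0)) stop("control_value must be > 0")
  value / control_value
}

#' Percent knockdown relative to a control
#'
#' `1 - value / control_value`, the fraction of signal lost relative to
#' the control; 0.85 means 85\% repression.
#'
#' @inheritParams normalized_readout
#' @return Knockdown fraction (can be negative if the readout exceeds the
#'   control).
#' @export
percent_knockdown <- function(value, control_value) {
  1 - normalized_readout(value, control_value)
}
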