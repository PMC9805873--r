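#' Construct a guide spacer
#'
#' A spacer is the ~20-nt portion of an sgRNA that base-pairs with the
#' genomic protospacer. The intended target annotation (gene and TSS
#' coordinate) is optional; when present it is used to flag on-target sites
#' during scanning.
#'
#' @param guide_id Identifier for the guide.
#' @param sequence Spacer sequence, 18-25 unambiguous bases over A/C/G/T
#'   (degenerate IUPAC codes are rejected). Written 5' to 3'; the 3' end is
#'   the PAM-proximal (seed) end.
#' @param intended_gene Intended target gene identifier, or `NA`.
#' @param intended_chrom,intended_tss_pos Chromosome and 0-based coordinate
#'   of the intended target TSS, or `NA`.
#' @return An object of class `spacer`.
#' @examples
#' spacer("sg1", "ACGTACGTACGTACGTACGT", intended_gene = "GENE1")
#' @export
spacer <- function(guide_id, sequence, intended_gene = NA_character_,
                   intended_chrom = NA_character_,
                   intended_tss_pos = NA_integer_) {
  stopifnot(is.character(guide_id), length(guide_id) == 1L, nzchar(guide_id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("spacer sequence must contain only A/C/G/T (no IUPAC ambiguity codes)")
  if (nchar(sequence) < 18L || nchar(sequence) > 25L)
    stop("spacer length must be between 18 and 25 nt, got ", nchar(sequence))
  structure(
    list(guide_id = guide_id, sequence = sequence,
         intended_gene = as.character(intended_gene),
         intended_chrom = as.character(intended_chrom),
         intended_tss_pos = if (is.na(intended_tss_pos)) NA_integer_
                            else as.integer(intended_tss_pos)),
    class = "spacer")
}

#' @export
print.spacer <- function(x, ...) {
  cat("<spacer>", x$guide_id, x$sequence,
      if (!is.na(x$intended_gene)) paste0("-> ", x$intended_gene) else "",
      "\n")
  invisible(x)
}

#' Mismatch ("flaw") budget for off-target scanning
#'
#' Caps on the number of spacer/protospacer mismatches tolerated in the
#' PAM-proximal seed region, the non-seed remainder, and overall. The total
#' cap is independent of the two regional caps, so e.g. a budget of
#' (2, 2, 3) admits at most three mismatches even though the regional caps
#' sum to four.
#'
#' @param max_seed_flaws Maximum mismatches in the seed region (default 2).
#' @param max_nonseed_flaws Maximum mismatches outside the seed (default 2).
#' @param max_total_flaws Maximum mismatches overall (default 4).
#' @param seed_length Number of PAM-proximal bases treated as the seed
#'   (default 12, the conventional SpCas9 seed).
#' @return An object of class `flaw_budget`.
#' @examples
#' flaw_budget()            # the default 2/2/4 budget, 12-nt seed
#' flaw_budget(0, 0, 0)     # exact matches only
#' @export
flaw_budget <- function(max_seed_flaws = 2L, max_nonseed_flaws = 2L,
                        max_total_flaws = 4L, seed_length = 12L) {
  vals <- c(max_seed_flaws, max_nonseed_flaws, max_total_flaws, seed_length)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("flaw budget fields must be non-negative integers")
  structure(
    list(max_seed_flaws = as.integer(max_seed_flaws),
         max_nonseed_flaws = as.integer(max_nonseed_flaws),
         max_total_flaws = as.integer(max_total_flaws),
         seed_length = as.integer(seed_length)),
    class = "flaw_budget")
}

#' @export
print.flaw_budget <- function(x, ...) {
  cat(sprintf("<flaw_budget> seed<=%d nonseed<=%d total<=%d (seed region %d nt)\n",
              x$max_seed_flaws, x$max_nonseed_flaws, x$max_total_flaws,
              x$seed_length))
  invisible(x)
}

#' Significance thresholds for differential-expression calls
#'
#' A gene is called significantly differentially expressed when its absolute
#' log2 fold change strictly exceeds `min_abs_log2fc` and its (adjusted)
#' p-value is strictly below `alpha`.
#'
#' @param min_abs_log2fc Minimum absolute log2 fold change, strict
#'   (default 1.5).
#' @param alpha Significance level, strict (default 0.05).
#' @param use_adjusted Use the adjusted p-value column when available
#'   (default `TRUE`); set `FALSE` to threshold the raw p-value instead.
#' @return An object of class `de_thresholds`.
#' @export
thresholds <- function(min_abs_log2fc = 1.5, alpha = 0.05,
                       use_adjusted = TRUE) {
  stopifnot(is.numeric(min_abs_log2fc), min_abs_log2fc >= 0,
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.logical(use_adjusted), length(use_adjusted) == 1L)
  structure(list(min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                 use_adjusted = use_adjusted),
            class = "de_thresholds")
}

# ---- internal genome helpers -------------------------------------------

# Accept a Biostrings::DNAStringSet or a named character vector of
# chromosome sequences; return a named uppercase character vector.
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (length(out) == 0L) return(out)
  if (is.null(names(out)) || anyDuplicated(names(out)) || any(!nzchar(names(out))))
    stop("genome chromosomes must have unique non-empty names")
  if (any(!nzchar(out))) stop("genome sequences must be non-empty")
  if (any(grepl("[^ACGTN]", out)))
    stop("genome sequences must be over the A/C/G/T/N alphabet")
  out
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.chrom_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

.revcomp_chars <- function(chars) unname(rev(.COMP[chars]))

# Per-position allowed-base sets for an IUPAC PAM pattern. A genomic 'N' is
# never accepted at a PAM position: an unresolved base cannot be confirmed
# to satisfy the motif.
.pam_sets <- function(pam) {
  pam <- toupper(pam)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pam))
    stop("PAM pattern must be a valid IUPAC string, got '", pam, "'")
  lapply(strsplit(pam, "", fixed = TRUE)[[1L]], function(code)
    strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "", fixed = TRUE)[[1L]])
}
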