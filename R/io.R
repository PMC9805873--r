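# Readers and writers for the plain-text interchange formats: FASTA
# genomes, guide/TSS/DE TSV tables, site TSV and BED6.

#' Read a genome from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A `DNAStringSet`; record names are truncated at the first
#'   whitespace.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a guide table
#'
#' Expects a TSV with header
#' `guide_id  sequence  intended_gene  intended_chrom  intended_tss_pos`
#' (the three intended-target columns may be absent or empty).
#'
#' @param path Path to the TSV file.
#' @return A list of [spacer()] objects.
#' @export
read_spacers <- function(path) {
  .as_spacers(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a TSS table from TSV or BED
#'
#' A `.bed` file is read as BED6 with the name field as the gene and the
#' 0-based start as the TSS position; anything else is read as a TSV with
#' columns `gene`, `chrom`, `pos` (0-based) and optionally `strand`.
#'
#' @param path Path to the file.
#' @return A TSS data frame (`gene`, `chrom`, `pos`, `strand`).
#' @export
read_tss <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(bed) < 4L) stop("BED TSS input needs at least 4 columns")
    tss <- data.frame(gene = bed[[4L]], chrom = bed[[1L]],
                      pos = as.integer(bed[[2L]]),
                      strand = if (ncol(bed) >= 6L) bed[[6L]] else "+",
                      stringsAsFactors = FALSE)
  } else {
    tss <- read.delim(path, stringsAsFactors = FALSE)
    if (!"strand" %in% names(tss)) tss$strand <- "+"
  }
  .check_tss(tss[, c("gene", "chrom", "pos", "strand")])
}

#' Read a differential-expression table
#'
#' Expects a TSV with header `gene  log2fc  pvalue  padj` and optional
#' `tpm_treated`, `tpm_control` columns.
#'
#' @param path Path to the TSV file.
#' @return A validated DE data frame.
#' @export
read_de_table <- function(path) {
  .check_de_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a site table as TSV
#'
#' @param sites Site data frame from [enumerate_sites()] or
#'   [pool_sites()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a site table as BED6
#'
#' Coordinates stay 0-based half-open as BED requires; the name field is
#' `guide_id|seed_flaws|nonseed_flaws` and the score is the total flaw
#' count.
#'
#' @inheritParams write_sites
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$end,
                    name = paste(sites$guide_id, sites$seed_flaws,
                                 sites$nonseed_flaws, sep = "|"),
                    score = sites$total_flaws, strand = sites$strand,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
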