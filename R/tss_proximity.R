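# TSS-proximity annotation: which genes lie near candidate off-target
# binding sites, and which genes neighbour the on-target locus.

.check_tss <- function(tss) {
  stopifnot(is.data.frame(tss),
            all(c("gene", "chrom", "pos") %in% names(tss)))
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0")
  key <- paste(tss$gene, tss$chrom, tss$pos,
               if ("strand" %in% names(tss)) tss$strand else "*", sep = "\r")
  if (anyDuplicated(key)) stop("duplicate TSS records")
  tss
}

#' Annotate off-target sites by TSS proximity
#'
#' Finds every (gene, site) pair in which a transcription start site of the
#' gene lies within `window` bp of the site. Distance is the minimum
#' separation between the TSS coordinate and any base of the site interval
#' (0 when the TSS falls inside the interval); the boundary is inclusive,
#' so a TSS exactly `window` bp away qualifies. A gene with several TSSs is
#' proximal if any of them qualifies; the hit reports the closest one.
#' TSS strand plays no role in the distance.
#'
#' Sites flagged `is_on_target` are excluded by default so that the
#' distinct genes of the result are the "genes proximal to potential
#' off-target binding sites" of a specificity report.
#'
#' @param sites Site data frame from [enumerate_sites()] or
#'   [pool_sites()].
#' @param tss TSS table: data frame with columns `gene`, `chrom`, `pos`
#'   (0-based) and optionally `strand`.
#' @param window Proximity window in bp (default 500), inclusive.
#' @param exclude_on_target Drop sites flagged `is_on_target` before
#'   annotation (default `TRUE`).
#' @return A data frame of proximal hits with columns `gene`, `guide_id`,
#'   `chrom`, `site_start`, `site_end`, `strand`, `total_flaws`,
#'   `distance`.
#' @seealso [proximal_genes()] for the distinct-gene set.
#' @export
annotate_proximal <- function(sites, tss, window = 500L,
                              exclude_on_target = TRUE) {
  if (window < 0) stop("window must be >= 0")
  tss <- .check_tss(tss)
  if (exclude_on_target && "is_on_target" %in% names(sites))
    sites <- sites[!sites$is_on_target, , drop = FALSE]
  empty <- data.frame(gene = character(), guide_id = character(),
                      chrom = character(), site_start = integer(),
                      site_end = integer(), strand = character(),
                      total_flaws = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L || nrow(tss) == 0L) return(empty)
  missing_chrom <- setdiff(unique(sites$chrom), unique(tss$chrom))
  if (length(missing_chrom))
    message("no TSS records on chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  # Expanding each site by `window` on both sides makes interval overlap
  # with the TSS point exactly equivalent to distance <= window.
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1L - window,
                                  sites$end + window))
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(tss$pos + 1L, width = 1L))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(site_gr, tss_gr, ignore.strand = TRUE))
  if (length(ov) == 0L) return(empty)
  si <- S4Vectors::queryHits(ov)
  ti <- S4Vectors::subjectHits(ov)
  hits <- data.frame(
    gene = tss$gene[ti], guide_id = sites$guide_id[si],
    chrom = sites$chrom[si], site_start = sites$start[si],
    site_end = sites$end[si], strand = sites$strand[si],
    total_flaws = sites$total_flaws[si],
    distance = .point_interval_distance(tss$pos[ti], sites$start[si],
                                        sites$end[si]),
    stringsAsFactors = FALSE)
  # one hit per (gene, site): keep the closest TSS of each gene
  hits <- hits[order(hits$distance), , drop = FALSE]
  key <- paste(hits$gene, hits$guide_id, hits$chrom, hits$site_start,
               hits$strand, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$site_start, hits$strand, hits$gene), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Distinct genes proximal to off-target sites
#'
#' @param hits Hit table from [annotate_proximal()].
#' @return Sorted character vector of distinct gene identifiers.
#' @export
proximal_genes <- function(hits) sort(unique(hits$gene))

#' Genes neighbouring a target site
#'
#' Lists the genes with any TSS within `half_window` bp (inclusive) of the
#' midpoint of a site — by default the +/- 1 Mb neighbourhood over which
#' repressive spreading from the on-target locus is assessed. The intended
#' target gene itself is excluded when given.
#'
#' @param target_site A single-row site data frame (or a list with
#'   `chrom`, `start`, `end`).
#' @param tss TSS table as in [annotate_proximal()].
#' @param half_window Half-width of the neighbourhood in bp
#'   (default 1e6).
#' @param exclude_gene Gene identifier(s) to drop, typically the intended
#'   target (default none).
#' @return Sorted character vector of gene identifiers.
#' @export
neighborhood_genes <- function(target_site, tss, half_window = 1e6,
                               exclude_gene = character()) {
  tss <- .check_tss(tss)
  if (is.data.frame(target_site)) {
    stopifnot(nrow(target_site) == 1L)
    target_site <- as.list(target_site)
  }
  mid <- (target_site$start + target_site$end) %/% 2L
  sel <- tss$chrom == target_site$chrom & abs(tss$pos - mid) <= half_window
  genes <- setdiff(unique(tss$gene[sel]),
                   exclude_gene[!is.na(exclude_gene)])
  sort(genes)
}
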