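# Off-target site enumeration under a seed/non-seed mismatch budget.
#
# Two implementations of the same contract are provided on purpose:
# enumerate_sites() is the vectorized scanner used by the pipeline, and
# brute_force_sites() is a deliberately literal position-by-position
# re-derivation used as an independent oracle in tests and verification.

.empty_sites <- function() {
  data.frame(guide_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             seed_flaws = integer(), nonseed_flaws = integer(),
             total_flaws = integer(), pam = character(),
             is_on_target = logical(), stringsAsFactors = FALSE)
}

.sort_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  sites <- sites[order(sites$chrom, sites$start, sites$strand, sites$guide_id), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Distance from a point coordinate to a 0-based half-open interval: 0 when
# the point falls on one of the interval's bases, otherwise the number of
# bases to the nearest end base.
.point_interval_distance <- function(pos, start, end) {
  pmax(0L, pmax(start - pos, pos - (end - 1L)))
}

# Scan one strand of one chromosome, given its character vector in the
# orientation being scanned. Returns 0-based starts in that orientation.
.scan_strand <- function(chars, sp_chars, budget, pam_sets) {
  L <- length(chars)
  m <- length(sp_chars)
  k <- length(pam_sets)
  n_start <- L - m - k + 1L
  if (n_start < 1L)
    return(list(start = integer(), seed = integer(), nonseed = integer(),
                pam = character()))
  idx <- seq_len(n_start)          # 1-based window starts
  ok <- rep(TRUE, n_start)
  for (j in seq_len(k)) {
    ok <- ok & (chars[idx + m + j - 1L] %in% pam_sets[[j]])
  }
  seed_from <- m - budget$seed_length + 1L   # spacer positions >= this are seed
  seed_mm <- integer(n_start)
  non_mm <- integer(n_start)
  for (j in seq_len(m)) {
    g <- chars[idx + j - 1L]
    mm <- (g != sp_chars[j]) | (g == "N")
    if (j >= seed_from) seed_mm <- seed_mm + mm else non_mm <- non_mm + mm
  }
  keep <- ok & seed_mm <= budget$max_seed_flaws &
    non_mm <= budget$max_nonseed_flaws &
    (seed_mm + non_mm) <= budget$max_total_flaws
  kept <- idx[keep]
  pam_seq <- vapply(kept, function(i)
    paste(chars[(i + m):(i + m + k - 1L)], collapse = ""), character(1L))
  list(start = kept - 1L, seed = seed_mm[keep], nonseed = non_mm[keep],
       pam = pam_seq)
}

.flag_on_target <- function(sites, sp, window = 500L) {
  if (nrow(sites) == 0L || is.na(sp$intended_chrom) ||
      is.na(sp$intended_tss_pos)) {
    sites$is_on_target <- logical(nrow(sites))
    return(sites)
  }
  d <- .point_interval_distance(sp$intended_tss_pos, sites$start, sites$end)
  sites$is_on_target <- sites$chrom == sp$intended_chrom & d <= window
  sites
}

#' Enumerate candidate guide binding sites under a flaw budget
#'
#' Scans every position of every chromosome, on both strands, for windows
#' where (a) the 3-mer (or PAM-pattern-length k-mer) immediately 3' of the
#' protospacer on the scanned strand matches the PAM pattern exactly, and
#' (b) the Hamming mismatches between the spacer and the genomic
#' protospacer, split into the PAM-proximal seed region and the non-seed
#' remainder, satisfy all three caps of the budget. A genomic `N` always
#' counts as a mismatch in the protospacer and never satisfies a PAM
#' position.
#'
#' Coordinates are 0-based half-open intervals of the protospacer on the
#' forward strand of the genome; the PAM is excluded from the interval.
#' Overlapping sites on opposite strands are distinct records. When the
#' spacer carries an intended TSS annotation, sites within 500 bp of it are
#' flagged `is_on_target`.
#'
#' @param genome A `DNAStringSet` or named character vector of chromosome
#'   sequences over A/C/G/T/N.
#' @param sp A [spacer()].
#' @param budget A [flaw_budget()].
#' @param pam IUPAC PAM pattern required immediately 3' of the protospacer
#'   (default `"NGG"`, SpCas9). The PAM itself tolerates no mismatches.
#' @param on_target_window Window (bp) around the intended TSS within which
#'   a site is flagged on-target (default 500).
#' @return A data frame with columns `guide_id`, `chrom`, `start`, `end`,
#'   `strand`, `seed_flaws`, `nonseed_flaws`, `total_flaws`, `pam`,
#'   `is_on_target`, sorted by (chrom, start, strand, guide_id).
#' @seealso [brute_force_sites()] for the literal reference implementation,
#'   [pool_sites()] to combine several guides.
#' @examples
#' g <- c(chr1 = "TTTTACGTACGTACGTACGTACGTTGGTTTT")
#' sp <- spacer("sg1", "ACGTACGTACGTACGTACGT")
#' enumerate_sites(g, sp, flaw_budget())
#' @export
enumerate_sites <- function(genome, sp, budget = flaw_budget(), pam = "NGG",
                            on_target_window = 500L) {
  stopifnot(inherits(sp, "spacer"), inherits(budget, "flaw_budget"))
  genome <- .as_genome(genome)
  m <- nchar(sp$sequence)
  if (budget$seed_length > m)
    stop("seed_length (", budget$seed_length, ") exceeds spacer length (", m, ")")
  pam_sets <- .pam_sets(pam)
  sp_chars <- .chrom_chars(sp$sequence)
  rows <- list()
  for (chrom in names(genome)) {
    chars <- .chrom_chars(genome[[chrom]])
    L <- length(chars)
    fw <- .scan_strand(chars, sp_chars, budget, pam_sets)
    if (length(fw$start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = sp$guide_id, chrom = chrom,
        start = fw$start, end = fw$start + m, strand = "+",
        seed_flaws = fw$seed, nonseed_flaws = fw$nonseed,
        total_flaws = fw$seed + fw$nonseed, pam = fw$pam,
        is_on_target = FALSE, stringsAsFactors = FALSE)
    }
    rv <- .scan_strand(.revcomp_chars(chars), sp_chars, budget, pam_sets)
    if (length(rv$start)) {
      # position j (0-based) on the reverse complement corresponds to the
      # forward-strand interval [L - j - m, L - j)
      start_fwd <- L - rv$start - m
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = sp$guide_id, chrom = chrom,
        start = start_fwd, end = start_fwd + m, strand = "-",
        seed_flaws = rv$seed, nonseed_flaws = rv$nonseed,
        total_flaws = rv$seed + rv$nonseed, pam = rv$pam,
        is_on_target = FALSE, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else .empty_sites()
  sites <- .flag_on_target(sites, sp, on_target_window)
  .sort_sites(sites)
}

#' Literal reference enumeration of guide binding sites
#'
#' Identical contract to [enumerate_sites()], implemented as the most
#' literal possible position-by-position comparison: every start position
#' on both strands is examined individually, the protospacer and PAM are
#' extracted (reverse-complemented for the minus strand in genome-forward
#' coordinates) and mismatches are counted per region. Intended as an
#' independent oracle for tests and `--verify-oracle` runs; it refuses
#' genomes larger than 1 Mb.
#'
#' @inheritParams enumerate_sites
#' @return Same shape as [enumerate_sites()].
#' @export
brute_force_sites <- function(genome, sp, budget = flaw_budget(),
                              pam = "NGG", on_target_window = 500L) {
  stopifnot(inherits(sp, "spacer"), inherits(budget, "flaw_budget"))
  genome <- .as_genome(genome)
  if (sum(nchar(genome)) > 1e6)
    stop("brute_force_sites is a verification tool; genome exceeds 1 Mb")
  m <- nchar(sp$sequence)
  if (budget$seed_length > m)
    stop("seed_length (", budget$seed_length, ") exceeds spacer length (", m, ")")
  pam_sets <- .pam_sets(pam)
  k <- length(pam_sets)
  sp_chars <- .chrom_chars(sp$sequence)
  seed_idx <- seq.int(m - budget$seed_length + 1L, length.out = budget$seed_length)
  nonseed_idx <- setdiff(seq_len(m), seed_idx)
  pam_ok <- function(p3) {
    for (j in seq_len(k)) if (!(p3[j] %in% pam_sets[[j]])) return(FALSE)
    TRUE
  }
  within_budget <- function(seed_f, non_f) {
    seed_f <= budget$max_seed_flaws && non_f <= budget$max_nonseed_flaws &&
      (seed_f + non_f) <= budget$max_total_flaws
  }
  rows <- list()
  add <- function(chrom, start, strand, seed_f, non_f, pam_seq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      guide_id = sp$guide_id, chrom = chrom, start = start, end = start + m,
      strand = strand, seed_flaws = seed_f, nonseed_flaws = non_f,
      total_flaws = seed_f + non_f, pam = pam_seq, is_on_target = FALSE,
      stringsAsFactors = FALSE)
  }
  for (chrom in names(genome)) {
    chars <- .chrom_chars(genome[[chrom]])
    L <- length(chars)
    if (L < m + k) next
    # plus strand: protospacer [s, s+m), PAM [s+m, s+m+k)
    for (s in 0:(L - m - k)) {
      proto <- chars[(s + 1L):(s + m)]
      p3 <- chars[(s + m + 1L):(s + m + k)]
      if (!pam_ok(p3)) next
      mm <- (proto != sp_chars) | (proto == "N")
      seed_f <- sum(mm[seed_idx])
      non_f <- sum(mm[nonseed_idx])
      if (within_budget(seed_f, non_f))
        add(chrom, s, "+", seed_f, non_f, paste(p3, collapse = ""))
    }
    # minus strand: protospacer occupies forward interval [s, s+m); on the
    # minus strand it reads as the reverse complement, and its PAM sits at
    # forward interval [s-k, s)
    for (s in k:(L - m)) {
      proto <- unname(rev(.COMP[chars[(s + 1L):(s + m)]]))
      p3 <- unname(rev(.COMP[chars[(s - k + 1L):s]]))
      if (!pam_ok(p3)) next
      mm <- (proto != sp_chars) | (proto == "N")
      seed_f <- sum(mm[seed_idx])
      non_f <- sum(mm[nonseed_idx])
      if (within_budget(seed_f, non_f))
        add(chrom, s, "-", seed_f, non_f, paste(p3, collapse = ""))
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else .empty_sites()
  sites <- .flag_on_target(sites, sp, on_target_window)
  .sort_sites(sites)
}

#' Pool sites across the guides of one target
#'
#' Combines the site lists of several guides targeting the same gene, as
#' used for pooled-guide comparisons. Records are de-duplicated on
#' (guide_id, chrom, start, strand); the same genomic locus hit by more
#' than one guide keeps one record per guide and is flagged `shared_locus`.
#'
#' @param site_lists A list of site data frames from [enumerate_sites()].
#' @return One combined site data frame with an extra `shared_locus`
#'   column, sorted as [enumerate_sites()] sorts.
#' @export
pool_sites <- function(site_lists) {
  stopifnot(is.list(site_lists), length(site_lists) >= 1L)
  pooled <- do.call(rbind, site_lists)
  if (nrow(pooled) == 0L) {
    pooled$shared_locus <- logical(0)
    return(pooled)
  }
  key <- paste(pooled$guide_id, pooled$chrom, pooled$start, pooled$strand,
               sep = "\r")
  pooled <- pooled[!duplicated(key), , drop = FALSE]
  locus <- paste(pooled$chrom, pooled$start, pooled$strand, sep = "\r")
  n_guides <- vapply(split(pooled$guide_id, locus),
                     function(g) length(unique(g)), integer(1L))
  pooled$shared_locus <- unname(n_guides[locus] > 1L)
  .sort_sites(pooled)
}
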