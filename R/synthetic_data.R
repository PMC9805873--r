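# Synthetic fixtures with planted ground truth: random genomes, planted
# protospacer sites with chosen seed/non-seed mismatch counts, TSS tables
# at chosen distances, and differential-expression tables with planted
# on-target, pathway-shared and off-target-proximal signals.

.BASES <- c("A", "C", "G", "T")

#' Generate a reproducible random genome
#'
#' Bases are drawn i.i.d. with the requested GC fraction (default 0.41,
#' roughly the human genome average). The same seed always yields the
#' same sequence.
#'
#' @param lengths Chromosome length(s) in bp; a named vector gives the
#'   chromosome names (a single unnamed length becomes `chr1`).
#' @param gc_fraction Probability of G or C at each position, in
#'   \[0, 1\].
#' @param rng_seed Integer seed.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' make_genome(c(chr1 = 1000), gc_fraction = 0.5, rng_seed = 7)
#' @export
make_genome <- function(lengths, gc_fraction = 0.41, rng_seed = 1L) {
  stopifnot(is.numeric(lengths), all(lengths >= 1))
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  if (is.null(names(lengths))) {
    if (length(lengths) != 1L)
      stop("multiple chromosome lengths must be named")
    names(lengths) <- "chr1"
  }
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
            (1 - gc_fraction) / 2)
  seqs <- withr::with_seed(rng_seed, vapply(lengths, function(L)
    paste(sample(.BASES, L, replace = TRUE, prob = prob), collapse = ""),
    character(1L)))
  Biostrings::DNAStringSet(seqs)
}

.check_plant_specs <- function(specs, genome, seed_length, k) {
  needed <- c("spacer", "chrom", "position", "strand", "seed_flaws",
              "nonseed_flaws", "pam")
  stopifnot(is.data.frame(specs), all(needed %in% names(specs)))
  lens <- nchar(genome)
  foot_start <- integer(nrow(specs))
  foot_end <- integer(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    m <- nchar(specs$spacer[i])
    if (!grepl("^[ACGT]+$", specs$spacer[i]))
      stop("planted spacer must be over A/C/G/T")
    if (!grepl("^[ACGT]+$", specs$pam[i]) || nchar(specs$pam[i]) != k)
      stop("planted PAM must be a concrete ", k, "-mer over A/C/G/T")
    if (specs$seed_flaws[i] > seed_length ||
        specs$nonseed_flaws[i] > m - seed_length)
      stop("planted flaw counts not achievable for spec ", i,
           " (seed region ", seed_length, " nt of a ", m, "-mer)")
    if (!specs$chrom[i] %in% names(genome))
      stop("unknown chromosome '", specs$chrom[i], "'")
    L <- lens[[specs$chrom[i]]]
    if (specs$strand[i] == "+") {
      foot_start[i] <- specs$position[i]
      foot_end[i] <- specs$position[i] + m + k
    } else {
      foot_start[i] <- specs$position[i] - k
      foot_end[i] <- specs$position[i] + m
    }
    if (foot_start[i] < 0 || foot_end[i] > L)
      stop("planted site ", i, " falls outside chromosome bounds")
  }
  ord <- order(specs$chrom, foot_start)
  same <- diff(as.integer(factor(specs$chrom[ord]))) == 0
  if (any(same & head(foot_end[ord], -1) > tail(foot_start[ord], -1)))
    stop("planted site footprints overlap")
  invisible(specs)
}

# Build the genomic protospacer for one spec: start from the spacer and
# mutate the requested number of positions inside the seed and non-seed
# regions (substitutions only, never to the original base).
.mutate_protospacer <- function(spacer_seq, seed_length, seed_flaws,
                                nonseed_flaws) {
  chars <- .chrom_chars(spacer_seq)
  m <- length(chars)
  seed_idx <- seq.int(m - seed_length + 1L, length.out = seed_length)
  nonseed_idx <- setdiff(seq_len(m), seed_idx)
  mut <- c(if (seed_flaws > 0) sample(seed_idx, seed_flaws),
           if (nonseed_flaws > 0) sample(nonseed_idx, nonseed_flaws))
  for (i in mut) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Plant protospacer sites with chosen flaw partitions into a genome
#'
#' Edits a genome so that each requested locus carries a protospacer with
#' exactly the requested number of seed and non-seed mismatches against
#' its spacer, followed (on the site's strand) by the given concrete PAM.
#' After editing, the whole genome is re-scanned with
#' [brute_force_sites()] and the found in-budget sites are required to
#' equal the planted in-budget truth exactly; if editing created an
#' accidental extra site (or destroyed a planted one), the mutation
#' positions are redrawn with the next seed, up to `max_attempts` times.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param specs Data frame with columns `spacer`, `chrom`, `position`
#'   (0-based start of the protospacer interval), `strand`, `seed_flaws`,
#'   `nonseed_flaws`, `pam` (concrete k-mer). Footprints (protospacer +
#'   PAM) must not overlap.
#' @param budget The [flaw_budget()] against which the planted truth is
#'   verified; also defines the seed length used for planting.
#' @param pam_pattern IUPAC pattern the verification scan requires
#'   (default `"NGG"`); planted PAMs not matching it yield sites invisible
#'   to the scan, which is permitted (useful for PAM-less decoys).
#' @param rng_seed Integer seed for the mismatch placement.
#' @param max_attempts Re-plant attempts before giving up (default 10).
#' @return A list with `genome` (the edited `DNAStringSet`), `truth`
#'   (data frame: `chrom`, `start`, `end`, `strand`, `seed_flaws`,
#'   `nonseed_flaws`, `total_flaws`, `pam`, `protospacer`, `in_budget`)
#'   and `attempts`.
#' @export
plant_sites <- function(genome, specs, budget = flaw_budget(),
                        pam_pattern = "NGG", rng_seed = 1L,
                        max_attempts = 10L) {
  genome <- .as_genome(genome)
  k <- nchar(specs$pam[1])
  seed_length <- budget$seed_length
  .check_plant_specs(specs, genome, seed_length, k)
  pam_sets <- .pam_sets(pam_pattern)
  pam_visible <- vapply(seq_len(nrow(specs)), function(i) {
    p <- .chrom_chars(specs$pam[i])
    all(vapply(seq_len(k), function(j) p[j] %in% pam_sets[[j]], logical(1L)))
  }, logical(1L))
  in_budget <- specs$seed_flaws <= budget$max_seed_flaws &
    specs$nonseed_flaws <= budget$max_nonseed_flaws &
    (specs$seed_flaws + specs$nonseed_flaws) <= budget$max_total_flaws &
    pam_visible

  for (attempt in seq_len(max_attempts)) {
    protos <- withr::with_seed(rng_seed + attempt - 1L,
      vapply(seq_len(nrow(specs)), function(i)
        .mutate_protospacer(specs$spacer[i], seed_length,
                            specs$seed_flaws[i], specs$nonseed_flaws[i]),
        character(1L)))
    edited <- genome
    for (i in seq_len(nrow(specs))) {
      m <- nchar(specs$spacer[i])
      chars <- .chrom_chars(edited[[specs$chrom[i]]])
      if (specs$strand[i] == "+") {
        piece <- .chrom_chars(paste0(protos[i], specs$pam[i]))
        at <- specs$position[i] + seq_along(piece)        # 1-based
      } else {
        piece <- .revcomp_chars(.chrom_chars(paste0(protos[i], specs$pam[i])))
        at <- specs$position[i] - k + seq_along(piece)
      }
      chars[at] <- piece
      edited[[specs$chrom[i]]] <- paste(chars, collapse = "")
    }
    # verify: for every spacer, the in-budget sites found genome-wide must
    # be exactly the planted in-budget truth for that spacer
    ok <- TRUE
    for (sq in unique(specs$spacer)) {
      found <- brute_force_sites(edited, spacer("plantcheck", sq), budget,
                                 pam = pam_pattern)
      sel <- specs$spacer == sq & in_budget
      want <- sort(paste(specs$chrom[sel], specs$position[sel],
                         specs$strand[sel], specs$seed_flaws[sel],
                         specs$nonseed_flaws[sel], sep = ":"))
      got <- sort(paste(found$chrom, found$start, found$strand,
                        found$seed_flaws, found$nonseed_flaws, sep = ":"))
      if (!identical(want, got)) { ok <- FALSE; break }
    }
    if (ok) {
      m_all <- nchar(specs$spacer)
      truth <- data.frame(
        chrom = specs$chrom, start = as.integer(specs$position),
        end = as.integer(specs$position + m_all), strand = specs$strand,
        seed_flaws = as.integer(specs$seed_flaws),
        nonseed_flaws = as.integer(specs$nonseed_flaws),
        total_flaws = as.integer(specs$seed_flaws + specs$nonseed_flaws),
        pam = specs$pam, protospacer = protos, in_budget = in_budget,
        stringsAsFactors = FALSE)
      return(list(genome = Biostrings::DNAStringSet(edited), truth = truth,
                  attempts = attempt))
    }
  }
  stop("failed to plant sites without accidental extra in-budget matches ",
       "after ", max_attempts, " attempts")
}

#' Build a TSS table from explicit placements
#'
#' @param placements Data frame with columns `gene`, `chrom`, `pos`
#'   (0-based TSS coordinate) and optionally `strand` (default `"+"`).
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   to bound-check the placements.
#' @return A validated TSS data frame (`gene`, `chrom`, `pos`, `strand`).
#' @export
make_tss_table <- function(placements, chrom_lengths = NULL) {
  stopifnot(is.data.frame(placements),
            all(c("gene", "chrom", "pos") %in% names(placements)))
  if (!"strand" %in% names(placements)) placements$strand <- "+"
  placements$pos <- as.integer(placements$pos)
  if (!is.null(chrom_lengths)) {
    bad <- placements$pos < 0 |
      placements$pos >= chrom_lengths[placements$chrom]
    if (any(is.na(bad) | bad))
      stop("TSS placement outside chromosome bounds: ",
           paste(placements$gene[is.na(bad) | bad], collapse = ", "))
  }
  .check_tss(placements[, c("gene", "chrom", "pos", "strand")])
}

#' Specification of planted differential-expression structure
#'
#' Describes the signal planted into a matched pair of CRISPRi and siRNA
#' differential-expression tables: a strongly repressed target gene, a set
#' of pathway genes perturbed in both tables (downstream of target
#' knockdown), a set of off-target genes perturbed only in the CRISPRi
#' table, and a null background.
#'
#' @param genes Character vector of the gene universe.
#' @param target_gene The intended target, repressed in both tables;
#'   `NULL` for a fully null pair of tables (used to study false-positive
#'   calibration).
#' @param pathway_genes Genes perturbed in both tables.
#' @param offtarget_genes Genes perturbed only in the CRISPRi table.
#' @param target_log2fc Planted target log2 fold change (default -3.5, a
#'   strong knockdown).
#' @param planted_abs_log2fc Absolute log2 fold change of planted
#'   pathway/off-target effects (default 2.2, comfortably past the 1.5
#'   significance threshold); effects are planted as repression.
#' @param null_sd Standard deviation of the null genes' log2 fold change
#'   (default 0.4).
#' @param rng_seed Integer seed.
#' @return An object of class `de_plant_spec`.
#' @export
de_plant_spec <- function(genes, target_gene = NULL,
                          pathway_genes = character(),
                          offtarget_genes = character(),
                          target_log2fc = -3.5, planted_abs_log2fc = 2.2,
                          null_sd = 0.4, rng_seed = 1L) {
  stopifnot(is.character(genes), length(genes) >= 4L,
            !anyDuplicated(genes))
  planted <- c(target_gene, pathway_genes, offtarget_genes)
  if (anyDuplicated(planted))
    stop("target, pathway and off-target gene sets must be disjoint")
  if (!all(planted %in% genes))
    stop("all planted genes must be in the gene universe")
  stopifnot(abs(target_log2fc) > 1.5, planted_abs_log2fc > 1.5,
            null_sd >= 0)
  if (is.null(target_gene) &&
      (length(pathway_genes) || length(offtarget_genes)))
    stop("pathway/off-target genes require a target gene")
  structure(list(genes = genes, target_gene = target_gene,
                 pathway_genes = pathway_genes,
                 offtarget_genes = offtarget_genes,
                 target_log2fc = target_log2fc,
                 planted_abs_log2fc = planted_abs_log2fc,
                 null_sd = null_sd, rng_seed = as.integer(rng_seed)),
            class = "de_plant_spec")
}

.one_de_table <- function(spec, planted_genes, planted_lfc) {
  planted_genes <- as.character(planted_genes)
  n <- length(spec$genes)
  log2fc <- rnorm(n, 0, spec$null_sd)
  pvalue <- runif(n)
  names(log2fc) <- names(pvalue) <- spec$genes
  log2fc[planted_genes] <- planted_lfc
  pvalue[planted_genes] <- runif(length(planted_genes), 1e-12, 1e-8)
  tpm_control <- 2^runif(n, 2, 10)
  tpm_treated <- tpm_control * 2^log2fc
  data.frame(gene = spec$genes, log2fc = unname(log2fc),
             pvalue = unname(pvalue),
             padj = p.adjust(unname(pvalue), method = "BH"),
             tpm_treated = tpm_treated, tpm_control = tpm_control,
             stringsAsFactors = FALSE)
}

#' Generate matched CRISPRi and siRNA differential-expression tables
#'
#' Null genes receive log2 fold changes from `Normal(0, null_sd)` and
#' uniform p-values (so the raw-p false-positive rate is calibrated at
#' alpha); planted genes receive effects past the significance thresholds
#' with very small p-values. Adjusted p-values are Benjamini-Hochberg.
#' The target and pathway genes are planted in both tables, off-target
#' genes only in the CRISPRi table. Identical seeds give identical
#' tables.
#'
#' @param spec A [de_plant_spec()].
#' @return A list with data frames `crispri` and `sirna` (columns `gene`,
#'   `log2fc`, `pvalue`, `padj`, `tpm_treated`, `tpm_control`).
#' @export
make_de_tables <- function(spec) {
  stopifnot(inherits(spec, "de_plant_spec"))
  withr::with_seed(spec$rng_seed, {
    eff <- function(genes) -spec$planted_abs_log2fc *
      (1 + runif(length(genes), -0.1, 0.1))
    target_lfc <- if (is.null(spec$target_gene)) numeric(0)
                  else spec$target_log2fc
    crispri_genes <- c(spec$target_gene, spec$pathway_genes,
                       spec$offtarget_genes)
    crispri_lfc <- c(target_lfc,
                     eff(spec$pathway_genes), eff(spec$offtarget_genes))
    crispri <- .one_de_table(spec, crispri_genes, crispri_lfc)
    sirna_genes <- c(spec$target_gene, spec$pathway_genes)
    sirna_lfc <- c(target_lfc, eff(spec$pathway_genes))
    sirna <- .one_de_table(spec, sirna_genes, sirna_lfc)
    list(crispri = crispri, sirna = sirna)
  })
}

#' Standard planted-site fixture for scanner verification
#'
#' A 20 kb single-chromosome genome carrying one planted site for every
#' flaw partition from (0,0) to (2,2) — ten in-budget sites under the
#' default 2/2/4 budget, including one duplicated partition and both
#' strands — plus four over-budget decoys: (3,0), (0,3), (2,3) and (3,2).
#'
#' @param rng_seed Integer seed.
#' @param budget [flaw_budget()] used for planting verification.
#' @return As [plant_sites()], plus the `spacer` object used.
#' @export
make_site_fixture <- function(rng_seed = 1L, budget = flaw_budget()) {
  genome <- make_genome(c(chr1 = 20000L), rng_seed = rng_seed)
  spacer_seq <- withr::with_seed(rng_seed + 1L,
    paste(sample(.BASES, 20L, replace = TRUE), collapse = ""))
  partitions <- rbind(expand.grid(seed = 0:2, nonseed = 0:2),
                      data.frame(seed = c(1L, 3L, 0L, 2L, 3L),
                                 nonseed = c(1L, 0L, 3L, 3L, 2L)))
  n <- nrow(partitions)
  specs <- data.frame(
    spacer = spacer_seq, chrom = "chr1",
    position = 500L + 1200L * (seq_len(n) - 1L),
    strand = rep(c("+", "-"), length.out = n),
    seed_flaws = partitions$seed, nonseed_flaws = partitions$nonseed,
    pam = rep(c("AGG", "TGG", "CGG", "GGG"), length.out = n),
    stringsAsFactors = FALSE)
  out <- plant_sites(genome, specs, budget = budget,
                     rng_seed = rng_seed + 2L)
  out$spacer <- spacer("sg_fixture", spacer_seq)
  out
}

#' Simulate a complete synthetic specificity study
#'
#' Builds a two-chromosome genome with one guide, plants its on-target
#' site near the target gene's TSS on `chr1` and a set of in-budget
#' off-target sites and over-budget decoys on `chr2`, places TSSs so that
#' two pathway genes and one off-target gene fall within 500 bp of
#' distinct planted off-target sites, spreads the null genes' TSSs over
#' both chromosomes away from the planted sites, and generates matched
#' CRISPRi and siRNA differential-expression tables with the
#' corresponding planted signals. The returned `truth` element records
#' everything planted, so a pipeline run can be checked exactly.
#'
#' @param rng_seed Integer seed driving every random choice.
#' @param n_genes Size of the gene universe including planted genes
#'   (default 1200, i.e. 1196 nulls).
#' @param chrom_length Length of each of the two chromosomes (default
#'   20000 bp).
#' @param budget [flaw_budget()] used for planting verification.
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `tss.tsv`, `guides.tsv`, `de.tsv`, `sirna_de.tsv` and `truth.json`.
#' @return A list with `genome`, `guides` (data frame), `spacers` (list
#'   of [spacer()]), `tss`, `de`, `sirna_de`, `sites_truth` and `truth`
#'   (planted gene sets and expected report contents).
#' @export
simulate_study <- function(rng_seed = 1L, n_genes = 1200L,
                           chrom_length = 20000L, budget = flaw_budget(),
                           out_dir = NULL) {
  stopifnot(n_genes >= 10L, chrom_length >= 16000L)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  target_gene <- genes[1L]
  pathway_genes <- genes[2:3]
  offtarget_gene <- genes[4L]

  genome <- make_genome(c(chr1 = chrom_length, chr2 = chrom_length),
                        gc_fraction = 0.41, rng_seed = rng_seed)
  spacer_seq <- withr::with_seed(rng_seed + 1L,
    paste(sample(.BASES, 20L, replace = TRUE), collapse = ""))

  specs <- data.frame(
    spacer = spacer_seq,
    chrom = c("chr1", "chr2", "chr2", "chr2", "chr2",
              "chr2", "chr2", "chr2"),
    position = c(10000L, 2000L, 6000L, 10000L, 14000L,
                 4000L, 8000L, 12000L),
    strand = c("+", "+", "-", "+", "+", "+", "-", "+"),
    seed_flaws = c(0L, 1L, 0L, 2L, 2L, 3L, 0L, 2L),
    nonseed_flaws = c(0L, 0L, 2L, 2L, 0L, 0L, 3L, 3L),
    pam = c("AGG", "TGG", "CGG", "GGG", "AGG", "TGG", "AGG", "CGG"),
    stringsAsFactors = FALSE)
  planted <- plant_sites(genome, specs, budget = budget,
                         rng_seed = rng_seed + 2L)

  target_tss <- 10000L - 150L
  sp <- spacer("sg1", spacer_seq, intended_gene = target_gene,
               intended_chrom = "chr1", intended_tss_pos = target_tss)
  guides <- data.frame(guide_id = "sg1", sequence = spacer_seq,
                       intended_gene = target_gene,
                       intended_chrom = "chr1",
                       intended_tss_pos = target_tss,
                       stringsAsFactors = FALSE)

  # planted-gene TSSs near distinct in-budget off-target sites on chr2
  placements <- data.frame(
    gene = c(target_gene, pathway_genes, offtarget_gene),
    chrom = c("chr1", "chr2", "chr2", "chr2"),
    pos = c(target_tss,
            2000L + 20L - 1L + 200L,   # 200 bp right of site at 2000
            6000L - 300L,              # 300 bp left of site at 6000
            10000L + 20L - 1L + 450L), # 450 bp right of site at 10000
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)

  # null TSSs on a jittered grid, kept clear of planted in-budget sites
  in_budget <- planted$truth[planted$truth$in_budget, , drop = FALSE]
  clear_of_sites <- function(chrom, pos) {
    sel <- in_budget$chrom == chrom
    if (!any(sel)) return(rep(TRUE, length(pos)))
    keep <- rep(TRUE, length(pos))
    for (i in which(sel)) {
      keep <- keep & .point_interval_distance(pos, in_budget$start[i],
                                              in_budget$end[i]) > 600L
    }
    keep
  }
  n_null <- n_genes - 4L
  n_per_chrom <- ceiling(n_null / 2)
  null_pos <- list()
  for (chrom in c("chr1", "chr2")) {
    step <- max(1L, (chrom_length - 200L) %/% ceiling(n_per_chrom * 1.5))
    grid <- seq.int(100L, chrom_length - 100L, by = step)
    grid <- grid[clear_of_sites(chrom, grid)]
    grid <- grid[abs(grid - target_tss) > 600L | chrom != "chr1"]
    if (length(grid) < n_per_chrom)
      stop("chromosome too short to place the null TSS grid")
    null_pos[[chrom]] <- grid[seq_len(n_per_chrom)]
  }
  null_df <- data.frame(
    gene = genes[5:n_genes],
    chrom = rep(c("chr1", "chr2"), times = c(n_per_chrom, n_per_chrom))[
      seq_len(n_null)],
    pos = c(null_pos$chr1, null_pos$chr2)[seq_len(n_null)],
    strand = rep(c("+", "-"), length.out = n_null),
    stringsAsFactors = FALSE)
  tss <- make_tss_table(rbind(placements, null_df),
                        chrom_lengths = c(chr1 = chrom_length,
                                          chr2 = chrom_length))

  de_spec <- de_plant_spec(genes, target_gene,
                           pathway_genes = pathway_genes,
                           offtarget_genes = offtarget_gene,
                           rng_seed = rng_seed + 3L)
  tables <- make_de_tables(de_spec)

  truth <- list(target_gene = target_gene,
                pathway_genes = pathway_genes,
                offtarget_genes = offtarget_gene,
                proximal_genes = sort(c(pathway_genes, offtarget_gene)),
                spacer = spacer_seq,
                on_target = list(chrom = "chr1", start = 10000L,
                                 end = 10020L, tss_pos = target_tss))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(planted$genome,
                                file.path(out_dir, "genome.fa"))
    write_tsv <- function(x, f) write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_tsv(tss, "tss.tsv")
    write_tsv(guides, "guides.tsv")
    write_tsv(tables$crispri, "de.tsv")
    write_tsv(tables$sirna, "sirna_de.tsv")
    jsonlite::write_json(c(truth, list(sites = planted$truth)),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(genome = planted$genome, guides = guides, spacers = list(sp),
       tss = tss, de = tables$crispri, sirna_de = tables$sirna,
       sites_truth = planted$truth, truth = truth)
}
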