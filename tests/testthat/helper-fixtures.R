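# Shared helpers: tiny deterministic sequence constructors and a canonical
# site-set key for comparing scanner outputs.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# genome string with one protospacer+PAM embedded at a known 0-based
# protospacer start, on either strand, inside low-complexity flanks that
# cannot themselves harbour a within-budget site for an unrelated spacer
embed_site <- function(proto, pam, strand = "+", left = 50, right = 50) {
  lf <- strrep("T", left)
  rf <- strrep("T", right)
  if (strand == "+") {
    list(seq = paste0(lf, proto, pam, rf), start = left)
  } else {
    list(seq = paste0(lf, revcomp(paste0(proto, pam)), rf),
         start = left + nchar(pam))
  }
}

# order-free canonical representation of a site set (ignores guide_id and
# the on-target flag, which trivially match in these comparisons)
site_key <- function(sites) {
  sort(paste(sites$chrom, sites$start, sites$end, sites$strand,
             sites$seed_flaws, sites$nonseed_flaws, sites$pam, sep = ":"))
}

FIXED_SPACER <- "ACGTACGTACGTACGTACGT"
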