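test_that("an exact protospacer with a valid PAM is found once, flawless", {
  sp <- spacer("sg1", FIXED_SPACER)
  emb <- embed_site(FIXED_SPACER, "TGG", "+")
  sites <- enumerate_sites(c(chr1 = emb$seq), sp, flaw_budget())
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, emb$start)
  expect_equal(sites$end, emb$start + 20L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$seed_flaws, 0L)
  expect_equal(sites$nonseed_flaws, 0L)
  expect_equal(sites$pam, "TGG")
})

test_that("a zero-flaw budget rejects any mismatched site", {
  sp <- spacer("sg1", FIXED_SPACER)
  proto <- sub("^A", "C", FIXED_SPACER)          # one non-seed mismatch
  emb <- embed_site(proto, "TGG", "+")
  expect_equal(nrow(enumerate_sites(c(chr1 = emb$seq), sp,
                                    flaw_budget(0, 0, 0))), 0L)
  # seed mismatch instead
  proto2 <- paste0(substr(FIXED_SPACER, 1, 19), "C")
  emb2 <- embed_site(proto2, "TGG", "+")
  expect_equal(nrow(enumerate_sites(c(chr1 = emb2$seq), sp,
                                    flaw_budget(0, 0, 0))), 0L)
})

test_that("the total-flaw cap is an independent constraint", {
  sp <- spacer("sg1", FIXED_SPACER)
  # 2 seed + 2 non-seed mismatches: within the regional caps but over a
  # total cap of 3
  chars <- strsplit(FIXED_SPACER, "")[[1]]
  flip <- function(b) setdiff(BASES, b)[1]
  for (i in c(1, 3, 15, 19)) chars[i] <- flip(chars[i])
  emb <- embed_site(paste(chars, collapse = ""), "AGG", "+")
  g <- c(chr1 = emb$seq)
  expect_equal(nrow(enumerate_sites(g, sp, flaw_budget(2, 2, 4))), 1L)
  expect_equal(nrow(enumerate_sites(g, sp, flaw_budget(2, 2, 3))), 0L)
})

test_that("a minus-strand site is reported in genome-forward coordinates", {
  sp <- spacer("sg1", FIXED_SPACER)
  emb <- embed_site(FIXED_SPACER, "CGG", "-")
  g <- c(chr1 = emb$seq)
  sites <- enumerate_sites(g, sp, flaw_budget())
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "-")
  expect_equal(sites$start, emb$start)
  expect_equal(sites$end, emb$start + 20L)
  expect_equal(sites$pam, "CGG")
  expect_identical(sites, brute_force_sites(g, sp, flaw_budget()))
})

test_that("the PAM must match exactly and genomic N never satisfies it", {
  sp <- spacer("sg1", FIXED_SPACER)
  for (pam in c("TAG", "TGC", "NGG")) {      # NGG here is a literal genome N
    emb <- embed_site(FIXED_SPACER, pam, "+")
    expect_equal(nrow(enumerate_sites(c(chr1 = emb$seq), sp, flaw_budget())),
                 0L, info = pam)
  }
  # IUPAC patterns widen the PAM: TTTV accepts TTTA but not TTTT
  emb <- embed_site(FIXED_SPACER, "TTTA", "+")
  expect_equal(nrow(enumerate_sites(c(chr1 = emb$seq), sp, flaw_budget(),
                                    pam = "TTTV")), 1L)
  emb2 <- embed_site(FIXED_SPACER, "TTTT", "+")
  expect_equal(nrow(enumerate_sites(c(chr1 = emb2$seq), sp, flaw_budget(),
                                    pam = "TTTV")), 0L)
})

test_that("genomic N counts as a protospacer mismatch", {
  sp <- spacer("sg1", FIXED_SPACER)
  chars <- strsplit(FIXED_SPACER, "")[[1]]
  chars[c(10, 15)] <- "N"                     # both inside the 12-nt seed
  emb <- embed_site(paste(chars, collapse = ""), "TGG", "+")
  sites <- enumerate_sites(c(chr1 = emb$seq), sp, flaw_budget())
  expect_equal(sites$seed_flaws, 2L)
  expect_equal(sites$nonseed_flaws, 0L)
  chars[5] <- "N"                             # a third N, now non-seed
  emb3 <- embed_site(paste(chars, collapse = ""), "TGG", "+")
  sites3 <- enumerate_sites(c(chr1 = emb3$seq), sp, flaw_budget())
  expect_equal(sites3$total_flaws, 3L)
})

test_that("planted partitions are recovered exactly and decoys excluded", {
  fx <- make_site_fixture(rng_seed = 11)
  truth <- fx$truth[fx$truth$in_budget, , drop = FALSE]
  sites <- enumerate_sites(fx$genome, fx$spacer, flaw_budget())
  expect_identical(site_key(sites), site_key(truth))
  expect_equal(nrow(sites), 10L)        # every (0..2, 0..2) partition + a dup
  # no reported site violates any cap
  expect_true(all(sites$seed_flaws <= 2 & sites$nonseed_flaws <= 2 &
                    sites$total_flaws <= 4))
})

test_that("input validation rejects bad spacers and short seeds", {
  expect_error(spacer("sg1", "ACGTNACGTACGTACGTACG"), "A/C/G/T")
  expect_error(spacer("sg1", "ACGT"), "between 18 and 25")
  sp <- spacer("sg1", FIXED_SPACER)
  expect_error(enumerate_sites(c(chr1 = strrep("A", 100)), sp,
                               flaw_budget(seed_length = 25)),
               "seed_length")
  # chromosome shorter than spacer+PAM yields no sites, not an error
  expect_equal(nrow(enumerate_sites(c(chr1 = "ACGTACGT"), sp,
                                    flaw_budget())), 0L)
})

test_that("on-target flagging marks sites near the intended TSS", {
  emb <- embed_site(FIXED_SPACER, "TGG", "+", left = 600)
  sp_near <- spacer("sg1", FIXED_SPACER, "GENE1", "chr1",
                    emb$start - 400L)
  sites <- enumerate_sites(c(chr1 = emb$seq), sp_near, flaw_budget())
  expect_true(sites$is_on_target)
  sp_far <- spacer("sg1", FIXED_SPACER, "GENE1", "chr1",
                   emb$start - 501L)
  expect_false(enumerate_sites(c(chr1 = emb$seq), sp_far,
                               flaw_budget())$is_on_target)
})

test_that("budget monotonicity: smaller budgets yield subset site sets", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      g <- c(chr1 = random_seq(3000))
      sp <- spacer("sg1", random_seq(20))
      small <- flaw_budget(sample(0:2, 1), sample(0:2, 1), sample(0:3, 1))
      big <- flaw_budget(small$max_seed_flaws + 1,
                         small$max_nonseed_flaws + 1,
                         small$max_total_flaws + 1)
      expect_true(all(site_key(enumerate_sites(g, sp, small)) %in%
                        site_key(enumerate_sites(g, sp, big))))
    })
  }
})

test_that("scanning the reverse-complemented genome mirrors the site set", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      L <- 2500L
      g <- random_seq(L)
      sp <- spacer("sg1", random_seq(20))
      fwd <- enumerate_sites(c(chr1 = g), sp, flaw_budget(2, 2, 4))
      rev <- enumerate_sites(c(chr1 = revcomp(g)), sp, flaw_budget(2, 2, 4))
      mirrored <- rev
      mirrored$start <- L - rev$end
      mirrored$end <- mirrored$start + 20L
      mirrored$strand <- ifelse(rev$strand == "+", "-", "+")
      expect_identical(site_key(fwd), site_key(mirrored))
    })
  }
})

test_that("vectorized and brute-force scanners agree on random inputs", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      g <- c(chr1 = random_seq(sample(100:2000, 1)))
      sp <- spacer("sg1", random_seq(sample(c(18L, 20L, 22L), 1)))
      bud <- flaw_budget(sample(0:3, 1), sample(0:3, 1), sample(0:4, 1),
                         seed_length = sample(8:14, 1))
      expect_identical(enumerate_sites(g, sp, bud),
                       brute_force_sites(g, sp, bud))
    })
  }
  expect_error(brute_force_sites(c(chr1 = strrep("A", 2e6)),
                                 spacer("sg1", FIXED_SPACER)), "1 Mb")
})

test_that("pool_sites unions guides and flags shared loci", {
  emb1 <- embed_site(FIXED_SPACER, "TGG", "+")
  g <- c(chr1 = emb1$seq)
  s1 <- enumerate_sites(g, spacer("sgA", FIXED_SPACER), flaw_budget())
  s2 <- enumerate_sites(g, spacer("sgB", FIXED_SPACER), flaw_budget())
  # pool of one guide is the guide's own list (modulo the shared flag)
  p1 <- pool_sites(list(s1))
  expect_equal(p1[names(s1)], s1)
  expect_false(any(p1$shared_locus))
  # same locus hit by both guides: one record per guide, flagged shared
  p2 <- pool_sites(list(s1, s2))
  expect_equal(nrow(p2), 2L)
  expect_true(all(p2$shared_locus))
  # disjoint sites simply union; duplicates within a guide collapse
  other <- embed_site(FIXED_SPACER, "AGG", "-", left = 200)
  g2 <- c(chr2 = other$seq)
  s3 <- enumerate_sites(g2, spacer("sgB", FIXED_SPACER), flaw_budget())
  p3 <- pool_sites(list(s1, s3, s3))
  expect_equal(nrow(p3), 2L)
  expect_false(any(p3$shared_locus))
})
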