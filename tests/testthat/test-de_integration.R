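de_row <- function(gene, log2fc, pvalue, padj = pvalue) {
  data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("significance requires strict thresholds on both axes", {
  tab <- rbind(de_row("null", 0, 1),
               de_row("at_fc_threshold", 1.5, 1e-6),
               de_row("at_alpha", 2.0, 0.04, padj = 0.05),
               de_row("hit_up", 2.0, 1e-6),
               de_row("hit_down", -1.6, 1e-4, padj = 0.01))
  expect_identical(call_significant(tab, thresholds()),
                   c("hit_down", "hit_up"))
  # raw-p mode admits the gene whose adjusted p sits exactly at alpha
  expect_identical(call_significant(tab, thresholds(use_adjusted = FALSE)),
                   c("at_alpha", "hit_down", "hit_up"))
})

test_that("missing adjusted p-values fall back to raw p with a warning", {
  tab <- de_row(c("a", "b"), c(2, 2), c(0.01, 0.5), padj = NA_real_)
  expect_warning(got <- call_significant(tab, thresholds()), "falling back")
  expect_identical(got, "a")
  # partially missing padj: NA means not significant, no fallback
  tab2 <- de_row(c("a", "b"), c(2, 2), c(0.01, 0.01),
                 padj = c(NA_real_, 0.01))
  expect_identical(call_significant(tab2, thresholds()), "b")
  # non-finite log2fc records are skipped with a warning
  tab3 <- de_row(c("a", "b"), c(NaN, 2), c(0.001, 0.001))
  expect_warning(got3 <- call_significant(tab3, thresholds()), "non-finite")
  expect_identical(got3, "b")
})

test_that("planted significant genes are recovered exactly from a null sea", {
  withr::with_seed(42, {
    n_null <- 990L
    nulls <- de_row(sprintf("null%03d", 1:n_null), rnorm(n_null, 0, 0.3),
                    runif(n_null), padj = pmin(1, runif(n_null) + 0.2))
    planted <- de_row(sprintf("hit%02d", 1:10),
                      sample(c(-2, 2), 10, TRUE), 1e-8, padj = 0.001)
    tab <- rbind(nulls, planted)[sample(n_null + 10L), ]
    expect_identical(call_significant(tab, thresholds()),
                     sort(planted$gene))
  })
})

test_that("significance calls are monotone in alpha and fold-change cut", {
  withr::with_seed(7, {
    tab <- de_row(sprintf("g%03d", 1:300), rnorm(300, 0, 2), runif(300))
    for (i in 1:5) {
      a1 <- runif(1, 0.001, 0.5); a2 <- a1 + runif(1, 0, 0.4)
      f1 <- runif(1, 0, 3); f2 <- f1 + runif(1, 0, 2)
      s_small <- call_significant(tab, thresholds(f2, a1))
      s_big <- call_significant(tab, thresholds(f1, a2))
      expect_true(all(s_small %in% s_big))
    }
  })
})

test_that("cross_reference is the plain set intersection", {
  expect_identical(cross_reference(c("a", "b"), c("c", "d")), character(0))
  expect_identical(cross_reference(c("a", "b"), c("a", "b", "c")),
                   c("a", "b"))
})

test_that("orthogonal attribution partitions the candidates", {
  att <- attribute_orthogonal(c("x", "y", "z"), character(0))
  expect_identical(att$possible_offtarget, c("x", "y", "z"))
  expect_identical(att$pathway_attributed, character(0))
  att2 <- attribute_orthogonal(c("x", "y"), c("x", "y", "w"))
  expect_identical(att2$pathway_attributed, c("x", "y"))
  expect_identical(att2$possible_offtarget, character(0))
  # partition property on random sets
  withr::with_seed(99, {
    universe <- sprintf("g%02d", 1:40)
    for (i in 1:20) {
      cand <- sample(universe, sample(0:15, 1))
      sirna <- sample(universe, sample(0:25, 1))
      att <- attribute_orthogonal(cand, sirna)
      expect_length(intersect(att$pathway_attributed,
                              att$possible_offtarget), 0L)
      expect_setequal(c(att$pathway_attributed, att$possible_offtarget),
                      cand)
    }
  })
})

test_that("spreading check intersects significant and neighbouring genes", {
  expect_identical(spreading_check(c("a", "b"), character(0)), character(0))
  expect_identical(spreading_check(c("a", "b"), c("b", "c")), "b")
})

test_that("specificity correlation matches a closed-form Pearson r", {
  tpm <- c(g1 = 5, g2 = 10, g3 = 20, g4 = 40, g5 = 80, g6 = 160)
  expect_equal(specificity_correlation(tpm, tpm), 1)
  # treated differs from control only at the excluded target
  treated <- tpm; treated["g1"] <- 0.1
  expect_equal(specificity_correlation(treated, tpm, exclude = "g1"), 1)
  # six-gene toy against the explicit sum formula
  ctrl <- c(g1 = 6, g2 = 9, g3 = 25, g4 = 35, g5 = 70, g6 = 180)
  x <- log2(tpm + 1); y <- log2(ctrl + 1); n <- 6
  r_manual <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(specificity_correlation(tpm, ctrl), r_manual,
               tolerance = 1e-12)
  # invariance under an identical permutation of the gene order
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(specificity_correlation(tpm[perm], ctrl[perm]),
               specificity_correlation(tpm, ctrl))
  # degenerate inputs
  expect_warning(r0 <- specificity_correlation(
    c(a = 2, b = 2, c = 2), c(a = 1, b = 5, c = 9)), "zero variance")
  expect_true(is.na(r0))
  expect_error(specificity_correlation(c(a = 1, b = 2), c(a = 1, b = 2)),
               "at least 3")
})

test_that("an all-null comparison yields an empty report", {
  withr::with_seed(5, {
    tab <- de_row(sprintf("g%03d", 1:100), rnorm(100, 0, 0.2),
                  runif(100, 0.2, 1))
  })
  rep <- build_report("null vs null", tab, proximal = character())
  expect_equal(rep$n_significant, 0L)
  expect_equal(rep$n_proximal_genes, 0L)
  expect_length(rep$candidates, 0L)
  expect_length(rep$possible_offtarget, 0L)
  expect_true(is.na(rep$pearson_r))
})

test_that("report invariants hold and serialization round-trips", {
  withr::with_seed(21, {
    genes <- sprintf("g%03d", 1:200)
    tab <- de_row(genes, rnorm(200, 0, 1.5), runif(200, 0, 0.2))
    tab$tpm_control <- 2^runif(200, 2, 10)
    tab$tpm_treated <- tab$tpm_control * 2^tab$log2fc
    sirna <- de_row(genes, rnorm(200, 0, 1.5), runif(200, 0, 0.2))
    prox <- sample(genes, 50)
  })
  rep <- build_report("random", tab, prox, sirna_table = sirna,
                      neighborhood = sample(genes, 30))
  expect_setequal(c(rep$pathway_attributed, rep$possible_offtarget),
                  rep$candidates)
  expect_length(intersect(rep$pathway_attributed, rep$possible_offtarget),
                0L)
  expect_true(all(rep$candidates %in% rep$significant))
  expect_true(all(rep$candidates %in% prox))
  expect_true(rep$pearson_r >= -1 && rep$pearson_r <= 1)
  row <- as.data.frame(rep)
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_significant, rep$n_significant)
  parsed <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(parsed$n_significant, rep$n_significant)
  expect_setequal(parsed$possible_offtarget, rep$possible_offtarget)
})
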