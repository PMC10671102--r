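hap <- function(text, id = "S") parse_haplotype(text, sample_id = id, ref = REF)

test_that("pairwise matching honors range, indels and IUPAC policy", {
  pol <- match_policy("literal")
  # indels ignored by default
  expect_true(haplotypes_match(hap("73G 263G"), hap("73G 263G 315.1C"), pol))
  expect_false(haplotypes_match(hap("73G 263G"), hap("73G 263G 315.1C"),
                                match_policy("literal", ignore_indels = FALSE)))
  # PHP at a hotspot position: pattern matches the homoplasmic state
  expect_true(haplotypes_match(hap("152Y"), hap("152C"), match_policy("pattern")))
  expect_false(haplotypes_match(hap("152Y"), hap("152C"), match_policy("literal")))
  # a difference inside the range breaks the match
  hvs <- match_policy("literal", range = standard_range("hvs"))
  expect_false(haplotypes_match(hap("73G"), hap("73G 16189C"), hvs))
  # ... but differences outside the range are invisible
  expect_true(haplotypes_match(hap("73G"), hap("73G 8860G"), hvs))
  # N is missing data and never breaks a match
  expect_true(haplotypes_match(hap("73G 152N"), hap("73G 152C"),
                               match_policy("literal")))
})

test_that("literal clustering groups identical haplotypes exactly", {
  hs <- c(replicate(4, hap("73G 263G"), simplify = FALSE),
          replicate(2, hap("263G"), simplify = FALSE),
          list(hap("73G"), hap("150T"), hap("16189C")))
  cl <- cluster_haplotypes(hs, match_policy("literal"))
  expect_equal(cl$spectrum$classes, c(`1` = 3L, `2` = 1L, `4` = 1L))
  expect_equal(sum(cl$spectrum$classes), 5L)
  expect_equal(cl$spectrum$n, 9L)
})

test_that("pattern clustering merges an ambiguity with its first partner only", {
  hs <- list(hap("263Y", "a"), hap("263C", "b"), hap("263T", "c"))
  cl <- cluster_haplotypes(hs, match_policy("pattern"), ref = REF)
  # Y and C share a class; T fails against the C member and stands alone
  expect_equal(cl$assignment, c(1L, 1L, 2L))
  lit <- cluster_haplotypes(hs, match_policy("literal"))
  expect_lte(sum(cl$spectrum$classes), sum(lit$spectrum$classes))
})

test_that("spectrum statistics match the worked examples", {
  s <- freq_spectrum(classes = c(`1` = 746, `2` = 51, `3` = 16, `4` = 5,
                                 `5` = 1, `6` = 1, `7` = 1))
  expect_equal(s$n, 934L)
  expect_equal(round(observed_rmp(s), 6), 0.001472)
  expect_equal(empirical_rmp(s), 350 / 871422)
  expect_equal(round(haplotype_diversity(s), 4), 0.9996)

  all_unique <- freq_spectrum(rep(1L, 4))
  expect_equal(observed_rmp(all_unique), 0.25)
  expect_equal(empirical_rmp(all_unique), 0)
  expect_equal(haplotype_diversity(all_unique), 1)

  s2 <- freq_spectrum(c(2L, 1L, 1L))
  expect_equal(observed_rmp(s2), 0.375)
  expect_equal(empirical_rmp(s2), 2 / 12)
  expect_equal(round(haplotype_diversity(s2), 4), 0.8333)

  expect_error(empirical_rmp(freq_spectrum(1L)), "two")
  expect_error(freq_spectrum(integer(0)), "empty")
})

test_that("spectrum statistics equal brute-force all-pairs enumeration", {
  cfg <- sim_config(n_samples = 24, clade_sizes = c(5, 4, 3, 3, 2, 2, 1, 1, 1, 1, 1),
                    seed = 21)
  pop <- simulate_population(cfg, REF)
  hs <- pop$haplotypes
  pol <- match_policy("literal")
  cl <- cluster_haplotypes(hs, pol)
  n <- length(hs)
  match_mat <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    haplotypes_match(hs[[i]], hs[[j]], pol)
  }))
  expect_equal(observed_rmp(cl$spectrum), sum(match_mat) / n^2)
  expect_equal(empirical_rmp(cl$spectrum),
               (sum(match_mat) - n) / (n * (n - 1)))
  expect_lte(empirical_rmp(cl$spectrum), observed_rmp(cl$spectrum))
})

test_that("unique-haplotype counts shrink with the reporting range", {
  cfg <- sim_config(n_samples = 40, clade_sizes = c(rep(2, 5), rep(1, 30)),
                    seed = 31)
  pop <- simulate_population(cfg, REF)
  uniq <- vapply(c("mitogenome", "cr", "hvs"), function(rg) {
    cl <- cluster_haplotypes(pop$haplotypes,
                             match_policy("literal", range = standard_range(rg)))
    sum(cl$spectrum$classes)
  }, numeric(1))
  expect_true(uniq["mitogenome"] >= uniq["cr"])
  expect_true(uniq["cr"] >= uniq["hvs"])
})

test_that("pattern-mode merging never increases RMP below the literal value", {
  base <- c("73G 263G 750G", "73G 263G 750G", "263G 2706G", "263G 2706G 4769G",
            "150T 263G", "73G 263G 750Y", "263G 2706R", "16311C 263G",
            "73G 263G 750G 8860G", "150T 263R")
  hs <- lapply(seq_along(base), function(i) hap(base[i], paste0("s", i)))
  lit <- pop_stats(cluster_haplotypes(hs, match_policy("literal"))$spectrum)
  pat <- pop_stats(cluster_haplotypes(hs, match_policy("pattern"), ref = REF)$spectrum)
  expect_lte(pat$total_haplotypes, lit$total_haplotypes)
  expect_gte(pat$observed_rmp, lit$observed_rmp)
  expect_lte(pat$haplotype_diversity, lit$haplotype_diversity)
})

test_that("maternal relatives sharing a haplotype are deduplicated once", {
  hs <- list(hap("73G 263G", "A1"), hap("73G 263G", "A2"),
             hap("73G 263G", "A3"), hap("150T", "B1"), hap("150T", "B2"))
  rel <- data.frame(sample1 = c("A1", "A2"), sample2 = c("A2", "A3"),
                    degree = c("first", "second"), stringsAsFactors = FALSE)
  out <- dedup_related(hs, rel)
  ids <- vapply(out, function(h) h$sample_id, character(1))
  # the three-sample related cluster keeps its lowest id; unflagged B1/B2 stay
  expect_equal(ids, c("A1", "B1", "B2"))

  # identical haplotypes but no relatedness flag: both retained
  out2 <- dedup_related(hs[4:5], rel[0, ])
  expect_equal(length(out2), 2L)

  # heteroplasmy is ignored when grouping shared haplotypes
  hs3 <- list(hap("73G 263G 152Y", "C1"), hap("73G 263G", "C2"))
  rel3 <- data.frame(sample1 = "C1", sample2 = "C2", degree = "first")
  expect_equal(length(dedup_related(hs3, rel3)), 1L)

  expect_warning(dedup_related(hs, data.frame(sample1 = "ZZ", sample2 = "A1",
                                              degree = "first")),
                 "unknown")
})

test_that("the Yates-corrected chi-squared test matches the worked example", {
  res <- chisq_yates(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(res$statistic, 5.4)
  expect_equal(res$df, 1L)
  expect_equal(round(res$p_value, 4), 0.0201)

  same <- chisq_yates(matrix(c(15, 15, 15, 15), 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(chisq_yates(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("chisq_yates agrees with the standard implementation on 2x2 tables", {
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(4, lambda = sample(5:80, 1)) + 1L, 2, 2)
    ours <- chisq_yates(tab)
    std <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_lt(abs(ours$statistic - unname(std$statistic)), 1e-10)
    expect_lt(abs(ours$p_value - std$p.value), 1e-10)
  }
})

test_that("chi-squared p-values are near-uniform under the null", {
  # large per-bin counts, where the continuity correction is asymptotically
  # negligible and the p-value distribution approaches uniformity
  set.seed(43)
  probs <- c(0.45, 0.25, 0.2, 0.1)
  pvals <- replicate(200, {
    a <- rmultinom(1, 6000, probs)[, 1]
    b <- rmultinom(1, 6000, probs)[, 1]
    chisq_yates(rbind(a, b))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("summary proportions reproduce printed-count arithmetic", {
  sc <- summarize_counts(
    n_samples = 934,
    php_per_haplotype = c(`1` = 177L, `2` = 25L, `3` = 3L),
    n_php_transitions = 181L, n_php = 236L,
    n_lhp_haplotypes = 682L, max_class_size = 7L,
    total_variants = 23857L)
  expect_equal(sc$n_php_haplotypes, 205L)
  expect_equal(sc$percent$php_haplotypes, 21.9)
  expect_equal(sc$percent$single_php_share, 86.3)
  expect_equal(sc$percent$php_transition_share, 76.7)
  expect_equal(sc$percent$lhp_prevalence, 73.0)
  expect_equal(sc$percent$most_common_haplotype, 0.7)
  expect_equal(sc$mean_variants_per_haplotype_rounded, 25.5)
})

test_that("dataset summaries handle empty and degenerate inputs", {
  empty <- summarize_dataset(hs = list())
  expect_equal(empty$n_samples, 0L)

  hs <- list(hap("73G 152Y", "a"), hap("73G 152Y", "b"))
  rep2 <- summarize_dataset(hs = hs, ref = REF)
  expect_equal(rep2$mean_variants_per_haplotype, 2)
  expect_equal(rep2$php$total, 2L)
  expect_equal(unname(rep2$php$class_tally["transition"]), 2L)
  tab <- rep2$diversity_table
  expect_equal(tab$total_haplotypes[tab$range == "mitogenome" &
                                      tab$mode == "literal"], 1L)
})
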