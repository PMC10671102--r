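test_that("a biallelic position above threshold is reported as a PHP", {
  # reference G with A at 84.7% and G at 15.3%: IUPAC R, minor 0.153
  row <- list(pos = 13105L, depth = 1000L, A = 847L, C = 0L, G = 153L, T = 0L,
              del = 0L, ins = "")
  cl <- call_position(row, "G")
  expect_true(cl$is_php)
  expect_equal(cl$symbol, "R")
  expect_equal(cl$minor_fraction, 0.153)

  # unanimous reference base: no variant
  cl2 <- call_position(list(pos = 100L, depth = 500L, A = 500L, C = 0L,
                            G = 0L, T = 0L, del = 0L, ins = ""), "A")
  expect_true(is.na(cl2$symbol))
  expect_false(cl2$is_php)

  # three alleles above 10%: mixture-indicative, major still reported
  cl3 <- call_position(list(pos = 100L, depth = 1000L, A = 500L, C = 300L,
                            G = 200L, T = 0L, del = 0L, ins = ""), "T")
  expect_true(cl3$mixture_indicative)
  expect_equal(cl3$symbol, "A")
  expect_false(cl3$is_php)
})

test_that("the PHP threshold is sharp at the configured minimum VF", {
  # brute-force oracle: for counts around the 10% boundary, PHP iff the
  # minor fraction (minor/depth) is at least min_vf
  depth <- 1000L
  for (minor in 95:105) {
    row <- list(pos = 200L, depth = depth, A = depth - minor, C = 0L,
                G = minor, T = 0L, del = 0L, ins = "")
    cl <- call_position(row, "A")
    expect_identical(cl$is_php, minor / depth >= 0.10,
                     label = paste("minor count", minor))
  }
})

test_that("coverage classes follow the below-depth position count", {
  cfg <- call_config()
  expect_equal(classify_coverage(0, cfg), "complete")
  expect_equal(classify_coverage(1, cfg), "nearly_complete")
  expect_equal(classify_coverage(4, cfg), "nearly_complete")
  expect_equal(classify_coverage(5, cfg), "incomplete")
  expect_error(classify_coverage(-1, cfg))
})

test_that("a clean pileup reproduces the exemplar haplotype exactly", {
  pu <- make_pileup_from_haplotype(HAP_U5B1B1A, REF, depth = 1500)
  res <- call_haplotype(pu, REF, call_config())
  expect_equal(serialize_haplotype(res$haplotype),
               serialize_haplotype(parse_haplotype(gsub("\\.x", ".1", HAP_U5B1B1A))))
  expect_equal(res$coverage_class, "complete")
  expect_equal(res$n_php, 0L)
  expect_false(res$mixture_flag)
})

test_that("an all-reference pileup yields the empty haplotype", {
  pu <- make_pileup(REF, depth = 400)
  res <- call_haplotype(pu, REF, call_config())
  expect_equal(n_variants(res$haplotype), 0L)
  expect_equal(res$coverage_class, "complete")
})

test_that("low-coverage positions drive the coverage class and the 20X rule", {
  low <- data.frame(pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
                    depth = rep(80L, 5))
  pu <- make_pileup(REF, depth = 500, depth_override = low)
  res <- call_haplotype(pu, REF, call_config())
  expect_equal(res$n_below_min_depth, 5L)
  expect_equal(res$coverage_class, "incomplete")
  # re-analysis at the 20X minimum depth: all positions covered
  res20 <- call_haplotype(pu, REF, call_config(min_depth = 20L,
                                               fallback_min_depth = 10L))
  expect_equal(res20$coverage_class, "complete")
})

test_that("positions below the fallback depth are uncovered, not genotyped", {
  low <- data.frame(pos = c(7000L, 7001L), depth = c(10L, 0L))
  pu <- make_pileup(REF, depth = 500, subs = data.frame(pos = 7000L, base = "A"),
                    depth_override = low)
  res <- call_haplotype(pu, REF, call_config())
  expect_equal(res$uncovered_positions, c(7000L, 7001L))
  expect_false(7000L %in% res$haplotype$variants$pos)
})

test_that("PHPs at the polyA artifact positions are suppressed to the major base", {
  mixed <- data.frame(pos = c(302L, 16183L, 152L), base = c("C", "C", "C"),
                      frac = c(0.45, 0.40, 0.30))
  pu <- make_pileup(REF, depth = 1000, mixed = mixed)
  res <- call_haplotype(pu, REF, call_config())
  v <- res$haplotype$variants
  # 302 and 16183 (both reference A, majority A) vanish; 152 is a real PHP Y
  expect_false(any(v$pos %in% c(302L, 16183L)))
  expect_equal(v$obs[v$pos == 152L], "Y")
  expect_equal(res$n_php, 1L)
})

test_that("homopolymer length variation is reported as the major length molecule", {
  # 60% of molecules carry +1C at the HVS2 stretch: insertion reported, LHP flagged
  pu <- make_pileup(REF, depth = 1000,
                    ins = data.frame(pos = 315L, seq = "C", frac = 0.60))
  res <- call_haplotype(pu, REF, call_config())
  expect_equal(serialize_haplotype(res$haplotype), "315.1C")
  expect_true("HVS2" %in% res$haplotype$lhp_regions)

  # 30% minor insertion: dropped from the haplotype but the region is flagged
  pu2 <- make_pileup(REF, depth = 1000,
                     ins = data.frame(pos = 315L, seq = "C", frac = 0.30))
  res2 <- call_haplotype(pu2, REF, call_config())
  expect_equal(n_variants(res2$haplotype), 0L)
  expect_true("HVS2" %in% res2$haplotype$lhp_regions)

  # essentially homoplasmic insertion: reported, no length heteroplasmy
  pu3 <- make_pileup(REF, depth = 1000,
                     ins = data.frame(pos = 315L, seq = "C", frac = 0.97))
  res3 <- call_haplotype(pu3, REF, call_config())
  expect_equal(serialize_haplotype(res3$haplotype), "315.1C")
  expect_false("HVS2" %in% res3$haplotype$lhp_regions)
})

test_that("deletions are called at the variant-frequency threshold", {
  pu <- make_pileup(REF, depth = 1000, dels = 8281:8289)
  res <- call_haplotype(pu, REF, call_config())
  v <- res$haplotype$variants
  expect_equal(v$pos[v$kind == "del"], 8281:8289)
})

test_that("average VF behaves as a mean over variant positions", {
  expect_equal(average_vf(c(0.99, 1.00, 0.995)), 0.995)
  expect_true(is.na(average_vf(numeric(0))))
  # a 50% PHP drags the all-positions average below the no-HP average
  mixed <- data.frame(pos = 152L, base = "C", frac = 0.5)
  subs <- data.frame(pos = c(750L, 4769L), base = c("G", "G"))
  pu <- make_pileup(REF, depth = 1000, subs = subs, mixed = mixed)
  res <- call_haplotype(pu, REF, call_config())
  expect_lt(res$avg_vf_all, res$avg_vf_no_hp)
  expect_equal(res$avg_vf_no_hp, 1.0)
})

test_that("the mixture flag follows the multi-allelic cap and the VF floor", {
  cfg <- call_config()
  expect_false(flag_mixture(list(n_multiallelic_positions = 1L,
                                 avg_vf_no_hp = 0.996), cfg))
  expect_true(flag_mixture(list(n_multiallelic_positions = 10L,
                                avg_vf_no_hp = 0.999), cfg))
  expect_true(flag_mixture(list(n_multiallelic_positions = 0L,
                                avg_vf_no_hp = 0.97), cfg))
  expect_false(flag_mixture(list(n_multiallelic_positions = 0L,
                                 avg_vf_no_hp = NA_real_), cfg))
})

test_that("calls depend on frequencies, not absolute counts", {
  mixed <- data.frame(pos = c(152L, 16311L), base = c("C", "C"),
                      frac = c(0.20, 0.45))
  subs <- data.frame(pos = c(750L, 2706L), base = c("G", "G"))
  pu1 <- make_pileup(REF, depth = 400, subs = subs, mixed = mixed)
  pu3 <- pu1
  for (col in c("depth", "A", "C", "G", "T", "del")) pu3[[col]] <- 3L * pu3[[col]]
  r1 <- call_haplotype(pu1, REF, call_config())
  r3 <- call_haplotype(pu3, REF, call_config())
  expect_equal(serialize_haplotype(r1$haplotype),
               serialize_haplotype(r3$haplotype))
})

test_that("NUMT hotspot calls are flagged and sub-threshold signal is noticed", {
  cfg <- sim_config(n_samples = 1, seed = 3)
  h <- mt_haplotype(sample_id = "numt")
  set.seed(19)
  base <- simulate_pileup(h, cfg, REF, mean_depth = 2000)
  # f = 15%: the hotspot allele crosses the calling threshold and is flagged
  hot <- inject_numt(base, cfg$numt_blocks, 0.15, REF)
  res <- call_haplotype(hot, REF, call_config())
  expect_true(nrow(res$numt_flags) >= 4)
  expect_true(13105L %in% res$numt_flags$pos)
  expect_true(13105L %in% res$haplotype$variants$pos)
  # f = 5%: nothing called, but signal above the 2% noise floor is reported
  set.seed(19)
  base2 <- simulate_pileup(h, cfg, REF, mean_depth = 2000)
  low <- inject_numt(base2, cfg$numt_blocks, 0.05, REF)
  res2 <- call_haplotype(low, REF, call_config())
  expect_equal(nrow(res2$numt_flags), 0L)
  expect_equal(n_variants(res2$haplotype), 0L)
  expect_true(res2$sub_threshold_numt_signal)
})

test_that("a pileup with missing positions is rejected with the gaps listed", {
  pu <- make_pileup(REF, depth = 100)
  expect_error(call_haplotype(pu[-c(5, 6), ], REF, call_config()),
               "missing positions: 5, 6")
})
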