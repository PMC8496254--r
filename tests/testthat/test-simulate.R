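test_that("simulated parent is heterozygous everywhere with seed-stable phase", {
  cfg <- sim_config(chrom_lengths_cM = 50, markers_per_chromosome = 3,
                    n_individuals = 5, seed = 7)
  tr <- simulate_parent(cfg)
  expect_equal(nrow(tr$markers), 3)
  expect_true(all(tr$markers$allele_a != tr$markers$allele_b))
  expect_true(all(tr$markers$phase %in% 0:1))
  tr2 <- simulate_parent(cfg)
  expect_identical(tr$markers, tr2$markers)
  expect_true(all(diff(tr$markers$pos_bp) > 0))
})

test_that("default genome matches the published 12-group map dimensions", {
  cfg <- sim_config()
  expect_length(cfg$chrom_lengths_cM, 12)
  expect_lt(abs(sum(cfg$chrom_lengths_cM) - 942.17), 0.02)
})

test_that("non-increasing explicit marker positions are a configuration error", {
  expect_error(
    sim_config(chrom_lengths_cM = 50, markers_per_chromosome = list(c(0, 10, 10))),
    "strictly increasing"
  )
})

test_that("gamete crossovers follow the Poisson / Haldane model", {
  cfg <- sim_config(chrom_lengths_cM = 100,
                    markers_per_chromosome = list(c(0, 20)),
                    n_individuals = 5, seed = 3)
  tr <- simulate_parent(cfg)
  n_draw <- 10000
  set.seed(42)
  gams <- replicate(n_draw, simulate_gamete(tr, 1), simplify = FALSE)
  n_xo <- vapply(gams, function(g) length(g$breaks_cM), numeric(1))
  # Poisson mean L/100 = 1, checked within 3 standard errors
  se <- sqrt(1 / n_draw)
  expect_lt(abs(mean(n_xo) - 1), 3 * se)
  # recombinant fraction between markers 20 cM apart vs inverse Haldane
  rec <- vapply(gams, function(g) g$hap_at_marker[1] != g$hap_at_marker[2], logical(1))
  r_exp <- haldane_inv(20)
  expect_lt(abs(mean(rec) - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n_draw))
})

test_that("selfed genotype frequencies fit 1:2:1 without selection", {
  # one marker per chromosome so the 10,000 cells are independent draws
  tr <- small_truth(lengths = rep(50, 20), markers = 1, n = 500,
                    missing_rate = 0)
  counts <- table(factor(tr$geno, levels = 0:2))
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
})

test_that("zygotic and gametic selection shift locus frequencies as modelled", {
  # zygotic, strength 0 against AA at a marker position: AA absent, AB:BB ~ 2:1
  sel <- selection_spec(1, 40, "zygotic", "AA", strength = 0)
  cfg <- sim_config(chrom_lengths_cM = 80,
                    markers_per_chromosome = list(c(0, 40, 80)),
                    n_individuals = 300, selection = list(sel),
                    missing_rate = 0, seed = 9)
  tr <- simulate_s1_population(simulate_parent(cfg))
  hap_dose <- truth_phased_geno(tr)[, 2]  # dose of haplotype-2 allele; AA = 0
  expect_equal(sum(hap_dose == 0), 0)
  expect_lt(abs(mean(hap_dose == 1) - 2 / 3), 0.1)

  # gametic one-sex, strength 0 against allele A: AA absent, AB:BB ~ 1:1
  sel <- selection_spec(1, 40, "gametic_one_sex", "A", strength = 0)
  cfg <- sim_config(chrom_lengths_cM = 80,
                    markers_per_chromosome = list(c(0, 40, 80)),
                    n_individuals = 400, selection = list(sel),
                    missing_rate = 0, seed = 10)
  tr <- simulate_s1_population(simulate_parent(cfg))
  hap_dose <- truth_phased_geno(tr)[, 2]
  expect_equal(sum(hap_dose == 0), 0)
  expect_lt(abs(mean(hap_dose == 1) - 0.5), 0.1)
})

test_that("flipping recorded phase complements the emitted genotypes", {
  tr <- small_truth(lengths = 60, markers = 10, n = 40, missing_rate = 0)
  flipped <- tr
  flip_set <- c(2, 5, 9)
  flipped$markers$phase[flip_set] <- 1L - flipped$markers$phase[flip_set]
  tr_re <- simulate_s1_population(flipped)
  expect_identical(tr_re$geno[, flip_set], 2L - tr$geno[, flip_set])
  expect_identical(tr_re$geno[, -flip_set], tr$geno[, -flip_set])
})

test_that("per-individual streams are prefix-stable and deterministic", {
  tr_small <- small_truth(lengths = 60, markers = 8, n = 15, seed = 21)
  tr_big <- small_truth(lengths = 60, markers = 8, n = 30, seed = 21)
  expect_identical(tr_big$geno[1:15, ], tr_small$geno)
  counts_small <- simulate_read_counts(tr_small)
  counts_big <- simulate_read_counts(tr_big)
  expect_identical(counts_big[seq_len(nrow(counts_small)), ], counts_small)
  expect_identical(simulate_read_counts(tr_small), counts_small)
})

test_that("read-count emission matches the declared model", {
  tr <- small_truth(lengths = c(100, 100), markers = 50, n = 100, seed = 4,
                    missing_rate = 0, seq_error_rate = 0)
  counts <- simulate_read_counts(tr)
  expect_true(all(counts$count_a + counts$count_b + counts$count_other ==
                    counts$depth))
  # e = 0: homozygotes emit no reads of the other allele, no error reads
  dose <- tr$geno[cbind(match(counts$individual_id, rownames(tr$geno)),
                        match(counts$marker_id, colnames(tr$geno)))]
  expect_true(all(counts$count_other == 0))
  expect_true(all(counts$count_b[dose == 0] == 0))
  expect_true(all(counts$count_a[dose == 2] == 0))
  # mean depth within 2% of the target at 10^4 cells (no missing cells)
  expect_lt(abs(mean(counts$depth) - 96) / 96, 0.02)
  # missing cells appear at roughly the configured rate
  tr2 <- small_truth(lengths = 100, markers = 50, n = 100, seed = 5,
                     missing_rate = 0.1)
  counts2 <- simulate_read_counts(tr2)
  expect_lt(abs(mean(counts2$depth == 0) - 0.1), 0.02)
})

test_that("crossover truth is consistent with recorded genotypes", {
  tr <- small_truth(lengths = 100, markers = 50, n = 60, missing_rate = 0,
                    seed = 13)
  g <- truth_phased_geno(tr)
  # obligate crossovers never exceed the simulated crossover count
  obl <- count_obligate_xo(colnames(g), g)$per_individual
  true_n <- table(factor(tr$crossovers$individual, levels = rownames(g)))
  expect_true(all(obl <= as.numeric(true_n)))
  # dense markers: mean obligate count close to 2L/100
  expect_lt(abs(mean(obl) - 2), 0.35)
})
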