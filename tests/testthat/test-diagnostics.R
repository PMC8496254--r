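test_that("segregation chi-square matches hand-computed values", {
  perfect <- segregation_test(25, 50, 25)
  expect_equal(perfect$chi_square, 0)
  expect_equal(perfect$p_value, 1)
  expect_equal(segregation_test(0, 50, 50)$chi_square, 50)
  expect_equal(segregation_test(100, 200, 100)$chi_square, 0)
  expect_true(is.na(segregation_test(0, 0, 0)$chi_square))
  expect_error(segregation_test(-1, 2, 3), ">= 0")
  # vectorized over markers
  multi <- segregation_test(c(25, 0), c(50, 50), c(25, 50))
  expect_equal(multi$chi_square, c(0, 50))
})

test_that("Bonferroni flagging is monotone in the number of tests", {
  expect_true(flag_distorted(0.04, n_tests = 1))
  expect_false(flag_distorted(0.04, n_tests = 1919))
  expect_true(flag_distorted(0, n_tests = 1919))
  expect_false(flag_distorted(NA_real_, n_tests = 10))
  set.seed(71)
  p <- runif(200)
  n1 <- sum(flag_distorted(p, n_tests = 50))
  n2 <- sum(flag_distorted(p, n_tests = 500))
  expect_gte(n1, n2)
})

test_that("undistorted simulations rarely trigger the distortion flag", {
  tr <- small_truth(lengths = c(90, 90), markers = 40, n = 415,
                    missing_rate = 0.03, seed = 73)
  seg <- marker_segregation(tr$geno)
  flags <- flag_distorted(seg$p_value, n_tests = nrow(seg))
  expect_lte(sum(flags), 3)
})

test_that("selection produces detectably distorted markers", {
  sel <- selection_spec(1, 30, "zygotic", "AA", strength = 0.05)
  cfg <- sim_config(chrom_lengths_cM = 60, markers_per_chromosome = 15,
                    n_individuals = 415, selection = list(sel),
                    missing_rate = 0, seed = 75)
  tr <- simulate_s1_population(simulate_parent(cfg))
  seg <- marker_segregation(truth_phased_geno(tr))
  flags <- flag_distorted(seg$p_value, n_tests = nrow(seg))
  near <- abs(tr$markers$pos_cM - 30) < 10
  expect_true(all(flags[near]))
})

test_that("crossover screen matches a brute-force filter", {
  tr <- small_truth(lengths = c(80, 60), markers = 25, n = 120,
                    missing_rate = 0.03, seed = 77)
  g <- truth_phased_geno(tr)
  groups <- split(tr$markers$marker_id, tr$markers$chromosome)
  scr <- crossover_screen(groups, g, bounds = c(1, 6))
  brute <- vapply(rownames(g), function(i) {
    sum(vapply(groups, function(ord)
      count_obligate_xo(ord, g[i, , drop = FALSE])$total, numeric(1)))
  }, numeric(1))
  expect_equal(setNames(scr$per_individual$n_xo, scr$per_individual$individual),
               brute)
  expect_setequal(scr$flagged, names(brute)[brute < 1 | brute > 6])
  # a non-recombinant individual scores zero
  none <- make_geno(matrix("A", 1, 5))
  expect_equal(crossover_screen(list(colnames(none)), none)$per_individual$n_xo, 0)
})

test_that("Marey statistics detect collinearity, inversions and strays", {
  tr <- small_truth(lengths = 60, markers = 20, n = 50, seed = 79)
  mp <- structure(list(markers = tr$markers$marker_id,
                       pos_cM = setNames(tr$markers$pos_cM,
                                         tr$markers$marker_id)),
                  class = "lg_map")
  mar <- marey_table(list(LG01 = mp), tr$markers)
  expect_equal(mar$groups$spearman_abs, 1)
  expect_equal(mar$groups$n_from_other_scaffold, 0)
  # planted inversion of 6 markers breaks perfect collinearity
  meta_inv <- tr$markers
  meta_inv$pos_bp[8:13] <- rev(meta_inv$pos_bp[8:13])
  mar_inv <- marey_table(list(LG01 = mp), meta_inv)
  expect_lt(mar_inv$groups$spearman_abs, 1)
  expect_gte(mar_inv$groups$discordant_len, 3)
  expect_lte(abs(mar_inv$groups$discordant_start - 8), 2)
  # markers from another scaffold and from a contig are counted
  meta_mix <- tr$markers
  meta_mix$scaffold[3] <- "S09"
  meta_mix$scaffold[5] <- "X394_1"
  mar_mix <- marey_table(list(LG01 = mp), meta_mix)
  expect_equal(mar_mix$groups$n_from_other_scaffold, 1)
  expect_equal(mar_mix$groups$n_from_contig, 1)
})

test_that("map summary reproduces published density and percentage arithmetic", {
  mk_map <- function(n, len, gname) {
    structure(list(markers = sprintf("%s_m%03d", gname, seq_len(n)),
                   pos_cM = setNames(seq(0, len, length.out = n),
                                     sprintf("%s_m%03d", gname, seq_len(n))),
                   length_cM = len), class = "lg_map")
  }
  maps <- list(LG01 = mk_map(168, 87.65, "a"), LG03 = mk_map(191, 63.96, "b"),
               LG06 = mk_map(140, 122.61, "c"))
  dist <- data.frame(marker_id = unlist(lapply(maps, `[[`, "markers")),
                     p_value = 1)
  out <- map_summary(maps, dist)
  expect_equal(out$density_cM[1:3], c(0.52, 0.33, 0.88))
  tot <- out[out$linkage_group == "Total", ]
  expect_equal(tot$n_markers, 168 + 191 + 140)
  expect_equal(tot$length_cM, round(87.65 + 63.96 + 122.61, 2))
  expect_equal(out$pct_distorted, rep(0, 4))
  # percentage cell arithmetic: 92 distorted of 176 markers -> 52.27
  expect_equal(round(100 * 92 / 176, 2), 52.27)
  expect_error(map_summary(list(structure(list(markers = character()),
                                          class = "lg_map")), dist),
               "empty")
})

test_that("scaffold summary totals and genome percentages are exact", {
  scaf <- read.delim(extdata("mint_scaffold_summary.tsv"))
  out <- scaffold_summary(scaf, total_genome_mbp = 536.34)
  s_tot <- out[out$name == "Total" & out$type == "Scaffold", ]
  expect_equal(s_tot$size_mbp, 528.07)
  expect_equal(s_tot$n_targeted, 4846)
  expect_equal(s_tot$n_retained, 1895)
  expect_equal(out$pct_genome[out$name == "S01"], 11.64)
  c_tot <- out[out$name == "Total" & out$type == "Contig", ]
  # row sizes are printed rounded; their sum is within 0.01 of the
  # published 3.10 Mbp contig total
  expect_lt(abs(c_tot$size_mbp - 3.10), 0.011)
  expect_equal(c_tot$n_retained, 24)
  # one scaffold only: 100% of its own genome
  one <- scaffold_summary(data.frame(type = "Scaffold", name = "S01",
                                     size_mbp = 10, n_targeted = 5,
                                     n_retained = 2))
  expect_equal(one$pct_genome, c(100, 100))
})
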