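test_that("individuals below the typed-marker threshold are removed", {
  g <- make_geno(rbind(c("A", "H", "B", "A"),
                       c("A", NA, NA, NA),
                       c(NA, NA, NA, NA)))
  res <- filter_individuals(g, min_markers = 1)
  expect_identical(res$removed, "i03")
  res <- filter_individuals(g, min_markers = 2)
  expect_setequal(res$removed, c("i02", "i03"))
  # threshold is strict "fewer than": typed exactly at threshold is kept
  res <- filter_individuals(g, min_markers = 4)
  expect_identical(rownames(res$geno), "i01")
  # all above threshold: unchanged
  expect_identical(filter_individuals(g, min_markers = 0)$geno, g)
})

test_that("genotype similarity counts matches over shared typed markers", {
  a <- geno_encode(c("A", "H", "B", "A", NA))
  b <- geno_encode(c("A", "H", "A", NA, "B"))
  expect_equal(genotype_similarity(a, a), 1)
  expect_equal(genotype_similarity(a, b), 2 / 3)
  expect_equal(genotype_similarity(geno_encode(c("A", "A")),
                                   geno_encode(c("B", "B"))), 0)
  expect_true(is.na(genotype_similarity(geno_encode(c("A", NA)),
                                        geno_encode(c(NA, "A")))))
  v10 <- geno_encode(c(rep("A", 9), "H"))
  w10 <- geno_encode(c(rep("A", 9), "B"))
  expect_equal(genotype_similarity(v10, w10), 0.9)
})

test_that("duplicate individuals are removed keeping the better-typed member", {
  set.seed(3)
  base <- matrix(sample(0:2, 20 * 40, replace = TRUE), 20, 40)
  dimnames(base) <- list(sprintf("i%02d", 1:20), sprintf("m%02d", 1:40))
  storage.mode(base) <- "integer"
  # plant 5 duplicate pairs at ~95% similarity; copy has extra missing data
  for (k in 1:5) {
    src <- k; dst <- 10 + k
    base[dst, ] <- base[src, ]
    base[dst, sample(40, 2)] <- sample(0:2, 2, replace = TRUE)  # ~95% similar
    base[dst, sample(40, 3)] <- NA
  }
  res <- remove_duplicate_individuals(base, 0.90)
  expect_length(res$removed, 5)
  expect_setequal(res$removed, sprintf("i%02d", 11:15))
  # no pair above threshold: nothing happens
  res2 <- remove_duplicate_individuals(res$geno, 0.999)
  expect_length(res2$removed, 0)
  expect_identical(res2$geno, res$geno)
  # tie in missing data: the larger id goes
  tie <- base[1:2, ]
  tie[2, ] <- tie[1, ]
  expect_identical(remove_duplicate_individuals(tie, 0.9)$removed, "i02")
})

test_that("excess-heterozygosity filter uses a strict 90% threshold", {
  g <- make_geno(rbind(c("H", "H", "H", "A"),
                       c("H", "H", "A", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "H", "B", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "H", "H", "H"),
                       c("H", "A", "H", "H")))
  # m01: 100% H -> removed; m02: exactly 90% -> retained; m03/m04: retained
  res <- filter_excess_het(g, 0.90)
  expect_identical(res$removed, "m01")
  expect_setequal(colnames(res$geno), c("m02", "m03", "m04"))
})

test_that("redundant markers collapse to the best-typed representative", {
  g <- make_geno(rbind(c("A", "A", "A", "B", "A"),
                       c("H", "H", NA, "H", "B"),
                       c("B", "B", "B", "A", "H"),
                       c("A", "A", "A", "B", NA)))
  # m01 and m02 match (m02 has one extra NA) -> keep m01.
  # m04 differs from m01 at every typed individual -> kept.
  res <- collapse_redundant_markers(g)
  expect_true("m01" %in% res$kept)
  expect_true("m02" %in% res$removed)
  expect_true(all(c("m04", "m05") %in% res$kept))
  # planted group of 5 matching markers -> exactly 1 survivor
  set.seed(5)
  base <- matrix(sample(0:2, 30 * 10, replace = TRUE), 30, 10)
  storage.mode(base) <- "integer"
  dimnames(base) <- list(sprintf("i%02d", 1:30), sprintf("m%02d", 1:10))
  for (k in 2:5) {
    base[, k] <- base[, 1]
    base[sample(30, k - 1), k] <- NA  # same calls, increasing missingness
  }
  res2 <- collapse_redundant_markers(base)
  grp <- res2$groups[[which(vapply(res2$groups, function(g) "m01" %in% g,
                                   logical(1)))]]
  expect_setequal(grp, sprintf("m%02d", 1:5))
  expect_identical(intersect(res2$kept, sprintf("m%02d", 1:5)), "m01")
  # markers differing at one doubly-typed individual: both kept
  two <- base[, c(1, 6)]
  two[1, 2] <- (two[1, 1] + 1L) %% 3L
  two[-1, 2] <- two[-1, 1]
  expect_length(collapse_redundant_markers(two)$removed, 0)
})

test_that("filters are idempotent and the cascade accounting balances", {
  set.seed(9)
  g <- matrix(sample(c(0:2, NA), 40 * 60, replace = TRUE,
                     prob = c(0.3, 0.35, 0.3, 0.05)), 40, 60)
  storage.mode(g) <- "integer"
  dimnames(g) <- list(sprintf("i%02d", 1:40), sprintf("m%02d", 1:60))
  params <- filter_params(min_markers_per_individual = 50,
                          min_individuals_per_marker = 30,
                          dup_similarity = 0.9, max_het_fraction = 0.6)
  once <- list(
    filter_individuals(g, 50)$geno,
    filter_markers_by_count(g, 30)$geno,
    remove_duplicate_individuals(g, 0.9)$geno,
    filter_excess_het(g, 0.6)$geno,
    collapse_redundant_markers(g)$geno
  )
  twice <- list(
    filter_individuals(once[[1]], 50)$geno,
    filter_markers_by_count(once[[2]], 30)$geno,
    remove_duplicate_individuals(once[[3]], 0.9)$geno,
    filter_excess_het(once[[4]], 0.6)$geno,
    collapse_redundant_markers(once[[5]])$geno
  )
  for (k in seq_along(once)) expect_identical(twice[[k]], once[[k]])
  res <- filter_cascade(g, params)
  st <- res$stages
  expect_identical(st$stage[1], "input")
  for (k in 2:nrow(st)) {
    expect_equal(st$n_individuals[k],
                 st$n_individuals[k - 1] - st$removed_individuals[k])
    expect_equal(st$n_markers[k], st$n_markers[k - 1] - st$removed_markers[k])
  }
  expect_identical(dim(res$geno),
                   c(st$n_individuals[nrow(st)], st$n_markers[nrow(st)]))
})

test_that("redundancy groups plus singletons partition the marker set", {
  tr <- small_truth(lengths = 30, markers = 25, n = 50, seed = 17)
  g <- tr$geno
  res <- collapse_redundant_markers(g)
  grouped <- unlist(res$groups)
  singles <- setdiff(colnames(g), grouped)
  expect_setequal(c(grouped, singles), colnames(g))
  expect_true(all(vapply(res$groups, function(gr)
    sum(gr %in% res$kept) == 1, logical(1))))
})
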