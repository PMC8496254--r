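test_that("mirror_call complements calls and is an involution", {
  expect_identical(mirror_call(c("A", "A", "H", "B")), c("B", "B", "H", "A"))
  expect_identical(mirror_call(mirror_call(c("A", "H", "B", NA))),
                   c("A", "H", "B", NA))
  expect_identical(mirror_call(c("H", "H")), c("H", "H"))
  expect_identical(mirror_call(geno_encode(c("A", "H", "B"))), c(2L, 1L, 0L))
})

test_that("mirror augmentation doubles the marker set exactly once", {
  g <- make_geno(rbind(c("A", "H"), c("B", NA)))
  aug <- mirror_augment(g)
  expect_equal(ncol(aug$geno), 4)
  expect_identical(aug$geno[, "m01.mir"], mirror_call(g[, "m01"]))
  expect_identical(aug$mirrorset$mirror, paste0(colnames(g), ".mir"))
  expect_error(mirror_augment(aug$geno), "already contains mirror")
  one <- g[, 1, drop = FALSE]
  expect_equal(ncol(mirror_augment(one)$geno), 2)
})

test_that("linkage rule requires both the rf and LOD thresholds", {
  ids <- c("a", "b", "c", "d")
  rf <- matrix(0.4, 4, 4, dimnames = list(ids, ids))
  lod <- matrix(0, 4, 4, dimnames = list(ids, ids))
  diag(rf) <- 0
  rf["a", "b"] <- rf["b", "a"] <- 0.04
  lod["a", "b"] <- lod["b", "a"] <- 12   # linked: passes both
  rf["c", "d"] <- rf["d", "c"] <- 0.04
  lod["c", "d"] <- lod["d", "c"] <- 8    # fails the LOD condition
  tp <- structure(list(markers = ids, rf = rf, lod = lod,
                       n = matrix(100, 4, 4)), class = "twopoint")
  groups <- form_linkage_groups(tp, grouping_params(max_rf = 0.05, min_lod = 10))
  expect_length(groups, 3)
  expect_setequal(groups[[1]], c("a", "b"))
  expect_true(all(c("c", "d") %in% unlist(groups[2:3])))
})

test_that("mirror groups pair up and phase inconsistencies are caught", {
  groups <- list(c("m1", "m2"), c("m1.mir", "m2.mir"), c("m3"))
  mirrorset <- data.frame(original = c("m1", "m2", "m3"),
                          mirror = c("m1.mir", "m2.mir", "m3.mir"))
  pr <- pair_mirror_groups(groups, mirrorset)
  expect_length(pr$pairs, 1)
  expect_identical(sort(pr$pairs[[1]]), c(1L, 2L))
  expect_identical(pr$orphans, 3L)
  bad <- list(c("m1", "m1.mir", "m2"))
  expect_error(pair_mirror_groups(bad, mirrorset), "phase inconsistency.*m1")
})

test_that("resolve_phase keeps one phase-consistent copy per pair", {
  g <- make_geno(matrix(sample(c("A", "H", "B"), 200, replace = TRUE), 10, 20))
  aug <- mirror_augment(g)
  # two mirror pairs (one large, one small) and one orphan
  groups <- list(paste0(sprintf("m%02d", 1:10)),
                 paste0(sprintf("m%02d", 1:10), ".mir"),
                 sprintf("m%02d", 11:14),
                 paste0(sprintf("m%02d", 11:14), ".mir"),
                 "m15")
  pr <- pair_mirror_groups(groups, aug$mirrorset)
  expect_length(pr$pairs, 2)
  res <- resolve_phase(groups, pr, aug$geno, grouping_params(min_group_size = 8))
  # the 4-marker pair is below min_group_size and dropped; orphan dropped
  expect_length(res$groups, 1)
  expect_setequal(res$groups[[1]], sprintf("m%02d", 1:10))
  # retained ids are original ids; no marker coexists with its mirror
  expect_false(any(endsWith(colnames(res$geno), ".mir")))
  expect_identical(unname(res$phase[sprintf("m%02d", 1:10)]),
                   rep(0L, 10))  # group 1 contains the original copies
  expect_identical(res$geno[, "m01"], g[, "m01"])
  expect_length(res$dropped_pairs, 1)
  expect_length(res$orphans, 1)
})

test_that("grouping a simulated genome recovers chromosomes and true phase", {
  tr <- small_truth(lengths = c(60, 45, 50), markers = 30, n = 415, seed = 19,
                    missing_rate = 0.03)
  cm <- call_matrix(simulate_read_counts(tr))
  aug <- mirror_augment(cm$geno)
  tp <- twopoint_all(aug$geno)
  groups <- form_linkage_groups(tp)
  pr <- pair_mirror_groups(groups, aug$mirrorset)
  expect_equal(length(pr$pairs), 3)
  res <- resolve_phase(groups, pr, aug$geno)
  expect_length(res$groups, 3)
  # phase recovery: within each group, assigned phase equals the simulated
  # phase up to one global flip
  truth_phase <- setNames(tr$markers$phase, tr$markers$marker_id)
  for (g in res$groups) {
    agree <- res$phase[g] == truth_phase[g]
    expect_true(all(agree) || all(!agree))
  }
  # markers assigned to groups correspond to chromosomes
  truth_chrom <- setNames(tr$markers$chromosome, tr$markers$marker_id)
  for (g in res$groups) {
    expect_length(unique(truth_chrom[g]), 1)
  }
})

test_that("grouping output is invariant to arbitrary input phase flips", {
  tr <- small_truth(lengths = c(50, 40), markers = 25, n = 300, seed = 29,
                    missing_rate = 0)
  g <- truth_phased_geno(tr)
  run <- function(mat) {
    aug <- mirror_augment(mat)
    tp <- twopoint_all(aug$geno)
    groups <- form_linkage_groups(tp)
    pr <- pair_mirror_groups(groups, aug$mirrorset)
    resolve_phase(groups, pr, aug$geno)
  }
  res1 <- run(g)
  set.seed(77)
  flip <- sample(ncol(g), 12)
  g2 <- g
  g2[, flip] <- 2L - g2[, flip]
  res2 <- run(g2)
  expect_equal(length(res2$groups), length(res1$groups))
  for (k in seq_along(res1$groups)) {
    expect_setequal(res2$groups[[k]], res1$groups[[k]])
    # retained calls identical up to one global flip per group
    a <- res1$geno[, res1$groups[[k]]]
    b <- res2$geno[, res1$groups[[k]]]
    expect_true(identical(a, b) || identical(2L - a, b))
  }
})
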