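# Shared fixtures and independent oracles, built in code at test time.

# Character-call matrix -> encoded dose matrix with ids.
make_geno <- function(calls, individuals = NULL, markers = NULL) {
  g <- geno_encode(calls)
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  if (is.null(individuals)) individuals <- sprintf("i%02d", seq_len(nrow(g)))
  if (is.null(markers)) markers <- sprintf("m%02d", seq_len(ncol(g)))
  dimnames(g) <- list(individuals, markers)
  g
}

# Small simulated population (defaults tuned for test speed).
small_truth <- function(lengths = c(80, 60), markers = 20, n = 150, seed = 11,
                        missing_rate = 0.03, ...) {
  cfg <- sim_config(chrom_lengths_cM = lengths, markers_per_chromosome = markers,
                    n_individuals = n, missing_rate = missing_rate,
                    seed = seed, ...)
  simulate_s1_population(simulate_parent(cfg))
}

# Independent closed-form joint genotype-pair probabilities (S1, coupling),
# derived from the textbook gamete frequencies rather than the package's
# enumeration.
probs_tbl <- function(r) {
  matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
           r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
           r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4),
         3, 3, byrow = TRUE)
}

# Brute-force grid MLE of the recombination fraction for a 3x3 count table.
grid_rf_mle <- function(N, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    P <- probs_tbl(r)
    sum(ifelse(N > 0, N * log(pmax(P, 1e-300)), 0))
  }, numeric(1))
  grid[which.max(ll)]
}

# Exhaustive-enumeration oracle for the obligate crossover count: missing
# calls dropped, then minimize gamete switches over every assignment of
# the heterozygous calls to ordered gamete pairs.
xo_oracle <- function(calls) {
  d <- calls[!is.na(calls)]
  if (length(d) < 2) return(0L)
  hpos <- which(d == 1L)
  base <- ifelse(d == 0L, 0L, ifelse(d == 2L, 1L, NA_integer_))
  best <- Inf
  for (mask in 0:(2^length(hpos) - 1)) {
    a <- base
    b <- base
    if (length(hpos)) {
      bits <- as.integer(intToBits(mask))[seq_along(hpos)]
      a[hpos] <- bits
      b[hpos] <- 1L - bits
    }
    cost <- sum(abs(diff(a))) + sum(abs(diff(b)))
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# Random 3x3 count table with positive total.
rand_count_table <- function() {
  repeat {
    N <- matrix(rpois(9, lambda = sample(c(1, 5, 20, 60), 9, replace = TRUE)), 3, 3)
    if (sum(N) > 0) return(N)
  }
}

extdata <- function(...) {
  system.file("extdata", ..., package = "mirrormap", mustWork = TRUE)
}
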