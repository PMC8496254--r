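# Two-point recombination-fraction / LOD estimation for S1 (F2 intercross)
# genotypes, plus Haldane map-function utilities.

#' Haldane map function and its inverse
#'
#' `haldane_cM(r)` converts a recombination fraction to a genetic distance,
#' d = -50 ln(1 - 2r) cM (no crossover interference); `haldane_inv(d)` is
#' the inverse, r = (1 - exp(-2d/100)) / 2. A fraction of exactly 0.5 maps
#' to `Inf` (unlinked loci).
#'
#' @param r Recombination fraction(s) in [0, 0.5].
#' @param d Distance(s) in cM, >= 0.
#' @return Numeric vector.
#' @examples
#' haldane_cM(0.25)    # 34.657
#' haldane_inv(100)    # 0.43233
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("r must be in [0, 0.5]")
  ifelse(r == 0.5, Inf, -50 * log(1 - 2 * r))
}

#' @rdname haldane_cM
#' @export
haldane_inv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Joint genotype probabilities for a marker pair in an S1 population
#'
#' Probability table P(g1, g2) over genotype pairs in \{A, H, B\}^2 for two
#' loci with recombination fraction `r`, obtained by enumerating the four
#' gamete haplotypes (each of the two gametes is independently recombinant
#' with probability `r`).
#'
#' @param r Recombination fraction in [0, 0.5].
#' @return 3 x 3 matrix with dimnames A/H/B summing to 1.
#' @export
joint_genotype_probs <- function(r) {
  if (r < 0 || r > 0.5) stop("r must be in [0, 0.5]")
  # gamete (allele at locus 1, allele at locus 2), alleles coded 0/1
  gam <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  pg <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  P <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  for (i in 1:4) {
    for (j in 1:4) {
      g1 <- gam[i, 1] + gam[j, 1] + 1L  # dose at locus 1 -> index
      g2 <- gam[i, 2] + gam[j, 2] + 1L
      P[g1, g2] <- P[g1, g2] + pg[i] * pg[j]
    }
  }
  P
}

# Expected number of recombinant gametes given the observed genotype pair
# (the E-step weights). Same-corner cells imply 0 recombinant gametes,
# one-het cells exactly 1, opposite corners 2; the double-het cell is a
# mixture: 2 r^2 / ((1-r)^2 + r^2).
recombinant_weights <- function(r) {
  w_hh <- if (r == 0) 0 else 2 * r^2 / ((1 - r)^2 + r^2)
  matrix(c(0, 1, 2,
           1, w_hh, 1,
           2, 1, 0), 3, 3, byrow = TRUE,
         dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
}

# log10 likelihood of a 3x3 count table at recombination fraction r,
# treating 0 * log(0) as 0.
loglik10_table <- function(counts, r) {
  P <- joint_genotype_probs(r)
  lp <- suppressWarnings(log10(P))
  sum(ifelse(counts > 0, counts * lp, 0))
}

#' Two-point recombination fraction and LOD by EM
#'
#' Estimates the recombination fraction from a 3 x 3 table of joint
#' genotype counts (rows: first marker A/H/B, columns: second marker) by
#' EM, treating the number of recombinant gametes per individual as the
#' missing data. The E-step computes the expected recombinant gametes per
#' observed genotype pair; the M-step sets r to the expected total over
#' 2n. The estimate is clamped to [0, 0.5]; phase-reversed linkage
#' (r > 0.5) is by design reported as 0.5, with the mirror marker carrying
#' the linkage signal. The LOD score compares the likelihood at the
#' estimate against independence (r = 0.5).
#'
#' @param counts 3 x 3 numeric matrix of counts.
#' @param tol Convergence tolerance on r.
#' @param max_iter Maximum EM iterations.
#' @param trace If `TRUE`, also return the per-iteration r path.
#' @return List with `rf`, `lod`, `n` (total count), `n_iter`, and
#'   optionally `trace`.
#' @export
estimate_rf_em <- function(counts, tol = 1e-12, max_iter = 1000, trace = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)))
  n <- sum(counts)
  if (n == 0) return(list(rf = NA_real_, lod = NA_real_, n = 0, n_iter = 0L))
  fixed <- 2 * (counts[1, 3] + counts[3, 1]) +
    counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2]
  n_hh <- counts[2, 2]
  r <- 0.25
  path <- if (trace) numeric(max_iter) else NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- if (r == 0) 0 else 2 * r^2 / ((1 - r)^2 + r^2)
    r_new <- min((fixed + n_hh * w) / (2 * n), 0.5)
    if (trace) path[iter] <- r_new
    if (abs(r_new - r) < tol || iter >= max_iter) {
      r <- r_new
      break
    }
    r <- r_new
  }
  lod <- loglik10_table(counts, r) - loglik10_table(counts, 0.5)
  out <- list(rf = r, lod = lod, n = n, n_iter = iter)
  if (trace) out$trace <- path[seq_len(iter)]
  out
}

# Cross-tabulate two dose vectors into a 3x3 count matrix.
joint_counts <- function(g1, g2) {
  both <- !is.na(g1) & !is.na(g2)
  tab <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  if (any(both)) {
    t0 <- table(factor(g1[both], levels = 0:2), factor(g2[both], levels = 0:2))
    tab[] <- as.numeric(t0)
  }
  tab
}

#' All-pairs two-point analysis
#'
#' Computes recombination fractions and LOD scores for every marker pair
#' by the EM of [estimate_rf_em()], vectorized over the nine joint-genotype
#' cell counts (indicator cross-products; exact numerics, no sampling).
#' Pairs with fewer than `min_cotyped` co-typed individuals are reported
#' as `NA` to avoid unstable estimates.
#'
#' @param geno Integer dose matrix (individuals x markers), >= 2 markers.
#' @param min_cotyped Minimum co-typed individuals per pair.
#' @param tol,max_iter EM controls.
#' @return Object of class `twopoint`: list with `markers`, symmetric `rf`
#'   and `lod` matrices (rf diagonal 0, lod diagonal `NA`), and `n`
#'   (co-typed counts).
#' @export
twopoint_all <- function(geno, min_cotyped = 20, tol = 1e-12, max_iter = 1000) {
  check_geno(geno)
  m <- ncol(geno)
  if (m < 2) stop("need at least 2 markers")
  I0 <- ((!is.na(geno)) & geno == 0) * 1
  I1 <- ((!is.na(geno)) & geno == 1) * 1
  I2 <- ((!is.na(geno)) & geno == 2) * 1
  N11 <- crossprod(I0, I0); N12 <- crossprod(I0, I1); N13 <- crossprod(I0, I2)
  N21 <- crossprod(I1, I0); N22 <- crossprod(I1, I1); N23 <- crossprod(I1, I2)
  N31 <- crossprod(I2, I0); N32 <- crossprod(I2, I1); N33 <- crossprod(I2, I2)
  n_pair <- N11 + N12 + N13 + N21 + N22 + N23 + N31 + N32 + N33
  valid <- n_pair >= min_cotyped
  fixed <- 2 * (N13 + N31) + N12 + N21 + N23 + N32
  denom <- 2 * n_pair
  denom[denom == 0] <- 1
  r <- matrix(0.25, m, m)
  for (iter in seq_len(max_iter)) {
    w <- 2 * r^2 / ((1 - r)^2 + r^2)
    r_new <- pmin((fixed + N22 * w) / denom, 0.5)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  # LOD from cell counts at the converged estimates
  l10 <- function(x) suppressWarnings(log10(x))
  term <- function(N, p, p0) ifelse(N > 0, N * (l10(p) - l10(p0)), 0)
  p_same <- (1 - r)^2 / 4
  p_cross <- r^2 / 4
  p_edge <- r * (1 - r) / 2
  p_hh <- ((1 - r)^2 + r^2) / 2
  lod <- term(N11, p_same, 1 / 16) + term(N33, p_same, 1 / 16) +
    term(N13, p_cross, 1 / 16) + term(N31, p_cross, 1 / 16) +
    term(N12, p_edge, 1 / 8) + term(N21, p_edge, 1 / 8) +
    term(N23, p_edge, 1 / 8) + term(N32, p_edge, 1 / 8) +
    term(N22, p_hh, 1 / 4)
  # exact symmetry (summation order differs across the triangle)
  r <- (r + t(r)) / 2
  lod <- (lod + t(lod)) / 2
  rf <- r
  rf[!valid] <- NA_real_
  lod[!valid] <- NA_real_
  diag(rf) <- 0
  diag(lod) <- NA_real_
  ids <- colnames(geno)
  dimnames(rf) <- dimnames(lod) <- dimnames(n_pair) <- list(ids, ids)
  structure(list(markers = ids, rf = rf, lod = lod, n = n_pair),
            class = "twopoint")
}

#' @export
print.twopoint <- function(x, ...) {
  cat("Two-point analysis:", length(x$markers), "markers;",
      sum(!is.na(x$rf[upper.tri(x$rf)])), "estimable pairs\n")
  invisible(x)
}
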