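# Multipoint genetic-map estimation: hidden Markov model over true
# genotypes {AA, AB, BB} with genotyping error, interval recombination
# fractions fitted by EM (forward-backward), Haldane map function.

# Transition matrix between true genotypes across an interval with
# recombination fraction r: the two gametes recombine independently.
hmm_transition <- function(r) {
  matrix(c((1 - r)^2,     2 * r * (1 - r), r^2,
           r * (1 - r),   (1 - r)^2 + r^2, r * (1 - r),
           r^2,           2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

#' Estimate a multipoint genetic map for an ordered linkage group
#'
#' Hidden Markov model per individual over the true genotypes
#' \{AA, AB, BB\}: the chain starts from the S1 prior (1/4, 1/2, 1/4),
#' interval transitions follow independent recombination of the two
#' gametes at fraction r_k, and the observed call equals the true genotype
#' with probability 1 - `error_prob` (each other class `error_prob`/2;
#' missing calls are uninformative). Interval fractions are fitted by EM:
#' forward-backward yields expected recombinant-gamete counts per
#' interval, and the M-step divides by twice the number of individuals.
#' Converged fractions are mapped to cM with the Haldane function and
#' accumulated from 0 at the first marker.
#'
#' @param order Character vector of marker ids in map order (>= 1).
#' @param geno Integer dose matrix containing those markers.
#' @param error_prob Genotyping error probability in [0, 0.5).
#' @param map_function Only `"haldane"`.
#' @param tol Convergence tolerance on max interval |delta r|.
#' @param max_iter Maximum EM iterations.
#' @param trace If `TRUE`, keep the per-iteration log-likelihood path.
#' @return Object of class `lg_map`: list with `markers`, `pos_cM`
#'   (starting at 0), `rf` (per-interval fractions in [0, 0.5)),
#'   `length_cM`, `loglik10`, `n_ind`, `n_iter`, and optionally
#'   `ll_trace` (natural-log likelihoods).
#' @export
estimate_map <- function(order, geno, error_prob = 1e-4,
                         map_function = "haldane", tol = 1e-9,
                         max_iter = 500, trace = FALSE) {
  map_function <- match.arg(map_function, "haldane")
  check_geno(geno)
  idx <- match(order, colnames(geno))
  if (anyNA(idx)) stop("markers not in matrix: ",
                       paste(order[is.na(idx)], collapse = ", "))
  X <- geno[, idx, drop = FALSE]
  m <- ncol(X)
  n <- nrow(X)
  if (m == 1) {
    return(structure(list(markers = order, pos_cM = setNames(0, order),
                          rf = numeric(0), length_cM = 0, loglik10 = 0,
                          n_ind = n, n_iter = 0L),
                     class = "lg_map"))
  }
  eps <- error_prob
  emis <- vector("list", m)
  for (k in seq_len(m)) {
    obs <- X[, k]
    E <- matrix(1, n, 3)
    for (s in 1:3) {
      E[, s] <- ifelse(is.na(obs), 1, ifelse(obs == s - 1L, 1 - eps, eps / 2))
    }
    emis[[k]] <- E
  }
  # init from adjacent two-point estimates, floored away from 0
  r <- vapply(seq_len(m - 1), function(k) {
    est <- estimate_rf_em(joint_counts(X[, k], X[, k + 1]))
    if (is.na(est$rf)) 0.25 else min(max(est$rf, 1e-4), 0.49)
  }, numeric(1))
  pi0 <- c(0.25, 0.5, 0.25)
  W_edge <- matrix(c(0, 1, 2,
                     1, 0, 1,
                     2, 1, 0), 3, 3, byrow = TRUE)
  alpha <- vector("list", m)
  cscale <- vector("list", m)
  ll <- -Inf
  ll_path <- if (trace) numeric(max_iter) else NULL
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    # forward with per-step scaling
    a <- matrix(pi0, n, 3, byrow = TRUE) * emis[[1]]
    c1 <- rowSums(a)
    a <- a / c1
    alpha[[1]] <- a
    cscale[[1]] <- c1
    for (k in 2:m) {
      Tk <- hmm_transition(r[k - 1])
      a <- (a %*% Tk) * emis[[k]]
      ck <- rowSums(a)
      a <- a / ck
      alpha[[k]] <- a
      cscale[[k]] <- ck
    }
    ll_new <- sum(vapply(cscale, function(ck) sum(log(ck)), numeric(1)))
    if (!is.finite(ll_new)) {
      stop("non-finite multipoint likelihood (interval rfs: ",
           paste(signif(r, 4), collapse = ", "), ")")
    }
    # backward + expected recombinant gametes per interval
    b <- matrix(1, n, 3)
    e_rec <- numeric(m - 1)
    for (k in (m - 1):1) {
      Tk <- hmm_transition(r[k])
      Ebc <- (emis[[k + 1]] * b) / cscale[[k + 1]]
      S <- crossprod(alpha[[k]], Ebc) * Tk
      w_hh <- if (r[k] == 0) 0 else 2 * r[k]^2 / ((1 - r[k])^2 + r[k]^2)
      W <- W_edge
      W[2, 2] <- w_hh
      e_rec[k] <- sum(S * W)
      b <- Ebc %*% t(Tk)
    }
    r_new <- pmin(pmax(e_rec / (2 * n), 0), 0.4999)
    if (trace) ll_path[n_iter] <- ll_new
    done <- max(abs(r_new - r)) < tol || n_iter >= max_iter
    r <- r_new
    ll <- ll_new
    if (done) break
  }
  pos <- cumsum(c(0, haldane_cM(r)))
  names(pos) <- order
  out <- structure(list(markers = order, pos_cM = pos, rf = r,
                        length_cM = pos[[length(pos)]],
                        loglik10 = ll / log(10), n_ind = n, n_iter = n_iter),
                   class = "lg_map")
  if (trace) out$ll_trace <- ll_path[seq_len(n_iter)]
  out
}

#' @export
print.lg_map <- function(x, ...) {
  cat("Linkage-group map:", length(x$markers), "markers,",
      sprintf("%.2f cM", x$length_cM),
      sprintf("(log10 lik %.2f, %d EM iterations)\n", x$loglik10, x$n_iter))
  invisible(x)
}

#' Gap summary of an estimated map
#'
#' @param lg_map An `lg_map` from [estimate_map()], or a numeric vector of
#'   cM positions.
#' @param threshold_cM Gap size above which gaps are counted.
#' @return List with `largest_gap`, `n_above`, and `gaps` (a data frame of
#'   all inter-marker distances).
#' @examples
#' map_gaps(c(0, 5, 31))  # largest 26, one gap > 10
#' @export
map_gaps <- function(lg_map, threshold_cM = 10) {
  pos <- if (inherits(lg_map, "lg_map")) lg_map$pos_cM else as.numeric(lg_map)
  if (length(pos) < 2) {
    return(list(largest_gap = 0, n_above = 0L,
                gaps = data.frame(from = character(), to = character(),
                                  gap_cM = numeric())))
  }
  d <- diff(pos)
  nm <- names(pos)
  if (is.null(nm)) nm <- as.character(seq_along(pos))
  list(largest_gap = max(d), n_above = sum(d > threshold_cM),
       gaps = data.frame(from = nm[-length(nm)], to = nm[-1], gap_cM = d,
                         row.names = NULL))
}
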