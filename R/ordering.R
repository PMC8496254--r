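# Marker ordering within a linkage group: obligate-crossover counting,
# greedy seriation, permuted-sliding-window refinement, and the multi-run
# driver that picks the winning order by multipoint likelihood.

#' Ordering parameters
#'
#' @param window Size of the sliding window of permuted markers (2..8; the
#'   window factorial is enumerated, so 8 is the practical cap).
#' @param error_prob Genotyping error probability used by the multipoint
#'   likelihood ([estimate_map()]).
#' @param n_runs Number of independent seeded ordering runs; the winner is
#'   the order with the highest multipoint log10 likelihood.
#' @param map_function Map function; only `"haldane"` is supported.
#' @param seed Integer seed controlling run starts and random tie-breaks.
#' @return Object of class `ordering_params`.
#' @export
ordering_params <- function(window = 7, error_prob = 1e-4, n_runs = 9,
                            map_function = "haldane", seed = 1L) {
  if (window < 2) stop("window must be >= 2")
  if (window > 8) stop("window is capped at 8 (window! permutations are enumerated)")
  if (error_prob < 0 || error_prob >= 0.5) stop("error_prob must be in [0, 0.5)")
  if (n_runs < 1) stop("n_runs must be >= 1")
  map_function <- match.arg(map_function, "haldane")
  structure(list(window = as.integer(window), error_prob = error_prob,
                 n_runs = as.integer(n_runs), map_function = map_function,
                 seed = as.integer(seed)),
            class = "ordering_params")
}

#' Minimum crossovers consistent with observed genotypes
#'
#' Per individual, the minimum number of recombination events that can
#' explain the ordered call sequence (missing calls skipped), computed by
#' dynamic programming over the four phased genotype states: adjacent
#' A and B calls imply 2 crossovers (both gametes switch), A-H or H-B
#' imply 1.
#'
#' @param order Character vector of marker ids in map order.
#' @param geno Integer dose matrix containing those markers.
#' @return List with `per_individual` (named integer vector) and `total`.
#' @examples
#' g <- matrix(geno_encode(c("A", "A", "H", "B")), 1, 4,
#'             dimnames = list("i1", paste0("m", 1:4)))
#' count_obligate_xo(paste0("m", 1:4), g)$total  # 2
#' @export
count_obligate_xo <- function(order, geno) {
  check_geno(geno)
  idx <- match(order, colnames(geno))
  if (anyNA(idx)) stop("markers not in matrix: ",
                       paste(order[is.na(idx)], collapse = ", "))
  per <- count_xo_cpp(geno, idx - 1L)
  names(per) <- rownames(geno)
  list(per_individual = per, total = sum(per))
}

# Pairwise mean dose-difference distance between markers (the expected
# obligate crossovers a pair contributes per co-typed individual).
marker_dose_dist <- function(geno) {
  I0 <- ((!is.na(geno)) & geno == 0) * 1
  I1 <- ((!is.na(geno)) & geno == 1) * 1
  I2 <- ((!is.na(geno)) & geno == 2) * 1
  typed <- I0 + I1 + I2
  diff1 <- crossprod(I0, I1) + crossprod(I1, I0) +
    crossprod(I1, I2) + crossprod(I2, I1)
  diff2 <- crossprod(I0, I2) + crossprod(I2, I0)
  shared <- crossprod(typed)
  D <- (diff1 + 2 * diff2) / pmax(shared, 1)
  D[shared == 0] <- max(D) + 1  # no information: treat as distant
  dimnames(D) <- list(colnames(geno), colnames(geno))
  D
}

#' Greedy seriation start order
#'
#' Builds a chain by nearest-neighbour extension on the mean pairwise
#' dose-difference distance (the per-individual obligate crossovers a
#' marker pair implies): starting from a randomly chosen marker (current
#' RNG state; seed upstream for determinism), the unplaced marker closest
#' to either chain end is appended there, ties broken by marker id.
#'
#' @param markers Character vector of marker ids (>= 2).
#' @param geno Integer dose matrix.
#' @return Character vector: the chain order.
#' @export
initial_order <- function(markers, geno) {
  if (length(markers) < 2) return(markers)
  D <- marker_dose_dist(geno[, markers, drop = FALSE])
  m <- length(markers)
  start <- sample.int(m, 1L)
  chain <- c(start)
  left <- setdiff(seq_len(m), start)
  while (length(left)) {
    dh <- D[chain[1], left]
    dt <- D[chain[length(chain)], left]
    if (min(dh) < min(dt)) {
      cand <- left[which(dh == min(dh))]
      pick <- cand[order(markers[cand])][1]
      chain <- c(pick, chain)
    } else {
      cand <- left[which(dt == min(dt))]
      pick <- cand[order(markers[cand])][1]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  markers[chain]
}

#' Refine an order with a permuted sliding window
#'
#' Slides a window of `window` markers across the order; at each position
#' all `window!` arrangements are scored by the total obligate crossovers
#' they imply and a minimal one is adopted (ties broken at random using
#' the current RNG state). Passes repeat until a full pass yields no
#' reduction in the crossover total. With `window = 2` this reduces to
#' adjacent-swap hill climbing.
#'
#' @param order Character vector of marker ids.
#' @param geno Integer dose matrix.
#' @param window Window size; shrunk to the group size when larger.
#' @param max_passes Safety cap on the number of passes.
#' @return List with `order`, `total_xo`, and `passes`.
#' @export
ripple_window <- function(order, geno, window = 7, max_passes = 50) {
  check_geno(geno)
  m <- length(order)
  if (m < 2) {
    return(list(order = order,
                total_xo = count_obligate_xo(order, geno)$total, passes = 0L))
  }
  window <- min(window, m)
  if (window < 2) window <- 2L
  if (window > 8) stop("window is capped at 8")
  idx <- match(order, colnames(geno))
  if (anyNA(idx)) stop("markers not in matrix")
  perms <- perm_matrix(as.integer(window)) - 1L
  passes <- 0L
  cur <- idx - 1L
  last_total <- Inf
  repeat {
    passes <- passes + 1L
    res <- ripple_pass_cpp(geno, cur, as.integer(window), perms)
    cur <- res$order
    if (!isTRUE(res$improved) || res$total_xo >= last_total || passes >= max_passes) {
      last_total <- res$total_xo
      break
    }
    last_total <- res$total_xo
  }
  list(order = colnames(geno)[cur + 1L], total_xo = last_total, passes = passes)
}

#' Multipoint log10 likelihood of a marker order
#'
#' Fits the multipoint map for the order with [estimate_map()] and returns
#' the summed log10 likelihood over individuals at the EM-converged map.
#' Reversing an order leaves the likelihood unchanged.
#'
#' @param order Character vector of marker ids.
#' @param geno Integer dose matrix.
#' @param error_prob Genotyping error probability.
#' @return log10 likelihood (scalar).
#' @export
order_likelihood <- function(order, geno, error_prob = 1e-4) {
  estimate_map(order, geno, error_prob = error_prob)$loglik10
}

#' Order the markers of a linkage group
#'
#' Runs `n_runs` independent seeded rounds of greedy seriation
#' ([initial_order()]) followed by sliding-window refinement
#' ([ripple_window()]); candidate orders (deduplicated up to reversal) are
#' compared by multipoint likelihood and the best is returned. The final
#' orientation places physical positions of the majority scaffold in
#' increasing order when `metadata` is supplied, otherwise the end with
#' the lexicographically smaller marker id comes first.
#'
#' @param markers Character vector of marker ids in the group.
#' @param geno Integer dose matrix.
#' @param params An [ordering_params()] object.
#' @param metadata Optional data frame with marker_id, scaffold, pos_bp
#'   used to orient the final order.
#' @return List with `order`, `loglik10`, `total_xo`, and `runs` (per-run
#'   crossover totals and the candidate each run produced).
#' @export
order_markers <- function(markers, geno, params = ordering_params(),
                          metadata = NULL) {
  if (length(markers) < 2) {
    return(list(order = markers, loglik10 = 0, total_xo = 0,
                runs = data.frame(run = integer(), total_xo = numeric(),
                                  candidate = integer())))
  }
  run_seeds <- with_seed(params$seed, sample.int(.Machine$integer.max - 1L,
                                                 params$n_runs))
  candidates <- list()
  cand_key <- character()
  run_log <- data.frame(run = seq_len(params$n_runs), total_xo = NA_real_,
                        candidate = NA_integer_)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  for (k in seq_len(params$n_runs)) {
    set.seed(run_seeds[k])
    ord <- initial_order(markers, geno)
    rip <- ripple_window(ord, geno, params$window)
    key <- paste(c(min(paste(rip$order, collapse = "|"),
                       paste(rev(rip$order), collapse = "|"))), collapse = "")
    hit <- match(key, cand_key)
    if (is.na(hit)) {
      candidates[[length(candidates) + 1L]] <- rip$order
      cand_key <- c(cand_key, key)
      hit <- length(candidates)
    }
    run_log$total_xo[k] <- rip$total_xo
    run_log$candidate[k] <- hit
  }
  lls <- vapply(candidates, order_likelihood, numeric(1),
                geno = geno, error_prob = params$error_prob)
  best <- which.max(lls)
  order <- orient_order(candidates[[best]], metadata)
  list(order = order, loglik10 = lls[best],
       total_xo = count_obligate_xo(order, geno)$total,
       runs = run_log)
}

# Normalize order orientation: majority-scaffold bp increasing when
# metadata is available, else smaller first marker id.
orient_order <- function(order, metadata = NULL) {
  if (!is.null(metadata) &&
      all(c("marker_id", "scaffold", "pos_bp") %in% names(metadata))) {
    meta <- metadata[match(order, metadata$marker_id), ]
    if (!all(is.na(meta$scaffold))) {
      maj <- names(sort(table(meta$scaffold), decreasing = TRUE))[1]
      bp <- meta$pos_bp[!is.na(meta$scaffold) & meta$scaffold == maj]
      pos <- seq_along(order)[!is.na(meta$scaffold) & meta$scaffold == maj]
      if (length(bp) >= 2) {
        rho <- suppressWarnings(cor(pos, bp, method = "spearman"))
        if (!is.na(rho) && rho < 0) return(rev(order))
        if (!is.na(rho)) return(order)
      }
    }
  }
  if (order[1] <= order[length(order)]) order else rev(order)
}
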