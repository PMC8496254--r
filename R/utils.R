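# Shared helpers: genotype codes, union-find, RNG streams.

#' Encode genotype calls as B-allele dose
#'
#' Genotype matrices in this package are integer matrices of the dose of the
#' second parental allele: 0 = A (homozygous first allele), 1 = H
#' (heterozygous), 2 = B (homozygous second allele), `NA` = missing.
#' `geno_encode()` converts character calls (`"A"`, `"H"`, `"B"`, with
#' `"-"`, `""`, `"NA"` and `NA` all read as missing) to dose codes;
#' `geno_decode()` is the inverse and writes `NA` for missing.
#'
#' @param x Character vector or matrix of calls, or (for `geno_decode`)
#'   integer dose codes.
#' @return Integer (resp. character) vector or matrix of the same shape.
#' @examples
#' geno_encode(c("A", "H", "B", "-"))
#' geno_decode(c(0L, 1L, 2L, NA))
#' @export
geno_encode <- function(x) {
  codes <- c(A = 0L, H = 1L, B = 2L)
  v <- as.character(x)
  out <- rep(NA_integer_, length(v))
  known <- v %in% names(codes)
  out[known] <- codes[v[known]]
  bad <- !known & !(is.na(v) | v %in% c("-", "", "NA"))
  if (any(bad)) {
    stop("unknown genotype code(s): ", paste(unique(v[bad]), collapse = ", "))
  }
  if (is.matrix(x)) {
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  out
}

#' @rdname geno_encode
#' @export
geno_decode <- function(x) {
  out <- c("A", "H", "B")[as.integer(x) + 1L]
  if (is.matrix(x)) {
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  out
}

# Validate an encoded genotype matrix (individuals x markers).
check_geno <- function(geno) {
  if (!is.matrix(geno) || !(is.integer(geno) || is.numeric(geno))) {
    stop("genotype matrix must be an integer matrix of doses 0/1/2 (see geno_encode)")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype doses must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix needs individual rownames and marker colnames")
  }
  if (anyDuplicated(rownames(geno))) stop("duplicated individual ids")
  if (anyDuplicated(colnames(geno))) stop("duplicated marker ids")
  invisible(geno)
}

# Connected components by union-find with path halving.
# edge_i/edge_j: integer endpoints in 1..n_items. Returns component labels
# renumbered 1..k in order of first appearance.
union_find_groups <- function(n_items, edge_i, edge_j) {
  parent <- seq_len(n_items)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(edge_i)) {
    ri <- find(edge_i[k])
    rj <- find(edge_j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n_items), find, integer(1))
  match(roots, unique(roots))
}

# Deterministic per-individual seed streams. Drawing with sample.int one
# value at a time keeps the prefix stable when n grows, so enlarging a
# population does not reshuffle previously simulated individuals.
# `stream` offsets the master seed so e.g. meiosis and read-count noise use
# unrelated streams.
derive_stream_seeds <- function(master_seed, n, stream = c("population", "reads")) {
  stream <- match.arg(stream)
  offset <- c(population = 0L, reads = 1000003L)[[stream]]
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed((as.integer(master_seed) + offset) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  code
}

# All permutations of 1..n as a matrix (n! rows); row 1 is the identity.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(
      if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE],
      n,
      if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE],
      deparse.level = 0
    )
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  # reorder so identity comes first and order is lexicographic
  out[do.call(order, as.data.frame(out)), , drop = FALSE]
}

fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
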