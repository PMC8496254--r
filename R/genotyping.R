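# Genotype calling from targeted-capture allele counts.

#' Genotype-calling parameters
#'
#' Thresholds for calling genotypes from per-cell allele depths: cells with
#' depth outside `[min_cov, max_cov]` are missing; with `f` the minor
#' parental-allele fraction, calls are homozygous when `f < homo_minor_max`,
#' heterozygous when both parental fractions are at least `het_min`, and
#' missing for intermediate fractions. Markers for which fewer than
#' `marker_cov_fraction` of individuals have in-range coverage are dropped.
#'
#' @param min_cov,max_cov Acceptable depth range (reads), inclusive.
#' @param homo_minor_max Strict upper bound on the minor-allele fraction
#'   for a homozygous call.
#' @param het_min Inclusive lower bound on both allele fractions for a
#'   heterozygous call.
#' @param marker_cov_fraction Minimum fraction of individuals with in-range
#'   coverage for a marker to be retained.
#' @param fraction_denominator `"parental"` computes allele fractions over
#'   parental reads only (count_a + count_b); `"total"` uses full depth.
#' @return Object of class `call_params`.
#' @export
call_params <- function(min_cov = 20, max_cov = 1000,
                        homo_minor_max = 0.05, het_min = 0.30,
                        marker_cov_fraction = 0.80,
                        fraction_denominator = c("parental", "total")) {
  fraction_denominator <- match.arg(fraction_denominator)
  if (!(min_cov < max_cov)) stop("min_cov must be < max_cov")
  if (!(homo_minor_max >= 0 && homo_minor_max < het_min && het_min <= 0.5)) {
    stop("need 0 <= homo_minor_max < het_min <= 0.5")
  }
  if (marker_cov_fraction < 0 || marker_cov_fraction > 1) {
    stop("marker_cov_fraction must be in [0, 1]")
  }
  structure(list(min_cov = min_cov, max_cov = max_cov,
                 homo_minor_max = homo_minor_max, het_min = het_min,
                 marker_cov_fraction = marker_cov_fraction,
                 fraction_denominator = fraction_denominator),
            class = "call_params")
}

#' Call genotypes from allele counts
#'
#' Vectorized single-cell calling rule. Cells with total depth below
#' `min_cov` or above `max_cov` are `NA`. Otherwise, with fractions of the
#' two parental alleles computed over parental reads (or total depth, per
#' `params`): a homozygous call when the other parental allele is absent or
#' its fraction is strictly below `homo_minor_max`; heterozygous when both
#' fractions are at least `het_min`; `NA` for intermediate situations or
#' when no parental reads are present.
#'
#' @param count_a,count_b,count_other Non-negative read counts (vectors
#'   recycled to a common length).
#' @param params A [call_params()] object.
#' @return Character vector of calls in `A`, `H`, `B`, `NA`.
#' @examples
#' call_genotype(48, 2, 0)   # "A": minor fraction 4% < 5%
#' call_genotype(30, 30, 0)  # "H": both fractions >= 30%
#' call_genotype(40, 10, 0)  # NA: 20% is between 5% and 30%
#' @export
call_genotype <- function(count_a, count_b, count_other = 0,
                          params = call_params()) {
  k <- max(length(count_a), length(count_b), length(count_other))
  a <- rep_len(as.numeric(count_a), k)
  b <- rep_len(as.numeric(count_b), k)
  o <- rep_len(as.numeric(count_other), k)
  if (any(c(a, b, o) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  depth <- a + b + o
  denom <- if (params$fraction_denominator == "parental") a + b else depth
  fa <- ifelse(denom > 0, a / denom, NA_real_)
  fb <- ifelse(denom > 0, b / denom, NA_real_)
  minor <- pmin(fa, fb)
  call <- rep(NA_character_, k)
  in_range <- depth >= params$min_cov & depth <= params$max_cov
  has_par <- in_range & (a + b) > 0
  homo <- has_par & minor < params$homo_minor_max
  call[homo & a >= b] <- "A"
  call[homo & b > a] <- "B"
  call[has_par & minor >= params$het_min] <- "H"
  call
}

#' Call a genotype matrix from an allele-count table
#'
#' Applies [call_genotype()] to every (marker, individual) cell of a long
#' allele-count table, assembles the individuals x markers genotype matrix,
#' and drops markers whose fraction of individuals with in-range coverage
#' falls below `params$marker_cov_fraction`.
#'
#' @param counts Data frame with columns marker_id, individual_id, depth,
#'   count_a, count_b, count_other. Duplicate (marker, individual) rows are
#'   an error. Cells absent from the table are treated as depth 0.
#' @param params A [call_params()] object.
#' @return List with `geno` (integer dose matrix, retained markers only),
#'   `cov_fraction` (named per-marker in-range fraction, all input
#'   markers), and `dropped` (ids of markers removed by the coverage-
#'   fraction rule).
#' @export
call_matrix <- function(counts, params = call_params()) {
  need <- c("marker_id", "individual_id", "depth", "count_a", "count_b", "count_other")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(counts$marker_id, counts$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- counts[duplicated(key), c("marker_id", "individual_id")][1, ]
    stop("duplicate (marker, individual) rows, e.g. ",
         dup$marker_id, " / ", dup$individual_id)
  }
  markers <- sort(unique(counts$marker_id))
  inds <- sort(unique(counts$individual_id))
  calls <- call_genotype(counts$count_a, counts$count_b, counts$count_other, params)
  geno <- matrix(NA_integer_, length(inds), length(markers),
                 dimnames = list(inds, markers))
  geno[cbind(match(counts$individual_id, inds), match(counts$marker_id, markers))] <-
    geno_encode(calls)
  in_range <- counts$depth >= params$min_cov & counts$depth <= params$max_cov
  n_in <- tapply(in_range, counts$marker_id, sum)
  cov_fraction <- as.numeric(n_in)[match(markers, names(n_in))] / length(inds)
  names(cov_fraction) <- markers
  keep <- cov_fraction >= params$marker_cov_fraction
  list(
    geno = geno[, keep, drop = FALSE],
    cov_fraction = cov_fraction,
    dropped = markers[!keep]
  )
}

#' Capture fold-enrichment
#'
#' Ratio of mean on-target to mean off-target coverage.
#'
#' @param on_target_mean_cov,off_target_mean_cov Mean depths.
#' @return List with `fold_enrichment` and logical `infinite` (off-target
#'   mean of zero with positive on-target coverage).
#' @examples
#' enrichment_stats(90, 0.44)$fold_enrichment  # about 204.5
#' @export
enrichment_stats <- function(on_target_mean_cov, off_target_mean_cov) {
  if (on_target_mean_cov < 0 || off_target_mean_cov < 0) {
    stop("mean coverages must be >= 0")
  }
  if (off_target_mean_cov == 0) {
    return(list(fold_enrichment = if (on_target_mean_cov > 0) Inf else NA_real_,
                infinite = on_target_mean_cov > 0))
  }
  list(fold_enrichment = on_target_mean_cov / off_target_mean_cov,
       infinite = FALSE)
}
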