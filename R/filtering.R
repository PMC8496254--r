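# Marker / individual quality-control cascade.

#' Filtering parameters
#'
#' @param min_markers_per_individual Individuals typed at fewer markers are
#'   removed.
#' @param min_individuals_per_marker Markers typed in fewer individuals are
#'   removed.
#' @param dup_similarity Similarity at or above which a pair of individuals
#'   is flagged as a probable double sample.
#' @param max_het_fraction Markers with a heterozygous fraction strictly
#'   above this (among non-missing calls) are removed.
#' @return Object of class `filter_params`.
#' @export
filter_params <- function(min_markers_per_individual = 3500,
                          min_individuals_per_marker = 300,
                          dup_similarity = 0.90,
                          max_het_fraction = 0.90) {
  if (min_markers_per_individual < 0 || min_individuals_per_marker < 0) {
    stop("count thresholds must be >= 0")
  }
  if (dup_similarity < 0 || dup_similarity > 1 ||
      max_het_fraction < 0 || max_het_fraction > 1) {
    stop("fractions must be in [0, 1]")
  }
  structure(list(min_markers_per_individual = min_markers_per_individual,
                 min_individuals_per_marker = min_individuals_per_marker,
                 dup_similarity = dup_similarity,
                 max_het_fraction = max_het_fraction),
            class = "filter_params")
}

#' Remove individuals with excessive missing data
#'
#' @param geno Integer dose matrix (individuals x markers).
#' @param min_markers Minimum number of non-missing calls; individuals with
#'   fewer are removed. Pass the result of [typed_marker_outlier_threshold()]
#'   to derive the threshold from the typed-count distribution instead of
#'   fixing it.
#' @return List with `geno` and `removed` (individual ids).
#' @export
filter_individuals <- function(geno, min_markers = 3500) {
  check_geno(geno)
  typed <- rowSums(!is.na(geno))
  keep <- typed >= min_markers
  list(geno = geno[keep, , drop = FALSE], removed = rownames(geno)[!keep])
}

#' Outlier-scan threshold for typed markers per individual
#'
#' Tukey lower fence (Q1 - 1.5 IQR) of the typed-marker counts, an
#' automatic alternative to a fixed `min_markers` threshold.
#'
#' @param geno Integer dose matrix.
#' @return Numeric threshold.
#' @export
typed_marker_outlier_threshold <- function(geno) {
  typed <- rowSums(!is.na(geno))
  q <- quantile(typed, c(0.25, 0.75), names = FALSE, type = 7)
  q[1] - 1.5 * (q[2] - q[1])
}

#' Remove markers typed in too few individuals
#'
#' @param geno Integer dose matrix.
#' @param min_individuals Minimum number of non-missing calls per marker.
#' @return List with `geno` and `removed` (marker ids).
#' @export
filter_markers_by_count <- function(geno, min_individuals = 300) {
  check_geno(geno)
  typed <- colSums(!is.na(geno))
  keep <- typed >= min_individuals
  list(geno = geno[, keep, drop = FALSE], removed = colnames(geno)[!keep])
}

#' Genotype similarity between two individuals
#'
#' Fraction of matching calls among markers typed in both.
#'
#' @param ind_i,ind_j Dose vectors for two individuals.
#' @return Similarity in [0, 1], or `NA` if no marker is typed in both.
#' @export
genotype_similarity <- function(ind_i, ind_j) {
  both <- !is.na(ind_i) & !is.na(ind_j)
  if (!any(both)) return(NA_real_)
  mean(ind_i[both] == ind_j[both])
}

# All-pairs similarity matrix via indicator cross-products.
similarity_matrix <- function(geno) {
  I0 <- (!is.na(geno)) & geno == 0
  I1 <- (!is.na(geno)) & geno == 1
  I2 <- (!is.na(geno)) & geno == 2
  agree <- tcrossprod(I0 * 1) + tcrossprod(I1 * 1) + tcrossprod(I2 * 1)
  shared <- tcrossprod((!is.na(geno)) * 1)
  sim <- agree / shared
  sim[shared == 0] <- NA_real_
  dimnames(sim) <- list(rownames(geno), rownames(geno))
  sim
}

#' Remove probable double-sampled individuals
#'
#' Pairs with similarity at or above the threshold are flagged; flagged
#' pairs are processed in order of decreasing similarity and, from each
#' pair whose members are both still present, the member with more missing
#' data is removed (ties broken by removing the lexicographically larger
#' id). This greedy pass also resolves transitive clusters.
#'
#' @param geno Integer dose matrix.
#' @param dup_similarity Flagging threshold (inclusive).
#' @return List with `geno`, `removed` (ids), and `pairs` (data frame of
#'   flagged pairs with similarity and the removed member).
#' @export
remove_duplicate_individuals <- function(geno, dup_similarity = 0.90) {
  check_geno(geno)
  empty <- data.frame(ind_i = character(), ind_j = character(),
                      similarity = numeric(), removed = character())
  if (nrow(geno) < 2) return(list(geno = geno, removed = character(), pairs = empty))
  sim <- similarity_matrix(geno)
  sim[lower.tri(sim, diag = TRUE)] <- NA_real_
  hits <- which(sim >= dup_similarity, arr.ind = TRUE)
  if (nrow(hits) == 0) return(list(geno = geno, removed = character(), pairs = empty))
  ids <- rownames(geno)
  ord <- order(-sim[hits], ids[hits[, 1]], ids[hits[, 2]])
  hits <- hits[ord, , drop = FALSE]
  n_na <- rowSums(is.na(geno))
  removed <- character()
  pairs <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    i <- ids[hits[k, 1]]
    j <- ids[hits[k, 2]]
    drop <- if (i %in% removed || j %in% removed) {
      NA_character_
    } else if (n_na[i] != n_na[j]) {
      if (n_na[i] > n_na[j]) i else j
    } else {
      max(i, j)
    }
    if (!is.na(drop)) removed <- c(removed, drop)
    pairs[[k]] <- data.frame(ind_i = i, ind_j = j,
                             similarity = sim[hits[k, 1], hits[k, 2]],
                             removed = drop, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  list(geno = geno[setdiff(ids, removed), , drop = FALSE],
       removed = removed, pairs = pairs)
}

#' Remove markers with excess heterozygosity
#'
#' Markers whose heterozygous fraction among non-missing calls is strictly
#' greater than `max_het_fraction` are removed (a marker at exactly the
#' threshold is retained).
#'
#' @param geno Integer dose matrix.
#' @param max_het_fraction Strict threshold.
#' @return List with `geno` and `removed`.
#' @export
filter_excess_het <- function(geno, max_het_fraction = 0.90) {
  check_geno(geno)
  typed <- colSums(!is.na(geno))
  n_het <- colSums(geno == 1, na.rm = TRUE)
  hfrac <- ifelse(typed > 0, n_het / typed, 0)
  keep <- hfrac <= max_het_fraction
  list(geno = geno[, keep, drop = FALSE], removed = colnames(geno)[!keep])
}

#' Collapse redundant (identical-genotype) markers
#'
#' Two markers "match" when their calls agree at every individual typed in
#' both. Because this relation is not transitive, matches are closed into
#' redundancy groups by union-find, and one marker is kept per group: the
#' one with the least missing data (ties broken by the smallest id).
#'
#' @param geno Integer dose matrix.
#' @return List with `geno` (kept markers), `groups` (list of redundancy
#'   groups of size >= 2), `kept` and `removed`.
#' @export
collapse_redundant_markers <- function(geno) {
  check_geno(geno)
  m <- ncol(geno)
  if (m < 2) {
    return(list(geno = geno, groups = list(), kept = colnames(geno),
                removed = character()))
  }
  I0 <- ((!is.na(geno)) & geno == 0) * 1
  I1 <- ((!is.na(geno)) & geno == 1) * 1
  I2 <- ((!is.na(geno)) & geno == 2) * 1
  typed <- (!is.na(geno)) * 1
  agree <- crossprod(I0) + crossprod(I1) + crossprod(I2)
  shared <- crossprod(typed)
  disagree <- shared - agree
  edges <- which(upper.tri(disagree) & disagree == 0, arr.ind = TRUE)
  labels <- union_find_groups(m, edges[, 1], edges[, 2])
  ids <- colnames(geno)
  n_na <- colSums(is.na(geno))
  keep <- logical(m)
  groups <- list()
  for (g in unique(labels)) {
    members <- which(labels == g)
    best <- members[order(n_na[members], ids[members])][1]
    keep[best] <- TRUE
    if (length(members) > 1) groups[[length(groups) + 1L]] <- ids[members]
  }
  list(geno = geno[, keep, drop = FALSE], groups = groups,
       kept = ids[keep], removed = ids[!keep])
}

#' Run the full quality-control cascade
#'
#' Applies, in order: individual missing-data filter, marker typed-count
#' filter, duplicate-individual removal, excess-heterozygosity filter, and
#' redundant-marker collapse, logging counts at each stage.
#'
#' @param geno Integer dose matrix.
#' @param params A [filter_params()] object.
#' @return List with `geno` (filtered matrix), `stages` (data frame of
#'   per-stage individual/marker counts and removals), and the per-stage
#'   detail objects.
#' @export
filter_cascade <- function(geno, params = filter_params()) {
  check_geno(geno)
  log_stage <- function(stage, geno, rem_ind, rem_mark) {
    data.frame(stage = stage, n_individuals = nrow(geno), n_markers = ncol(geno),
               removed_individuals = rem_ind, removed_markers = rem_mark,
               stringsAsFactors = FALSE)
  }
  stages <- log_stage("input", geno, 0L, 0L)
  s1 <- filter_individuals(geno, params$min_markers_per_individual)
  stages <- rbind(stages, log_stage("individual_missing", s1$geno, length(s1$removed), 0L))
  s2 <- filter_markers_by_count(s1$geno, params$min_individuals_per_marker)
  stages <- rbind(stages, log_stage("marker_count", s2$geno, 0L, length(s2$removed)))
  s3 <- remove_duplicate_individuals(s2$geno, params$dup_similarity)
  stages <- rbind(stages, log_stage("duplicate_individuals", s3$geno, length(s3$removed), 0L))
  s4 <- filter_excess_het(s3$geno, params$max_het_fraction)
  stages <- rbind(stages, log_stage("excess_het", s4$geno, 0L, length(s4$removed)))
  s5 <- collapse_redundant_markers(s4$geno)
  stages <- rbind(stages, log_stage("collapse_redundant", s5$geno, 0L, length(s5$removed)))
  list(geno = s5$geno, stages = stages,
       individuals = s1, marker_counts = s2, duplicates = s3,
       excess_het = s4, redundancy = s5)
}
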