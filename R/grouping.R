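# Mirror-marker augmentation, linkage-group formation, mirror-pair
# resolution and phase assignment.
#
# Unphased selfed-population genotypes are problematic because two linked
# markers recorded in opposite phase look unlinked (their apparent
# recombination fraction exceeds 0.5 and is clamped). Adding, for every
# marker, an artificial "mirror" marker carrying the complementary
# genotype guarantees that for each marker one of the two phase
# orientations shows the true linkage; linkage groups then appear in
# complementary pairs, and keeping one group per pair yields a
# phase-consistent marker set.

MIRROR_SUFFIX <- ".mir"

#' Grouping parameters
#'
#' @param max_rf Maximum recombination fraction for a pair to be linked.
#' @param min_lod Minimum LOD for a pair to be linked (both conditions
#'   must hold).
#' @param min_group_size Mirror group pairs smaller than this are dropped
#'   as unlinked debris.
#' @param expected_chromosomes Optional chromosome count; when given, only
#'   the largest `expected_chromosomes` mirror pairs are retained.
#' @return Object of class `grouping_params`.
#' @export
grouping_params <- function(max_rf = 0.05, min_lod = 10, min_group_size = 8,
                            expected_chromosomes = NULL) {
  if (max_rf <= 0 || max_rf > 0.5) stop("max_rf must be in (0, 0.5]")
  if (min_lod < 0) stop("min_lod must be >= 0")
  structure(list(max_rf = max_rf, min_lod = min_lod,
                 min_group_size = as.integer(min_group_size),
                 expected_chromosomes = expected_chromosomes),
            class = "grouping_params")
}

#' Complement genotype calls
#'
#' Swaps the homozygous classes (A and B), leaving heterozygous and
#' missing calls unchanged; an involution. Accepts dose codes (0/1/2) or
#' character calls.
#'
#' @param call Integer dose vector/matrix or character calls.
#' @return Same type as the input.
#' @examples
#' mirror_call(c("A", "A", "H", "B"))  # "B" "B" "H" "A"
#' @export
mirror_call <- function(call) {
  if (is.character(call)) {
    return(geno_decode(2L - geno_encode(call)))
  }
  2L - call
}

mirror_ids <- function(ids) {
  is_mir <- endsWith(ids, MIRROR_SUFFIX)
  out <- paste0(ids, MIRROR_SUFFIX)
  out[is_mir] <- substr(ids[is_mir], 1L, nchar(ids[is_mir]) - nchar(MIRROR_SUFFIX))
  out
}

strip_mirror_ids <- function(ids) {
  is_mir <- endsWith(ids, MIRROR_SUFFIX)
  ids[is_mir] <- substr(ids[is_mir], 1L, nchar(ids[is_mir]) - nchar(MIRROR_SUFFIX))
  ids
}

#' Add mirror markers to a genotype matrix
#'
#' Appends, for every marker, a complementary "mirror" marker (ids get the
#' reserved suffix `".mir"`), exactly doubling the marker count.
#'
#' @param geno Integer dose matrix.
#' @return List with `geno` (doubled matrix) and `mirrorset`, a data frame
#'   with the original/mirror id bijection.
#' @export
mirror_augment <- function(geno) {
  check_geno(geno)
  ids <- colnames(geno)
  if (any(endsWith(ids, MIRROR_SUFFIX))) {
    stop("matrix already contains mirror markers (reserved suffix '",
         MIRROR_SUFFIX, "')")
  }
  mir <- 2L - geno
  colnames(mir) <- paste0(ids, MIRROR_SUFFIX)
  list(geno = cbind(geno, mir),
       mirrorset = data.frame(original = ids,
                              mirror = paste0(ids, MIRROR_SUFFIX),
                              stringsAsFactors = FALSE))
}

#' Form linkage groups from two-point results
#'
#' Two markers are linked when their recombination fraction is at most
#' `max_rf` AND their LOD is at least `min_lod`; linkage groups are the
#' connected components of this relation (union-find), sorted by
#' decreasing size.
#'
#' @param twopoint A `twopoint` object from [twopoint_all()].
#' @param params A [grouping_params()] object.
#' @return List of character vectors (marker ids), largest group first.
#' @export
form_linkage_groups <- function(twopoint, params = grouping_params()) {
  stopifnot(inherits(twopoint, "twopoint"))
  rf <- twopoint$rf
  lod <- twopoint$lod
  m <- length(twopoint$markers)
  linked <- !is.na(rf) & !is.na(lod) & rf <= params$max_rf & lod >= params$min_lod
  linked[lower.tri(linked, diag = TRUE)] <- FALSE
  edges <- which(linked, arr.ind = TRUE)
  labels <- union_find_groups(m, edges[, 1], edges[, 2])
  groups <- split(twopoint$markers, labels)
  sizes <- lengths(groups)
  first_id <- vapply(groups, function(g) min(g), character(1))
  groups <- groups[order(-sizes, first_id)]
  names(groups) <- NULL
  groups
}

#' Pair complementary linkage groups from a mirror-augmented set
#'
#' On a mirror-augmented marker set, every chromosome should produce two
#' complementary linkage groups. Groups whose mirror-image marker set
#' exactly equals another group are paired (such pairs necessarily have
#' equal sizes); the rest are reported as orphans. A group containing a
#' marker together with its own mirror indicates a phase inconsistency
#' and is an error.
#'
#' @param groups List of marker-id vectors from [form_linkage_groups()].
#' @param mirrorset The bijection from [mirror_augment()].
#' @return List with `pairs` (list of integer 2-vectors: indices into
#'   `groups`) and `orphans` (integer vector of group indices).
#' @export
pair_mirror_groups <- function(groups, mirrorset) {
  for (g in groups) {
    self <- intersect(g, mirror_ids(g))
    if (length(self)) {
      bad <- strip_mirror_ids(self)[1]
      stop("phase inconsistency: group contains both ", bad, " and its mirror")
    }
  }
  keys <- vapply(groups, function(g) paste(sort(g), collapse = "\r"), character(1))
  mirror_keys <- vapply(groups, function(g) paste(sort(mirror_ids(g)), collapse = "\r"),
                        character(1))
  pairs <- list()
  used <- logical(length(groups))
  for (i in seq_along(groups)) {
    if (used[i]) next
    j <- match(mirror_keys[i], keys)
    if (!is.na(j) && j != i && !used[j]) {
      stopifnot(length(groups[[i]]) == length(groups[[j]]))
      pairs[[length(pairs) + 1L]] <- c(i, j)
      used[i] <- used[j] <- TRUE
    }
  }
  orphans <- which(!used)
  list(pairs = pairs, orphans = orphans)
}

#' Resolve phase: keep one group per mirror pair
#'
#' Mirror group pairs carry the same information in complementary phase,
#' so one member of each pair is discarded. The choice is made
#' deterministic: the kept group is the one containing, in its un-mirrored
#' (original-id) form, the lexicographically smallest underlying marker id
#' of the pair. Pairs smaller than `min_group_size` markers are dropped,
#' as are orphan groups; when `expected_chromosomes` is set only the
#' largest pairs up to that count are retained. Retained markers get their
#' original ids back; their calls are the phase-consistent (possibly
#' complemented) versions.
#'
#' @param groups List of marker-id vectors from [form_linkage_groups()].
#' @param pairing Result of [pair_mirror_groups()].
#' @param geno_aug The mirror-augmented dose matrix.
#' @param params A [grouping_params()] object.
#' @return List with `geno` (phased matrix, original ids), `groups` (list
#'   of original-id vectors per retained linkage group, largest first),
#'   `phase` (named 0/1 vector: 1 when the mirror orientation was kept),
#'   and `dropped_pairs` / `orphans` (marker-id lists).
#' @export
resolve_phase <- function(groups, pairing, geno_aug, params = grouping_params()) {
  check_geno(geno_aug)
  keep_pairs <- pairing$pairs
  sizes <- vapply(keep_pairs, function(p) length(groups[[p[1]]]), integer(1))
  big <- sizes >= params$min_group_size
  dropped <- keep_pairs[!big]
  keep_pairs <- keep_pairs[big]
  sizes <- sizes[big]
  if (!is.null(params$expected_chromosomes) &&
      length(keep_pairs) > params$expected_chromosomes) {
    ord <- order(-sizes)
    sel <- ord[seq_len(params$expected_chromosomes)]
    dropped <- c(dropped, keep_pairs[-sel])
    keep_pairs <- keep_pairs[sel]
  }
  out_groups <- vector("list", length(keep_pairs))
  phase <- integer(0)
  for (k in seq_along(keep_pairs)) {
    p <- keep_pairs[[k]]
    g1 <- groups[[p[1]]]
    g2 <- groups[[p[2]]]
    smallest <- min(strip_mirror_ids(c(g1, g2)))
    keep <- if (smallest %in% g1) g1 else g2
    ph <- as.integer(endsWith(keep, MIRROR_SUFFIX))
    ids <- strip_mirror_ids(keep)
    ord <- order(ids)
    out_groups[[k]] <- ids[ord]
    phase <- c(phase, setNames(ph[ord], ids[ord]))
    names(out_groups)[k] <- NULL
  }
  ord <- order(-lengths(out_groups),
               vapply(out_groups, function(g) if (length(g)) min(g) else "",
                      character(1)))
  out_groups <- out_groups[ord]
  retained <- unlist(out_groups, use.names = FALSE)
  # extract retained (phase-consistent) columns and restore original ids
  aug_ids <- ifelse(phase[retained] == 1L,
                    paste0(retained, MIRROR_SUFFIX), retained)
  geno <- geno_aug[, aug_ids, drop = FALSE]
  colnames(geno) <- retained
  list(geno = geno, groups = out_groups, phase = phase[retained],
       dropped_pairs = lapply(dropped, function(p)
         strip_mirror_ids(groups[[p[1]]])),
       orphans = lapply(pairing$orphans, function(i)
         strip_mirror_ids(groups[[i]])))
}
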