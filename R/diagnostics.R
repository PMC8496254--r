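# Map diagnostics: segregation distortion, crossover screens, Marey
# (genetic vs physical) comparison, and summary tables.

#' Chi-square segregation test against the 1:2:1 expectation
#'
#' In an S1 (selfed) population the genotype classes AA, AB, BB are
#' expected in proportions 25:50:25. This tests each marker's non-missing
#' counts against that expectation (goodness of fit, df = 2, no continuity
#' correction).
#'
#' @param n_AA,n_H,n_BB Non-negative count vectors (recycled).
#' @return Data frame with columns n_AA, n_H, n_BB, chi_square, p_value;
#'   markers with zero total get `NA` statistics.
#' @examples
#' segregation_test(0, 50, 50)$chi_square  # 50
#' @export
segregation_test <- function(n_AA, n_H, n_BB) {
  k <- max(length(n_AA), length(n_H), length(n_BB))
  o <- cbind(rep_len(n_AA, k), rep_len(n_H, k), rep_len(n_BB, k))
  if (any(o < 0)) stop("counts must be >= 0")
  n <- rowSums(o)
  e <- cbind(n * 0.25, n * 0.5, n * 0.25)
  chi <- ifelse(n > 0, rowSums((o - e)^2 / ifelse(e > 0, e, 1)), NA_real_)
  p <- pchisq(chi, df = 2, lower.tail = FALSE)
  data.frame(n_AA = o[, 1], n_H = o[, 2], n_BB = o[, 3],
             chi_square = chi, p_value = p)
}

#' Per-marker genotype counts and distortion test
#'
#' @param geno Integer dose matrix.
#' @return Data frame (one row per marker): marker_id, counts,
#'   chi_square, p_value.
#' @export
marker_segregation <- function(geno) {
  check_geno(geno)
  res <- segregation_test(colSums(geno == 0, na.rm = TRUE),
                          colSums(geno == 1, na.rm = TRUE),
                          colSums(geno == 2, na.rm = TRUE))
  cbind(data.frame(marker_id = colnames(geno), stringsAsFactors = FALSE), res)
}

#' Bonferroni distortion flags
#'
#' A marker is flagged as distorted when its p-value is below
#' `alpha / n_tests`.
#'
#' @param p_value Numeric vector of p-values.
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests corrected for; defaults to the number of
#'   markers tested.
#' @return Logical vector (`NA` p-values give `FALSE`).
#' @export
flag_distorted <- function(p_value, alpha = 0.05, n_tests = length(p_value)) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  !is.na(p_value) & p_value < alpha / n_tests
}

#' Per-individual crossover screen
#'
#' Sums the obligate crossover counts of every individual across all
#' linkage groups of a map and flags individuals outside the given
#' bounds. Flagged individuals are reported, never removed.
#'
#' @param group_orders List of ordered marker-id vectors (one per linkage
#'   group), e.g. the `markers` of each `lg_map`.
#' @param geno Integer dose matrix.
#' @param bounds Optional length-2 numeric vector; individuals with totals
#'   outside `[bounds[1], bounds[2]]` are flagged.
#' @return List with `per_individual` (data frame: individual, n_xo) and
#'   `flagged` (ids).
#' @export
crossover_screen <- function(group_orders, geno, bounds = NULL) {
  check_geno(geno)
  total <- setNames(numeric(nrow(geno)), rownames(geno))
  for (ord in group_orders) {
    total <- total + count_obligate_xo(ord, geno)$per_individual
  }
  flagged <- character()
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2)
    flagged <- names(total)[total < bounds[1] | total > bounds[2]]
  }
  list(per_individual = data.frame(individual = names(total), n_xo = as.numeric(total),
                                   row.names = NULL, stringsAsFactors = FALSE),
       flagged = flagged)
}

#' Marey comparison of genetic and physical positions
#'
#' Links each mapped marker to its physical metadata and, per linkage
#' group, reports the majority scaffold, how many markers come from other
#' scaffolds or from unintegrated contigs, the absolute Spearman
#' correlation between cM and bp among majority-scaffold markers
#' (collinearity), and the longest contiguous block of physical steps
#' running against the dominant direction (a candidate inversion).
#'
#' @param maps List of `lg_map` objects (or ordered marker-id vectors with
#'   an attached `pos_cM`), named or numbered by linkage group.
#' @param metadata Data frame with marker_id, scaffold, pos_bp.
#' @param contig_pattern Regular expression identifying unintegrated
#'   contigs among scaffold ids.
#' @return List with `markers` (per-marker group, cM, scaffold, bp) and
#'   `groups` (per-group collinearity statistics, including
#'   `discordant_start`/`discordant_len`, the longest counter-direction
#'   block among majority-scaffold markers).
#' @export
marey_table <- function(maps, metadata, contig_pattern = "^X") {
  need <- c("marker_id", "scaffold", "pos_bp")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  marker_rows <- list()
  group_rows <- list()
  for (g in seq_along(maps)) {
    mp <- maps[[g]]
    ord <- if (inherits(mp, "lg_map")) mp$markers else as.character(mp)
    pos <- if (inherits(mp, "lg_map")) mp$pos_cM else attr(mp, "pos_cM")
    gname <- names(maps)[g]
    if (is.null(gname) || !nzchar(gname)) gname <- sprintf("LG%02d", g)
    meta <- metadata[match(ord, metadata$marker_id), ]
    if (anyNA(meta$marker_id)) {
      stop("metadata missing for mapped marker(s): ",
           paste(ord[is.na(meta$marker_id)], collapse = ", "))
    }
    marker_rows[[g]] <- data.frame(
      marker_id = ord, linkage_group = gname, pos_cM = as.numeric(pos),
      scaffold = meta$scaffold, pos_bp = meta$pos_bp,
      stringsAsFactors = FALSE
    )
    maj <- names(sort(table(meta$scaffold), decreasing = TRUE))[1]
    on_maj <- meta$scaffold == maj
    rho <- NA_real_
    disc_start <- NA_integer_
    disc_len <- 0L
    if (sum(on_maj) >= 3) {
      cM <- as.numeric(pos)[on_maj]
      bp <- meta$pos_bp[on_maj]
      rho <- abs(suppressWarnings(cor(cM, bp, method = "spearman")))
      dirn <- sign(suppressWarnings(cor(cM, bp, method = "spearman")))
      step_bad <- sign(diff(bp)) * dirn < 0
      if (any(step_bad)) {
        runs <- rle(step_bad)
        best <- which(runs$values)[which.max(runs$lengths[runs$values])]
        disc_len <- runs$lengths[best]
        disc_start <- c(0L, cumsum(runs$lengths))[best] + 1L
      }
    }
    group_rows[[g]] <- data.frame(
      linkage_group = gname, n_markers = length(ord),
      majority_scaffold = maj,
      n_from_other_scaffold = sum(!on_maj & !grepl(contig_pattern, meta$scaffold)),
      n_from_contig = sum(grepl(contig_pattern, meta$scaffold)),
      spearman_abs = rho,
      discordant_start = disc_start, discordant_len = disc_len,
      stringsAsFactors = FALSE
    )
  }
  list(markers = do.call(rbind, marker_rows),
       groups = do.call(rbind, group_rows))
}

#' Per-linkage-group map summary table
#'
#' One row per linkage group: marker count, markers from other scaffolds
#' and from unintegrated contigs, marker density (length / n, 2 decimals),
#' map length, largest gap, gaps above the threshold, and distortion
#' counts; plus a totals row.
#'
#' @param maps List of `lg_map` objects.
#' @param distortion Data frame from [marker_segregation()] covering the
#'   mapped markers (flags are computed at `alpha` over the total mapped
#'   marker count).
#' @param metadata Optional physical metadata (marker_id, scaffold,
#'   pos_bp) for the scaffold columns.
#' @param gap_threshold_cM Gap-count threshold.
#' @param alpha Family-wise error rate for the Bonferroni distortion flag.
#' @param contig_pattern Regular expression identifying contigs.
#' @return Data frame with one row per group and a final `Total` row.
#' @export
map_summary <- function(maps, distortion, metadata = NULL,
                        gap_threshold_cM = 10, alpha = 0.05,
                        contig_pattern = "^X") {
  if (!length(maps)) stop("no linkage groups")
  for (mp in maps) {
    if (length(mp$markers) == 0) stop("empty linkage group")
  }
  n_total <- sum(vapply(maps, function(m) length(m$markers), integer(1)))
  flags <- setNames(flag_distorted(distortion$p_value, alpha, n_total),
                    distortion$marker_id)
  marey <- if (!is.null(metadata)) marey_table(maps, metadata, contig_pattern) else NULL
  rows <- vector("list", length(maps))
  for (g in seq_along(maps)) {
    mp <- maps[[g]]
    gname <- names(maps)[g]
    if (is.null(gname) || !nzchar(gname)) gname <- sprintf("LG%02d", g)
    gaps <- map_gaps(mp, gap_threshold_cM)
    nd <- sum(flags[mp$markers], na.rm = TRUE)
    nm <- length(mp$markers)
    rows[[g]] <- data.frame(
      linkage_group = gname,
      n_markers = nm,
      n_from_other_scaffold = if (is.null(marey)) NA_integer_ else
        marey$groups$n_from_other_scaffold[g],
      n_from_contig = if (is.null(marey)) NA_integer_ else
        marey$groups$n_from_contig[g],
      density_cM = round(mp$length_cM / nm, 2),
      length_cM = round(mp$length_cM, 2),
      largest_gap_cM = round(gaps$largest_gap, 2),
      n_gaps_above = gaps$n_above,
      n_distorted = nd,
      pct_distorted = round(100 * nd / nm, 2),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  total_len <- sum(vapply(maps, function(m) m$length_cM, numeric(1)))
  totals <- data.frame(
    linkage_group = "Total",
    n_markers = sum(out$n_markers),
    n_from_other_scaffold = if (is.null(marey)) NA_integer_ else
      sum(out$n_from_other_scaffold),
    n_from_contig = if (is.null(marey)) NA_integer_ else sum(out$n_from_contig),
    density_cM = round(total_len / sum(out$n_markers), 2),
    length_cM = round(total_len, 2),
    largest_gap_cM = max(out$largest_gap_cM),
    n_gaps_above = sum(out$n_gaps_above),
    n_distorted = sum(out$n_distorted),
    pct_distorted = round(100 * sum(out$n_distorted) / sum(out$n_markers), 2),
    stringsAsFactors = FALSE
  )
  rbind(out, totals)
}

#' Scaffold-level summary of targeted and retained markers
#'
#' Per-scaffold (and contig) totals: size, percent of the genome, and
#' marker counts, with per-type totals rows.
#'
#' @param scaffolds Data frame with columns type (e.g. "Scaffold" /
#'   "Contig"), name, size_mbp, n_targeted, n_retained.
#' @param total_genome_mbp Genome size used as the percentage denominator;
#'   defaults to the sum of `size_mbp` (pass the assembly total to account
#'   for untargeted sequence).
#' @param digits Decimal places for the percent column.
#' @return Data frame with per-scaffold rows plus one totals row per type.
#' @export
scaffold_summary <- function(scaffolds, total_genome_mbp = NULL, digits = 2) {
  need <- c("type", "name", "size_mbp", "n_targeted", "n_retained")
  if (!all(need %in% names(scaffolds))) {
    stop("scaffolds must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(total_genome_mbp)) total_genome_mbp <- sum(scaffolds$size_mbp)
  rows <- scaffolds
  rows$pct_genome <- round(100 * rows$size_mbp / total_genome_mbp, digits)
  totals <- do.call(rbind, lapply(split(rows, rows$type), function(d) {
    data.frame(type = d$type[1], name = "Total",
               size_mbp = sum(d$size_mbp),
               n_targeted = sum(d$n_targeted), n_retained = sum(d$n_retained),
               pct_genome = round(100 * sum(d$size_mbp) / total_genome_mbp, digits),
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  rbind(rows[c(need, "pct_genome")], totals[c(need, "pct_genome")])
}
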