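# Truth-known S1 population simulator: meiosis under the Haldane model
# (Poisson crossovers, no interference), optional selection, and a
# negative-binomial / binomial read-count emission model.

# Genetic lengths (cM) of the 12 apple-mint linkage groups used as the
# default simulated genome.
MINT_LG_LENGTHS_CM <- c(
  87.65, 89.48, 63.96, 77.20, 66.11, 122.61,
  84.09, 58.26, 56.32, 92.64, 57.72, 86.14
)

#' Simulation configuration for an S1 capture-genotyping experiment
#'
#' Defines the simulated genome (chromosome genetic lengths and marker
#' placement), population size, the read-count emission model, and any
#' selection acting on the population. Defaults emulate the apple-mint
#' mapping experiment: 12 chromosomes with the published linkage-group
#' lengths, n = 415 selfed individuals, mean target coverage 96 reads with
#' an overdispersed (negative-binomial) tail, and 3\% missing data.
#'
#' @param chrom_lengths_cM Numeric vector of chromosome genetic lengths in
#'   centimorgans. Default: the 12 published linkage-group lengths.
#' @param markers_per_chromosome Either a single count, a vector of counts
#'   (one per chromosome), or a list of strictly increasing cM position
#'   vectors (explicit marker placement). Counts place markers evenly from
#'   0 to the chromosome length.
#' @param n_individuals Number of S1 individuals to simulate.
#' @param coverage_mean Mean sequencing depth per (marker, individual) cell.
#' @param coverage_dispersion Negative-binomial size parameter; default
#'   `coverage_mean / 2`, which gives variance of about three times the mean
#'   (a long right tail like real capture data).
#' @param seq_error_rate Per-read probability of a miscalled base.
#' @param missing_rate Fraction of cells with no data (depth 0).
#' @param selection List of [selection_spec()] objects.
#' @param coldspot_weight,coldspot_scale Shape of the monotone cM-to-bp map
#'   used to assign synthetic physical positions: a logistic "coldspot"
#'   component of this weight and steepness is mixed with a linear term so
#'   that each chromosome has a region of large physical span per cM
#'   (compare a Marey-map sigmoid).
#' @param mbp_per_cM Average physical megabases per cM used to size
#'   synthetic scaffolds.
#' @param seed Master integer seed; all randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_parent()], [simulate_s1_population()],
#'   [simulate_read_counts()]
#' @export
sim_config <- function(chrom_lengths_cM = MINT_LG_LENGTHS_CM,
                       markers_per_chromosome = 100,
                       n_individuals = 415,
                       coverage_mean = 96,
                       coverage_dispersion = NULL,
                       seq_error_rate = 0.001,
                       missing_rate = 0.03,
                       selection = list(),
                       coldspot_weight = 0.6,
                       coldspot_scale = 0.06,
                       mbp_per_cM = 0.56,
                       seed = 1L) {
  if (any(!is.finite(chrom_lengths_cM)) || any(chrom_lengths_cM <= 0)) {
    stop("chromosome lengths must be positive")
  }
  n_chrom <- length(chrom_lengths_cM)
  if (is.list(markers_per_chromosome)) {
    if (length(markers_per_chromosome) != n_chrom) {
      stop("need one marker position vector per chromosome")
    }
    for (i in seq_len(n_chrom)) {
      pos <- markers_per_chromosome[[i]]
      if (any(diff(pos) <= 0)) {
        stop("marker positions must be strictly increasing (chromosome ", i, ")")
      }
      if (any(pos < 0) || any(pos > chrom_lengths_cM[i])) {
        stop("marker positions outside chromosome ", i)
      }
    }
  } else {
    counts <- rep_len(as.integer(markers_per_chromosome), n_chrom)
    if (any(counts < 1)) stop("markers_per_chromosome must be >= 1")
    markers_per_chromosome <- counts
  }
  for (p in c(seq_error_rate, missing_rate)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("rates must be probabilities in [0, 1]")
  }
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (coverage_mean < 0) stop("coverage_mean must be >= 0")
  if (is.null(coverage_dispersion)) coverage_dispersion <- coverage_mean / 2
  if (coverage_dispersion <= 0) stop("coverage_dispersion must be > 0")
  if (!is.list(selection)) stop("selection must be a list of selection_spec objects")
  if (inherits(selection, "selection_spec")) selection <- list(selection)
  for (s in selection) {
    if (!inherits(s, "selection_spec")) stop("selection entries must be selection_spec objects")
    if (s$chromosome < 1 || s$chromosome > n_chrom) stop("selection chromosome out of range")
    if (s$position_cM < 0 || s$position_cM > chrom_lengths_cM[s$chromosome]) {
      stop("selection locus outside its chromosome")
    }
  }
  structure(list(
    chrom_lengths_cM = as.numeric(chrom_lengths_cM),
    markers_per_chromosome = markers_per_chromosome,
    n_individuals = as.integer(n_individuals),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    seq_error_rate = seq_error_rate,
    missing_rate = missing_rate,
    selection = selection,
    coldspot_weight = coldspot_weight,
    coldspot_scale = coldspot_scale,
    mbp_per_cM = mbp_per_cM,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specify a selection locus for the simulator
#'
#' Selection acts at a cM position on a chromosome, on the labels of the two
#' parental haplotypes there (allele "A" = haplotype 1, allele "B" =
#' haplotype 2). `zygotic` selection rejects zygotes of the disfavored
#' genotype (`"AA"` or `"BB"`) with probability `1 - strength`;
#' `gametic_one_sex` rejects gametes carrying the disfavored allele (`"A"`
#' or `"B"`) in one of the two gamete draws; `gametic_both` does so in both.
#'
#' @param chromosome Chromosome index.
#' @param position_cM Position of the selected locus in cM.
#' @param mode One of `"zygotic"`, `"gametic_one_sex"`, `"gametic_both"`.
#' @param disfavored Genotype `"AA"`/`"BB"` (zygotic) or allele `"A"`/`"B"`
#'   (gametic).
#' @param strength Survival probability of the disfavored class, in [0, 1].
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(chromosome, position_cM,
                           mode = c("zygotic", "gametic_one_sex", "gametic_both"),
                           disfavored, strength = 0) {
  mode <- match.arg(mode)
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (mode == "zygotic") {
    if (!disfavored %in% c("AA", "BB")) {
      stop("zygotic selection needs disfavored genotype 'AA' or 'BB'")
    }
  } else if (!disfavored %in% c("A", "B")) {
    stop("gametic selection needs disfavored allele 'A' or 'B'")
  }
  structure(list(
    chromosome = as.integer(chromosome),
    position_cM = as.numeric(position_cM),
    mode = mode,
    disfavored = disfavored,
    strength = strength
  ), class = "selection_spec")
}

# Monotone cM -> physical-fraction map with a steep central "coldspot".
coldspot_bp_fraction <- function(u, weight, scale) {
  lo <- stats::plogis(-0.5 / scale)
  hi <- stats::plogis(0.5 / scale)
  sig <- (stats::plogis((u - 0.5) / scale) - lo) / (hi - lo)
  (1 - weight) * u + weight * sig
}

#' Simulate the heterozygous parent: markers, alleles and phase
#'
#' Builds the truth skeleton for a simulated mapping experiment: marker
#' positions on each chromosome, two distinct parental alleles per marker
#' (every marker heterozygous in the parent, as targeted capture markers
#' are by design), a random linkage phase per marker, and synthetic
#' physical coordinates via a monotone cM-to-bp map with a compressed
#' central recombination coldspot.
#'
#' Phase is recorded as 0/1: phase 0 means parental haplotype 1 carries
#' allele A (`allele_a`) at that marker, phase 1 means haplotype 1 carries
#' allele B. Randomizing phase per marker makes downstream mirror-marker
#' phasing a genuine inference problem.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: list with `config` and a
#'   `markers` data frame (marker_id, chromosome, pos_cM, scaffold, pos_bp,
#'   allele_a, allele_b, phase).
#' @export
simulate_parent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_chrom <- length(config$chrom_lengths_cM)
    rows <- vector("list", n_chrom)
    bases <- c("A", "C", "G", "T")
    for (ch in seq_len(n_chrom)) {
      L <- config$chrom_lengths_cM[ch]
      pos <- if (is.list(config$markers_per_chromosome)) {
        config$markers_per_chromosome[[ch]]
      } else {
        k <- config$markers_per_chromosome[ch]
        if (k == 1) L / 2 else seq(0, L, length.out = k)
      }
      m <- length(pos)
      size_bp <- round(L * config$mbp_per_cM * 1e6)
      frac <- coldspot_bp_fraction(pos / L, config$coldspot_weight, config$coldspot_scale)
      bp <- as.integer(pmax(1, round(frac * size_bp)))
      # enforce strict monotonicity after rounding
      bp <- bp + cumsum(c(0L, as.integer(diff(bp) <= 0)))
      allele_idx <- t(vapply(seq_len(m), function(i) sample.int(4L, 2L), integer(2)))
      phase <- sample(0:1, m, replace = TRUE)
      rows[[ch]] <- data.frame(
        marker_id = sprintf("S%02d_%09d", ch, bp),
        chromosome = ch,
        pos_cM = pos,
        scaffold = sprintf("S%02d", ch),
        pos_bp = bp,
        allele_a = bases[allele_idx[, 1]],
        allele_b = bases[allele_idx[, 2]],
        phase = phase,
        stringsAsFactors = FALSE
      )
    }
    markers <- do.call(rbind, rows)
    rownames(markers) <- NULL
    structure(list(config = config, markers = markers), class = "sim_truth")
  })
}

#' Simulate one gamete from the parent
#'
#' Crossover count on a chromosome of genetic length L cM is Poisson with
#' mean L/100 (Haldane model, no interference); breakpoint positions are
#' uniform; the starting parental haplotype is chosen uniformly. Uses the
#' current RNG state (callers control seeding).
#'
#' @param truth A `sim_truth` from [simulate_parent()].
#' @param chromosome Chromosome index.
#' @return List with `start_hap` (1 or 2), sorted `breaks_cM`, and
#'   `hap_at_marker`, the haplotype (1/2) carried at each marker of the
#'   chromosome in map order.
#' @export
simulate_gamete <- function(truth, chromosome) {
  stopifnot(inherits(truth, "sim_truth"))
  L <- truth$config$chrom_lengths_cM[chromosome]
  if (is.na(L)) stop("no such chromosome: ", chromosome)
  n_xo <- rpois(1L, L / 100)
  breaks <- sort(runif(n_xo, 0, L))
  start <- sample(1:2, 1L)
  pos <- truth$markers$pos_cM[truth$markers$chromosome == chromosome]
  list(
    start_hap = start,
    breaks_cM = breaks,
    hap_at_marker = gamete_hap_at(start, breaks, pos)
  )
}

# Haplotype carried at arbitrary cM positions given start haplotype and
# sorted breakpoints.
gamete_hap_at <- function(start_hap, breaks_cM, pos_cM) {
  n_before <- findInterval(pos_cM, breaks_cM)
  1L + (start_hap - 1L + n_before) %% 2L
}

# Evaluate a selection spec against one gamete: TRUE if it carries the
# disfavored allele at the locus.
gamete_carries_disfavored <- function(gam, spec) {
  hap <- gamete_hap_at(gam$start_hap, gam$breaks_cM, spec$position_cM)
  allele <- c("A", "B")[hap]
  allele == spec$disfavored
}

draw_gamete_set <- function(truth, specs_for_slot, max_attempts = 10000L) {
  n_chrom <- length(truth$config$chrom_lengths_cM)
  for (attempt in seq_len(max_attempts)) {
    gams <- lapply(seq_len(n_chrom), function(ch) simulate_gamete(truth, ch))
    ok <- TRUE
    for (spec in specs_for_slot) {
      if (gamete_carries_disfavored(gams[[spec$chromosome]], spec) &&
          runif(1) >= spec$strength) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(gams)
  }
  stop("gametic selection rejection cap reached (", max_attempts, " attempts)")
}

#' Simulate an S1 population with optional selection
#'
#' Each individual is the fusion of two independently drawn gametes per
#' chromosome. Gametic selection is applied by rejection sampling during
#' the gamete draws (slot 1 only for `gametic_one_sex`, both slots for
#' `gametic_both`); zygotic selection rejects whole zygotes of the
#' disfavored genotype with probability `1 - strength`. Rejection loops are
#' capped at 10,000 attempts.
#'
#' Per-individual RNG streams are derived from the master seed, so
#' enlarging `n_individuals` leaves earlier individuals unchanged.
#'
#' @param truth A `sim_truth` from [simulate_parent()].
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @return The `sim_truth` augmented with: `geno`, an individuals x markers
#'   integer matrix of true B-allele doses (0/1/2) in physical allele
#'   coordinates; `crossovers`, a data frame of breakpoints (individual,
#'   gamete slot, chromosome, pos_cM); and `gamete_starts`.
#' @export
simulate_s1_population <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- config$n_individuals
  mk <- truth$markers
  m <- nrow(mk)
  seeds <- derive_stream_seeds(config$seed, n, "population")
  specs <- config$selection
  zygotic <- Filter(function(s) s$mode == "zygotic", specs)
  gam1_specs <- Filter(function(s) s$mode != "zygotic", specs)
  gam2_specs <- Filter(function(s) s$mode == "gametic_both", specs)
  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(sprintf("ind%04d", seq_len(n)), mk$marker_id))
  xo_rows <- vector("list", n)
  starts <- matrix(NA_integer_, n, 2L)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    for (attempt in seq_len(10000L)) {
      g1 <- draw_gamete_set(truth, gam1_specs)
      g2 <- draw_gamete_set(truth, gam2_specs)
      ok <- TRUE
      for (spec in zygotic) {
        h1 <- gamete_hap_at(g1[[spec$chromosome]]$start_hap,
                            g1[[spec$chromosome]]$breaks_cM, spec$position_cM)
        h2 <- gamete_hap_at(g2[[spec$chromosome]]$start_hap,
                            g2[[spec$chromosome]]$breaks_cM, spec$position_cM)
        geno_label <- paste0(c("A", "B")[sort(c(h1, h2))], collapse = "")
        geno_label <- c("AA" = "AA", "AB" = "AB", "BB" = "BB")[[geno_label]]
        if (geno_label == spec$disfavored && runif(1) >= spec$strength) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
      if (attempt == 10000L) stop("zygotic selection rejection cap reached")
    }
    hap1 <- unlist(lapply(g1, `[[`, "hap_at_marker"))
    hap2 <- unlist(lapply(g2, `[[`, "hap_at_marker"))
    # physical allele is B when (haplotype 2 and phase 0) or (haplotype 1
    # and phase 1)
    b1 <- as.integer((hap1 == 2L) != (mk$phase == 1L))
    b2 <- as.integer((hap2 == 2L) != (mk$phase == 1L))
    geno[i, ] <- b1 + b2
    brk <- lapply(seq_along(g1), function(ch) {
      rbind(
        if (length(g1[[ch]]$breaks_cM)) {
          data.frame(individual = rownames(geno)[i], gamete = 1L,
                     chromosome = ch, pos_cM = g1[[ch]]$breaks_cM)
        },
        if (length(g2[[ch]]$breaks_cM)) {
          data.frame(individual = rownames(geno)[i], gamete = 2L,
                     chromosome = ch, pos_cM = g2[[ch]]$breaks_cM)
        }
      )
    })
    xo_rows[[i]] <- do.call(rbind, brk)
    starts[i, ] <- c(g1[[1]]$start_hap, g2[[1]]$start_hap)
  }
  xo <- do.call(rbind, xo_rows)
  if (is.null(xo)) {
    xo <- data.frame(individual = character(), gamete = integer(),
                     chromosome = integer(), pos_cM = numeric())
  }
  rownames(xo) <- NULL
  truth$geno <- geno
  truth$crossovers <- xo
  truth$gamete_starts <- starts
  truth$config <- config
  truth
}

#' Simulate capture read counts from true genotypes
#'
#' Depth per (marker, individual) cell is negative-binomial around
#' `coverage_mean`; a `missing_rate` fraction of cells is zeroed. Within a
#' cell, miscalled ("other") reads are Binomial(depth, e); the remaining
#' parental reads split A vs B by Binomial with the A-read probability
#' 1 - e, 1/2, or e for true genotypes AA, AB, BB (e = `seq_error_rate`).
#'
#' @param truth A `sim_truth` containing `geno` (see
#'   [simulate_s1_population()]).
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @return Data frame with columns marker_id, individual_id, depth,
#'   count_a, count_b, count_other (an allele-count table).
#' @export
simulate_read_counts <- function(truth, config = truth$config) {
  if (is.null(truth$geno)) stop("simulate the population first")
  geno <- truth$geno
  n <- nrow(geno)
  m <- ncol(geno)
  e <- config$seq_error_rate
  seeds <- derive_stream_seeds(config$seed, n, "reads")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  out <- vector("list", n)
  p_a <- c(1 - e, 0.5, e)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    depth <- rnbinom(m, mu = config$coverage_mean, size = config$coverage_dispersion)
    depth[runif(m) < config$missing_rate] <- 0L
    other <- rbinom(m, depth, e)
    rem <- depth - other
    count_a <- rbinom(m, rem, p_a[geno[i, ] + 1L])
    out[[i]] <- data.frame(
      marker_id = colnames(geno),
      individual_id = rownames(geno)[i],
      depth = as.integer(depth),
      count_a = as.integer(count_a),
      count_b = as.integer(rem - count_a),
      count_other = as.integer(other),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("S1 simulation truth:", length(x$config$chrom_lengths_cM), "chromosomes,",
      nrow(x$markers), "markers")
  if (!is.null(x$geno)) cat(",", nrow(x$geno), "individuals")
  cat("\n  total map length:", sum(x$config$chrom_lengths_cM), "cM\n")
  invisible(x)
}

#' Phase-consistent true genotype matrix
#'
#' The physical-allele genotype matrix (`truth$geno`) is unphased: which
#' homozygote is "A" at a marker depends on the marker's random phase.
#' This accessor returns genotypes in haplotype coordinates (dose of the
#' parental haplotype-2 allele), i.e. with every marker in a consistent
#' phase — the matrix a perfect phasing step would recover, used to
#' evaluate ordering and map estimation against truth.
#'
#' @param truth A `sim_truth` containing `geno`.
#' @return Integer dose matrix like `truth$geno`.
#' @export
truth_phased_geno <- function(truth) {
  if (is.null(truth$geno)) stop("simulate the population first")
  geno <- truth$geno
  flip <- truth$markers$phase == 1L
  geno[, flip] <- 2L - geno[, flip]
  geno
}
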