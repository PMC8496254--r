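# Readers and writers for the on-disk formats. All writers are
# deterministic (stable ordering, numbers at 6 significant digits) so
# identical inputs give byte-identical files. gzip is handled
# transparently through R connections (a ".gz" path works everywhere).

open_out <- function(path) {
  if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
}

write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  con <- open_out(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv_checked <- function(path, columns, classes) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  df <- df[columns]
  for (j in seq_along(columns)) {
    cls <- classes[j]
    if (cls == "integer") {
      v <- suppressWarnings(as.integer(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]))
      if (length(bad)) {
        stop("malformed value in ", path, " column '", columns[j],
             "' at line ", bad[1] + 1L)
      }
      df[[j]] <- v
    } else if (cls == "numeric") {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]))
      if (length(bad)) {
        stop("malformed value in ", path, " column '", columns[j],
             "' at line ", bad[1] + 1L)
      }
      df[[j]] <- v
    } else {
      df[[j]] <- as.character(df[[j]])
    }
  }
  df
}

#' Read and write allele-count tables
#'
#' Tab-separated table with header columns marker_id, individual_id,
#' depth, count_a, count_b, count_other; writing then reading returns an
#' identical data frame. Counts must satisfy
#' `count_a + count_b + count_other == depth`.
#'
#' @param path File path (`.gz` accepted).
#' @param counts Allele-count data frame (see [simulate_read_counts()]).
#' @return `read_allele_counts`: the validated data frame.
#' @export
read_allele_counts <- function(path) {
  cols <- c("marker_id", "individual_id", "depth", "count_a", "count_b",
            "count_other")
  df <- read_tsv_checked(path, cols,
                         c("character", "character", "integer", "integer",
                           "integer", "integer"))
  bad <- which(df$count_a + df$count_b + df$count_other != df$depth |
                 df$count_a < 0 | df$count_b < 0 | df$count_other < 0)
  if (length(bad)) {
    stop("counts do not sum to depth in ", path, " at line ", bad[1] + 1L)
  }
  df
}

#' @rdname read_allele_counts
#' @export
write_allele_counts <- function(counts, path) {
  cols <- c("marker_id", "individual_id", "depth", "count_a", "count_b",
            "count_other")
  write_tsv_det(counts[cols], path)
}

#' Read and write marker metadata
#'
#' Tab-separated table with columns marker_id, scaffold, pos_bp (1-based),
#' allele_a, allele_b.
#'
#' @param path File path (`.gz` accepted).
#' @param metadata Metadata data frame.
#' @return `read_marker_metadata`: the validated data frame.
#' @export
read_marker_metadata <- function(path) {
  cols <- c("marker_id", "scaffold", "pos_bp", "allele_a", "allele_b")
  df <- read_tsv_checked(path, cols,
                         c("character", "character", "integer", "character",
                           "character"))
  if (any(df$pos_bp < 1)) stop("pos_bp must be >= 1 in ", path)
  df
}

#' @rdname read_marker_metadata
#' @export
write_marker_metadata <- function(metadata, path) {
  cols <- c("marker_id", "scaffold", "pos_bp", "allele_a", "allele_b")
  write_tsv_det(metadata[cols], path)
}

#' Read and write genotype matrices in the intercross cross-CSV dialect
#'
#' Layout: row 1 holds the individual-id column header followed by marker
#' ids; row 2 the linkage group of each marker; row 3 the cM position
#' (blank allowed before mapping); the body holds one individual per row
#' with calls in A/H/B and `-` for missing (`NA` and empty cells are also
#' accepted on read, `-` only is written). Writing then reading restores
#' the matrix, groups and positions.
#'
#' @param path File path (`.gz` accepted).
#' @param geno Integer dose matrix.
#' @param groups Optional per-marker group labels (named or in column
#'   order).
#' @param pos_cM Optional per-marker positions.
#' @return `read_cross_csv`: list with `geno`, `groups`, `pos_cM`.
#' @export
read_cross_csv <- function(path) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 4) stop("cross CSV needs header rows plus individuals")
  markers <- as.character(raw[1, -1])
  groups <- as.character(raw[2, -1])
  pos <- suppressWarnings(as.numeric(raw[3, -1]))
  body <- raw[-(1:3), , drop = FALSE]
  inds <- body[[1]]
  calls <- as.matrix(body[, -1, drop = FALSE])
  ok <- calls %in% c("A", "H", "B", "-", "", "NA") | is.na(calls)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", calls[bad[1], bad[2]], "' at individual ",
         inds[bad[1]], ", marker ", markers[bad[2]])
  }
  geno <- geno_encode(calls)
  dimnames(geno) <- list(inds, markers)
  groups[!nzchar(groups)] <- NA_character_
  list(geno = geno, groups = setNames(groups, markers),
       pos_cM = setNames(pos, markers))
}

#' @rdname read_cross_csv
#' @export
write_cross_csv <- function(geno, path, groups = NULL, pos_cM = NULL) {
  check_geno(geno)
  markers <- colnames(geno)
  pick <- function(x) {
    if (is.null(x)) return(rep("", length(markers)))
    if (!is.null(names(x))) x <- x[markers]
    out <- as.character(x)
    out[is.na(out)] <- ""
    out
  }
  grp <- pick(groups)
  pos <- if (is.null(pos_cM)) rep("", length(markers)) else {
    v <- if (!is.null(names(pos_cM))) pos_cM[markers] else pos_cM
    ifelse(is.na(v), "", fmt_num(as.numeric(v)))
  }
  calls <- geno_decode(geno)
  calls[is.na(calls)] <- "-"
  lines <- c(
    paste(c("id", markers), collapse = ","),
    paste(c("", grp), collapse = ","),
    paste(c("", pos), collapse = ","),
    vapply(seq_len(nrow(geno)), function(i) {
      paste(c(rownames(geno)[i], calls[i, ]), collapse = ",")
    }, character(1))
  )
  con <- open_out(path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read allele counts from a VCF with per-sample allele depths
#'
#' Extracts the two parental alleles of each metadata marker from the AD
#' (allele depth) FORMAT field of a VCF; sites are matched to metadata by
#' contig and position. Depth of alleles other than the two parental ones
#' counts as `count_other`. Sites absent from the metadata are skipped
#' with a warning giving the count. Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param metadata Marker metadata (see [read_marker_metadata()]).
#' @return Allele-count data frame as in [read_allele_counts()].
#' @export
read_vcf_allele_depths <- function(path, metadata) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_allele_depths requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fmt <- v@gt[, 1]
  if (!any(grepl("(^|:)AD(:|$)", fmt))) stop("VCF has no AD FORMAT field")
  ad <- vcfR::extract.gt(v, element = "AD")
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  mkey <- paste(metadata$scaffold, metadata$pos_bp)
  hit <- match(key, mkey)
  n_skip <- sum(is.na(hit))
  if (n_skip) warning(n_skip, " VCF site(s) absent from metadata; skipped")
  rows <- list()
  for (i in which(!is.na(hit))) {
    m <- metadata[hit[i], ]
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    depths <- lapply(strsplit(ad[i, ], ","), function(x)
      suppressWarnings(as.integer(x)))
    ia <- match(m$allele_a, alleles)
    ib <- match(m$allele_b, alleles)
    get <- function(d, j) if (!is.na(j) && j <= length(d) && !is.na(d[j])) d[j] else 0L
    ca <- vapply(depths, get, integer(1), j = ia)
    cb <- vapply(depths, get, integer(1), j = ib)
    tot <- vapply(depths, function(d) sum(d, na.rm = TRUE), integer(1))
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = m$marker_id, individual_id = colnames(ad),
      depth = tot, count_a = ca, count_b = cb, count_other = tot - ca - cb,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(marker_id = character(), individual_id = character(),
                      depth = integer(), count_a = integer(),
                      count_b = integer(), count_other = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a genetic map as TSV
#'
#' One row per mapped marker (marker_id, linkage_group, position_cM, and,
#' when metadata is given, scaffold and pos_bp), sorted by group then
#' position; positions start at 0 within each group.
#'
#' @param maps Named list of `lg_map` objects.
#' @param path Output path.
#' @param metadata Optional marker metadata.
#' @return The path, invisibly.
#' @export
write_map_tsv <- function(maps, path, metadata = NULL) {
  rows <- lapply(seq_along(maps), function(g) {
    mp <- maps[[g]]
    gname <- names(maps)[g]
    if (is.null(gname) || !nzchar(gname)) gname <- sprintf("LG%02d", g)
    data.frame(marker_id = mp$markers, linkage_group = gname,
               position_cM = as.numeric(mp$pos_cM), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    hit <- match(df$marker_id, metadata$marker_id)
    df$scaffold <- metadata$scaffold[hit]
    df$pos_bp <- metadata$pos_bp[hit]
  }
  df <- df[order(df$linkage_group, df$position_cM, df$marker_id), ]
  rownames(df) <- NULL
  write_tsv_det(df, path)
}

#' Read a structured pipeline configuration
#'
#' YAML (or JSON, a YAML subset) file with sections mirroring the
#' parameter objects: `sim`, `calling`, `filtering`, `grouping`,
#' `ordering`, plus optional `paths` and `seed`.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
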