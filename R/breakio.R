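#' Extract UMI and sample barcode from raw read sequences
#'
#' DSB end-capture libraries carry an 8-nt unique molecular identifier (UMI)
#' followed by an 8-nt sample barcode at the 5' end of read 1. Reads
#' shorter than 16 nt, reads whose prefix contains characters outside
#' {A,C,G,T,N}, and (when a whitelist is supplied) reads whose barcode is
#' not whitelisted are rejected with a reason.
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `read` column.
#' @param whitelist optional character vector of allowed barcodes.
#' @return tibble with `umi`, `barcode`, `read_trimmed`, `accepted` and
#'   `reason` (NA when accepted).
#' @export
#' @examples
#' extract_umi_barcode("AAAAAAAACCCCCCCCGATTACA")
extract_umi_barcode <- function(reads, whitelist = NULL) {
  if (is.data.frame(reads)) reads <- reads$read
  reads <- unname(as.character(reads))
  out <- tibble(
    read = reads,
    umi = substr(reads, 1L, 8L),
    barcode = substr(reads, 9L, 16L),
    read_trimmed = substr(reads, 17L, nchar(reads)))
  out$reason <- NA_character_
  bad_alpha <- grepl("[^ACGTN]", paste0(out$umi, out$barcode))
  out$reason[bad_alpha] <- "invalid_prefix_alphabet"
  if (!is.null(whitelist)) {
    out$reason[!out$barcode %in% whitelist & is.na(out$reason)] <-
      "barcode_not_in_whitelist"
  }
  short <- nchar(out$read) < 16L
  out$reason[short] <- "too_short"
  out$umi[short] <- NA_character_
  out$barcode[short] <- NA_character_
  out$read_trimmed[short] <- NA_character_
  out$accepted <- is.na(out$reason)
  select(out, "umi", "barcode", "read_trimmed", "accepted", "reason")
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @return tibble with `id` and `read`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = names(x), read = as.character(x))
}

#' Retain uniquely-mapping read ends
#'
#' Keeps aligned records with mapping quality at or above `min_mapq`
#' (default 60, the score assigned to uniquely placed reads by common
#' short-read aligners). Input order is preserved.
#'
#' @param ends tibble of aligned read ends with a `mapq` column.
#' @param min_mapq minimum retained mapping quality.
#' @return filtered tibble.
#' @export
filter_mapq <- function(ends, min_mapq = 60L) {
  filter(ends, .data$mapq >= min_mapq)
}

## Hamming distance between one UMI and a set; N mismatches every base
umi_hamming <- function(umi, umis) {
  a <- utf8ToInt(umi)
  n_code <- utf8ToInt("N")
  vapply(umis, function(u) {
    b <- utf8ToInt(u)
    sum(a != b | a == n_code | b == n_code)
  }, integer(1), USE.NAMES = FALSE)
}

## UMI strings -> integer matrix; N encoded as 0 (mismatches everything)
umi_int_matrix <- function(umi) {
  m <- matrix(utf8ToInt(paste(umi, collapse = "")), nrow = length(umi),
              byrow = TRUE)
  m[m == utf8ToInt("N")] <- 0L
  m
}

## greedy positional/UMI clustering within one (barcode, chrom, strand) group;
## records must arrive sorted by pos0. Anchors accumulate in position order,
## so the live window is a contiguous tail tracked with two pointers.
cluster_group <- function(pos0, umat, window_bp, max_umi_mismatch) {
  n <- length(pos0)
  w <- ncol(umat)
  keep <- logical(n)
  a_pos <- integer(n)
  a_mat <- matrix(0L, n, w)
  lo <- 1L; hi <- 0L
  for (i in seq_len(n)) {
    while (lo <= hi && a_pos[lo] < pos0[i] - window_bp) lo <- lo + 1L
    dup <- FALSE
    if (lo <= hi) {
      block <- a_mat[lo:hi, , drop = FALSE]
      rec <- umat[i, ]
      diffs <- block != rep(rec, each = hi - lo + 1L)
      if (any(rec == 0L)) diffs[, rec == 0L] <- TRUE
      diffs[block == 0L] <- TRUE
      dup <- any(rowSums(diffs) <= max_umi_mismatch)
    }
    if (!dup) {
      keep[i] <- TRUE
      hi <- hi + 1L
      a_pos[hi] <- pos0[i]
      a_mat[hi, ] <- umat[i, ]
    }
  }
  keep
}

#' Remove PCR duplicates from aligned break ends
#'
#' Within each sample barcode, chromosome and strand, records are scanned
#' in position order; a record is considered a close PCR duplicate and
#' dropped when its position lies within `window_bp` of an open cluster
#' anchor and its UMI is within `max_umi_mismatch` Hamming mismatches of
#' the anchor's UMI (`N` mismatches every base). The first-seen record of
#' each cluster is the surviving molecule, at its own position. Records on
#' opposite strands are never clustered together.
#'
#' `dedup_keep()` returns the surviving records; [dedup_ends()] aggregates
#' them into a per-position pileup.
#'
#' @param ends tibble of aligned read ends (`chrom`, `pos0`, `strand`,
#'   `umi`, `barcode`).
#' @param window_bp clustering window in bp.
#' @param max_umi_mismatch maximum UMI Hamming distance; `-1` disables
#'   fuzzy matching so that only exact (position, UMI) duplicates collapse.
#' @return `dedup_keep()`: the surviving records; `dedup_ends()`: a pileup
#'   tibble (`chrom`, `pos0`, `strand`, `count`).
#' @export
dedup_keep <- function(ends, window_bp = 30L, max_umi_mismatch = 2L) {
  if (nrow(ends) == 0L) return(ends)
  if (any(grepl("[^ACGTN]", ends$umi))) {
    stop("malformed UMI: alphabet must be {A,C,G,T,N}", call. = FALSE)
  }
  if (max_umi_mismatch < 0L) {
    return(distinct(ends, .data$barcode, .data$chrom, .data$strand,
                    .data$pos0, .data$umi, .keep_all = TRUE))
  }
  ## exact (position, UMI) duplicates always collapse under the fuzzy rule
  ## too, so fold them first; first-seen order is preserved
  ends <- distinct(ends, .data$barcode, .data$chrom, .data$strand,
                   .data$pos0, .data$umi, .keep_all = TRUE)
  ends <- arrange(ends, .data$barcode, .data$chrom, .data$strand, .data$pos0)
  grp <- paste(ends$barcode, ends$chrom, ends$strand, sep = "\r")
  umat <- umi_int_matrix(ends$umi)
  keep <- logical(nrow(ends))
  for (idx in split(seq_len(nrow(ends)), factor(grp, levels = unique(grp)))) {
    keep[idx] <- cluster_group(ends$pos0[idx], umat[idx, , drop = FALSE],
                               window_bp, max_umi_mismatch)
  }
  ends[keep, ]
}

#' @rdname dedup_keep
#' @export
dedup_ends <- function(ends, window_bp = 30L, max_umi_mismatch = 2L) {
  kept <- dedup_keep(ends, window_bp, max_umi_mismatch)
  if (nrow(kept) == 0L) {
    return(tibble(chrom = character(0), pos0 = integer(0),
                  strand = character(0), count = integer(0)))
  }
  kept |>
    count(.data$chrom, .data$pos0, .data$strand, name = "count") |>
    arrange(.data$chrom, .data$pos0, .data$strand)
}

#' Read and write break-end pileups as BED6
#'
#' Pileups are stored as BED6 with the unique-molecule count in the score
#' column (`chrom`, `start`, `start + 1`, `.`, `count`, `strand`).
#' `write_pileup_bed()` followed by `read_pileup_bed()` is the identity on
#' canonically sorted records.
#'
#' @param path file path.
#' @param standard_chroms_only drop records on non-standard contigs
#'   (see [is_standard_chrom()]).
#' @return `read_pileup_bed()`: pileup tibble (`chrom`, `pos0`, `strand`,
#'   `count`).
#' @export
read_pileup_bed <- function(path, standard_chroms_only = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": expected 6 tab-separated fields",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end != start + 1L |
                 is.na(score) | score < 1 | !m[, 6] %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": ", lines[bad[1]], call. = FALSE)
  }
  out <- tibble(chrom = m[, 1], pos0 = start, strand = m[, 6],
                count = as.integer(score))
  if (standard_chroms_only) out <- filter(out, is_standard_chrom(.data$chrom))
  arrange(out, .data$chrom, .data$pos0, .data$strand)
}

#' @rdname read_pileup_bed
#' @param pileup pileup tibble to write.
#' @export
write_pileup_bed <- function(pileup, path) {
  stopifnot(all(c("chrom", "pos0", "strand", "count") %in% names(pileup)))
  pileup <- arrange(pileup, .data$chrom, .data$pos0, .data$strand)
  bed <- tibble(chrom = pileup$chrom, start = pileup$pos0,
                end = pileup$pos0 + 1L, name = ".",
                score = pileup$count, strand = pileup$strand)
  write_atomic(function(tmp) {
    readr::write_tsv(bed, tmp, col_names = FALSE)
  }, path)
}

#' Read a guide RNA table
#'
#' @param path TSV with columns `name` and `spacer` (20-nt, ACGT).
#' @return tibble of guides.
#' @export
read_guides <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "spacer") %in% names(g)))
  assert_spacer(g$spacer)
  as_tibble(g[, c("name", "spacer")])
}
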