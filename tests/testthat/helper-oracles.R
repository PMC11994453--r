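## shared fixture builders and independent oracles

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

make_ends <- function(chrom, pos0, strand, umi = NULL, barcode = "ACGTACGT",
                      mapq = 60L) {
  n <- max(length(chrom), length(pos0), length(strand), length(umi),
           length(barcode))
  if (is.null(umi)) {
    umi <- vapply(seq_len(n), function(.) rand_seq(8), "")
  }
  tibble::tibble(chrom = rep_len(chrom, n), pos0 = rep_len(pos0, n),
                 strand = rep_len(strand, n), umi = rep_len(umi, n),
                 barcode = rep_len(barcode, n), mapq = rep_len(mapq, n))
}

make_pileup <- function(chrom, pos0, strand, count) {
  n <- max(length(chrom), length(pos0), length(strand), length(count))
  tibble::tibble(chrom = rep_len(chrom, n), pos0 = rep_len(pos0, n),
                 strand = rep_len(strand, n), count = rep_len(count, n))
}

empty_pileup <- function() make_pileup(character(0), integer(0),
                                       character(0), integer(0))[0, ]

## brute-force all-positions Hamming scan for candidate protospacers
## (independent of find_candidate_sites: plain substring arithmetic)
brute_force_candidates <- function(chr_str, chrom, spacer, max_mm = 7L,
                                   pam_regex = "^.GG$") {
  len <- nchar(chr_str)
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  rows <- list()
  for (s1 in seq_len(len - 22L)) {        # 1-based protospacer start, + strand
    pam <- substr(chr_str, s1 + 20L, s1 + 22L)
    if (!grepl(pam_regex, pam)) next
    proto <- substr(chr_str, s1, s1 + 19L)
    if (grepl("[^ACGT]", proto)) next
    d <- ham(proto, spacer)
    if (d <= max_mm) {
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = s1 - 1L, strand = "+",
                   n_mismatches = d)
    }
  }
  for (s1 in 4:(len - 19L)) {             # - strand; PAM left of the match
    pam <- rc(substr(chr_str, s1 - 3L, s1 - 1L))
    if (!grepl(pam_regex, pam)) next
    proto <- rc(substr(chr_str, s1, s1 + 19L))
    if (grepl("[^ACGT]", proto)) next
    d <- ham(proto, spacer)
    if (d <= max_mm) {
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = s1 - 1L, strand = "-",
                   n_mismatches = d)
    }
  }
  do.call(rbind, rows)
}

## direct Poisson upper-tail summation
poisson_tail <- function(obs, lambda) {
  sum(dpois(seq.int(obs, obs + max(200L, 20L * ceiling(lambda))), lambda))
}

## ---- reframe translation oracle -------------------------------------------
## chromosome as a char vector with a per-base CDS mask; edits act on the
## vectors directly, so exon bookkeeping is independent of the package's
## interval mapping

oracle_state <- function(chr_str, cds_start1, cds_end1) {
  chars <- strsplit(chr_str, "")[[1]]
  mask <- logical(length(chars))
  mask[cds_start1:cds_end1] <- TRUE
  list(chars = chars, mask = mask)
}

oracle_delete <- function(st, pos1) {
  list(chars = st$chars[-pos1], mask = st$mask[-pos1])
}

## insert before 1-based index pos1; inserted base is coding iff both
## neighbours are coding
oracle_insert <- function(st, pos1, base) {
  in_cds <- pos1 > 1 && pos1 <= length(st$chars) &&
    st$mask[pos1 - 1L] && st$mask[pos1]
  list(chars = append(st$chars, base, after = pos1 - 1L),
       mask = append(st$mask, in_cds, after = pos1 - 1L),
       inserted_in_cds = in_cds)
}

oracle_protein <- function(st, strand) {
  cds <- paste(st$chars[st$mask], collapse = "")
  if (strand == "-") {
    cds <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
                 collapse = "")
  }
  if (nchar(cds) %% 3L != 0L) return(NULL)
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

## random toy CDS case: one transcript, one exon, a planted 1-nt deletion
## strictly inside the exon, genome long enough for guide placement
toy_deletion_case <- function(chrom_len = 400L) {
  chr_str <- rand_seq(chrom_len)
  cds_start <- 60L
  cds_len <- 3L * sample(40:60, 1L)
  cds_end <- cds_start + cds_len - 1L
  strand <- sample(c("+", "-"), 1L)
  del1 <- sample((cds_start + 5L):(cds_end - 5L), 1L)  # deleted base, 1-based
  anchor <- substr(chr_str, del1 - 1L, del1 - 1L)
  list(
    genome = Biostrings::DNAStringSet(setNames(chr_str, "chrT")),
    chr_str = chr_str,
    cds = tibble::tibble(transcript = "tx1", chrom = "chrT", strand = strand,
                         start = cds_start, end = cds_end),
    variants = tibble::tibble(chrom = "chrT", pos = del1 - 1L,
                              ref = paste0(anchor,
                                           substr(chr_str, del1, del1)),
                              alt = anchor,
                              significance = "Pathogenic"),
    cds_start = cds_start, cds_end = cds_end, del1 = del1)
}
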