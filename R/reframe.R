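#' Validate a CDS exon table against a genome
#'
#' The CDS model is a tibble with one row per coding exon: `transcript`,
#' `chrom`, `strand`, `start`, `end` (1-based, inclusive, GFF-style).
#' Each transcript's total coding length must be a multiple of 3.
#'
#' @param cds CDS exon tibble.
#' @param genome genome (for chromosome-name checking).
#' @return the validated tibble, invisibly.
#' @export
validate_cds <- function(cds, genome = NULL) {
  stopifnot(all(c("transcript", "chrom", "strand", "start", "end") %in%
                  names(cds)))
  lens <- cds |>
    group_by(.data$transcript) |>
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  bad <- lens$transcript[lens$len %% 3L != 0L]
  if (length(bad)) {
    stop("CDS length of transcript ", bad[1],
         " is not a multiple of 3: inconsistent CDS/genome annotation",
         call. = FALSE)
  }
  if (!is.null(genome)) {
    genome <- load_genome(genome)
    missing <- setdiff(unique(cds$chrom), names(genome))
    if (length(missing)) {
      stop("CDS chromosome ", missing[1], " absent from the genome",
           call. = FALSE)
    }
  }
  invisible(cds)
}

#' Read coding exons from a GFF3 file
#'
#' Extracts `CDS` features with rtracklayer and returns them in the CDS
#' exon table format of [validate_cds()].
#'
#' @param path GFF3 path.
#' @param id_attribute attribute naming the transcript (default `Parent`).
#' @return CDS exon tibble.
#' @export
read_cds_gff3 <- function(path, id_attribute = "Parent") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  id <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  tibble(transcript = id,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         strand = as.character(BiocGenerics::strand(gr)),
         start = BiocGenerics::start(gr), end = BiocGenerics::end(gr))
}

#' Filter variants to correctable pathogenic 1-nt deletions
#'
#' Applies, in order: (1) the variant is a 1-nt deletion in anchored VCF
#' representation (REF two bases, ALT the first REF base); (2) it lies on
#' a standard chromosome; (3) its significance is `Pathogenic` or
#' `Likely_pathogenic`; (4) the deleted base overlaps a coding exon;
#' (5) the anchored REF matches the genome. Dropped counts are tallied
#' per filter.
#'
#' @param variants tibble (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `significance`), e.g. from [read_snv_vcf()] with
#'   `info_field = "CLNSIG"`.
#' @param cds CDS exon table (see [validate_cds()]).
#' @param genome genome.
#' @param standard_chroms optional explicit vector of allowed chromosome
#'   names (default: [is_standard_chrom()], with synthetic `chr*` names
#'   always allowed when they appear in the genome).
#' @return list with `deletions` (retained records, with `deleted_pos0`,
#'   the 0-based coordinate of the deleted base, and `transcript`) and
#'   `audit` (tibble of per-filter drop counts).
#' @export
find_correctable_deletions <- function(variants, cds, genome,
                                       standard_chroms = NULL) {
  genome <- load_genome(genome)
  validate_cds(cds, genome)
  chr_str <- setNames(as.character(genome), names(genome))
  audit <- tibble(filter = character(0), dropped = integer(0))
  note <- function(audit, name, n) bind_rows(audit,
                                             tibble(filter = name, dropped = n))
  d <- variants
  keep <- nchar(d$ref) == 2L & nchar(d$alt) == 1L &
    substr(d$ref, 1L, 1L) == d$alt
  audit <- note(audit, "not_1nt_deletion", sum(!keep)); d <- d[keep, ]

  ok_chrom <- if (is.null(standard_chroms)) {
    is_standard_chrom(d$chrom) | d$chrom %in% names(genome)
  } else d$chrom %in% standard_chroms
  audit <- note(audit, "nonstandard_chromosome", sum(!ok_chrom))
  d <- d[ok_chrom, ]

  sig_ok <- d$significance %in% c("Pathogenic", "Likely_pathogenic")
  audit <- note(audit, "not_pathogenic", sum(!sig_ok)); d <- d[sig_ok, ]

  d$deleted_pos0 <- d$pos  # anchored: deleted base is POS + 1 (1-based)
  d$transcript <- NA_character_
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      hit <- cds$chrom == d$chrom[i] &
        cds$start <= d$deleted_pos0[i] + 1L & cds$end >= d$deleted_pos0[i] + 1L
      if (any(hit)) d$transcript[i] <- cds$transcript[which(hit)[1L]]
    }
  }
  audit <- note(audit, "not_exonic", sum(is.na(d$transcript)))
  d <- d[!is.na(d$transcript), ]

  ref_ok <- vapply(seq_len(nrow(d)), function(i) {
    substr(chr_str[[d$chrom[i]]], d$pos[i], d$pos[i] + 1L) == d$ref[i]
  }, logical(1))
  audit <- note(audit, "ref_mismatch", sum(!ref_ok)); d <- d[ref_ok, ]

  list(deletions = as_tibble(d), audit = audit)
}

## deletion-allele sequence of one chromosome (base at 0-based d0 removed)
delete_base <- function(chr_str, d0) {
  paste0(substr(chr_str, 1L, d0), substr(chr_str, d0 + 2L, nchar(chr_str)))
}

## exon intervals (0-based half-open) mapped through a deletion at d0
map_exons_del <- function(exons, d0) {
  a <- exons$s; b <- exons$e
  shift_a <- d0 < a
  inside <- a <= d0 & d0 < b
  exons$s <- a - shift_a
  exons$e <- b - (shift_a | inside)
  exons
}

## ... and through an insertion before allele coordinate i0
map_exons_ins <- function(exons, i0) {
  a <- exons$s; b <- exons$e
  before <- i0 <= a
  inside <- a < i0 & i0 < b
  exons$s <- a + before
  exons$e <- b + (before | inside)
  exons
}

extract_cds <- function(chr_str, exons, strand) {
  exons <- exons[order(exons$s), ]
  seqs <- substr(rep(chr_str, nrow(exons)), exons$s + 1L, exons$e)
  cds <- paste(seqs, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  cds
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Place candidate guides around a pathogenic 1-nt deletion
#'
#' On the deletion-allele sequence, finds every NGG PAM on either strand
#' lying 0 to `max_upstream` nt from the deletion junction on its
#' PAM-proximal side, and returns the 20-nt deletion-allele protospacer of
#' each placement. Offset 0 means the PAM starts directly at the deleted
#' position. Deletions within 25 bp of a contig end are skipped with a
#' warning.
#'
#' @param deletions `deletions` tibble from [find_correctable_deletions()].
#' @param genome genome.
#' @param max_upstream maximum PAM offset from the junction (nt).
#' @return tibble of placements: identification columns plus `strand`,
#'   `pam_offset`, `allele_start` (0-based protospacer start on the
#'   deletion allele), `protospacer` (= the guide spacer, matching the
#'   deletion allele), `pam`.
#' @export
place_guides <- function(deletions, genome, max_upstream = 4L) {
  genome <- load_genome(genome)
  chr_str <- setNames(as.character(genome), names(genome))
  out <- vector("list", 0L)
  for (i in seq_len(nrow(deletions))) {
    v <- deletions[i, ]
    seq <- chr_str[[v$chrom]]
    d0 <- v$deleted_pos0
    if (d0 < 25L || d0 > nchar(seq) - 26L) {
      warning("deletion ", v$chrom, ":", v$pos,
              " within 25 bp of a contig end; placement skipped")
      next
    }
    allele <- delete_base(seq, d0)
    alen <- nchar(allele)
    j <- d0  # junction coordinate on the deletion allele
    for (d in 0:max_upstream) {
      q <- j + d  # plus-strand PAM start (0-based)
      if (q - 20L >= 0L && q + 3L <= alen) {
        pam <- substr(allele, q + 1L, q + 3L)
        if (grepl("^.GG$", pam)) {
          out[[length(out) + 1L]] <- tibble(
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            transcript = v$transcript, deleted_pos0 = d0,
            strand = "+", pam_offset = d, allele_start = q - 20L,
            protospacer = substr(allele, q - 19L, q), pam = pam)
        }
      }
      ps <- j - d  # minus-strand protospacer start
      if (ps - 3L >= 0L && ps + 20L <= alen) {
        pam_fwd <- substr(allele, ps - 2L, ps)
        if (grepl("^CC.$", pam_fwd)) {
          out[[length(out) + 1L]] <- tibble(
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            transcript = v$transcript, deleted_pos0 = d0,
            strand = "-", pam_offset = d, allele_start = ps,
            protospacer = revcomp(substr(allele, ps + 1L, ps + 20L)),
            pam = revcomp(pam_fwd))
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), transcript = character(0),
                  deleted_pos0 = integer(0), strand = character(0),
                  pam_offset = integer(0), allele_start = integer(0),
                  protospacer = character(0), pam = character(0)))
  }
  bind_rows(out)
}

#' Templated +1 insertion outcome of a candidate guide
#'
#' Models the repair of a staggered cut at the blunt boundary (between
#' protospacer positions 17 and 18) as a templated +1 insertion
#' duplicating the deletion-allele base at position 17, applies it to the
#' deletion allele and asks whether the reading frame and the protein
#' sequence of the overlapping transcript are restored. When the
#' insertion point falls outside the coding exons the outcome is computed
#' at the DNA level only and the protein flag is NA.
#'
#' @param candidates placements from [place_guides()].
#' @param cds CDS exon table.
#' @param genome genome.
#' @return `candidates` with `insert_base`, `frame_restored` and
#'   `protein_restored`.
#' @export
templated_insertion_outcome <- function(candidates, cds, genome) {
  genome <- load_genome(genome)
  validate_cds(cds, genome)
  chr_str <- setNames(as.character(genome), names(genome))
  candidates$insert_base <- substr(candidates$protospacer, 17L, 17L)
  candidates$frame_restored <- NA
  candidates$protein_restored <- NA
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    seq <- chr_str[[cand$chrom]]
    tx <- cds[cds$transcript == cand$transcript, ]
    exons <- data.frame(s = tx$start - 1L, e = tx$end)  # 0-based half-open
    strand_tx <- tx$strand[1]

    cds_ref <- extract_cds(seq, exons, strand_tx)
    allele <- delete_base(seq, cand$deleted_pos0)
    exons_del <- map_exons_del(exons, cand$deleted_pos0)

    if (cand$strand == "+") {
      i0 <- cand$allele_start + 17L
      ins_top <- cand$insert_base
    } else {
      i0 <- cand$allele_start + 3L
      ins_top <- comp_base(cand$insert_base)
    }
    edited <- paste0(substr(allele, 1L, i0), ins_top,
                     substr(allele, i0 + 1L, nchar(allele)))
    exons_edit <- map_exons_ins(exons_del, i0)
    cds_edit <- extract_cds(edited, exons_edit, strand_tx)

    frame_ok <- (nchar(cds_edit) %% 3L) == (nchar(cds_ref) %% 3L)
    candidates$frame_restored[i] <- frame_ok
    in_cds <- any(exons_del$s < i0 & i0 < exons_del$e)
    candidates$protein_restored[i] <- if (!in_cds) NA else {
      frame_ok && identical(translate_cds(cds_edit), translate_cds(cds_ref))
    }
  }
  candidates
}

#' Rank correction candidates by predicted staggeredness
#'
#' Predicts the log2 blunt rate of each candidate guide (guide matching
#' the deletion allele, 0 mismatches) under one or more nuclease models
#' and assigns a scission class: `blunt` (rate > 0), `staggered`
#' (-2 < rate <= 0) or `highly_staggered` (rate <= -2, the regime in which
#' templated +1 insertions dominate the repair outcome). With several
#' models, the per-model highly-staggered sets and their
#' intersection/exclusive counts are summarised.
#'
#' @param candidates output of [templated_insertion_outcome()].
#' @param models a single `blunt_model` or a named list of them.
#' @param highly_staggered_cutoff log2 blunt-rate cutoff (default -2).
#' @return list with `candidates` (one `rate_<model>` and
#'   `class_<model>` column pair per model, sorted by the first model's
#'   rate) and `summary` (per-model candidate counts and overlaps).
#' @export
rank_candidates <- function(candidates, models,
                            highly_staggered_cutoff = -2) {
  if (inherits(models, "blunt_model")) models <- list(model = models)
  stopifnot(length(names(models)) == length(models))
  class_of <- function(rate) {
    factor(dplyr::case_when(rate > 0 ~ "blunt",
                            rate <= highly_staggered_cutoff ~ "highly_staggered",
                            TRUE ~ "staggered"),
           levels = c("blunt", "staggered", "highly_staggered"))
  }
  hs_sets <- list()
  for (nm in names(models)) {
    rate <- predict(models[[nm]], tibble(protospacer = candidates$protospacer,
                                         spacer = candidates$protospacer))
    candidates[[paste0("rate_", nm)]] <- rate
    candidates[[paste0("class_", nm)]] <- class_of(rate)
    hs_sets[[nm]] <- which(rate <= highly_staggered_cutoff)
  }
  inter <- Reduce(intersect, hs_sets)
  summary <- purrr::imap_dfr(hs_sets, function(idx, nm) {
    others <- unlist(hs_sets[setdiff(names(hs_sets), nm)])
    tibble(model = nm, n_highly_staggered = length(idx),
           n_exclusive = length(setdiff(idx, others)))
  })
  attr(summary, "n_intersection") <- length(inter)
  list(candidates = arrange(candidates,
                            .data[[paste0("rate_", names(models)[1])]]),
       summary = summary)
}

T7_PROMOTER <- "GGATCCTAATACGACTCACTATAG"
SPCAS9_SCAFFOLD <- "GTTTTAGAGCTAGAA"

#' Design a T7 in-vitro-transcription sgRNA construct
#'
#' Prepends the T7 promoter and appends the SpCas9 scaffold handle to a
#' 20-nt spacer whose 5'-terminal (PAM-distal) nucleotide is replaced by G
#' for efficient T7 transcription initiation. The assembled template is
#' 24 + 20 + 15 = 59 nt.
#'
#' @param spacer 20-nt ACGT spacer(s).
#' @return character vector of 59-nt construct sequences.
#' @export
#' @examples
#' design_t7_construct("ATGCATGCATGCATGCATGC")
design_t7_construct <- function(spacer) {
  assert_spacer(spacer)
  substr(spacer, 1L, 1L) <- "G"
  paste0(T7_PROMOTER, spacer, SPCAS9_SCAFFOLD)
}
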