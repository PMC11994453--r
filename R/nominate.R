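## Tally pileup molecules in the scission window of each site.
## Adds prox_14..prox_20 (boundary-label counts on the PAM-proximal side)
## and distal_count to a tibble of sites (chrom, start, strand).
tally_window <- function(sites, pileup, labels = 14:20) {
  if (nrow(sites) == 0L) {
    for (l in labels) sites[[paste0("prox_", l)]] <- integer(0)
    sites$distal_count <- integer(0)
    return(sites)
  }
  key <- function(chrom, pos0, strand) paste(chrom, pos0, strand, sep = "\r")
  lut <- setNames(pileup$count, key(pileup$chrom, pileup$pos0, pileup$strand))
  for (l in labels) {
    k <- key(sites$chrom, proximal_pos0(sites$start, sites$strand, l),
             proximal_strand(sites$strand))
    cnt <- unname(lut[k])
    sites[[paste0("prox_", l)]] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  }
  k <- key(sites$chrom, distal_pos0(sites$start, sites$strand),
           distal_strand(sites$strand))
  cnt <- unname(lut[k])
  sites$distal_count <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  sites
}

prox_cols <- function(labels = 14:20) paste0("prox_", labels)

#' Find candidate protospacer sites for a guide in a genome
#'
#' Scans both strands for every 20-mer lying immediately 5' of a PAM
#' matching `pam_pattern` (IUPAC) whose Hamming distance to the guide
#' spacer is at most `max_mismatches`. Matches are substitution-only; no
#' RNA/DNA bulges. Coordinates are 0-based half-open on the protospacer.
#'
#' @param genome DNAStringSet, named character vector or FASTA path.
#' @param guides tibble with `name` and `spacer` columns, or a single
#'   20-nt spacer string.
#' @param max_mismatches maximum substitutions between spacer and
#'   protospacer.
#' @param pam_pattern IUPAC PAM pattern 3' of the protospacer (default
#'   `"NGG"`; use `"NNN"` for a PAM-agnostic scan).
#' @return tibble of candidate sites: `guide`, `chrom`, `start`, `end`,
#'   `strand`, `protospacer` (genome sequence, PAM-adjacent orientation),
#'   `pam`, `mismatch_positions` (list column), `n_mismatches`,
#'   `mm_nonseed` (positions 1-10), `mm_seed` (positions 11-20).
#' @export
find_candidate_sites <- function(genome, guides, max_mismatches = 7L,
                                 pam_pattern = "NGG") {
  genome <- load_genome(genome)
  if (is.character(guides)) guides <- tibble(name = "guide1", spacer = guides)
  assert_spacer(guides$spacer)
  pam_re <- iupac_regex(pam_pattern)
  out <- vector("list", 0L)
  for (gi in seq_len(nrow(guides))) {
    spacer <- guides$spacer[gi]
    fwd <- Biostrings::DNAString(spacer)
    rev <- Biostrings::reverseComplement(fwd)
    for (ci in seq_along(genome)) {
      subj <- genome[[ci]]
      chrom <- names(genome)[ci]
      len <- length(subj)
      chr_str <- as.character(subj)

      st <- Biostrings::start(Biostrings::matchPattern(
        fwd, subj, max.mismatch = max_mismatches))
      st <- st[st + 22L <= len]
      if (length(st)) {
        pam <- substr(rep(chr_str, length(st)), st + 20L, st + 22L)
        ok <- grepl(pam_re, pam)
        if (any(ok)) {
          st2 <- st[ok]
          out[[length(out) + 1L]] <- tibble(
            guide = guides$name[gi], chrom = chrom,
            start = st2 - 1L, end = st2 + 19L, strand = "+",
            protospacer = substr(rep(chr_str, length(st2)), st2, st2 + 19L),
            pam = pam[ok])
        }
      }

      st <- Biostrings::start(Biostrings::matchPattern(
        rev, subj, max.mismatch = max_mismatches))
      st <- st[st >= 4L & st + 19L <= len]
      if (length(st)) {
        pam <- revcomp(substr(rep(chr_str, length(st)), st - 3L, st - 1L))
        ok <- grepl(pam_re, pam)
        if (any(ok)) {
          st2 <- st[ok]
          out[[length(out) + 1L]] <- tibble(
            guide = guides$name[gi], chrom = chrom,
            start = st2 - 1L, end = st2 + 19L, strand = "-",
            protospacer = revcomp(substr(rep(chr_str, length(st2)),
                                         st2, st2 + 19L)),
            pam = pam[ok])
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(guide = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  protospacer = character(0), pam = character(0),
                  mismatch_positions = list(), n_mismatches = integer(0),
                  mm_nonseed = integer(0), mm_seed = integer(0)))
  }
  res <- bind_rows(out)
  spacer_of <- setNames(guides$spacer, guides$name)
  mm <- purrr::map2(res$protospacer, spacer_of[res$guide], function(p, s) {
    which(strsplit(p, "")[[1]] != strsplit(s, "")[[1]])
  })
  res$mismatch_positions <- mm
  res$n_mismatches <- lengths(mm)
  res$mm_nonseed <- vapply(mm, function(x) sum(x <= 10L), integer(1))
  res$mm_seed <- vapply(mm, function(x) sum(x > 10L), integer(1))
  res <- filter(res, .data$n_mismatches <= max_mismatches)
  arrange(res, .data$guide, .data$chrom, .data$start, .data$strand)
}

#' Upper-tail Poisson enrichment p-value against a matched control
#'
#' Probability of observing at least `obs` molecules under a Poisson rate
#' estimated from the non-target control: `lambda = (ntc_count + 1) *
#' size_ratio`, where the +1 pseudocount guards against empty control
#' windows and `size_ratio` scales for library size (target / control).
#'
#' @param obs_count observed molecule count.
#' @param ntc_count control molecule count in the matched window.
#' @param size_ratio target-to-control library size ratio.
#' @return p-value(s), `P(X >= obs)`.
#' @export
#' @examples
#' enrichment_pvalue(10, 0, 1)  # ~1.1e-7
enrichment_pvalue <- function(obs_count, ntc_count, size_ratio = 1) {
  stopifnot(all(obs_count >= 0), all(ntc_count >= 0), all(size_ratio > 0))
  ppois(obs_count - 1, lambda = (ntc_count + 1) * size_ratio,
        lower.tail = FALSE)
}

#' Nominate cleaved target sites from a break-end pileup
#'
#' Tallies unique molecules in the scission window of each candidate
#' (boundary labels `17 - stack_distance` to `17 + stack_distance` on the
#' PAM-proximal side, plus the fixed PAM-distal position). Candidates with
#' at least `min_stack` molecules are tested for enrichment over the
#' non-target control with [enrichment_pvalue()]; Benjamini-Hochberg FDR is
#' computed across all tested candidates of the run, and sites at or below
#' `fdr_threshold` are reported.
#'
#' @param candidates candidate sites from [find_candidate_sites()].
#' @param pileup deduplicated target-library pileup.
#' @param ntc_pileup deduplicated non-target control pileup (NULL = none).
#' @param min_stack minimum molecules (both sides summed) to test a site.
#' @param stack_distance half-width of the scission window in nt.
#' @param fdr_threshold report sites with `fdr <= fdr_threshold`.
#' @param size_ratio target/control library size ratio; by default the
#'   ratio of total pileup counts (1 when the control is empty).
#' @param keep_all return every candidate (with NA statistics for untested
#'   ones) instead of only the nominated set.
#' @return tibble of target sites with per-label proximal counts,
#'   `distal_count`, `total_count`, `ntc_count`, `pvalue` and `fdr`.
#' @export
call_targets <- function(candidates, pileup, ntc_pileup = NULL,
                         min_stack = 3L, stack_distance = 3L,
                         fdr_threshold = 0.05, size_ratio = NULL,
                         keep_all = FALSE) {
  labels <- (17L - stack_distance):(17L + stack_distance)
  if (nrow(candidates) > 0 &&
      !any(candidates$chrom %in% unique(pileup$chrom)) && nrow(pileup) > 0) {
    stop("pileup and candidates share no chromosome names", call. = FALSE)
  }
  if (is.null(ntc_pileup)) {
    ntc_pileup <- tibble(chrom = character(0), pos0 = integer(0),
                         strand = character(0), count = integer(0))
  }
  if (is.null(size_ratio)) {
    size_ratio <- if (sum(ntc_pileup$count) > 0) {
      sum(pileup$count) / sum(ntc_pileup$count)
    } else 1
  }
  res <- tally_window(candidates, pileup, labels)
  res$total_count <- rowSums(res[prox_cols(labels)]) + res$distal_count
  ntc <- tally_window(select(candidates, "chrom", "start", "strand"),
                      ntc_pileup, labels)
  res$ntc_count <- rowSums(ntc[prox_cols(labels)]) + ntc$distal_count
  tested <- res$total_count >= min_stack
  res$pvalue <- NA_real_
  res$pvalue[tested] <- enrichment_pvalue(res$total_count[tested],
                                          res$ntc_count[tested], size_ratio)
  res$fdr <- NA_real_
  res$fdr[tested] <- p.adjust(res$pvalue[tested], method = "BH")
  if (keep_all) return(res)
  filter(res, !is.na(.data$fdr) & .data$fdr <= fdr_threshold)
}

#' Remove targets ambiguous between pooled guides
#'
#' A nominated locus attributable to two or more guides of the pool -- its
#' protospacer within `max_hamming` substitutions of more than one spacer
#' -- cannot be assigned to a single guide and is removed.
#'
#' @param targets nominated target tibble (with `protospacer`).
#' @param guides tibble of pool guides (`name`, `spacer`).
#' @param max_hamming ambiguity distance.
#' @return targets with ambiguous loci removed.
#' @export
remove_ambiguous <- function(targets, guides, max_hamming = 7L) {
  if (nrow(targets) == 0L || nrow(guides) < 2L) return(targets)
  n_claim <- vapply(targets$protospacer, function(p) {
    sum(hamming(rep(p, nrow(guides)), guides$spacer) <= max_hamming)
  }, integer(1), USE.NAMES = FALSE)
  targets[n_claim < 2L, ]
}

#' Per-position mismatch rate across nominated targets
#'
#' @param targets target tibble with a `mismatch_positions` list column.
#' @return tibble with `position` (1-20) and `rate` (fraction of targets
#'   mismatched at that position).
#' @export
mismatch_position_profile <- function(targets) {
  if (nrow(targets) == 0L) stop("no targets", call. = FALSE)
  hits <- table(factor(unlist(targets$mismatch_positions), levels = 1:20))
  tibble(position = 1:20, rate = as.numeric(hits) / nrow(targets))
}

#' PAM trinucleotide usage of a PAM-agnostic run
#'
#' Frequencies of the observed PAM 3-mers among nominated sites, both per
#' trinucleotide and aggregated into N-prefixed classes (NGG, NAG, NGA,
#' other).
#'
#' @param targets targets nominated with `pam_pattern = "NNN"`.
#' @return list with `trinucleotide` and `class` frequency tibbles (each
#'   summing to 1).
#' @export
pam_usage <- function(targets) {
  tri <- count(targets, pam = .data$pam, name = "n") |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    arrange(desc(.data$frequency))
  suffix <- substr(targets$pam, 2L, 3L)
  cls <- dplyr::case_when(suffix == "GG" ~ "NGG",
                          suffix == "AG" ~ "NAG",
                          suffix == "GA" ~ "NGA",
                          TRUE ~ "other")
  cls_tbl <- count(tibble(class = cls), .data$class, name = "n") |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    arrange(desc(.data$frequency))
  list(trinucleotide = tri, class = cls_tbl)
}

#' Shannon sequence complexity of protospacers
#'
#' Shannon entropy (bits) of the mononucleotide composition of each 20-mer:
#' `-sum f_b log2 f_b` over the base frequencies `f_b`.
#'
#' @param protospacer_seq character vector of 20-nt ACGT sequences.
#' @return numeric vector of entropies in `[0, 2]` bits.
#' @export
#' @examples
#' shannon_complexity(strrep("ACGT", 5))  # 2 bits
shannon_complexity <- function(protospacer_seq) {
  assert_spacer(protospacer_seq, "protospacer")
  vapply(protospacer_seq, function(s) {
    f <- table(factor(strsplit(s, "")[[1]], levels = BASES)) / 20
    f <- f[f > 0]
    -sum(f * log2(f))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Activity and specificity of nuclease variants
#'
#' Activity of a variant is its total on-target molecule count normalised
#' by the reference nuclease's; specificity is reported in both
#' conventions: `on / (on + off)` (higher = more specific) and the raw
#' off-to-on ratio.
#'
#' @param variant_runs named list of target tibbles (one per nuclease),
#'   each with `total_count` and `n_mismatches`.
#' @param reference_run target tibble of the reference nuclease.
#' @return tibble with `nuclease`, `activity`, `specificity` (on/(on+off))
#'   and `offtarget_ratio` (off/on).
#' @export
activity_specificity <- function(variant_runs, reference_run) {
  on_off <- function(tbl) {
    on <- sum(tbl$total_count[tbl$n_mismatches == 0L])
    off <- sum(tbl$total_count[tbl$n_mismatches > 0L])
    c(on = on, off = off)
  }
  ref <- on_off(reference_run)
  if (ref["on"] == 0) stop("reference on-target total is zero", call. = FALSE)
  purrr::imap_dfr(variant_runs, function(tbl, nm) {
    v <- on_off(tbl)
    tibble(nuclease = nm,
           activity = unname(v["on"] / ref["on"]),
           specificity = unname(v["on"] / (v["on"] + v["off"])),
           offtarget_ratio = unname(v["off"] / v["on"]))
  })
}
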