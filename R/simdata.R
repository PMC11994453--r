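#' Default additive blunt-rate sequence rule
#'
#' The generator's default mapping from the protospacer bases flanking the
#' canonical cut (positions 17 and 18) to a log2 blunt rate. The effects
#' encode the qualitative biology of SpCas9 scission: a guanine at position
#' 17 strongly favours blunt cuts and a guanine at position 18 strongly
#' favours staggered cuts, with milder secondary effects (T17 mildly
#' staggered, C18 mildly blunt) so that every one of the 16 base
#' combinations has a distinct expected rate. The implied blunt *fraction*
#' is the logistic transform `f = 2^r / (1 + 2^r)` of the log2 rate `r`,
#' so rule extremes 17G|18C (+3) and 17T|18G (-3) correspond to 89% and
#' 11% blunt molecules.
#'
#' @param effect17,effect18 named numeric vectors of per-base log2 effects
#'   (names A, C, G, T).
#' @return list with `effect17`, `effect18` and `fraction` (4x4 matrix of
#'   blunt fractions, rows = base 17, cols = base 18).
#' @export
#' @examples
#' rule <- blunt_rule_default()
#' rule$fraction["G", "C"]  # most blunt combination
blunt_rule_default <- function(effect17 = c(A = 0, C = 0.5, G = 2, T = -1),
                               effect18 = c(A = 0, C = 1, G = -2, T = -0.5)) {
  stopifnot(identical(names(effect17), BASES), identical(names(effect18), BASES))
  r <- outer(effect17, effect18, "+")
  list(effect17 = effect17, effect18 = effect18,
       fraction = 2^r / (1 + 2^r))
}

## log2 blunt rate implied by the rule for a vector of protospacers
rule_log2_rate <- function(rule, protospacer) {
  b17 <- substr(protospacer, 17, 17)
  b18 <- substr(protospacer, 18, 18)
  unname(rule$effect17[b17] + rule$effect18[b18])
}

#' Configuration of the synthetic break-end generator
#'
#' Bundles every tunable of the simulated experiment: genome size, the
#' number of guides and planted off-targets, sequencing depth per site, the
#' sequence rule giving each site its true blunt fraction, the 5' overhang
#' length distribution for staggered molecules, the uniform background
#' break rate, and the PCR duplication rate. Identical configurations
#' (including `seed`) reproduce byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (>= 200).
#' @param n_guides number of guide RNAs.
#' @param offtargets_per_guide planted off-targets per guide (the on-target
#'   is always planted in addition).
#' @param max_planted_mismatches maximum substitutions per planted
#'   off-target, in `[0, 7]`.
#' @param depth_per_site unique molecule pairs per planted site.
#' @param blunt_fraction_rule 4x4 matrix of blunt fractions indexed by
#'   protospacer bases 17 (rows) and 18 (columns); defaults to
#'   [blunt_rule_default()].
#' @param overhang_length_probs probabilities of 1/2/3-nt 5' overhangs for
#'   staggered molecules; must sum to 1.
#' @param noise_rate expected background read ends per bp per strand.
#' @param pcr_duplicate_rate probability that a record is re-emitted with
#'   identical position and UMI.
#' @param mismatch_penalty log2 units subtracted from a site's blunt rate
#'   per planted mismatch (0 = scission independent of mismatches).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_length = 50000L,
                       n_guides = 5L,
                       offtargets_per_guide = 3L,
                       max_planted_mismatches = 7L,
                       depth_per_site = 100L,
                       blunt_fraction_rule = blunt_rule_default()$fraction,
                       overhang_length_probs = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                       noise_rate = 1e-4,
                       pcr_duplicate_rate = 0.1,
                       mismatch_penalty = 0) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_guides = as.integer(n_guides),
              offtargets_per_guide = as.integer(offtargets_per_guide),
              max_planted_mismatches = as.integer(max_planted_mismatches),
              depth_per_site = as.integer(depth_per_site),
              blunt_fraction_rule = blunt_fraction_rule,
              overhang_length_probs = overhang_length_probs,
              noise_rate = noise_rate,
              pcr_duplicate_rate = pcr_duplicate_rate,
              mismatch_penalty = mismatch_penalty)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$chrom_length >= 200L,
            cfg$n_chrom >= 1L, cfg$n_guides >= 1L,
            cfg$offtargets_per_guide >= 0L,
            cfg$max_planted_mismatches >= 0L,
            cfg$max_planted_mismatches <= 7L,
            cfg$depth_per_site >= 1L,
            cfg$noise_rate >= 0,
            cfg$pcr_duplicate_rate >= 0, cfg$pcr_duplicate_rate < 1)
  r <- cfg$blunt_fraction_rule
  if (!is.matrix(r) || !identical(dim(r), c(4L, 4L)) ||
      any(r < 0) || any(r > 1)) {
    stop("blunt_fraction_rule must be a 4x4 matrix of probabilities",
         call. = FALSE)
  }
  p <- cfg$overhang_length_probs
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("overhang_length_probs must be 3 probabilities summing to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

## blunt fraction of a planted site under the config rule
site_blunt_fraction <- function(cfg, protospacer, n_mismatches) {
  b17 <- substr(protospacer, 17, 17)
  b18 <- substr(protospacer, 18, 18)
  f <- cfg$blunt_fraction_rule[cbind(b17, b18)]
  if (cfg$mismatch_penalty != 0) {
    f <- plogis(qlogis(f) - log(2) * cfg$mismatch_penalty * n_mismatches)
  }
  f
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

mutate_spacer <- function(spacer, k) {
  if (k == 0L) return(list(seq = spacer, positions = integer(0)))
  pos <- sort(sample.int(20L, k))
  chars <- strsplit(spacer, "")[[1]]
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(BASES, b), 1L), "")
  list(seq = paste(chars, collapse = ""), positions = pos)
}

#' Generate a synthetic genome with planted Cas9 target sites
#'
#' Draws random guide spacers and a uniform-random genome, then plants for
#' each guide one exact on-target and `offtargets_per_guide` mutated copies
#' (1 to `max_planted_mismatches` substitutions each), every one followed
#' by an NGG PAM on a random strand. Planted footprints never overlap. The
#' true blunt fraction of each site follows the configured sequence rule
#' applied to its planted protospacer.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (DNAStringSet), `truth` (tibble: one row per
#'   planted site with chrom, 0-based half-open protospacer interval,
#'   strand, pam, guide, protospacer, mismatch annotation, true blunt
#'   fraction and an optional `fixed_overhang` column), `guides`
#'   (tibble: name, spacer) and the config.
#' @export
#' @examples
#' sim <- gen_genome(sim_config(seed = 1, n_guides = 2, chrom_length = 5000))
#' sim$truth
gen_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    seqs <- setNames(vapply(chroms, function(.) random_seq(config$chrom_length), ""),
                     chroms)
    guides <- tibble(name = paste0("guide", seq_len(config$n_guides)),
                     spacer = vapply(seq_len(config$n_guides),
                                     function(.) random_seq(20L), ""))

    n_per_guide <- 1L + config$offtargets_per_guide
    sites <- tidyr::crossing(guide = guides$name,
                             idx = seq_len(n_per_guide))
    taken <- setNames(vector("list", length(chroms)), chroms)
    rows <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      g <- sites$guide[i]
      spacer <- guides$spacer[guides$name == g]
      k <- if (sites$idx[i] == 1L || config$max_planted_mismatches == 0L) 0L
           else sample.int(config$max_planted_mismatches, 1L)
      mut <- mutate_spacer(spacer, k)
      placed <- FALSE
      for (try in seq_len(2000L)) {
        chrom <- sample(chroms, 1L)
        strand <- sample(c("+", "-"), 1L)
        start <- sample(30:(config$chrom_length - 55L), 1L)  # 0-based
        occ <- if (strand == "+") c(start - 3L, start + 26L)
               else c(start - 6L, start + 23L)
        clash <- any(vapply(taken[[chrom]],
                            function(iv) occ[1] < iv[2] && iv[1] < occ[2],
                            logical(1)))
        if (!clash) {
          taken[[chrom]] <- c(taken[[chrom]], list(occ))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("genome too short to place all planted sites without overlap",
             call. = FALSE)
      }
      pam <- paste0(sample(BASES, 1L), "GG")
      if (strand == "+") {
        substr(seqs[[chrom]], start + 1L, start + 20L) <- mut$seq
        substr(seqs[[chrom]], start + 21L, start + 23L) <- pam
      } else {
        substr(seqs[[chrom]], start + 1L, start + 20L) <- revcomp(mut$seq)
        substr(seqs[[chrom]], start - 2L, start) <- revcomp(pam)
      }
      rows[[i]] <- tibble(
        chrom = chrom, start = start, end = start + 20L, strand = strand,
        pam = pam, guide = g, protospacer = mut$seq,
        mismatch_positions = list(mut$positions), n_mismatches = k)
    }
    truth <- bind_rows(rows)
    truth$true_blunt_fraction <-
      site_blunt_fraction(config, truth$protospacer, truth$n_mismatches)
    truth$fixed_overhang <- NA_integer_
    list(genome = Biostrings::DNAStringSet(seqs), truth = truth,
         guides = guides, config = config)
  })
}

random_umis <- function(n) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, 8L * n, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate end-capture break-end records for planted sites
#'
#' For each site in the truth table, emits `depth_per_site` molecule pairs:
#' a PAM-proximal and a PAM-distal break-end record, each with its own
#' random 8-nt UMI. Blunt molecules place the proximal end at boundary
#' label 17; an n-nt 5' overhang (end-repair fill-in toward the PAM) moves
#' the proximal end to label `17 - n` while the distal end stays at label
#' 17 regardless of the cut configuration. A site with a non-missing
#' `fixed_overhang` (signed; negative = 3' overhang, proximal end at
#' `17 + n`) emits all molecules at that footprint. Uniform background
#' read ends are added at `noise_rate` per bp per strand, and each record
#' is re-emitted once with identical position and UMI with probability
#' `pcr_duplicate_rate`.
#'
#' @param truth truth tibble from [gen_genome()].
#' @param genome the matching genome (DNAStringSet or FASTA path).
#' @param config the [sim_config()] used.
#' @param barcode 8-nt sample barcode stamped on every record.
#' @return tibble of aligned read-end records: `chrom`, `pos0` (0-based
#'   coordinate of the break-proximal terminal base), `strand`, `umi`,
#'   `barcode`, `mapq`, plus provenance columns `site` (truth row index,
#'   NA for background) and `side`.
#' @export
sim_break_ends <- function(truth, genome, config, barcode = "ACGTACGT") {
  genome <- load_genome(genome)
  validate_sim_config(config)
  if (any(truth$end > Biostrings::width(genome)[match(truth$chrom,
                                                      names(genome))])) {
    stop("truth sites must lie within the genome", call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    recs <- vector("list", nrow(truth) + 1L)
    for (i in seq_len(nrow(truth))) {
      s <- truth[i, ]
      n <- config$depth_per_site
      if (!is.na(s$fixed_overhang)) {
        if (abs(s$fixed_overhang) > 3L) {
          stop("Cas9-mode overhang length must be in {-3,...,3}; use ",
               "sim_restriction_fixture() for longer footprints", call. = FALSE)
        }
        labels <- rep(17L - s$fixed_overhang, n)
      } else {
        blunt <- runif(n) < s$true_blunt_fraction
        ov <- integer(n)
        n_stag <- sum(!blunt)
        if (n_stag > 0) {
          ov[!blunt] <- sample(1:3, n_stag, replace = TRUE,
                               prob = config$overhang_length_probs)
        }
        labels <- 17L - ov
      }
      prox <- tibble(chrom = s$chrom,
                     pos0 = proximal_pos0(s$start, s$strand, labels),
                     strand = proximal_strand(s$strand),
                     umi = random_umis(n), barcode = barcode, mapq = 60L,
                     site = i, side = "proximal")
      dist <- tibble(chrom = s$chrom,
                     pos0 = rep(distal_pos0(s$start, s$strand), n),
                     strand = distal_strand(s$strand),
                     umi = random_umis(n), barcode = barcode, mapq = 60L,
                     site = i, side = "distal")
      recs[[i]] <- bind_rows(prox, dist)
    }
    widths <- Biostrings::width(genome)
    n_noise <- rpois(1L, config$noise_rate * sum(widths) * 2)
    if (n_noise > 0) {
      chrom_idx <- sample.int(length(genome), n_noise, replace = TRUE,
                              prob = widths)
      recs[[nrow(truth) + 1L]] <- tibble(
        chrom = names(genome)[chrom_idx],
        pos0 = floor(runif(n_noise) * widths[chrom_idx]),
        strand = sample(c("+", "-"), n_noise, replace = TRUE),
        umi = random_umis(n_noise), barcode = barcode, mapq = 60L,
        site = NA_integer_, side = "background")
    }
    ends <- bind_rows(recs)
    if (config$pcr_duplicate_rate > 0 && nrow(ends) > 0) {
      dup <- runif(nrow(ends)) < config$pcr_duplicate_rate
      ends <- bind_rows(ends, ends[dup, ])
    }
    arrange(ends, .data$chrom, .data$strand, .data$pos0, .data$umi)
  })
}

#' Simulate a restriction-enzyme footprint fixture
#'
#' Emits two read-end stacks around a single cut whose separation encodes
#' the end structure: abutting stacks for a blunt cut, an overlap of `n`
#' for an n-nt 5' overhang (positive `overhang`) and a gap of `n` for an
#' n-nt 3' overhang (negative `overhang`). The top-strand stack sits at
#' `position - overhang` and the bottom-strand stack at `position - 1`,
#' where `position` is the 0-based top-strand cut boundary.
#'
#' @param position 0-based cut boundary.
#' @param overhang signed overhang length, `|overhang| <= 10`.
#' @param genome DNAStringSet (for bounds checking).
#' @param chrom chromosome name.
#' @param depth records per stack.
#' @param seed RNG seed for the UMIs.
#' @return tibble of aligned read-end records (as [sim_break_ends()]).
#' @export
sim_restriction_fixture <- function(position, overhang, genome,
                                    chrom = names(genome)[1],
                                    depth = 50L, seed = 1L) {
  genome <- load_genome(genome)
  if (abs(overhang) > 10L) stop("|overhang| must be <= 10", call. = FALSE)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(len) || position - abs(overhang) < 1L || position + abs(overhang) > len - 1L) {
    stop("cut site outside the genome", call. = FALSE)
  }
  withr::with_seed(seed, {
    bind_rows(
      tibble(chrom = chrom, pos0 = rep(position - overhang, depth),
             strand = "+", umi = random_umis(depth),
             barcode = "ACGTACGT", mapq = 60L,
             site = NA_integer_, side = "plus_stack"),
      tibble(chrom = chrom, pos0 = rep(position - 1L, depth),
             strand = "-", umi = random_umis(depth),
             barcode = "ACGTACGT", mapq = 60L,
             site = NA_integer_, side = "minus_stack"))
  })
}

#' Signed stack offset between opposing read-end stacks
#'
#' The footprint of a cut read directly from its two stacks: 0 when the
#' stacks abut (blunt), `+n` when they overlap by n (n-nt 5' overhang) and
#' `-n` when they are separated by a gap of n (n-nt 3' overhang).
#'
#' @param plus_pos0 0-based position of the top-strand stack.
#' @param minus_pos0 0-based position of the bottom-strand stack.
#' @return signed overhang length.
#' @export
#' @examples
#' stack_offset(100, 99)   # abutting: blunt
#' stack_offset(96, 99)    # 4-nt 5' overhang
stack_offset <- function(plus_pos0, minus_pos0) {
  (minus_pos0 + 1L) - plus_pos0
}

#' Write simulation outputs to disk
#'
#' Writes the genome as FASTA, the truth table and guide list as TSV, and
#' the aligned read ends as TSV, using stable column orders so a fixed
#' seed reproduces byte-identical files.
#'
#' @param sim list from [gen_genome()].
#' @param ends tibble from [sim_break_ends()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, ends, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genome.fa", "truth.tsv", "guides.tsv", "ends.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[1])
  truth <- sim$truth
  truth$mismatch_positions <-
    vapply(truth$mismatch_positions, paste, "", collapse = ",")
  readr::write_tsv(truth, paths[2])
  readr::write_tsv(sim$guides, paths[3])
  readr::write_tsv(ends, paths[4])
  invisible(paths)
}
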