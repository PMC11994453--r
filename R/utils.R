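#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n row_number across all_of desc distinct count pull
#' @importFrom stats ppois p.adjust lm coef cor qlogis plogis rbinom rpois
#'   runif setNames complete.cases binom.test quantile median
#' @importFrom utils head
NULL

BASES <- c("A", "C", "G", "T")

#' Boundary-label geometry of break-proximal read ends
#'
#' A Cas9 target is a 20-nt protospacer stored as a 0-based half-open
#' interval `[start, start + 20)` with the PAM immediately 3' of position 20
#' (the PAM-adjacent end). Boundary label `b` (14-20) names the break
#' boundary between protospacer positions `b` and `b + 1`; label 17 is the
#' canonical blunt cut, labels 16-14 are 1-3 nt 5' overhangs after end
#' repair. These helpers convert between labels and the genomic coordinate
#' of the terminal aligned base of a break-proximal read end.
#'
#' For a plus-strand target the PAM-proximal record is a `+` read end at
#' `start + b` and the PAM-distal record a `-` read end fixed at
#' `start + 16`; minus-strand targets are the mirror image (`-` read end at
#' `start + 19 - b`, distal `+` read end at `start + 3`).
#'
#' @param start 0-based protospacer start.
#' @param strand `"+"` or `"-"`.
#' @param label boundary label (integer).
#' @return `proximal_pos0()`/`distal_pos0()` return 0-based genomic
#'   coordinates; `proximal_label()` inverts `proximal_pos0()`.
#' @keywords internal
#' @name geometry
NULL

recycle2 <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

proximal_pos0 <- function(start, strand, label) {
  a <- recycle2(start, strand, label)
  ifelse(a[[2]] == "+", a[[1]] + a[[3]], a[[1]] + 19L - a[[3]])
}

proximal_label <- function(start, strand, pos0) {
  a <- recycle2(start, strand, pos0)
  ifelse(a[[2]] == "+", a[[3]] - a[[1]], a[[1]] + 19L - a[[3]])
}

proximal_strand <- function(strand) strand

distal_pos0 <- function(start, strand) {
  a <- recycle2(start, strand)
  ifelse(a[[2]] == "+", a[[1]] + 16L, a[[1]] + 3L)
}

distal_strand <- function(strand) ifelse(strand == "+", "-", "+")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

## Hamming distance between equal-length strings; NA-safe for ACGT alphabets
hamming <- function(a, b) {
  stopifnot(length(a) == length(b) | length(a) == 1L | length(b) == 1L)
  m1 <- do.call(rbind, strsplit(a, ""))
  m2 <- do.call(rbind, strsplit(b, ""))
  if (nrow(m1) == 1L && nrow(m2) > 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
  if (nrow(m2) == 1L && nrow(m1) > 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
  rowSums(m1 != m2)
}

assert_spacer <- function(x, what = "spacer") {
  bad <- nchar(x) != 20L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " must be 20-nt over {A,C,G,T}; offending value: ",
         x[which(bad)[1L]], call. = FALSE)
  }
  invisible(x)
}

## IUPAC pattern (e.g. "NGG") -> regex anchored match against 3-mers
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !chars %in% names(map)
  if (any(bad)) stop("invalid IUPAC letter in PAM pattern: ", chars[bad][1])
  paste0("^", paste0("[", map[chars], "]", collapse = ""), "$")
}

#' Identify standard chromosome names
#'
#' Standard chromosomes are autosomes, X, Y and the mitochondrial contig,
#' with or without a `chr` prefix. Unplaced/random contigs
#' (e.g. `chrUn_...`, `*_random`) are non-standard.
#'
#' @param chrom character vector of sequence names.
#' @return logical vector.
#' @export
#' @examples
#' is_standard_chrom(c("chr1", "chrX", "chrUn_gl000220", "7"))
is_standard_chrom <- function(chrom) {
  grepl("^(chr)?([0-9]{1,2}|X|Y|M|MT)$", chrom)
}

## genome loader: DNAStringSet, named character vector, or FASTA path
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path", call. = FALSE)
}

## write a file atomically (write to sibling temp file, then rename)
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
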