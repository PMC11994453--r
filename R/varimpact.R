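#' Read biallelic SNVs from a VCF
#'
#' Parses a VCF with vcfR and keeps biallelic single-nucleotide variants;
#' indels and multiallelic records are skipped with a warning.
#'
#' @param path VCF path.
#' @param info_field optional INFO key to extract (e.g. `"CLNSIG"`),
#'   returned as a `significance` column.
#' @return tibble with `chrom`, `pos` (1-based, as in the source file),
#'   `ref`, `alt` and optionally `significance`.
#' @export
read_snv_vcf <- function(path, info_field = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble(chrom = fx$CHROM, pos = as.integer(fx$POS),
                ref = fx$REF, alt = fx$ALT)
  if (!is.null(info_field)) {
    out$significance <- vcfR::extract.info(v, info_field)
  }
  keep <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    !grepl(",", out$alt) & out$ref %in% BASES & out$alt %in% BASES
  if (any(!keep)) {
    warning(sum(!keep), " non-SNV or multiallelic record(s) skipped")
  }
  out[keep, ]
}

#' Enumerate NGG target placements carrying a SNV at position 17 or 18
#'
#' For each biallelic SNV and each strand, emits every placement of a
#' 20-mer protospacer with an adjacent NGG PAM (on the reference allele)
#' in which the variant base falls at protospacer position 17 or 18. A
#' single SNV can yield multiple placements; SNVs inside the PAM yield
#' none by construction. The PAM itself is never affected by the variant.
#'
#' @param genome DNAStringSet, named character vector or FASTA path.
#' @param variants tibble from [read_snv_vcf()] (`chrom`, `pos` 1-based,
#'   `ref`, `alt`).
#' @param positions protospacer positions at which the SNV may sit.
#' @return tibble of placements: `chrom`, `pos`, `ref`, `alt`, `strand`,
#'   `start`, `end` (0-based half-open protospacer), `snp_position`,
#'   `pam`, `protospacer_ref`, `protospacer_alt`.
#' @export
enumerate_snp_targets <- function(genome, variants, positions = c(17L, 18L)) {
  genome <- load_genome(genome)
  chr_str <- setNames(as.character(genome), names(genome))
  lens <- setNames(Biostrings::width(genome), names(genome))
  bad <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
    variants$ref == variants$alt
  if (any(bad)) {
    warning(sum(bad), " non-SNV record(s) skipped")
    variants <- variants[!bad, ]
  }
  out <- vector("list", 0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$chrom %in% names(chr_str)) next
    seq <- chr_str[[v$chrom]]
    len <- lens[[v$chrom]]
    v0 <- v$pos - 1L
    gref <- substr(seq, v$pos, v$pos)
    if (gref != v$ref) next
    for (p in positions) {
      ## plus strand: protospacer position p sits at start + p - 1
      t0 <- v0 - (p - 1L)
      if (t0 >= 0L && t0 + 23L <= len) {
        pam <- substr(seq, t0 + 21L, t0 + 23L)
        if (grepl("^.GG$", pam)) {
          proto <- substr(seq, t0 + 1L, t0 + 20L)
          alt_proto <- proto
          substr(alt_proto, p, p) <- v$alt
          out[[length(out) + 1L]] <- tibble(
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            strand = "+", start = t0, end = t0 + 20L,
            snp_position = p, pam = pam,
            protospacer_ref = proto, protospacer_alt = alt_proto)
        }
      }
      ## minus strand: position p sits at start + 20 - p
      t0 <- v0 - (20L - p)
      if (t0 >= 3L && t0 + 20L <= len) {
        pam_fwd <- substr(seq, t0 - 2L, t0)
        if (grepl("^CC.$", pam_fwd)) {
          proto <- revcomp(substr(seq, t0 + 1L, t0 + 20L))
          alt_proto <- proto
          substr(alt_proto, p, p) <- comp_base(v$alt)
          out[[length(out) + 1L]] <- tibble(
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            strand = "-", start = t0, end = t0 + 20L,
            snp_position = p, pam = revcomp(pam_fwd),
            protospacer_ref = proto, protospacer_alt = alt_proto)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), strand = character(0),
                  start = integer(0), end = integer(0),
                  snp_position = integer(0), pam = character(0),
                  protospacer_ref = character(0),
                  protospacer_alt = character(0)))
  }
  bind_rows(out)
}

#' Predict allele-specific blunt-rate changes at SNV-containing targets
#'
#' Predicts the log2 blunt rate of each placement for the reference allele
#' (guide matching the reference protospacer, 0 mismatches) and for the
#' alternative allele (guide carrying the variant), and reports
#' `delta = predicted(ALT) - predicted(REF)`. Results are sorted by
#' decreasing `|delta|` for candidate picking.
#'
#' @param model a trained `blunt_model` (typically the reduced flavor).
#' @param sites placements from [enumerate_snp_targets()].
#' @return `sites` with `predicted_rate_ref`, `predicted_rate_alt` and
#'   `delta`.
#' @export
predict_allele_delta <- function(model, sites) {
  if (nrow(sites) == 0L) return(sites)
  if (any(sites$protospacer_ref == sites$protospacer_alt)) {
    stop("REF and ALT protospacers are identical for some sites",
         call. = FALSE)
  }
  sites$predicted_rate_ref <- predict(model, tibble(
    protospacer = sites$protospacer_ref, spacer = sites$protospacer_ref))
  sites$predicted_rate_alt <- predict(model, tibble(
    protospacer = sites$protospacer_alt, spacer = sites$protospacer_alt))
  sites$delta <- sites$predicted_rate_alt - sites$predicted_rate_ref
  arrange(sites, desc(abs(.data$delta)))
}
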