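#' Assign pileup records to a side of a target's cut
#'
#' Classifies read-end records relative to one target as PAM-proximal
#' (terminal base at a boundary label 14-20 on the PAM-containing side),
#' PAM-distal (the fixed distal geometry, always labelled 17 because end
#' repair fills in toward the PAM) or outside.
#'
#' @param ends tibble of records (`chrom`, `pos0`, `strand`).
#' @param target one-row tibble or list with `chrom`, `start`, `strand`.
#' @return `ends` with `side` (`"proximal"`, `"distal"`, `"outside"`) and
#'   `boundary_label` columns.
#' @export
assign_side <- function(ends, target) {
  stopifnot(all(ends$chrom == target$chrom))
  lab <- proximal_label(target$start, target$strand, ends$pos0)
  is_prox_strand <- ends$strand == proximal_strand(target$strand)
  is_distal <- ends$strand == distal_strand(target$strand) &
    ends$pos0 == distal_pos0(target$start, target$strand)
  ends$side <- dplyr::case_when(
    is_distal ~ "distal",
    is_prox_strand & lab >= 14L & lab <= 20L ~ "proximal",
    TRUE ~ "outside")
  ends$boundary_label <- dplyr::case_when(
    ends$side == "distal" ~ 17L,
    is_prox_strand ~ as.integer(lab),
    TRUE ~ NA_integer_)
  ends
}

#' Compute scission profiles for nominated targets
#'
#' For each target, tallies PAM-proximal molecules at boundary labels
#' 14-20 and the PAM-distal count, then derives two blunt-rate forms:
#' the raw fraction `c17 / sum(c14..c20)` and the pseudocounted log2 ratio
#' `log2((c17 + 1) / (sum(c14..16, c18..20) + 1))`. Sites with zero
#' proximal signal are flagged uncomputable; sites below `min_proximal`
#' proximal molecules are flagged ineligible for rate statistics. Only
#' NGG-PAM targets have an unambiguous expected cut site, so others are
#' dropped (with a message) when a `pam` column is present.
#'
#' @param targets target tibble (`chrom`, `start`, `strand`, ...).
#' @param pileup deduplicated pileup tibble.
#' @param min_proximal minimum proximal molecules for rate statistics
#'   (16 for scission statistics; 8 is conventional for variant
#'   comparisons).
#' @param require_ngg drop non-NGG targets when a `pam` column exists.
#' @return the targets with `prox_14`..`prox_20`, `distal_count`,
#'   `proximal_total`, `blunt_fraction`, `log2_blunt_rate`, `computable`,
#'   `eligible` and `scission_class` columns.
#' @export
scission_profile <- function(targets, pileup, min_proximal = 16L,
                             require_ngg = TRUE) {
  if (require_ngg && "pam" %in% names(targets)) {
    drop <- !grepl("^.GG$", targets$pam)
    if (any(drop)) {
      message("dropping ", sum(drop), " non-NGG target(s)")
      targets <- targets[!drop, ]
    }
  }
  res <- tally_window(targets, pileup, 14:20)
  pc <- as.matrix(res[prox_cols()])
  res$proximal_total <- as.integer(rowSums(pc))
  outside <- res$proximal_total - res$prox_17
  res$computable <- res$proximal_total > 0L
  res$eligible <- res$proximal_total >= min_proximal
  res$blunt_fraction <- ifelse(res$computable,
                               res$prox_17 / res$proximal_total, NA_real_)
  res$log2_blunt_rate <- log2((res$prox_17 + 1) / (outside + 1))
  res$scission_class <- classify_site(res$blunt_fraction)
  res
}

#' Classify a site as blunt, middle or staggered
#'
#' The staggered fraction is `1 - blunt_fraction`; sites fall into
#' left-closed intervals `[0, 1/3)` (blunt), `[1/3, 2/3)` (middle) and
#' `[2/3, 1]` (staggered).
#'
#' @param blunt_fraction numeric vector in `[0, 1]` (NA allowed).
#' @return factor with levels blunt/middle/staggered.
#' @export
#' @examples
#' classify_site(c(0.9, 0.5, 0.1))
classify_site <- function(blunt_fraction) {
  staggered <- 1 - blunt_fraction
  ## small snap so count ratios that equal 1/3 or 2/3 exactly in rational
  ## arithmetic land in their left-closed interval despite double rounding
  idx <- findInterval(staggered + 1e-9, c(1 / 3, 2 / 3)) + 1L
  factor(c("blunt", "middle", "staggered")[idx],
         levels = c("blunt", "middle", "staggered"))
}

#' Aggregate overhang-structure distribution across sites
#'
#' Pools proximal boundary-label counts over computable profiles and
#' reports the fraction of molecules that are blunt (label 17), carry a
#' 1-3 nt 5' overhang (labels 16-14) or map to labels 18-20 ("other").
#'
#' @param profiles output of [scission_profile()].
#' @return tibble with `structure` and `fraction` (summing to 1).
#' @export
overhang_distribution <- function(profiles) {
  profiles <- filter(profiles, .data$computable)
  if (nrow(profiles) == 0L) stop("no computable profiles", call. = FALSE)
  tot <- sum(profiles[prox_cols()])
  frac <- function(lab) sum(profiles[[paste0("prox_", lab)]]) / tot
  tibble(
    structure = c("blunt", "5p_overhang_1nt", "5p_overhang_2nt",
                  "5p_overhang_3nt", "other"),
    fraction = c(frac(17), frac(16), frac(15), frac(14),
                 (profiles |> select(all_of(prox_cols(18:20))) |> sum()) / tot))
}

#' Infer the signed overhang footprint from the proximal boundary label
#'
#' Returns `17 - label`: 0 for a blunt cut, `+n` for an n-nt 5' overhang
#' (proximal and distal read stacks overlap by n) and `-n` for an n-nt 3'
#' overhang (stacks separated by a gap of n).
#'
#' @param proximal_label boundary label(s) of the proximal stack.
#' @return signed overhang length(s).
#' @export
#' @examples
#' infer_footprint(c(17, 14, 19))  # 0, +3, -2
infer_footprint <- function(proximal_label) {
  17L - as.integer(proximal_label)
}

#' @describeIn infer_footprint Infer the footprint from raw stack
#'   positions relative to a target, verifying the distal geometry.
#' @param target one-row target (`chrom`, `start`, `strand`).
#' @param prox_pos0,dist_pos0 0-based stack positions.
#' @export
footprint_from_stacks <- function(target, prox_pos0, dist_pos0) {
  if (any(dist_pos0 != distal_pos0(target$start, target$strand))) {
    stop("distal stack does not match the fixed distal geometry",
         call. = FALSE)
  }
  infer_footprint(proximal_label(target$start, target$strand, prox_pos0))
}

#' @describeIn infer_footprint Modal footprint of each site in a profile
#'   table: the signed overhang of the most populated proximal label.
#' @param profiles output of [scission_profile()].
#' @export
site_footprint <- function(profiles) {
  pc <- as.matrix(profiles[prox_cols()])
  lab <- (14:20)[max.col(pc, ties.method = "first")]
  ifelse(profiles$proximal_total > 0L, infer_footprint(lab), NA_integer_)
}

#' Significance of non-blunt signal at each site
#'
#' Tests whether the proximal signal outside the expected cut site
#' (labels 14-16 and 18-20) exceeds the non-target control in the same
#' window, using [enrichment_pvalue()] with Benjamini-Hochberg correction
#' across sites.
#'
#' @param profiles output of [scission_profile()].
#' @param ntc_pileup non-target control pileup.
#' @param size_ratio library size ratio (default: totals ratio, 1 when the
#'   control is empty).
#' @return `profiles` with `outside_count`, `outside_ntc`,
#'   `outside_pvalue` and `outside_fdr`.
#' @export
outside_signal_test <- function(profiles, ntc_pileup, size_ratio = NULL) {
  if (is.null(size_ratio)) {
    tot <- sum(profiles$proximal_total) + sum(profiles$distal_count)
    size_ratio <- if (sum(ntc_pileup$count) > 0) {
      tot / sum(ntc_pileup$count)
    } else 1
  }
  ntc <- tally_window(select(profiles, "chrom", "start", "strand"),
                      ntc_pileup, 14:20)
  out_lab <- prox_cols(c(14:16, 18:20))
  profiles$outside_count <- as.integer(rowSums(profiles[out_lab]))
  profiles$outside_ntc <- as.integer(rowSums(ntc[out_lab]))
  profiles$outside_pvalue <- enrichment_pvalue(profiles$outside_count,
                                               profiles$outside_ntc,
                                               size_ratio)
  profiles$outside_fdr <- p.adjust(profiles$outside_pvalue, method = "BH")
  profiles
}

#' Blunt rate as a function of mismatch load
#'
#' Stratifies computable, eligible profiles by planted/annotated mismatch
#' count and fits an ordinary least-squares line of blunt fraction on
#' mismatch count.
#'
#' @param profiles output of [scission_profile()] carrying an
#'   `n_mismatches` column.
#' @return object of class `bluntrate_mm`; see [tidy.bluntrate_mm()] for
#'   the per-stratum table and [glance.bluntrate_mm()] for slope, Pearson
#'   r and p-value.
#' @export
bluntrate_vs_mismatch <- function(profiles) {
  d <- filter(profiles, .data$computable, .data$eligible)
  if (nrow(d) == 0L) stop("no eligible profiles", call. = FALSE)
  strata <- d |>
    group_by(n_mismatches = .data$n_mismatches) |>
    summarise(n = n(),
              mean_blunt_fraction = mean(.data$blunt_fraction),
              median_blunt_fraction = median(.data$blunt_fraction),
              q25 = quantile(.data$blunt_fraction, 0.25),
              q75 = quantile(.data$blunt_fraction, 0.75),
              .groups = "drop")
  fit <- if (nrow(strata) >= 2L) {
    lm(blunt_fraction ~ n_mismatches, data = d)
  } else NULL
  structure(list(strata = strata, fit = fit, data = d,
                 single_stratum = is.null(fit)),
            class = "bluntrate_mm")
}

#' @export
print.bluntrate_mm <- function(x, ...) {
  cat("Blunt rate by mismatch count (", nrow(x$data), " sites)\n", sep = "")
  print(x$strata)
  if (!x$single_stratum) {
    g <- glance.bluntrate_mm(x)
    cat(sprintf("slope = %.4f, Pearson r = %.3f\n", g$slope, g$pearson_r))
  } else {
    cat("single mismatch stratum: slope undefined\n")
  }
  invisible(x)
}

#' Tidy the per-stratum blunt-rate table
#' @param x a `bluntrate_mm` object.
#' @param ... unused.
#' @export
tidy.bluntrate_mm <- function(x, ...) x$strata

#' One-row summary of the blunt-rate/mismatch fit
#' @param x a `bluntrate_mm` object.
#' @param ... unused.
#' @export
glance.bluntrate_mm <- function(x, ...) {
  if (x$single_stratum) {
    return(tibble(n_sites = nrow(x$data), slope = NA_real_,
                  pearson_r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x$data$n_mismatches, x$data$blunt_fraction)
  tibble(n_sites = nrow(x$data),
         slope = unname(coef(x$fit)[2]),
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value)
}
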