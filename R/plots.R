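#' Plot the scission profile of one or more sites
#'
#' Bar chart of PAM-proximal molecule counts by boundary label (14-20);
#' label 17 is the canonical blunt cut, 16-14 are 1-3 nt 5' overhangs.
#'
#' @param profiles output of [scission_profile()].
#' @param max_sites facet at most this many sites.
#' @return a ggplot object.
#' @export
plot_scission_profile <- function(profiles, max_sites = 12L) {
  profiles <- head(profiles, max_sites)
  profiles$site <- sprintf("%s:%d (%s)", profiles$chrom, profiles$start,
                           profiles$strand)
  long <- profiles |>
    select("site", all_of(prox_cols())) |>
    tidyr::pivot_longer(all_of(prox_cols()), names_to = "label",
                        names_prefix = "prox_", values_to = "count") |>
    mutate(label = as.integer(.data$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$count,
                                     fill = .data$label == 17L)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::scale_x_continuous(breaks = 14:20) +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(x = "boundary label (17 = blunt)",
                  y = "unique molecules") +
    ggplot2::theme_minimal()
}

#' Plot the per-position mismatch profile of nominated targets
#'
#' @param profile output of [mismatch_position_profile()].
#' @return a ggplot object.
#' @export
plot_mismatch_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_vline(xintercept = 10.5, linetype = "dashed") +
    ggplot2::annotate("text", x = 5.5, y = Inf, vjust = 1.5,
                      label = "PAM-distal") +
    ggplot2::annotate("text", x = 15.5, y = Inf, vjust = 1.5,
                      label = "seed") +
    ggplot2::labs(x = "protospacer position", y = "mismatch rate") +
    ggplot2::theme_minimal()
}

#' Plot a position-17/18 combination grid
#'
#' @param grid output of [combo_grid_17_18()].
#' @return a ggplot object.
#' @export
plot_combo_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$base18, y = .data$base17,
                                     fill = .data$mean_predicted_rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_predicted_rate))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", high = "#2166ac",
                                  name = "mean log2\nblunt rate") +
    ggplot2::labs(x = "base at position 18", y = "base at position 17") +
    ggplot2::theme_minimal()
}

#' Observed versus cross-validated predicted blunt rates
#'
#' @param object a `blunt_model` with CV predictions.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.blunt_model <- function(object, ...) {
  if (is.null(object$cv)) stop("model has no CV predictions", call. = FALSE)
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$observed,
                                          y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = "observed log2 blunt rate",
                  y = "held-out predicted log2 blunt rate",
                  subtitle = sprintf("%d-fold CV, Pearson r = %.3f",
                                     object$nfolds, object$cv_r)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
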