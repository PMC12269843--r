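#' @describeIn fit_steady_state Equilibrium binding curve: observed points
#'   and the fitted one-site isotherm on a log concentration axis, with the
#'   fitted KD marked.
#' @param object A fitted object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  stopifnot(object$converged)
  conc <- object$data$concentration_uM
  grid <- tibble(
    concentration_uM = exp(seq(log(min(conc)), log(max(conc)),
                               length.out = 200))
  ) %>%
    mutate(response = object$rmax * .data$concentration_uM /
             (object$kd + .data$concentration_uM))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_uM, .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (µM)", y = "Equilibrium response (RU)",
      title = sprintf("One-site steady-state fit: KD = %.3g µM",
                      object$kd)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_competition Competition curve: normalized binding versus
#'   competitor concentration with the fitted 4PL and the IC50 marked.
#' @param object A fitted object.
#' @export
autoplot.ic50_fit <- function(object, ...) {
  stopifnot(object$converged)
  conc <- object$data$competitor_conc_uM
  grid <- tibble(
    competitor_conc_uM = exp(seq(log(min(conc)), log(max(conc)),
                                 length.out = 200))
  ) %>%
    mutate(normalized_binding = object$bottom +
             (object$top - object$bottom) /
             (1 + (.data$competitor_conc_uM / object$ic50)^object$hill))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$competitor_conc_uM,
                               .data$normalized_binding)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Competitor (µM)", y = "Normalized binding (%)",
      title = if (object$ic50_gt_max) {
        sprintf("IC50 > %g µM", object$max_tested)
      } else {
        sprintf("4PL competition fit: IC50 = %.3g µM", object$ic50)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn compute_bsa Bar chart of region contributions to TCR-side
#'   burial (the pie-chart view of the footprint, drawn as bars).
#' @param object A `bsa_breakdown` object.
#' @export
autoplot.bsa_breakdown <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) abort("No region decomposition to plot")
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$label, -.data$pct),
                                   .data$pct)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = "% of TCR-side BSA",
                  title = sprintf("Interface footprint (total BSA %.0f Å²)",
                                  object$total_bsa)) +
    ggplot2::theme_minimal()
}

#' Footprint contact-count plot
#'
#' Stacked bar chart of interface contacts per TCR region, split by contact
#' kind.
#'
#' @param footprint Tibble from [summarize_footprint()].
#' @return A ggplot object.
#' @export
plot_footprint <- function(footprint) {
  long <- footprint %>%
    select("label", hbond = "n_hbond", vdw = "n_vdw",
           salt_bridge = "n_salt_bridge", disulfide = "n_disulfide") %>%
    tidyr::pivot_longer(-"label", names_to = "kind", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$n,
                                     fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Contacts",
                  title = "Interface contacts by region") +
    ggplot2::theme_minimal()
}
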