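#' Plot a viscoelastic spectrum
#'
#' Storage modulus, loss modulus and loss tangent against frequency (log
#' axis), faceted by quantity.
#'
#' @param object A `viscoelastic_spectrum` from [frequency_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.viscoelastic_spectrum <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("frequency_hz", "storage_mpa", "loss_mpa", "tan_delta") %>%
    tidyr::pivot_longer(-"frequency_hz", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = "Viscoelastic spectrum")
}

#' Loss-versus-storage damping scatter
#'
#' @param spectra A tibble of spectra (e.g. the `spectra` table of a study
#'   report), optionally with a `group` column.
#' @return A ggplot.
#' @export
plot_loss_storage <- function(spectra) {
  spectra <- as_tibble(spectra)
  p <- ggplot2::ggplot(spectra, ggplot2::aes(.data$storage_mpa, .data$loss_mpa))
  if ("group" %in% names(spectra)) {
    p <- p + ggplot2::aes(colour = .data$group, shape = .data$group)
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "storage modulus E' (MPa)", y = "loss modulus E'' (MPa)",
                  title = "Loss versus storage modulus")
}

#' Plot a load-displacement curve with its analysis landmarks
#'
#' Marks yield, ultimate and fracture points and any pop-in events on the
#' curve.
#'
#' @param curve A load-displacement tibble.
#' @param result The matching `bending_result` (optional; without it only
#'   the curve is drawn).
#' @return A ggplot.
#' @export
plot_bending_curve <- function(curve, result = NULL) {
  curve <- as_tibble(curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$displacement_mm, .data$load_n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "displacement (mm)", y = "load (N)",
                  title = "Three-point-bending curve")
  if (!is.null(result)) {
    stopifnot(inherits(result, "bending_result"))
    marks <- tibble(
      landmark = c("yield", "ultimate", "fracture"),
      displacement_mm = c(result$yield$displacement_mm,
                          result$ultimate$displacement_mm,
                          result$fracture$displacement_mm),
      load_n = c(result$yield$load_n, result$ultimate$load_n,
                 result$fracture$load_n)
    ) %>% dplyr::filter(!is.na(.data$displacement_mm))
    p <- p + ggplot2::geom_point(data = marks,
                                 ggplot2::aes(colour = .data$landmark), size = 3)
    if (nrow(result$popins) > 0) {
      p <- p + ggplot2::geom_point(data = result$popins,
                                   ggplot2::aes(y = .data$load_after_n),
                                   shape = 4, size = 3)
    }
  }
  p
}

#' Plot cohort weight trajectories
#'
#' @param object A `cohort_table` from [generate_cohort()].
#' @param ... Unused.
#' @return A ggplot of group mean body weight (with SE ribbon) over weeks.
#' @export
autoplot.cohort_table <- function(object, ...) {
  means <- as_tibble(object) %>%
    group_by(.data$group, .data$week) %>%
    summarise(mean_g = mean(.data$body_weight_g),
              se_g = sd(.data$body_weight_g) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(.data$week, .data$mean_g,
                                      colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_g - .data$se_g,
                                      ymax = .data$mean_g + .data$se_g),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "study week", y = "body weight (g)",
                  title = "Cohort weight trajectories")
}

#' Standard figure set for a study report
#'
#' Builds the conventional figure set from a [run_study()] report: weight
#' trajectories, viscoelastic spectra by group, the loss-versus-storage
#' scatter, and one annotated bending curve per group. Figures are built
#' from the report's tables only and are never inputs to any computation.
#'
#' @param report A `study_report`.
#' @param dir Optional directory; when given, figures are also written as
#'   PDFs there.
#' @return A named list of ggplot objects, invisibly if `dir` is given.
#' @export
make_figures <- function(report, dir = NULL) {
  stopifnot(inherits(report, "study_report"))
  spectra_plot <- ggplot2::ggplot(
    tidyr::pivot_longer(report$spectra,
                        c("storage_mpa", "loss_mpa", "tan_delta"),
                        names_to = "quantity"),
    ggplot2::aes(.data$frequency_hz, .data$value, colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, title = "Viscoelastic spectra")
  figs <- list(
    weights = autoplot(report$cohort),
    spectra = spectra_plot,
    loss_storage = plot_loss_storage(report$spectra)
  )
  for (g in report$config$groups) {
    mc <- report$config$mechanics[[g]]
    curve <- generate_bending_curve(mc$truth)
    res <- analyze_bending(curve, mc$geometry)
    figs[[paste0("bending_", g)]] <- plot_bending_curve(curve, res) +
      ggplot2::ggtitle(paste("Three-point bending -", g))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(figs)) {
      ggplot2::ggsave(file.path(dir, paste0(nm, ".pdf")), figs[[nm]],
                      width = 7, height = 5)
    }
    return(invisible(figs))
  }
  figs
}
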