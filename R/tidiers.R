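# broom-style tidiers and ggplot2 autoplot methods for sampler results.

#' Tidy a loop ensemble
#'
#' One row per model with its energies and metrics (structures and move
#' lineage dropped).
#'
#' @param x A `loop_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.loop_ensemble <- function(x, ...) {
  x$models[, setdiff(names(x$models), c("structure", "move_info", "best_trace"))]
}

#' Glance at a loop ensemble
#'
#' One-row summary: model counts, acceptance rate, lowest-energy-model RMSD
#' and sub-angstrom fraction (when a reference was supplied).
#'
#' @param x A `loop_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.loop_ensemble <- function(x, ...) {
  ok <- !x$models$failed
  out <- tibble::tibble(
    mode = x$config$mode,
    n_models = nrow(x$models),
    n_failed = sum(!ok),
    acceptance_rate = sum(x$models$accepted[ok]) / max(1, sum(x$models$attempted[ok])),
    best_total = if (any(ok)) min(x$models$total[ok]) else NA_real_)
  if (any(ok) && !all(is.na(x$models$rmsd[ok]))) {
    em <- evaluate_ensemble(x)
    out$lowest_energy_rmsd <- em$lowest_energy_rmsd
    out$fraction_subangstrom <- em$fraction_subangstrom
  }
  out
}

#' Energy-versus-RMSD funnel plot of a loop ensemble
#'
#' @param object A `loop_ensemble` with reference RMSDs.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.loop_ensemble <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$failed, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rmsd, y = .data$total)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "segment backbone RMSD to native (Å)",
                  y = "total energy",
                  title = sprintf("%s ensemble (%d models)",
                                  object$config$mode, nrow(df))) +
    ggplot2::theme_minimal()
}

#' Ramachandran scatter of a structure's torsions
#'
#' @param bb A `backbone` tibble.
#' @param segment Optional [segment_spec()] restricting the plot.
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(bb, segment = NULL) {
  tor <- backbone_torsions(bb, segment)
  tor <- tor[!is.na(tor$phi) & !is.na(tor$psi), , drop = FALSE]
  ggplot2::ggplot(tor, ggplot2::aes(x = .data$phi, y = .data$psi)) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi), y = expression(psi)) +
    ggplot2::theme_minimal()
}

#' Benchmark metric plot: fragment distance versus sampling success
#'
#' @param metrics Per-case metrics tibble with `fragment_distance` and
#'   `fraction_subangstrom` columns.
#' @return A ggplot object.
#' @export
plot_fragment_correlation <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$fragment_distance,
                                        y = .data$fraction_subangstrom)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean 3-mer fragment distance to native",
                  y = "fraction of sub-Å models") +
    ggplot2::theme_minimal()
}
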