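#' Step plot of a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tibble::as_tibble(object)[, c("time", "survival")]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "Survival",
                  title = paste("Freedom from", attr(object, "endpoint"))) +
    ggplot2::theme_minimal()
}

#' Step plot of region-stratified survival curves
#'
#' @param object A `region_survival` from [survival_by_region()].
#' @param ... Unused.
#' @return A ggplot with one step curve per group and the omnibus log-rank
#'   p value in the subtitle.
#' @export
autoplot.region_survival <- function(object, ...) {
  d <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")]
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Age (years)", y = "Survival", colour = "Region",
      title = paste("Freedom from", object$endpoint),
      subtitle = sprintf("log-rank p = %.3g", object$omnibus$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Arc diagram of inter-chain residue contacts
#'
#' A simple linear arc rendering of a (state-classified) contact table:
#' residue positions along the x axis grouped by entity, with one arc per
#' contact, coloured by calcium-state class when present.
#'
#' @param contacts Contact tibble, e.g. from [classify_contact_states()].
#' @return A ggplot.
#' @export
plot_contact_arcs <- function(contacts) {
  entities <- sort(unique(c(contacts$entity_a, contacts$entity_b)))
  offsets <- stats::setNames(
    c(0, cumsum(rep(1.1, length(entities) - 1))) *
      max(contacts$pos_a, contacts$pos_b), entities)
  d <- contacts |>
    dplyr::mutate(
      x0 = unname(offsets[.data$entity_a]) + .data$pos_a,
      x1 = unname(offsets[.data$entity_b]) + .data$pos_b,
      state = if ("state_class" %in% names(contacts)) .data$state_class else "contact"
    )
  ggplot2::ggplot(d) +
    ggplot2::geom_curve(
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = 0, yend = 0,
                   colour = .data$state),
      curvature = -0.4, alpha = 0.7) +
    ggplot2::labs(x = "Residue position (entities offset)", y = NULL,
                  colour = "State") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Per-site selective pressure along a protein
#'
#' Plots omega against reference position, highlighting the selection
#' class; the neutral line at omega = 1 is drawn for reference.
#'
#' @param sites Per-site table from [site_selection_table()] or
#'   [site_kaks()] (needs `omega` and a position column).
#' @return A ggplot.
#' @export
plot_site_selection <- function(sites) {
  xcol <- if ("ref_position" %in% names(sites)) "ref_position" else "column"
  d <- sites[!is.na(sites$omega), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xcol]], y = .data$omega,
                                  colour = .data$selection_class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Residue position", y = expression(omega == Ka / Ks),
                  colour = "Selection") +
    ggplot2::theme_minimal()
}

#' Per-residue RMSF profile plot
#'
#' @param rmsf Tibble from [rmsf_profile()].
#' @return A ggplot.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
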