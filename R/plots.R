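#' Plot a pipeline report
#'
#' Dot-and-error-bar plot of the mean caliper distance per structure
#' (± replicate SD), coloured by predicted siRNA length class, with the
#' reference distance as a dashed line.
#'
#' @param object A `ruler_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ruler_report <- function(object, ...) {
  df <- object$results
  d_ref <- if (!is.null(object$model)) object$model$d_ref else
    object$model_summary$d_ref
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$structure_id, .data$mean_distance),
    y = .data$mean_distance,
    colour = factor(.data$predicted_nt))) +
    ggplot2::geom_hline(yintercept = d_ref, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_distance - .data$sd,
      ymax = .data$mean_distance + .data$sd)) +
    ggplot2::labs(x = NULL, y = "mean caliper distance (Å)",
                  colour = "predicted nt") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot a calibration model
#'
#' The distance-to-length relation over a distance range; for a fitted model
#' the calibration points are overlaid.
#'
#' @param object A `ruler_calibration` object.
#' @param from,to Distance range in Å (defaults cover the insect Dicer-2
#'   range).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ruler_calibration <- function(object, from = 56, to = 66, ...) {
  d <- seq(from, to, by = 0.05)
  pred <- suppressWarnings(predict_length(d, object))
  p <- ggplot2::ggplot(pred, ggplot2::aes(.data$mean_distance,
                                          .data$predicted_nt)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "mean caliper distance (Å)",
                  y = "predicted siRNA length (nt)") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(.data$mean_distance, .data$length_nt),
      colour = "firebrick", size = 2)
  }
  p
}

#' Plot the caliper geometry of an annotated structure
#'
#' 2D projection (first two principal axes of the Cα cloud) of a structure
#' with the four caliper sites highlighted and the two measured
#' pocket-to-catalytic-center segments drawn.
#'
#' @param structure A `dicer_structure` atom table.
#' @param sites A `site_map` for the structure.
#' @return A ggplot object.
#' @export
plot_ruler_geometry <- function(structure, sites) {
  ca <- dplyr::filter(as_tibble(structure), .data$atom %in% c("CA", "P"))
  m <- as.matrix(ca[, c("x", "y", "z")])
  mc <- sweep(m, 2, colMeans(m))
  v <- svd(mc, nu = 0, nv = 2)$v
  pr <- mc %*% v
  ca$pc1 <- pr[, 1]
  ca$pc2 <- pr[, 2]
  lab <- dplyr::left_join(ca,
                          dplyr::filter(as_tibble(sites), .data$resolved),
                          by = c("chain", "resno"))
  cents <- lapply(RULER_SITES, function(s) {
    cen <- site_centroid(structure, sites, s)
    cc <- (cen - colMeans(m)) %*% v
    tibble(site = s, pc1 = cc[1], pc2 = cc[2])
  })
  cents <- dplyr::bind_rows(cents)
  seg <- tibble(
    x = cents$pc1[cents$site == "pocket_3prime"],
    y = cents$pc2[cents$site == "pocket_3prime"],
    xend = cents$pc1[cents$site == "RIII_A"],
    yend = cents$pc2[cents$site == "RIII_A"])
  seg <- dplyr::bind_rows(seg, tibble(
    x = cents$pc1[cents$site == "pocket_5prime"],
    y = cents$pc2[cents$site == "pocket_5prime"],
    xend = cents$pc1[cents$site == "RIII_B"],
    yend = cents$pc2[cents$site == "RIII_B"]))
  ggplot2::ggplot(lab, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(colour = "grey70", size = 1) +
    ggplot2::geom_point(data = dplyr::filter(lab, !is.na(.data$site)),
                        ggplot2::aes(colour = .data$site), size = 2) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          inherit.aes = FALSE, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)", colour = "site") +
    ggplot2::theme_minimal()
}
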