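#' Plot evaluation metrics across candidate delineations
#'
#' Kappa, accuracy and precision per candidate, candidates ordered by source
#' time step (abiotic partitions last); the best candidate is highlighted.
#'
#' @param object An [evaluate_all()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_evaluation <- function(object, ...) {
  tbl <- tibble::as_tibble(object) |>
    dplyr::mutate(name = factor(.data$name, levels = unique(.data$name))) |>
    tidyr::pivot_longer(c("kappa", "accuracy", "precision"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$name, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2.5) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "best") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box plot of within- vs between-metacommunity beta-diversity
#'
#' @param ev An [evaluate_all()] result.
#' @param d The [delineation] to classify pairs against.
#' @return A ggplot.
#' @export
plot_beta_pairs <- function(ev, d) {
  pr <- pair_diagnostics(ev, d) |>
    dplyr::filter(!.data$excluded)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$pair_class, y = .data$beta)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = attr(ev, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Jaccard dissimilarity",
                  title = delineation_label(d)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of gamma diversity against a size metric
#'
#' @param records A [build_gamma_records()] table.
#' @param predictor `"total_area"`, `"n_patches"` or `"diameter"`.
#' @return A ggplot (log-scaled predictor axis).
#' @export
plot_gamma_scatter <- function(records,
                               predictor = c("total_area", "n_patches",
                                             "diameter")) {
  predictor <- match.arg(predictor)
  rec <- dplyr::filter(records, .data$included)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data[[predictor]], y = .data$gamma)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(predictor, " (log scale)"),
                  y = "gamma diversity") +
    ggplot2::theme_minimal()
}

#' Map a patch layer
#'
#' @param layer A raster-kind [patch_layer].
#' @param delineation Optional [delineation] whose extents are overlaid.
#' @return A ggplot tile map of the patches.
#' @export
plot_patch_map <- function(layer, delineation = NULL) {
  stopifnot(layer_kind(layer) == "raster")
  meta <- layer_meta(layer)
  tiles <- purrr::map_dfr(seq_len(nrow(layer)), function(i) {
    cells <- layer$geometry[[i]]
    ctr <- cell_centre_xy(meta, cells[, 1], cells[, 2])
    tibble::tibble(x = ctr[, 1], y = ctr[, 2], patch_id = layer$patch_id[i])
  })
  p <- ggplot2::ggplot(tiles, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$patch_id),
                       width = meta$cell, height = meta$cell,
                       show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(delineation)) {
    hulls <- purrr::map_dfr(seq_len(nrow(delineation$metacommunities)),
                            function(k) {
      ring <- delineation$metacommunities$extent[[k]]
      tibble::tibble(x = ring[, 1], y = ring[, 2],
                     mc_id = delineation$metacommunities$mc_id[k])
    })
    p <- p + ggplot2::geom_polygon(data = hulls,
                                   ggplot2::aes(group = .data$mc_id),
                                   fill = NA, colour = "black")
  }
  p
}
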