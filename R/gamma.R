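#' Per-metacommunity gamma diversity and size metrics
#'
#' For each metacommunity of a delineation: gamma diversity (richness union
#' over member current patches), total area and patch count of the member
#' patches at the delineation's source time step (the historical extent is
#' the size that matters for a historical definition), and the network
#' diameter (mean shortest-path distance) from the source network.
#' Metacommunities with species data in fewer than two patches are flagged
#' `included = FALSE` and left out of correlations: their within-group
#' structure is unobservable.
#'
#' @param d A [delineation] derived from `net`.
#' @param m An [build_occurrence_matrix()] result.
#' @param net The source [build_network()] network (`NULL` for polygon
#'   delineations; diameter is then `NA`).
#' @return Tibble `mc_id`, `gamma`, `total_area`, `n_patches`, `diameter`,
#'   `diameter_max`, `n_data_patches`, `included`.
#' @export
build_gamma_records <- function(d, m, net = NULL) {
  stopifnot(inherits(d, "delineation"))
  mt <- d$metacommunities
  purrr::map_dfr(seq_len(nrow(mt)), function(k) {
    members <- mt$members[[k]]
    data_members <- intersect(members, rownames(m))
    gamma <- gamma_richness(m, members)
    src_members <- mt$source_members[[k]]
    dia <- dia_max <- NA_real_
    if (!is.null(net) && length(src_members) >= 2) {
      v <- suppressWarnings(network_diameter(net, src_members))
      dia <- as.numeric(v); dia_max <- attr(v, "max")
    }
    tibble::tibble(
      mc_id = mt$mc_id[k],
      gamma = gamma,
      total_area = mt$total_source_area[k],
      n_patches = mt$n_source_patches[k],
      diameter = dia, diameter_max = dia_max,
      n_data_patches = length(data_members),
      included = length(data_members) >= 2 && !mt$singleton[k] && !is.na(gamma)
    )
  })
}

#' Correlate gamma diversity with a metacommunity size metric
#'
#' Pearson correlation (two-sided p-value) of gamma diversity against the
#' log-transformed predictor, over included metacommunities. The predictors
#' are log-transformed (natural log; correlation is base-invariant) as size
#' spans orders of magnitude; gamma itself is not transformed by default.
#'
#' @param records A [build_gamma_records()] table.
#' @param predictor `"total_area"`, `"n_patches"` or `"diameter"`.
#' @param transform `"log"` (default) or `"none"` for the predictor.
#' @param transform_gamma Also log-transform gamma (sensitivity option).
#' @return One-row tibble `predictor`, `transform`, `pearson_r`, `p_value`,
#'   `n`.
#' @export
correlate_gamma <- function(records,
                            predictor = c("total_area", "n_patches", "diameter"),
                            transform = c("log", "none"),
                            transform_gamma = FALSE) {
  predictor <- match.arg(predictor)
  transform <- match.arg(transform)
  rec <- dplyr::filter(records, .data$included, !is.na(.data[[predictor]]))
  x <- rec[[predictor]]
  y <- rec$gamma
  if (transform == "log") {
    stopifnot(all(x > 0))
    x <- log(x)
  }
  if (transform_gamma) y <- log(y)
  out <- tibble::tibble(predictor = predictor, transform = transform,
                        pearson_r = NA_real_, p_value = NA_real_,
                        n = length(x))
  if (length(x) < 3) {
    warning("fewer than 3 included metacommunities: correlation undefined")
    return(out)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: correlation undefined")
    return(out)
  }
  ct <- cor.test(x, y, method = "pearson")
  out$pearson_r <- unname(ct$estimate)
  out$p_value <- ct$p.value
  out
}

#' Metacommunity change over a harmonized time series
#'
#' For each time step's delineation, the mean member-patch count and mean
#' member-patch area over the metacommunities that have species data in more
#' than one patch (others say nothing about within-metacommunity structure).
#' On a strictly degrading landscape both summaries shrink through time.
#'
#' @param delineations List of network-sourced [delineation]s, one per time
#'   step, each built with its source layer.
#' @param m An [build_occurrence_matrix()] result.
#' @return Tibble `timestep`, `n_metacommunities`, `mean_n_patches`,
#'   `mean_patch_area` (`NA` with a warning when no metacommunity qualifies).
#' @export
summarize_timeseries <- function(delineations, m) {
  purrr::map_dfr(delineations, function(d) {
    mt <- d$metacommunities
    qual <- purrr::map_lgl(mt$members, function(mem) {
      length(intersect(mem, rownames(m))) > 1
    })
    ts <- as.numeric(d$source$timestep)
    if (!any(qual)) {
      warning("no metacommunity with species data in >1 patch at t = ",
              format(ts))
      return(tibble::tibble(timestep = ts, n_metacommunities = 0L,
                            mean_n_patches = NA_real_,
                            mean_patch_area = NA_real_))
    }
    tibble::tibble(
      timestep = ts,
      n_metacommunities = sum(qual),
      mean_n_patches = mean(mt$n_source_patches[qual]),
      mean_patch_area = mean(mt$total_source_area[qual] /
                               mt$n_source_patches[qual])
    )
  })
}
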