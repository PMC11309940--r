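#' Enumerate eligible patch pairs
#'
#' All unordered pairs of patches with species data whose edge-to-edge
#' separation is at most `limit` (default 15 km). The limit exists because
#' pairs much farther apart are almost always completely dissimilar, and that
#' saturation of dissimilarity values swamps the classification signal.
#'
#' @param m An [build_occurrence_matrix()] result.
#' @param layer The current-time [patch_layer] (must contain the matrix
#'   patches).
#' @param limit Pairing limit in metres (default 15000); `Inf` keeps all
#'   pairs.
#' @param d Optional precomputed [pairwise_edge_distance()] matrix for
#'   `layer`.
#' @return Tibble `patch_i`, `patch_j`, `separation` (one row per unordered
#'   pair).
#' @export
enumerate_pairs <- function(m, layer, limit = 15000, d = NULL) {
  ids <- rownames(m)
  stopifnot(all(ids %in% layer$patch_id))
  if (is.null(d)) d <- pairwise_edge_distance(layer)
  d <- d[ids, ids, drop = FALSE]
  idx <- which(upper.tri(d) & d <= limit, arr.ind = TRUE)
  tibble::tibble(patch_i = ids[idx[, 1]], patch_j = ids[idx[, 2]],
                 separation = as.numeric(d[idx]))
}

#' Classify patch pairs as within or between metacommunities
#'
#' A pair is `within` when both patches share a metacommunity, `between`
#' otherwise. Pairs touching an unassigned patch or a singleton
#' metacommunity are ineligible (isolated single-patch metacommunities are
#' not used for assessment) and flagged `excluded`.
#'
#' @param pairs Tibble from [enumerate_pairs()].
#' @param d A [delineation].
#' @return `pairs` with added `pair_class` (`"within"`/`"between"`, `NA` when
#'   excluded) and logical `excluded`.
#' @export
classify_pairs <- function(pairs, d) {
  stopifnot(inherits(d, "delineation"))
  mc <- setNames(d$membership$mc_id, d$membership$patch_id)
  singleton <- d$metacommunities$mc_id[d$metacommunities$singleton]
  mi <- unname(mc[pairs$patch_i])
  mj <- unname(mc[pairs$patch_j])
  excluded <- is.na(mi) | is.na(mj) | mi %in% singleton | mj %in% singleton
  pair_class <- ifelse(excluded, NA_character_,
                       ifelse(mi == mj, "within", "between"))
  dplyr::mutate(pairs, pair_class = pair_class, excluded = excluded)
}

#' Binarize beta-diversity values
#'
#' Splits pairwise dissimilarities into `low` and `high` at the median (the
#' default) or at a fixed value. Values exactly at the threshold go to
#' `high`, so at most half the values are strictly below a median threshold.
#'
#' @param beta Numeric dissimilarities of all eligible pairs.
#' @param threshold `"median"` or a fixed numeric cut.
#' @return Character vector `"low"`/`"high"`; attributes `threshold` (the cut
#'   used) and `degenerate` (TRUE when all values are identical).
#' @export
binarize_beta <- function(beta, threshold = "median") {
  stopifnot(length(beta) >= 2)
  cut <- if (identical(threshold, "median")) median(beta) else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  degenerate <- length(unique(beta)) == 1
  if (degenerate) warning("all beta values identical: binarization degenerate")
  structure(ifelse(beta < cut, "low", "high"),
            threshold = cut, degenerate = degenerate)
}

#' Classification agreement metrics for a within/between contingency table
#'
#' Rows are the pair class (`within`, `between`), columns the binarized
#' beta class (`low`, `high`). Expected agreement: within pairs are low,
#' between pairs are high. Accuracy is the agreeing fraction; precision takes
#' (within, low) as the positive class; Cohen's kappa corrects accuracy for
#' chance agreement from the marginals,
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param tab 2x2 numeric matrix of counts, rows `within`/`between`, columns
#'   `low`/`high`.
#' @return One-row tibble `accuracy`, `precision`, `kappa` (kappa is `NA`
#'   when the marginals are degenerate, i.e. `p_e = 1`).
#' @export
agreement_metrics <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  p_o <- (tab[1, 1] + tab[2, 2]) / n
  p_e <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_ else {
    (p_o - p_e) / (1 - p_e)
  }
  precision <- if (sum(tab[, 1]) == 0) NA_real_ else tab[1, 1] / sum(tab[, 1])
  tibble::tibble(accuracy = p_o, precision = precision, kappa = kappa)
}

#' Compare within- and between-metacommunity beta distributions
#'
#' Two-sided t-test (Welch's unequal-variance form by default, a pooled
#' Student variant on request) on the dissimilarity values of the two pair
#' classes, plus the direction check that a sensible delineation must pass:
#' the mean within-metacommunity dissimilarity is *lower* than the
#' between-metacommunity mean.
#'
#' @param within,between Numeric beta values of the two pair classes (each
#'   length >= 2).
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @return One-row tibble `t_stat`, `df`, `p_value`, `direction_ok`.
#' @export
beta_distribution_test <- function(within, between, var_equal = FALSE) {
  stopifnot(length(within) >= 2, length(between) >= 2)
  if (stats::sd(within) == 0 && stats::sd(between) == 0) {
    if (mean(within) == mean(between)) {
      return(tibble::tibble(t_stat = 0, df = NA_real_, p_value = 1,
                            direction_ok = FALSE))
    }
    warning("zero variance in both groups: p-value unstable")
  }
  tt <- t.test(within, between, var.equal = var_equal)
  tibble::tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 direction_ok = mean(within) < mean(between))
}

#' Score one delineation against the shared pair universe
#'
#' @param d A [delineation].
#' @param pairs Pair universe with `beta` and `beta_class` columns (see
#'   [evaluate_all()]).
#' @param var_equal Passed to [beta_distribution_test()].
#' @return One-row tibble of counts and metrics; `degenerate` flags runs with
#'   an empty within or between class.
#' @keywords internal
evaluate_delineation <- function(d, pairs, var_equal = FALSE) {
  cls <- classify_pairs(pairs, d)
  src <- d$source
  base <- tibble::tibble(
    source = src$type,
    timestep = if (src$type == "network") as.numeric(src$timestep) else NA_real_,
    theta = src$theta, name = delineation_label(d)
  )
  el <- dplyr::filter(cls, !.data$excluded)
  n_w <- sum(el$pair_class == "within")
  n_b <- sum(el$pair_class == "between")
  if (n_w < 2 || n_b < 2) {
    return(dplyr::bind_cols(base, tibble::tibble(
      n_within = n_w, n_between = n_b, n_excluded = sum(cls$excluded),
      accuracy = NA_real_, precision = NA_real_, kappa = NA_real_,
      t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
      direction_ok = FALSE, degenerate = TRUE)))
  }
  tab <- matrix(c(
    sum(el$pair_class == "within" & el$beta_class == "low"),
    sum(el$pair_class == "between" & el$beta_class == "low"),
    sum(el$pair_class == "within" & el$beta_class == "high"),
    sum(el$pair_class == "between" & el$beta_class == "high")
  ), 2, 2, dimnames = list(c("within", "between"), c("low", "high")))
  met <- agreement_metrics(tab)
  tst <- beta_distribution_test(el$beta[el$pair_class == "within"],
                                el$beta[el$pair_class == "between"],
                                var_equal = var_equal)
  dplyr::bind_cols(base, tibble::tibble(
    n_within = n_w, n_between = n_b, n_excluded = sum(cls$excluded)),
    met, tst, tibble::tibble(degenerate = FALSE))
}

#' Evaluate candidate delineations against beta-diversity
#'
#' Builds the shared pair universe once (all patch pairs with species data
#' within the pairing limit), attaches each pair's Jaccard dissimilarity,
#' binarizes it once globally — the median threshold is computed over the
#' shared universe, not per delineation, so kappa values are comparable
#' across candidates — and scores every delineation. Candidate delineations
#' only reshuffle pairs between the within and between classes (minus
#' per-candidate singleton/unassigned exclusions, which are reported).
#'
#' @param delineations List of [delineation] objects.
#' @param m An [build_occurrence_matrix()] result.
#' @param layer The current-time [patch_layer].
#' @param limit Pairing limit in metres (default 15000).
#' @param threshold `"median"` or a fixed numeric beta cut.
#' @param var_equal Use the pooled Student t-test instead of Welch.
#' @param d_matrix Optional precomputed distance matrix for `layer`.
#' @return Tibble of class `mc_evaluation`, one row per delineation, with a
#'   logical `best` flag on the row maximising kappa among candidates whose
#'   direction check passes (ties go to the later/current time step, the
#'   delineation needing the fewest historical assumptions). The pair
#'   universe (with beta and class columns) is attached as attribute
#'   `pairs`; the beta cut as `threshold`.
#' @export
evaluate_all <- function(delineations, m, layer, limit = 15000,
                         threshold = "median", var_equal = FALSE,
                         d_matrix = NULL) {
  stopifnot(length(delineations) >= 1)
  pairs <- enumerate_pairs(m, layer, limit = limit, d = d_matrix)
  if (nrow(pairs) < 2) stop("fewer than two eligible patch pairs")
  b <- beta_matrix(m)
  pairs$beta <- b[cbind(pairs$patch_i, pairs$patch_j)]
  bc <- binarize_beta(pairs$beta, threshold = threshold)
  pairs$beta_class <- as.character(bc)
  res <- purrr::map_dfr(delineations, evaluate_delineation, pairs = pairs,
                        var_equal = var_equal)
  cand <- which(res$direction_ok & !res$degenerate & !is.na(res$kappa))
  res$best <- FALSE
  if (length(cand)) {
    best <- cand[order(-res$kappa[cand], -dplyr::coalesce(res$timestep[cand], -Inf))][1]
    res$best[best] <- TRUE
  }
  structure(res, pairs = pairs, threshold = attr(bc, "threshold"),
            class = c("mc_evaluation", class(res)))
}

#' @export
print.mc_evaluation <- function(x, ...) {
  cat(sprintf("<mc_evaluation> %d delineation(s), beta cut %.3f\n", nrow(x),
              attr(x, "threshold")))
  NextMethod()
}

#' Tidy an evaluation table
#'
#' @param x An [evaluate_all()] result.
#' @param ... Unused.
#' @return A plain tibble of per-delineation metrics.
#' @export
tidy.mc_evaluation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line summary of an evaluation
#'
#' @param x An [evaluate_all()] result.
#' @param ... Unused.
#' @return One-row tibble: number of candidates, the beta cut, and the best
#'   candidate's name and kappa.
#' @export
glance.mc_evaluation <- function(x, ...) {
  best <- dplyr::filter(tibble::as_tibble(x), .data$best)
  tibble::tibble(
    n_delineations = nrow(x),
    beta_threshold = attr(x, "threshold"),
    best_name = if (nrow(best)) best$name else NA_character_,
    best_kappa = if (nrow(best)) best$kappa else NA_real_
  )
}

#' Per-pair diagnostics for box-plot reproduction
#'
#' @param ev An [evaluate_all()] result.
#' @param d The [delineation] to classify against.
#' @return Tibble of pair ids, separation, beta, pair class and beta class.
#' @export
pair_diagnostics <- function(ev, d) {
  classify_pairs(attr(ev, "pairs"), d)
}
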