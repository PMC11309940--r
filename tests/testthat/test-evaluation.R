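# a delineation object assembled directly from a membership table
mk_delineation <- function(members, unassigned = character(),
                           source = list(type = "network", timestep = 2010,
                                         theta = 500, name = NA)) {
  membership <- tibble::tibble(
    patch_id = unlist(members),
    mc_id = rep(names(members), lengths(members))
  )
  meta <- tibble::tibble(
    mc_id = names(members),
    source_members = unname(members),
    n_source_patches = lengths(members),
    total_source_area = NA_real_,
    members = unname(members),
    n_members = lengths(members),
    singleton = lengths(members) < 2,
    extent = replicate(length(members), cbind(0, 0), simplify = FALSE)
  )
  structure(list(membership = membership, metacommunities = meta,
                 unassigned = unassigned, source = source),
            class = "delineation")
}

test_that("pair enumeration respects the separation limit", {
  l <- rect_layer(list(c(0, 100, 0, 100), c(2000, 2100, 0, 100),
                       c(4000, 4100, 0, 100), c(30000, 30100, 0, 100)))
  m <- mk_occmat(setNames(list("a", "b", "c", "d"), l$patch_id))
  p <- enumerate_pairs(m, l, limit = 15000)
  expect_equal(nrow(p), 3)                       # the 20 km patch drops out
  expect_false("P0004" %in% c(p$patch_i, p$patch_j))
  p_all <- enumerate_pairs(m, l, limit = Inf)
  expect_equal(nrow(p_all), choose(4, 2))
  l3 <- rect_layer(list(c(0, 1, 0, 1), c(10, 11, 0, 1), c(20, 21, 0, 1)))
  m3 <- mk_occmat(setNames(list("a", "b", "c"), l3$patch_id))
  expect_equal(nrow(enumerate_pairs(m3, l3)), 3)
})

test_that("pairs classify as within/between with singleton exclusion", {
  pairs <- expand.grid(i = 1:4, j = 1:4) |>
    subset(i < j)
  pairs <- tibble::tibble(patch_i = paste0("P", pairs$i),
                          patch_j = paste0("P", pairs$j),
                          separation = 100)
  d <- mk_delineation(list(MC1 = c("P1", "P2"), MC2 = c("P3", "P4")))
  cls <- classify_pairs(pairs, d)
  expect_equal(sum(cls$pair_class == "within", na.rm = TRUE), 2)
  expect_equal(sum(cls$pair_class == "between", na.rm = TRUE), 4)
  # a singleton metacommunity excludes all its pairs
  d5 <- mk_delineation(list(MC1 = c("P1", "P2"), MC2 = c("P3", "P4"),
                            MC3 = "P5"))
  pairs5 <- tibble::tibble(patch_i = c("P5", "P5", "P1"),
                           patch_j = c("P1", "P3", "P2"), separation = 100)
  cls5 <- classify_pairs(pairs5, d5)
  expect_equal(cls5$excluded, c(TRUE, TRUE, FALSE))
  # unassigned patches are excluded too
  d6 <- mk_delineation(list(MC1 = c("P1", "P2")), unassigned = "P9")
  cls6 <- classify_pairs(tibble::tibble(patch_i = "P1", patch_j = "P9",
                                        separation = 1), d6)
  expect_true(cls6$excluded)
})

test_that("beta binarization uses a strict-below-threshold rule", {
  v <- c(0.2, 0.5, 0.8, 0.9)
  cls <- binarize_beta(v)
  expect_equal(as.character(cls), c("low", "low", "high", "high"))
  expect_equal(attr(cls, "threshold"), median(v))
  # value exactly at the threshold is high
  expect_equal(as.character(binarize_beta(c(0.79, 0.80), threshold = 0.8)),
               c("low", "high"))
  # median rule: at most half the values strictly below
  set.seed(2)
  for (rep in 1:10) {
    v <- runif(sample(5:30, 1))
    cls <- binarize_beta(v)
    expect_lte(sum(cls == "low"), length(v) / 2)
  }
  expect_warning(binarize_beta(rep(0.8, 5)), "degenerate")
})

test_that("agreement metrics match closed-form accuracy, precision and kappa", {
  tab <- matrix(c(40, 10, 10, 40), 2, 2,
                dimnames = list(c("within", "between"), c("low", "high")))
  met <- agreement_metrics(tab)
  expect_equal(met$accuracy, 0.8)
  expect_equal(met$precision, 0.8)
  expect_equal(met$kappa, (0.8 - 0.5) / (1 - 0.5))
  # perfect agreement
  perfect <- agreement_metrics(matrix(c(50, 0, 0, 50), 2, 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  # degenerate marginals: kappa undefined
  expect_true(is.na(agreement_metrics(matrix(c(10, 0, 0, 0), 2, 2))$kappa))
  # kappa invariant under a simultaneous swap of both label pairs
  set.seed(13)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    k1 <- agreement_metrics(tab)$kappa
    k2 <- agreement_metrics(tab[2:1, 2:1])$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (rep in 1:30) {
    tab <- matrix(rpois(4, 25) + 1, 2, 2)
    expect_equal(agreement_metrics(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("Welch test reproduces the hand-computed example", {
  res <- beta_distribution_test(c(0.2, 0.3, 0.4), c(0.8, 0.9, 1.0))
  expect_equal(res$t_stat, -7.348, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-7.348469, 4), tolerance = 1e-4)
  expect_true(res$direction_ok)
  # identical groups
  same <- beta_distribution_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$direction_ok)
  # significance and direction are decoupled
  rev <- beta_distribution_test(c(0.8, 0.9, 1.0), c(0.2, 0.3, 0.4))
  expect_lt(rev$p_value, 0.01)
  expect_false(rev$direction_ok)
})

test_that("the pooled-variance variant is available", {
  set.seed(4)
  a <- runif(8); b <- runif(12)
  w <- beta_distribution_test(a, b)
  s <- beta_distribution_test(a, b, var_equal = TRUE)
  expect_equal(s$df, 18)
  expect_false(isTRUE(all.equal(w$df, s$df)))
})

test_that("evaluate_all scores one delineation and flags best iff direction holds", {
  l <- rect_layer(list(c(0, 100, 0, 100), c(300, 400, 0, 100),
                       c(5000, 5100, 0, 100), c(5300, 5400, 0, 100)))
  # two tight communities: within pairs similar, between pairs dissimilar
  m <- mk_occmat(setNames(
    list(c("a", "b", "c"), c("a", "b", "c", "d"),
         c("x", "y", "z"), c("x", "y", "w")), l$patch_id))
  d <- mk_delineation(list(MC1 = c("P0001", "P0002"),
                           MC2 = c("P0003", "P0004")))
  ev <- evaluate_all(list(d), m, l)
  expect_s3_class(ev, "mc_evaluation")
  expect_equal(nrow(ev), 1)
  expect_true(ev$direction_ok)
  expect_true(ev$best)
  expect_equal(ev$n_within, 2)
  expect_equal(ev$n_between, 4)
  expect_gt(ev$kappa, 0.9)
  # reversed labels: direction fails, so nothing is flagged best
  d_bad <- mk_delineation(list(MC1 = c("P0001", "P0003"),
                               MC2 = c("P0002", "P0004")))
  ev2 <- evaluate_all(list(d_bad), m, l)
  expect_false(any(ev2$best))
  # tidy/glance accessors
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(glance(ev)$best_kappa, ev$kappa)
})

test_that("degenerate delineations (no between pairs) are flagged, not scored", {
  l <- rect_layer(list(c(0, 100, 0, 100), c(300, 400, 0, 100),
                       c(600, 700, 0, 100)))
  m <- mk_occmat(setNames(list(c("a", "b"), c("a", "c"), c("b", "c")),
                          l$patch_id))
  d_one <- mk_delineation(list(MC1 = l$patch_id))
  # all three communities here are equally dissimilar, so binarization also
  # reports a degenerate threshold
  expect_warning(ev <- evaluate_all(list(d_one), m, l), "degenerate")
  expect_true(ev$degenerate)
  expect_true(is.na(ev$kappa))
  expect_false(any(ev$best))
})

test_that("the beta threshold is shared across all candidate delineations", {
  lp <- small_lp(9)
  scn <- generate_landscape(lp)
  series <- degrade(scn, lp, small_dp(9))
  cur <- series[[3]]$layer
  occ <- generate_communities(cur, dplyr::rename(series[[3]]$truth,
                                                 group = "cluster"),
                              community_params(s_pool = 40, seed = 99))
  m <- build_occurrence_matrix(occ, cur)
  dels <- lapply(c(1, 3), function(t) {
    part <- network_components(build_network(
      pairwise_edge_distance(series[[t]]$layer), 500,
      timestep = c(1899, 1955, 2010)[t]))
    delineate_from_components(part, series[[t]]$layer, cur)
  })
  ev <- evaluate_all(dels, m, cur)
  pairs <- attr(ev, "pairs")
  expect_equal(attr(ev, "threshold"), median(pairs$beta))
  # the shared universe itself never shrinks per candidate; only exclusions
  expect_true(all(ev$n_within + ev$n_between + ev$n_excluded == nrow(pairs)))
})
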