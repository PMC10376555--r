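# Printed single-factor season values that the derived tables are
# recomputed from: effective ratios and coverage ratios per factor.
published_ratios <- list(
  temperature = data.frame(
    season = c("spring", "summer", "autumn", "winter"),
    re = c(0.41, 0.52, 0.42, 0.43), rc = c(0.39, 0.71, 0.45, 0.71)),
  salinity = data.frame(
    season = c("spring", "summer", "autumn", "winter"),
    re = c(0.35, 0.38, 0.30, 0.44), rc = c(0.45, 0.50, 0.39, 0.56)),
  depth = data.frame(
    season = c("spring", "summer", "autumn", "winter"),
    re = c(0.20, 0.39, 0.44, 0.28), rc = c(0.41, 0.63, 0.41, 0.64))
)
published_composite <- list(
  temperature = c(0.40, 0.61, 0.43, 0.55, avg = 0.50),
  salinity = c(0.40, 0.44, 0.34, 0.50, avg = 0.42),
  depth = c(0.29, 0.50, 0.42, 0.42, avg = 0.41)
)

test_that("factor range masks are unions of closed intervals", {
  g <- grid_spec(0, 0, 10, 2, 1)
  f <- new_field(g, rep(1:10, 2), "temperature")
  all_iv <- data.frame(lower = 1, upper = 10)
  expect_true(all(factor_range_mask(f, all_iv)$membership))
  expect_false(any(factor_range_mask(f, NULL)$membership))
  expect_false(any(factor_range_mask(f, all_iv[0, ])$membership))

  a <- data.frame(lower = 2, upper = 4)
  b <- data.frame(lower = 7, upper = 9)
  both <- factor_range_mask(f, rbind(a, b))
  expect_identical(both$membership,
                   factor_range_mask(f, a)$membership |
                     factor_range_mask(f, b)$membership)
  # closed endpoints
  expect_true(factor_range_mask(f, a)$membership[2])
  expect_true(factor_range_mask(f, a)$membership[4])
})

test_that("mask area counts cells; a disc's count approximates pi r^2", {
  g <- grid_spec(0, 0, 100, 100, 0.01)
  expect_equal(mask_area(new_mask(g, rep(TRUE, 10000))), 10000)
  ctr <- grid_centers(g)
  expect_equal(mask_area(new_mask(g, ctr$lon < 0.5)), 5000)

  gfine <- grid_spec(0, 0, 200, 200, 0.005)
  ctr <- grid_centers(gfine)
  err_prev <- Inf
  for (r in c(0.1, 0.2, 0.3)) {
    disc <- new_mask(gfine, (ctr$lon - 0.5)^2 + (ctr$lat - 0.5)^2 <= r^2)
    est <- mask_area(disc) * 0.005^2
    expect_lt(abs(est - pi * r^2) / (pi * r^2), 0.01)
  }
  # error shrinks as the point array is refined
  errs <- vapply(c(0.02, 0.005), function(res) {
    gg <- grid_spec(0, 0, 1 / res, 1 / res, res)
    cc <- grid_centers(gg)
    disc <- new_mask(gg, (cc$lon - 0.5)^2 + (cc$lat - 0.5)^2 <= 0.3^2)
    abs(mask_area(disc) * res^2 - pi * 0.09) / (pi * 0.09)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("mask intersection is idempotent, empty on complements, monotone", {
  g <- grid_spec(0, 0, 12, 12, 0.5)
  set.seed(17)
  a <- new_mask(g, runif(144) < 0.6, "A")
  expect_identical(intersect_masks(list(a, a))$membership, a$membership)
  not_a <- new_mask(g, !a$membership, "notA")
  expect_equal(mask_area(intersect_masks(list(a, not_a))), 0)

  for (i in 1:5) {
    ms <- lapply(1:3, function(j) new_mask(g, runif(144) < runif(1)))
    inter <- intersect_masks(ms)
    expect_lte(mask_area(inter), min(vapply(ms, mask_area, numeric(1))))
  }
  g2 <- grid_spec(0, 0, 12, 12, 0.25)
  expect_error(intersect_masks(list(a, new_mask(g2, rep(TRUE, 144)))),
               "different grids")
})

test_that("overlap statistics cover the identity, disjoint and printed cases", {
  g <- grid_spec(0, 0, 10, 10, 0.1)
  set.seed(23)
  bio <- new_mask(g, runif(100) < 0.5, "bio")
  same <- overlap_stats(bio, bio, "self", "spring")
  expect_equal(same$R_effective, 1)
  expect_equal(same$R_covering, 1)
  expect_equal(same$I_comp, 1)

  other <- new_mask(g, !bio$membership, "disjoint")
  dis <- overlap_stats(other, bio, "disjoint", "spring")
  expect_equal(dis$R_effective + dis$R_covering + dis$I_comp, 0)

  expect_error(overlap_stats(new_mask(g, rep(FALSE, 100)), bio), "zero area")

  # printed summer temperature ratios give the printed composite index
  expect_equal(round_half_away(composite_index(0.52, 0.71), 2), 0.61)
})

test_that("the composite index is the geometric mean of the two ratios", {
  set.seed(11)
  re <- runif(50); rc <- runif(50)
  expect_true(all(abs(composite_index(re, rc)^2 - re * rc) < 1e-12))
  expect_true(all(composite_index(re, rc) >= pmin(re, rc) - 1e-12))
  expect_true(all(composite_index(re, rc) <= pmax(re, rc) + 1e-12))
})

test_that("all twelve published composite-index cells are reproduced", {
  for (f in names(published_ratios)) {
    tab <- published_ratios[[f]]
    idx <- composite_index(tab$re, tab$rc)
    expect_identical(round_half_away(idx, 2),
                     unname(published_composite[[f]][1:4]), label = f)
    expect_equal(round_half_away(mean(idx), 2),
                 unname(published_composite[[f]]["avg"]), label = f)
  }
})

test_that("coverage declines reproduce the published spot checks", {
  expect_equal(round_half_away(coverage_decline(0.39, 0.22), 2), -0.44)
  expect_equal(round_half_away(coverage_decline(0.45, 0.22), 2), -0.51)
  expect_equal(coverage_decline(0.37, 0.37), 0)
  expect_error(coverage_decline(0, 0.2), "positive")
})

test_that("published pair/triple coverages give the decline table to 0.01", {
  pair_cov <- data.frame(
    season = c("spring", "summer", "autumn", "winter"),
    temp_sal = c(0.22, 0.36, 0.22, 0.49),
    temp_dep = c(0.28, 0.49, 0.21, 0.57),
    sal_dep = c(0.30, 0.33, 0.21, 0.46),
    triple = c(0.17, 0.26, 0.11, 0.43))
  # published decline cells, columns as (combination | constituent)
  published <- cbind(
    c(-0.44, -0.49, -0.51, -0.31),  # temp∩sal | temp
    c(-0.51, -0.28, -0.44, -0.13),  # temp∩sal | sal
    c(-0.28, -0.31, -0.53, -0.20),  # temp∩dep | temp
    c(-0.32, -0.22, -0.49, -0.11),  # temp∩dep | dep
    c(-0.33, -0.34, -0.46, -0.18),  # sal∩dep | sal
    c(-0.27, -0.48, -0.49, -0.28),  # sal∩dep | dep
    c(-0.23, -0.28, -0.50, -0.12),  # triple | temp∩sal
    c(-0.39, -0.47, -0.48, -0.25),  # triple | temp∩dep
    c(-0.43, -0.21, -0.48, -0.07))  # triple | sal∩dep
  singles <- published_ratios
  computed <- cbind(
    coverage_decline(singles$temperature$rc, pair_cov$temp_sal),
    coverage_decline(singles$salinity$rc, pair_cov$temp_sal),
    coverage_decline(singles$temperature$rc, pair_cov$temp_dep),
    coverage_decline(singles$depth$rc, pair_cov$temp_dep),
    coverage_decline(singles$salinity$rc, pair_cov$sal_dep),
    coverage_decline(singles$depth$rc, pair_cov$sal_dep),
    coverage_decline(pair_cov$temp_sal, pair_cov$triple),
    coverage_decline(pair_cov$temp_dep, pair_cov$triple),
    coverage_decline(pair_cov$sal_dep, pair_cov$triple))
  # a few printed cells derive from unrounded internals; allow 0.01
  expect_true(all(abs(round_half_away(computed, 2) - published) <= 0.01 + 1e-12))
  # and the majority agree exactly at 2 decimals
  expect_gte(mean(round_half_away(computed, 2) == published), 0.7)
})

test_that("seasonal summaries use the sample-SD convention", {
  s <- season_summary(c(398, 2164, 1845, 1949))
  expect_equal(round_half_away(s$mean, 0), 1589)
  expect_equal(round_half_away(s$sd, 0), 805)

  flat <- season_summary(rep(3.2, 4))
  expect_equal(flat$mean, 3.2)
  expect_equal(flat$sd, 0)

  s3 <- season_summary(c(0.17, 0.26, 0.11, 0.43))
  expect_equal(round_half_away(s3$mean, 2), 0.24)
  expect_error(season_summary(5), "at least 2")
})

test_that("full overlap tables obey subset monotonicity and identity elements", {
  g <- grid_spec(0, 0, 20, 20, 0.1)
  set.seed(31)
  bio <- new_mask(g, runif(400) < 0.5, "bio")
  masks <- list(temperature = new_mask(g, runif(400) < 0.6),
                salinity = new_mask(g, runif(400) < 0.5),
                depth = new_mask(g, runif(400) < 0.7))
  out <- full_overlap_table(bio, masks, "spring")
  expect_equal(nrow(out$stats), 7)
  singles <- out$stats$A_effective[1:3]
  pairs <- out$stats$A_effective[4:6]
  triple <- out$stats$A_effective[7]
  expect_true(all(triple <= pairs))
  expect_true(max(pairs) <= max(singles))
  expect_true(all(pairs[1] <= singles[1:2]))  # pair <= each constituent
  expect_equal(nrow(out$declines), 9)

  # a full-grid factor is the identity element of intersection
  masks$temperature <- new_mask(g, rep(TRUE, 400))
  out2 <- full_overlap_table(bio, masks, "spring")
  stats <- out2$stats
  pair_ts <- stats[stats$label == "temperature ∩ salinity", ]
  expect_equal(pair_ts$A_effective,
               stats[stats$label == "salinity", "A_effective"])
})
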