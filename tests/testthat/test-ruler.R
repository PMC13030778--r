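test_that("site centroids are unweighted means over resolved residues", {
  st <- tiny_structure(rbind(c(0, 0, 0), c(2, 0, 0)), resno = c(10L, 11L))
  sites <- tiny_sites("t", rep("RIII_A", 2), c(10L, 11L))
  expect_equal(as.numeric(site_centroid(st, sites, "RIII_A")), c(1, 0, 0))

  one <- tiny_sites("t", "RIII_A", 10L)
  expect_equal(as.numeric(site_centroid(st, one, "RIII_A")), c(0, 0, 0))

  # 4 entries, one unresolved: centroid of the 3 resolved ones
  st3 <- tiny_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 3)),
                        resno = c(1L, 2L, 3L))
  s4 <- dicerruler:::new_site_map(tibble::tibble(
    structure_id = "t", site = "pocket_3prime", chain = "A",
    resno = c(1L, 2L, 3L, NA), expected_aa = c("A", "A", "A", "?"),
    resolved = c(TRUE, TRUE, TRUE, FALSE)))
  cen <- site_centroid(st3, s4, "pocket_3prime")
  expect_equal(as.numeric(cen), c(1, 1, 1))
  expect_equal(attr(cen, "n_residues"), 3)
  expect_equal(attr(cen, "n_skipped"), 1)

  empty <- tiny_sites("t", "RIII_B", 99L)
  expect_error(site_centroid(st, empty, "RIII_B"),
               class = "dicerruler_error_missing_site")
})

test_that("ruler measurement reproduces the reference-species geometry", {
  sc <- generate_scaffold("dmel", 61.0, 59.6, seed = 1)
  m <- measure_ruler(sc$structure, sc$sites)
  expect_equal(m$d_3p_riiia, 61.0, tolerance = 1e-6)
  expect_equal(m$d_5p_riiib, 59.6, tolerance = 1e-6)
  expect_equal(m$mean_distance, 60.3, tolerance = 1e-6)
  expect_equal(m$mean_distance, (m$d_3p_riiia + m$d_5p_riiib) / 2,
               tolerance = 1e-12)

  sc2 <- generate_scaffold("bter", 61.7, 62.7, seed = 2)
  m2 <- measure_ruler(sc2$structure, sc2$sites)
  expect_equal(m2$mean_distance, 62.2, tolerance = 1e-6)

  # all four centroids coincident -> zero distances
  st <- tiny_structure(matrix(0, 4, 3), resno = 1:4)
  sites <- tiny_sites("z", c("RIII_A", "RIII_B", "pocket_3prime",
                             "pocket_5prime"), 1:4)
  m0 <- measure_ruler(st, sites)
  expect_equal(m0$mean_distance, 0)

  # a missing site errors and names the site
  incomplete <- dplyr::filter(sc$sites, site != "pocket_5prime")
  err <- expect_error(measure_ruler(sc$structure, incomplete),
                      class = "dicerruler_error_missing_site")
  expect_match(conditionMessage(err), "pocket_5prime")
})

test_that("ruler distances are invariant under rigid motion of the structure", {
  sc <- generate_scaffold("inv", 59.2, 63.4, seed = 9)
  base <- measure_ruler(sc$structure, sc$sites)
  withr::with_seed(10, {
    for (i in 1:5) {
      R <- random_proper_rotation()
      tr <- runif(3, -100, 100)
      moved <- sc$structure
      m <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
      moved$x <- m[, 1] + tr[1]
      moved$y <- m[, 2] + tr[2]
      moved$z <- m[, 3] + tr[3]
      got <- measure_ruler(moved, sc$sites)
      expect_equal(got$d_3p_riiia, base$d_3p_riiia, tolerance = 1e-9)
      expect_equal(got$d_5p_riiib, base$d_5p_riiib, tolerance = 1e-9)
    }
  })
})

test_that("replicate statistics use the sample (n-1) standard deviation", {
  ms <- tibble::tibble(mean_distance = c(60.0, 60.3, 60.6))
  st <- replicate_stats(ms)
  expect_equal(st$mean, 60.3)
  expect_equal(st$sd, 0.3)

  same <- tibble::tibble(mean_distance = rep(61.1, 3))
  expect_equal(replicate_stats(same)$sd, 0)

  single <- tibble::tibble(mean_distance = 59.9)
  expect_equal(replicate_stats(single)$sd, 0)
  expect_equal(replicate_stats(single)$mean, 59.9)

  expect_error(replicate_stats(tibble::tibble(mean_distance = numeric())),
               class = "dicerruler_error_empty_input")
})

test_that("least-squares calibration matches the closed-form solution", {
  two <- data.frame(mean_distance = c(60, 62), length_nt = c(21, 22))
  cal2 <- fit_calibration(two)
  expect_equal(cal2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal2$rise, 2.0, tolerance = 1e-12)

  tbl <- table2_fixture()
  pts <- data.frame(mean_distance = tbl$reported_mean,
                    length_nt = tbl$reported_nt)
  cal <- fit_calibration(pts)
  x <- pts$mean_distance
  y <- pts$length_nt
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(cal$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(round(cal$slope, 3), 0.490)

  degenerate <- data.frame(mean_distance = c(60, 60, 60),
                           length_nt = c(20, 21, 22))
  expect_error(fit_calibration(degenerate),
               class = "dicerruler_error_calibration")
})

test_that("anchored prediction reproduces the published length classes", {
  model <- calibration_anchored(d_ref = 60.3, l_ref = 21, rise = 2.0)
  pred <- predict_length(c(59.8, 62.2, 62.3, 58.3), model)
  expect_equal(pred$predicted_nt, c(21L, 22L, 22L, 20L))

  # the crystallographic A-form rise gives the same classes
  model281 <- calibration_anchored(d_ref = 60.3, l_ref = 21, rise = 2.81)
  pred281 <- predict_length(c(59.8, 62.2, 62.3, 58.3), model281)
  expect_equal(pred281$predicted_nt, c(21L, 22L, 22L, 20L))

  # anchor identity
  expect_equal(predict_length(60.3, model)$predicted_nt, 21L)

  # monotone in distance
  withr::with_seed(41, d <- sort(runif(50, 56, 66)))
  expect_true(all(diff(predict_length(d, model)$predicted_nt) >= 0))

  # out-of-range predictions warn but are returned
  expect_warning(far <- predict_length(80, model), "18-24")
  expect_true(far$out_of_range)
  expect_equal(far$predicted_nt, 31L)

  expect_error(predict_length(-1, model), class = "dicerruler_error_domain")
})

test_that("relevance threshold is strict in absolute value", {
  expect_false(relevance_flag(0.4))
  expect_false(relevance_flag(0.5))
  expect_true(relevance_flag(-0.6))
  expect_true(relevance_flag(0.51))
  expect_error(relevance_flag(0.4, threshold = 0),
               class = "dicerruler_error_domain")
})

test_that("linear calibration recovers a known rise from noisy classes", {
  true_slope <- 0.5  # nt per A, i.e. rise 2.0
  withr::with_seed(42, {
    d <- runif(20, 56, 66)
    nt <- round(true_slope * d + (21 - true_slope * 60.3))
  })
  cal <- fit_calibration(data.frame(mean_distance = d, length_nt = nt))
  expect_lt(abs(cal$slope - true_slope) / true_slope, 0.1)

  pred <- predict_length(60.3, cal)
  expect_equal(pred$predicted_nt, 21L)
})

test_that("reported-mean checking flags only genuine inconsistencies", {
  chk <- check_reported_means(table2_fixture())
  expect_equal(chk$computed_mean,
               c(60.3, 60.0, 62.2, 62.3, 58.35), tolerance = 1e-12)
  expect_equal(chk$discrepancy, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})
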