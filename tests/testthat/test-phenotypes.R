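ff <- c(0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26)
resp_tab <- function(counts, paw = "left", forces = ff) {
  data.frame(paw = paw, force_g = forces, response_count = counts)
}

test_that("withdrawal threshold is the lowest filament with >= 3/5 responses", {
  expect_equal(von_frey_threshold(resp_tab(rep(5, 11)))$threshold_g, 0.4)
  cens <- von_frey_threshold(resp_tab(rep(2, 11)))
  expect_equal(cens$threshold_g, 26.0)
  expect_true(cens$censored)
  expect_equal(von_frey_threshold(
    resp_tab(c(0, 1, 2, 3, 5, 5, 5, 5, 5, 5, 5)))$threshold_g, 1.4)
  expect_error(von_frey_threshold(resp_tab(rep(5, 10), forces = ff[-3]),
                                  filament_forces = ff), "filament")
})

test_that("threshold call is monotone in response counts and censored at 26 g", {
  set.seed(21)
  for (rep in 1:100) {
    counts <- sample(0:5, 11, replace = TRUE)
    thr <- von_frey_threshold(resp_tab(counts))$threshold_g
    expect_lte(thr, 26.0)
    bump <- pmin(counts + sample(0:2, 11, replace = TRUE), 5)
    thr_bump <- von_frey_threshold(resp_tab(bump))$threshold_g
    expect_lte(thr_bump, thr)
  }
})

test_that("paw averaging and baseline normalization", {
  expect_equal(paw_average_and_normalize(6, 6)$threshold_g, 6)
  expect_equal(paw_average_and_normalize(4, 8)$threshold_g, 6)
  expect_equal(paw_average_and_normalize(3, 3, baseline_g = 6)$normalized_threshold, 0.5)
  expect_equal(paw_average_and_normalize(6, 6, baseline_g = 6)$normalized_threshold, 1.0)
  expect_true(is.na(paw_average_and_normalize(NA, 8)$threshold_g))
})

test_that("IVD height from borders: parallel lines, isometry, wedge oracle", {
  cr <- cbind(seq(0, 5, length.out = 20), rep(1, 20))
  ca <- cbind(seq(0, 5, length.out = 20), rep(0, 20))
  expect_equal(ivd_height_from_borders(cr, ca), 1.0, tolerance = 1e-9)
  # rigid rotation by 30 degrees
  rot <- function(m, a) m %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(ivd_height_from_borders(rot(cr, pi / 6), rot(ca, pi / 6)),
               1.0, tolerance = 1e-9)
  # wedge about a hinge: mean gap ~ (L/2) tan(alpha), checked against a
  # dense numeric oracle (mean vertical gap of the tilted border)
  alpha <- 0.05; L <- 5
  xs <- seq(0, L, length.out = 50)
  wedge <- ivd_height_from_borders(cbind(xs, xs * tan(alpha)), cbind(xs, 0))
  xd <- seq(0, L, length.out = 20000)
  oracle <- mean(xd * tan(alpha) * cos(alpha))  # perpendicular distances
  expect_equal(wedge, oracle, tolerance = 0.01)
  # crossing borders rejected
  expect_error(ivd_height_from_borders(cbind(c(0, 5), c(-1, 1)),
                                       cbind(c(0, 5), c(1, -1))), "cross")
})

test_that("height percent change: per level, punctured average, invariances", {
  rec <- function(h0, h6, levels = c("L3/4", "L4/5", "L5/6")) {
    rbind(data.frame(level = levels, timepoint = "baseline", height_mm = h0),
          data.frame(level = levels, timepoint = "6wk", height_mm = h6))
  }
  same <- height_percent_change(rec(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unname(same$per_level), c(0, 0, 0))
  expect_equal(same$punctured_average, 0)
  expect_equal(height_percent_change(rec(c(1, 1, 1), c(0.8, 0.8, 0.8)))$punctured_average,
               -20)
  # average-of-means, not mean of per-level changes
  h0 <- c(1.0, 1.2, 0.8); h6 <- c(0.9, 1.2, 0.6)
  pc <- height_percent_change(rec(h0, h6))
  expect_equal(pc$punctured_average, 100 * (mean(h6) - mean(h0)) / mean(h0))
  expect_false(isTRUE(all.equal(pc$punctured_average,
                                mean(100 * (h6 - h0) / h0))))
  # scale invariance
  pc2 <- height_percent_change(rec(3.7 * h0, 3.7 * h6))
  expect_equal(pc2$punctured_average, pc$punctured_average)
  expect_equal(pc2$per_level, pc$per_level)
  # missing level -> missing punctured average
  pm <- height_percent_change(rec(c(1, 1), c(0.9, 0.9), levels = c("L3/4", "L4/5")))
  expect_true(is.na(pm$punctured_average))
})

test_that("delta-Ct relative expression", {
  expect_equal(relative_expression(20, 20), 1.0)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(18, 20), 4.0)
  expect_true(is.na(relative_expression(20, NA)))
})

test_that("ROUT flags the gross outlier and nothing else", {
  v <- c(0.95, 1.0, 1.05, 1.02, 0.98, 10.0)
  expect_equal(rout_outliers(v, Q = 1), v == 10.0)
  expect_equal(rout_outliers(v, Q = 1), rout_oracle(v, Q = 1))
  expect_equal(rout_outliers(rep(1, 8)), rep(FALSE, 8))
  expect_warning(m <- rout_outliers(c(1, 2, 100)), "fewer than 4")
  expect_equal(m, rep(FALSE, 3))
})

test_that("ROUT agrees with the independent oracle on contaminated samples", {
  set.seed(33)
  n_hit_pkg <- 0; n_hit_orc <- 0; n_false_pkg <- 0; n_false_orc <- 0
  for (rep in 1:300) {
    v <- rnorm(12)
    v[12] <- 8  # one outlier at 8 SD
    mp <- rout_outliers(v, Q = 1)
    mo <- rout_oracle(v, Q = 1)
    expect_equal(mp, mo)
    n_hit_pkg <- n_hit_pkg + mp[12]; n_hit_orc <- n_hit_orc + mo[12]
    n_false_pkg <- n_false_pkg + sum(mp[1:11]); n_false_orc <- n_false_orc + sum(mo[1:11])
  }
  expect_equal(n_hit_pkg, n_hit_orc)
  expect_equal(n_false_pkg, n_false_orc)
  expect_gt(n_hit_pkg / 300, 0.9)  # an 8-SD point should almost always flag
})

test_that("ROUT flags nothing on at least 95% of clean Gaussian samples", {
  set.seed(44)
  clean <- vapply(1:1000, function(i) !any(rout_outliers(rnorm(12), Q = 1)),
                  logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("degeneration grade aggregates rater subscores", {
  sub <- function(...) {
    sc <- rbind(...)
    data.frame(rater = rep(seq_len(nrow(sc)), each = 5),
               category = rep(c("AF_integrity", "AF_NP_border",
                                "NP_cellularity", "NP_matrix", "endplate"),
                              nrow(sc)),
               subscore = as.vector(t(sc)))
  }
  expect_equal(total_degeneration_grade(sub(rep(0, 5), rep(0, 5), rep(0, 5)))$total, 0)
  expect_equal(total_degeneration_grade(sub(rep(2, 5), rep(2, 5), rep(2, 5)))$total, 10)
  g <- total_degeneration_grade(sub(c(1, 1, 1, 1, 1), c(2, 1, 1, 1, 1),
                                    c(0, 1, 1, 1, 1)))
  expect_equal(unname(g$category_means), rep(1, 5))
  expect_equal(g$total, 5)
  expect_error(total_degeneration_grade(sub(c(3, 0, 0, 0, 0))), "\\[0, 2\\]")
})
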