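test_that("Spearman matrix: monotone, anti-monotone, ties, missingness", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1))
  sm <- spearman_matrix(x, min_n = 3)
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  # exact permutation p for a perfect n = 5 monotone pair is 2/5! ~ 0.017
  expect_equal(sm$p["a", "b"], 2 / factorial(5), tolerance = 1e-6)
  # tie-corrected rho equals Pearson on midranks
  xt <- c(1, 2, 2, 3, 5, 5, 6); yt <- c(2, 1, 3, 3, 4, 6, 5)
  smt <- spearman_matrix(cbind(x = xt, y = yt))
  expect_equal(smt$rho["x", "y"], spearman_oracle(xt, yt), tolerance = 1e-12)
  # pairwise-complete counts and the min_n rule
  xm <- cbind(u = c(1, 2, 3, NA, NA, NA), v = c(2, 1, 4, 5, 2, 8),
              w = c(1, 4, 9, 16, 25, 36))
  smm <- spearman_matrix(xm, min_n = 4)
  expect_equal(smm$n["u", "v"], 3)
  expect_true(is.na(smm$rho["u", "v"]))  # below min_n -> untested
  expect_equal(smm$rho["v", "w"], spearman_oracle(xm[, "v"], xm[, "w"]))
  # constant column is undefined
  smc <- spearman_matrix(cbind(k = rep(1, 6), v = c(2, 1, 4, 5, 2, 8)))
  expect_true(is.na(smc$rho["k", "v"]))
  expect_true(is.na(smc$p["k", "v"]))
})

test_that("BH adjustment: hand examples, oracle, monotonicity, validation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 7)), rep(0.02, 7))
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # exact agreement with the brute-force step-up oracle
  set.seed(8)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # missing p-values stay missing and do not enter the family
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
  # decreasing any one p never increases any q
  set.seed(9)
  for (rep in 1:30) {
    p <- runif(12)
    q <- bh_adjust(p)
    i <- sample(12, 1)
    p2 <- p; p2[i] <- p2[i] * runif(1)
    expect_true(all(bh_adjust(p2) <= q + 1e-12))
  }
})

test_that("network construction thresholds q and carries signs and classes", {
  traits <- c("t1", "t2", "t3", "t4")
  rho <- matrix(0.5, 4, 4, dimnames = list(traits, traits))
  rho["t1", "t3"] <- rho["t3", "t1"] <- -0.8
  q <- matrix(0.9, 4, 4, dimnames = list(traits, traits))
  net0 <- build_network(rho, q)
  expect_equal(nrow(net0$edges), 0)
  q["t1", "t2"] <- q["t2", "t1"] <- 0.01
  q["t1", "t3"] <- q["t3", "t1"] <- 0.04
  q["t2", "t4"] <- q["t4", "t2"] <- 0.05
  net <- build_network(rho, q, classes = c(t1 = "design", t2 = "behavior",
                                           t3 = "radiology", t4 = "histology"))
  expect_equal(nrow(net$edges), 3)
  expect_true(has_edge(net, "t1", "t2") && has_edge(net, "t3", "t1") &&
                has_edge(net, "t2", "t4"))
  expect_equal(net$edges$sign[net$edges$trait_a == "t1" &
                                net$edges$trait_b == "t3"], -1)
  expect_equal(net$nodes$class[net$nodes$trait == "t3"], "radiology")
  expect_lte(nrow(net$edges), 4 * 3 / 2)
})

test_that("correlation power: design value, null limit, Monte-Carlo check", {
  pw <- correlation_power(24, 0.5, 0.05)
  expect_gt(pw, 0.71); expect_lt(pw, 0.74)
  # null limit equals alpha up to the Fisher-z normal approximation
  expect_lt(abs(correlation_power(24, 1e-8, 0.05) - 0.05), 0.002)
  expect_error(correlation_power(3, 0.5, 0.05), "n >= 4")
  set.seed(10)
  n <- 24; rho <- 0.5; reps <- 10000
  t_crit <- qt(0.975, n - 2)
  rej <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- cor(x, y)
    abs(r * sqrt((n - 2) / (1 - r^2))) > t_crit
  }, logical(1))
  expect_lt(abs(mean(rej) - pw), 0.02)
})

test_that("network comparison: Jaccard, degrees, edges of interest", {
  mknet <- function(edges, traits) {
    rho <- matrix(0.5, length(traits), length(traits),
                  dimnames = list(traits, traits))
    q <- matrix(1, length(traits), length(traits),
                dimnames = list(traits, traits))
    for (e in edges) q[e[1], e[2]] <- q[e[2], e[1]] <- 0.01
    build_network(rho, q)
  }
  tr <- paste0("t", 1:5)
  a <- mknet(list(c("t1", "t2"), c("t2", "t3"), c("t4", "t5")), tr)
  b <- mknet(list(c("t1", "t2"), c("t2", "t3"), c("t1", "t5")), tr)
  expect_equal(compare_networks(a, a)$jaccard, 1)
  cmp <- compare_networks(a, b, edges_of_interest = data.frame(
    x = c("t1", "t4"), y = c("t2", "t5")))
  expect_equal(cmp$jaccard, 2 / 4)
  expect_equal(sort(cmp$shared_edges), c("t1|t2", "t2|t3"))
  expect_true(cmp$edges_of_interest$in_a[2] && !cmp$edges_of_interest$in_b[2])
  expect_equal(cmp$degrees$a$degree[cmp$degrees$a$trait == "t2"], 2)
  disj <- mknet(list(c("t3", "t4")), tr)  # edge-disjoint from a
  expect_equal(compare_networks(a, disj)$jaccard, 0)
  only12 <- mknet(list(c("t1", "t2")), c("t1", "t2"))
  expect_error(compare_networks(only12, mknet(list(), c("t3", "t4"))),
               "share no traits")
})

test_that("trait tables key by animal, include estrous only for females", {
  cfg <- small_study_config(seed = 12)
  ds <- generate_study(cfg)
  red <- reduce_study(ds, fit_creep = FALSE)
  dict_m <- default_trait_dictionary("male")
  dict_m <- dict_m[!grepl("^creep", dict_m$trait), ]
  dict_f <- default_trait_dictionary("female")
  dict_f <- dict_f[!grepl("^creep", dict_f$trait), ]
  tm <- assemble_trait_table(ds, "male", reductions = red, dictionary = dict_m)
  tf <- assemble_trait_table(ds, "female", reductions = red, dictionary = dict_f)
  expect_equal(nrow(tm), sum(ds$animals$sex == "male"))
  expect_false("estrous" %in% names(tm))
  expect_true("estrous" %in% names(tf))
  expect_true(all(tf$estrous %in% 1:4))
  # shuffling the animal records leaves the table identical (keyed by id)
  ds2 <- ds
  perm <- sample(nrow(ds2$animals))
  ds2$animals <- ds2$animals[perm, ]
  tm2 <- assemble_trait_table(ds2, "male", reductions = red, dictionary = dict_m)
  expect_equal(tm, tm2, ignore_attr = TRUE)
  # unknown dictionary entries are named in the error
  bad <- rbind(dict_m, data.frame(trait = "no_such_trait", class = "design"))
  expect_error(assemble_trait_table(ds, "male", reductions = red,
                                    dictionary = bad), "no_such_trait")
})

test_that("full-table default study: 23 males and the default dictionary", {
  ds <- generate_study(study_config(seed = 1))
  red <- reduce_study(ds)
  tm <- assemble_trait_table(ds, "male", reductions = red)
  expect_equal(nrow(tm), 23)  # 24 - 1 excluded
  expect_equal(setdiff(names(tm), "animal_id"),
               default_trait_dictionary("male")$trait)
})

test_that("declared edges control the false discovery proportion under the null", {
  set.seed(15)
  fdp <- vapply(1:50, function(i) {
    x <- matrix(rnorm(24 * 30), 24, 30,
                dimnames = list(NULL, paste0("t", 1:30)))
    net <- trait_network(tibble::as_tibble(x), alpha = 0.05)
    if (nrow(net$edges) == 0) 0 else 1  # every declared edge is false
  }, numeric(1))
  expect_lte(mean(fdp), 0.07)
})
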