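# Independent oracles used across the test suite. These deliberately take
# different computational routes than the package implementations.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j,
# computed with an explicit double loop over the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) m * ps[j] / j, numeric(1)), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Spearman rho as Pearson on midranks, written out from first principles.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Area of a closed parametric loop by dense Green-theorem quadrature
# (0.5 * integral of (x y' - y x') dt on a fine parameter grid).
loop_area_quadrature <- function(fx, fy, n = 200000) {
  tt <- seq(0, 2 * pi, length.out = n + 1)
  x <- fx(tt); y <- fy(tt)
  dx <- c(diff(x), 0); dy <- c(diff(y), 0)
  abs(sum(x * dy - y * dx)) / 2
}

# Type III two-way ANOVA sums of squares by explicit projection: for each
# term, SS = RSS(model dropping that term's sum-contrast columns, all other
# terms kept) - RSS(full model).
anova3_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  XA <- model.matrix(~A, contrasts.arg = list(A = "contr.sum"))[, -1, drop = FALSE]
  XB <- model.matrix(~B, contrasts.arg = list(B = "contr.sum"))[, -1, drop = FALSE]
  XAB <- matrix(0, length(y), ncol(XA) * ncol(XB))
  k <- 0
  for (i in seq_len(ncol(XA))) for (j in seq_len(ncol(XB))) {
    k <- k + 1
    XAB[, k] <- XA[, i] * XB[, j]
  }
  one <- matrix(1, length(y), 1)
  rss <- function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  full <- cbind(one, XA, XB, XAB)
  rss_full <- rss(full)
  df_err <- length(y) - qr(full)$rank
  ss <- c(A = rss(cbind(one, XB, XAB)) - rss_full,
          B = rss(cbind(one, XA, XAB)) - rss_full,
          `A:B` = rss(cbind(one, XA, XB)) - rss_full)
  df <- c(A = ncol(XA), B = ncol(XB), `A:B` = ncol(XAB))
  mse <- rss_full / df_err
  f <- (ss / df) / mse
  list(ss = ss, df = df, f = f, p = pf(f, df, df_err, lower.tail = FALSE),
       mse = mse, df_error = df_err)
}

# Independent ROUT (constant model): a second implementation of the
# published procedure, structured differently (vectorized candidate set).
rout_oracle <- function(values, Q = 1) {
  n <- length(values)
  res <- abs(values - median(values))
  rsdr <- as.numeric(quantile(res, 0.6827, type = 7)) * n / (n - 1)
  flag <- rep(FALSE, n)
  if (rsdr <= 0 || n < 4) return(flag)
  ord <- order(res, decreasing = TRUE)
  pvals <- 2 * pt(-res[ord] / rsdr, df = n - 1)
  alphas <- (Q / 100) * seq_len(n) / n
  kmax <- floor(0.3 * n)
  n_flag <- 0
  for (k in seq_len(kmax)) {
    if (pvals[k] < alphas[k]) n_flag <- k else break
  }
  if (n_flag > 0) flag[ord[seq_len(n_flag)]] <- TRUE
  flag
}

# Expected called paw-withdrawal threshold for one group of the generator's
# latent model, by numerical integration over the lognormal latent threshold
# and exact binomial call probabilities per filament.
expected_call_oracle <- function(mu_log, sd_log, forces, slope, n_app = 5,
                                 criterion = 3, n_grid = 4001) {
  z <- seq(-6, 6, length.out = n_grid)
  w <- dnorm(z); w <- w / sum(w)
  ev <- vapply(z, function(zi) {
    theta <- exp(mu_log + sd_log * zi)
    p <- plogis(slope * log(forces / theta))
    p_hit <- pbinom(criterion - 1, n_app, p, lower.tail = FALSE)
    p_first <- p_hit * cumprod(c(1, 1 - p_hit))[seq_along(p_hit)]
    sum(p_first * forces) + (1 - sum(p_first)) * max(forces)
  }, numeric(1))
  sum(ev * w)
}

# small default study scaled for quick pipeline tests
small_study_config <- function(seed = 11, n_per_group = 6) {
  study_config(n_per_group = n_per_group, seed = seed)
}

# an effect block with every injury/sex effect switched off
null_effects <- function() {
  list(vf_injury_ratio_male = 1, vf_injury_ratio_female = 1,
       vf_female_injury_sd_mult = 1, grade_injury_severity = 0,
       height_loss_frac = 0, calca_l2_male_log2fc = 0,
       tac1_l5_male_log2fc = 0,
       torsional_stiffness_male = 2.4,  # same as female default
       weight_male = 280, weight_gain_male = 20)
}
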