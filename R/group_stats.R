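#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `value ~ A * B` with sum-to-zero contrasts and reports Type III
#' sums of squares (the convention of the commercial package the emulated
#' study used, appropriate for its mildly unbalanced n = 11-12 cells),
#' optionally Type II. Cell summaries and a Tukey-Kramer table over the
#' A x B cells are attached.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (or coercible); >= 2 levels each, no
#'   empty cells.
#' @param factor_names length-2 character, names used in the output table.
#' @param type `3` (default) or `2` sums of squares.
#' @return An `anova_result`: list with `table` (term, df, sum_sq, f, p),
#'   `cells` (per-cell n/mean/sd), `tukey` (pairwise table), `mse`,
#'   `df_error`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          factor_names = c("A", "B"), type = 3) {
  df <- data.frame(y = values, A = factor(factor_a), B = factor(factor_b))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$A)) < 2 || nlevels(droplevels(df$B)) < 2) {
    stop("both factors need >= 2 observed levels", call. = FALSE)
  }
  df$A <- droplevels(df$A); df$B <- droplevels(df$B)
  counts <- table(df$A, df$B)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factor_names[1], rownames(counts)[empty[1]],
                 factor_names[2], colnames(counts)[empty[2]]), call. = FALSE)
  }
  mod <- lm(y ~ A * B, data = df,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  at <- car::Anova(mod, type = type)
  rn <- rownames(at)
  term_map <- c(A = factor_names[1], B = factor_names[2])
  pretty <- function(r) {
    r <- gsub("A:B", paste(factor_names, collapse = ":"), r, fixed = TRUE)
    r <- ifelse(r %in% names(term_map), term_map[r], r)
    r
  }
  keep <- setdiff(rn, c("(Intercept)", "Residuals"))
  tab <- tibble::tibble(
    term = unname(pretty(keep)),
    df = at[keep, "Df"],
    sum_sq = at[keep, "Sum Sq"],
    f = at[keep, "F value"],
    p = at[keep, "Pr(>F)"]
  )
  df_error <- at["Residuals", "Df"]
  mse <- at["Residuals", "Sum Sq"] / df_error

  cell_lab <- interaction(df$A, df$B, sep = ":", lex.order = TRUE)
  cells <- group_summary(df$y, cell_lab)
  tuk <- tukey_hsd(setNames(cells$mean, cells$group),
                   setNames(cells$n, cells$group), mse, df_error)
  structure(list(table = tab, cells = cells, tukey = tuk,
                 mse = mse, df_error = df_error,
                 factor_names = factor_names, type = type),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s x %s), Type %s SS\n",
              x$factor_names[1], x$factor_names[2], x$type))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer pairwise comparisons from cell summaries
#'
#' Studentized-range adjusted p-values for all pairs of cells, using the
#' Tukey-Kramer standard error for unequal cell sizes.
#'
#' @param cell_means,cell_ns named vectors of cell means and sizes.
#' @param mse error mean square from the fitted ANOVA.
#' @param df_error error degrees of freedom (> 0).
#' @return Tibble with `pair`, `diff`, `se`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(cell_means, cell_ns, mse, df_error) {
  if (df_error <= 0) stop("df_error must be positive", call. = FALSE)
  k <- length(cell_means)
  if (k < 2) stop("need at least 2 cells", call. = FALSE)
  nm <- names(cell_means)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- cell_means[i1] - cell_means[i2]
    se <- sqrt((mse / 2) * (1 / cell_ns[i1] + 1 / cell_ns[i2]))
    q <- abs(d) / se
    tibble::tibble(pair = paste(nm[i1], nm[i2], sep = " - "),
                   diff = unname(d), se = unname(se), q = unname(q),
                   p_adj = ptukey(unname(q), nmeans = k, df = df_error,
                                  lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

#' Per-group summary of a trait
#'
#' @param values numeric trait.
#' @param grouping grouping vector (factor or coercible).
#' @return Tibble with `group`, `n` (non-missing), `mean`, `sd`,
#'   `n_missing`.
#' @export
group_summary <- function(values, grouping) {
  g <- factor(grouping)
  out <- lapply(levels(g), function(lv) {
    v <- values[g == lv]
    nm <- sum(is.na(v))
    v <- v[!is.na(v)]
    tibble::tibble(group = lv, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   n_missing = nm)
  })
  dplyr::bind_rows(out)
}
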