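#' Paw withdrawal threshold from a filament response table
#'
#' Applies the ascending-filament rule: the threshold is the lowest force
#' filament that elicited nocifensive responses in at least 3 of 5
#' applications; animals never reaching 3 responses are censored at the
#' maximal filament (26 g with the default set).
#'
#' @param table data frame with columns `paw`, `force_g`, `response_count`
#'   (one row per filament per paw).
#' @param filament_forces optional expected filament set; if given, each paw
#'   must have exactly these forces (error otherwise).
#' @param criterion minimum response count that defines a withdrawal
#'   (default 3).
#' @return A tibble with columns `paw`, `threshold_g`, `censored`.
#' @export
von_frey_threshold <- function(table, filament_forces = NULL, criterion = 3) {
  stopifnot(all(c("paw", "force_g", "response_count") %in% names(table)))
  if (any(table$response_count < 0 | table$response_count > 5)) {
    stop("response counts must be in 0..5", call. = FALSE)
  }
  out <- lapply(split(table, table$paw), function(df) {
    df <- df[order(df$force_g), ]
    if (!is.null(filament_forces) &&
        !isTRUE(all.equal(df$force_g, sort(filament_forces)))) {
      stop("missing or unexpected filament rows", call. = FALSE)
    }
    hit <- which(df$response_count >= criterion)
    if (length(hit)) {
      tibble::tibble(paw = df$paw[1], threshold_g = df$force_g[hit[1]],
                     censored = FALSE)
    } else {
      tibble::tibble(paw = df$paw[1], threshold_g = max(df$force_g),
                     censored = TRUE)
    }
  })
  dplyr::bind_rows(out)
}

#' Average paw thresholds and normalize to baseline
#'
#' The reported withdrawal threshold is the mean of the left and right
#' hindpaw thresholds; the normalized threshold is the ratio of that mean to
#' the animal's pre-operative (week 0) mean.
#'
#' @param left_g,right_g per-paw thresholds (grams); `NA` propagates.
#' @param baseline_g optional week-0 averaged threshold for normalization.
#' @return List with `threshold_g` and `normalized_threshold` (`NA` if no
#'   baseline given).
#' @export
paw_average_and_normalize <- function(left_g, right_g, baseline_g = NULL) {
  thr <- (left_g + right_g) / 2
  norm <- if (is.null(baseline_g)) NA_real_ else thr / baseline_g
  list(threshold_g = thr, normalized_threshold = norm)
}

# -- geometric IVD height -------------------------------------------------

.resample_polyline <- function(poly, n) {
  s <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  if (s[length(s)] == 0) return(poly[rep(1, n), , drop = FALSE])
  tt <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, poly[, 1], tt)$y, approx(s, poly[, 2], tt)$y)
}

.point_polyline_dist <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  tt <- pmin(pmax(ifelse(len2 > 0, rowSums(ap * ab) / len2, 0), 0), 1)
  proj <- a + ab * tt
  min(sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

.segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' IVD height from vertebral border polylines
#'
#' Computes disc height as the symmetrized mean perpendicular distance
#' between the cranial and caudal vertebral borders: points are resampled
#' evenly along each border, each point's distance to the opposite polyline
#' is the minimum point-to-segment distance, and the two directed means are
#' averaged. Rigid rotations and translations leave the result unchanged.
#'
#' @param cranial_border,caudal_border two-column (x, y) matrices in mm.
#' @param n_points resampling density per border (default 100).
#' @return Height in mm.
#' @export
ivd_height_from_borders <- function(cranial_border, caudal_border,
                                    n_points = 100) {
  cr <- as.matrix(cranial_border); ca <- as.matrix(caudal_border)
  if (ncol(cr) != 2 || ncol(ca) != 2 || nrow(cr) < 2 || nrow(ca) < 2) {
    stop("borders must be 2-column polylines with >= 2 points", call. = FALSE)
  }
  for (i in seq_len(nrow(cr) - 1)) {
    for (j in seq_len(nrow(ca) - 1)) {
      if (.segments_cross(cr[i, ], cr[i + 1, ], ca[j, ], ca[j + 1, ])) {
        stop("border polylines cross", call. = FALSE)
      }
    }
  }
  pa <- .resample_polyline(cr, n_points)
  pb <- .resample_polyline(ca, n_points)
  d_ab <- mean(vapply(seq_len(n_points),
                      function(i) .point_polyline_dist(pa[i, ], ca), numeric(1)))
  d_ba <- mean(vapply(seq_len(n_points),
                      function(i) .point_polyline_dist(pb[i, ], cr), numeric(1)))
  (d_ab + d_ba) / 2
}

#' Percent change in IVD height from baseline
#'
#' Per level, percent change is 100 (h6 - h0) / h0. The punctured-level
#' summary first averages heights across the punctured levels at each
#' timepoint and then takes the percent change of the averages (this is not
#' the mean of the per-level changes).
#'
#' @param records data frame for one animal with columns `level`,
#'   `timepoint` (`"baseline"` / `"6wk"`), `height_mm`.
#' @param punctured_levels levels entering the punctured-average summary.
#' @return List with `per_level` (named vector of percent changes) and
#'   `punctured_average`.
#' @export
height_percent_change <- function(records,
                                  punctured_levels = c("L3/4", "L4/5", "L5/6")) {
  if (any(records$height_mm <= 0, na.rm = TRUE)) {
    stop("heights must be positive", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(records[, c("level", "timepoint", "height_mm")],
                             names_from = "timepoint",
                             values_from = "height_mm")
  per_level <- setNames(100 * (wide$`6wk` - wide$baseline) / wide$baseline,
                        wide$level)
  sel <- wide$level %in% punctured_levels
  punct <- if (sum(sel) == length(punctured_levels) &&
               all(is.finite(wide$baseline[sel])) &&
               all(is.finite(wide$`6wk`[sel]))) {
    100 * (mean(wide$`6wk`[sel]) - mean(wide$baseline[sel])) /
      mean(wide$baseline[sel])
  } else {
    NA_real_
  }
  list(per_level = per_level, punctured_average = punct)
}

#' Relative expression by the delta-Ct method
#'
#' Expression relative to the Gapdh housekeeping gene within the same sample:
#' 2^-(Ct_gene - Ct_Gapdh).
#'
#' @param ct_gene,ct_gapdh threshold-cycle values; `NA` propagates.
#' @return Relative expression (> 0).
#' @export
relative_expression <- function(ct_gene, ct_gapdh) {
  2^(-(ct_gene - ct_gapdh))
}

#' ROUT outlier detection on a single group
#'
#' Robust outlier flagging for one group of values using the ROUT procedure
#' specialized to the constant (mean-only) model: the robust center is the
#' median, the robust scale (RSDR) is the 68.27th percentile of the absolute
#' residuals with an n/(n-1) small-sample correction, and candidate outliers
#' are tested outside-in by their t-ratio against an FDR-style threshold
#' alpha_k = (Q/100) k / n, stopping at the first non-significant candidate.
#' At most 30% of the points can be flagged.
#'
#' @param values numeric vector (one group; n >= 4 required for testing).
#' @param Q the false-discovery target among flagged outliers, in percent
#'   (default 1, the setting used for the qPCR data).
#' @return Logical mask, `TRUE` for flagged outliers, in input order.
#' @export
rout_outliers <- function(values, Q = 1) {
  mask <- rep(FALSE, length(values))
  ok <- which(is.finite(values))
  n <- length(ok)
  if (n < 4) {
    warning("fewer than 4 values; no outlier test performed")
    return(mask)
  }
  v <- values[ok]
  res <- v - median(v)
  absr <- abs(res)
  rsdr <- quantile(absr, 0.6827, names = FALSE, type = 7) * n / (n - 1)
  if (rsdr <= 0) return(mask)
  ord <- order(absr, decreasing = TRUE)
  max_out <- floor(0.3 * n)
  for (k in seq_len(max_out)) {
    t_ratio <- absr[ord[k]] / rsdr
    p <- 2 * pt(-t_ratio, df = n - 1)
    if (p < (Q / 100) * k / n) {
      mask[ok[ord[k]]] <- TRUE
    } else {
      break
    }
  }
  mask
}

#' Total histological degeneration grade
#'
#' Aggregates the 5-category, 0-2 subscores of multiple blinded raters:
#' each category is averaged across raters and the total grade is the sum of
#' the category means (0-10 scale).
#'
#' @param subscores data frame with columns `rater`, `category`, `subscore`.
#' @return List with `category_means` (named vector) and `total` (0-10).
#' @export
total_degeneration_grade <- function(subscores) {
  stopifnot(all(c("rater", "category", "subscore") %in% names(subscores)))
  if (any(subscores$subscore < 0 | subscores$subscore > 2)) {
    stop("subscores must lie in [0, 2]", call. = FALSE)
  }
  m <- c(tapply(subscores$subscore, subscores$category, mean))
  list(category_means = m, total = sum(m))
}
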