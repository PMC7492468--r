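#' Default trait dictionary
#'
#' The configurable roster of traits entering a per-sex correlation network,
#' with a variable-type class per trait (used for node coloring and
#' reporting). The default covers the study design (injury, surgery
#' cohort), body weights, von Frey thresholds (raw weeks 0-6 and
#' baseline-normalized weeks 2-6), per-level and punctured-average IVD
#' height changes, total histology grade plus its five subcategories, the
#' axial/torsional/creep biomechanical properties, qPCR fold changes for
#' both genes over the six DRG levels, and (females only) the ordinal
#' estrous stage.
#'
#' @param sex `"female"` or `"male"`: females include the estrous trait.
#' @param ivd_levels,drg_levels,genes level/gene rosters.
#' @return Tibble with columns `trait`, `class`.
#' @export
default_trait_dictionary <- function(sex = c("female", "male"),
                                     ivd_levels = c("L1/2", "L2/3", "L3/4", "L4/5", "L5/6"),
                                     drg_levels = c("T13", "L1", "L2", "L3", "L4", "L5"),
                                     genes = c("Calca", "Tac1")) {
  sex <- match.arg(sex)
  lvl_id <- function(x) gsub("/", "_", x)
  d <- rbind(
    data.frame(trait = c("injury", "surgery_date"), class = "design"),
    data.frame(trait = c("weight_preop", "weight_6wk"), class = "body"),
    data.frame(trait = c(paste0("vonfrey_w", c(0, 2, 4, 6)),
                         paste0("vonfrey_norm_w", c(2, 4, 6))),
               class = "behavior"),
    data.frame(trait = c(paste0("height_pct_", lvl_id(ivd_levels)),
                         "height_pct_punctured"), class = "radiology"),
    data.frame(trait = c("grade_total", "grade_AF_integrity",
                         "grade_AF_NP_border", "grade_NP_cellularity",
                         "grade_NP_matrix", "grade_endplate"),
               class = "histology"),
    data.frame(trait = c("tensile_stiffness", "compressive_stiffness",
                         "axial_ROM", "axial_hysteresis"),
               class = "biomech_axial"),
    data.frame(trait = c("torsional_stiffness", "torque_range",
                         "torsional_hysteresis"), class = "biomech_torsional"),
    data.frame(trait = c("creep_k_e", "creep_k_f", "creep_k_s",
                         "creep_tau_f", "creep_tau_s",
                         "creep_total_displacement"), class = "biomech_creep"),
    data.frame(trait = paste0("fold_", rep(genes, each = length(drg_levels)),
                              "_", rep(drg_levels, length(genes))),
               class = "expression")
  )
  if (sex == "female") {
    d <- rbind(d, data.frame(trait = "estrous", class = "estrous"))
  }
  tibble::as_tibble(d)
}

# ordinal coding of the estrous cycle, in cycle order
.estrous_code <- c(proestrus = 1, estrus = 2, metestrus = 3, diestrus = 4)

#' Assemble the per-sex trait table
#'
#' Builds the animals x traits matrix feeding one sex's correlation network
#' from the reductions of a study dataset. Rows are keyed by animal id;
#' qPCR values flagged as ROUT outliers enter as missing; missing traits
#' stay missing (no imputation).
#'
#' @param dataset a `study_dataset`.
#' @param sex which animals to include.
#' @param reductions a [reduce_study()] result; computed here if `NULL`.
#' @param dictionary trait dictionary (default
#'   [default_trait_dictionary()] for `sex`); traits it names must be
#'   computable or an error names the offender.
#' @return A tibble, first column `animal_id`, remaining columns in
#'   dictionary order, with attribute `trait_classes`.
#' @export
assemble_trait_table <- function(dataset, sex, reductions = NULL,
                                 dictionary = NULL) {
  if (is.null(reductions)) reductions <- reduce_study(dataset)
  if (is.null(dictionary)) {
    cfg <- dataset$provenance$config
    dictionary <- default_trait_dictionary(
      sex, ivd_levels = cfg$ivd_levels, drg_levels = cfg$drg_levels)
  }
  an <- dataset$animals[dataset$animals$sex == sex, ]
  an <- an[order(an$animal_id), ]
  ids <- an$animal_id
  lvl_id <- function(x) gsub("/", "_", x)

  wide_from <- function(df, key, val, prefix = "") {
    w <- tidyr::pivot_wider(df, id_cols = "animal_id",
                            names_from = dplyr::all_of(key),
                            values_from = dplyr::all_of(val),
                            names_prefix = prefix)
    w[match(ids, w$animal_id), , drop = FALSE]
  }
  vf <- reductions$vonfrey[reductions$vonfrey$animal_id %in% ids, ]
  vf_raw <- wide_from(vf[, c("animal_id", "week", "threshold_g")],
                      "week", "threshold_g", "vonfrey_w")
  vf_norm <- wide_from(vf[vf$week > 0, c("animal_id", "week", "normalized_threshold")],
                       "week", "normalized_threshold", "vonfrey_norm_w")
  hh <- reductions$heights[reductions$heights$animal_id %in% ids, ]
  hh$level <- ifelse(hh$level == "punctured_average", "punctured",
                     lvl_id(hh$level))
  hts <- wide_from(hh, "level", "pct_change", "height_pct_")
  hg <- reductions$histology[reductions$histology$animal_id %in% ids, ]
  grades <- wide_from(hg, "measure", "grade", "grade_")
  ex <- reductions$expression[reductions$expression$animal_id %in% ids, ]
  ex$fold_use <- ifelse(ex$outlier, NA_real_, ex$fold_change)
  ex$key <- paste0("fold_", ex$gene, "_", ex$drg_level)
  folds <- wide_from(ex[, c("animal_id", "key", "fold_use")], "key", "fold_use")
  bm <- reductions$biomech[match(ids, reductions$biomech$animal_id), ]

  tab <- tibble::tibble(
    animal_id = ids,
    injury = an$injury_group,
    surgery_date = an$surgery_date,
    weight_preop = an$weight_preop,
    weight_6wk = an$weight_6wk,
    estrous = unname(.estrous_code[an$estrous_stage])
  )
  tab <- dplyr::bind_cols(
    tab,
    vf_raw[, setdiff(names(vf_raw), "animal_id")],
    vf_norm[, setdiff(names(vf_norm), "animal_id")],
    hts[, setdiff(names(hts), "animal_id")],
    grades[, setdiff(names(grades), "animal_id")],
    folds[, setdiff(names(folds), "animal_id")]
  )
  bm_traits <- setdiff(names(bm), "animal_id")
  creep_named <- c(k_e = "creep_k_e", k_f = "creep_k_f", k_s = "creep_k_s",
                   tau_f = "creep_tau_f", tau_s = "creep_tau_s",
                   total_displacement = "creep_total_displacement")
  for (b in bm_traits) {
    nm <- if (b %in% names(creep_named)) creep_named[[b]] else b
    tab[[nm]] <- bm[[b]]
  }

  missing_traits <- setdiff(dictionary$trait, names(tab))
  if (length(missing_traits)) {
    stop("trait(s) in dictionary never computed: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  out <- tab[, c("animal_id", dictionary$trait)]
  attr(out, "trait_classes") <- setNames(dictionary$class, dictionary$trait)
  out
}

#' Pairwise Spearman correlation matrices
#'
#' Tie-corrected Spearman rho on pairwise-complete observations, with the
#' two-sided p-value computed the way base R's `cor.test` computes it: for
#' an untied pair the AS89 (Edgeworth) null distribution of the rank
#' statistic, and in the presence of ties the t approximation at
#' df = n - 2. (At the sample sizes of a per-sex study, n ~ 23, the t
#' approximation is markedly anti-conservative in the deep tail that an
#' FDR correction over ~1000 pairs probes, so AS89 matters for honest FDR
#' control.) Pairs with fewer than `min_n` complete observations, or an
#' undefined rho (constant trait), are reported as missing.
#'
#' @param table a trait table (tibble whose `animal_id` column is dropped)
#'   or a numeric matrix with named columns.
#' @param min_n minimum pairwise-complete sample size (default 4).
#' @return List of matrices `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(table, min_n = 4) {
  x <- as.data.frame(table)
  x$animal_id <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(x))
  low <- n < min_n
  rho[low] <- NA_real_
  k <- ncol(x)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (is.na(rho[i, j])) next
      ok <- complete.cases(x[, i], x[, j])
      xi <- x[ok, i]; xj <- x[ok, j]
      nn <- length(xi)
      p[i, j] <- if (anyDuplicated(xi) || anyDuplicated(xj)) {
        r <- rho[i, j]
        if (abs(r) >= 1) 0
        else 2 * pt(-abs(r) * sqrt((nn - 2) / (1 - r^2)), df = nn - 2)
      } else {
        suppressWarnings(
          stats::cor.test(xi, xj, method = "spearman")$p.value)
      }
      p[j, i] <- p[i, j]
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q(i) = min over j >= i of (m p(j) / j) over the non-missing p-values,
#' preserving input order; missing entries stay missing and do not count
#' toward the family size m.
#'
#' @param p_values p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Build a correlation network from rho and q matrices
#'
#' One edge per trait pair with q <= alpha; edge sign is the sign of rho.
#'
#' @param rho,q symmetric matrices with identical named dimensions (e.g.
#'   from [spearman_matrix()] and [bh_adjust()]).
#' @param alpha FDR threshold (default 0.05).
#' @param p optional raw p matrix carried onto the edges.
#' @param classes optional named vector of node classes.
#' @return A `correlation_network`: list with `nodes` (trait, class),
#'   `edges` (trait_a, trait_b, rho, p, q, sign), `alpha`.
#' @export
build_network <- function(rho, q, alpha = 0.05, p = NULL, classes = NULL) {
  stopifnot(identical(dim(rho), dim(q)))
  traits <- colnames(rho)
  idx <- which(upper.tri(q) & !is.na(q) & q <= alpha, arr.ind = TRUE)
  rho_e <- rho[idx]
  edges <- tibble::tibble(
    trait_a = traits[idx[, 1]],
    trait_b = traits[idx[, 2]],
    rho = rho_e,
    p = if (is.null(p)) NA_real_ else p[idx],
    q = q[idx],
    sign = sign(rho_e)
  )
  nodes <- tibble::tibble(
    trait = traits,
    class = if (is.null(classes)) NA_character_ else unname(classes[traits]))
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Correlation network: %d nodes, %d edges (FDR q <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Spearman-FDR correlation network of a trait table
#'
#' Convenience wrapper: [spearman_matrix()], one [bh_adjust()] across all
#' testable trait pairs of this table (the FDR family is the within-sex
#' network), then [build_network()].
#'
#' @param table a trait table from [assemble_trait_table()].
#' @param alpha FDR threshold.
#' @param min_n minimum pairwise-complete n per pair.
#' @return A `correlation_network`.
#' @export
trait_network <- function(table, alpha = 0.05, min_n = 4) {
  sm <- spearman_matrix(table, min_n = min_n)
  ut <- upper.tri(sm$p)
  qv <- bh_adjust(sm$p[ut])
  qmat <- matrix(NA_real_, nrow(sm$p), ncol(sm$p), dimnames = dimnames(sm$p))
  qmat[ut] <- qv
  qmat[lower.tri(qmat)] <- t(qmat)[lower.tri(qmat)]
  build_network(sm$rho, qmat, alpha = alpha, p = sm$p,
                classes = attr(table, "trait_classes"))
}

.edge_keys <- function(net, traits = NULL) {
  e <- net$edges
  if (!is.null(traits)) {
    e <- e[e$trait_a %in% traits & e$trait_b %in% traits, ]
  }
  if (nrow(e) == 0) return(character(0))
  apply(cbind(pmin(e$trait_a, e$trait_b), pmax(e$trait_a, e$trait_b)),
        1, paste, collapse = "|")
}

#' Does a network contain a given edge?
#'
#' @param net a `correlation_network`.
#' @param trait_a,trait_b trait names (order-free).
#' @return `TRUE` if the edge is present.
#' @export
has_edge <- function(net, trait_a, trait_b) {
  key <- paste(min(trait_a, trait_b), max(trait_a, trait_b), sep = "|")
  key %in% .edge_keys(net)
}

#' Compare two correlation networks
#'
#' Restricted to the traits present in both networks, reports shared and
#' unique edges, per-node degrees, the Jaccard index of the edge sets, and
#' presence flags for named edges of interest.
#'
#' @param net_a,net_b `correlation_network` objects (e.g. male and female).
#' @param edges_of_interest optional 2-column data frame / matrix of trait
#'   pairs to flag.
#' @return List with `shared_traits`, `shared_edges`, `unique_a`,
#'   `unique_b`, `degrees`, `jaccard`, and `edges_of_interest` flags.
#' @export
compare_networks <- function(net_a, net_b, edges_of_interest = NULL) {
  shared <- intersect(net_a$nodes$trait, net_b$nodes$trait)
  if (length(shared) == 0) stop("networks share no traits", call. = FALSE)
  ka <- .edge_keys(net_a, shared)
  kb <- .edge_keys(net_b, shared)
  un <- union(ka, kb)
  jac <- if (length(un) == 0) NA_real_ else length(intersect(ka, kb)) / length(un)
  degree_of <- function(net) {
    e <- net$edges
    tab <- table(factor(c(e$trait_a, e$trait_b), levels = net$nodes$trait))
    tibble::tibble(trait = names(tab), degree = as.integer(tab))
  }
  flags <- NULL
  if (!is.null(edges_of_interest)) {
    eoi <- as.data.frame(edges_of_interest)
    flags <- tibble::tibble(
      trait_a = eoi[[1]], trait_b = eoi[[2]],
      in_a = mapply(has_edge, eoi[[1]], eoi[[2]], MoreArgs = list(net = net_a)),
      in_b = mapply(has_edge, eoi[[1]], eoi[[2]], MoreArgs = list(net = net_b)))
  }
  list(shared_traits = shared,
       shared_edges = intersect(ka, kb),
       unique_a = setdiff(ka, kb),
       unique_b = setdiff(kb, ka),
       degrees = list(a = degree_of(net_a), b = degree_of(net_b)),
       jaccard = jac,
       edges_of_interest = flags)
}

#' Power of the two-sided correlation test (Fisher z)
#'
#' Analytic power to detect a population correlation `r` at level `alpha`
#' with `n` pairs: the critical correlation comes from the t quantile at
#' df = n - 2, and power is evaluated on the Fisher-z scale with the
#' r / (2(n-1)) bias term. With n = 24 and r = 0.5 (a large effect by
#' Cohen's guidelines) this gives ~0.73, the design power of the emulated
#' study's per-sex networks.
#'
#' @param n sample size (>= 4).
#' @param r population correlation (0 < r < 1).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @examples
#' correlation_power(24, 0.5, 0.05)
#' @export
correlation_power <- function(n, r, alpha = 0.05) {
  if (n < 4 || r <= 0 || r >= 1 || alpha <= 0 || alpha >= 1) {
    stop("need n >= 4, 0 < r < 1, 0 < alpha < 1", call. = FALSE)
  }
  t_crit <- qt(1 - alpha / 2, df = n - 2)
  r_crit <- t_crit / sqrt(t_crit^2 + n - 2)
  mu <- atanh(r) + r / (2 * (n - 1))  # Fisher z with bias term
  # both rejection tails (the far tail only matters as r -> 0)
  pnorm((mu - atanh(r_crit)) * sqrt(n - 3)) +
    pnorm((-mu - atanh(r_crit)) * sqrt(n - 3))
}
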