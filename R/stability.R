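#' Enumerate same-size subsamples of a cohort
#'
#' All `choose(n, k)` animal-index combinations, one per row, in
#' lexicographic order. Sizes below 3 are rejected: a Pearson p-value needs
#' at least 3 animals, so smaller subgroups are never analyzed.
#'
#' @param n cohort size.
#' @param k subgroup size, `3 <= k <= n`.
#' @return integer matrix, `choose(n, k)` rows by `k` columns.
#' @export
enumerate_subsamples <- function(n, k) {
  if (k < 3) stop("subgroup size must be >= 3, got ", k, call. = FALSE)
  if (k > n) stop("subgroup size ", k, " exceeds cohort size ", n, call. = FALSE)
  t(utils::combn(n, k))
}

# Upper-triangle r and p vectors for a column subset, with the zero-variance
# rule (r = 0, p = 1) applied silently; degenerate pair counts are tallied by
# the caller.
corr_pvalues_ut <- function(values, ut) {
  k <- ncol(values)
  r <- suppressWarnings(stats::cor(t(values)))
  const <- rowSums((values - rowMeans(values))^2) == 0
  n_const <- sum(const)
  if (n_const) {
    r[const, ] <- 0
    r[, const] <- 0
  }
  r_ut <- r[ut]
  p_ut <- p_two_tailed(r_ut, k)
  if (n_const) {
    pm <- matrix(FALSE, nrow(values), nrow(values))
    pm[const, ] <- TRUE
    pm[, const] <- TRUE
    p_ut[pm[ut]] <- 1
  }
  list(r = r_ut, p = p_ut, n_const = n_const)
}

#' Exhaustive group-size stability scan
#'
#' The group-size robustness analysis: for every subgroup size `k` in
#' `sizes` and every one of the `choose(n, k)` same-size subsamples of the
#' cohort, the correlation matrix is recomputed on the column subset and each
#' region pair is classified significant/nonsignificant under `spec` (the
#' FDR family, when configured, is re-applied within each subsample). Per
#' edge and size the scan accumulates the *flip rate* — the fraction of
#' subsamples whose verdict differs from the full-cohort verdict (a
#' false-negative-type flip for edges significant at full cohort, a
#' false-positive-type flip otherwise) — and the variance of the p-value
#' across the subsamples. Per size, the per-edge variances are aggregated.
#'
#' The exhaustive enumeration matches the all-possible-combinations design;
#' for cohorts above `mc_threshold` animals, where `choose(n, k)` explodes, a
#' seeded Monte-Carlo sample of at most `mc_cap` combinations per size is
#' used instead and flagged in the result.
#'
#' @param table a [region_table()].
#' @param sizes integer vector of subgroup sizes (default `3:n`).
#' @param spec a [threshold_spec()] applied to full cohort and every
#'   subsample alike.
#' @param aggregate how per-edge p-variances are pooled per size: `"mean"`
#'   (default) or `"median"`.
#' @param mc_threshold cohort size above which Monte-Carlo subsampling
#'   replaces exhaustive enumeration (default 14).
#' @param mc_cap maximum combinations per size in Monte-Carlo mode.
#' @param mc_seed seed for Monte-Carlo mode.
#' @return a `stability_report`: list with `sizes`; `edges` (data.frame of
#'   region pairs with the full-cohort p, verdict and flip class);
#'   `flip_rate` and `p_variance` (edge-by-size matrices);
#'   `variance_by_size` (named aggregate vector); `n_combinations` (per
#'   size); `n_zero_variance` (tally of degenerate region instances met
#'   across subsamples); `spec`; `exhaustive` (logical).
#' @export
subsample_scan <- function(table, sizes = NULL, spec = threshold_spec(),
                           aggregate = c("mean", "median"),
                           mc_threshold = 14L, mc_cap = 2000L, mc_seed = 1L) {
  aggregate <- match.arg(aggregate)
  table <- as_region_table(table)
  values <- unclass(table)
  n <- ncol(values)
  if (is.null(sizes)) sizes <- 3:n
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 3) || any(sizes > n)) {
    stop("`sizes` must lie within [3, ", n, "]", call. = FALSE)
  }
  ut <- upper.tri(diag(nrow(values)))
  pair_idx <- which(ut, arr.ind = TRUE)
  n_edges <- nrow(pair_idx)
  exhaustive <- n <= mc_threshold

  full <- corr_pvalues_ut(values, ut)
  full_sig <- edge_verdict(full$r, full$p, spec)

  flip_rate <- p_var <- matrix(NA_real_, n_edges, length(sizes),
                               dimnames = list(NULL, paste0("k", sizes)))
  n_comb <- stats::setNames(integer(length(sizes)), paste0("k", sizes))
  n_zero_var <- 0L

  for (si in seq_along(sizes)) {
    k <- sizes[si]
    combos <- enumerate_subsamples(n, k)
    if (!exhaustive && nrow(combos) > mc_cap) {
      pick <- withr::with_seed(as.integer(mc_seed) + k,
                               sample.int(nrow(combos), mc_cap))
      combos <- combos[sort(pick), , drop = FALSE]
    }
    m <- nrow(combos)
    s1 <- s2 <- flips <- numeric(n_edges)
    for (ci in seq_len(m)) {
      sub <- values[, combos[ci, ], drop = FALSE]
      cp <- corr_pvalues_ut(sub, ut)
      n_zero_var <- n_zero_var + cp$n_const
      sig <- edge_verdict(cp$r, cp$p, spec)
      s1 <- s1 + cp$p
      s2 <- s2 + cp$p^2
      flips <- flips + (sig != full_sig)
    }
    flip_rate[, si] <- flips / m
    p_var[, si] <- if (m > 1) pmax(0, (s2 - s1^2 / m) / (m - 1)) else 0
    n_comb[si] <- m
  }
  if (n_zero_var > 0) {
    warning(n_zero_var, " zero-variance region instance(s) encountered ",
            "across subsamples; their pairs followed the r = 0, p = 1 rule",
            call. = FALSE)
  }
  agg_fun <- if (aggregate == "mean") mean else stats::median
  edges <- data.frame(
    region_a = rownames(values)[pair_idx[, 1]],
    region_b = rownames(values)[pair_idx[, 2]],
    full_p = full$p,
    full_significant = full_sig,
    class = ifelse(full_sig, "false_negative_type", "false_positive_type"),
    stringsAsFactors = FALSE)
  structure(list(
    sizes = sizes,
    edges = edges,
    flip_rate = flip_rate,
    p_variance = p_var,
    variance_by_size = stats::setNames(apply(p_var, 2L, agg_fun),
                                       paste0("k", sizes)),
    aggregate = aggregate,
    n_combinations = n_comb,
    n_zero_variance = n_zero_var,
    spec = spec,
    exhaustive = exhaustive),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> ", nrow(x$edges), " edges x sizes ",
      paste(range(x$sizes), collapse = ".."), " (",
      sum(x$n_combinations), " subsample networks, ",
      if (x$exhaustive) "exhaustive" else "Monte-Carlo", ")\n", sep = "")
  cat("  ", x$aggregate, " p-variance by size: ",
      paste(sprintf("%s=%.4f", names(x$variance_by_size), x$variance_by_size),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-size flip-rate curve of one edge
#'
#' Extracts, for a single region pair, the fraction of same-size subsamples
#' whose significance verdict flipped relative to the full cohort, together
#' with the flip class: a pair significant in the full cohort flips toward
#' false negatives as the group shrinks, a nonsignificant pair toward false
#' positives.
#'
#' @param report a [subsample_scan()] result.
#' @param edge character vector of the two region labels.
#' @return data.frame with columns `size`, `flip_rate`, `class`.
#' @export
flip_rate_curves <- function(report, edge) {
  stopifnot(inherits(report, "stability_report"), length(edge) == 2L)
  hit <- (report$edges$region_a == edge[1] & report$edges$region_b == edge[2]) |
    (report$edges$region_a == edge[2] & report$edges$region_b == edge[1])
  if (!any(hit)) {
    stop("unknown region pair: ", edge[1], " - ", edge[2], call. = FALSE)
  }
  i <- which(hit)[1]
  data.frame(size = report$sizes,
             flip_rate = unname(report$flip_rate[i, ]),
             class = report$edges$class[i],
             stringsAsFactors = FALSE)
}

#' Median-variance network at a reduced group size
#'
#' Reproduces the representative-small-network selection: every
#' `choose(n, k)` subsample of size `k` is scored by the variance of its
#' p-value distribution over all region pairs, the combinations are ranked by
#' that score, and the median-ranked combination (lower median for an even
#' count) is rebuilt into a binary network under `spec`. Ties in the score
#' are broken by lexicographic combination order (a message reports when this
#' happens).
#'
#' @param table a [region_table()].
#' @param k subgroup size.
#' @param spec a [threshold_spec()].
#' @return list with `network` (the rebuilt `fc_network`), `animals` (member
#'   animal IDs), `combination` (column indices), `score` (the combination's
#'   p-variance), and `scores` (all combinations' scores, for inspection).
#' @export
select_median_variance_network <- function(table, k, spec = threshold_spec()) {
  table <- as_region_table(table)
  values <- unclass(table)
  n <- ncol(values)
  combos <- enumerate_subsamples(n, k)
  ut <- upper.tri(diag(nrow(values)))
  scores <- vapply(seq_len(nrow(combos)), function(ci) {
    cp <- corr_pvalues_ut(values[, combos[ci, ], drop = FALSE], ut)
    stats::var(cp$p)
  }, numeric(1))
  ord <- order(scores)  # stable: ties keep lexicographic combination order
  if (anyDuplicated(scores)) {
    message("ties in aggregate p-variance broken by lexicographic combination order")
  }
  med_rank <- if (length(ord) %% 2L == 1L) (length(ord) + 1L) %/% 2L else length(ord) %/% 2L
  sel <- ord[med_rank]
  idx <- combos[sel, ]
  sub <- region_table(values[, idx, drop = FALSE], check_nonnegative = FALSE)
  net <- binarize(correlate_table(sub), spec)
  list(network = net,
       animals = colnames(values)[idx],
       combination = idx,
       score = scores[sel],
       scores = scores)
}
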