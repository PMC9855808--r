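#' Pearson product-moment correlation of two regional activity vectors
#'
#' Thin, validating wrapper around [stats::cor()] for a single pair of
#' regions. The coefficient is symmetric in its arguments and invariant to
#' affine rescaling of either vector. A constant vector has no defined
#' correlation and raises an error here; the matrix-level routine
#' [correlate_table()] instead maps such pairs to `r = 0, p = 1` with a
#' warning, so a degenerate region can never gain edges without crashing a
#' cohort-level run.
#'
#' @param x,y numeric vectors of equal length `>= 3` (one density per animal).
#' @return the correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 animals, got ", length(x), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance vector: correlation undefined for a constant region",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Exact t-transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a
#' Student t distribution with `n - 2` degrees of freedom, two tails. At
#' `|r| = 1` the p-value is 0 by convention.
#'
#' @param r correlation coefficient(s), `|r| <= 1`. Vectorized.
#' @param n group size (number of animals), `>= 3`.
#' @return two-tailed p-value(s) in `[0, 1]`.
#' @examples
#' p_two_tailed(0.6193, 12)  # ~0.0318
#' p_two_tailed(0.2539, 12)  # ~0.4258
#' @export
p_two_tailed <- function(r, n) {
  if (length(n) != 1L || !is.finite(n) || n < 3) {
    stop("`n` must be a single group size >= 3", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  df <- n - 2
  tstat <- r[!exact] * sqrt(df / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p
}

#' Cross-correlate a region table across animals
#'
#' Computes the full symmetric matrix of pairwise Pearson coefficients
#' between regions (each region is a vector of densities across the cohort)
#' together with two-tailed p-values from the t-transform. This is the
#' correlated-activity ("functional connectivity") matrix from which binary
#' networks are thresholded.
#'
#' Regions with zero variance across the cohort would make `r` undefined;
#' every pair involving such a region is assigned `r = 0, p = 1` and a single
#' warning reports how many regions were degenerate. A constant region can
#' therefore never gain edges, and a cohort-level run never aborts midway.
#'
#' @param table a [region_table()].
#' @return a `correlation_result`: list with elements `r` (symmetric
#'   coefficient matrix, unit diagonal), `p` (symmetric p-value matrix,
#'   diagonal `NA`), `n` (group size used) and `regions`.
#' @export
correlate_table <- function(table) {
  table <- as_region_table(table)
  values <- unclass(table)
  n <- ncol(values)
  sds <- apply(values, 1L, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(t(values)))
  if (any(const)) {
    warning(sum(const), " region(s) with zero variance across animals; ",
            "their pairs are assigned r = 0, p = 1: ",
            paste(utils::head(rownames(values)[const], 5), collapse = ", "),
            call. = FALSE)
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  p <- matrix(p_two_tailed(r[seq_along(r)], n), nrow(r), ncol(r),
              dimnames = dimnames(r))
  if (any(const)) {
    p[const, ] <- 1
    p[, const] <- 1
  }
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, regions = rownames(values)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", length(x$regions), " regions, n = ", x$n,
      " animals\n", sep = "")
  ut <- upper.tri(x$r)
  cat(sum(ut), " region pairs; |r| range ",
      sprintf("%.3f..%.3f", min(abs(x$r[ut])), max(abs(x$r[ut]))), "\n",
      sep = "")
  invisible(x)
}

#' Thresholding specification for network binarization
#'
#' Bundles the filters applied when a correlation matrix is binarized into a
#' network: a significance level `alpha` (edges require `p <= alpha`), an
#' optional Benjamini-Hochberg false discovery rate `fdr_q` applied to the
#' family of all unique region pairs, an optional critical-value floor
#' `r_min` on `|r|`, and the policy for negative correlations.
#'
#' `sign_policy = "positive_only"` (the default) drops anticorrelations, the
#' most common practice in the field; `"absolute"` admits them by magnitude;
#' `"signed"` admits them and stores the edge signs, so exclusion of
#' anticorrelations is always an explicit choice rather than a silent one.
#'
#' @param alpha significance level in (0, 1]; typical choices 0.05, 0.005,
#'   0.0005. Comparison is `p <= alpha`.
#' @param fdr_q optional FDR rate in (0, 1] (the conventional choice is
#'   0.05); `NULL` disables FDR filtering.
#' @param r_min optional minimum `|r|` in `[0, 1)`; `NULL` disables the floor.
#' @param sign_policy one of `"positive_only"`, `"absolute"`, `"signed"`.
#' @return a `threshold_spec`.
#' @export
threshold_spec <- function(alpha = 0.05, fdr_q = NULL, r_min = NULL,
                           sign_policy = c("positive_only", "absolute", "signed")) {
  sign_policy <- match.arg(sign_policy)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(fdr_q) &&
      (length(fdr_q) != 1L || !is.finite(fdr_q) || fdr_q <= 0 || fdr_q > 1)) {
    stop("`fdr_q` must be in (0, 1] or NULL", call. = FALSE)
  }
  if (!is.null(r_min) &&
      (length(r_min) != 1L || !is.finite(r_min) || r_min < 0 || r_min >= 1)) {
    stop("`r_min` must be in [0, 1) or NULL", call. = FALSE)
  }
  structure(list(alpha = alpha, fdr_q = fdr_q, r_min = r_min,
                 sign_policy = sign_policy),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec> alpha <= ", format(x$alpha),
      if (!is.null(x$fdr_q)) paste0(", BH FDR q = ", format(x$fdr_q)),
      if (!is.null(x$r_min)) paste0(", |r| >= ", format(x$r_min)),
      ", sign policy: ", x$sign_policy, "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg retention flags
#'
#' Step-up FDR filter over one family of p-values (for networks, the family
#' is the upper triangle of the current node set — all unique region pairs).
#' Sort the m p-values, find the largest rank k with
#' `p(k) <= k * q / m`, and retain every p-value `<= p(k)`; retain none if no
#' rank qualifies. Implemented through [stats::p.adjust()], whose BH-adjusted
#' values are `<= q` exactly for the retained set.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q false discovery rate in (0, 1].
#' @return logical vector: `TRUE` where the p-value is retained.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.8), 0.05)  # TRUE TRUE FALSE FALSE
#' @export
bh_fdr <- function(pvalues, q) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q > 1) {
    stop("`q` must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Binarize a correlation matrix into a functional connectivity network
#'
#' An edge joins regions i and j iff every configured filter passes:
#' `p(i,j) <= alpha`; the pair is retained by the Benjamini-Hochberg step-up
#' at `fdr_q` over the family of all unique pairs (when `fdr_q` is set);
#' `|r(i,j)| >= r_min` (when set); and the sign condition of the policy
#' (`positive_only`: `r > 0`; `absolute` and `signed`: either sign, with
#' `signed` additionally recording edge signs). The result is a binary,
#' symmetric, hollow adjacency matrix.
#'
#' @param corr a `correlation_result` from [correlate_table()].
#' @param spec a [threshold_spec()].
#' @return an `fc_network`: list with `adjacency` (0/1 integer matrix),
#'   `regions`, `spec`, and `signs` (matrix of -1/0/1, only when
#'   `sign_policy = "signed"`).
#' @export
binarize <- function(corr, spec = threshold_spec()) {
  stopifnot(inherits(corr, "correlation_result"), inherits(spec, "threshold_spec"))
  nr <- length(corr$regions)
  ut <- upper.tri(corr$r)
  keep <- edge_verdict(corr$r[ut], corr$p[ut], spec)
  adj <- matrix(0L, nr, nr, dimnames = list(corr$regions, corr$regions))
  adj[ut][keep] <- 1L
  adj <- adj + t(adj)
  signs <- NULL
  if (spec$sign_policy == "signed") {
    signs <- matrix(0L, nr, nr, dimnames = list(corr$regions, corr$regions))
    signs[ut][keep] <- as.integer(sign(corr$r[ut][keep]))
    signs <- signs + t(signs)
  }
  structure(list(adjacency = adj, regions = corr$regions, spec = spec,
                 signs = signs),
            class = "fc_network")
}

# Edge rule on upper-triangle vectors; shared by binarize() and the
# subsampling scan so both apply identical significance semantics.
edge_verdict <- function(r_ut, p_ut, spec) {
  keep <- p_ut <= spec$alpha
  if (!is.null(spec$fdr_q)) keep <- keep & bh_fdr(p_ut, spec$fdr_q)
  if (!is.null(spec$r_min)) keep <- keep & abs(r_ut) >= spec$r_min
  if (spec$sign_policy == "positive_only") keep <- keep & r_ut > 0
  keep
}

#' Construct a network directly from an adjacency matrix
#'
#' @param adjacency binary symmetric hollow matrix with region dimnames.
#' @param spec optional [threshold_spec()] provenance.
#' @return an `fc_network`.
#' @export
fc_network <- function(adjacency, spec = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("`adjacency` must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(adjacency))) {
    dimnames(adjacency) <- list(paste0("R", seq_len(nrow(adjacency))),
                                paste0("R", seq_len(nrow(adjacency))))
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("`adjacency` entries must be 0/1", call. = FALSE)
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("`adjacency` must be symmetric", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("`adjacency` must be hollow (zero diagonal)", call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  structure(list(adjacency = adjacency, regions = rownames(adjacency),
                 spec = spec, signs = NULL),
            class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  e <- sum(x$adjacency) / 2
  cat("<fc_network> ", length(x$regions), " regions, ", e, " edges (density ",
      sprintf("%.3f", network_density(x)), ")\n", sep = "")
  invisible(x)
}

#' Edge list of a network
#'
#' @param net an `fc_network`.
#' @param corr optional `correlation_result` used to annotate each edge with
#'   its r and p.
#' @return data.frame with columns `region_a`, `region_b`, and (when `corr`
#'   is given) `r`, `p`, `sign`.
#' @export
edge_list <- function(net, corr = NULL) {
  stopifnot(inherits(net, "fc_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  out <- data.frame(region_a = net$regions[idx[, 1]],
                    region_b = net$regions[idx[, 2]],
                    stringsAsFactors = FALSE)
  if (!is.null(corr)) {
    out$r <- corr$r[idx]
    out$p <- corr$p[idx]
    out$sign <- as.integer(sign(out$r))
  }
  out[order(idx[, 2], idx[, 1]), , drop = FALSE]
}
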