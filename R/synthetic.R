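#' Sample a ground-truth coactivation network
#'
#' Draws the binary "true" network that a synthetic cohort's inter-regional
#' correlations are built around: `round(edge_density * choose(n_regions, 2))`
#' region pairs sampled uniformly without replacement. The true structure that
#' a real experiment can only estimate is therefore known exactly, so edge
#' recovery, calibration and stability analyses are quantifiable.
#'
#' @param n_regions number of regions (nodes), `>= 2`.
#' @param edge_density fraction of the `choose(n_regions, 2)` possible edges
#'   to realize, in `[0, 1]`.
#' @param seed integer seed; the draw is deterministic given the seed and is
#'   performed in a local RNG scope (the caller's RNG state is untouched).
#' @param effect_r target pairwise Pearson correlation on true edges, strictly
#'   between -1 and 1 (default 0.7).
#' @param regions optional character vector of region labels; defaults to
#'   `R01, R02, ...`.
#' @return a `ground_truth`: list with `n_regions`, `adjacency` (binary
#'   symmetric hollow integer matrix), `effect_r`, `seed`.
#' @export
make_ground_truth <- function(n_regions, edge_density, seed, effect_r = 0.7,
                              regions = NULL) {
  if (length(n_regions) != 1L || !is.finite(n_regions) ||
      n_regions != round(n_regions) || n_regions < 2) {
    stop("`n_regions` must be an integer >= 2", call. = FALSE)
  }
  if (length(edge_density) != 1L || !is.finite(edge_density) ||
      edge_density < 0 || edge_density > 1) {
    stop("`edge_density` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(effect_r) >= 1) {
    stop("`effect_r` must be strictly between -1 and 1", call. = FALSE)
  }
  n_regions <- as.integer(n_regions)
  if (is.null(regions)) {
    regions <- sprintf("R%02d", seq_len(n_regions))
  }
  stopifnot(length(regions) == n_regions)
  n_pairs <- choose(n_regions, 2)
  n_edges <- round(edge_density * n_pairs)
  adj <- matrix(0L, n_regions, n_regions, dimnames = list(regions, regions))
  if (n_edges > 0) {
    picked <- withr::with_seed(as.integer(seed),
                               sample.int(n_pairs, n_edges))
    ut <- which(upper.tri(adj))
    adj[ut[picked]] <- 1L
    adj <- adj + t(adj)
  }
  structure(list(n_regions = n_regions, adjacency = adj,
                 effect_r = effect_r, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$n_regions, " regions, ",
      sum(x$adjacency) / 2, " true edges, effect r = ", x$effect_r,
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Target correlation matrix of a ground truth
#'
#' The population correlation structure the cohort is sampled from:
#' `I + effect_r * adjacency`, i.e. exactly `effect_r` on true edges and 0
#' elsewhere. When that matrix is not positive-definite (dense graphs or
#' strong effects make it indefinite), it is replaced by the nearest
#' positive-definite correlation matrix under Frobenius distance
#' (Higham's alternating-projection algorithm via [Matrix::nearPD()]). The
#' projection shrinks on-edge correlations toward feasibility and introduces
#' small off-edge correlations; the attributes `projected` (logical) and
#' `max_shift` (largest absolute entry change) document the shrinkage, and
#' recovery should always be benchmarked against the *returned* matrix.
#'
#' @param truth a [make_ground_truth()] object.
#' @param maxit iteration cap for the projection (default 200).
#' @return a valid correlation matrix (unit diagonal, symmetric,
#'   positive-definite) with attributes `projected` and `max_shift`.
#' @export
target_correlation_matrix <- function(truth, maxit = 200) {
  stopifnot(inherits(truth, "ground_truth"))
  S <- diag(truth$n_regions) + truth$effect_r * truth$adjacency
  dimnames(S) <- dimnames(truth$adjacency)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) {
    attr(S, "projected") <- FALSE
    attr(S, "max_shift") <- 0
    return(S)
  }
  pd <- Matrix::nearPD(S, corr = TRUE, maxit = maxit)
  if (!pd$converged) {
    stop("nearest positive-definite projection failed to converge within ",
         maxit, " iterations; residual norm ", format(pd$normF), call. = FALSE)
  }
  out <- as.matrix(pd$mat)
  dimnames(out) <- dimnames(truth$adjacency)
  attr(out, "projected") <- TRUE
  attr(out, "max_shift") <- max(abs(out - S))
  out
}

#' Cohort sampling specification
#'
#' Describes how latent network-structured Gaussian activity is turned into a
#' non-negative region-by-animal density table.
#'
#' @param n_animals group size, `>= 3` (default 12, a typical IEG cohort).
#' @param baseline per-region mean density (scalar or length-`n_regions`
#'   vector), non-negative. Default 5.
#' @param noise_sd per-region dispersion (scalar or vector), positive.
#'   Default 1. Neither quantity is estimated from published data — regional
#'   density variability is essentially never reported — so both are free,
#'   explicit parameters.
#' @param transform mapping from latent values to non-negative densities:
#'   `"softplus"` (default; smooth, strictly increasing, `log(1 + exp(x))`),
#'   `"exponential"` (`exp(x)`, log-normal densities), or `"none"` (identity;
#'   latent scale, may be negative — intended for statistical calibration
#'   where exact multivariate normality is wanted).
#' @param outlier optional list `list(n = <animals to perturb>,
#'   magnitude = <size in noise-sd units>)`; each perturbed animal's latent
#'   vector is replaced by `baseline + magnitude * noise_sd * u` with `u` a
#'   uniformly random unit direction, emulating the single-animal outliers
#'   that destabilize small-cohort correlations.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 12, baseline = 5, noise_sd = 1,
                        transform = c("softplus", "exponential", "none"),
                        outlier = NULL) {
  transform <- match.arg(transform)
  if (length(n_animals) != 1L || !is.finite(n_animals) ||
      n_animals != round(n_animals) || n_animals < 3) {
    stop("`n_animals` must be an integer >= 3", call. = FALSE)
  }
  if (any(!is.finite(baseline)) || any(baseline < 0)) {
    stop("`baseline` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (!is.null(outlier)) {
    if (!is.list(outlier) || is.null(outlier$n) || is.null(outlier$magnitude) ||
        outlier$n < 0 || outlier$magnitude < 0) {
      stop("`outlier` must be list(n = <count >= 0>, magnitude = <sd units >= 0>)",
           call. = FALSE)
    }
  }
  structure(list(n_animals = as.integer(n_animals), baseline = baseline,
                 noise_sd = noise_sd, transform = transform, outlier = outlier),
            class = "cohort_spec")
}

#' Simulate a synthetic cohort from a ground-truth network
#'
#' Draws `n_animals` independent animals from a zero-mean multivariate
#' Gaussian with covariance [target_correlation_matrix()] (so true-edge pairs
#' are correlated at the projected effect size and non-edges at ~0), scales by
#' `noise_sd`, shifts by `baseline`, optionally replaces designated outlier
#' animals, and applies the non-negativity transform. Deterministic for a
#' fixed seed. One seed governs the network structure
#' ([make_ground_truth()]), a second governs the sampling here, so the same
#' truth can back many cohorts.
#'
#' @param truth a [make_ground_truth()] object.
#' @param spec a [cohort_spec()]; `baseline`/`noise_sd` scalars are recycled
#'   across regions.
#' @param seed integer sampling seed (local RNG scope).
#' @return a [region_table()] with `n_regions` rows and `n_animals` columns
#'   (animal IDs `A01, A02, ...`). All entries are `>= 0` unless
#'   `transform = "none"`.
#' @export
simulate_cohort <- function(truth, spec = cohort_spec(), seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "cohort_spec"))
  nr <- truth$n_regions
  baseline <- rep_len(spec$baseline, nr)
  noise_sd <- rep_len(spec$noise_sd, nr)
  if (length(spec$baseline) > 1L && length(spec$baseline) != nr) {
    stop("`baseline` length must be 1 or n_regions (", nr, ")", call. = FALSE)
  }
  if (length(spec$noise_sd) > 1L && length(spec$noise_sd) != nr) {
    stop("`noise_sd` length must be 1 or n_regions (", nr, ")", call. = FALSE)
  }
  R <- target_correlation_matrix(truth)
  latent <- withr::with_seed(as.integer(seed), {
    Z <- t(MASS::mvrnorm(spec$n_animals, mu = rep(0, nr), Sigma = R))
    L <- baseline + noise_sd * Z
    if (!is.null(spec$outlier) && spec$outlier$n > 0) {
      who <- sample.int(spec$n_animals, min(spec$outlier$n, spec$n_animals))
      for (j in who) {
        u <- stats::rnorm(nr)
        u <- u / sqrt(sum(u^2))
        L[, j] <- baseline + spec$outlier$magnitude * noise_sd * u
      }
    }
    L
  })
  values <- switch(spec$transform,
                   none = latent,
                   softplus = softplus(latent),
                   exponential = exp(latent))
  dimnames(values) <- list(rownames(truth$adjacency),
                           sprintf("A%02d", seq_len(spec$n_animals)))
  region_table(values, check_nonnegative = spec$transform != "none")
}

# Overflow-safe log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Write a ground truth to disk
#'
#' Writes the true network both as an edge-list TSV (`region_a`, `region_b`)
#' and as a labelled adjacency CSV.
#'
#' @param truth a [make_ground_truth()] object.
#' @param edges_tsv,adjacency_csv output paths (either may be `NULL` to skip).
#' @return invisibly, a character vector of the paths written.
#' @export
write_ground_truth <- function(truth, edges_tsv = NULL, adjacency_csv = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  written <- character(0)
  if (!is.null(edges_tsv)) {
    idx <- which(upper.tri(truth$adjacency) & truth$adjacency == 1L,
                 arr.ind = TRUE)
    df <- data.frame(region_a = rownames(truth$adjacency)[idx[, 1]],
                     region_b = rownames(truth$adjacency)[idx[, 2]])
    utils::write.table(df, edges_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, edges_tsv)
  }
  if (!is.null(adjacency_csv)) {
    df <- data.frame(region = rownames(truth$adjacency), truth$adjacency,
                     check.names = FALSE)
    utils::write.csv(df, adjacency_csv, row.names = FALSE, quote = FALSE)
    written <- c(written, adjacency_csv)
  }
  invisible(written)
}
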