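#' Mutual information of a discrete joint table (nats)
#'
#' Plug-in estimator `sum p(x,y) log[p(x,y)/(p(x)p(y))]` with the convention
#' `0 log 0 = 0`. The table must be normalized.
#'
#' @param joint numeric matrix summing to 1.
#' @return non-negative scalar, in nats.
#' @export
mutual_information <- function(joint) {
  s <- sum(joint)
  if (!is.finite(s) || abs(s - 1) > 1e-8) stop("joint table is not normalized")
  if (any(joint < 0)) stop("joint table has negative entries")
  px <- rowSums(joint); py <- colSums(joint)
  nz <- which(joint > 0, arr.ind = TRUE)
  p <- joint[nz]
  max(0, sum(p * log(p / (px[nz[, 1]] * py[nz[, 2]]))))
}

# shared binning rule: equal-width bins on [0, x_max]
bin_counts <- function(x, n_bins, x_max) {
  b <- floor(x * n_bins / (x_max + 1)) + 1L
  pmin(b, n_bins)
}

# internal: pull the (member x time) sample vector of one species
buffer_samples <- function(buffer, i) {
  if (length(dim(buffer)) == 3) as.vector(buffer[, i, ]) else buffer[, i]
}

#' Estimate a binned joint distribution from a sample buffer
#'
#' Histograms two species' samples over an `n_bins x n_bins` grid of
#' equal-width count bins on `[0, x_max]` and normalizes.
#'
#' @param buffer `n_pop x N x dt_av` integer array (or samples-by-species
#'   matrix) of recorded counts.
#' @param i,j species indices.
#' @param n_bins number of bins per axis (at least 2).
#' @param x_max copy-number cap defining the binning range (scalar or
#'   per-species vector).
#' @return normalized `n_bins x n_bins` matrix (rows: species `i`).
#' @export
estimate_joint <- function(buffer, i, j, n_bins = 10, x_max = 1000) {
  if (length(buffer) == 0) stop("empty sample buffer")
  stopifnot(n_bins >= 2)
  xm <- rep_len(x_max, max(i, j))
  bi <- bin_counts(buffer_samples(buffer, i), n_bins, xm[i])
  bj <- bin_counts(buffer_samples(buffer, j), n_bins, xm[j])
  tab <- table(factor(bi, levels = seq_len(n_bins)),
               factor(bj, levels = seq_len(n_bins)))
  unname(as.matrix(tab) / length(bi))
}

#' Pearson correlation of two species from a sample buffer
#'
#' @inheritParams estimate_joint
#' @return correlation in `[-1, 1]`, or `NA` when either variance is zero
#'   (undefined correlation is reported as missing, not 0).
#' @export
correlation <- function(buffer, i, j) {
  xi <- buffer_samples(buffer, i); xj <- buffer_samples(buffer, j)
  if (stats::var(xi) == 0 || stats::var(xj) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(xi, xj)
}

#' Three-level coarse-grained activity
#'
#' Maps a species' mean count to an activity level: `-1` below
#' `threshold - sd`, `+1` above `threshold + sd`, else `0`.
#'
#' @param mean,sd,threshold numeric (vectorized).
#' @return integer vector in `{-1, 0, +1}`.
#' @export
coarse_activity <- function(mean, sd, threshold) {
  stopifnot(all(sd >= 0))
  as.integer(ifelse(mean < threshold - sd, -1L, ifelse(mean > threshold + sd, 1L, 0L)))
}

#' Signal-to-response objective from an MI matrix
#'
#' `E = sum_{i in S} (1/|R(i)|) sum_{j in R(i)} MI(i, j)`: each signal
#' contributes the mean mutual information to its assigned response species.
#'
#' @param mi symmetric mutual-information matrix.
#' @param signals integer vector of signal species.
#' @param responses named list mapping signal index (character) to response
#'   species indices.
#' @return non-negative scalar.
#' @export
network_objective <- function(mi, signals, responses) {
  if (length(signals) == 0) {
    warning("empty signal set: objective is 0")
    return(0)
  }
  sum(vapply(signals, function(s)
    mean(mi[s, responses[[as.character(s)]]]), numeric(1)))
}

# internal: objective from per-pair MI values as produced by run_ensemble
objective_from_pair_mi <- function(mi, pairs, net) {
  if (length(net$signals) == 0) return(0)
  sum(vapply(net$signals, function(s) {
    rs <- net$responses[[as.character(s)]]
    sel <- pairs[, 1] == s & pairs[, 2] %in% rs
    if (!any(sel)) return(0)
    mean(mi[sel])
  }, numeric(1)))
}

#' Mean absolute concentration distance between two states
#'
#' `d = sum_i |c_i(t) - c_i(0)| / N` over concentrations
#' `c_i = <X_i>/x_max in [0, 1]`; a pseudometric on concentration profiles.
#'
#' @param c_t,c_0 concentration vectors of equal length with entries in
#'   `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
state_distance <- function(c_t, c_0) {
  if (length(c_t) != length(c_0)) stop("concentration vectors differ in length")
  mean(abs(c_t - c_0))
}

#' Binary sign variables from population counts
#'
#' Maps counts to medical-sign variables: `S_i = +1` when a member's count
#' exceeds the threshold `X_i*`, else `-1` (a count exactly at threshold maps
#' to `-1`). Also returns the population sign frequencies `Pr(S_i = +1)`.
#'
#' @param counts `n_pop x N` count matrix (or 3D sample buffer).
#' @param thresholds per-species thresholds `X_i*`.
#' @return list with `signs` (same shape as `counts`, values -1/+1) and
#'   `freq` (per-species frequency of `+1`).
#' @export
signs_from_population <- function(counts, thresholds) {
  if (length(counts) == 0) stop("empty counts")
  nd <- length(dim(counts))
  pos <- if (nd == 3) sweep(counts, 2, thresholds, ">") else
    sweep(counts, 2, thresholds, ">")
  signs <- ifelse(pos, 1L, -1L)
  freq <- if (nd == 3) apply(pos, 2, mean) else colMeans(pos)
  list(signs = signs, freq = freq)
}

#' Full statistical characterization of an ensemble buffer
#'
#' Computes per-species means, standard deviations, concentrations, the
#' three-level coarse activities, the symmetric mutual-information and
#' correlation matrices over all species pairs, and the objective `E` of the
#' network's signal/response assignment.
#'
#' @param buffer `n_pop x N x dt_av` sample buffer.
#' @param net the simulated `reaction_network`.
#' @param n_bins bins per axis for the joint histograms.
#' @param thresholds per-species sign thresholds (default `x_max/2`).
#' @return an `ensemble_stats` list.
#' @export
ensemble_stats <- function(buffer, net, n_bins = 10, thresholds = NULL) {
  ns <- n_species(net)
  if (is.null(thresholds)) thresholds <- net$species$x_max / 2
  samples <- vapply(seq_len(ns), function(i) buffer_samples(buffer, i),
                    numeric(length(buffer) / ns))
  mean_x <- colMeans(samples)
  sd_x <- apply(samples, 2, stats::sd)
  mi <- matrix(0, ns, ns); cc <- diag(1, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    mi[i, j] <- mi[j, i] <- mutual_information(
      estimate_joint(buffer, i, j, n_bins, net$species$x_max))
    r <- suppressWarnings(correlation(buffer, i, j))
    cc[i, j] <- cc[j, i] <- r
  }
  diag(mi) <- NA_real_
  structure(list(
    mean = mean_x, sd = sd_x, thresholds = thresholds,
    concentration = mean_x / net$species$x_max,
    activity = coarse_activity(mean_x, sd_x, thresholds),
    mi = mi, correlation = cc,
    objective = network_objective(mi, net$signals, net$responses)),
    class = "ensemble_stats")
}

#' Scale a matrix to unit maximum
#'
#' Divides by the maximum absolute entry so the largest magnitude is one
#' (used for displaying MI and correlation matrices on a common scale).
#'
#' @param m numeric matrix.
#' @return rescaled matrix (unchanged when the maximum is 0).
#' @export
scale_max1 <- function(m) {
  mx <- max(abs(m), na.rm = TRUE)
  if (mx == 0) m else m / mx
}
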