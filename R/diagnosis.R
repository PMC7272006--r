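#' Fit the single-defect naive-Bayes (D1S1) diagnostic model
#'
#' Estimates the time-indexed conditional sign probabilities
#' `Pr_t(S_i = +1 | D_r)` for every elementary defect cohort in the archive,
#' and `Pr_t(S_i = +1 | no defect)` from the healthy cohort, as
#' Laplace-smoothed frequencies `(count + c) / (n + 2c)` over the cohort's
#' realizations of the disease dynamics. A realization's sign vector at step
#' `t` is its macroscopic (population-mean) coarse state binarized at the
#' thresholds `X_i*`. Defects are assumed marginally independent with a
#' uniform prior, and signs conditionally independent given the defect.
#'
#' @param archive a `cohort_archive` containing one cohort per elementary
#'   defect plus a healthy (all-zero pattern) cohort.
#' @param pseudocount Laplace smoothing pseudocount `c` (default 1).
#' @param healthy_label name of the healthy cohort in the archive.
#' @return a `d1s1_model`: array `p[t+1, i, r]` of defect conditionals,
#'   matrix `p_healthy[t+1, i]`, uniform `prior`, defect `labels` and node
#'   indices.
#' @export
fit_d1s1 <- function(archive, pseudocount = 1, healthy_label = "healthy") {
  if (!healthy_label %in% archive$labels)
    stop("archive has no healthy cohort '", healthy_label, "'")
  def_labels <- setdiff(archive$labels, healthy_label)
  if (length(def_labels) == 0) stop("archive has no defect cohorts")
  for (lb in def_labels) {
    if (archive$defects[[lb]]$size != 1L)
      stop("cohort '", lb, "' is not an elementary (single-node) defect")
  }
  n_t <- archive$t_max + 1L
  ns <- archive$n_species
  pool <- function(label) {
    trajs <- archive$runs[[label]]
    pos <- Reduce(`+`, lapply(trajs, function(tr) (tr$signs > 0) + 0))
    (pos + pseudocount) / (length(trajs) + 2 * pseudocount)
  }
  p <- array(NA_real_, dim = c(n_t, ns, length(def_labels)),
             dimnames = list(NULL, NULL, def_labels))
  for (k in seq_along(def_labels)) p[, , k] <- pool(def_labels[k])
  structure(list(
    p = p, p_healthy = pool(healthy_label),
    prior = stats::setNames(rep(1 / length(def_labels), length(def_labels)), def_labels),
    labels = def_labels,
    nodes = vapply(def_labels, function(lb) which(archive$defects[[lb]]$d == 1L),
                   integer(1)),
    pseudocount = pseudocount, t_max = archive$t_max,
    n_species = ns), class = "d1s1_model")
}

#' Posterior over elementary defects given observed signs
#'
#' Naive-Bayes posterior `Pr(D_r | obs)` proportional to
#' `Pr(D_r) * prod_{i in obs} Pr_t(S_i | D_r)`, normalized over the
#' elementary defects. An empty observation set returns the prior.
#'
#' @param model a `d1s1_model`.
#' @param idx indices of the observed sign species (distinct).
#' @param signs observed sign values, `+1`/`-1`, aligned with `idx`.
#' @param t observation time step (0-based, up to the model's `t_max`).
#' @return named posterior vector summing to 1.
#' @export
posterior_single_defect <- function(model, idx, signs, t) {
  stopifnot(t >= 0, t <= model$t_max, !anyDuplicated(idx),
            length(idx) == length(signs))
  if (length(idx) == 0) return(model$prior)
  loglik <- vapply(seq_along(model$labels), function(k) {
    p_pos <- model$p[t + 1L, idx, k]
    sum(log(ifelse(signs > 0, p_pos, 1 - p_pos)))
  }, numeric(1))
  w <- log(model$prior) + loglik
  w <- exp(w - max(w))
  if (!any(is.finite(w)) || sum(w) == 0) {
    warning("all likelihoods vanish: returning uniform posterior")
    return(stats::setNames(rep(1 / length(model$labels), length(model$labels)),
                           model$labels))
  }
  stats::setNames(w / sum(w), model$labels)
}

#' Eq-style accuracy from aggregate confusion counts
#'
#' The plain ratio `(P_true + N_true) / (P_total + N_total)` of correctly
#' classified positive and negative cases.
#'
#' @param p_true,n_true correctly classified positive / negative cases.
#' @param p_total,n_total total positive / negative cases.
#' @return scalar in `[0, 1]`.
#' @export
accuracy_from_counts <- function(p_true, n_true, p_total, n_total) {
  (p_true + n_true) / (p_total + n_total)
}

# per-trial balanced accuracy contribution under one-vs-rest accounting
trial_accuracy <- function(hit, n_classes) {
  if (n_classes < 2) stop("accuracy needs at least 2 defect classes")
  ifelse(hit, 1, 0.5 * (n_classes - 2) / (n_classes - 1))
}

#' Multi-class diagnosis accuracy with one-vs-rest accounting
#'
#' Each trial contributes one positive case (the true defect) and
#' `n_classes - 1` negative cases (the other elementary defects); a
#' predicted label marks one class positive. The aggregate true-positive
#' and true-negative rates are combined with equal weight, which equals the
#' raw ratio of [accuracy_from_counts()] when positive and negative case
#' totals balance, and yields exactly 1/2 for uniformly random predictions
#' regardless of the number of classes.
#'
#' @param predicted,truth vectors of class labels (or indices).
#' @param n_classes number of elementary defect classes (default: number of
#'   distinct labels observed).
#' @return scalar accuracy in `[0, 1]`, with attributes `se` (standard error
#'   over trials) and `counts` (the aggregate confusion counts).
#' @export
diagnosis_accuracy <- function(predicted, truth, n_classes = NULL) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  if (is.null(n_classes)) n_classes <- length(unique(c(predicted, truth)))
  hit <- predicted == truth
  n <- length(hit)
  contrib <- trial_accuracy(hit, n_classes)
  ac <- mean(contrib)
  counts <- c(p_true = sum(hit), p_total = n,
              n_true = sum(n_classes - 2L + hit),
              n_total = n * (n_classes - 1L))
  structure(ac, se = stats::sd(contrib) / sqrt(n), counts = counts)
}

# internal: one batch of held-out diagnosis trials at a single time step
d1s1_trials <- function(model, archive, n_obs, t) {
  truth <- character(0); pred <- character(0)
  for (lb in model$labels) {
    for (tr in archive$runs[[lb]]) {
      idx <- sample.int(model$n_species, n_obs)
      s <- tr$signs[t + 1L, idx]
      post <- posterior_single_defect(model, idx, s, t)
      truth <- c(truth, lb)
      pred <- c(pred, model$labels[which.max(post)])
    }
  }
  list(truth = truth, predicted = pred)
}

#' Diagnosis accuracy as a function of disease time
#'
#' For each requested time step, runs one diagnosis trial per realization of
#' the (held-out) defect cohorts: `n_obs` sign indices are drawn uniformly
#' without replacement, the realization's observed signs at step `t` are fed
#' to the posterior over elementary defects, and the maximum-a-posteriori
#' defect is compared with the cohort's true defect. Accuracy uses the
#' balanced one-vs-rest accounting of [diagnosis_accuracy()].
#'
#' @param model a `d1s1_model` (fit on training cohorts).
#' @param archive a `cohort_archive` of held-out realizations.
#' @param n_obs number of observed signs `N_O` (between 1 and `N`).
#' @param times step indices to evaluate (default all).
#' @return data.frame `(t, n_obs, ac, se, n_trials)`.
#' @export
accuracy_curve <- function(model, archive, n_obs, times = NULL) {
  stopifnot(n_obs >= 1, n_obs <= model$n_species)
  if (is.null(times)) times <- 0:model$t_max
  out <- lapply(times, function(t) {
    tri <- d1s1_trials(model, archive, n_obs, t)
    ac <- diagnosis_accuracy(tri$predicted, tri$truth,
                             n_classes = length(model$labels))
    data.frame(t = t, n_obs = n_obs, ac = as.numeric(ac),
               se = attr(ac, "se"), n_trials = length(tri$truth))
  })
  do.call(rbind, out)
}

#' Intervention trade-off objective
#'
#' `L(t : N_O) = lambda E(t)/E(0) + (1 - lambda) sqrt(AC(t:N_O) - 1/2)`,
#' balancing remaining network function against diagnostic confidence; the
#' square root is clamped at 0 when sampling noise puts `AC` below chance.
#'
#' @param e_t objective at time `t`.
#' @param e_0 healthy objective (positive).
#' @param ac diagnosis accuracy at time `t`.
#' @param lambda trade-off weight in `[0, 1]`.
#' @return scalar (vectorized over `e_t`/`ac`).
#' @export
intervention_objective <- function(e_t, e_0, ac, lambda) {
  stopifnot(e_0 > 0, lambda >= 0, lambda <= 1)
  lambda * e_t / e_0 + (1 - lambda) * sqrt(pmax(0, ac - 0.5))
}

#' Build an intervention curve
#'
#' @param times step indices.
#' @param e_t objective values `E(t)` aligned with `times`.
#' @param e_0 healthy objective `E(0)`.
#' @param ac accuracy values aligned with `times`.
#' @param lambda trade-off weight.
#' @return an `intervention_curve` data.frame `(t, e_ratio, ac, L)`.
#' @export
intervention_curve <- function(times, e_t, e_0, ac, lambda) {
  structure(data.frame(t = times, e_ratio = e_t / e_0, ac = ac,
                       L = intervention_objective(e_t, e_0, ac, lambda)),
            class = c("intervention_curve", "data.frame"), lambda = lambda)
}

#' Optimal intervention time
#'
#' The earliest step maximizing `L` (ties broken toward the earliest time).
#'
#' @param curve an `intervention_curve` (or data.frame with `t` and `L`).
#' @return the optimal step `t*`.
#' @export
optimal_time <- function(curve) {
  stopifnot(nrow(curve) > 0)
  curve$t[which.max(curve$L)]
}

#' @export
print.d1s1_model <- function(x, ...) {
  cat("<d1s1_model> ", length(x$labels), " elementary defects, ",
      x$n_species, " signs, t = 0..", x$t_max,
      ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}
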