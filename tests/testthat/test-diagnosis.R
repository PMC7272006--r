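make_defs <- function(m, nodes) {
  out <- c(list(healthy = defect_pattern(m)),
           stats::setNames(lapply(nodes, function(q) defect_pattern(m, q)),
                           paste0("d", nodes)))
  out
}

test_that("D1S1 conditionals are smoothed sign frequencies per cohort", {
  t_max <- 2; ns <- 3
  all_pos <- matrix(1L, t_max + 1, ns)
  all_neg <- -all_pos
  defs <- make_defs(2, 1:2)
  arch <- fake_archive(
    list(healthy = list(all_pos, all_pos),
         d1 = list(all_pos, all_pos, all_pos),
         d2 = list(all_neg, all_pos)),
    defs, t_max, ns)
  m <- fit_d1s1(arch, pseudocount = 1)
  expect_equal(dim(m$p), c(3, 3, 2))
  # three positive realizations with c = 1: (3 + 1) / (3 + 2)
  expect_equal(unname(m$p[1, 1, "d1"]), 4 / 5)
  # balanced signs with no smoothing give exactly 1/2
  m0 <- fit_d1s1(arch, pseudocount = 0)
  expect_equal(unname(m0$p[1, 1, "d2"]), 0.5)
  expect_equal(unname(m0$p[1, 1, "d1"]), 1)  # unsmoothed extreme
  expect_equal(unname(m$prior), c(0.5, 0.5))
  expect_equal(unname(m$nodes), 1:2)

  expect_error(fit_d1s1(fake_archive(list(d1 = list(all_pos)),
                                     defs["d1"], t_max, ns)), "healthy")
  bad <- make_defs(2, 1); bad$dd <- defect_pattern(2, 1:2)
  arch_bad <- fake_archive(list(healthy = list(all_pos), d1 = list(all_pos),
                                dd = list(all_pos)), bad, t_max, ns)
  expect_error(fit_d1s1(arch_bad), "elementary")
})

test_that("single-defect posterior follows Bayes rule on the observed signs", {
  model <- structure(list(
    p = array(c(0.9, 0.1), dim = c(1, 1, 2),
              dimnames = list(NULL, NULL, c("d1", "d2"))),
    p_healthy = matrix(0.5, 1, 1),
    prior = c(d1 = 0.5, d2 = 0.5), labels = c("d1", "d2"),
    nodes = c(d1 = 1L, d2 = 2L), pseudocount = 1, t_max = 0,
    n_species = 1), class = "d1s1_model")
  post <- posterior_single_defect(model, idx = 1, signs = 1, t = 0)
  expect_equal(unname(post), c(0.9, 0.1))
  expect_equal(sum(post), 1)
  # the opposite sign flips the posterior
  post_neg <- posterior_single_defect(model, idx = 1, signs = -1, t = 0)
  expect_equal(unname(post_neg), c(0.1, 0.9))
  # empty observations return the prior
  expect_equal(posterior_single_defect(model, integer(0), integer(0), 0),
               model$prior)
  # identical conditionals across defects are uninformative
  model$p[1, 1, ] <- 0.7
  expect_equal(unname(posterior_single_defect(model, 1, 1, 0)), c(0.5, 0.5))
})

test_that("accuracy accounting matches its confusion-count definitions", {
  expect_equal(accuracy_from_counts(3, 5, 4, 6), 0.8)
  expect_equal(as.numeric(diagnosis_accuracy(c("a", "b"), c("a", "b"))), 1)
  # a wrong 2-class prediction has no true positives or negatives
  expect_equal(as.numeric(diagnosis_accuracy("a", "b", n_classes = 2)), 0)
  # chance level is 1/2 for any number of classes
  set.seed(15)
  for (m in c(2, 6)) {
    truth <- sample(m, 2e4, replace = TRUE)
    pred <- sample(m, 2e4, replace = TRUE)
    ac <- diagnosis_accuracy(pred, truth, n_classes = m)
    expect_lt(abs(as.numeric(ac) - 0.5), 3 * attr(ac, "se"))
  }
  counts <- attr(diagnosis_accuracy(c(1, 2), c(1, 3), n_classes = 3), "counts")
  expect_equal(unname(counts["p_true"]), 1)
  expect_equal(unname(counts["p_total"]), 2)
})

test_that("accuracy curves separate separable cohorts and not identical ones", {
  t_max <- 1; ns <- 4
  defs <- make_defs(2, 1:2)
  sig1 <- matrix(c(1L, 1L, -1L, -1L), t_max + 1, ns, byrow = TRUE)
  sig2 <- matrix(c(-1L, -1L, 1L, 1L), t_max + 1, ns, byrow = TRUE)
  train <- fake_archive(list(healthy = replicate(3, sig1, simplify = FALSE),
                             d1 = replicate(3, sig1, simplify = FALSE),
                             d2 = replicate(3, sig2, simplify = FALSE)),
                        defs, t_max, ns)
  model <- fit_d1s1(train, pseudocount = 0.5)
  test_arch <- fake_archive(list(d1 = replicate(5, sig1, simplify = FALSE),
                                 d2 = replicate(5, sig2, simplify = FALSE)),
                            defs[c("d1", "d2")], t_max, ns)
  set.seed(16)
  ac <- accuracy_curve(model, test_arch, n_obs = 4, times = 0:1)
  expect_equal(ac$ac, c(1, 1))
  expect_equal(ac$n_trials, c(10, 10))
  # indistinguishable cohorts sit at chance
  train_same <- fake_archive(list(healthy = replicate(3, sig1, simplify = FALSE),
                                  d1 = replicate(6, sig1, simplify = FALSE),
                                  d2 = replicate(6, sig1, simplify = FALSE)),
                             defs, t_max, ns)
  m2 <- fit_d1s1(train_same)
  test2 <- fake_archive(list(d1 = replicate(20, sig1, simplify = FALSE),
                             d2 = replicate(20, sig1, simplify = FALSE)),
                        defs[c("d1", "d2")], t_max, ns)
  set.seed(17)
  ac2 <- accuracy_curve(m2, test2, n_obs = 2, times = 0)
  expect_lt(abs(ac2$ac - 0.5), 0.35)
  expect_error(accuracy_curve(model, test_arch, n_obs = 9), "n_obs")
})

test_that("intervention objective trades function against confidence", {
  expect_equal(intervention_objective(0.8, 1, 0.99, lambda = 1), 0.8)
  expect_equal(intervention_objective(0.8, 1, 0.5, lambda = 0), 0)
  expect_equal(intervention_objective(0.8, 1, 0.75, lambda = 0.5),
               0.5 * 0.8 + 0.5 * 0.5)
  # sampling noise below chance is clamped, not complex
  expect_equal(intervention_objective(1, 1, 0.45, lambda = 0), 0)

  cv <- intervention_curve(0:10, e_t = seq(1, 0, length.out = 11), e_0 = 1,
                           ac = c(rep(0.5, 4), rep(0.9, 7)), lambda = 0)
  expect_equal(optimal_time(cv), 4)                 # argmax of the AC step
  cv1 <- intervention_curve(0:10, seq(1, 0, length.out = 11), 1,
                            rep(0.5, 11), lambda = 1)
  expect_equal(optimal_time(cv1), 0)                # strictly decreasing E
  cv_flat <- intervention_curve(0:5, rep(1, 6), 1, rep(0.5, 6), 0.3)
  expect_equal(optimal_time(cv_flat), 0)            # ties break earliest
})
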