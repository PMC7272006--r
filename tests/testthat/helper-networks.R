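# Small fixture networks built in code.

# birth-death: 0 -> A at rate k1, A -> 0 at mass-action rate k2 * X_A
bd_network <- function(k1 = 40, k2 = 0.1, x_max = 1000) {
  build_network(
    species = "A",
    reactions = list(
      list(from = integer(0), to = c(A = 1L), kappa = k1),
      list(from = c(A = 1L), to = integer(0), kappa = k2)),
    x_max = x_max, rate_bounds = c(0, max(2, k1 * 2)))
}

# single irreversible conversion A -> B
ab_network <- function(kappa = 0.5, x_max = 1000) {
  build_network(
    species = c("A", "B"),
    reactions = list(list(from = c(A = 1L), to = c(B = 1L), kappa = kappa)),
    x_max = x_max)
}

# two-species reversible toggle used for propensity-ratio checks
toggle_network <- function(kf = 1, kb = 3, x_max = 1000) {
  build_network(
    species = c("A", "B"),
    reactions = list(list(from = c(A = 1L), to = c(B = 1L),
                          kappa = kf, kappa_rev = kb, reversible = TRUE)),
    x_max = x_max, rate_bounds = c(0, max(2, kf, kb) + 1))
}

# sample n pairs from a 2x2 joint over values {0, 1}
sample_joint2 <- function(joint, n) {
  stopifnot(all(dim(joint) == c(2, 2)))
  cells <- sample.int(4, n, replace = TRUE, prob = as.vector(joint))
  list(x = (cells - 1) %% 2, y = (cells - 1) %/% 2)
}

# minimal hand-built cohort archive with prescribed per-step sign matrices
fake_archive <- function(signs_by_label, defects, t_max, n_species, n_pop = 100) {
  runs <- lapply(signs_by_label, function(trajs) {
    lapply(trajs, function(sg) {
      list(signs = sg, sign_freq = (sg > 0) + 0,
           n_pop = n_pop,
           steps = data.frame(t = 0:t_max, E = 1, d = 0))
    })
  })
  structure(list(runs = runs, labels = names(signs_by_label), defects = defects,
                 t_max = t_max, n_species = n_species, n_pop = n_pop),
            class = "cohort_archive")
}
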