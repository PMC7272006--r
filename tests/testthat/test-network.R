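test_that("mass-action propensity matches closed-form combination counts", {
  # zero-order source: empty reactant product is 1
  src <- build_network("A", reactions = list(
    list(from = integer(0), to = c(A = 1L), kappa = 0.7)))
  expect_equal(propensity(src, 0L, 1), 0.7)

  # first order: kappa * C(X, 1)
  ab <- ab_network(kappa = 0.5)
  expect_equal(propensity(ab, c(10L, 0L), 1), 5.0)

  # second order in one species: kappa * C(3, 2) = 3
  dim2 <- build_network(c("A", "B"), reactions = list(
    list(from = c(A = 2L), to = c(B = 1L), kappa = 1)))
  expect_equal(propensity(dim2, c(3L, 0L), 1), 3.0)

  # bimolecular with a missing reactant fires at rate zero
  bi <- build_network(c("A", "B", "C"), reactions = list(
    list(from = c(A = 1L, B = 1L), to = c(C = 1L), kappa = 1)))
  expect_equal(propensity(bi, c(0L, 5L, 0L), 1), 0)
  # and scales as 1/omega^(|L|-1)
  bi2 <- build_network(c("A", "B", "C"), reactions = list(
    list(from = c(A = 1L, B = 1L), to = c(C = 1L), kappa = 1)), omega = 2)
  expect_equal(propensity(bi2, c(4L, 5L, 0L), 1), 4 * 5 / 2)

  expect_error(propensity(ab, c(-1L, 0L), 1), "non-negative")
})

test_that("firings that would exceed the copy-number cap are blocked", {
  ab <- ab_network(kappa = 1, x_max = 10)
  expect_equal(propensity(ab, c(5L, 10L), 1), 0)     # B at cap
  expect_gt(propensity(ab, c(5L, 9L), 1), 0)
  # a driven product does not block
  drv <- build_network(c("A", "B"), driven = "B", reactions = list(
    list(from = c(A = 1L), to = c(B = 1L), kappa = 1)), x_max = 10)
  expect_gt(propensity(drv, c(5L, 10L), 1), 0)
})

test_that("propensity is monotone non-decreasing in reactant count", {
  dim2 <- build_network(c("A", "B"), reactions = list(
    list(from = c(A = 2L), to = c(B = 1L), kappa = 0.3)))
  vals <- vapply(2:50, function(x) propensity(dim2, c(x, 0L), 1), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("apply_reaction does stoichiometric bookkeeping", {
  ab <- ab_network()
  expect_equal(apply_reaction(ab, c(5L, 2L), 1), c(4L, 3L))

  # catalytic species unchanged
  cat_net <- build_network(c("A", "E", "B"), reactions = list(
    list(from = c(A = 1L, E = 1L), to = c(B = 1L, E = 1L), kappa = 1)))
  expect_equal(apply_reaction(cat_net, c(5L, 3L, 0L), 1), c(4L, 3L, 1L))

  # driven reactant is not decremented but still gates the reaction
  drv <- build_network(c("S", "B"), driven = "S", reactions = list(
    list(from = c(S = 1L), to = c(B = 1L), kappa = 1)))
  expect_equal(apply_reaction(drv, c(7L, 0L), 1), c(7L, 1L))

  # conservation of uninvolved species
  three <- build_network(c("A", "B", "C"), reactions = list(
    list(from = c(A = 1L), to = c(B = 1L), kappa = 1)))
  expect_equal(apply_reaction(three, c(2L, 0L, 9L), 1)[3], 9L)

  expect_error(apply_reaction(ab, c(0L, 5L), 1), "not fireable")
})

test_that("total propensity sums directed reactions and is zero only when stuck", {
  tg <- toggle_network(kf = 1, kb = 3)
  expect_equal(total_propensity(tg, c(1L, 1L)), 1 + 3)
  expect_equal(total_propensity(tg, c(0L, 0L)), 0)
  ab <- ab_network(kappa = 0.5)
  expect_equal(total_propensity(ab, c(10L, 0L)), propensity(ab, c(10L, 0L), 1))
})

test_that("catalog networks are valid and match their descriptions", {
  for (id in letters[1:10]) {
    net <- catalog_network(id)
    expect_silent(validate_network(net))
    expect_gt(length(net$signals), 0)
  }
  a <- catalog_network("a")
  expect_equal(a$species$name[a$signals], "X0")
  expect_equal(a$species$name[a$responses[["1"]]], "X2")
  expect_true(a$species$driven[a$signals])

  j <- catalog_network("j")
  expect_equal(n_species(j), 13)
  expect_equal(n_reaction_nodes(j), 6)
  expect_equal(n_reactions_directed(j), 12)
  expect_equal(j$species$name[j$signals], c("X0", "X3", "X6"))
  expect_equal(unname(vapply(j$responses, function(v) j$species$name[v], "")),
               c("X2", "X5", "X8"))

  j_irr <- catalog_network("j", reversible = FALSE)
  expect_equal(n_reactions_directed(j_irr), 6)
  expect_equal(n_reaction_nodes(j_irr), 6)

  expect_error(catalog_network("z"))
})

test_that("reversible pairs have mutually consistent partner links", {
  j <- catalog_network("j")
  for (r in seq_len(n_reactions_directed(j))) {
    p <- j$partner[r]
    expect_false(is.na(p))
    expect_equal(j$partner[p], r)
    expect_equal(j$node[p], j$node[r])
    # reverse stoichiometry mirrors forward
    expect_equal(j$nu_minus[p, ], j$nu_plus[r, ])
  }
})

test_that("network validation names the offending field", {
  a <- catalog_network("a")
  bad <- a; bad$kappa[1] <- -1
  expect_error(validate_network(bad), "kappa")
  bad <- a; bad$nu_minus[1, 1] <- -2L
  expect_error(validate_network(bad), "nu_minus")
  bad <- a; bad$responses[["1"]] <- integer(0)
  expect_error(validate_network(bad), "responses")
  bad <- a; bad$partner[1] <- 1L
  expect_error(validate_network(bad), "partner")
})
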