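chain_eco <- function(bound = 10) {
  p <- generate_pair(toy_spec("neutralism", substrate_bound = c(bound, 7)))
  eco <- build_ecosystem(list(p$models[[1]]))
  apply_diet(eco, diet_spec(lumen_bounds = list(glc1_e = c(-bound, 0))))
}

test_that("FBA solves the chain model and honors equality pins", {
  eco <- chain_eco(10)
  expect_equal(unname(solve_fba(eco)$objective_values), 10, tolerance = 1e-9)
  # pin biomass at an interior value
  sol <- solve_fba(eco, fixed = c(`A:BIOMASS` = 4))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$objective_values), 4, tolerance = 1e-9)
  # pins outside the declared bounds are refused outright
  expect_error(solve_fba(eco, fixed = c(`A:BIOMASS` = 4000)),
               "outside reaction bounds")
  # pins inside bounds but stoichiometrically unreachable: infeasible status
  expect_equal(solve_fba(eco, fixed = c(`A:BIOMASS` = 40))$status,
               "infeasible")
})

test_that("FBA matches the enumeration oracle on a two-pathway model", {
  # two routes of unequal yield from one substrate
  m <- metabolic_model(
    "two", data.frame(id = c("g_e", "x_c"),
                      compartment = c("e", "c")),
    data.frame(id = c("EX_g_e", "T1", "T2", "B"),
               lb = c(-1000, 0, 0, 0), ub = 1000,
               objective = c(0, 0, 0, 1)),
    list(EX_g_e = c(g_e = -1),
         T1 = c(g_e = -1, x_c = 1),        # yield 1
         T2 = c(g_e = -1, x_c = 0.5),      # yield 0.5
         B = c(x_c = -1)))
  eco <- apply_diet(build_ecosystem(list(m)),
                    diet_spec(lumen_bounds = list(g_e = c(-6, 0))))
  sol <- solve_fba(eco)
  expect_equal(unname(sol$objective_values), 6, tolerance = 1e-9)
  cc <- drop(1 %*% eco$objectives)
  oracle <- enum_lp_oracle(cc, as.matrix(eco$S), rep(0, nrow(eco$S)),
                           eco$rxns$lb, eco$rxns$ub)
  expect_equal(unname(sol$objective_values), oracle, tolerance = 1e-7)
})

test_that("FVA collapses pinned chains and frees redundant branches", {
  eco <- chain_eco(10)
  # blocked reaction -> (0, 0)
  eco0 <- eco
  i <- which(eco0$rxns$orig_id == "T_glc1")
  eco0$rxns$lb[i] <- eco0$rxns$ub[i] <- 0
  expect_equal(unlist(solve_fva(eco0, eco0$rxns$id[i])[, c("min", "max")]),
               c(min = 0, max = 0))
  # chain pinned at its max: every interval collapses
  fva <- solve_fva(eco, fixed = c(`A:BIOMASS` = 10))
  expect_lt(max(fva$max - fva$min), 1e-7)
  # redundant parallel branches at pinned demand: each spans [0, demand]
  m <- metabolic_model(
    "par", data.frame(id = c("g_e", "g_c"), compartment = c("e", "c")),
    data.frame(id = c("EX_g_e", "Ta", "Tb", "B"),
               lb = c(-1000, 0, 0, 0), ub = 1000, objective = c(0, 0, 0, 1)),
    list(EX_g_e = c(g_e = -1), Ta = c(g_e = -1, g_c = 1),
         Tb = c(g_e = -1, g_c = 1), B = c(g_c = -1)))
  epar <- apply_diet(build_ecosystem(list(m)),
                     diet_spec(lumen_bounds = list(g_e = c(-10, 0))))
  fvab <- solve_fva(epar, c("par:Ta", "par:Tb"), fixed = c(`par:B` = 4))
  expect_equal(fvab$min, c(0, 0), tolerance = 1e-9)
  expect_equal(fvab$max, c(4, 4), tolerance = 1e-9)
  # infeasible pins error out
  expect_error(solve_fva(epar, "par:Ta", fixed = c(`par:B` = 4),
                         extra_A = matrix(epar$objectives, 1),
                         extra_b = 5), "infeasible")
})

test_that("NISE enumerates the expected front vertices", {
  # shared substrate, equal yields: the two lexicographic endpoints
  x <- build_pair_eco("competition", substrate_bound = 10)
  fr <- compute_pareto_front(x$eco)
  expect_equal(fr$points, rbind(c(0, 10), c(10, 0)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # disjoint substrates: a single vertex at the joint optimum
  x2 <- build_pair_eco("neutralism", substrate_bound = c(5, 7))
  fr2 <- compute_pareto_front(x2$eco)
  expect_equal(fr2$points, matrix(c(5, 7), 1),
               ignore_attr = TRUE, tolerance = 1e-8)
  # one-way cross-feeding: B's best exceeds its alone-max of 10
  x3 <- build_pair_eco("crossfeed_oneway")
  fr3 <- compute_pareto_front(x3$eco)
  expect_equal(nrow(fr3$points), 2)
  expect_gt(max(fr3$points[, 2]), 10 + 1e-6)
  # some vertex has both members growing with B above its alone-max
  expect_true(any(fr3$points[, 1] > 0 & fr3$points[, 2] > 10 + 1e-6))
})

test_that("NISE front matches the epsilon-constraint sweep on random toys", {
  kinds <- c("competition", "crossfeed_oneway", "crossfeed_mutual",
             "neutralism")
  for (seed in 1:20) {
    x <- build_pair_eco(kinds[(seed %% 4) + 1], seed = seed,
                        randomize = TRUE)
    fr <- compute_pareto_front(x$eco)
    xs <- seq(min(fr$points[, 1]), max(fr$points[, 1]), length.out = 100)
    for (xv in xs) {
      expect_equal(front_polyline_value(fr$points, xv),
                   eps_constraint_value(x$eco, xv), tolerance = 1e-6)
    }
  }
})

test_that("every front vertex is supported by some nonnegative weight", {
  for (kind in c("competition", "crossfeed_oneway", "crossfeed_mutual")) {
    x <- build_pair_eco(kind)
    fr <- compute_pareto_front(x$eco)
    pts <- fr$points[order(fr$points[, 1]), , drop = FALSE]
    np <- nrow(pts)
    for (i in seq_len(np)) {
      # supporting weight from the adjacent chords (endpoints: axis weights)
      wl <- if (i == 1) c(0, 1) else
        c(pts[i - 1, 2] - pts[i, 2], pts[i, 1] - pts[i - 1, 1])
      wr <- if (i == np) c(1, 0) else
        c(pts[i, 2] - pts[i + 1, 2], pts[i + 1, 1] - pts[i, 1])
      w <- wl / max(sum(abs(wl)), 1e-12) + wr / max(sum(abs(wr)), 1e-12)
      sol <- solve_fba(x$eco, w)
      expect_equal(sum(w * pts[i, ]), sum(w * sol$objective_values),
                   tolerance = 1e-6)
    }
  }
})

test_that("scaling one objective scales that front coordinate exactly", {
  x <- build_pair_eco("crossfeed_oneway")
  fr <- compute_pareto_front(x$eco)
  models2 <- x$pair$models
  i <- which(models2[[2]]$reactions$objective != 0)
  models2[[2]]$reactions$objective[i] <- 3 *
    models2[[2]]$reactions$objective[i]
  eco2 <- suppressMessages(apply_diet(build_ecosystem(models2),
                                      x$pair$diet))
  fr2 <- compute_pareto_front(eco2)
  o <- order(fr$points[, 1]); o2 <- order(fr2$points[, 1])
  expect_equal(fr2$points[o2, 1], fr$points[o, 1], tolerance = 1e-8)
  expect_equal(fr2$points[o2, 2], 3 * fr$points[o, 2], tolerance = 1e-8)
})

test_that("k >= 3 fronts recover coupled and neutral vertices", {
  cm <- generate_community(toy_spec("crossfeed_mutual", n_members = 3))
  eco <- suppressMessages(apply_diet(build_ecosystem(cm$models), cm$diet))
  fr <- compute_pareto_front(eco)
  # fully coupled community: a single vertex, pair at 2x alone, bystander at
  # its own optimum
  expect_equal(fr$points, matrix(c(20, 20, 10), 1),
               ignore_attr = TRUE, tolerance = 1e-7)
})

test_that("front points are non-dominated and deduplicated", {
  for (kind in c("competition", "crossfeed_oneway")) {
    x <- build_pair_eco(kind, seed = 3, randomize = TRUE)
    fr <- compute_pareto_front(x$eco)
    pts <- fr$points
    for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
      if (i == j) next
      expect_false(all(pts[j, ] >= pts[i, ] - 1e-9) &&
                     any(pts[j, ] > pts[i, ] + 1e-6))
    }
  }
})
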