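test_that("normalization divides by alone-growth and appends unit vectors", {
  x <- score_pair("competition")
  expect_equal(unname(x$nf$alone_maxima), c(10, 10), tolerance = 1e-9)
  expect_equal(x$nf$points, rbind(c(0, 1), c(1, 0)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # units already on the front: not duplicated
  expect_equal(nrow(x$nf$augmented), 2)
  xn <- score_pair("neutralism", substrate_bound = c(5, 7))
  expect_equal(xn$nf$augmented[order(xn$nf$augmented[, 1],
                                     xn$nf$augmented[, 2]), ],
               rbind(c(0, 1), c(1, 0), c(1, 1)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # mutual cross-feeding doubles both coordinates
  xm <- score_pair("crossfeed_mutual")
  expect_equal(xm$nf$points, matrix(c(2, 2), 1),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("zero standalone growth makes the score undefined", {
  p <- generate_pair(toy_spec("neutralism"))
  eco <- apply_diet(build_ecosystem(p$models),
                    diet_spec(lumen_bounds = list(glc1_e = c(0, 0),
                                                  glc2_e = c(-7, 0))))
  fr <- compute_pareto_front(eco)
  expect_error(normalize_front(fr, eco), "zero standalone growth for A")
})

test_that("auc_2d reproduces the trapezoid oracle, incl. the last-point rule", {
  expect_equal(auc_2d(rbind(c(0, 1), c(1, 0))), 0.5)
  # monotone 3-point case: 0.8*1.25 + 0.2*0.5
  pts <- rbind(c(0, 1.5), c(0.8, 1.0), c(1, 0))
  expect_equal(auc_2d(pts), 1.1)
  expect_equal(auc_2d(pts), trapezoid_area(pts))
  # non-monotone last point: signed-trapezoid oracle gives 0.78 - 0.03
  nm <- rbind(c(0, 1), c(1.3, 0.2), c(1, 0))
  expect_equal(auc_2d(nm), 0.75)
  expect_equal(auc_2d(nm),
               trapezoid_area(nm[1:2, ]) - trapezoid_area(nm[2:3, ]))
  # fewer than 2 points, or an interior break, are errors
  expect_error(auc_2d(matrix(c(0, 1), 1)), "at least 2")
  expect_error(auc_2d(rbind(c(0, 1), c(2, 1), c(1, 1), c(3, 0))),
               "interior monotonicity")
})

test_that("hypervolume is exact on known bodies", {
  expect_equal(hypervolume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))), 1)
  expect_equal(hypervolume(rbind(rep(0, 3), diag(3))), 1 / 6)
  # interior and duplicate points change nothing
  expect_equal(hypervolume(rbind(rep(0, 3), diag(3), rep(1 / 6, 3),
                                 diag(3))), 1 / 6)
  # rank-deficient set: zero volume
  expect_equal(hypervolume(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                 c(1, 1, 0))), 0)
  expect_error(hypervolume(matrix(1:3, 3)), "k >= 2")
  # 4-D hypercube
  G <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  expect_equal(hypervolume(G), 1)
})

test_that("interaction scores hit the closed forms of the fixtures", {
  expect_equal(score_pair("neutralism")$report$score, 0, tolerance = 1e-9)
  x <- score_pair("competition")
  expect_equal(x$report$score, -0.5, tolerance = 1e-9)
  expect_equal(x$report$auc_p, 0.5, tolerance = 1e-9)
  expect_equal(x$report$auc_ni, 1)
  # one-way: S = alpha*sA/(2*sB) with defaults = 0.25... plus obligate part
  xo <- score_pair("crossfeed_oneway")
  expect_gt(xo$report$score, 0)
  xm <- score_pair("crossfeed_mutual")
  # front (2,2): AUC = 2*(1+2)/2 - (2-1)*(2+0)/2 = 3 - 1 = 2; S = 1
  expect_equal(xm$report$score, 1, tolerance = 1e-9)
})

test_that("interaction types follow the front-shape flags", {
  expect_equal(score_pair("neutralism")$report$interaction_type,
               "Neutralism")
  x <- score_pair("competition")
  expect_equal(x$report$interaction_type, "Competition")
  expect_equal(x$report$flags$sign, "-")
  expect_false(x$report$flags$E_plus || x$report$flags$B_plus)
  xo <- score_pair("crossfeed_oneway")
  expect_equal(xo$report$interaction_type, "FavorsBacteria")
  expect_true(xo$report$flags$B_plus)
  expect_false(xo$report$flags$E_plus)
  xm <- score_pair("crossfeed_mutual")
  expect_equal(xm$report$interaction_type, "Mutualism")
  expect_true(xm$report$flags$EB_plus)
  # host-favoring mirror of the one-way construction
  h <- generate_host_like()
  b <- generate_pair(toy_spec("crossfeed_oneway"))$models[[1]]
  b <- apply_namespace(b, namespace_map(c(byp_e = "cho_e", byp_c = "cho_c"),
                                        "metabolite"))
  d <- diet_spec(lumen_bounds = list(gh_e = c(-10, 1000),
                                     gA_e = c(-10, 1000),
                                     cho_e = c(0, 1000)))
  eco <- suppressMessages(apply_diet(build_ecosystem(list(h, b)), d))
  nf <- suppressMessages(normalize_front(compute_pareto_front(eco), eco))
  expect_equal(interaction_score(nf)$interaction_type, "FavorsHost")
  # typing is bi-objective only
  cm <- generate_community(toy_spec("crossfeed_mutual", n_members = 3))
  eco3 <- suppressMessages(apply_diet(build_ecosystem(cm$models), cm$diet))
  nf3 <- suppressMessages(normalize_front(compute_pareto_front(eco3), eco3))
  expect_error(classify_interaction(nf3), "two-member")
})

test_that("hypervolume-based score equals AUC-based score on monotone fronts", {
  for (kind in c("neutralism", "competition")) {
    x <- score_pair(kind)
    aug <- rbind(x$nf$augmented, c(0, 0))
    s_hull <- hypervolume(aug) -
      hypervolume(rbind(diag(2), c(1, 1), c(0, 0)))
    expect_equal(s_hull, x$report$score, tolerance = 1e-9)
  }
})

test_that("score is invariant to member order and objective rescaling", {
  for (kind in c("competition", "crossfeed_oneway", "crossfeed_mutual")) {
    p <- generate_pair(toy_spec(kind))
    s1 <- score_ecosystem(p$models, p$diet)$score
    s2 <- score_ecosystem(rev(p$models), p$diet)$score
    expect_lt(abs(s1 - s2), 1e-9)
    # rescale member 2's objective vector by 7
    m2 <- p$models
    i <- which(m2[[2]]$reactions$objective != 0)
    m2[[2]]$reactions$objective[i] <- 7 * m2[[2]]$reactions$objective[i]
    s3 <- score_ecosystem(m2, p$diet)$score
    expect_lt(abs(s1 - s3), 1e-9)
    expect_equal(score_ecosystem(m2, p$diet)$interaction_type,
                 score_ecosystem(p$models, p$diet)$interaction_type)
  }
  # 3-member permutation invariance
  cm <- generate_community(toy_spec("crossfeed_mutual", n_members = 3))
  eco <- suppressMessages(apply_diet(build_ecosystem(cm$models), cm$diet))
  nf <- suppressMessages(normalize_front(compute_pareto_front(eco), eco))
  s <- interaction_score(nf)$score
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    ecop <- suppressMessages(apply_diet(build_ecosystem(cm$models[perm]),
                                        cm$diet))
    nfp <- suppressMessages(normalize_front(compute_pareto_front(ecop),
                                            ecop))
    expect_lt(abs(interaction_score(nfp)$score - s), 1e-9)
  }
})

test_that("removal analysis separates cross-feeders from bystanders", {
  # three mutually neutral members: all removal scores are zero
  cmn <- generate_community(toy_spec("crossfeed_mutual", n_members = 3,
                                     byproduct_stoich = 0))
  # byproduct_stoich 0 removes the coupling: all members independent
  econ <- suppressMessages(apply_diet(build_ecosystem(cmn$models),
                                      cmn$diet))
  rsn <- suppressMessages(removal_analysis(econ))
  expect_true(all(abs(rsn) < 1e-8))
  # A and B cross-feed, N3 is independent
  cm <- generate_community(toy_spec("crossfeed_mutual", n_members = 3))
  eco <- suppressMessages(apply_diet(build_ecosystem(cm$models), cm$diet))
  rs <- suppressMessages(removal_analysis(eco))
  expect_lt(abs(rs[["A"]]), 1e-8)
  expect_lt(abs(rs[["B"]]), 1e-8)
  expect_gt(rs[["N3"]], 1e-6)
  expect_equal(attr(rs, "dimension"), 2)
})

test_that("score_ecosystem runs the full pipeline deterministically", {
  p <- generate_pair(toy_spec("competition"))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_model(p$models[[1]], dir1, "tabular")
  write_model(p$models[[2]], dir2, "tabular")
  dietf <- withr::local_tempfile(fileext = ".tsv")
  write_diet(p$diet, dietf)
  r1 <- score_ecosystem(c(dir1, dir2), dietf)
  r2 <- score_ecosystem(c(dir1, dir2), dietf)
  expect_equal(r1$score, -0.5, tolerance = 1e-8)
  expect_equal(r1$interaction_type, "Competition")
  expect_identical(r1$score, r2$score)
  expect_identical(r1$front$points, r2$front$points)
  expect_error(score_ecosystem(dir1), "at least 2")
})
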