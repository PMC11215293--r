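toy_chain_model <- function(id = "chain", bound = 10) {
  metabolic_model(
    id,
    metabolites = data.frame(id = c("glc_e", "glc_c"),
                             compartment = c("e", "c")),
    reactions = data.frame(id = c("EX_glc_e", "T_glc", "BIOMASS"),
                           lb = c(-bound, 0, 0), ub = 1000,
                           objective = c(0, 0, 1)),
    stoichiometry = list(EX_glc_e = c(glc_e = -1),
                         T_glc = c(glc_e = -1, glc_c = 1),
                         BIOMASS = c(glc_c = -1)))
}

test_that("constructor validates invariants", {
  m <- toy_chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$exchange_ids, "EX_glc_e")
  # crossed bounds
  expect_error(metabolic_model(
    "bad", data.frame(id = "a_c", compartment = "c"),
    data.frame(id = "R", lb = 1, ub = -1, objective = 1),
    list(R = c(a_c = -1))), "lower bound")
  # empty objective
  expect_error(metabolic_model(
    "bad", data.frame(id = "a_c", compartment = "c"),
    data.frame(id = "R", lb = 0, ub = 1, objective = 0),
    list(R = c(a_c = -1))), "empty objective")
  # undeclared metabolite in stoichiometry
  expect_error(metabolic_model(
    "bad", data.frame(id = "a_c", compartment = "c"),
    data.frame(id = "R", lb = 0, ub = 1, objective = 1),
    list(R = c(zz = -1))), "undeclared")
})

test_that("unspecified bounds default to the +/-1000 flux cap", {
  m <- metabolic_model(
    "d", data.frame(id = "a_e", compartment = "e"),
    data.frame(id = c("EX_a_e", "B"), objective = c(0, 1)),
    list(EX_a_e = c(a_e = -1), B = c(a_e = 1)))
  expect_equal(m$reactions$lb, c(-1000, -1000))
  expect_equal(m$reactions$ub, c(1000, 1000))
})

test_that("tabular and SBML round trips preserve the model exactly", {
  p <- generate_pair(toy_spec("crossfeed_mutual"))
  for (m in p$models) {
    d <- withr::local_tempdir()
    write_model(m, d, "tabular")
    m2 <- read_model(d, model_id = m$model_id)
    expect_identical(as.matrix(m2$S)[rownames(m$S), colnames(m$S)],
                     as.matrix(m$S))
    expect_equal(m2$reactions[match(m$reactions$id, m2$reactions$id), ],
                 m$reactions, ignore_attr = TRUE)
    f <- withr::local_tempfile(fileext = ".xml")
    write_model(m, f, "sbml")
    m3 <- read_model(f)
    expect_identical(as.matrix(m3$S)[rownames(m$S), colnames(m$S)],
                     as.matrix(m$S))
    expect_equal(m3$reactions[match(m$reactions$id, m3$reactions$id), ],
                 m$reactions, ignore_attr = TRUE)
    expect_setequal(m3$exchange_ids, m$exchange_ids)
  }
})

test_that("SBML reader rejects malformed input and missing objectives", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml>", f)
  expect_error(read_model(f), "format error")
  writeLines(c("<sbml><model id='m'><listOfReactions>",
               "<reaction id='R'/></listOfReactions></model></sbml>"), f)
  expect_error(read_model(f), "objective")
})

test_that("exchange detection policies agree on fixtures and skip blood", {
  m <- toy_chain_model()
  expect_equal(detect_exchanges(m, "boundary"), detect_exchanges(m, "prefix"))
  h <- generate_host_like()
  lumen <- c("EX_gh_e", "EX_cho_e", "EX_vit_e")
  expect_setequal(detect_exchanges(h, "boundary"), lumen)
  expect_setequal(detect_exchanges(h, "prefix"), lumen)
  # blood sinks are single-metabolite but never exchanges
  expect_false(any(c("SINK_w_b", "SINK_vit_b") %in%
                     detect_exchanges(h, "boundary")))
  # a model with no single-metabolite external reaction -> empty set
  m2 <- metabolic_model(
    "int", data.frame(id = c("a_c", "b_c"), compartment = "c"),
    data.frame(id = c("R1", "R2"), lb = 0, ub = 10, objective = c(0, 1)),
    list(R1 = c(a_c = -1, b_c = 1), R2 = c(b_c = -1, a_c = 1)),
    exchange_ids = character())
  expect_length(detect_exchanges(m2, "boundary"), 0)
})

test_that("namespace mapping renames, is identity-safe, refuses collisions", {
  h <- generate_host_like()
  m2 <- apply_namespace(h, namespace_map(c(cho_e = "choline_e"),
                                         "metabolite"))
  expect_true("choline_e" %in% m2$metabolites$id)
  expect_false("cho_e" %in% m2$metabolites$id)
  expect_identical(unname(as.matrix(m2$S)), unname(as.matrix(h$S)))
  # empty map is the identity
  m3 <- apply_namespace(h, namespace_map(character(), "metabolite"))
  expect_equal(m3, h)
  # two sources to one target: refused
  expect_error(namespace_map(c(a = "x", b = "x")), "conflict")
  # renaming onto an existing untouched id: refused
  expect_error(apply_namespace(h, namespace_map(c(cho_e = "gh_e"),
                                                "metabolite")), "conflict")
  # reaction-scope renaming keeps exchange bookkeeping
  m4 <- apply_namespace(h, namespace_map(c(EX_cho_e = "EX_choline_e"),
                                         "reaction"))
  expect_true("EX_choline_e" %in% m4$exchange_ids)
})

test_that("namespace map round-trips through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\ttarget_id", "glc__D[e]\tglc__D_e"), f)
  nm <- read_namespace_map(f)
  expect_equal(unname(nm$entries["glc__D[e]"]), "glc__D_e")
})

test_that("diet specs round-trip through TSV and validate bounds", {
  d <- diet_spec("wd", lumen_bounds = list(glc_e = c(-10, 0),
                                           fru_e = c(-2.5, 1000)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_diet(d, f)
  d2 <- read_diet(f)
  expect_equal(d2$lumen_bounds, d$lumen_bounds)
  expect_equal(d2$name, "wd")
  expect_equal(d2$default_policy, "unconstrained")
  expect_error(diet_spec(lumen_bounds = list(x = c(1, -1))), "bad bounds")
})
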