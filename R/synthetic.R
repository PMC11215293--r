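#' Specification of a synthetic toy ecosystem
#'
#' Describes a small generated ecosystem with known ground-truth interaction
#' structure. The default parameters are the package's reference study
#' conditions; with `randomize = TRUE` the yields, substrate bounds and
#' byproduct stoichiometries are drawn (integer-friendly values, so oracle
#' arithmetic stays exact) from the RNG stream fixed by `seed`.
#'
#' @param kind one of `"competition"` (both members consume one pooled
#'   substrate), `"neutralism"` (disjoint substrates), `"crossfeed_oneway"`
#'   (member A secretes a byproduct, obligately with biomass and facultatively
#'   at the cost of its own growth, which boosts member B), and
#'   `"crossfeed_mutual"` (reciprocal obligate byproduct exchange with each
#'   member's alone-growth substrate-limited).
#' @param n_members number of members (2 for pairs; 3-11 for
#'   [generate_community()]).
#' @param yields positive biomass yields per substrate unit (recycled to
#'   `n_members`). Default 1.
#' @param substrate_bound positive supply bound(s) of the private/shared
#'   substrates, mmol/gDW/h. Default 10, except 5 and 7 for neutral pairs.
#' @param byproduct_stoich byproduct produced per unit of converted
#'   substrate (facultative route) or per unit biomass (obligate coupling in
#'   the mutual design). Default 0.5.
#' @param obligate_stoich byproduct obligately co-produced per unit biomass
#'   in the one-way design. Default 0.1.
#' @param seed integer fixing all randomized choices. Default 1.
#' @param randomize draw parameters from `seed` instead of the defaults.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(kind = c("competition", "neutralism",
                              "crossfeed_oneway", "crossfeed_mutual"),
                     n_members = 2L, yields = NULL, substrate_bound = NULL,
                     byproduct_stoich = NULL, obligate_stoich = NULL,
                     seed = 1L, randomize = FALSE) {
  kind <- match.arg(kind)
  if (randomize) {
    drawn <- with_seed(seed, list(
      yields = sample(c(0.5, 1, 2), n_members, replace = TRUE),
      substrate_bound = sample(4:12, n_members, replace = TRUE),
      byproduct_stoich = sample(c(0.25, 0.5, 0.75), 1),
      obligate_stoich = sample(c(0.05, 0.1, 0.2), 1)))
    if (is.null(yields)) yields <- drawn$yields
    if (is.null(substrate_bound)) substrate_bound <- drawn$substrate_bound
    if (is.null(byproduct_stoich)) byproduct_stoich <- drawn$byproduct_stoich
    if (is.null(obligate_stoich)) obligate_stoich <- drawn$obligate_stoich
  }
  if (is.null(yields)) yields <- rep(1, n_members)
  if (is.null(substrate_bound))
    substrate_bound <- if (kind == "neutralism" && n_members == 2L) c(5, 7)
                       else rep(10, n_members)
  if (is.null(byproduct_stoich)) byproduct_stoich <- 0.5
  if (is.null(obligate_stoich)) obligate_stoich <- 0.1
  yields <- rep_len(yields, n_members)
  substrate_bound <- rep_len(substrate_bound, n_members)
  stopifnot(all(yields > 0), all(substrate_bound > 0),
            byproduct_stoich >= 0, obligate_stoich >= 0)
  structure(list(kind = kind, n_members = as.integer(n_members),
                 yields = yields, substrate_bound = substrate_bound,
                 byproduct_stoich = byproduct_stoich,
                 obligate_stoich = obligate_stoich, seed = as.integer(seed),
                 randomize = randomize),
            class = "toy_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# a minimal consumer: EX -> transport -> biomass, on substrate `sub`
toy_consumer <- function(id, sub, yield, extra_mets = NULL,
                         extra_rxns = NULL, extra_stoich = NULL,
                         biomass_stoich = NULL) {
  mets <- rbind(data.frame(id = c(paste0(sub, "_e"), "c_c"),
                           compartment = c("e", "c"),
                           stringsAsFactors = FALSE),
                extra_mets)
  bio <- c(c_c = -1 / yield)
  if (!is.null(biomass_stoich)) bio <- c(bio, biomass_stoich)
  rxns <- rbind(data.frame(
    id = c(paste0("EX_", sub, "_e"), paste0("T_", sub), "BIOMASS"),
    lb = c(-1000, 0, 0), ub = 1000, objective = c(0, 0, 1),
    stringsAsFactors = FALSE), extra_rxns)
  stoich <- c(stats::setNames(list(
    stats::setNames(-1, paste0(sub, "_e")),
    stats::setNames(c(-1, 1), c(paste0(sub, "_e"), "c_c")),
    bio),
    c(paste0("EX_", sub, "_e"), paste0("T_", sub), "BIOMASS")),
    extra_stoich)
  metabolic_model(id, mets, rxns, stoich)
}

#' Generate a two-member toy ecosystem with known interaction structure
#'
#' Builds two small (<= 8 reactions) metabolic models plus the diet that
#' realizes the interaction named by the spec's `kind`, along with the
#' expected ground truth. Competition shares one pooled substrate (expected
#' S < 0), neutralism uses disjoint substrates (S = 0), one-way cross-feeding
#' lets A's byproduct boost B (S > 0, FavorsBacteria), and mutual
#' cross-feeding couples reciprocal byproducts so both members exceed their
#' alone-growth together (S > 0, Mutualism).
#'
#' @param spec a [toy_spec()] with `n_members = 2`.
#' @return list with `models` (list of 2 `metabolic_model`s), `diet`
#'   (a [diet_spec()]), and `truth` (list with `sign` in -1/0/1 and `type`).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  if (spec$n_members != 2L)
    stop("generate_pair needs n_members = 2")
  y <- spec$yields; s <- spec$substrate_bound
  a <- spec$byproduct_stoich; b <- spec$obligate_stoich
  cap <- 1000
  byp <- function(met) { # secretion machinery shared by the cross-feed kinds
    list(
      mets = data.frame(id = c(paste0(met, "_c"), paste0(met, "_e")),
                        compartment = c("c", "e"), stringsAsFactors = FALSE),
      rxns = data.frame(id = c(paste0("T_", met), paste0("EX_", met, "_e")),
                        lb = c(0, -1000), ub = 1000, objective = 0,
                        stringsAsFactors = FALSE),
      stoich = stats::setNames(list(
        stats::setNames(c(-1, 1), paste0(met, c("_c", "_e"))),
        stats::setNames(-1, paste0(met, "_e"))),
        c(paste0("T_", met), paste0("EX_", met, "_e"))))
  }
  uptake <- function(met) { # consumption of a pooled byproduct as substrate
    list(
      mets = data.frame(id = paste0(met, "_e"), compartment = "e",
                        stringsAsFactors = FALSE),
      rxns = data.frame(id = c(paste0("EX_", met, "_e"), paste0("U_", met)),
                        lb = c(-1000, 0), ub = 1000, objective = 0,
                        stringsAsFactors = FALSE),
      stoich = stats::setNames(list(
        stats::setNames(-1, paste0(met, "_e")),
        stats::setNames(c(-1, 1), c(paste0(met, "_e"), "c_c"))),
        c(paste0("EX_", met, "_e"), paste0("U_", met))))
  }
  unconstrained_supply <- function(ids, bounds) {
    diet_spec(name = paste0("toy_", spec$kind),
              lumen_bounds = stats::setNames(bounds, ids))
  }
  out <- switch(spec$kind,
    competition = {
      A <- toy_consumer("A", "glc", y[1])
      B <- toy_consumer("B", "glc", y[2])
      diet <- unconstrained_supply("glc_e", list(c(-s[1], cap)))
      list(models = list(A, B), diet = diet,
           truth = list(sign = -1, type = "Competition"))
    },
    neutralism = {
      A <- toy_consumer("A", "glc1", y[1])
      B <- toy_consumer("B", "glc2", y[2])
      diet <- unconstrained_supply(c("glc1_e", "glc2_e"),
                                   list(c(-s[1], cap), c(-s[2], cap)))
      list(models = list(A, B), diet = diet,
           truth = list(sign = 0, type = "Neutralism"))
    },
    crossfeed_oneway = {
      sec <- byp("byp")
      A <- toy_consumer("A", "gA", y[1],
        extra_mets = sec$mets,
        extra_rxns = rbind(sec$rxns,
          data.frame(id = "CONV", lb = 0, ub = 1000, objective = 0,
                     stringsAsFactors = FALSE)),
        extra_stoich = c(sec$stoich,
          list(CONV = c(c_c = -1, byp_c = a))),
        biomass_stoich = c(byp_c = b))
      upt <- uptake("byp")
      B <- toy_consumer("B", "gB", y[2], extra_mets = upt$mets,
                        extra_rxns = upt$rxns, extra_stoich = upt$stoich)
      diet <- unconstrained_supply(c("gA_e", "gB_e", "byp_e"),
        list(c(-s[1], cap), c(-s[2], cap), c(0, cap)))
      list(models = list(A, B), diet = diet,
           truth = list(sign = 1, type = "FavorsBacteria"))
    },
    crossfeed_mutual = {
      secA <- byp("pA"); uptB <- uptake("pB")
      A <- toy_consumer("A", "gA", y[1],
        extra_mets = rbind(secA$mets, uptB$mets),
        extra_rxns = rbind(secA$rxns, uptB$rxns),
        extra_stoich = c(secA$stoich, uptB$stoich),
        biomass_stoich = c(pA_c = a))
      secB <- byp("pB"); uptA <- uptake("pA")
      B <- toy_consumer("B", "gB", y[2],
        extra_mets = rbind(secB$mets, uptA$mets),
        extra_rxns = rbind(secB$rxns, uptA$rxns),
        extra_stoich = c(secB$stoich, uptA$stoich),
        biomass_stoich = c(pB_c = a))
      diet <- unconstrained_supply(c("gA_e", "gB_e", "pA_e", "pB_e"),
        list(c(-s[1], cap), c(-s[2], cap), c(0, cap), c(0, cap)))
      list(models = list(A, B), diet = diet,
           truth = list(sign = 1, type = "Mutualism"))
    })
  out
}

#' Generate a small host-like model with lumen and blood compartments
#'
#' Emulates the structure of a host epithelial-cell model: lumen-facing
#' exchange reactions, blood-facing sink reactions that are excluded from
#' exchange detection, and a maintenance-style objective (turnover without
#' replication). The host can take up a choline-like lumen metabolite
#' (`cho_e`) as an alternative maintenance substrate, so pairing it with a
#' bacterium secreting that metabolite yields a host-favoring interaction.
#'
#' @param substrate_bound not used directly by the model (bounds live in the
#'   diet); kept for symmetric parameterization of test fixtures.
#' @param maintenance_yield biomass-equivalent per substrate unit (default 1).
#' @return a `metabolic_model` with id `"host"`.
#' @export
generate_host_like <- function(substrate_bound = 10, maintenance_yield = 1) {
  mets <- data.frame(
    id = c("gh_e", "cho_e", "vit_e", "gh_c", "vit_c", "w_b", "vit_b"),
    compartment = c("e", "e", "e", "c", "c", "b", "b"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_gh_e", "EX_cho_e", "EX_vit_e", "T_gh", "T_cho", "T_vit",
           "MAINT", "EXPORT_vit", "SINK_w_b", "SINK_vit_b"),
    lb = c(-1000, -1000, -1000, 0, 0, 0, 0, 0, 0, 0),
    ub = 1000,
    objective = c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_gh_e = c(gh_e = -1),
    EX_cho_e = c(cho_e = -1),
    EX_vit_e = c(vit_e = -1),
    T_gh = c(gh_e = -1, gh_c = 1),
    T_cho = c(cho_e = -1, gh_c = 1),
    T_vit = c(vit_e = -1, vit_c = 1),
    MAINT = c(gh_c = -1 / maintenance_yield, vit_c = -0.01, w_b = 0.2),
    EXPORT_vit = c(vit_c = -1, vit_b = 1),
    SINK_w_b = c(w_b = -1),
    SINK_vit_b = c(vit_b = -1))
  metabolic_model("host", mets, rxns, stoich,
                  external_compartments = "e", blood_compartment = "b")
}

#' Generate a multi-member toy community with known pairwise structure
#'
#' Members 1 and 2 form a mutual cross-feeding pair (as in
#' `crossfeed_mutual`); the remaining members are neutral bystanders on
#' private substrates. The returned `truth` matrix holds the expected
#' pairwise interaction signs (+1 for the cross-feeding pair, 0 elsewhere).
#'
#' @param spec a [toy_spec()] with `n_members` between 3 and 11.
#' @return list with `models`, `diet`, and `truth` (k x k sign matrix).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  k <- spec$n_members
  if (k < 3L || k > 11L)
    stop("generate_community needs 3 <= n_members <= 11")
  pair_spec <- toy_spec("crossfeed_mutual", 2L,
                        yields = spec$yields[1:2],
                        substrate_bound = spec$substrate_bound[1:2],
                        byproduct_stoich = spec$byproduct_stoich,
                        obligate_stoich = spec$obligate_stoich,
                        seed = spec$seed)
  pair <- generate_pair(pair_spec)
  models <- pair$models
  lumen <- pair$diet$lumen_bounds
  cap <- 1000
  for (i in seq(3L, k)) {
    sub <- paste0("g", i)
    models[[i]] <- toy_consumer(paste0("N", i), sub, spec$yields[i])
    lumen[[paste0(sub, "_e")]] <- c(-spec$substrate_bound[i], cap)
  }
  truth <- matrix(0, k, k)
  truth[1, 2] <- truth[2, 1] <- 1
  ids <- vapply(models, `[[`, "", "model_id")
  dimnames(truth) <- list(ids, ids)
  list(models = models,
       diet = diet_spec(name = paste0("toy_community_k", k),
                        lumen_bounds = lumen),
       truth = truth)
}
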