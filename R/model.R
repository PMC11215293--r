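#' Construct a single-organism metabolic model
#'
#' The basic container of the package: a stoichiometric matrix with flux
#' bounds and a linear objective, i.e. everything flux balance analysis needs.
#' Exchange reactions (single-metabolite reactions that move a metabolite in
#' or out of the system) follow the BiGG sign convention: negative flux is
#' uptake into the organism, positive flux is secretion.
#'
#' @param model_id character scalar identifying the organism.
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions data.frame with column `id` and optional numeric columns
#'   `lb`, `ub`, `objective`. Missing bounds default to `c(-default_bound,
#'   default_bound)` for reversible handling at the caller's discretion; a
#'   missing `lb`/`ub` entry (NA) is replaced by `-default_bound` /
#'   `default_bound`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param objective optional named numeric vector of objective weights keyed
#'   by reaction id; overrides the `objective` column if both given.
#' @param exchange_ids optional character vector of exchange reaction ids;
#'   when `NULL` they are detected with the `boundary` policy of
#'   [detect_exchanges()].
#' @param external_compartments compartments considered outward-facing
#'   (default `"e"`); used by the boundary exchange-detection policy.
#' @param blood_compartment compartment tag of host blood reactions, which
#'   are never treated as exchanges (default `"b"`).
#' @param default_bound magnitude used for unspecified flux bounds, in
#'   mmol/gDW/h (default 1000).
#' @return an object of class `metabolic_model`.
#' @seealso [read_model()], [detect_exchanges()], [apply_namespace()]
#' @export
metabolic_model <- function(model_id, metabolites, reactions, stoichiometry,
                            objective = NULL, exchange_ids = NULL,
                            external_compartments = "e",
                            blood_compartment = "b",
                            default_bound = 1000) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!all(c("id", "compartment") %in% names(metabolites)))
    stop("metabolites must have columns 'id' and 'compartment'")
  if (!"id" %in% names(reactions)) stop("reactions must have column 'id'")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (is.null(reactions$lb)) reactions$lb <- NA_real_
  if (is.null(reactions$ub)) reactions$ub <- NA_real_
  reactions$lb[is.na(reactions$lb)] <- -default_bound
  reactions$ub[is.na(reactions$ub)] <- default_bound
  if (is.null(objective)) {
    if (is.null(reactions$objective)) reactions$objective <- 0
    reactions$objective[is.na(reactions$objective)] <- 0
  } else {
    reactions$objective <- 0
    bad <- setdiff(names(objective), reactions$id)
    if (length(bad))
      stop("objective references undeclared reactions: ",
           paste(bad, collapse = ", "))
    reactions$objective[match(names(objective), reactions$id)] <-
      as.numeric(objective)
  }
  S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                      dimnames = list(metabolites$id, reactions$id))
  for (rid in names(stoichiometry)) {
    if (!rid %in% reactions$id)
      stop("stoichiometry given for undeclared reaction: ", rid)
    coefs <- stoichiometry[[rid]]
    bad <- setdiff(names(coefs), metabolites$id)
    if (length(bad))
      stop("reaction ", rid, " references undeclared metabolites: ",
           paste(bad, collapse = ", "))
    S[names(coefs), rid] <- as.numeric(coefs)
  }
  m <- structure(list(
    model_id = model_id,
    metabolites = metabolites[, c("id", "compartment")],
    reactions = reactions[, c("id", "lb", "ub", "objective")],
    S = S,
    exchange_ids = character(),
    external_compartments = external_compartments,
    blood_compartment = blood_compartment,
    default_bound = default_bound
  ), class = "metabolic_model")
  m$exchange_ids <- if (is.null(exchange_ids)) {
    detect_exchanges(m, policy = "boundary")
  } else {
    as.character(exchange_ids)
  }
  validate_metabolic_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks bound ordering, that the objective is non-empty, and that exchange
#' reactions each touch exactly one metabolite. Called by the constructor and
#' by the readers; exported because the tabular/SBML round-trip tests and
#' downstream assemblies re-validate models after editing them.
#'
#' @param m a `metabolic_model`.
#' @return `m`, invisibly; stops with a validation error otherwise.
#' @export
validate_metabolic_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  rx <- m$reactions
  if (any(rx$lb > rx$ub))
    stop("validation error: lower bound exceeds upper bound for ",
         paste(rx$id[rx$lb > rx$ub], collapse = ", "))
  if (!any(rx$objective != 0))
    stop("validation error: model '", m$model_id, "' has an empty objective")
  bad <- setdiff(m$exchange_ids, rx$id)
  if (length(bad))
    stop("validation error: unknown exchange reactions ",
         paste(bad, collapse = ", "))
  nmet <- Matrix::colSums(m$S[, m$exchange_ids, drop = FALSE] != 0)
  if (any(nmet != 1))
    stop("validation error: exchange reactions must touch exactly one ",
         "metabolite: ", paste(m$exchange_ids[nmet != 1], collapse = ", "))
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$model_id, ": ",
      nrow(x$reactions), " reactions, ", nrow(x$metabolites),
      " metabolites, ", length(x$exchange_ids), " exchanges\n", sep = "")
  invisible(x)
}

#' Identify exchange reactions of a model
#'
#' Two policies are supported. `boundary` flags reactions that touch exactly
#' one metabolite whose compartment is in `external_compartments`; `prefix`
#' flags reaction ids beginning with `prefix`. Under both policies, reactions
#' whose single metabolite sits in the blood compartment are excluded: in a
#' host model the blood side is not part of the shared lumen environment.
#'
#' @param model a `metabolic_model`.
#' @param policy `"boundary"` (default) or `"prefix"`.
#' @param prefix id prefix used by the prefix policy (default `"EX_"`).
#' @return character vector of reaction ids (possibly empty).
#' @export
detect_exchanges <- function(model, policy = c("boundary", "prefix"),
                             prefix = "EX_") {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "metabolic_model"))
  nmet <- Matrix::colSums(model$S != 0)
  single <- model$reactions$id[nmet == 1]
  met_of <- vapply(single, function(r) {
    rownames(model$S)[Matrix::which(model$S[, r] != 0)]
  }, character(1))
  comp <- model$metabolites$compartment[match(met_of, model$metabolites$id)]
  blood <- single[comp %in% model$blood_compartment]
  if (policy == "boundary") {
    setdiff(single[comp %in% model$external_compartments], blood)
  } else {
    setdiff(model$reactions$id[startsWith(model$reactions$id, prefix)], blood)
  }
}

#' Construct a namespace mapping
#'
#' A renaming table used to reconcile metabolite or reaction identifiers
#' between models reconstructed under different nomenclatures, so that shared
#' pool metabolites actually collide (collision is how sharing is expressed
#' during ecosystem assembly).
#'
#' @param entries named character vector: `names(entries)` are source ids,
#'   values are target ids. Must be injective.
#' @param scope `"metabolite"` or `"reaction"`.
#' @return an object of class `namespace_map`.
#' @export
namespace_map <- function(entries, scope = c("metabolite", "reaction")) {
  scope <- match.arg(scope)
  entries <- unlist(entries)
  if (length(entries) && anyDuplicated(entries))
    stop("conflict error: namespace map is not injective (",
         paste(unique(entries[duplicated(entries)]), collapse = ", "), ")")
  structure(list(entries = entries, scope = scope), class = "namespace_map")
}

#' Read a two-column TSV into a namespace map
#'
#' @param path TSV file with columns `source_id` and `target_id` (header
#'   required).
#' @param scope `"metabolite"` or `"reaction"`.
#' @return a `namespace_map`.
#' @export
read_namespace_map <- function(path, scope = c("metabolite", "reaction")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(tab)))
    stop("format error: namespace map needs columns source_id, target_id")
  namespace_map(stats::setNames(tab$target_id, tab$source_id),
                scope = match.arg(scope))
}

#' Rename model identifiers through a namespace map
#'
#' Ids present in the map are renamed; all others are left unchanged. A
#' renaming that would merge two distinct ids of the model is refused, since
#' it would silently alter the stoichiometry.
#'
#' @param model a `metabolic_model`.
#' @param map a [namespace_map()].
#' @return the renamed `metabolic_model`.
#' @export
apply_namespace <- function(model, map) {
  stopifnot(inherits(model, "metabolic_model"), inherits(map, "namespace_map"))
  ren <- function(ids) {
    hit <- ids %in% names(map$entries)
    out <- ids
    out[hit] <- unname(map$entries[ids[hit]])
    if (anyDuplicated(out))
      stop("conflict error: renaming collides ids: ",
           paste(unique(out[duplicated(out)]), collapse = ", "))
    out
  }
  if (map$scope == "metabolite") {
    model$metabolites$id <- ren(model$metabolites$id)
    rownames(model$S) <- model$metabolites$id
  } else {
    old <- model$reactions$id
    new <- ren(old)
    model$reactions$id <- new
    colnames(model$S) <- new
    model$exchange_ids <- new[match(model$exchange_ids, old)]
  }
  validate_metabolic_model(model)
  model
}
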