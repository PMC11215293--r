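#' Read a metabolic model from disk
#'
#' Two formats are supported. `tabular` is a small TSV dialect: a directory
#' holding `reactions.tsv` (columns `id`, `equation`, `lb`, `ub`, `objective`)
#' and `metabolites.tsv` (columns `id`, `compartment`). `sbml` reads SBML
#' Level 3 with the fbc package (flux bounds as referenced parameters, the
#' active fbc objective as the model objective). Bounds absent from the file
#' default to +/- 1000 mmol/gDW/h.
#'
#' @param path file (SBML) or directory (tabular).
#' @param format `"tabular"` or `"sbml"`; default guesses from `path`.
#' @param ... passed to [metabolic_model()] (e.g. `external_compartments`).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("guess", "tabular", "sbml"), ...) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (dir.exists(path)) "tabular" else "sbml"
  switch(format,
         tabular = read_model_tabular(path, ...),
         sbml = read_model_sbml(path, ...))
}

#' Write a metabolic model to disk
#'
#' Inverse of [read_model()]; a written model re-reads to identical
#' stoichiometry, bounds and objective.
#'
#' @param model a `metabolic_model`.
#' @param path output directory (tabular) or file (SBML).
#' @param format `"tabular"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tabular = write_model_tabular(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# "2 a_c + b_c --> 0.5 x_c" / "<=>" for reversible; empty side allowed
parse_equation <- function(eq, rid) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("-->", eq, fixed = TRUE)) "-->"
           else stop("format error: reaction ", rid,
                     " has no '-->' or '<=>' arrow")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        out[parts] <- sign * 1
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("format error: bad coefficient '", parts[1],
               "' in reaction ", rid)
        out[parts[2]] <- sign * coef
      } else stop("format error: cannot parse term '", tm,
                  "' in reaction ", rid)
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  coefs <- c(lhs, rhs)
  # merge duplicated metabolites across sides
  tapply_sum <- tapply(coefs, names(coefs), sum)
  coefs <- stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
  coefs[coefs != 0]
}

format_equation <- function(coefs, reversible) {
  one_side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v), paste(fmt_num(v), names(v))),
          collapse = " + ")
  }
  lhs <- -coefs[coefs < 0]
  rhs <- coefs[coefs > 0]
  paste(one_side(lhs), if (reversible) "<=>" else "-->", one_side(rhs))
}

read_model_tabular <- function(path, model_id = basename(normalizePath(path)),
                               ...) {
  rfile <- file.path(path, "reactions.tsv")
  mfile <- file.path(path, "metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile))
    stop("format error: expected reactions.tsv and metabolites.tsv in ", path)
  rx <- utils::read.delim(rfile, stringsAsFactors = FALSE)
  mets <- utils::read.delim(mfile, stringsAsFactors = FALSE)
  if (!all(c("id", "equation") %in% names(rx)))
    stop("format error: reactions.tsv needs columns id, equation")
  stoich <- lapply(seq_len(nrow(rx)),
                   function(i) parse_equation(rx$equation[i], rx$id[i]))
  names(stoich) <- rx$id
  metabolic_model(model_id, mets,
                  rx[, intersect(c("id", "lb", "ub", "objective"), names(rx))],
                  stoich, ...)
}

write_model_tabular <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rx <- model$reactions
  rx$equation <- vapply(rx$id, function(r) {
    v <- model$S[, r]
    format_equation(v[v != 0], reversible = rx$lb[rx$id == r] < 0)
  }, character(1))
  out <- rx[, c("id", "equation", "lb", "ub", "objective")]
  out$lb <- fmt_num(out$lb); out$ub <- fmt_num(out$ub)
  out$objective <- fmt_num(out$objective)
  utils::write.table(out, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---- SBML level 3 + fbc ----------------------------------------------------

sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(TRUE, names(at) == name | endsWith(names(at), paste0(":", name)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

read_model_sbml <- function(path, model_id = NULL, ...) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: cannot parse SBML: ",
                                           conditionMessage(e)))
  find <- function(xp) xml2::xml_find_all(doc, xp)
  mnode <- find("//*[local-name()='model']")
  if (length(mnode) == 0) stop("format error: no <model> element in ", path)
  if (is.null(model_id))
    model_id <- sbml_attr(mnode[[1]], "id")
  sp <- find("//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- data.frame(
    id = vapply(sp, sbml_attr, "", name = "id"),
    compartment = vapply(sp, sbml_attr, "", name = "compartment"),
    stringsAsFactors = FALSE)
  pars <- find("//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(
    as.numeric(vapply(pars, sbml_attr, "", name = "value")),
    vapply(pars, sbml_attr, "", name = "id"))
  rnodes <- find("//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rnodes) == 0) stop("format error: no reactions in ", path)
  ids <- character(); lbs <- ubs <- numeric(); stoich <- list()
  for (rn in rnodes) {
    rid <- sbml_attr(rn, "id")
    if (is.na(rid)) stop("format error: reaction without id")
    coefs <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0(
        "./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        s <- sbml_attr(ref, "species")
        k <- suppressWarnings(as.numeric(sbml_attr(ref, "stoichiometry")))
        if (is.na(k)) k <- 1
        if (side == "listOfReactants") k <- -k
        coefs[s] <- (if (s %in% names(coefs)) coefs[s] else 0) + k
      }
    }
    lbp <- sbml_attr(rn, "lowerFluxBound")
    ubp <- sbml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else NA_real_
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else NA_real_
    ids <- c(ids, rid); lbs <- c(lbs, lb); ubs <- c(ubs, ub)
    stoich[[rid]] <- coefs[coefs != 0]
  }
  fo <- find(paste0("//*[local-name()='listOfObjectives']",
                    "/*[local-name()='objective']",
                    "/*[local-name()='listOfFluxObjectives']",
                    "/*[local-name()='fluxObjective']"))
  if (length(fo) == 0)
    stop("validation error: SBML model has no fbc objective")
  objective <- stats::setNames(
    as.numeric(vapply(fo, sbml_attr, "", name = "coefficient")),
    vapply(fo, sbml_attr, "", name = "reaction"))
  metabolic_model(model_id, mets,
                  data.frame(id = ids, lb = lbs, ub = ubs,
                             stringsAsFactors = FALSE),
                  stoich, objective = objective, ...)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  e <- xml_escape
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', e(model$model_id), '" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment))
    w('      <compartment id="', e(cp), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites)))
    w('      <species id="', e(model$metabolites$id[i]),
      '" compartment="', e(model$metabolites$compartment[i]),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"/>')
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    w('      <parameter id="', e(rid), '_lb" value="',
      fmt_num(model$reactions$lb[i]), '" constant="true"/>')
    w('      <parameter id="', e(rid), '_ub" value="',
      fmt_num(model$reactions$ub[i]), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    v <- model$S[, rid]
    coefs <- v[v != 0]
    w('      <reaction id="', e(rid), '" reversible="',
      tolower(model$reactions$lb[i] < 0), '" fast="false" ',
      'fbc:lowerFluxBound="', e(rid), '_lb" fbc:upperFluxBound="',
      e(rid), '_ub">')
    for (side in c(-1, 1)) {
      sel <- coefs * side > 0
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      w('        <', tag, '>')
      for (sn in names(coefs)[sel])
        w('          <speciesReference species="', e(sn),
          '" stoichiometry="', fmt_num(abs(coefs[[sn]])),
          '" constant="true"/>')
      w('        </', tag, '>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  sel <- model$reactions$objective != 0
  for (i in which(sel))
    w('          <fbc:fluxObjective fbc:reaction="',
      e(model$reactions$id[i]), '" fbc:coefficient="',
      fmt_num(model$reactions$objective[i]), '"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('  </model>')
  w('</sbml>')
}

## ---- diets -----------------------------------------------------------------

#' Construct a diet specification
#'
#' A diet (growth medium) constrains the pool exchange reactions of an
#' assembled ecosystem: for each listed lumen metabolite, bounds on the pool
#' exchange flux (negative flux = supply from the environment into the pool).
#' Pool exchanges not listed follow `default_policy`: `"unconstrained"`
#' leaves them at the numerical flux cap (nutrients of unknown concentration
#' are treated as freely available, since blocking them abolishes growth),
#' `"blocked"` forbids them entirely. Host models may additionally carry
#' blood-side bounds keyed by reaction id.
#'
#' @param name character label.
#' @param lumen_bounds named list/ named 2-column matrix: metabolite id ->
#'   c(lower, upper).
#' @param blood_bounds named list: reaction id -> c(lower, upper), applied to
#'   host blood reactions.
#' @param default_policy `"unconstrained"` (default) or `"blocked"`.
#' @return an object of class `diet_spec`.
#' @export
diet_spec <- function(name = "diet", lumen_bounds = list(),
                      blood_bounds = list(),
                      default_policy = c("unconstrained", "blocked")) {
  default_policy <- match.arg(default_policy)
  norm <- function(b) {
    b <- lapply(b, as.numeric)
    for (id in names(b)) {
      if (length(b[[id]]) != 2 || b[[id]][1] > b[[id]][2])
        stop("validation error: bad bounds for '", id, "'")
    }
    b
  }
  structure(list(name = name, lumen_bounds = norm(lumen_bounds),
                 blood_bounds = norm(blood_bounds),
                 default_policy = default_policy),
            class = "diet_spec")
}

#' Read a diet from a TSV file
#'
#' The file holds a TSV body with columns `metabolite_id`, `lower`, `upper`
#' plus optional `#`-prefixed header lines `# name:`, `# default_policy:` and
#' `# blood:` (path, relative to the diet file, of a second TSV with columns
#' `reaction_id`, `lower`, `upper` for host blood bounds).
#'
#' @param path path to the diet TSV.
#' @return a `diet_spec`.
#' @export
read_diet <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getfield <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  if (nrow(tab) && !all(c("metabolite_id", "lower", "upper") %in% names(tab)))
    stop("format error: diet TSV needs columns metabolite_id, lower, upper")
  lumen <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) c(tab$lower[i], tab$upper[i])),
    tab$metabolite_id)
  blood <- list()
  bpath <- getfield("blood", "")
  if (nzchar(bpath)) {
    btab <- utils::read.delim(file.path(dirname(path), bpath),
                              stringsAsFactors = FALSE)
    blood <- stats::setNames(
      lapply(seq_len(nrow(btab)), function(i) c(btab$lower[i], btab$upper[i])),
      btab$reaction_id)
  }
  diet_spec(name = getfield("name", basename(path)),
            lumen_bounds = lumen, blood_bounds = blood,
            default_policy = getfield("default_policy", "unconstrained"))
}

#' Write a diet to a TSV file
#'
#' @param diet a `diet_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diet <- function(diet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name: ", diet$name),
               paste0("# default_policy: ", diet$default_policy),
               "metabolite_id\tlower\tupper"), con)
  for (id in names(diet$lumen_bounds))
    writeLines(paste(id, fmt_num(diet$lumen_bounds[[id]][1]),
                     fmt_num(diet$lumen_bounds[[id]][2]), sep = "\t"), con)
  invisible(path)
}
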