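#' Write an interaction report to JSON
#'
#' Serializes the scoring results (score, areas/volumes, flags, type, alone
#' maxima, front vertices, optional removal scores) into a plain JSON file,
#' the exchange format used by the command-line interface.
#'
#' @param report an `interaction_report` (see [interaction_score()],
#'   [score_ecosystem()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "interaction_report"))
  out <- list(
    score = report$score,
    auc_p = report$auc_p,
    auc_ni = report$auc_ni,
    k = report$k,
    organism_order = report$organism_order,
    alone_maxima = as.list(report$alone_maxima),
    interaction_type = report$interaction_type,
    flags = report$flags,
    removal_scores = if (!is.null(report$removal_scores))
      as.list(unclass(report$removal_scores)) else NULL)
  if (!is.null(report$front))
    out$front_points <- apply(report$front$points, 1, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a Pareto front to TSV with JSON metadata
#'
#' One row per extreme point, one labeled column per member; solver metadata
#' (dimension, tolerance, member order) goes to a `.json` side file.
#'
#' @param front a `pareto_front`.
#' @param path output TSV path; metadata is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_front <- function(front, path) {
  stopifnot(inherits(front, "pareto_front"))
  utils::write.table(as.data.frame(front$points), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(dimension = front$dimension,
         organism_order = front$organism_order,
         solver_tolerance = front$solver_tolerance,
         n_points = nrow(front$points)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
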