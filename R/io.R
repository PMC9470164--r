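#' Read a simulation configuration from YAML
#'
#' @param path YAML file with fields matching [sim_config()] (when
#'   `type = "tracks"`) or [reaction_sim_config()] (`type = "reaction"`).
#' @param type which config constructor to apply.
#' @return A validated `sim_config` or `reaction_sim_config`.
#' @export
read_sim_config <- function(path, type = c("tracks", "reaction")) {
  type <- match.arg(type)
  vals <- yaml::read_yaml(path)
  ctor <- if (type == "tracks") sim_config else reaction_sim_config
  known <- names(formals(ctor))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    warning("ignoring unknown config field(s): ", paste(extra, collapse = ", "))
  do.call(ctor, vals[intersect(names(vals), known)])
}

#' Write a simulation config or ground-truth record as YAML
#'
#' @param x a `sim_config`, `reaction_sim_config`, or the `truth`
#'   element of a [simulate_tracks()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_yaml <- function(x, path) {
  if (is.data.frame(x)) x <- as.list(x)
  x <- unclass(x)
  x$undersampled <- NULL  # derived, not a constructor argument
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes the scalar fields of a `dwell_fit`, `step_fit`, `hill_fit`,
#' `feedback_fit`, `calibration_curve` or `filter_report` to a JSON file
#' (curve/table fields are dropped), mirroring the columns reported in
#' single-molecule summary tables.
#'
#' @param x a fit/report object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  keep <- vapply(unclass(x), function(el)
    (is.numeric(el) || is.logical(el) || is.character(el)) &&
      length(el) <= 8 && !is.data.frame(el), logical(1))
  out <- unclass(x)[keep]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
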