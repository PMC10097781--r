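#' Write a parameter set to a YAML or JSON file
#'
#' Serializes passive, active, circulation or geometry parameter objects
#' with a units header, so runs can be configured from files and every
#' default overridden per run.
#'
#' @param params a `passive_params`, `active_params`, `circulation_params`
#'   or `lv_geometry_spec` object (or a plain named list).
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
write_params_file <- function(params, path) {
  type <- class(params)[1]
  payload <- list(type = type,
                  units = "mm, ml, ms (circulation: s), mmHg, kPa, degrees, um",
                  params = unclass(params))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop_lv("unsupported parameter file extension: %s", path)
  invisible(path)
}

#' Read a parameter set written by [write_params_file()]
#'
#' @param path YAML or JSON parameter file.
#' @return the parameter object with its original class, revalidated through
#'   its constructor where one exists.
#' @export
read_params_file <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
             else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
             else stop_lv("unsupported parameter file extension: %s", path)
  if (is.null(payload$type) || is.null(payload$params))
    stop_lv("malformed parameter file (missing type/params): %s", path)
  pr <- payload$params
  switch(payload$type,
         passive_params = do.call(passive_params, pr),
         active_params = do.call(active_params, pr),
         circulation_params = {
           keep <- setdiff(names(pr), c("k_R", "k_C"))
           do.call(circulation_params,
                   c(pr[keep], list(k_R = pr$k_R %||% 1, k_C = pr$k_C %||% 1)))
         },
         lv_geometry_spec = do.call(lv_geometry_spec, pr),
         structure(pr, class = payload$type))
}
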