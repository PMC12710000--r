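# Reading generator / noise / perturbation parameters from config files.
# JSON is the canonical format; YAML is accepted when the yaml package is
# available.

read_config_list <- function(path) {
  if (!file.exists(path))
    stop_with("rsaeval_config_error", "config file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_with("rsaeval_config_error",
                "the yaml package is required to read %s", path)
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e)
               stop_with("rsaeval_config_error", "cannot parse %s: %s",
                         path, conditionMessage(e)))
  }
}

config_call <- function(fields, constructor, what) {
  known <- names(formals(constructor))
  unknown <- setdiff(names(fields), known)
  if (length(unknown))
    stop_with("rsaeval_config_error", "unknown %s field(s): %s", what,
              paste(unknown, collapse = ", "))
  do.call(constructor, fields)
}

#' Read parameter objects from a JSON or YAML config file
#'
#' Field names match the arguments of [generator_params()],
#' [noise_config()] and [perturbation_params()]; unknown fields are a
#' configuration error rather than being silently dropped.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return The corresponding parameter object.
#' @export
read_generator_params <- function(path)
  config_call(read_config_list(path), generator_params, "generator")

#' @rdname read_generator_params
#' @export
read_noise_config <- function(path)
  config_call(read_config_list(path), noise_config, "noise")

#' @rdname read_generator_params
#' @export
read_perturbation_params <- function(path)
  config_call(read_config_list(path), perturbation_params, "perturbation")
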