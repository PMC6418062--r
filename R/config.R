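#' Default model configuration
#'
#' The embedded defaults: fixed constants and the truncation values of
#' the six stochastic fall parameters.
#'
#' @return Nested list with `constants` (`c, dt, n_fall, g, k`) and
#'   `fall_model` (each parameter as a list `a`, `b`).
#' @export
default_config <- function() {
  fm <- fall_model_default()
  list(
    constants = unclass(fixed_constants()),
    fall_model = lapply(fm, function(s) list(a = s$a, b = s$b))
  )
}

#' Load and validate a model configuration file
#'
#' Reads a YAML (or JSON, which YAML parses) configuration and
#' deep-merges it over the embedded defaults. Unknown keys are rejected
#' as a typo guard; truncation specs with `a >= b` are rejected. An
#' empty file returns the pure defaults.
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return Validated configuration list (same shape as
#'   [default_config()]).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(.validate_config(cfg))
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(.validate_config(cfg))
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) {
    stop(sprintf("unknown configuration section(s): %s",
                 paste(bad, collapse = ", ")))
  }
  for (sec in names(user)) {
    bad2 <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad2) > 0) {
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad2, collapse = ", ")))
    }
    for (k in names(user[[sec]])) {
      v <- user[[sec]][[k]]
      if (is.list(cfg[[sec]][[k]]) && !is.list(v)) {
        stop(sprintf("'%s.%s' must be a mapping with keys a, b", sec, k))
      }
      if (is.list(v)) {
        cfg[[sec]][[k]][names(v)] <- v
      } else {
        cfg[[sec]][[k]] <- v
      }
    }
  }
  .validate_config(cfg)
}

.validate_config <- function(cfg) {
  do.call(fixed_constants, cfg$constants)        # validates positivity
  for (k in names(cfg$fall_model)) {
    s <- cfg$fall_model[[k]]
    if (!all(c("a", "b") %in% names(s))) {
      stop(sprintf("fall_model.%s must provide both a and b", k))
    }
    if (s$a >= s$b) {
      stop(sprintf("fall_model.%s: lower truncation a must be below b", k))
    }
  }
  ep <- cfg$fall_model$eta_P
  if (ep$a < 0 || ep$b > 1) stop("fall_model.eta_P bounds must lie in [0, 1]")
  cfg
}

#' Build runtime objects from a configuration
#'
#' @param cfg A configuration list from [load_config()].
#' @return List with `constants` ([fixed_constants()]) and `fall_model`
#'   (named list of [trunc_spec()]s).
#' @export
config_objects <- function(cfg) {
  list(
    constants = do.call(fixed_constants, cfg$constants),
    fall_model = structure(
      lapply(cfg$fall_model, function(s) trunc_spec(s$a, s$b)),
      class = "arf_fall_model")
  )
}

#' Write a run manifest
#'
#' Records command, configuration hash, root seed, timestamps and output
#' paths so that any result file can be regenerated from its manifest.
#'
#' @param path Manifest JSON path.
#' @param command Character description of the invocation.
#' @param cfg Configuration list used.
#' @param seed Root seed.
#' @param outputs Character vector of produced file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, cfg, seed, outputs) {
  manifest <- list(
    command = command,
    config_hash = .config_hash(cfg),
    root_seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.character(outputs),
    package_version = as.character(utils::packageVersion("arfsim"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
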