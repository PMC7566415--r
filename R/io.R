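#' Write a simulation trace to CSV
#'
#' Writes the trace with the canonical header
#' `time_ms,V_mV,Vm_mV,n,m,h,iNa_uAcm2,iK_uAcm2,iL_uAcm2` (plus any extra
#' columns), floats printed with 9 significant digits.
#'
#' @param trace An `hh_trace` (or any data frame of numeric columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  fmt <- lapply(trace, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 9) else col
  })
  df <- as.data.frame(fmt, check.names = FALSE, optional = TRUE)
  names(df) <- names(trace)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a simulation trace from CSV
#'
#' @param path CSV file written by [write_trace()].
#' @return A tibble of class `hh_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(tibble::as_tibble(df),
            class = c("hh_trace", class(tibble::tibble())))
}

#' Export the model topology as Graphviz DOT
#'
#' One graph node per top-level component; solid edges for electrical
#' connections, dashed red edges for temperature signal bindings — an
#' equation-accurate sketch of the model diagram.
#'
#' @param model An `hh_circuit`.
#' @return A single character string of DOT source.
#' @export
#' @examples
#' cat(export_dot(build_hh_model()))
export_dot <- function(model) {
  stopifnot(inherits(model, "hh_circuit"))
  owner <- function(pin) split_qualified(pin)$path
  top <- function(path) strsplit(path, ".", fixed = TRUE)[[1]][1]
  lines <- c("graph hhmodel {", "  node [shape=box];")
  for (nm in names(model$components)) {
    lines <- c(lines, sprintf('  "%s" [label="%s\\n(%s)"];', nm, nm,
                              model$components[[nm]]$class))
  }
  for (cn in model$electrical) {
    lines <- c(lines, sprintf('  "%s" -- "%s" [style=solid, kind=electrical];',
                              top(owner(cn[["a"]])), top(owner(cn[["b"]]))))
  }
  for (s in model$signals) {
    lines <- c(lines, sprintf(
      '  "%s" -- "%s" [style=dashed, color=red, kind=temperature];',
      top(owner(s[["out"]])), top(owner(s[["inp"]]))))
  }
  paste0(paste(lines, collapse = "\n"), "\n}\n")
}

config_keys <- c("duration", "output_step", "v_init", "i_const",
                 "temperature", "solver", "rtol", "atol", "seed", "parameters")

# qualified component-parameter names accepted in config files, mapped to
# the flat hh_parameters() fields
qualified_param_map <- c(
  "bilayer.c" = "c", "bilayer.v_init" = "v_init",
  "bilayer.temp_m" = "temperature",
  "sodium.g_max" = "g_na", "sodium.v_eq" = "e_na",
  "potassium.g_max" = "g_k", "potassium.v_eq" = "e_k",
  "leak.g_max" = "g_l", "leak.v_eq" = "e_l",
  "clamp.i_const" = "i_const"
)

#' Read an experiment configuration file
#'
#' Reads a JSON or YAML document mirroring [experiment_config()] plus an
#' optional `parameters` block of overrides, keyed either by the flat
#' [hh_parameters()] names (`g_na`, `e_k`, ...) or by qualified component
#' names (`sodium.g_max`, `clamp.i_const`, ...). Unknown keys are rejected.
#' Units are fixed by the schema: ms, mV, uA/cm2, mS/cm2, degrees Celsius.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `config` (an `hh_experiment_config`) and
#'   `parameters` (named list of parameter overrides, possibly empty).
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext),
         call. = FALSE)
  )
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pars <- raw$parameters %||% list()
  allowed <- c(setdiff(names(formals(hh_parameters)), "e_r"), "e_r",
               names(qualified_param_map))
  bad <- setdiff(names(pars), allowed)
  if (length(bad)) {
    stop("unknown parameter overrides: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mapped <- stats::setNames(
    pars,
    ifelse(names(pars) %in% names(qualified_param_map),
           qualified_param_map[names(pars)], names(pars))
  )
  cfg_args <- raw[setdiff(names(raw), "parameters")]
  config <- do.call(experiment_config, cfg_args)
  list(config = config, parameters = as.list(mapped))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
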