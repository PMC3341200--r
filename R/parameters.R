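# Core parameter set: the 30 rate/production/degradation constants of the
# network plus the fixed total RSK1 pool.  All amounts are in the model's
# arbitrary unit (au), time is in minutes.

#' Names of the 30 core kinetic parameters
#'
#' The order is fixed and shared by [default_parameters()], the sensitivity
#' sampler and the compiled right-hand side.  Names are ASCII
#' transliterations of the published symbols (`_plus`/`_minus` for
#' superscript +/-, `gamma_` for degradation rates).
#'
#' @return Character vector of length 30.
#' @export
core_parameter_names <- function() {
  c("k_Mp73E_plus", "k_Mp73_minus", "k_Mp73a_plus",
    "k_Mp409_plus", "k_Mp409_minus",
    "k_Mass", "k_Mdiss",
    "k_Mp73ass", "k_Mp73diss",
    "k_Mp409ass", "k_Mp409diss",
    "k_Mppass", "k_Mppdiss",
    "k_Sp_plus", "k_Sp_minus",
    "k_Spass", "k_Spdiss",
    "p_MITF", "gamma_MITF", "gamma_MITFp73", "gamma_MITFp409",
    "p_PIAS3", "gamma_PIAS3",
    "p_STAT3", "gamma_STAT3",
    "k_Rp_plus", "k_Rp_minus",
    "ERKp_baseline", "JAKp_baseline",
    "k_u")
}

#' Default core parameters of the MITF-PIAS3-STAT3 model
#'
#' Returns the published default parameterization.  The source prints two
#' conflicting values for the PIAS3 production rate: the parameter table
#' lists 0.262 au/min while the modelling prose and every experiment
#' protocol use 1.262 au/min as the un-transfected baseline.  Both readings
#' are exposed through `dialect`; `"methods"` (the default) uses 1.262,
#' which is the value the experiment catalog is anchored to, `"table1"`
#' uses 0.262.
#'
#' @param dialect Either `"methods"` (PIAS3 production 1.262 au/min) or
#'   `"table1"` (0.262 au/min).  All other values are identical.
#' @return Named numeric vector of length 31 with class `"pias3net_params"`:
#'   the 30 core constants (see [core_parameter_names()]) plus `RSK1_total`
#'   (500 au), the fixed size of the RSK1 pool.
#' @examples
#' p <- default_parameters()
#' p[["k_Mdiss"]]    # 1 /min
#' p[["p_PIAS3"]]    # 1.262 under the "methods" dialect
#' @export
default_parameters <- function(dialect = c("methods", "table1")) {
  dialect <- match.arg(dialect)
  p <- c(
    k_Mp73E_plus   = 0.00015, # MITF S73 phosphorylation by ERKp (au^-1 min^-1)
    k_Mp73_minus   = 0.03,    # MITF S73 de-phosphorylation (min^-1)
    k_Mp73a_plus   = 0.025,   # MITF S73 auto-phosphorylation (min^-1)
    k_Mp409_plus   = 0.0001,  # MITF S409 phosphorylation by RSK1p (au^-1 min^-1)
    k_Mp409_minus  = 0.04,    # MITF S409 de-phosphorylation (min^-1)
    k_Mass         = 0.01,    # MITF/PIAS3 association (au^-1 min^-1)
    k_Mdiss        = 1,       # MITF/PIAS3 dissociation (min^-1)
    k_Mp73ass      = 0.03,    # MITFp73/PIAS3 association (au^-1 min^-1)
    k_Mp73diss     = 0.5,     # MITFp73/PIAS3 dissociation (min^-1)
    k_Mp409ass     = 0.0001,  # MITFp409/PIAS3 association (au^-1 min^-1)
    k_Mp409diss    = 1,       # MITFp409/PIAS3 dissociation (min^-1)
    k_Mppass       = 0.01,    # MITFpp/PIAS3 association (au^-1 min^-1)
    k_Mppdiss      = 1,       # MITFpp/PIAS3 dissociation (min^-1)
    k_Sp_plus      = 0.0002,  # STAT3 phosphorylation by JAKp (au^-1 min^-1)
    k_Sp_minus     = 0.04,    # STAT3 de-phosphorylation (min^-1)
    k_Spass        = 0.005,   # STAT3p/PIAS3 association (au^-1 min^-1)
    k_Spdiss       = 0.2,     # STAT3p/PIAS3 dissociation (min^-1)
    p_MITF         = 1,       # MITF production (au min^-1)
    gamma_MITF     = 0.0012,  # MITF degradation (min^-1)
    gamma_MITFp73  = 0.02,    # MITFp73 degradation, applies to ubiquitinated share (min^-1)
    gamma_MITFp409 = 0.01,    # MITFp409 degradation (min^-1)
    p_PIAS3        = if (dialect == "methods") 1.262 else 0.262,
    gamma_PIAS3    = 0.008,   # PIAS3 degradation (min^-1)
    p_STAT3        = 0.211,   # STAT3 production (au min^-1)
    gamma_STAT3    = 0.002,   # STAT3 degradation (min^-1)
    k_Rp_plus      = 0.0004,  # RSK1 phosphorylation by ERKp (au^-1 min^-1)
    k_Rp_minus     = 0.04,    # RSK1 de-phosphorylation (min^-1)
    ERKp_baseline  = 10,      # resting phosphorylated ERK level (au)
    JAKp_baseline  = 10,      # resting phosphorylated JAK level (au)
    k_u            = 0.0001,  # ubiquitination of S73-phosphorylated MITF (au^-1 min^-1)
    RSK1_total     = 500      # fixed total RSK1 pool (au)
  )
  structure(p, class = "pias3net_params", dialect = dialect)
}

#' Validate a parameter vector
#'
#' @param params Named numeric vector carrying at least the 30 core
#'   constants and `RSK1_total`.
#' @return `params`, invisibly, after checking names and non-negativity.
#' @keywords internal
validate_parameters <- function(params) {
  required <- c(core_parameter_names(), "RSK1_total")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.numeric(params[required])
  if (anyNA(vals)) stop("parameters contain NA", call. = FALSE)
  if (any(vals < 0)) {
    bad <- required[vals < 0]
    stop("negative parameters: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

#' Apply named overrides to a parameter vector
#'
#' Overrides are absolute values (not factors).  Unknown names are an
#' error, with a suggestion for the closest valid name.
#'
#' @param params Parameter vector as from [default_parameters()].
#' @param overrides Named numeric vector or list of replacement values.
#' @return Modified parameter vector.
#' @export
override_parameters <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  overrides <- unlist(overrides)
  valid <- c(core_parameter_names(), "RSK1_total")
  unknown <- setdiff(names(overrides), valid)
  if (length(unknown) > 0) {
    hint <- vapply(unknown, closest_name, character(1), candidates = valid)
    stop("unknown parameter(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, hint), collapse = ", "),
         call. = FALSE)
  }
  params[names(overrides)] <- overrides
  params
}

# Nearest valid key by edit distance, used for error messages.
closest_name <- function(x, candidates) {
  candidates[which.min(utils::adist(x, candidates, ignore.case = TRUE))]
}

#' Degradation rate of a binary protein complex
#'
#' Proteins are stabilized in complex: the complex degrades at 20% of the
#' mean of its constituents' free degradation rates, i.e.
#' `(gamma_a + gamma_b) / 10`.
#'
#' @param gamma_a,gamma_b Non-negative degradation rates (min^-1).
#' @return The complex degradation rate (min^-1).
#' @examples
#' complex_degradation_rate(0.0012, 0.008)  # MITF/PIAS3 complex: 0.00092
#' @export
complex_degradation_rate <- function(gamma_a, gamma_b) {
  if (any(gamma_a < 0) || any(gamma_b < 0)) {
    stop("degradation rates must be non-negative", call. = FALSE)
  }
  (gamma_a + gamma_b) / 10
}

#' Write a parameter set to a flat key-value file
#'
#' @param params Parameter vector.
#' @param path Output path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  vals <- as.list(as.numeric(params[c(core_parameter_names(), "RSK1_total")]))
  names(vals) <- c(core_parameter_names(), "RSK1_total")
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a parameter set from a flat key-value file
#'
#' @param path Path to a JSON or YAML file as written by
#'   [write_parameters()].
#' @return Named numeric vector of class `"pias3net_params"`.
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  p <- unlist(vals)
  validate_parameters(p)
  structure(p[c(core_parameter_names(), "RSK1_total")], class = "pias3net_params")
}
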