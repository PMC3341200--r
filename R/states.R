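# Model state: 14 molecular species plus the shared ubiquitination
# fraction R of S73-phosphorylated MITF.

#' Names of the model state variables
#'
#' Fourteen species amounts (au) followed by `R`, the dimensionless
#' fraction of S73-phosphorylated MITF (free and PIAS3-bound) that is
#' ubiquitin-tagged.  Complexes are named inhibitor-first with an
#' underscore (`PIAS3_MITFp73` is the PIAS3-bound, S73-phosphorylated
#' MITF).
#'
#' @return Character vector of length 15.
#' @export
state_names <- function() {
  c("MITF", "MITFp73", "MITFp409", "MITFpp",
    "PIAS3",
    "PIAS3_MITF", "PIAS3_MITFp73", "PIAS3_MITFp409", "PIAS3_MITFpp",
    "RSK1", "RSK1p",
    "STAT3", "STAT3p", "PIAS3_STAT3p",
    "R")
}

# Species grouped by protein content; used for conservation checks and
# experiment readouts.
mitf_free_states    <- function() c("MITF", "MITFp73", "MITFp409", "MITFpp")
mitf_complex_states <- function() c("PIAS3_MITF", "PIAS3_MITFp73",
                                    "PIAS3_MITFp409", "PIAS3_MITFpp")
mitf_states         <- function() c(mitf_free_states(), mitf_complex_states())
pias3_states        <- function() c("PIAS3", mitf_complex_states(), "PIAS3_STAT3p")
stat3_states        <- function() c("STAT3", "STAT3p", "PIAS3_STAT3p")

#' A minimal admissible initial state
#'
#' All protein pools empty except the RSK1 cycle, which holds the fixed
#' total in un-phosphorylated form; `R = 0`.  Long integration from this
#' state is how resting steady states are found.
#'
#' @param params Parameter vector (supplies `RSK1_total`).
#' @return Named numeric state vector of length 15.
#' @export
empty_state <- function(params = default_parameters()) {
  s <- stats::setNames(numeric(15), state_names())
  s[["RSK1"]] <- as.numeric(params[["RSK1_total"]])
  s
}

#' Validate a model state vector
#' @param state Named numeric vector over [state_names()].
#' @return `state`, invisibly.
#' @keywords internal
validate_state <- function(state) {
  missing <- setdiff(state_names(), names(state))
  if (length(missing) > 0) {
    stop("missing state variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(state[state_names()])) stop("state contains NA", call. = FALSE)
  invisible(state)
}

#' Rescale the RSK1 pool to a new fixed total
#'
#' The RSK1 total is conserved by the dynamics, so experiments that
#' overexpress RSK1 change the pool size directly.  Both phosphoforms are
#' scaled proportionally, preserving the current phosphorylated fraction.
#'
#' @param state State vector.
#' @param total New total RSK1 amount (au).
#' @return Modified state vector.
#' @export
set_rsk1_total <- function(state, total) {
  stopifnot(total >= 0)
  cur <- state[["RSK1"]] + state[["RSK1p"]]
  if (cur > 0) {
    f <- state[["RSK1p"]] / cur
  } else {
    f <- 0
  }
  state[["RSK1"]] <- total * (1 - f)
  state[["RSK1p"]] <- total * f
  state
}
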