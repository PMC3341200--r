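# Transcriptional-activity readouts: the quantities that stand in for
# luciferase / target-gene measurements in the virtual experiments.

#' Weights of the MITF transcriptional-activity score
#'
#' MITF activity is approximated by a weighted sum over the four free
#' phosphoforms plus an offset.  The weights were calibrated against
#' reporter measurements of MITF phosphosite mutants; the offset keeps
#' the score positive over the regimes studied here.
#'
#' @param A0 Offset (default 10).
#' @param A_M,A_M73,A_M409,A_Mpp Weights of free un-phosphorylated,
#'   S73-, S409- and doubly phosphorylated MITF.
#' @return Named numeric vector of length 5, class
#'   `"pias3net_weights"`.
#' @export
activity_weights <- function(A0 = 10, A_M = -0.11, A_M73 = 0.44,
                             A_M409 = 0.11, A_Mpp = 0.56) {
  structure(c(A0 = A0, A_M = A_M, A_M73 = A_M73,
              A_M409 = A_M409, A_Mpp = A_Mpp),
            class = "pias3net_weights")
}

#' MITF transcriptional activity
#'
#' `A0 + A_M [MITF] + A_M73 [MITFp73] + A_M409 [MITFp409] + A_Mpp [MITFpp]`,
#' over the free (non-PIAS3-bound) species only: complexed MITF cannot
#' bind DNA.  The score is linear in each species and can in principle
#' go negative (the un-phosphorylated weight is negative); values are
#' returned as computed.
#'
#' @param state Named state vector, or a matrix/data frame with columns
#'   `MITF`, `MITFp73`, `MITFp409`, `MITFpp` (e.g. a trajectory).
#' @param weights Weights from [activity_weights()].
#' @return Activity score(s), one per state row.
#' @examples
#' mitf_activity(c(MITF = 0, MITFp73 = 100, MITFp409 = 0, MITFpp = 0))  # 54
#' @export
mitf_activity <- function(state, weights = activity_weights()) {
  if (is.null(dim(state))) {
    weights[["A0"]] +
      weights[["A_M"]] * state[["MITF"]] +
      weights[["A_M73"]] * state[["MITFp73"]] +
      weights[["A_M409"]] * state[["MITFp409"]] +
      weights[["A_Mpp"]] * state[["MITFpp"]]
  } else {
    weights[["A0"]] +
      weights[["A_M"]] * state[, "MITF"] +
      weights[["A_M73"]] * state[, "MITFp73"] +
      weights[["A_M409"]] * state[, "MITFp409"] +
      weights[["A_Mpp"]] * state[, "MITFpp"]
  }
}

#' STAT3 transcriptional activity
#'
#' The amount of free phosphorylated STAT3.  PIAS3-bound STAT3p is
#' transcriptionally inert and excluded.
#'
#' @param state Named state vector, or a matrix/data frame with a
#'   `STAT3p` column.
#' @return Activity score(s).
#' @export
stat3_activity <- function(state) {
  if (is.null(dim(state))) state[["STAT3p"]] else state[, "STAT3p"]
}
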