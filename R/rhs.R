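# Right-hand side of the ODE system, in R.  A compiled C version of the
# same equations (src/rhs.c) is what simulate_model() integrates by
# default; this R version is the readable reference and the one unit
# tests interrogate directly.

#' Ubiquitination-fraction dynamics
#'
#' The fraction `R` of S73-phosphorylated MITF that is ubiquitin-tagged
#' evolves by three processes: (i) ubiquitination of un-tagged MITF,
#' catalysed by phosphorylated ERK; (ii) preferential loss of tagged MITF
#' to degradation, which depletes the tagged share; and (iii) influx of
#' newly produced, un-tagged MITF, which dilutes it.  The depletion term
#' is implemented in a singularity-free algebraic form,
#' `-gamma_MITFp73 * a * R * (1 - R) / (1 - R * gamma_MITFp73 * a)`,
#' which agrees with the published one-minute-turnover derivation for
#' `R > 0` and is regular at `R = 0`.  The dilution factor `A` is the
#' share of the S73-phosphorylated pool that survives one minute of
#' production influx; it is clamped to `[0, 1]`, and defined as 1 (no
#' dilution) when its denominator is non-positive.
#'
#' @param state Named state vector (uses `MITFp73`, `MITFpp`, `MITFp409`,
#'   `R`).
#' @param params Parameter vector.
#' @param erkp Current phosphorylated ERK level (au).
#' @return List with components `term_i`, `term_ii`, `term_iii` (min^-1),
#'   the dilution ratio `A`, the S73-phosphorylated pool `B` (au), and
#'   `dR = term_i + term_ii + term_iii`.
#' @export
ubiquitination_terms <- function(state, params, erkp) {
  R   <- state[["R"]]
  g73 <- params[["gamma_MITFp73"]]
  a   <- 1  # minutes; unit carrier of the one-minute turnover derivation
  if (R < -1e-8 || R > 1 + 1e-8) stop("R must lie in [0, 1]", call. = FALSE)
  R <- min(1, max(0, R))  # absorb solver round-off at the boundary

  term_i <- (1 - R) * erkp * params[["k_u"]]

  # depletion of the tagged share by its faster degradation
  term_ii <- -g73 * a * R * (1 - R) / (1 - R * g73 * a)

  # dilution by production of new, un-tagged MITF
  B <- state[["MITFp73"]] + state[["MITFpp"]]
  influx <- params[["p_MITF"]] - state[["MITFp409"]] * params[["gamma_MITFp409"]]
  denom <- B + influx * a
  if (denom <= 0) {
    A <- 1
  } else {
    A <- min(1, max(0, B / denom))
  }
  term_iii <- -(R - R * A) / a

  list(term_i = term_i, term_ii = term_ii, term_iii = term_iii,
       A = A, B = B, dR = term_i + term_ii + term_iii)
}

#' Time-derivatives of the model state
#'
#' Mass-action assembly of the reaction scheme: ERK-driven and
#' auto-phosphorylation of MITF at S73, RSK1p-driven phosphorylation at
#' S409 (with the RSK1 cycle itself driven by ERKp), reversible binding
#' of each MITF phosphoform and of phosphorylated STAT3 to PIAS3,
#' JAK-driven STAT3 phosphorylation, constant production and first-order
#' degradation of MITF, PIAS3 and STAT3.  Degradation of
#' S73-phosphorylated MITF (free or in complex) applies only to the
#' ubiquitinated share `R`; complexes degrade at 20% of the mean of their
#' constituents' rates (see [complex_degradation_rate()]).
#'
#' @param t Time (minutes); unused, the system is autonomous between
#'   input changes.
#' @param state Named state vector over [state_names()].
#' @param params Parameter vector.
#' @param erkp,jakp Phosphorylated ERK and JAK levels (au).  Default to
#'   the baselines carried in `params`.
#' @return Named numeric vector of the 15 time-derivatives.
#' @export
model_rhs <- function(t, state, params,
                      erkp = params[["ERKp_baseline"]],
                      jakp = params[["JAKp_baseline"]]) {
  s <- state
  p <- params
  Rr <- s[["R"]]

  gMP   <- complex_degradation_rate(p[["gamma_MITF"]],    p[["gamma_PIAS3"]])
  g73P  <- complex_degradation_rate(p[["gamma_MITFp73"]], p[["gamma_PIAS3"]])
  g409P <- complex_degradation_rate(p[["gamma_MITFp409"]], p[["gamma_PIAS3"]])
  gSP   <- complex_degradation_rate(p[["gamma_STAT3"]],   p[["gamma_PIAS3"]])

  d <- stats::setNames(numeric(15), state_names())

  d[["MITF"]] <- p[["p_MITF"]] -
    p[["k_Mp73E_plus"]] * s[["MITF"]] * erkp -
    p[["k_Mp73a_plus"]] * s[["MITF"]] +
    p[["k_Mp73_minus"]] * s[["MITFp73"]] -
    p[["k_Mp409_plus"]] * s[["MITF"]] * s[["RSK1p"]] +
    p[["k_Mp409_minus"]] * s[["MITFp409"]] -
    p[["k_Mass"]] * s[["MITF"]] * s[["PIAS3"]] +
    p[["k_Mdiss"]] * s[["PIAS3_MITF"]] -
    p[["gamma_MITF"]] * s[["MITF"]]

  d[["MITFp73"]] <-
    p[["k_Mp73E_plus"]] * erkp * s[["MITF"]] +
    p[["k_Mp73a_plus"]] * s[["MITF"]] -
    p[["k_Mp73_minus"]] * s[["MITFp73"]] -
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["MITFp73"]] +
    p[["k_Mp409_minus"]] * s[["MITFpp"]] -
    p[["k_Mp73ass"]] * s[["MITFp73"]] * s[["PIAS3"]] +
    p[["k_Mp73diss"]] * s[["PIAS3_MITFp73"]] -
    p[["gamma_MITFp73"]] * Rr * s[["MITFp73"]]

  d[["MITFp409"]] <-
    -p[["k_Mp73E_plus"]] * erkp * s[["MITFp409"]] -
    p[["k_Mp73a_plus"]] * s[["MITFp409"]] +
    p[["k_Mp73_minus"]] * s[["MITFpp"]] +
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["MITF"]] -
    p[["k_Mp409_minus"]] * s[["MITFp409"]] -
    p[["k_Mp409ass"]] * s[["MITFp409"]] * s[["PIAS3"]] +
    p[["k_Mp409diss"]] * s[["PIAS3_MITFp409"]] -
    p[["gamma_MITFp409"]] * s[["MITFp409"]]

  d[["MITFpp"]] <-
    p[["k_Mp73E_plus"]] * erkp * s[["MITFp409"]] +
    p[["k_Mp73a_plus"]] * s[["MITFp409"]] -
    p[["k_Mp73_minus"]] * s[["MITFpp"]] +
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["MITFp73"]] -
    p[["k_Mp409_minus"]] * s[["MITFpp"]] -
    p[["k_Mppass"]] * s[["MITFpp"]] * s[["PIAS3"]] +
    p[["k_Mppdiss"]] * s[["PIAS3_MITFpp"]] -
    p[["gamma_MITFp73"]] * Rr * s[["MITFpp"]] -
    p[["gamma_MITFp409"]] * s[["MITFpp"]]

  d[["PIAS3"]] <- p[["p_PIAS3"]] -
    p[["k_Mass"]] * s[["PIAS3"]] * s[["MITF"]] +
    p[["k_Mdiss"]] * s[["PIAS3_MITF"]] -
    p[["k_Mp73ass"]] * s[["PIAS3"]] * s[["MITFp73"]] +
    p[["k_Mp73diss"]] * s[["PIAS3_MITFp73"]] -
    p[["k_Mp409ass"]] * s[["PIAS3"]] * s[["MITFp409"]] +
    p[["k_Mp409diss"]] * s[["PIAS3_MITFp409"]] -
    p[["k_Mppass"]] * s[["PIAS3"]] * s[["MITFpp"]] +
    p[["k_Mppdiss"]] * s[["PIAS3_MITFpp"]] -
    p[["k_Spass"]] * s[["PIAS3"]] * s[["STAT3p"]] +
    p[["k_Spdiss"]] * s[["PIAS3_STAT3p"]] -
    p[["gamma_PIAS3"]] * s[["PIAS3"]]

  d[["PIAS3_MITF"]] <-
    -p[["k_Mp73E_plus"]] * erkp * s[["PIAS3_MITF"]] +
    p[["k_Mp73_minus"]] * s[["PIAS3_MITFp73"]] -
    p[["k_Mp73a_plus"]] * s[["PIAS3_MITF"]] -
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["PIAS3_MITF"]] +
    p[["k_Mp409_minus"]] * s[["PIAS3_MITFp409"]] +
    p[["k_Mass"]] * s[["MITF"]] * s[["PIAS3"]] -
    p[["k_Mdiss"]] * s[["PIAS3_MITF"]] -
    gMP * s[["PIAS3_MITF"]]

  d[["PIAS3_MITFp73"]] <-
    p[["k_Mp73E_plus"]] * erkp * s[["PIAS3_MITF"]] -
    p[["k_Mp73_minus"]] * s[["PIAS3_MITFp73"]] +
    p[["k_Mp73a_plus"]] * s[["PIAS3_MITF"]] -
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["PIAS3_MITFp73"]] +
    p[["k_Mp409_minus"]] * s[["PIAS3_MITFpp"]] +
    p[["k_Mp73ass"]] * s[["MITFp73"]] * s[["PIAS3"]] -
    p[["k_Mp73diss"]] * s[["PIAS3_MITFp73"]] -
    g73P * Rr * s[["PIAS3_MITFp73"]]

  d[["PIAS3_MITFp409"]] <-
    -p[["k_Mp73E_plus"]] * erkp * s[["PIAS3_MITFp409"]] +
    p[["k_Mp73_minus"]] * s[["PIAS3_MITFpp"]] -
    p[["k_Mp73a_plus"]] * s[["PIAS3_MITFp409"]] +
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["PIAS3_MITF"]] -
    p[["k_Mp409_minus"]] * s[["PIAS3_MITFp409"]] +
    p[["k_Mp409ass"]] * s[["MITFp409"]] * s[["PIAS3"]] -
    p[["k_Mp409diss"]] * s[["PIAS3_MITFp409"]] -
    g409P * s[["PIAS3_MITFp409"]]

  d[["PIAS3_MITFpp"]] <-
    p[["k_Mp73E_plus"]] * erkp * s[["PIAS3_MITFp409"]] -
    p[["k_Mp73_minus"]] * s[["PIAS3_MITFpp"]] +
    p[["k_Mp73a_plus"]] * s[["PIAS3_MITFp409"]] +
    p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[["PIAS3_MITFp73"]] -
    p[["k_Mp409_minus"]] * s[["PIAS3_MITFpp"]] +
    p[["k_Mppass"]] * s[["MITFpp"]] * s[["PIAS3"]] -
    p[["k_Mppdiss"]] * s[["PIAS3_MITFpp"]] -
    g73P * Rr * s[["PIAS3_MITFpp"]] -
    g409P * s[["PIAS3_MITFpp"]]

  d[["RSK1"]] <- -p[["k_Rp_plus"]] * s[["RSK1"]] * erkp +
    p[["k_Rp_minus"]] * s[["RSK1p"]]
  d[["RSK1p"]] <- -d[["RSK1"]]

  d[["STAT3"]] <- p[["p_STAT3"]] -
    p[["k_Sp_plus"]] * jakp * s[["STAT3"]] +
    p[["k_Sp_minus"]] * s[["STAT3p"]] -
    p[["gamma_STAT3"]] * s[["STAT3"]]

  d[["STAT3p"]] <-
    p[["k_Sp_plus"]] * jakp * s[["STAT3"]] -
    p[["k_Sp_minus"]] * s[["STAT3p"]] -
    p[["k_Spass"]] * s[["STAT3p"]] * s[["PIAS3"]] +
    p[["k_Spdiss"]] * s[["PIAS3_STAT3p"]] -
    p[["gamma_STAT3"]] * s[["STAT3p"]]

  d[["PIAS3_STAT3p"]] <-
    p[["k_Spass"]] * s[["STAT3p"]] * s[["PIAS3"]] -
    p[["k_Spdiss"]] * s[["PIAS3_STAT3p"]] -
    gSP * s[["PIAS3_STAT3p"]]

  d[["R"]] <- ubiquitination_terms(s, p, erkp)$dR

  d
}
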