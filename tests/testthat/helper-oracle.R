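# Independent oracles used by the unit tests.
#
# The stoichiometry oracle assembles the species derivatives as S %*% v
# from the reaction scheme (one row per species, one column per
# unidirectional reaction), written down independently of the ODE
# transcription in model_rhs().  The ubiquitination oracle evaluates the
# published one-minute-turnover ratio forms literally (valid for R > 0).

oracle_species <- c("MITF", "MITFp73", "MITFp409", "MITFpp", "PIAS3",
                    "PIAS3_MITF", "PIAS3_MITFp73", "PIAS3_MITFp409",
                    "PIAS3_MITFpp", "RSK1", "RSK1p", "STAT3", "STAT3p",
                    "PIAS3_STAT3p")

# reaction list: each entry gives the net species changes and a rate
# function of (state, params, erkp, jakp)
oracle_reactions <- function() {
  rx <- list()
  add <- function(change, rate) rx[[length(rx) + 1]] <<- list(change = change,
                                                             rate = rate)
  # RSK1 cycle
  add(c(RSK1 = -1, RSK1p = 1),
      function(s, p, e, j) p[["k_Rp_plus"]] * s[["RSK1"]] * e)
  add(c(RSK1 = 1, RSK1p = -1),
      function(s, p, e, j) p[["k_Rp_minus"]] * s[["RSK1p"]])
  # S73 phosphorylation (ERK-catalysed) and de-phosphorylation, on the
  # four S73-capable substrates (free and PIAS3-bound)
  s73 <- list(c("MITF", "MITFp73"), c("MITFp409", "MITFpp"),
              c("PIAS3_MITF", "PIAS3_MITFp73"),
              c("PIAS3_MITFp409", "PIAS3_MITFpp"))
  for (pair in s73) {
    local({
      from <- pair[1]; to <- pair[2]
      add(stats::setNames(c(-1, 1), c(from, to)),
          function(s, p, e, j) p[["k_Mp73E_plus"]] * e * s[[from]])
      add(stats::setNames(c(1, -1), c(from, to)),
          function(s, p, e, j) p[["k_Mp73_minus"]] * s[[to]])
      # auto-phosphorylation, same substrates
      add(stats::setNames(c(-1, 1), c(from, to)),
          function(s, p, e, j) p[["k_Mp73a_plus"]] * s[[from]])
    })
  }
  # S409 phosphorylation (RSK1p-catalysed) and de-phosphorylation
  s409 <- list(c("MITF", "MITFp409"), c("MITFp73", "MITFpp"),
               c("PIAS3_MITF", "PIAS3_MITFp409"),
               c("PIAS3_MITFp73", "PIAS3_MITFpp"))
  for (pair in s409) {
    local({
      from <- pair[1]; to <- pair[2]
      add(stats::setNames(c(-1, 1), c(from, to)),
          function(s, p, e, j) p[["k_Mp409_plus"]] * s[["RSK1p"]] * s[[from]])
      add(stats::setNames(c(1, -1), c(from, to)),
          function(s, p, e, j) p[["k_Mp409_minus"]] * s[[to]])
    })
  }
  # PIAS3 binding equilibria
  bind <- list(list("MITF", "PIAS3_MITF", "k_Mass", "k_Mdiss"),
               list("MITFp73", "PIAS3_MITFp73", "k_Mp73ass", "k_Mp73diss"),
               list("MITFp409", "PIAS3_MITFp409", "k_Mp409ass", "k_Mp409diss"),
               list("MITFpp", "PIAS3_MITFpp", "k_Mppass", "k_Mppdiss"),
               list("STAT3p", "PIAS3_STAT3p", "k_Spass", "k_Spdiss"))
  for (b in bind) {
    local({
      free <- b[[1]]; cplx <- b[[2]]; ka <- b[[3]]; kd <- b[[4]]
      add(stats::setNames(c(-1, -1, 1), c(free, "PIAS3", cplx)),
          function(s, p, e, j) p[[ka]] * s[[free]] * s[["PIAS3"]])
      add(stats::setNames(c(1, 1, -1), c(free, "PIAS3", cplx)),
          function(s, p, e, j) p[[kd]] * s[[cplx]])
    })
  }
  # STAT3 phosphorylation cycle
  add(c(STAT3 = -1, STAT3p = 1),
      function(s, p, e, j) p[["k_Sp_plus"]] * j * s[["STAT3"]])
  add(c(STAT3 = 1, STAT3p = -1),
      function(s, p, e, j) p[["k_Sp_minus"]] * s[["STAT3p"]])
  # production
  add(c(MITF = 1), function(s, p, e, j) p[["p_MITF"]])
  add(c(PIAS3 = 1), function(s, p, e, j) p[["p_PIAS3"]])
  add(c(STAT3 = 1), function(s, p, e, j) p[["p_STAT3"]])
  # degradation; S73-phosphorylated species only via the ubiquitinated
  # share R, complexes at 20% of the constituents' mean
  cdr <- function(p, a, b) (p[[a]] + p[[b]]) / 10
  add(c(MITF = -1), function(s, p, e, j) p[["gamma_MITF"]] * s[["MITF"]])
  add(c(MITFp73 = -1),
      function(s, p, e, j) p[["gamma_MITFp73"]] * s[["R"]] * s[["MITFp73"]])
  add(c(MITFp409 = -1),
      function(s, p, e, j) p[["gamma_MITFp409"]] * s[["MITFp409"]])
  add(c(MITFpp = -1),
      function(s, p, e, j) p[["gamma_MITFp73"]] * s[["R"]] * s[["MITFpp"]])
  add(c(MITFpp = -1),
      function(s, p, e, j) p[["gamma_MITFp409"]] * s[["MITFpp"]])
  add(c(PIAS3 = -1), function(s, p, e, j) p[["gamma_PIAS3"]] * s[["PIAS3"]])
  add(c(PIAS3_MITF = -1),
      function(s, p, e, j) cdr(p, "gamma_MITF", "gamma_PIAS3") * s[["PIAS3_MITF"]])
  add(c(PIAS3_MITFp73 = -1),
      function(s, p, e, j) cdr(p, "gamma_MITFp73", "gamma_PIAS3") * s[["R"]] *
        s[["PIAS3_MITFp73"]])
  add(c(PIAS3_MITFp409 = -1),
      function(s, p, e, j) cdr(p, "gamma_MITFp409", "gamma_PIAS3") *
        s[["PIAS3_MITFp409"]])
  add(c(PIAS3_MITFpp = -1),
      function(s, p, e, j) cdr(p, "gamma_MITFp73", "gamma_PIAS3") * s[["R"]] *
        s[["PIAS3_MITFpp"]])
  add(c(PIAS3_MITFpp = -1),
      function(s, p, e, j) cdr(p, "gamma_MITFp409", "gamma_PIAS3") *
        s[["PIAS3_MITFpp"]])
  add(c(STAT3 = -1), function(s, p, e, j) p[["gamma_STAT3"]] * s[["STAT3"]])
  add(c(STAT3p = -1), function(s, p, e, j) p[["gamma_STAT3"]] * s[["STAT3p"]])
  add(c(PIAS3_STAT3p = -1),
      function(s, p, e, j) cdr(p, "gamma_STAT3", "gamma_PIAS3") *
        s[["PIAS3_STAT3p"]])
  rx
}

# species derivatives as stoichiometry x rate-law vector
oracle_rhs_species <- function(state, params, erkp, jakp) {
  rx <- oracle_reactions()
  d <- stats::setNames(numeric(length(oracle_species)), oracle_species)
  for (r in rx) {
    v <- r$rate(state, params, erkp, jakp)
    d[names(r$change)] <- d[names(r$change)] + r$change * v
  }
  d
}

# literal evaluation of the published ubiquitination-ratio forms
# (requires R > 0 and a positive dilution denominator)
oracle_dR_literal <- function(state, params, erkp) {
  R <- state[["R"]]
  g73 <- params[["gamma_MITFp73"]]
  a <- 1
  term_i <- (1 - R) * erkp * params[["k_u"]]
  Rprime <- (1 - g73 * a) / (1 / R - g73 * a)
  term_ii <- -(R - Rprime) / a
  B <- state[["MITFp73"]] + state[["MITFpp"]]
  den <- B + (params[["p_MITF"]] - state[["MITFp409"]] * params[["gamma_MITFp409"]]) * a
  Rpp <- R * B / den
  term_iii <- -(R - Rpp) / a
  term_i + term_ii + term_iii
}

# random admissible state for property tests
random_state <- function(scale = 100) {
  s <- stats::setNames(stats::runif(15, 0, scale), state_names())
  s[["R"]] <- stats::runif(1)
  s
}

# random parameter perturbation within a factor range of the defaults
perturbed_parameters <- function(params, which = core_parameter_names(),
                                 range = c(0.5, 2)) {
  f <- exp(stats::runif(length(which), log(range[1]), log(range[2])))
  params[which] <- as.numeric(params[which]) * f
  params
}
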