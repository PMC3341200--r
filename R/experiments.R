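# The virtual-experiment harness: 28 published wet-lab experiments
# formalized as data (perturbations, schedules, readouts, boolean
# success criteria), plus the machinery to run and score them.
#
# A condition is one simulated cell population: an optional equilibration
# setting (parameter overrides and input levels used to find the
# pre-protocol resting steady state), optional initial-state edits, and a
# list of phases, each a (duration, parameter overrides, input levels)
# record.  Readouts name a condition, a quantity and an absolute time;
# criteria are conjunctions of window / ratio / ordering clauses over the
# readouts.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- quantities -----------------------------------------------------------

#' Derived readout quantities of a trajectory
#'
#' In addition to the raw state variables, experiments read: `mitf_total`
#' (all eight MITF-containing species), `mitf_phospho_fraction` and
#' `mitf_unphospho_fraction` (share of total MITF, free and complexed, in
#' phosphorylated resp. un-phosphorylated states), `mitf_complex_total`
#' (the four MITF-PIAS3 complexes), `mitf_activity` and `stat3_activity`.
#'
#' @param traj Trajectory (or any data frame with the state columns).
#' @param quantity Quantity name: a state variable or one of the derived
#'   names above.
#' @return Numeric vector, one value per trajectory row.
#' @export
quantity_series <- function(traj, quantity) {
  tot <- function() rowSums(as.data.frame(traj)[mitf_states()])
  switch(quantity,
    mitf_total = tot(),
    mitf_complex_total = rowSums(as.data.frame(traj)[mitf_complex_states()]),
    mitf_phospho_fraction = 1 - (traj$MITF + traj$PIAS3_MITF) / tot(),
    mitf_unphospho_fraction = (traj$MITF + traj$PIAS3_MITF) / tot(),
    mitf_activity = traj$MITF_activity,
    stat3_activity = traj$STAT3_activity,
    {
      if (!quantity %in% names(traj)) {
        stop("unknown quantity: ", quantity, call. = FALSE)
      }
      traj[[quantity]]
    })
}

# ---- catalog --------------------------------------------------------------

new_experiment <- function(id, description, conditions, readouts, criterion) {
  structure(list(id = id, description = description,
                 conditions = conditions, readouts = readouts,
                 criterion = criterion),
            class = "pias3net_experiment")
}

phase <- function(duration, params = NULL, erkp = NULL, jakp = NULL) {
  stopifnot(duration > 0)
  list(duration = duration, params = params, erkp = erkp, jakp = jakp)
}

condition <- function(phases = list(), ss = NULL, init = NULL) {
  list(ss = ss, init = init, phases = phases)
}

readout <- function(condition, quantity, time) {
  list(condition = condition, quantity = quantity, time = time)
}

# clause constructors; all comparisons are inclusive
cl_window <- function(readout, lo, hi, what = NULL) {
  list(type = "window", readout = readout, lo = lo, hi = hi,
       what = what %||% sprintf("%s in [%g, %g]", readout, lo, hi))
}
cl_ratio <- function(num, den, lo, hi, what = NULL) {
  list(type = "ratio", num = num, den = den, lo = lo, hi = hi,
       what = what %||% sprintf("%s/%s in [%g, %g]", num, den, lo, hi))
}
# ordering clauses are strict: "higher than" never passes on equality,
# so degenerate all-zero readouts fail as they should
cl_ge <- function(a, b, factor = 1, what = NULL) {
  list(type = "ge", a = a, b = b, factor = factor,
       what = what %||% sprintf("%s > %g * %s", a, factor, b))
}
cl_le <- function(a, b, factor = 1, what = NULL) {
  list(type = "le", a = a, b = b, factor = factor,
       what = what %||% sprintf("%s < %g * %s", a, factor, b))
}
cl_t90 <- function(condition, quantity, frac, lo, hi, what = NULL) {
  list(type = "t90", condition = condition, quantity = quantity,
       frac = frac, lo = lo, hi = hi,
       what = what %||% sprintf("time to %g%% of max %s in [%g, %g] min",
                                100 * frac, quantity, lo, hi))
}
cl_true <- function() list(type = "true", what = "always true")

#' The catalog of 28 formalized experiments
#'
#' Each entry encodes one published wet-lab experiment as parameter /
#' input / initial-state perturbations on top of the default model,
#' together with its printed success criterion.  Transfections are
#' modelled as elevated production rates (or, for RSK1, an enlarged fixed
#' pool), receptor activation as steps in the ERKp/JAKp inputs, and point
#' mutants as edits to the affected rate constants.  Unless an entry says
#' otherwise, a condition starts from the resting steady state at
#' baseline inputs.  Replicate series (#9-#12 and #19-#24) are built from
#' one shared base perturbation each.
#'
#' @return Named list of 28 `"pias3net_experiment"` specs, names `"1"`
#'   to `"28"`.
#' @export
experiment_catalog <- function() {
  specs <- list()

  specs[["1"]] <- new_experiment(
    1, "RSK1 phosphorylation kinetics after MAPK activation",
    conditions = list(act = condition(list(phase(60, erkp = 1000)))),
    readouts = list(),
    criterion = list(cl_t90("act", "RSK1p", 0.9, 3, 10)))

  specs[["2"]] <- new_experiment(
    2, "MITF phosphoform balance in growing (ERKp = 80) culture",
    conditions = list(ss = condition(ss = list(erkp = 80))),
    readouts = list(
      phos = readout("ss", "mitf_phospho_fraction", 0),
      unphos = readout("ss", "mitf_unphospho_fraction", 0)),
    criterion = list(cl_window("phos", 0.25, 0.75),
                     cl_window("unphos", 0.25, 0.75)))

  specs[["3"]] <- new_experiment(
    3, "MITF phosphorylation 30 min after full activation",
    conditions = list(act = condition(list(phase(30, erkp = 1000, jakp = 1000)))),
    readouts = list(ph30 = readout("act", "mitf_phospho_fraction", 30)),
    criterion = list(cl_window("ph30", 0.8, 1)))

  specs[["4"]] <- new_experiment(
    4, "MITF degradation time course under strong activation",
    conditions = list(act = condition(list(phase(300, erkp = 950, jakp = 950)))),
    readouts = list(
      tot0 = readout("act", "mitf_total", 0),
      tot60 = readout("act", "mitf_total", 60),
      tot300 = readout("act", "mitf_total", 300)),
    criterion = list(
      cl_ratio("tot60", "tot0", 0.5, Inf, "less than 50% degraded at 1 h"),
      cl_ratio("tot300", "tot0", 0, 1 / 3, "at least 2/3 degraded at 5 h")))

  pias3_doses <- c(p05 = 0.5, p1 = 1, p2 = 2, p4 = 4)
  specs[["5"]] <- new_experiment(
    5, "MITF activity under graded PIAS3 co-transfection",
    conditions = lapply(pias3_doses, function(dose) {
      condition(list(phase(2880, params = list(p_MITF = 18, p_PIAS3 = dose))))
    }),
    readouts = stats::setNames(
      lapply(names(pias3_doses), function(nm) readout(nm, "mitf_activity", 2880)),
      paste0("f_", names(pias3_doses))),
    criterion = list(
      cl_ge("f_p05", "f_p1"), cl_ge("f_p1", "f_p2"), cl_ge("f_p2", "f_p4"),
      cl_ratio("f_p4", "f_p05", 0, 0.5, "highest dose below half of lowest")))

  specs[["6"]] <- new_experiment(
    6, "MITF-PIAS3 complex kinetics after activation (endogenous levels)",
    conditions = list(act = condition(list(phase(30, erkp = 500, jakp = 50)))),
    readouts = list(
      c0 = readout("act", "mitf_complex_total", 0),
      c10 = readout("act", "mitf_complex_total", 10),
      c30 = readout("act", "mitf_complex_total", 30)),
    criterion = list(cl_ge("c10", "c0", what = "complex up at 10 min"),
                     cl_le("c30", "c10", what = "complex down again at 30 min")))

  t7 <- list(p_MITF = 10, p_PIAS3 = 10)
  specs[["7"]] <- new_experiment(
    7, "MITF-PIAS3 complex kinetics after activation (MITF+PIAS3 transfected)",
    conditions = list(act = condition(list(
      phase(2880, params = t7),
      phase(30, params = t7, erkp = 1200, jakp = 250)))),
    readouts = list(
      c0 = readout("act", "mitf_complex_total", 2880),
      c10 = readout("act", "mitf_complex_total", 2890),
      c30 = readout("act", "mitf_complex_total", 2910)),
    criterion = list(cl_ge("c10", "c0", what = "complex up at 10 min"),
                     cl_le("c30", "c10", what = "complex down again at 30 min")))

  specs[["8"]] <- new_experiment(
    8, "MITF activity with and without RSK1 overexpression",
    conditions = list(
      noR = condition(list(phase(2880, params = list(p_MITF = 7)))),
      withR = condition(list(phase(2880, params = list(p_MITF = 7))),
                        init = list(rsk1_total = 5000))),
    readouts = list(f_no = readout("noR", "mitf_activity", 2880),
                    f_with = readout("withR", "mitf_activity", 2880)),
    criterion = list(cl_ratio("f_with", "f_no", 0.5, 2,
                              "activities within two-fold")))

  # shared base for the PIAS3-inhibition reporter series (#9-#12):
  # MITF transfection, growing-culture activation level on the MAPK arm
  base912 <- list(p_MITF = 7)
  erk912 <- 20
  s409a <- list(k_Mp409_plus = 0)
  ratio_windows_912 <- list(`9` = c(0.02, 0.42), `10` = c(0.44, 0.84),
                            `11` = c(0.15, 0.55), `12` = c(0.10, 0.50))
  for (id in 9:12) {
    mut <- if (id %in% c(11, 12)) s409a else list()
    rsk <- if (id %in% c(10, 12)) list(rsk1_total = 5000) else NULL
    w <- ratio_windows_912[[as.character(id)]]
    specs[[as.character(id)]] <- new_experiment(
      id,
      sprintf("MITF%s activity inhibition by PIAS3%s",
              if (id %in% c(11, 12)) "-S409A" else "",
              if (id %in% c(10, 12)) " with RSK1 overexpression" else ""),
      conditions = list(
        noP = condition(list(phase(2880, params = c(base912, mut), erkp = erk912)),
                        init = rsk),
        withP = condition(list(phase(2880, params = c(base912, list(p_PIAS3 = 4), mut),
                                     erkp = erk912)),
                          init = rsk)),
      readouts = list(f_no = readout("noP", "mitf_activity", 2880),
                      f_with = readout("withP", "mitf_activity", 2880)),
      criterion = list(cl_ratio("f_with", "f_no", w[1], w[2])))
  }

  # phosphomimetic series (#13-#16): no endogenous MITF in the host cells
  base1316 <- list(p_MITF = 1.5)
  s73d <- list(k_Mp73_minus = 0, k_Mp73a_plus = 5)
  s409d <- list(k_Rp_plus = 0.04, k_Rp_minus = 0.004,
                k_Mp409_plus = 0.01, k_Mp409_minus = 0)
  muts1316 <- list(`13` = list(), `14` = s73d, `15` = s409d, `16` = c(s73d, s409d))
  ratio_windows_1316 <- list(`13` = c(0.30, 0.70), `14` = c(0.10, 0.50),
                             `15` = c(0.75, 1.15), `16` = c(0.45, 0.85))
  mutnames <- c(`13` = "wild-type", `14` = "S73D", `15` = "S409D",
                `16` = "S73/409D")
  for (id in 13:16) {
    mut <- muts1316[[as.character(id)]]
    w <- ratio_windows_1316[[as.character(id)]]
    specs[[as.character(id)]] <- new_experiment(
      id, sprintf("PIAS3 inhibition of %s MITF (MITF-free host cells)",
                  mutnames[[as.character(id)]]),
      conditions = list(
        noP = condition(list(phase(2880, params = c(base1316, mut))),
                        init = list(zero_mitf = TRUE)),
        withP = condition(list(phase(2880, params = c(base1316, list(p_PIAS3 = 4.5), mut))),
                          init = list(zero_mitf = TRUE))),
      readouts = list(f_no = readout("noP", "mitf_activity", 2880),
                      f_with = readout("withP", "mitf_activity", 2880)),
      criterion = list(cl_ratio("f_with", "f_no", w[1], w[2])))
  }

  t1718 <- list(p_MITF = 10, p_PIAS3 = 10, p_STAT3 = 10)
  specs[["17"]] <- new_experiment(
    17, "PIAS3-STAT3 complex response to activation (wild-type MITF)",
    conditions = list(
      stim = condition(list(phase(2880, params = t1718),
                            phase(15, params = t1718, erkp = 1000, jakp = 1000))),
      unstim = condition(list(phase(2895, params = t1718)))),
    readouts = list(cs = readout("stim", "PIAS3_STAT3p", 2895),
                    cu = readout("unstim", "PIAS3_STAT3p", 2895)),
    criterion = list(cl_ge("cs", "cu", 1.25,
                           "complex at least 25% higher with stimulation")))

  t18 <- c(t1718, s409a)
  specs[["18"]] <- new_experiment(
    18, "PIAS3-STAT3 complex response to activation (MITF-S409A)",
    conditions = list(
      wt_stim = condition(list(phase(2880, params = t1718),
                               phase(15, params = t1718, erkp = 1000, jakp = 1000))),
      mut_stim = condition(list(phase(2880, params = t18),
                                phase(15, params = t18, erkp = 1000, jakp = 1000))),
      mut_unstim = condition(list(phase(2895, params = t18)))),
    readouts = list(
      c_wt = readout("wt_stim", "PIAS3_STAT3p", 2895),
      c_ms = readout("mut_stim", "PIAS3_STAT3p", 2895),
      c_mu = readout("mut_unstim", "PIAS3_STAT3p", 2895)),
    criterion = list(
      cl_ge("c_wt", "c_ms", 1.25, "wild-type stimulated 25% above mutant stimulated"),
      cl_ge("c_wt", "c_mu", 1.25, "wild-type stimulated 25% above mutant unstimulated")))

  # shared base for the STAT3-reporter series (#19-#24)
  stat3_trans <- 5   # transfected STAT3 production rate
  pias3_trans <- 7   # transfected PIAS3 production rate
  mitf_small <- 10
  mitf_large <- 50
  fold_windows <- list(`19` = c(10, 20), `20` = c(2.67, 5.33),
                       `21` = c(2.67, 5.33), `22` = c(6.67, 13.33),
                       `23` = c(5.67, 11.33), `24` = c(10, 20))
  extra1924 <- list(
    `19` = list(),
    `20` = list(p_PIAS3 = pias3_trans),
    `21` = list(p_PIAS3 = pias3_trans, p_MITF = mitf_small),
    `22` = list(p_PIAS3 = pias3_trans, p_MITF = mitf_large),
    `23` = c(list(p_PIAS3 = pias3_trans, p_MITF = mitf_small), s409a),
    `24` = c(list(p_PIAS3 = pias3_trans, p_MITF = mitf_large), s409a))
  desc1924 <- c(`19` = "STAT3 only", `20` = "STAT3 + PIAS3",
                `21` = "STAT3 + PIAS3 + low MITF",
                `22` = "STAT3 + PIAS3 + high MITF",
                `23` = "STAT3 + PIAS3 + low MITF-S409A",
                `24` = "STAT3 + PIAS3 + high MITF-S409A")
  for (id in 19:24) {
    key <- as.character(id)
    pr <- c(list(p_STAT3 = stat3_trans), extra1924[[key]])
    w <- fold_windows[[key]]
    specs[[key]] <- new_experiment(
      id, sprintf("STAT3 activity after activation: %s", desc1924[[key]]),
      conditions = list(
        test = condition(list(phase(2880, params = pr),
                              phase(360, params = pr, erkp = 1000, jakp = 1000))),
        bg = condition(list(phase(3240, params = list(p_STAT3 = stat3_trans))))),
      readouts = list(s = readout("test", "stat3_activity", 3240),
                      b = readout("bg", "stat3_activity", 3240)),
      criterion = list(cl_ratio("s", "b", w[1], w[2],
                                sprintf("fold over background in [%g, %g]", w[1], w[2]))))
  }

  # #25: six co-transfection conditions in MITF/PIAS3-poor host cells
  y705f <- list(k_Sp_plus = 0)
  stat3c25 <- list(k_Sp_plus = 0.02, k_Sp_minus = 0)
  lowstart <- list(set = c(
    stats::setNames(as.list(rep(1, 10)),
                    c(mitf_states(), "PIAS3", "PIAS3_STAT3p"))))
  conds25 <- list(
    i   = c(list(p_STAT3 = 20, p_MITF = 0, p_PIAS3 = 0), y705f),
    ii  = c(list(p_STAT3 = 20, p_MITF = 0, p_PIAS3 = 0), stat3c25),
    iii = c(list(p_STAT3 = 20, p_MITF = 2, p_PIAS3 = 0), y705f),
    iv  = c(list(p_STAT3 = 20, p_MITF = 2, p_PIAS3 = 0), stat3c25),
    v   = c(list(p_STAT3 = 20, p_MITF = 2, p_PIAS3 = 2), y705f),
    vi  = c(list(p_STAT3 = 20, p_MITF = 2, p_PIAS3 = 2), stat3c25))
  specs[["25"]] <- new_experiment(
    25, "MITF activity under STAT3-Y705F vs constitutively active STAT3",
    conditions = lapply(conds25, function(pr) {
      condition(list(phase(2880, params = pr)), init = lowstart)
    }),
    readouts = stats::setNames(
      lapply(names(conds25), function(nm) readout(nm, "mitf_activity", 2880)),
      paste0("f_", names(conds25))),
    criterion = list(
      cl_ratio("f_i", "f_ii", 0.5, 1.5),
      cl_ratio("f_iii", "f_iv", 0.8, 1.2),
      cl_ratio("f_v", "f_vi", 0.125, 1.0),
      cl_le("f_i", "f_iii", what = "MITF transfection raises activity"),
      cl_ge("f_iii", "f_v", 2, "PIAS3 halves MITF-driven activity")))

  mut26 <- list(k_Mass = 0, k_Mp73ass = 0, k_Mp409ass = 0, k_Mppass = 0)
  specs[["26"]] <- new_experiment(
    26, "Activation response of wild-type vs PIAS3-binding-deficient MITF cells",
    conditions = list(
      wt_un = condition(),
      wt_act = condition(list(phase(240, erkp = 1000, jakp = 1000))),
      mut_un = condition(ss = list(params = mut26)),
      mut_act = condition(list(phase(240, params = mut26, erkp = 1000, jakp = 1000)),
                          ss = list(params = mut26))),
    readouts = list(
      fM_un = readout("wt_un", "mitf_activity", 0),
      fS_un = readout("wt_un", "stat3_activity", 0),
      fM_30 = readout("wt_act", "mitf_activity", 30),
      fS_240 = readout("wt_act", "stat3_activity", 240),
      gM_un = readout("mut_un", "mitf_activity", 0),
      gS_un = readout("mut_un", "stat3_activity", 0),
      gM_30 = readout("mut_act", "mitf_activity", 30),
      gM_240 = readout("mut_act", "mitf_activity", 240),
      gS_30 = readout("mut_act", "stat3_activity", 30),
      gS_240 = readout("mut_act", "stat3_activity", 240)),
    criterion = list(
      cl_ge("fM_30", "fM_un", 2, "wild type: MITF activity doubles by 30 min"),
      cl_ge("fS_240", "fS_un", 2, "wild type: STAT3 activity doubles by 4 h"),
      cl_le("gM_30", "gM_un", 2, "mutant: no MITF doubling at 30 min"),
      cl_le("gM_240", "gM_un", 2, "mutant: no MITF doubling at 4 h"),
      cl_le("gS_30", "gS_un", 2, "mutant: no STAT3 doubling at 30 min"),
      cl_le("gS_240", "gS_un", 2, "mutant: no STAT3 doubling at 4 h")))

  s409d_mimic <- list(k_Mp409_plus = 5, k_Mp409_minus = 0)
  base2728 <- list(p_STAT3 = 5)
  specs[["27"]] <- new_experiment(
    27, "STAT3 activity response to MITF or MITF-S409D transfection",
    conditions = list(
      none = condition(list(phase(2880, params = base2728))),
      wt = condition(list(phase(2880, params = c(base2728, list(p_MITF = 5))))),
      mut = condition(list(phase(2880, params = c(base2728, list(p_MITF = 5),
                                                  s409d_mimic))))),
    readouts = list(s_none = readout("none", "stat3_activity", 2880),
                    s_wt = readout("wt", "stat3_activity", 2880),
                    s_mut = readout("mut", "stat3_activity", 2880)),
    criterion = list(
      cl_ge("s_wt", "s_none", what = "MITF transfection raises STAT3 activity"),
      cl_ge("s_mut", "s_none", what = "mutant transfection raises STAT3 activity"),
      cl_ge("s_wt", "s_mut", what = "wild-type raises it more than the mutant")))

  stat3c28 <- list(p_STAT3 = 5, k_Sp_plus = 25 * 0.0002, k_Sp_minus = 0)
  specs[["28"]] <- new_experiment(
    28, "MITF activity response to constitutively active STAT3",
    conditions = list(
      base = condition(list(phase(2880, params = list(p_MITF = 5)))),
      stat3c = condition(list(phase(2880, params = c(list(p_MITF = 5), stat3c28))))),
    readouts = list(f_base = readout("base", "mitf_activity", 2880),
                    f_c = readout("stat3c", "mitf_activity", 2880)),
    criterion = list(cl_ge("f_c", "f_base", 1.1,
                           "MITF activity up by at least 10%")))

  specs
}

# ---- running --------------------------------------------------------------

# memoized steady state: keyed on the full parameter vector and inputs
cached_steady_state <- function(params, erkp, jakp, cache, atol, rtol) {
  if (is.null(cache)) {
    return(steady_state(params, erkp, jakp, atol = atol, rtol = rtol))
  }
  key <- paste(format(c(as.numeric(params[c(core_parameter_names(), "RSK1_total")]),
                        erkp, jakp), digits = 17), collapse = ",")
  if (is.null(cache[[key]])) {
    cache[[key]] <- steady_state(params, erkp, jakp, atol = atol, rtol = rtol)
  }
  cache[[key]]
}

apply_init <- function(state, init, params) {
  if (is.null(init)) return(state)
  if (isTRUE(init$zero_mitf)) {
    # host cells without endogenous MITF: release complexed PIAS3, drop MITF
    state[["PIAS3"]] <- state[["PIAS3"]] + sum(state[mitf_complex_states()])
    state[mitf_states()] <- 0
  }
  if (!is.null(init$set)) {
    state[names(init$set)] <- unlist(init$set)
  }
  if (!is.null(init$rsk1_total)) {
    state <- set_rsk1_total(state, init$rsk1_total)
  }
  state
}

# single-row pseudo-trajectory for steady-state readouts
state_as_trajectory <- function(state, erkp, jakp) {
  df <- data.frame(time_min = 0, as.data.frame(t(state)),
                   ERKp = erkp, JAKp = jakp, check.names = FALSE)
  df$MITF_activity <- mitf_activity(state)
  df$STAT3_activity <- stat3_activity(state)
  class(df) <- c("pias3net_trajectory", "data.frame")
  attr(df, "final_state") <- state
  df
}

run_condition <- function(cond, params, needed_times, fine = FALSE,
                          cache = NULL, atol = 1e-8, rtol = 1e-6) {
  ss <- cond$ss %||% list()
  ssp <- override_parameters(params, ss$params %||% list())
  erkp0 <- ss$erkp %||% ssp[["ERKp_baseline"]]
  jakp0 <- ss$jakp %||% ssp[["JAKp_baseline"]]
  state <- cached_steady_state(ssp, erkp0, jakp0, cache, atol, rtol)
  state <- apply_init(state, cond$init, params)

  if (length(cond$phases) == 0) {
    return(state_as_trajectory(state, erkp0, jakp0))
  }

  t0 <- 0
  pieces <- list()
  for (k in seq_along(cond$phases)) {
    ph <- cond$phases[[k]]
    pp <- override_parameters(params, ph$params %||% list())
    erkp <- ph$erkp %||% pp[["ERKp_baseline"]]
    jakp <- ph$jakp %||% pp[["JAKp_baseline"]]
    rel <- needed_times[needed_times > t0 & needed_times < t0 + ph$duration] - t0
    tms <- sort(unique(c(0, rel, ph$duration)))
    if (fine) tms <- sort(unique(c(tms, seq(0, ph$duration, by = 0.05))))
    traj <- simulate_model(pp, initial = state, duration = ph$duration,
                           erkp = erkp, jakp = jakp, times = tms,
                           atol = atol, rtol = rtol)
    state <- final_state(traj)
    piece <- as.data.frame(traj)
    piece$time_min <- piece$time_min + t0
    if (k > 1) piece <- piece[-1, , drop = FALSE]
    pieces[[k]] <- piece
    t0 <- t0 + ph$duration
  }
  df <- do.call(rbind, pieces)
  class(df) <- c("pias3net_trajectory", "data.frame")
  attr(df, "final_state") <- state
  df
}

eval_clause <- function(clause, values, trajectories) {
  res <- switch(clause$type,
    "true" = list(value = NA_real_, pass = TRUE),
    "window" = {
      v <- values[[clause$readout]]
      list(value = v, pass = v >= clause$lo && v <= clause$hi)
    },
    "ratio" = {
      v <- values[[clause$num]] / values[[clause$den]]
      list(value = v, pass = v >= clause$lo && v <= clause$hi)
    },
    "ge" = {
      a <- values[[clause$a]]; b <- values[[clause$b]]
      list(value = a / b, pass = a > clause$factor * b)
    },
    "le" = {
      a <- values[[clause$a]]; b <- values[[clause$b]]
      list(value = a / b, pass = a < clause$factor * b)
    },
    "t90" = {
      traj <- trajectories[[clause$condition]]
      q <- quantity_series(traj, clause$quantity)
      tt <- traj$time_min
      target <- clause$frac * max(q)
      i <- which(q >= target)[1]
      tcross <- if (is.na(i)) NA_real_ else if (i == 1) tt[1] else {
        tt[i - 1] + (tt[i] - tt[i - 1]) * (target - q[i - 1]) / (q[i] - q[i - 1])
      }
      list(value = tcross,
           pass = !is.na(tcross) && tcross >= clause$lo && tcross <= clause$hi)
    },
    stop("unknown clause type: ", clause$type, call. = FALSE))
  res
}

#' Run one virtual experiment
#'
#' Each condition is simulated phase by phase from its pre-protocol
#' steady state (the model state is carried across phases), the readouts
#' are extracted at their stated times, and the experiment's success
#' criterion -- a conjunction of clauses -- is evaluated.  A solver
#' failure marks the experiment as errored, which is distinct from a
#' criterion failure.
#'
#' @param spec An entry of [experiment_catalog()].
#' @param params Core parameter vector.
#' @param cache Optional environment memoizing steady states across
#'   experiments (used by [run_all_experiments()]).
#' @param atol,rtol Integration tolerances.
#' @param keep_trajectories If `TRUE`, attach the per-condition
#'   trajectories to the result.
#' @return List of class `"pias3net_result"`: `id`, `pass` (logical, `NA`
#'   if errored), `readouts` (named values), `clauses` (per-clause
#'   diagnostics data frame), `state_range` (per-condition min/max of
#'   every state variable), `error` (message or `NULL`).
#' @export
run_experiment <- function(spec, params = default_parameters(),
                           cache = NULL, atol = 1e-8, rtol = 1e-6,
                           keep_trajectories = FALSE) {
  out <- tryCatch({
    needed <- vapply(spec$readouts, function(r) r$time, numeric(1))
    fine_conditions <- unique(unlist(lapply(spec$criterion, function(cl) {
      if (cl$type == "t90") cl$condition else NULL
    })))
    trajectories <- lapply(names(spec$conditions), function(nm) {
      cond_times <- needed[vapply(spec$readouts, function(r) r$condition, "") == nm]
      run_condition(spec$conditions[[nm]], params, cond_times,
                    fine = nm %in% fine_conditions,
                    cache = cache, atol = atol, rtol = rtol)
    })
    names(trajectories) <- names(spec$conditions)

    values <- lapply(spec$readouts, function(r) {
      traj <- trajectories[[r$condition]]
      q <- quantity_series(traj, r$quantity)
      if (length(q) == 1) q else stats::approx(traj$time_min, q, xout = r$time, rule = 2)$y
    })

    clause_res <- lapply(spec$criterion, eval_clause,
                         values = values, trajectories = trajectories)
    clauses <- data.frame(
      what = vapply(spec$criterion, function(cl) cl$what, ""),
      value = vapply(clause_res, function(x) x$value, numeric(1)),
      pass = vapply(clause_res, function(x) x$pass, logical(1)))

    ranges <- lapply(trajectories, function(traj) {
      m <- as.matrix(as.data.frame(traj)[state_names()])
      rbind(min = apply(m, 2, min), max = apply(m, 2, max))
    })

    structure(list(id = spec$id, pass = all(clauses$pass),
                   readouts = unlist(values), clauses = clauses,
                   state_range = ranges,
                   trajectories = if (keep_trajectories) trajectories,
                   error = NULL),
              class = "pias3net_result")
  }, error = function(e) {
    structure(list(id = spec$id, pass = NA, readouts = NULL, clauses = NULL,
                   state_range = NULL, trajectories = NULL,
                   error = conditionMessage(e)),
              class = "pias3net_result")
  })
  out
}

#' Run the full experiment catalog
#'
#' Runs every experiment in the catalog against one core parameter set,
#' sharing steady-state computations between experiments with identical
#' pre-protocol settings.  Deterministic given parameters and solver
#' settings; per-experiment errors are recorded without aborting the
#' batch.
#'
#' @param params Core parameter vector.
#' @param catalog Experiment catalog (defaults to [experiment_catalog()]).
#' @param atol,rtol Integration tolerances.
#' @return List of class `"pias3net_batch"`: `passes` (logical vector
#'   keyed by experiment id; `NA` = errored), `n_pass`, and `results`
#'   (the per-experiment `"pias3net_result"` objects).
#' @export
run_all_experiments <- function(params = default_parameters(),
                                catalog = experiment_catalog(),
                                atol = 1e-8, rtol = 1e-6) {
  cache <- new.env(parent = emptyenv())
  results <- lapply(catalog, run_experiment, params = params, cache = cache,
                    atol = atol, rtol = rtol)
  ids <- vapply(results, function(r) as.character(r$id), "")
  passes <- stats::setNames(vapply(results, function(r) r$pass, NA), ids)
  structure(list(passes = passes, n_pass = sum(passes, na.rm = TRUE),
                 results = results),
            class = "pias3net_batch")
}

#' @export
print.pias3net_batch <- function(x, ...) {
  cat(sprintf("virtual-experiment batch: %d of %d passed\n",
              x$n_pass, length(x$passes)))
  failed <- names(x$passes)[!x$passes %in% TRUE]
  if (length(failed) > 0) {
    cat("not passing:", paste(failed, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- catalog serialization ------------------------------------------------

#' Write the experiment catalog to YAML
#' @param catalog Catalog list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  plain <- lapply(catalog, unclass)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Read an experiment catalog from YAML
#' @param path Path written by [write_catalog()].
#' @return Named list of `"pias3net_experiment"` specs.
#' @export
read_catalog <- function(path) {
  plain <- yaml::read_yaml(path)
  lapply(plain, function(x) {
    structure(x, class = "pias3net_experiment")
  })
}
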