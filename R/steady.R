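# Steady-state location by integration with a relative-RHS convergence
# check, plus a semianalytic root solve for the glycogen reference state.

# max_i |dy_i/dt| / max(|y_i|, floor): relative change per minute
relative_rhs_norm <- function(rhs_val, state, exclude = character(),
                              floor = 1e-8) {
  keep <- setdiff(names(state), exclude)
  max(abs(rhs_val[keep]) / pmax(abs(state[keep]), floor))
}

# integrate with horizon doubling until the relative RHS norm drops below
# tol; `exclude` names terminal-sink species ignored by the check
run_to_steady <- function(rhs, initial, tol = 1e-6, t0 = 200,
                          max_horizon = 1e6, exclude = character(),
                          rtol = 1e-10, atol = 1e-12, ...) {
  dots <- list(...)
  rhs_args <- dots
  names(rhs_args)[names(rhs_args) == "parms"] <- "params"
  state <- initial
  t_total <- 0
  horizon <- t0
  repeat {
    sol <- do.call(deSolve::ode, c(
      list(y = state, times = c(0, horizon), func = rhs,
           method = "lsoda", rtol = rtol, atol = atol), dots))
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed during steady-state search", call. = FALSE)
    }
    state <- sol[nrow(sol), -1]
    state[state < 0 & state > -1e-9] <- 0
    t_total <- t_total + horizon
    rhs_val <- do.call(rhs, c(list(0, state), rhs_args))[[1]]
    norm <- relative_rhs_norm(rhs_val, state, exclude = exclude)
    if (norm < tol) {
      return(list(state = state, converged = TRUE, time = t_total,
                  rhs_norm = norm))
    }
    if (t_total >= max_horizon) {
      return(list(state = state, converged = FALSE, time = t_total,
                  rhs_norm = norm))
    }
    horizon <- horizon * 2
  }
}

#' Steady state of the glycogenolysis model by integration
#'
#' Integrates [glycogen_rhs()] with horizon doubling until the relative RHS
#' norm (maximum per-minute fractional rate of change over all species)
#' falls below `tol`.
#'
#' @param params A [glycogen_params()] object.
#' @param drug_conc Drug concentration, uM.
#' @param initial Initial state; default the drug-free reference state.
#' @param tol Convergence tolerance on the relative RHS norm. The default
#'   is tight because the glycogen pool is the system's slow mode: a lax
#'   cut-off would stop integration while glycogen still carries a visible
#'   offset from its fixed point.
#' @param max_horizon Give up (with `converged = FALSE`) beyond this model
#'   time, minutes.
#' @return A list with `state` (named vector), `converged`, `time`,
#'   `rhs_norm`.
#' @export
steady_glycogen <- function(params = glycogen_params(), drug_conc = 0,
                            initial = glycogen_initial_state(params),
                            tol = 1e-9, max_horizon = 1e7) {
  stopifnot(inherits(params, "glycogen_params"), drug_conc >= 0)
  run_to_steady(glycogen_rhs, initial, tol = tol, t0 = 500,
                max_horizon = max_horizon,
                parms = params, drug_conc = drug_conc)
}

#' Steady state of the pentose-phosphate model by integration
#'
#' Ribulose-5-phosphate is a terminal sink (it accumulates linearly at
#' steady flux) and is excluded from the convergence check.
#'
#' @inheritParams steady_glycogen
#' @param params A [ppp_params()] object.
#' @param g6p_initial Initial/clamp-target G6P content, uM.
#' @return A list with `state`, `converged`, `time`, `rhs_norm`, and
#'   `nadph_ratio` (steady-state NADPH/NADP+).
#' @export
steady_ppp <- function(params = ppp_params(), g6p_initial = 100,
                       initial = ppp_initial_state(params, g6p_initial),
                       tol = 1e-8, max_horizon = 1e6) {
  stopifnot(inherits(params, "ppp_params"), g6p_initial >= 0)
  out <- run_to_steady(ppp_rhs, initial, tol = tol, t0 = 100,
                       max_horizon = max_horizon, exclude = "ru5p",
                       parms = params, g6p_initial = g6p_initial)
  out$nadph_ratio <- unname(out$state[["nadph"]] / max(out$state[["nadp"]], 1e-12))
  out
}

#' Steady state of the glutathione model by integration
#'
#' With the NADPH supply too small to match the H2O2 load no steady state
#' exists (H2O2 accumulates without bound); the search then returns
#' `converged = FALSE` with the state reached at `max_horizon`.
#'
#' @inheritParams steady_glycogen
#' @param params A [gsh_params()] object.
#' @return A list with `state`, `converged`, `time`, `rhs_norm`.
#' @export
steady_gsh <- function(params = gsh_params(),
                       initial = gsh_initial_state(params),
                       tol = 1e-8, max_horizon = 1e6) {
  stopifnot(inherits(params, "gsh_params"))
  run_to_steady(gsh_rhs, initial, tol = tol, t0 = 500,
                max_horizon = max_horizon, parms = params)
}

# Full steady state of the glycogen cascade by nested 1-D root solves:
# g6p* = k_in/k_out exactly; gpa*, gsa*, gly* from monotone 1-D equations.
# Used to construct the reference initial state; tests cross-check steady
# states with an independent multidimensional root-finder.
steady_state_glycogen_root <- function(params, drug_conc = 0) {
  p <- params
  gpa <- stats::uniroot(function(x) {
    p$vmax_phk * (p$gp_total - x) /
      (p$km_phk * (1 + drug_conc / p$ki_drug) + p$gp_total - x) -
      p$vmax_pp1 * x / (p$km_pp1 + x)
  }, c(1e-12, p$gp_total - 1e-12), tol = 1e-14)$root
  v_phk <- p$vmax_phk * (p$gp_total - gpa) /
    (p$km_phk * (1 + drug_conc / p$ki_drug) + p$gp_total - gpa)
  phk_scaled <- v_phk / p$vmax_phk
  gsa <- stats::uniroot(function(y) {
    p$vmax_pp1 * (p$gs_total - y) / (p$km_pp1 + p$gs_total - y) -
      p$k_gs_inact * phk_scaled * y
  }, c(1e-12, p$gs_total - 1e-12), tol = 1e-14)$root
  g6p <- p$k_g6p_in / p$k_g6p_out
  gly <- stats::uniroot(function(g) {
    p$vmax_gs * gsa * (g6p / (p$km_gs_g6p + g6p)) * (1 - g / p$gly_cap) -
      p$vmax_gp * gpa * g / (p$km_gp_gly + g)
  }, c(0, p$gly_cap), tol = 1e-12)$root
  c(gpa = gpa, gsa = gsa, gly = gly, g6p = g6p)
}
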