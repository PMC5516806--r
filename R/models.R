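#' Competitive-inhibition rate law of phosphorylase kinase
#'
#' `v = Vmax * S / (Km * (1 + I/Ki) + S)`: the drug raises the apparent Km
#' without touching Vmax, the signature of competitive inhibition. Substrate
#' here is inactive glycogen phosphorylase (GPb).
#'
#' @param substrate GPb concentration, uM (>= 0).
#' @param inhibitor Drug concentration, uM (>= 0).
#' @param params A [glycogen_params()] object (uses `vmax_phk`, `km_phk`,
#'   `ki_drug`).
#' @return Flux in uM/min.
#' @examples
#' p <- glycogen_params()
#' phk_rate(5, 0, p)                       # plain Michaelis-Menten
#' phk_rate(0.1, 5.5, p) / phk_rate(0.1, 0, p)  # ~1/2 in the S << Km limit
#' @export
phk_rate <- function(substrate, inhibitor, params) {
  stopifnot(inherits(params, "glycogen_params"))
  if (any(substrate < 0) || any(inhibitor < 0)) {
    stop("substrate and inhibitor concentrations must be >= 0", call. = FALSE)
  }
  with(params, vmax_phk * substrate /
         (km_phk * (1 + inhibitor / ki_drug) + substrate))
}

#' Reference initial state of the glycogenolysis model
#'
#' The exact drug-free steady state of the default [glycogen_params()]:
#' half-active enzyme pools, `g6p = k_g6p_in / k_g6p_out`, glycogen at its
#' drug-free fixed point.
#'
#' @param params A [glycogen_params()] object.
#' @return Named numeric state `c(gpa, gpb, gsa, gsb, gly, g6p)`.
#' @export
glycogen_initial_state <- function(params = glycogen_params()) {
  stopifnot(inherits(params, "glycogen_params"))
  ss <- steady_state_glycogen_root(params, drug_conc = 0)
  c(gpa = ss[["gpa"]], gpb = params$gp_total - ss[["gpa"]],
    gsa = ss[["gsa"]], gsb = params$gs_total - ss[["gsa"]],
    gly = ss[["gly"]], g6p = ss[["g6p"]])
}

glycogen_rates <- function(state, params, drug_conc) {
  with(as.list(c(state, params)), {
    v_phk <- vmax_phk * gpb / (km_phk * (1 + drug_conc / ki_drug) + gpb)
    v_pp1_gp <- vmax_pp1 * gpa / (km_pp1 + gpa)
    v_pp1_gs <- vmax_pp1 * gsb / (km_pp1 + gsb)
    phk_scaled <- v_phk / vmax_phk
    v_gs_inact <- k_gs_inact * phk_scaled * gsa
    v_gp <- vmax_gp * gpa * gly / (km_gp_gly + gly)
    v_gs <- vmax_gs * gsa * (g6p / (km_gs_g6p + g6p)) *
      max(0, 1 - gly / gly_cap)
    list(v_phk = v_phk, v_pp1_gp = v_pp1_gp, v_pp1_gs = v_pp1_gs,
         v_gs_inact = v_gs_inact, v_gp = v_gp, v_gs = v_gs)
  })
}

#' Right-hand side of the glycogenolysis ODE system
#'
#' Exposed so that steady states can be cross-checked by independent
#' root-finding. States: active/inactive glycogen phosphorylase (`gpa`,
#' `gpb`), active/inactive glycogen synthase (`gsa`, `gsb`), glycogen
#' glucosyl units (`gly`), glucose-6-phosphate (`g6p`).
#'
#' @param t Time (unused; autonomous system).
#' @param state Named state vector.
#' @param params A [glycogen_params()] object.
#' @param drug_conc Drug concentration, uM.
#' @return A list holding the derivative vector (deSolve convention).
#' @export
glycogen_rhs <- function(t, state, params, drug_conc) {
  v <- glycogen_rates(state, params, drug_conc)
  d_gpa <- v$v_phk - v$v_pp1_gp
  d_gsa <- v$v_pp1_gs - v$v_gs_inact
  d_gly <- v$v_gs - v$v_gp
  d_g6p <- params$k_g6p_in + v$v_gp - v$v_gs - params$k_g6p_out * state[["g6p"]]
  list(c(gpa = d_gpa, gpb = -d_gpa, gsa = d_gsa, gsb = -d_gsa,
         gly = d_gly, g6p = d_g6p))
}

#' Right-hand side of the oxidative pentose-phosphate ODE system
#'
#' States: `g6p`, 6-phosphogluconate `pg6`, ribulose-5-phosphate `ru5p`
#' (terminal sink), `nadp`, `nadph`. Both dehydrogenases follow bi-substrate
#' Michaelis-Menten kinetics `v = Vmax * A/(KmA+A) * NADP/(KmN+NADP)`.
#'
#' @param t Time (unused).
#' @param state Named state vector.
#' @param params A [ppp_params()] object.
#' @param g6p_initial Clamp target of the G6P supply, uM.
#' @return A list holding the derivative vector.
#' @export
ppp_rhs <- function(t, state, params, g6p_initial) {
  with(as.list(c(state, params)), {
    v1 <- vmax_g6pd * (g6p / (km_g6pd_g6p + g6p)) * (nadp / (km_g6pd_nadp + nadp))
    v2 <- vmax_6pgd * (pg6 / (km_6pgd_6pg + pg6)) * (nadp / (km_6pgd_nadp + nadp))
    d_g6p <- k_g6p_refresh * (g6p_initial - g6p) - v1
    d_pg6 <- v1 - v2
    d_ru5p <- v2
    d_nadph <- v1 + v2 - k_nadph_drain * nadph
    list(c(g6p = d_g6p, pg6 = d_pg6, ru5p = d_ru5p,
           nadp = -d_nadph, nadph = d_nadph))
  })
}

#' Default initial state of the pentose-phosphate model
#'
#' @param params A [ppp_params()] object.
#' @param g6p_initial Initial (and clamp-target) G6P content, uM.
#' @return Named numeric state `c(g6p, pg6, ru5p, nadp, nadph)`; the
#'   pyridine pool starts half-reduced.
#' @export
ppp_initial_state <- function(params = ppp_params(), g6p_initial = 100) {
  stopifnot(inherits(params, "ppp_params"), g6p_initial >= 0)
  c(g6p = g6p_initial, pg6 = 0, ru5p = 0,
    nadp = params$nadp_total / 2, nadph = params$nadp_total / 2)
}

#' Right-hand side of the glutathione redox ODE system
#'
#' States: `gsh`, `gssg`, `h2o2`, `nadph`, `nadp`. Peroxidase consumes
#' 2 GSH per H2O2; reductase regenerates 2 GSH per GSSG + NADPH; NADPH is
#' resupplied at `k_nadph_supply * nadp/nadp_total`; vitamin E (if enabled)
#' quenches H2O2 with second-order kinetics.
#'
#' @param t Time (unused).
#' @param state Named state vector.
#' @param params A [gsh_params()] object.
#' @return A list holding the derivative vector.
#' @export
gsh_rhs <- function(t, state, params) {
  with(as.list(c(state, params)), {
    v_gpx <- vmax_gpx * (gsh / (km_gpx_gsh + gsh)) * (h2o2 / (km_gpx_h2o2 + h2o2))
    v_gr <- vmax_gr * (gssg / (km_gr_gssg + gssg)) * (nadph / (km_gr_nadph + nadph))
    d_h2o2 <- k_h2o2_prod - v_gpx - k_vite_quench * vite_pool * h2o2
    d_gsh <- k_synth + 2 * v_gr - 2 * v_gpx
    d_gssg <- v_gpx - v_gr - k_efflux * gssg
    d_nadph <- k_nadph_supply * (nadp / nadp_total) - v_gr
    list(c(gsh = d_gsh, gssg = d_gssg, h2o2 = d_h2o2,
           nadph = d_nadph, nadp = -d_nadph))
  })
}

#' Default initial state of the glutathione model
#'
#' Starts with the glutathione moiety fully reduced (`gsh =
#' gsh_total_init`), no H2O2, and a part-reduced pyridine pool.
#'
#' @param params A [gsh_params()] object.
#' @return Named numeric state `c(gsh, gssg, h2o2, nadph, nadp)`.
#' @export
gsh_initial_state <- function(params = gsh_params()) {
  stopifnot(inherits(params, "gsh_params"))
  c(gsh = params$gsh_total_init, gssg = 0, h2o2 = 0,
    nadph = params$nadp_total / 2, nadp = params$nadp_total / 2)
}

integrate_model <- function(rhs, initial, times, rtol, atol, ...) {
  sol <- deSolve::ode(y = initial, times = times, func = rhs,
                      method = "lsoda", rtol = rtol, atol = atol, ...)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  }
  neg <- sol[, -1, drop = FALSE] < -1e-6
  if (any(neg)) {
    stop("negative state excursion beyond tolerance during integration",
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  out[out < 0] <- 0
  out
}

#' Simulate the glycogenolysis cascade under a drug dose
#'
#' Integrates [glycogen_rhs()] from `initial` over `0..horizon` minutes.
#'
#' @param params A [glycogen_params()] object.
#' @param drug_conc Drug concentration, uM (held constant).
#' @param horizon Simulation horizon, minutes.
#' @param initial Named initial state; default the drug-free reference
#'   steady state (must satisfy the enzyme-pool conservations).
#' @param n_out Number of saved time points.
#' @param rtol,atol Solver tolerances.
#' @return A `pathway_trajectory` tibble (`time` plus state columns) with
#'   the model, parameters and dose attached as attributes.
#' @export
simulate_glycogen <- function(params = glycogen_params(), drug_conc = 0,
                              horizon = 1000,
                              initial = glycogen_initial_state(params),
                              n_out = 201, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "glycogen_params"), drug_conc >= 0, horizon > 0)
  check_state(initial, c("gpa", "gpb", "gsa", "gsb", "gly", "g6p"))
  pools_ok <- abs(initial[["gpa"]] + initial[["gpb"]] - params$gp_total) <=
    1e-6 * params$gp_total &&
    abs(initial[["gsa"]] + initial[["gsb"]] - params$gs_total) <=
    1e-6 * params$gs_total
  if (!pools_ok) {
    stop("initial state violates the conserved GP/GS enzyme pools", call. = FALSE)
  }
  times <- seq(0, horizon, length.out = n_out)
  traj <- integrate_model(glycogen_rhs, initial, times, rtol, atol,
                          parms = params, drug_conc = drug_conc)
  new_trajectory(traj, "glycogen", params, drug_conc = drug_conc)
}

#' Simulate the oxidative pentose-phosphate pathway
#'
#' @param params A [ppp_params()] object.
#' @param g6p_initial Initial G6P content, uM; also the clamp target of the
#'   G6P supply when `k_g6p_refresh > 0`.
#' @param horizon Simulation horizon, minutes.
#' @param initial Optional named initial state; defaults to
#'   [ppp_initial_state()].
#' @inheritParams simulate_glycogen
#' @return A `pathway_trajectory` tibble.
#' @export
simulate_ppp <- function(params = ppp_params(), g6p_initial = 100,
                         horizon = 200,
                         initial = ppp_initial_state(params, g6p_initial),
                         n_out = 201, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ppp_params"), g6p_initial >= 0, horizon > 0)
  check_state(initial, c("g6p", "pg6", "ru5p", "nadp", "nadph"))
  times <- seq(0, horizon, length.out = n_out)
  traj <- integrate_model(ppp_rhs, initial, times, rtol, atol,
                          parms = params, g6p_initial = g6p_initial)
  new_trajectory(traj, "ppp", params, g6p_initial = g6p_initial)
}

#' Simulate glutathione redox cycling
#'
#' @param params A [gsh_params()] object.
#' @param horizon Simulation horizon, minutes.
#' @param initial Optional named initial state; defaults to
#'   [gsh_initial_state()].
#' @inheritParams simulate_glycogen
#' @return A `pathway_trajectory` tibble.
#' @export
simulate_gsh <- function(params = gsh_params(), horizon = 2000,
                         initial = gsh_initial_state(params),
                         n_out = 201, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "gsh_params"), horizon > 0)
  check_state(initial, c("gsh", "gssg", "h2o2", "nadph", "nadp"))
  times <- seq(0, horizon, length.out = n_out)
  traj <- integrate_model(gsh_rhs, initial, times, rtol, atol, parms = params)
  new_trajectory(traj, "gsh", params)
}

check_state <- function(state, fields) {
  if (!is.numeric(state) || !all(fields %in% names(state))) {
    stop("initial state must be a named numeric vector with components: ",
         paste(fields, collapse = ", "), call. = FALSE)
  }
  if (any(state < 0)) stop("initial state must be non-negative", call. = FALSE)
  invisible(state)
}

new_trajectory <- function(traj, model, params, ...) {
  attr(traj, "model") <- model
  attr(traj, "params") <- params
  extra <- list(...)
  for (nm in names(extra)) attr(traj, nm) <- extra[[nm]]
  class(traj) <- c("pathway_trajectory", class(traj))
  traj
}

#' Endpoint summary of a glycogenolysis trajectory
#'
#' Evaluates the cascade readouts at the final time point: PHK flux
#' (recomputed from the final state and the dose the trajectory was run
#' at), active fractions of glycogen phosphorylase and synthase, and
#' glycogen / G6P contents.
#'
#' @param trajectory A `pathway_trajectory` from [simulate_glycogen()].
#' @return A one-row tibble with columns `phk_activity` (uM/min),
#'   `gp_activity`, `gs_activity` (fractions), `glycogen`, `g6p` (uM).
#' @export
endpoint_summary <- function(trajectory) {
  stopifnot(inherits(trajectory, "pathway_trajectory"),
            identical(attr(trajectory, "model"), "glycogen"),
            nrow(trajectory) >= 1L)
  params <- attr(trajectory, "params")
  drug <- attr(trajectory, "drug_conc")
  fin <- trajectory[nrow(trajectory), ]
  tibble::tibble(
    phk_activity = phk_rate(fin$gpb, drug, params),
    gp_activity = fin$gpa / params$gp_total,
    gs_activity = fin$gsa / params$gs_total,
    glycogen = fin$gly,
    g6p = fin$g6p
  )
}
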