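# Dose / condition scans over the three pathway models.

#' Endpoint dose scan of the glycogenolysis model
#'
#' Runs [simulate_glycogen()] at each drug concentration from the reference
#' state over a fixed horizon and summarises the endpoint with
#' [endpoint_summary()]. Over an ascending grid PHK flux and glycogen
#' phosphorylase activity fall, glycogen synthase activity rises, glycogen
#' accumulates and G6P drops - the cascade signature of competitive PHK
#' inhibition.
#'
#' @param params A [glycogen_params()] object.
#' @param drug_grid Drug concentrations, uM.
#' @param horizon Simulation horizon per dose, minutes.
#' @return A tibble with one row per dose: `drug_conc`, `phk_activity`,
#'   `gp_activity`, `gs_activity`, `glycogen`, `g6p`.
#' @export
glycogen_dose_scan <- function(params = glycogen_params(),
                               drug_grid = c(0, 10^seq(-2, 2, length.out = 9)),
                               horizon = 1000) {
  stopifnot(inherits(params, "glycogen_params"), all(drug_grid >= 0))
  init <- glycogen_initial_state(params)
  purrr::map_dfr(drug_grid, function(d) {
    ep <- endpoint_summary(simulate_glycogen(params, drug_conc = d,
                                             horizon = horizon,
                                             initial = init))
    dplyr::bind_cols(tibble::tibble(drug_conc = d), ep)
  })
}

#' Steady-state NADPH/NADP+ ratio across a G6P grid
#'
#' Maps each initial G6P content to the converged steady-state NADPH/NADP+
#' ratio of the oxidative pentose-phosphate model. The ratio is monotone
#' nondecreasing in G6P: less substrate, less oxidative flux, a more
#' oxidized pyridine pool.
#'
#' @param params A [ppp_params()] object.
#' @param g6p_grid Initial G6P contents, uM (>= 0).
#' @return A tibble with `g6p_initial`, `nadph_ratio`, `converged`.
#' @export
nadph_ratio_curve <- function(params = ppp_params(),
                              g6p_grid = seq(0, 200, by = 25)) {
  stopifnot(inherits(params, "ppp_params"), all(g6p_grid >= 0))
  purrr::map_dfr(g6p_grid, function(g) {
    ss <- steady_ppp(params, g6p_initial = g)
    tibble::tibble(g6p_initial = g, nadph_ratio = ss$nadph_ratio,
                   converged = ss$converged)
  })
}

#' Steady-state GSH across an NADPH-supply grid
#'
#' Maps each NADPH supply flux to the steady-state reduced-glutathione
#' concentration. Lower supply forces a higher GSSG burden to sustain the
#' peroxidase flux, draining GSH; at supply below the H2O2 load no steady
#' state exists and the point is flagged unconverged.
#'
#' @param params A [gsh_params()] object (its `k_nadph_supply` is ignored;
#'   the grid value is used).
#' @param supply_grid NADPH supply fluxes, uM/min (>= 0).
#' @return A tibble with `k_nadph_supply`, `gsh`, `gssg`, `converged`.
#' @export
gsh_vs_nadph <- function(params = gsh_params(),
                         supply_grid = seq(2.5, 10, by = 2.5)) {
  stopifnot(inherits(params, "gsh_params"), all(supply_grid >= 0))
  purrr::map_dfr(supply_grid, function(s) {
    p <- params
    p$k_nadph_supply <- s
    ss <- steady_gsh(p, max_horizon = 2e5)
    tibble::tibble(k_nadph_supply = s,
                   gsh = unname(ss$state[["gsh"]]),
                   gssg = unname(ss$state[["gssg"]]),
                   converged = ss$converged)
  })
}

#' Steady-state GSH across a vitamin-E load under reduced NADPH supply
#'
#' Fixes the NADPH supply at a fraction of its reference value (the drug
#' condition propagated by the tandem chain) and scans the vitamin-E pool.
#' Vitamin E quenches H2O2 directly, relieving the peroxidase flux and
#' letting GSH recover toward the unstressed level even though NADPH supply
#' stays depressed.
#'
#' @param params A [gsh_params()] object holding the *reference*
#'   `k_nadph_supply`.
#' @param vite_grid Vitamin-E pool values, uM (>= 0).
#' @param supply_frac Fraction of the reference NADPH supply representing
#'   the drug effect (default 0.5).
#' @return A tibble with `vite_pool`, `gsh`, `gssg`, `h2o2`, `converged`.
#' @export
gsh_vs_vitamin_e <- function(params = gsh_params(),
                             vite_grid = c(0, 10^seq(0, 6, by = 1)),
                             supply_frac = 0.5) {
  stopifnot(inherits(params, "gsh_params"), all(vite_grid >= 0),
            supply_frac >= 0)
  base <- params
  base$k_nadph_supply <- params$k_nadph_supply * supply_frac
  purrr::map_dfr(vite_grid, function(v) {
    p <- base
    p$vite_pool <- v
    if (p$k_vite_quench == 0 && v > 0) p$k_vite_quench <- 0.1
    ss <- steady_gsh(p, max_horizon = 2e5)
    tibble::tibble(vite_pool = v,
                   gsh = unname(ss$state[["gsh"]]),
                   gssg = unname(ss$state[["gssg"]]),
                   h2o2 = unname(ss$state[["h2o2"]]),
                   converged = ss$converged)
  })
}
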