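#' Reference parameters for the glycogenolysis cascade model
#'
#' Units are uM and minutes throughout; no compartment volumes. The defaults
#' are a self-consistent reference set constructed so that the drug-free
#' system has an exact interior steady state (half-active enzyme pools,
#' `g6p = k_g6p_in / k_g6p_out`, glycogen at half the pool scale); they are
#' stand-ins for a liver-like cell, not measurements.
#'
#' @param vmax_phk,km_phk Phosphorylase-kinase Vmax (uM/min) and Km (uM)
#'   toward inactive phosphorylase GPb.
#' @param ki_drug Competitive inhibition constant of the drug at PHK, uM.
#'   Default 5.5 uM, a reported sunitinib-PHK dissociation constant.
#' @param vmax_pp1,km_pp1 Phosphatase (PP1) kinetics, shared by GPa
#'   dephosphorylation and GSb activation.
#' @param k_gs_inact Per-min rate coupling glycogen-synthase inactivation to
#'   scaled PHK activity.
#' @param vmax_gp,km_gp_gly Glycogenolysis rate per uM active GPa, and the
#'   glycogen Km.
#' @param vmax_gs,km_gs_g6p Glycogen-synthesis rate per uM active GSa, and
#'   the G6P Km.
#' @param k_g6p_in,k_g6p_out Constant G6P supply (lumped hexokinase, uM/min)
#'   and first-order G6P drain into glycolysis (per min).
#' @param gp_total,gs_total Conserved enzyme pools, uM.
#' @param gly_cap Glycogen capacity, uM glucosyl units; synthesis carries a
#'   `(1 - gly/gly_cap)` saturation so accumulation is bounded.
#' @return A `glycogen_params` list.
#' @export
glycogen_params <- function(vmax_phk = 5, km_phk = 10, ki_drug = 5.5,
                            vmax_pp1 = 5, km_pp1 = 10, k_gs_inact = 1,
                            vmax_gp = 0.6, km_gp_gly = 5000,
                            vmax_gs = 0.8, km_gs_g6p = 100,
                            k_g6p_in = 10, k_g6p_out = 0.1,
                            gp_total = 10, gs_total = 10, gly_cap = 20000) {
  p <- as.list(environment())
  validate_params(p, "glycogen_params")
}

#' Reference parameters for the oxidative pentose-phosphate model
#'
#' Bi-substrate Michaelis-Menten kinetics for G6PD and 6PGD (each reducing
#' NADP+), a first-order NADPH demand regenerating NADP+, and a clamped G6P
#' supply relaxing toward its initial content. Units uM and minutes.
#'
#' @param vmax_g6pd,km_g6pd_g6p,km_g6pd_nadp Glucose-6-phosphate
#'   dehydrogenase kinetics.
#' @param vmax_6pgd,km_6pgd_6pg,km_6pgd_nadp 6-phosphogluconate
#'   dehydrogenase kinetics.
#' @param k_nadph_drain First-order NADPH consumption (per min).
#' @param k_g6p_refresh Relaxation rate of G6P toward its initial value
#'   (per min); set 0 for the pure initial-condition (depleting) variant.
#' @param nadp_total Conserved pyridine pool, uM.
#' @return A `ppp_params` list.
#' @export
ppp_params <- function(vmax_g6pd = 50, km_g6pd_g6p = 100, km_g6pd_nadp = 10,
                       vmax_6pgd = 50, km_6pgd_6pg = 20, km_6pgd_nadp = 10,
                       k_nadph_drain = 1, k_g6p_refresh = 1,
                       nadp_total = 100) {
  p <- as.list(environment())
  validate_params(p, "ppp_params")
}

#' Reference parameters for the glutathione redox model
#'
#' Glutathione peroxidase (2 GSH + H2O2 -> GSSG) and reductase
#' (GSSG + NADPH -> 2 GSH + NADP+) cycling against a constant H2O2 load,
#' with NADPH regenerated at a supply flux scaled by the oxidized fraction
#' of the pyridine pool. `k_nadph_supply` is the tandem interface parameter:
#' the upstream NADPH/NADP+ fold-change multiplies it. An optional vitamin-E
#' node quenches H2O2 directly by second-order kinetics against a
#' non-depleting tocopherol pool (`k_vite_quench * vite_pool = 0` disables
#' it). Units uM and minutes.
#'
#' @param k_h2o2_prod Constant H2O2 production, uM/min.
#' @param vmax_gpx,km_gpx_gsh,km_gpx_h2o2 Glutathione-peroxidase kinetics.
#' @param vmax_gr,km_gr_gssg,km_gr_nadph Glutathione-reductase kinetics.
#' @param k_nadph_supply NADPH regeneration flux, uM/min.
#' @param k_synth GSH de-novo synthesis, uM/min (0 closes the moiety).
#' @param k_efflux First-order GSSG efflux/degradation, per min.
#' @param k_vite_quench Second-order vitamin-E/H2O2 quench constant,
#'   per uM per min.
#' @param vite_pool Vitamin-E pool, uM, treated as non-depleting.
#' @param nadp_total Conserved pyridine pool, uM.
#' @param gsh_total_init Initial total glutathione `GSH + 2 GSSG`, uM.
#' @return A `gsh_params` list.
#' @export
gsh_params <- function(k_h2o2_prod = 2,
                       vmax_gpx = 50, km_gpx_gsh = 100, km_gpx_h2o2 = 1,
                       vmax_gr = 16, km_gr_gssg = 20, km_gr_nadph = 100,
                       k_nadph_supply = 5, k_synth = 0, k_efflux = 0,
                       k_vite_quench = 0.1, vite_pool = 0,
                       nadp_total = 100, gsh_total_init = 200) {
  p <- as.list(environment())
  validate_params(p, "gsh_params")
}

validate_params <- function(p, cls) {
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0,
                logical(1))
  if (any(bad)) {
    stop("parameters must be single non-negative numbers: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  # quantities that must be strictly positive for the rate laws to make sense
  zero_ok <- c("k_synth", "k_efflux", "k_vite_quench", "vite_pool",
               "k_g6p_refresh", "k_h2o2_prod")
  strict <- setdiff(names(p), zero_ok)
  bad <- vapply(p[strict], function(v) v <= 0, logical(1))
  if (any(bad)) {
    stop("parameters must be strictly positive: ",
         paste(strict[bad], collapse = ", "), call. = FALSE)
  }
  structure(p, class = c(cls, "pathway_params"))
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("<", class(x)[1], "> (uM, min)\n", sep = "")
  print(tibble::tibble(parameter = names(x), value = unlist(x)), n = Inf)
  invisible(x)
}

# which parameters carry a concentration dimension (scale with the unit),
# per model class; first-order (per-min) rates and the external drug /
# vitamin-E axis are unit-free
conc_scaling_fields <- function(cls) {
  switch(
    cls,
    glycogen_params = c("vmax_phk", "km_phk", "vmax_pp1", "km_pp1",
                        "km_gp_gly", "km_gs_g6p", "k_g6p_in",
                        "gp_total", "gs_total", "gly_cap"),
    ppp_params = c("vmax_g6pd", "km_g6pd_g6p", "km_g6pd_nadp",
                   "vmax_6pgd", "km_6pgd_6pg", "km_6pgd_nadp", "nadp_total"),
    gsh_params = c("k_h2o2_prod", "vmax_gpx", "km_gpx_gsh", "km_gpx_h2o2",
                   "vmax_gr", "km_gr_gssg", "km_gr_nadph", "k_nadph_supply",
                   "k_synth", "nadp_total", "gsh_total_init"),
    stop("no unit-scaling map for class ", cls, call. = FALSE)
  )
}

#' Rescale a model's internal concentration unit
#'
#' Multiplies every concentration-dimensioned parameter (Vmax in uM/min, Km,
#' pools, zero-order supply fluxes) by `factor`, leaving first-order per-min
#' rates and the external drug/vitamin-E axes untouched. Trajectories of the
#' rescaled model are the original trajectories times `factor`, so all
#' fold-changes are invariant - the contract that lets tandem-coupled models
#' use different baseline scales.
#'
#' @param params A `glycogen_params`, `ppp_params` or `gsh_params` object.
#' @param factor Positive unit-conversion factor.
#' @return Rescaled parameters of the same class.
#' @export
rescale_params <- function(params, factor) {
  stopifnot(inherits(params, "pathway_params"),
            is.numeric(factor), length(factor) == 1L, factor > 0)
  fields <- conc_scaling_fields(class(params)[1])
  for (f in fields) params[[f]] <- params[[f]] * factor
  params
}

#' Jitter a parameter set by multiplicative log-normal noise
#'
#' Each strictly positive parameter is multiplied by an independent
#' log-normal factor with unit mean and coefficient of variation `cv`
#' (zero-valued parameters such as disabled fluxes stay zero). Used to probe
#' robustness of qualitative model behaviour to the exact parameter values.
#'
#' @param params A `pathway_params` object.
#' @param cv Coefficient of variation of the multiplicative factor (>= 0).
#' @param seed Integer seed; the jitter is a pure function of
#'   `(params, cv, seed)`.
#' @return Jittered parameters of the same class.
#' @export
jitter_params <- function(params, cv, seed) {
  stopifnot(inherits(params, "pathway_params"), is.numeric(cv), cv >= 0)
  if (cv == 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  factors <- withr::with_seed(as.integer(seed), {
    exp(stats::rnorm(length(params), mean = -sdlog^2 / 2, sd = sdlog))
  })
  cls <- class(params)[1]
  for (i in seq_along(params)) {
    if (params[[i]] > 0) params[[i]] <- params[[i]] * factors[[i]]
  }
  validate_params(unclass(params)[names(params)], cls)
}

#' Write / read a parameter set as YAML
#'
#' The YAML carries the model class and a unit note alongside the values, so
#' a file round-trips to an identical object.
#'
#' @param params A `pathway_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` the
#'   reconstructed parameter object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pathway_params"))
  yaml::write_yaml(
    list(model = class(params)[1], units = "uM, min",
         parameters = lapply(unclass(params), identity)),
    path, precision = 15
  )
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  ctor <- switch(doc$model %||% "",
    glycogen_params = glycogen_params,
    ppp_params = ppp_params,
    gsh_params = gsh_params,
    stop("unknown model class in parameter file: ", doc$model, call. = FALSE)
  )
  do.call(ctor, lapply(doc$parameters, as.numeric))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
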