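# Tandem coupling of the three pathway models. Models stay independently
# parameterized (possibly on different concentration scales); only relative
# "dose changes" (fold-changes) of interface metabolites cross a boundary,
# and no feedback runs upstream.

#' Specify an interface between two adjacent models
#'
#' @param upstream,downstream Model identifiers
#'   (`"glycogen"`, `"ppp"`, `"gsh"`).
#' @param map Named character vector: names are upstream output quantities,
#'   values the downstream input they adjust (e.g.
#'   `c(g6p = "g6p_initial")`).
#' @param mode `"fold_change"` (default) multiplies the downstream input by
#'   the upstream ratio; `"absolute"` overwrites it with the upstream value
#'   (meaningful only when both models share a concentration scale).
#' @return An `interface_spec` list.
#' @export
interface_spec <- function(upstream, downstream, map,
                           mode = c("fold_change", "absolute")) {
  mode <- match.arg(mode)
  if (length(map) == 0L || is.null(names(map)) || any(names(map) == "")) {
    stop("`map` must be a non-empty named character vector", call. = FALSE)
  }
  structure(list(upstream = upstream, downstream = downstream,
                 map = map, mode = mode),
            class = "interface_spec")
}

#' Fold-changes of model outputs under a perturbation
#'
#' Runs one pathway model at baseline and under a perturbation and returns
#' the ratio perturbed/baseline of the requested output quantities - the
#' "degree of change" that crosses a tandem interface. Ratios are invariant
#' to the model's internal concentration unit (see [rescale_params()]).
#'
#' @param model `"glycogen"`, `"ppp"` or `"gsh"`.
#' @param params The model's parameter object.
#' @param perturbation Named list understood by the model:
#'   glycogen takes `drug_conc`; ppp takes `g6p_initial` (baseline 100 um of
#'   its own scale unless `baseline_g6p_initial` is given); gsh takes
#'   `supply_frac` and/or `vite_pool`. An empty list is the null
#'   perturbation.
#' @param quantities Output quantities to ratio. Glycogen endpoints:
#'   `phk_activity`, `gp_activity`, `gs_activity`, `glycogen`, `g6p`;
#'   ppp: `nadph_ratio`, `nadph`, `nadp`; gsh: `gsh`, `gssg`, `h2o2`.
#' @param horizon Glycogen endpoint horizon, minutes (steady states are
#'   used for ppp and gsh).
#' @param baseline_g6p_initial Baseline G6P content for the ppp model.
#' @return A tibble of class `fold_changes` with columns `quantity`,
#'   `baseline`, `perturbed`, `ratio`.
#' @export
fold_changes <- function(model = c("glycogen", "ppp", "gsh"), params,
                         perturbation = list(), quantities,
                         horizon = 1000, baseline_g6p_initial = 100) {
  model <- match.arg(model)
  evaluate <- switch(
    model,
    glycogen = function(pert) {
      d <- pert$drug_conc %||% 0
      ep <- endpoint_summary(simulate_glycogen(params, drug_conc = d,
                                               horizon = horizon))
      unlist(ep)
    },
    ppp = function(pert) {
      g <- pert$g6p_initial %||% baseline_g6p_initial
      ss <- steady_ppp(params, g6p_initial = g)
      c(nadph_ratio = ss$nadph_ratio, ss$state[c("nadph", "nadp")])
    },
    gsh = function(pert) {
      p <- params
      p$k_nadph_supply <- p$k_nadph_supply * (pert$supply_frac %||% 1)
      if (!is.null(pert$vite_pool)) p$vite_pool <- pert$vite_pool
      ss <- steady_gsh(p, max_horizon = 2e5)
      ss$state[c("gsh", "gssg", "h2o2")]
    }
  )
  base <- evaluate(list())
  pert <- evaluate(perturbation)
  missing <- setdiff(quantities, names(base))
  if (length(missing) > 0L) {
    stop("unknown quantities for model '", model, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(base[quantities] <= 0)) {
    stop("fold-changes need strictly positive baseline quantities",
         call. = FALSE)
  }
  out <- tibble::tibble(
    quantity = quantities,
    baseline = unname(base[quantities]),
    perturbed = unname(pert[quantities]),
    ratio = unname(pert[quantities] / base[quantities])
  )
  new_tibble_class(out, "fold_changes")
}

#' Propagate fold-changes into a downstream model configuration
#'
#' In fold-change mode each mapped downstream input is multiplied by the
#' upstream ratio; in absolute mode it is overwritten with the upstream
#' perturbed value. Inputs are located first among the configuration's
#' top-level elements, then inside its `params` object.
#'
#' @param fc A `fold_changes` tibble (or any data frame with `quantity`,
#'   `ratio`, `perturbed`).
#' @param spec An [interface_spec()].
#' @param downstream Named list configuring the downstream model, e.g.
#'   `list(params = ppp_params(), g6p_initial = 100)`.
#' @return The adjusted downstream configuration.
#' @export
propagate <- function(fc, spec, downstream) {
  stopifnot(inherits(spec, "interface_spec"), is.list(downstream))
  for (q in names(spec$map)) {
    row <- which(fc$quantity == q)
    if (length(row) != 1L) {
      stop("interface quantity '", q, "' missing from the fold-change table",
           call. = FALSE)
    }
    target <- spec$map[[q]]
    update <- function(old) {
      if (spec$mode == "fold_change") old * fc$ratio[row] else fc$perturbed[row]
    }
    if (target %in% names(downstream)) {
      downstream[[target]] <- update(downstream[[target]])
    } else if ("params" %in% names(downstream) &&
               target %in% names(downstream$params)) {
      downstream$params[[target]] <- update(downstream$params[[target]])
    } else {
      stop("downstream configuration has no input '", target, "'",
           call. = FALSE)
    }
  }
  downstream
}

#' Assemble a three-model tandem chain
#'
#' Defaults to the canonical chain: glycogen cascade endpoint G6P
#' fold-change scales the pentose-phosphate model's initial G6P; the
#' pentose-phosphate steady-state NADPH/NADP+ ratio fold-change scales the
#' glutathione model's NADPH supply flux.
#'
#' @param glycogen,ppp,gsh Parameter objects for the three models.
#' @param g6p_initial Baseline G6P content of the pentose-phosphate model
#'   (its own scale).
#' @param horizon_glycogen Endpoint horizon of the glycogen stage, minutes.
#' @param vite_pool Vitamin-E pool applied in the glutathione stage, uM.
#' @param interfaces List of two [interface_spec()]s connecting adjacent
#'   models.
#' @return A `tandem_chain` object for [run_tandem()].
#' @export
tandem_chain <- function(glycogen = glycogen_params(), ppp = ppp_params(),
                         gsh = gsh_params(), g6p_initial = 100,
                         horizon_glycogen = 1000, vite_pool = 0,
                         interfaces = list(
                           interface_spec("glycogen", "ppp",
                                          c(g6p = "g6p_initial")),
                           interface_spec("ppp", "gsh",
                                          c(nadph_ratio = "k_nadph_supply"))
                         )) {
  stopifnot(inherits(glycogen, "glycogen_params"),
            inherits(ppp, "ppp_params"), inherits(gsh, "gsh_params"),
            length(interfaces) == 2L)
  ok <- identical(interfaces[[1]]$upstream, "glycogen") &&
    identical(interfaces[[1]]$downstream, "ppp") &&
    identical(interfaces[[2]]$upstream, "ppp") &&
    identical(interfaces[[2]]$downstream, "gsh")
  if (!ok) stop("interfaces must connect glycogen->ppp and ppp->gsh",
                call. = FALSE)
  structure(
    list(glycogen = glycogen, ppp = ppp, gsh = gsh,
         g6p_initial = g6p_initial, horizon_glycogen = horizon_glycogen,
         vite_pool = vite_pool, interfaces = interfaces),
    class = "tandem_chain"
  )
}

#' End-to-end dose scan through the tandem chain
#'
#' For each drug dose: the glycogen cascade is simulated to its endpoint
#' horizon; the G6P fold-change relative to the zero-dose endpoint crosses
#' interface 1; the pentose-phosphate model is run to steady state at the
#' scaled G6P; the NADPH/NADP+ ratio fold-change crosses interface 2; the
#' glutathione model is run to steady state at the scaled NADPH supply. A
#' stage failure at one dose is recorded (`converged = FALSE`, `NA`
#' endpoints) and the scan continues.
#'
#' @param chain A [tandem_chain()].
#' @param drug_grid Drug concentrations, uM; should include 0 (the baseline
#'   every fold-change is taken against is always computed at dose 0).
#' @return A tibble of class `tandem_scan`, one row per dose, with the
#'   glycogen endpoints, `g6p_fold`, `nadph_ratio`, `nadph_ratio_fold`,
#'   `gsh`, `gsh_fold`, `converged`.
#' @export
run_tandem <- function(chain, drug_grid = c(0, 10^seq(-2, 2, length.out = 9))) {
  stopifnot(inherits(chain, "tandem_chain"), all(drug_grid >= 0))
  init <- glycogen_initial_state(chain$glycogen)
  gly_endpoint <- function(dose) {
    endpoint_summary(simulate_glycogen(chain$glycogen, drug_conc = dose,
                                       horizon = chain$horizon_glycogen,
                                       initial = init))
  }
  base_gly <- gly_endpoint(0)
  base_ppp <- steady_ppp(chain$ppp, g6p_initial = chain$g6p_initial)
  gsh_base_par <- chain$gsh
  gsh_base_par$vite_pool <- chain$vite_pool
  base_gsh <- steady_gsh(gsh_base_par, max_horizon = 2e5)
  if (base_gly$g6p <= 0 || base_ppp$nadph_ratio <= 0) {
    stop("tandem baseline interface quantities must be positive", call. = FALSE)
  }

  rows <- purrr::map_dfr(drug_grid, function(dose) {
    tryCatch({
      ep <- gly_endpoint(dose)
      fc1 <- tibble::tibble(quantity = "g6p", baseline = base_gly$g6p,
                            perturbed = ep$g6p,
                            ratio = ep$g6p / base_gly$g6p)
      cfg_ppp <- propagate(fc1, chain$interfaces[[1]],
                           list(params = chain$ppp,
                                g6p_initial = chain$g6p_initial))
      ss_ppp <- steady_ppp(cfg_ppp$params, g6p_initial = cfg_ppp$g6p_initial)
      fc2 <- tibble::tibble(quantity = "nadph_ratio",
                            baseline = base_ppp$nadph_ratio,
                            perturbed = ss_ppp$nadph_ratio,
                            ratio = ss_ppp$nadph_ratio / base_ppp$nadph_ratio)
      cfg_gsh <- propagate(fc2, chain$interfaces[[2]],
                           list(params = gsh_base_par))
      ss_gsh <- steady_gsh(cfg_gsh$params, max_horizon = 2e5)
      dplyr::bind_cols(
        tibble::tibble(drug_conc = dose), ep,
        tibble::tibble(
          g6p_fold = fc1$ratio,
          nadph_ratio = ss_ppp$nadph_ratio,
          nadph_ratio_fold = fc2$ratio,
          gsh = unname(ss_gsh$state[["gsh"]]),
          gsh_fold = unname(ss_gsh$state[["gsh"]]) /
            unname(base_gsh$state[["gsh"]]),
          converged = ss_ppp$converged && ss_gsh$converged
        )
      )
    }, error = function(e) {
      tibble::tibble(
        drug_conc = dose, phk_activity = NA_real_, gp_activity = NA_real_,
        gs_activity = NA_real_, glycogen = NA_real_, g6p = NA_real_,
        g6p_fold = NA_real_, nadph_ratio = NA_real_,
        nadph_ratio_fold = NA_real_, gsh = NA_real_, gsh_fold = NA_real_,
        converged = FALSE
      )
    })
  })
  out <- new_tibble_class(rows, "tandem_scan")
  attr(out, "baseline") <- list(
    glycogen = base_gly, nadph_ratio = base_ppp$nadph_ratio,
    gsh = unname(base_gsh$state[["gsh"]])
  )
  out
}
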