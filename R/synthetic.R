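# Seedable generators for every input the pipeline consumes: two-drug
# kinome tables with planted off-targets, inhibition-assay curves with
# known IC50, and jittered parameter sets (see jitter_params()).

#' Describe a two-drug kinome scenario
#'
#' Emulates the structure of a drug pair that shares its primary targets
#' while only drug A binds a small set of off-targets: shared primaries get
#' tight Kd for both drugs, planted off-targets get intermediate Kd for
#' drug A and are censored for drug B, everything else gets weak background
#' Kd for both. The default ranges put primaries near saturation for both
#' drugs at the default exposures and guarantee every planted off-target
#' clears the documented shortlist thresholds (occupancy >= 0.5 for A,
#' <= 0.1 for B): off-target Kd never exceeds drug A's exposure.
#'
#' @param n_kinases Panel size.
#' @param n_shared_primary Number of shared primary targets.
#' @param n_offtarget_a Number of drug-A-only off-targets.
#' @param kd_primary_range,kd_offtarget_range,kd_background_range Kd
#'   sampling intervals, uM.
#' @param exposures Named numeric: unbound steady-state exposure per drug,
#'   uM.
#' @param seed Integer seed; generation is a pure function of the scenario.
#' @return A `kinome_scenario` list.
#' @export
kinome_scenario <- function(n_kinases = 50, n_shared_primary = 3,
                            n_offtarget_a = 4,
                            kd_primary_range = c(0.001, 0.05),
                            kd_offtarget_range = c(0.1, 0.5),
                            kd_background_range = c(10, 10000),
                            exposures = c(drug_a = 0.5, drug_b = 0.5),
                            seed = 1L) {
  stopifnot(n_shared_primary + n_offtarget_a <= n_kinases,
            length(exposures) == 2L, !is.null(names(exposures)),
            all(exposures >= 0))
  for (r in list(kd_primary_range, kd_offtarget_range, kd_background_range)) {
    stopifnot(length(r) == 2L, all(r > 0), r[1] <= r[2])
  }
  structure(as.list(environment()), class = "kinome_scenario")
}

#' Generate a two-drug kinome affinity table with planted truth
#'
#' @param scenario A [kinome_scenario()].
#' @return A list with `affinities` (tibble: `kinase_id`, `drug_id`, `kd`;
#'   censored = `NA`), `exposures` (tibble: `drug_id`, `cpuss`) and `truth`
#'   (list with `primary_ids`, `offtarget_ids`).
#' @export
generate_kinome_table <- function(scenario = kinome_scenario()) {
  stopifnot(inherits(scenario, "kinome_scenario"))
  s <- scenario
  drugs <- names(s$exposures)
  withr::with_seed(as.integer(s$seed), {
    ids <- sprintf("KIN%03d", seq_len(s$n_kinases))
    primary <- ids[seq_len(s$n_shared_primary)]
    offtarget <- ids[s$n_shared_primary + seq_len(s$n_offtarget_a)]
    background <- setdiff(ids, c(primary, offtarget))
    runif_range <- function(n, r) stats::runif(n, r[1], r[2])
    kd_a <- c(
      stats::setNames(runif_range(length(primary), s$kd_primary_range), primary),
      stats::setNames(runif_range(length(offtarget), s$kd_offtarget_range), offtarget),
      stats::setNames(runif_range(length(background), s$kd_background_range), background)
    )
    kd_b <- c(
      stats::setNames(runif_range(length(primary), s$kd_primary_range), primary),
      stats::setNames(rep(NA_real_, length(offtarget)), offtarget),
      stats::setNames(runif_range(length(background), s$kd_background_range), background)
    )
    affinities <- dplyr::bind_rows(
      tibble::tibble(kinase_id = ids, drug_id = drugs[1], kd = unname(kd_a[ids])),
      tibble::tibble(kinase_id = ids, drug_id = drugs[2], kd = unname(kd_b[ids]))
    )
    list(
      affinities = affinities,
      exposures = tibble::tibble(drug_id = drugs, cpuss = unname(s$exposures)),
      truth = list(primary_ids = primary, offtarget_ids = offtarget)
    )
  })
}

#' Describe an inhibition-assay scenario
#'
#' @param true_ic50 True IC50, uM.
#' @param true_hill True Hill slope.
#' @param top,bottom Uninhibited and fully inhibited signal levels.
#' @param conc_grid Inhibitor concentrations, uM; must include 0 and span
#'   at least two log units of positive concentration.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   noise (0 = noise-free).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return An `assay_scenario` list.
#' @export
assay_scenario <- function(true_ic50 = 5.5, true_hill = 1,
                           top = 100, bottom = 5,
                           conc_grid = c(0, 10^seq(-1.5, 2, length.out = 8)),
                           noise_cv = 0, replicates = 1L, seed = 1L) {
  stopifnot(true_ic50 > 0, true_hill > 0, bottom <= top, noise_cv >= 0,
            replicates >= 1L, any(conc_grid == 0))
  pos <- conc_grid[conc_grid > 0]
  if (length(pos) < 4L || log10(max(pos) / min(pos)) < 2) {
    stop("conc_grid needs >= 4 positive points spanning >= 2 log units",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "assay_scenario")
}

#' Generate an inhibition-assay curve with known truth
#'
#' Responses follow the four-parameter logistic [four_pl()] with
#' multiplicative Gaussian noise of the stated CV.
#'
#' @param scenario An [assay_scenario()].
#' @return A list with `assay` (tibble: `conc`, `response`, `replicate`)
#'   and `truth` (list of the generating parameters).
#' @export
generate_assay_curve <- function(scenario = assay_scenario()) {
  stopifnot(inherits(scenario, "assay_scenario"))
  s <- scenario
  conc <- rep(s$conc_grid, each = s$replicates)
  mu <- four_pl(conc, s$true_ic50, s$true_hill, s$top, s$bottom)
  response <- withr::with_seed(as.integer(s$seed), {
    mu * (1 + s$noise_cv * stats::rnorm(length(mu)))
  })
  response <- pmax(response, 1e-9)
  list(
    assay = tibble::tibble(
      conc = conc,
      response = response,
      replicate = rep(seq_len(s$replicates), times = length(s$conc_grid))
    ),
    truth = list(ic50 = s$true_ic50, hill = s$true_hill,
                 top = s$top, bottom = s$bottom)
  )
}
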