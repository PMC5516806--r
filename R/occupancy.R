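#' Fractional kinase occupancy from Kd and unbound exposure
#'
#' Occupancy of a kinase by a drug at equilibrium is `C / (Kd + C)`, where
#' `C` is the mean unbound plasma concentration at steady state (the free
#' concentration in cells is assumed to equilibrate with the unbound plasma
#' concentration) and `Kd` the dissociation constant of the drug-kinase pair.
#' A censored Kd (`NA`, "no measurable binding") yields occupancy 0.
#'
#' @param kd Dissociation constant(s), uM. Must be positive; `NA` marks a
#'   censored ("no binding") measurement.
#' @param cpuss Mean unbound plasma concentration(s) at steady state, uM
#'   (non-negative). Recycled against `kd`.
#' @return A numeric vector of occupancies in `[0, 1)`.
#' @examples
#' compute_occupancy(kd = 5.5, cpuss = 5.5)   # half occupancy at C = Kd
#' compute_occupancy(kd = c(1, NA), cpuss = 9)
#' @export
compute_occupancy <- function(kd, cpuss) {
  if (!is.numeric(kd) || !is.numeric(cpuss)) {
    stop("`kd` and `cpuss` must be numeric", call. = FALSE)
  }
  if (any(!is.na(kd) & kd <= 0)) {
    stop("`kd` must be positive (NA marks a censored measurement)", call. = FALSE)
  }
  if (any(is.na(cpuss)) || any(cpuss < 0)) {
    stop("`cpuss` must be non-negative and not NA", call. = FALSE)
  }
  occ <- cpuss / (kd + cpuss)
  occ[is.na(kd)] <- 0
  occ
}

#' Occupancy profile of one drug across a kinase panel
#'
#' Joins a drug-kinase affinity table with an exposure table and applies
#' [compute_occupancy()] per kinase.
#'
#' @param affinities Data frame with columns `kinase_id`, `drug_id`, `kd`
#'   (uM, `NA` = censored). `(kinase_id, drug_id)` pairs must be unique.
#' @param exposures Data frame with columns `drug_id`, `cpuss` (uM).
#' @param drug Drug identifier to profile; must occur in both tables.
#' @return A tibble of class `occupancy_profile` with columns `kinase_id`,
#'   `drug_id`, `kd`, `cpuss`, `occupancy`, sorted by `kinase_id`.
#' @examples
#' aff <- tibble::tibble(
#'   kinase_id = c("K1", "K2", "K3"), drug_id = "drugA", kd = c(1, 9, NA)
#' )
#' exp <- tibble::tibble(drug_id = "drugA", cpuss = 1)
#' occupancy_profile(aff, exp, "drugA")
#' @export
occupancy_profile <- function(affinities, exposures, drug) {
  check_affinity_table(affinities)
  check_exposure_table(exposures)
  stopifnot(is.character(drug), length(drug) == 1L)
  rows <- dplyr::filter(affinities, .data$drug_id == drug)
  if (nrow(rows) == 0L) {
    stop("drug '", drug, "' has no entries in the affinity table", call. = FALSE)
  }
  exp_row <- dplyr::filter(exposures, .data$drug_id == drug)
  if (nrow(exp_row) != 1L) {
    stop("drug '", drug, "' must have exactly one exposure entry", call. = FALSE)
  }
  out <- rows |>
    dplyr::mutate(
      cpuss = exp_row$cpuss,
      occupancy = compute_occupancy(.data$kd, exp_row$cpuss)
    ) |>
    dplyr::arrange(.data$kinase_id) |>
    dplyr::select("kinase_id", "drug_id", "kd", "cpuss", "occupancy")
  new_tibble_class(out, "occupancy_profile")
}

#' Differential off-target candidates between two occupancy profiles
#'
#' Shortlists kinases that drug A occupies strongly while drug B leaves
#' essentially free - the signature of a drug-specific off-target between two
#' compounds that share their primary targets. Profiles are aligned on the
#' union of kinases (a kinase missing from one profile gets occupancy 0
#' there). Candidates satisfy `occupancy_a >= min_occ_a` and
#' `occupancy_b <= max_occ_b`, ranked by `delta = occupancy_a - occupancy_b`
#' descending, ties broken lexicographically by `kinase_id`.
#'
#' The thresholds have no universal values; the defaults (0.5, 0.1) demand
#' majority occupancy by drug A at clinical exposure and near-absent binding
#' by drug B.
#'
#' @param profile_a,profile_b Occupancy profiles from [occupancy_profile()]
#'   (any data frame with `kinase_id` and `occupancy` columns works).
#' @param min_occ_a Minimum drug-A occupancy, in `[0, 1]`.
#' @param max_occ_b Maximum drug-B occupancy, in `[0, 1]`.
#' @return A tibble of class `differential_hits` with columns `kinase_id`,
#'   `occupancy_a`, `occupancy_b`, `delta`.
#' @export
differential_candidates <- function(profile_a, profile_b,
                                    min_occ_a = 0.5, max_occ_b = 0.1) {
  for (thr in list(min_occ_a, max_occ_b)) {
    if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) || thr < 0 || thr > 1) {
      stop("occupancy thresholds must be single numbers in [0, 1]", call. = FALSE)
    }
  }
  a <- dplyr::select(tibble::as_tibble(profile_a), "kinase_id", occupancy_a = "occupancy")
  b <- dplyr::select(tibble::as_tibble(profile_b), "kinase_id", occupancy_b = "occupancy")
  out <- dplyr::full_join(a, b, by = "kinase_id") |>
    tidyr::replace_na(list(occupancy_a = 0, occupancy_b = 0)) |>
    dplyr::mutate(delta = .data$occupancy_a - .data$occupancy_b) |>
    dplyr::filter(.data$occupancy_a >= min_occ_a, .data$occupancy_b <= max_occ_b) |>
    dplyr::arrange(dplyr::desc(.data$delta), .data$kinase_id)
  new_tibble_class(out, "differential_hits")
}

#' Read a drug-kinase affinity table from delimited text
#'
#' Expects header columns `kinase_id`, `drug_id`, `kd` and optionally `unit`
#' (`"nM"` or `"uM"`, default uM; nM values are converted to uM). Blank or
#' `NA` kd fields mark censored ("no binding") entries. The delimiter is
#' taken from the file extension (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `kinase_id`, `drug_id`, `kd` (uM).
#' @export
read_affinity_table <- function(path) {
  raw <- read_delimited(path)
  need <- c("kinase_id", "drug_id", "kd")
  if (!all(need %in% names(raw))) {
    stop("affinity table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  kd <- suppressWarnings(as.numeric(raw$kd))
  if ("unit" %in% names(raw)) {
    unit <- tolower(trimws(as.character(raw$unit)))
    if (!all(unit %in% c("nm", "um"))) {
      stop("affinity `unit` column values must be 'nM' or 'uM'", call. = FALSE)
    }
    kd <- ifelse(unit == "nm", kd / 1000, kd)
  }
  out <- tibble::tibble(
    kinase_id = as.character(raw$kinase_id),
    drug_id = as.character(raw$drug_id),
    kd = kd
  )
  check_affinity_table(out)
  out
}

#' Read a drug exposure table from delimited text
#'
#' Expects header columns `drug_id` and `cpuss_uM` (or `cpuss`), the mean
#' unbound plasma concentration at steady state in uM.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `drug_id`, `cpuss`.
#' @export
read_exposure_table <- function(path) {
  raw <- read_delimited(path)
  cp_col <- intersect(c("cpuss_uM", "cpuss_um", "cpuss"), names(raw))[1]
  if (!"drug_id" %in% names(raw) || is.na(cp_col)) {
    stop("exposure table must have columns drug_id and cpuss_uM", call. = FALSE)
  }
  out <- tibble::tibble(
    drug_id = as.character(raw$drug_id),
    cpuss = as.numeric(raw[[cp_col]])
  )
  check_exposure_table(out)
  out
}

check_affinity_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("kinase_id", "drug_id", "kd")
  if (!all(need %in% names(x))) {
    stop("affinity table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$kd) & x$kd <= 0)) {
    stop("affinity table kd values must be positive or censored (NA)", call. = FALSE)
  }
  if (anyDuplicated(x[c("kinase_id", "drug_id")])) {
    stop("(kinase_id, drug_id) pairs must be unique in an affinity table",
         call. = FALSE)
  }
  invisible(x)
}

check_exposure_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("drug_id", "cpuss") %in% names(x))) {
    stop("exposure table must have columns drug_id and cpuss", call. = FALSE)
  }
  if (any(is.na(x$cpuss)) || any(x$cpuss < 0)) {
    stop("cpuss must be non-negative", call. = FALSE)
  }
  invisible(x)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    na = c("", "NA"), col_types = readr::cols(.default = "c"))
}

new_tibble_class <- function(x, cls) {
  class(x) <- c(cls, class(tibble::as_tibble(x)))
  x
}
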