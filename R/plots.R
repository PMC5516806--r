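# ggplot2 views of the main result types.

#' Compare two kinase occupancy profiles
#'
#' Scatter of per-kinase occupancy for drug A against drug B; differential
#' off-targets sit near the bottom-right corner. Candidate thresholds are
#' drawn as dashed guides.
#'
#' @param profile_a,profile_b [occupancy_profile()] tibbles.
#' @param min_occ_a,max_occ_b Thresholds to draw (defaults match
#'   [differential_candidates()]).
#' @return A ggplot object.
#' @export
plot_occupancy_comparison <- function(profile_a, profile_b,
                                      min_occ_a = 0.5, max_occ_b = 0.1) {
  a <- dplyr::select(tibble::as_tibble(profile_a), "kinase_id",
                     occupancy_a = "occupancy")
  b <- dplyr::select(tibble::as_tibble(profile_b), "kinase_id",
                     occupancy_b = "occupancy")
  df <- dplyr::full_join(a, b, by = "kinase_id") |>
    tidyr::replace_na(list(occupancy_a = 0, occupancy_b = 0)) |>
    dplyr::mutate(candidate = .data$occupancy_a >= min_occ_a &
                    .data$occupancy_b <= max_occ_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$occupancy_a, .data$occupancy_b,
                                   colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = min_occ_a, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = max_occ_b, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#D55E00")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "occupancy, drug A", y = "occupancy, drug B",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @method autoplot ic50_fit
#' @export
autoplot.ic50_fit <- function(object, n_curve = 200, ...) {
  pos <- object$data$conc[object$data$conc > 0]
  grid <- c(0, exp(seq(log(min(pos)) - 1, log(max(pos)) + 1,
                       length.out = n_curve)))
  curve <- tibble::tibble(conc = grid,
                          response = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$response)) +
    ggplot2::geom_line(data = curve, colour = "#0072B2") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_continuous(
      trans = scales_pseudo_log(),
      name = "inhibitor concentration (uM)") +
    ggplot2::labs(y = "remaining signal",
                  title = sprintf("IC50 = %.3g uM (Hill %.2g)",
                                  object$ic50, object$hill)) +
    ggplot2::theme_minimal()
}

# pseudo-log keeps the zero-inhibitor point on a log-like axis
scales_pseudo_log <- function() scales::pseudo_log_trans(sigma = 0.01, base = 10)

#' @method autoplot pathway_trajectory
#' @export
autoplot.pathway_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "species", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)",
                  title = paste0(attr(object, "model"), " trajectory")) +
    ggplot2::theme_minimal()
}

#' @method autoplot tandem_scan
#' @export
autoplot.tandem_scan <- function(object, ...) {
  keep <- c("phk_activity", "gp_activity", "gs_activity", "glycogen",
            "g6p", "nadph_ratio", "gsh")
  long <- tibble::as_tibble(object) |>
    dplyr::select("drug_conc", dplyr::all_of(keep)) |>
    tidyr::pivot_longer(-"drug_conc", names_to = "readout",
                        values_to = "value") |>
    dplyr::mutate(readout = factor(.data$readout, levels = keep))
  ggplot2::ggplot(long, ggplot2::aes(.data$drug_conc, .data$value)) +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log(),
                                name = "drug concentration (uM)") +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(y = NULL, title = "tandem dose scan") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
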