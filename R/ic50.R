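#' Four-parameter logistic used for inhibition curves
#'
#' `response(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`; at c = 0
#' the response equals `top` (no inhibition).
#'
#' @param conc Inhibitor concentrations, uM (non-negative).
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill slope (> 0).
#' @param top,bottom Uninhibited and fully inhibited response levels.
#' @return Predicted responses.
#' @export
four_pl <- function(conc, ic50, hill, top, bottom) {
  stopifnot(all(conc >= 0), ic50 > 0, hill > 0)
  frac <- ifelse(conc == 0, 0, (conc / ic50)^hill)
  bottom + (top - bottom) / (1 + frac)
}

#' Fit an IC50 from an in-vitro inhibition assay curve
#'
#' Fits the four-parameter logistic [four_pl()] to remaining-substrate signal
#' (e.g. residual ATP in a luminescent kinase assay) versus inhibitor
#' concentration by uniformly weighted nonlinear least squares
#' (Levenberg-Marquardt, multi-started from a log-spaced grid of IC50
#' guesses spanning the positive concentrations). The minimized objective -
#' the unweighted residual sum of squares - is the contract; the optimizer
#' is an implementation detail. Because the signal is a concentration
#' readout, both plateaus are constrained non-negative.
#'
#' @param data Data frame with one row per measured point.
#' @param conc,response Column names (unquoted or strings) holding inhibitor
#'   concentration (uM) and signal (arbitrary units, > 0).
#' @param fix_hill Optional fixed Hill slope (e.g. `1`); default `NULL`
#'   estimates the slope.
#' @return An object of class `ic50_fit`: see [tidy.ic50_fit()],
#'   [glance.ic50_fit()], [autoplot.ic50_fit()]. Key fields: `ic50`, `hill`,
#'   `top`, `bottom`, `rss`, `converged`, `extrapolated` (TRUE when the
#'   fitted IC50 falls outside the spanned positive concentration range).
#' @export
fit_ic50 <- function(data, conc = "conc", response = "response",
                     fix_hill = NULL) {
  conc_col <- rlang::as_name(rlang::enquo(conc))
  resp_col <- rlang::as_name(rlang::enquo(response))
  stopifnot(is.data.frame(data), all(c(conc_col, resp_col) %in% names(data)))
  x <- as.numeric(data[[conc_col]])
  y <- as.numeric(data[[resp_col]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (any(x < 0)) stop("inhibitor concentrations must be >= 0", call. = FALSE)
  if (any(y <= 0)) stop("responses must be positive", call. = FALSE)
  if (length(unique(x)) < 4L) {
    stop("need at least 4 distinct inhibitor concentrations", call. = FALSE)
  }
  if (!any(x == 0)) {
    warning("no zero-inhibitor point; top plateau may be poorly determined")
  }
  if (stats::sd(y) < 1e-8 * max(abs(y))) {
    stop("flat curve: responses carry no inhibition signal, IC50 is not identifiable",
         call. = FALSE)
  }

  pos <- sort(unique(x[x > 0]))
  starts_ic50 <- exp(seq(log(min(pos)), log(max(pos)), length.out = 7))
  top0 <- max(y); bot0 <- min(y)
  df <- data.frame(x = x, y = y)

  fit_one <- function(ic50_0) {
    if (is.null(fix_hill)) {
      form <- y ~ four_pl(x, exp(lic50), hill, top, bottom)
      start <- list(lic50 = log(ic50_0), hill = 1, top = top0, bottom = bot0)
      lower <- c(-Inf, 1e-3, 0, 0)
    } else {
      form <- y ~ four_pl(x, exp(lic50), fix_hill, top, bottom)
      start <- list(lic50 = log(ic50_0), top = top0, bottom = bot0)
      lower <- c(-Inf, 0, 0)
    }
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = df, start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
  }

  fits <- lapply(starts_ic50, fit_one)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    stop("IC50 fit failed to converge from every starting value", call. = FALSE)
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  ic50 <- unname(exp(cf["lic50"]))
  hill <- if (is.null(fix_hill)) unname(cf["hill"]) else fix_hill
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  if (bottom > top) { # relabel so bottom <= top (slope sign absorbed by hill)
    tmp <- top; top <- bottom; bottom <- tmp
  }
  converged <- isTRUE(best$convInfo$isConv)
  if (!converged) {
    warning("IC50 fit did not formally converge; parameters returned as-is")
  }
  se <- tryCatch({
    s <- summary(best)$coefficients
    out <- s[, "Std. Error"]
    # delta method: sd(ic50) = ic50 * sd(log ic50)
    out["lic50"] <- ic50 * out["lic50"]
    names(out)[names(out) == "lic50"] <- "ic50"
    out
  }, error = function(e) NULL)

  structure(
    list(
      ic50 = ic50, hill = hill, top = top, bottom = bottom,
      rss = min(rss), converged = converged,
      extrapolated = ic50 < min(pos) || ic50 > max(pos),
      fixed_hill = !is.null(fix_hill),
      std_error = se, n = length(x), fit = best,
      data = tibble::tibble(conc = x, response = y)
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Four-parameter logistic inhibition fit\n")
  cat(sprintf("  IC50: %.4g uM%s\n", x$ic50,
              if (x$extrapolated) " (extrapolated beyond assayed range)" else ""))
  cat(sprintf("  Hill: %.4g%s   top: %.4g   bottom: %.4g\n",
              x$hill, if (x$fixed_hill) " (fixed)" else "", x$top, x$bottom))
  cat(sprintf("  RSS: %.4g over %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' Tidy an IC50 fit into one row per parameter
#'
#' @param x An `ic50_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy ic50_fit
#' @export
tidy.ic50_fit <- function(x, ...) {
  terms <- c("ic50", "hill", "top", "bottom")
  est <- c(x$ic50, x$hill, x$top, x$bottom)
  se <- rep(NA_real_, 4)
  if (!is.null(x$std_error)) {
    m <- match(c("ic50", "hill", "top", "bottom"), names(x$std_error))
    se <- unname(x$std_error[m])
  }
  tibble::tibble(term = terms, estimate = est, std.error = se)
}

#' One-row summary of an IC50 fit
#'
#' @param x An `ic50_fit`.
#' @param ... Unused.
#' @return A tibble with `ic50`, `hill`, `rss`, `sigma`, `n`, `converged`,
#'   `extrapolated`.
#' @method glance ic50_fit
#' @export
glance.ic50_fit <- function(x, ...) {
  p <- if (x$fixed_hill) 3L else 4L
  tibble::tibble(
    ic50 = x$ic50, hill = x$hill, rss = x$rss,
    sigma = sqrt(x$rss / max(x$n - p, 1L)),
    n = x$n, converged = x$converged, extrapolated = x$extrapolated
  )
}

#' @export
predict.ic50_fit <- function(object, conc, ...) {
  four_pl(conc, object$ic50, object$hill, object$top, object$bottom)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
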