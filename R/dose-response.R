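# Competitive-uptake dose-response analysis: plate normalization and
# four-parameter log-logistic IC50 fitting.

#' Background-subtract and protein-normalize plate wells
#'
#' `value = (fluorescence - mean(background)) / protein` per well. Wells with
#' non-positive protein content cannot be normalized and are excluded with a
#' warning.
#'
#' @param wells data frame with columns `conc_nmol_l`, `fluorescence`,
#'   `protein_ug` (and optionally `condition`, `replicate`).
#' @param background_wells numeric vector of fluorescence readings from wells
#'   not incubated with carrier (cells-only background).
#' @return The input data frame with an added `uptake` column
#'   (units/microgram protein), excluded wells removed.
#' @export
normalize_wells <- function(wells, background_wells) {
  assert_that(is.data.frame(wells) &&
                all(c("conc_nmol_l", "fluorescence", "protein_ug") %in% names(wells)),
              "`wells` must have columns conc_nmol_l, fluorescence, protein_ug")
  assert_that(length(background_wells) >= 1L,
              "need at least one background well")
  bad <- !(wells$protein_ug > 0)
  if (any(bad)) {
    warning(sprintf("excluding %d well(s) with non-positive protein content", sum(bad)))
    wells <- wells[!bad, , drop = FALSE]
  }
  wells$uptake <- (wells$fluorescence - mean(background_wells)) / wells$protein_ug
  wells
}

# 4PL response: decreasing from `top` to `bottom` with midpoint ic50
four_pl <- function(conc, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Four-parameter log-logistic IC50 fit
#'
#' Fits `y(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill)` to
#' concentration-response data by nonlinear least squares
#' ([minpack.lm::nlsLM()]), parameterizing the concentration axis as log10
#' for conditioning. The reported IC50 is the relative IC50 (curve
#' inflection). Starting values are derived from the data: `top`/`bottom`
#' from the extreme concentrations and IC50 from the concentration nearest
#' half-response. Zero-concentration wells anchor the `top` start value but
#' are excluded from the log-logistic abscissa. The fit is invariant to
#' rescaling all responses: `top`/`bottom` scale, IC50 and hill do not.
#'
#' @param table data frame with columns `conc_nmol_l` and `uptake` (e.g.
#'   from [normalize_wells()] or [simulate_dose_response()]).
#' @param fix_hill optionally constrain the Hill slope (e.g. `1`).
#' @param fix_bottom optionally constrain the lower asymptote (e.g. `0`).
#' @return An object of class `ic50_fit`: `ic50` (nmol/l), `hill`, `top`,
#'   `bottom`, `residual_sse`, `converged`, and the underlying `nls` object
#'   (`NULL` on failure). Supports `print()`, `coef()`, `predict()` and
#'   `plot()`. Non-convergence or a degenerate (flat) response is flagged
#'   via `converged = FALSE`, never reported as a silent number.
#' @examples
#' tab <- simulate_dose_response(344, concentrations = 10^seq(1, 4, length.out = 8))
#' fit <- fit_ic50(tab)
#' fit
#' @export
fit_ic50 <- function(table, fix_hill = NULL, fix_bottom = NULL) {
  assert_that(is.data.frame(table) &&
                all(c("conc_nmol_l", "uptake") %in% names(table)),
              "`table` must have columns conc_nmol_l and uptake")
  zero <- table$conc_nmol_l == 0
  d <- table[!zero, , drop = FALSE]
  assert_that(all(d$conc_nmol_l > 0), "concentrations must be non-negative")
  assert_that(length(unique(d$conc_nmol_l)) >= 4L,
              "need at least 4 distinct positive concentrations")
  d <- d[order(d$conc_nmol_l), , drop = FALSE]
  d$lc <- log10(d$conc_nmol_l)

  # data-driven starts
  lo_c <- min(d$conc_nmol_l); hi_c <- max(d$conc_nmol_l)
  top0 <- if (any(zero)) mean(table$uptake[zero]) else
    mean(d$uptake[d$conc_nmol_l == lo_c])
  bot0 <- mean(d$uptake[d$conc_nmol_l == hi_c])
  mid <- (top0 + bot0) / 2
  ic0 <- d$conc_nmol_l[which.min(abs(d$uptake - mid))]

  failed <- function(msg) {
    warning(paste("IC50 fit not converged:", msg))
    structure(list(ic50 = NA_real_, hill = NA_real_, top = top0,
                   bottom = bot0, residual_sse = NA_real_,
                   converged = FALSE, fit = NULL, data = d),
              class = "ic50_fit")
  }
  if (!(diff(range(d$uptake)) > 1e-9 * max(abs(d$uptake), 1e-12))) {
    return(failed("response is constant (no inhibition signal)"))
  }

  form <- uptake ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50)))
  start <- list(lic50 = log10(ic0), top = top0, bottom = bot0, hill = 1)
  fixed <- list()
  if (!is.null(fix_hill)) { fixed$hill <- fix_hill; start$hill <- NULL }
  if (!is.null(fix_bottom)) { fixed$bottom <- fix_bottom; start$bottom <- NULL }
  env_data <- d
  for (nm in names(fixed)) env_data[[nm]] <- fixed[[nm]]
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = env_data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  cf <- as.list(coef(fit))
  cf <- utils::modifyList(cf, fixed)
  ic50 <- 10^cf$lic50
  if (!is.finite(ic50) ||
      ic50 < lo_c / 1e4 || ic50 > hi_c * 1e4 ||
      !(cf$top > cf$bottom)) {
    return(failed("degenerate parameter estimates (flat or out-of-range curve)"))
  }
  structure(
    list(ic50 = ic50, hill = cf$hill, top = cf$top, bottom = cf$bottom,
         residual_sse = sum(residuals(fit)^2), converged = TRUE,
         fit = fit, data = d),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("IC50 fit: IC50 = %.4g nmol/l, hill = %.3g, top = %.4g, bottom = %.4g (SSE %.3g)\n",
                x$ic50, x$hill, x$top, x$bottom, x$residual_sse))
  } else {
    cat("IC50 fit: NOT CONVERGED (see warnings); partial diagnostics:",
        sprintf("top ~ %.4g, bottom ~ %.4g\n", x$top, x$bottom))
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @rdname fit_ic50
#' @param object an `ic50_fit`.
#' @param concentrations nmol/l at which to evaluate the fitted curve.
#' @param ... unused.
#' @export
predict.ic50_fit <- function(object, concentrations = NULL, ...) {
  assert_that(object$converged, "cannot predict from a non-converged fit")
  if (is.null(concentrations)) concentrations <- object$data$conc_nmol_l
  four_pl(concentrations, object$ic50, object$hill, object$top, object$bottom)
}

#' @rdname fit_ic50
#' @param x an `ic50_fit`.
#' @param y unused.
#' @export
plot.ic50_fit <- function(x, y, ...) {
  d <- x$data
  graphics::plot(d$conc_nmol_l, d$uptake, log = "x",
                 xlab = "inhibitor concentration (nmol/l)",
                 ylab = "normalized uptake", ...)
  if (x$converged) {
    cc <- 10^seq(min(d$lc), max(d$lc), length.out = 200L)
    graphics::lines(cc, predict(x, cc))
    graphics::abline(v = x$ic50, lty = 2)
  }
  invisible(x)
}

#' Active-transport component as a temperature contrast
#'
#' Subtracts the 4 C (passive) uptake from the 37 C uptake per
#' concentration: carrier uptake that disappears in the cold is the active,
#' transporter-mediated component.
#'
#' @param table_37c,table_4c data frames with columns `conc_nmol_l` and
#'   `uptake` measured at 37 C and 4 C on matched concentration grids
#'   (replicates are averaged per concentration).
#' @return Data frame with `conc_nmol_l`, `active_uptake` (difference of the
#'   per-concentration means) and `sd` (replicate SDs propagated in
#'   quadrature; `NA` without replicates).
#' @export
temperature_contrast <- function(table_37c, table_4c) {
  agg <- function(tab) {
    s <- split(tab$uptake, tab$conc_nmol_l)
    data.frame(conc_nmol_l = as.numeric(names(s)),
               mean = vapply(s, mean, numeric(1L)),
               sd = vapply(s, function(v) if (length(v) > 1L) sd(v) else NA_real_,
                           numeric(1L)))
  }
  a <- agg(table_37c); b <- agg(table_4c)
  assert_that(nrow(a) == nrow(b) &&
                isTRUE(all.equal(sort(a$conc_nmol_l), sort(b$conc_nmol_l))),
              "temperature tables must share the same concentration grid")
  a <- a[order(a$conc_nmol_l), ]; b <- b[order(b$conc_nmol_l), ]
  data.frame(conc_nmol_l = a$conc_nmol_l,
             active_uptake = a$mean - b$mean,
             sd = sqrt(a$sd^2 + b$sd^2))
}
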