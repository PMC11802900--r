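#' Rhodopsin difference spectrum from partial-bleach eyeshine measurements
#'
#' The pointwise difference between a dark-recovered and a partially bleached
#' eyeshine absorbance state estimates the absorbance spectrum of the bleached
#' rhodopsin (photoproduct decay and tapetal double-pass are not modelled; the
#' difference is taken as directly proportional to pigment absorbance). The
#' result is peak-normalized to 1.
#'
#' @param recovered,bleached Spectra tibbles (`wavelength`, `value`) on the
#'   same grid.
#' @return A tibble (`wavelength`, `value`, `kind = "absorbance"`) with peak 1.
#' @export
difference_spectrum <- function(recovered, bleached) {
  check_spectra(recovered)
  check_spectra(bleached)
  if (nrow(recovered) != nrow(bleached) ||
      any(recovered$wavelength != bleached$wavelength)) {
    abort("`recovered` and `bleached` must share one wavelength grid")
  }
  d <- recovered$value - bleached$value
  if (max(d) <= 0 || diff(range(d)) < 1e-12) {
    abort("difference spectrum is flat; cannot peak-normalize")
  }
  tibble(wavelength = recovered$wavelength, value = d / max(d),
         kind = "absorbance")
}

#' Estimate pigment peak absorbance by least-squares template fitting
#'
#' Minimizes \eqn{\sum_\lambda (s(\lambda) - a\,T(\lambda;\lambda_{max}))^2}
#' over the peak wavelength and the free amplitude \eqn{a} (closed form at
#' each candidate peak). The peak is located by a coarse grid search at
#' `step` nm over `search`, then refined by golden-section search to 0.01 nm;
#' the procedure is deterministic.
#'
#' @param s A spectrum tibble (`wavelength`, `value`), typically a normalized
#'   difference spectrum or expressed-pigment dark spectrum.
#' @param search Numeric length-2: peak search interval (nm), within 300-700.
#' @param step Grid-search step in nm (default 1).
#' @param fit_range Wavelength interval used for the residuals; defaults to
#'   `search`.
#' @param beta_band Include the template beta band (default `TRUE`; use
#'   `FALSE` for UV pigments).
#' @return An object of class `template_fit` with elements `lambda_max`,
#'   `amplitude`, `rss`, `fit_range`, `step`, `n`, and `boundary` (`TRUE`
#'   when the optimum sits on the search boundary, with a warning).
#' @examples
#' s <- pigment_template(530)
#' fit_lambda_max(s, search = c(450, 600))
#' @export
fit_lambda_max <- function(s, search = c(400, 650), step = 1,
                           fit_range = search, beta_band = TRUE) {
  check_spectra(s)
  if (search[1] < 300 || search[2] > 700 || search[1] >= search[2]) {
    abort("`search` must be an increasing interval within [300, 700] nm")
  }
  keep <- s$wavelength >= fit_range[1] & s$wavelength <= fit_range[2]
  wl <- s$wavelength[keep]
  y <- s$value[keep]
  if (length(wl) < 5) abort("fewer than 5 points in the fit range")

  rss_at <- function(lm) {
    tv <- template_values(lm, wl, beta_band)
    amp <- sum(y * tv) / sum(tv^2)
    sum((y - amp * tv)^2)
  }
  cand <- seq(search[1], search[2], by = step)
  rss_grid <- vapply(cand, rss_at, numeric(1))
  best <- cand[which.min(rss_grid)]
  lo <- max(search[1], best - step)
  hi <- min(search[2], best + step)
  opt <- optimize(rss_at, c(lo, hi), tol = 0.01)
  lambda_hat <- opt$minimum
  # if the bracket interior loses to the grid best (flat valley), keep grid best
  if (opt$objective > rss_grid[which.min(rss_grid)]) {
    lambda_hat <- best
    opt$objective <- rss_grid[which.min(rss_grid)]
  }
  boundary <- (lambda_hat - search[1] < step) || (search[2] - lambda_hat < step)
  if (boundary) {
    warn("fitted peak lies on the search boundary; widen `search`")
  }
  tv <- template_values(lambda_hat, wl, beta_band)
  amp <- sum(y * tv) / sum(tv^2)
  structure(list(lambda_max = lambda_hat, amplitude = amp,
                 rss = sum((y - amp * tv)^2), fit_range = fit_range,
                 step = step, n = length(wl), boundary = boundary,
                 beta_band = beta_band),
            class = "template_fit")
}

#' @export
print.template_fit <- function(x, ...) {
  cat("Pigment template fit\n")
  cat(sprintf("  lambda_max: %.2f nm   amplitude: %.4f   rss: %.3g (n = %d)\n",
              x$lambda_max, x$amplitude, x$rss, x$n))
  if (x$boundary) cat("  warning: optimum on search boundary\n")
  invisible(x)
}

#' @rdname fit_lambda_max
#' @param x A `template_fit` object.
#' @param ... Unused.
#' @method tidy template_fit
#' @export
tidy.template_fit <- function(x, ...) {
  tibble(term = c("lambda_max", "amplitude"),
         estimate = c(x$lambda_max, x$amplitude))
}

#' @rdname fit_lambda_max
#' @method glance template_fit
#' @export
glance.template_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, boundary = x$boundary)
}

#' Convert criterion-flux pupillometry data to spectral sensitivity
#'
#' Spectral sensitivity is the reciprocal of the quantum flux required to
#' produce the criterion pupillary response at each stimulus wavelength,
#' normalized to peak 1.
#'
#' @param pupil A tibble with columns `wavelength` (nm) and `criterion_flux`
#'   (photons/s, all > 0); see [read_pupil_dataset()].
#' @return A spectrum tibble (`wavelength`, `value`, `kind = "sensitivity"`).
#' @export
flux_to_sensitivity <- function(pupil) {
  if (!all(c("wavelength", "criterion_flux") %in% names(pupil))) {
    abort("`pupil` needs columns `wavelength` and `criterion_flux`")
  }
  if (any(pupil$criterion_flux <= 0)) {
    abort("criterion fluxes must be strictly positive")
  }
  s <- 1 / pupil$criterion_flux
  tibble(wavelength = pupil$wavelength, value = s / max(s),
         kind = "sensitivity")
}

#' Read a pupillary criterion-flux dataset
#'
#' Three-column delimited text: wavelength (nm), criterion quantum flux
#' (photons/s), criterion fraction (the fractional eyeshine-reflectance
#' decrease defining the criterion response).
#'
#' @param path File path.
#' @return A tibble with columns `wavelength`, `criterion_flux`, `criterion`.
#' @export
read_pupil_dataset <- function(path) {
  mat <- parse_delim_numeric(path)
  if (ncol(mat) < 3) abort(paste0(path, ": expected 3 numeric columns"))
  out <- tibble(wavelength = mat[, 1], criterion_flux = mat[, 2],
                criterion = mat[, 3])
  if (any(out$criterion_flux <= 0)) {
    abort(paste0(path, ": criterion fluxes must be positive"))
  }
  if (any(out$criterion <= 0 | out$criterion >= 1)) {
    abort(paste0(path, ": criterion fraction must be in (0, 1)"))
  }
  out
}

#' Fit a UV + long-wavelength pigment mixture to a pupillary sensitivity
#'
#' Fits the two-pigment model
#' \eqn{S(\lambda) \approx a\,T(\lambda;\lambda_{UV}) +
#' b\,T(\lambda;\lambda_{LW})} by joint least squares with non-negative
#' amplitudes, using only the wavelengths in `uv_range` (where the UV
#' receptor dominates) and `lw_range` (where the long-wavelength receptor
#' dominates). Fitting jointly matters because the long-wavelength pigment's
#' beta band falls in the ultraviolet and would otherwise bias the UV peak.
#' The intermediate blue region (390-480 nm by convention) is excluded from
#' fitting; any systematic positive residual there, exposed by
#' [blue_residual()], indicates a contribution from a blue-sensitive
#' receptor whose peak these data cannot pin down.
#'
#' Peaks are located by a 2-D grid search at 1 nm over the search intervals,
#' then refined by alternating golden-section passes to 0.01 nm.
#'
#' @param sens A normalized sensitivity spectrum tibble (`wavelength`,
#'   `value`), e.g. from [flux_to_sensitivity()].
#' @param uv_range,lw_range Length-2 nm intervals of wavelengths used for the
#'   UV and LW component fits; must not overlap.
#' @param free_peaks If `TRUE` (default) both peaks are estimated; if
#'   `FALSE` they are fixed at `uv_peak`/`lw_peak` and only amplitudes fit.
#' @param uv_search,lw_search Peak search intervals (nm) when peaks are free.
#' @param uv_peak,lw_peak Fixed peak wavelengths when `free_peaks = FALSE`.
#' @return An object of class `mixture_fit`: `lambda_uv`, `lambda_lw`,
#'   `amplitude_uv`, `amplitude_lw`, `rss` (summed over both fit regions),
#'   `uv_range`, `lw_range`.
#' @export
fit_pigment_mixture <- function(sens, uv_range = c(340, 380),
                                lw_range = c(490, 580), free_peaks = TRUE,
                                uv_search = c(330, 400),
                                lw_search = c(460, 600),
                                uv_peak = 355, lw_peak = 530) {
  check_spectra(sens)
  if (uv_range[1] <= lw_range[2] && lw_range[1] <= uv_range[2]) {
    abort("`uv_range` and `lw_range` must not overlap")
  }
  in_uv <- sens$wavelength >= uv_range[1] & sens$wavelength <= uv_range[2]
  in_lw <- sens$wavelength >= lw_range[1] & sens$wavelength <= lw_range[2]
  if (!any(in_uv) || !any(in_lw)) abort("fit range contains no data points")
  keep <- in_uv | in_lw
  wl <- sens$wavelength[keep]
  y <- sens$value[keep]

  # non-negative least squares for two regressors (clamp-and-refit)
  amps_rss <- function(tu, tl) {
    g <- rbind(c(sum(tu^2), sum(tu * tl)), c(sum(tu * tl), sum(tl^2)))
    ab <- drop(solve(g, c(sum(y * tu), sum(y * tl))))
    if (ab[1] < 0) ab <- c(0, max(0, sum(y * tl) / sum(tl^2)))
    if (ab[2] < 0) ab <- c(max(0, sum(y * tu) / sum(tu^2)), 0)
    list(a = ab[1], b = ab[2],
         rss = sum((y - ab[1] * tu - ab[2] * tl)^2))
  }
  rss_at <- function(luv, llw) {
    amps_rss(template_values(luv, wl, FALSE),
             template_values(llw, wl, TRUE))$rss
  }

  if (free_peaks) {
    if (sum(in_uv) < 3 || sum(in_lw) < 3) {
      abort("too few points to fit free peaks")
    }
    cand_uv <- seq(uv_search[1], uv_search[2], by = 1)
    cand_lw <- seq(lw_search[1], lw_search[2], by = 1)
    Tu <- vapply(cand_uv, template_values, numeric(length(wl)),
                 grid = wl, beta_band = FALSE)
    Tl <- vapply(cand_lw, template_values, numeric(length(wl)),
                 grid = wl, beta_band = TRUE)
    grid_rss <- matrix(NA_real_, length(cand_uv), length(cand_lw))
    for (j in seq_along(cand_lw)) {
      for (i in seq_along(cand_uv)) {
        grid_rss[i, j] <- amps_rss(Tu[, i], Tl[, j])$rss
      }
    }
    best <- arrayInd(which.min(grid_rss), dim(grid_rss))
    luv <- cand_uv[best[1]]
    llw <- cand_lw[best[2]]
    # alternating 1-D refinement around the grid optimum
    for (pass in 1:3) {
      luv <- optimize(function(l) rss_at(l, llw),
                      c(max(uv_search[1], luv - 1),
                        min(uv_search[2], luv + 1)), tol = 0.01)$minimum
      llw <- optimize(function(l) rss_at(luv, l),
                      c(max(lw_search[1], llw - 1),
                        min(lw_search[2], llw + 1)), tol = 0.01)$minimum
    }
  } else {
    luv <- uv_peak
    llw <- lw_peak
  }
  fin <- amps_rss(template_values(luv, wl, FALSE),
                  template_values(llw, wl, TRUE))
  structure(list(lambda_uv = luv, lambda_lw = llw,
                 amplitude_uv = fin$a, amplitude_lw = fin$b,
                 rss = fin$rss,
                 uv_range = uv_range, lw_range = lw_range),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("UV + LW pigment mixture fit\n")
  cat(sprintf("  UV: lambda_max %.2f nm, amplitude %.3f (fit %g-%g nm)\n",
              x$lambda_uv, x$amplitude_uv, x$uv_range[1], x$uv_range[2]))
  cat(sprintf("  LW: lambda_max %.2f nm, amplitude %.3f (fit %g-%g nm)\n",
              x$lambda_lw, x$amplitude_lw, x$lw_range[1], x$lw_range[2]))
  cat(sprintf("  rss: %.3g\n", x$rss))
  invisible(x)
}

#' @rdname fit_pigment_mixture
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(term = c("lambda_uv", "lambda_lw", "amplitude_uv", "amplitude_lw"),
         estimate = c(x$lambda_uv, x$lambda_lw, x$amplitude_uv,
                      x$amplitude_lw))
}

#' @rdname fit_pigment_mixture
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) tibble(rss = x$rss)

#' Residual sensitivity unexplained by the fitted UV + LW mixture
#'
#' Pointwise `sens - (a T_UV + b T_LW)` over `range`, the region excluded
#' from the mixture fit. A systematically positive residual there indicates
#' a minor blue-sensitive receptor contribution.
#'
#' @param sens The sensitivity spectrum the fit was produced on.
#' @param fit A [fit_pigment_mixture()] result.
#' @param range Length-2 nm interval (default the 390-480 nm blue window).
#' @return A tibble (`wavelength`, `value`) of residuals over `range`.
#' @export
blue_residual <- function(sens, fit, range = c(390, 480)) {
  check_spectra(sens)
  if (!inherits(fit, "mixture_fit")) abort("`fit` must be a mixture_fit")
  keep <- sens$wavelength >= range[1] & sens$wavelength <= range[2]
  if (!any(keep)) abort("`range` contains no data points")
  wl <- sens$wavelength[keep]
  pred <- fit$amplitude_uv * template_values(fit$lambda_uv, wl, FALSE) +
    fit$amplitude_lw * template_values(fit$lambda_lw, wl, TRUE)
  tibble(wavelength = wl, value = sens$value[keep] - pred)
}
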