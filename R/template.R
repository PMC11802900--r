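#' Visual-pigment absorbance template
#'
#' Peak-normalized absorbance of an A1 (retinal) visual pigment with peak at
#' `lambda_max`, using the standard rhodopsin nomogram: an alpha band
#' \deqn{S(\lambda) = 1 / [e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D]}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}},
#' b = 0.922, c = 1.104, plus an optional beta (cis) band
#' \eqn{0.26\,e^{-((\lambda-\lambda_{m\beta})/b_\beta)^2}} with
#' \eqn{\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}} and
#' \eqn{b_\beta = -40.5 + 0.195\,\lambda_{max}}. The sum is renormalized so
#' the curve peaks at 1.
#'
#' Butterfly pigments use a 3-hydroxy chromophore, but fitted peak estimates
#' are insensitive to that distinction at the 1 nm scale, so the A1 form is
#' used throughout. The beta band matters for long-wavelength and blue
#' pigments; for UV pigments the peak lies inside the alpha band and the beta
#' band is conventionally omitted.
#'
#' @param lambda_max Peak wavelength in nm, within 300-700.
#' @param grid Wavelength grid (nm), within 300-700.
#' @param beta_band Include the beta band? Default `TRUE`.
#' @return A tibble with columns `wavelength`, `value` and `kind`
#'   (`"sensitivity"`), peak value 1.
#' @examples
#' tmpl <- pigment_template(530)
#' tmpl[tmpl$wavelength == 530, ]
#' @export
pigment_template <- function(lambda_max, grid = default_grid(),
                             beta_band = TRUE) {
  v <- template_values(lambda_max, grid, beta_band)
  tibble(wavelength = grid, value = v, kind = "sensitivity")
}

# bare numeric template evaluation (vectorized over grid); normalization is
# grid-independent: the peak constant is taken over the canonical 1 nm grid so
# evaluations on any sub-grid stay consistent with the full curve
template_values <- function(lambda_max, grid, beta_band = TRUE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 300 || lambda_max > 700) {
    abort("`lambda_max` must be a single wavelength in [300, 700] nm")
  }
  if (min(grid) < 300 || max(grid) > 700) {
    abort("template grid must lie within 300-700 nm")
  }
  template_raw(lambda_max, grid, beta_band) /
    max(template_raw(lambda_max, default_grid(), beta_band))
}

template_raw <- function(lambda_max, grid, beta_band) {
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  v <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  if (beta_band) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    v <- v + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  v
}
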