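# CIE standard illuminant D65, relative spectral power (energy units),
# 300-700 nm at 5 nm. Standard colorimetric table, normalized to 100 at
# 560 nm.
d65_energy_table <- tibble::tibble(
  wavelength = seq(300, 700, by = 5),
  value = c(
    0.0341, 1.6643, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535, 38.5011,
    39.9488, 42.4302, 44.9117, 45.7750, 46.6383, 49.3637, 52.0891, 51.0323,
    49.9755, 52.3118, 54.6482, 68.7015, 82.7549, 87.1204, 91.4860, 92.4589,
    93.4318, 90.0570, 86.6823, 95.7736, 104.8650, 110.9360, 117.0080,
    117.4100, 117.8120, 116.3360, 114.8610, 115.3920, 115.9230, 112.3670,
    108.8110, 109.0820, 109.3540, 108.5780, 107.8020, 106.2960, 104.7900,
    106.2390, 107.6890, 106.0470, 104.4050, 104.2250, 104.0460, 102.0230,
    100.0000, 98.1671, 96.3342, 96.0611, 95.7880, 92.2368, 88.6856, 89.3459,
    90.0062, 89.8026, 89.5991, 88.6489, 87.6987, 85.4936, 83.2886, 83.4939,
    83.6992, 81.8630, 80.0268, 80.1207, 80.2146, 81.2462, 82.2778, 80.2810,
    78.2842, 74.0027, 69.7213, 70.6652, 71.6091))

#' Standard daylight (D65) illuminant in photon units
#'
#' Interpolates the bundled CIE D65 relative spectral power table onto `grid`
#' and, by default, converts from energy to photon-flux units by multiplying
#' by wavelength (a photon's energy is proportional to \eqn{1/\lambda}), then
#' peak-normalizes. Quantum-catch models are invariant to the overall
#' illuminant scale; only the spectral shape matters, and photon units are
#' the physiologically correct shape.
#'
#' @param grid Wavelength grid (nm) within 300-700.
#' @param photon Convert to photon units (default `TRUE`); `FALSE` returns
#'   the normalized energy-unit curve.
#' @return A spectrum tibble (`wavelength`, `value`, `kind = "irradiance"`),
#'   maximum value 1.
#' @export
d65_illuminant <- function(grid = default_grid(), photon = TRUE) {
  if (min(grid) < 300 || max(grid) > 700) {
    abort("the bundled D65 table covers 300-700 nm")
  }
  v <- approx(d65_energy_table$wavelength, d65_energy_table$value,
              xout = grid)$y
  if (photon) v <- v * grid
  tibble(wavelength = grid, value = v / max(v), kind = "irradiance")
}

#' Generate synthetic wing-patch reflectance spectra
#'
#' Emulates the structure of mimetic *Adelpha* wing reflectances: two
#' species' orange patches share a sigmoidal reflectance curve below 600 nm
#' and diverge beyond it (`orange_A` keeps the full long-wavelength plateau,
#' `orange_B`'s tail is reduced above ~620 nm); white stripes are high and
#' nearly flat; brown background is low and nearly flat. Each of the `n`
#' spectra gets independent multiplicative Gaussian noise; values are clipped
#' to \[0, 1\] afterwards.
#'
#' Measurements on the same individual are drawn independently here; real
#' within-individual correlation is not emulated.
#'
#' @param patch One of `"orange_A"`, `"orange_B"`, `"white"`, `"brown"`.
#' @param n Number of spectra.
#' @param grid Wavelength grid (nm).
#' @param noise_sd Noise standard deviation; relative to the value for
#'   `noise = "multiplicative"` (default), absolute for `"additive"`.
#' @param seed Integer seed; same seed, same output.
#' @param low,high Orange plateau reflectances below/above the rise.
#' @param midpoint,steepness Logistic rise location and width (nm).
#' @param tail_drop,tail_midpoint,tail_steepness Long-wavelength tail
#'   reduction of `orange_B` (reflectance units, nm, nm).
#' @param white_level,brown_level Plateau reflectances of the flat patches.
#' @param noise `"multiplicative"` or `"additive"`.
#' @return A spectra tibble with columns `label`, `patch`, `wavelength`,
#'   `value`, `kind`.
#' @examples
#' gen_wing_reflectance("orange_A", n = 3, seed = 1)
#' @export
gen_wing_reflectance <- function(patch = c("orange_A", "orange_B", "white",
                                           "brown"),
                                 n = 10, grid = default_grid(),
                                 noise_sd = 0.05, seed = NULL,
                                 low = 0.05, high = 0.55, midpoint = 600,
                                 steepness = 12, tail_drop = 0.08,
                                 tail_midpoint = 620, tail_steepness = 8,
                                 white_level = 0.5, brown_level = 0.08,
                                 noise = c("multiplicative", "additive")) {
  patch <- match.arg(patch)
  noise <- match.arg(noise)
  if (n < 1) abort("`n` must be at least 1")
  mu <- switch(patch,
    orange_A = low + (high - low) * plogis((grid - midpoint) / steepness),
    orange_B = low + (high - low) * plogis((grid - midpoint) / steepness) -
      tail_drop * plogis((grid - tail_midpoint) / tail_steepness),
    white = rep(white_level, length(grid)),
    brown = brown_level + 0.05 * (grid - min(grid)) / diff(range(grid)))
  if (!is.null(seed)) set.seed(seed)
  clipped <- 0L
  out <- purrr::map(seq_len(n), function(i) {
    v <- if (noise == "multiplicative") {
      mu * (1 + rnorm(length(grid), sd = noise_sd))
    } else {
      mu + rnorm(length(grid), sd = noise_sd)
    }
    clipped <<- clipped + sum(v < 0 | v > 1)
    tibble(label = sprintf("%s_%02d", patch, i), patch = patch,
           wavelength = grid, value = pmin(1, pmax(0, v)),
           kind = "reflectance")
  }) |> bind_rows()
  if (clipped > 0) {
    message("gen_wing_reflectance: clipped ", clipped,
            " value(s) into [0, 1]")
  }
  out
}

#' Generate a noisy synthetic rhodopsin difference spectrum
#'
#' A pigment nomogram template at `lambda_max` plus additive Gaussian noise,
#' renormalized to peak 1 — the structure of a partial-bleach difference
#' spectrum measured by epi-microspectrophotometry, or of an expressed
#' pigment dark spectrum.
#'
#' @param lambda_max Generating peak (nm, 300-700).
#' @param noise_sd Additive noise standard deviation (peak-relative units).
#' @param seed Integer seed.
#' @param grid Wavelength grid (nm).
#' @param beta_band Include the template beta band (default `TRUE`).
#' @return A spectrum tibble (`wavelength`, `value`, `kind = "absorbance"`).
#' @examples
#' s <- gen_difference_spectrum(530, noise_sd = 0.02, seed = 1)
#' fit_lambda_max(s, search = c(400, 650))
#' @export
gen_difference_spectrum <- function(lambda_max, noise_sd = 0.02, seed = NULL,
                                    grid = default_grid(), beta_band = TRUE) {
  v <- template_values(lambda_max, grid, beta_band)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) v <- v + rnorm(length(grid), sd = noise_sd)
  tibble(wavelength = grid, value = v / max(v), kind = "absorbance")
}

#' Generate a synthetic pupillary criterion-flux dataset
#'
#' The generating spectral sensitivity is
#' `uv_amplitude * T(lambda_uv) + T(lambda_lw)`, optionally plus a Gaussian
#' blue bump; the criterion flux is its reciprocal with multiplicative
#' Gaussian noise, on the standard 340-580 nm / 10 nm stimulus grid
#' (25 wavelengths).
#'
#' @param lambda_uv,lambda_lw Generating UV and long-wavelength peaks (nm).
#' @param uv_amplitude Relative amplitude of the UV component.
#' @param blue_bump Optional numeric `c(center_nm, height)` or
#'   `c(center_nm, height, width_nm)` (default width 30 nm) adding a
#'   blue-receptor contribution.
#' @param noise_sd Multiplicative noise sd on the flux.
#' @param seed Integer seed.
#' @param wavelengths Stimulus wavelengths (nm).
#' @param criterion Criterion response as a fraction (default 0.07, a 7%
#'   eyeshine-reflectance decrease).
#' @return A tibble (`wavelength`, `criterion_flux`, `criterion`) suitable
#'   for [flux_to_sensitivity()].
#' @export
gen_pupil_dataset <- function(lambda_uv = 355, lambda_lw = 530,
                              uv_amplitude = 0.25, blue_bump = NULL,
                              noise_sd = 0.02, seed = NULL,
                              wavelengths = seq(340, 580, by = 10),
                              criterion = 0.07) {
  s <- uv_amplitude * template_values(lambda_uv, wavelengths, FALSE) +
    template_values(lambda_lw, wavelengths, TRUE)
  if (!is.null(blue_bump)) {
    width <- if (length(blue_bump) >= 3) blue_bump[3] else 30
    s <- s + blue_bump[2] * exp(-((wavelengths - blue_bump[1]) / width)^2)
  }
  flux <- 1 / s
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) {
    flux <- flux * (1 + rnorm(length(flux), sd = noise_sd))
  }
  tibble(wavelength = wavelengths, criterion_flux = flux,
         criterion = criterion)
}

#' Generate a seeded synthetic amino-acid alignment
#'
#' Random aligned protein sequences with controlled residues at a tuning-site
#' column and, optionally, a controlled pairwise identity between the first
#' sequence and each later one (achieved by mutating exactly the required
#' number of positions).
#'
#' @param n_seqs Number of sequences.
#' @param length Alignment length (columns); must reach the site column.
#' @param site195_residues Optional character vector (recycled over
#'   sequences) of residues to place at the site-195 column.
#' @param identity Optional percent identity (0-100) of sequences 2..n to
#'   sequence 1.
#' @param seed Integer seed.
#' @param site_col Alignment column treated as site 195 (default 195,
#'   identity numbering).
#' @return An `aa_alignment`: named character vector of aligned sequences
#'   with a `numbering_offset` attribute (0 = site n is column n).
#' @examples
#' aln <- gen_opsin_alignment(2, site195_residues = c("Y", "F"), seed = 1)
#' predict_blue_peak(residue_at(aln, names(aln)[1], 195))
#' @export
gen_opsin_alignment <- function(n_seqs = 2, length = 330,
                                site195_residues = NULL, identity = NULL,
                                seed = NULL, site_col = 195) {
  if (length < site_col) abort("`length` must reach the site-195 column")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!is.null(seed)) set.seed(seed)
  base <- sample(aa, length, replace = TRUE)
  seqs <- lapply(seq_len(n_seqs), function(i) {
    s <- base
    if (i > 1) {
      n_mut <- if (is.null(identity)) {
        round(0.1 * length)
      } else {
        round((1 - identity / 100) * length)
      }
      if (n_mut > 0) {
        pos <- sample(setdiff(seq_len(length), site_col), n_mut)
        s[pos] <- vapply(s[pos], function(r) sample(setdiff(aa, r), 1),
                         character(1))
      }
    }
    s
  })
  if (!is.null(site195_residues)) {
    res <- rep_len(site195_residues, n_seqs)
    for (i in seq_len(n_seqs)) seqs[[i]][site_col] <- res[i]
  }
  out <- vapply(seqs, paste, character(1), collapse = "")
  names(out) <- sprintf("seq%02d", seq_len(n_seqs))
  structure(out, numbering_offset = site_col - 195L, class = "aa_alignment")
}
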