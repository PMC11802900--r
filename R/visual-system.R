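#' Construct a visual system
#'
#' A visual system is an ordered (short to long wavelength) set of receptor
#' classes, each with a peak sensitivity, a relative density and — depending
#' on the noise mode — a chromatic Weber fraction, plus an achromatic
#' (luminance) channel with its own Weber fraction. Receptor sensitivities
#' are built from the pigment nomogram template at each peak (beta band
#' included for peaks at or above 400 nm).
#'
#' Three presets are provided:
#' \describe{
#'   \item{`fessonia`}{the trichromatic *Adelpha fessonia* butterfly system:
#'     peaks 355/431/530 nm, relative densities 0.15:0.13:1, per-receptor
#'     chromatic Weber fractions 0.13/0.06/0.12 (honeybee estimates), the
#'     530 nm receptor as luminance channel with Weber fraction 0.16.}
#'   \item{`uv_bird`}{a UV-sensitive avian system (blue tit pigments):
#'     peaks 372/449/502/563 nm, densities 1:2:2:4, a single chromatic Weber
#'     fraction of 0.1 applied to the most abundant (longest) cone and scaled
#'     by relative density for the others, a 563 nm double cone with
#'     achromatic Weber fraction 0.18.}
#'   \item{`violet_bird`}{a violet-sensitive avian system (chicken pigments):
#'     peaks 418/453/507/571 nm, densities 1:2:4:4, chromatic Weber fraction
#'     0.06, a 571 nm double cone with achromatic Weber fraction 0.22.}
#' }
#'
#' @param preset One of `"fessonia"`, `"uv_bird"`, `"violet_bird"`.
#' @return An object of class `visual_system`.
#' @examples
#' visual_system("fessonia")
#' @export
visual_system <- function(preset = c("fessonia", "uv_bird", "violet_bird")) {
  preset <- match.arg(preset)
  switch(preset,
    fessonia = new_visual_system(
      name = "fessonia",
      receptors = tibble(receptor = c("uv", "s", "l"),
                         lambda_max = c(355, 431, 530),
                         density = c(0.15, 0.13, 1),
                         weber = c(0.13, 0.06, 0.12)),
      noise_mode = "per_receptor",
      achromatic = list(name = "l", lambda_max = 530, weber = 0.16)),
    uv_bird = new_visual_system(
      name = "uv_bird",
      receptors = tibble(receptor = c("uv", "s", "m", "l"),
                         lambda_max = c(372, 449, 502, 563),
                         density = c(1, 2, 2, 4),
                         weber = NA_real_),
      noise_mode = "density_scaled", weber = 0.1, weber_ref = "l",
      achromatic = list(name = "dc", lambda_max = 563, weber = 0.18)),
    violet_bird = new_visual_system(
      name = "violet_bird",
      receptors = tibble(receptor = c("v", "s", "m", "l"),
                         lambda_max = c(418, 453, 507, 571),
                         density = c(1, 2, 4, 4),
                         weber = NA_real_),
      noise_mode = "density_scaled", weber = 0.06, weber_ref = "l",
      achromatic = list(name = "dc", lambda_max = 571, weber = 0.22)))
}

#' Define a custom visual system
#'
#' @param name System label.
#' @param receptors A data frame with columns `receptor`, `lambda_max`,
#'   `density` and (for `noise_mode = "per_receptor"`) `weber`, ordered short
#'   to long wavelength.
#' @param noise_mode `"per_receptor"` (each receptor has its own chromatic
#'   Weber fraction) or `"density_scaled"` (one Weber fraction on a reference
#'   receptor, scaled as \eqn{e_i = \omega\sqrt{\eta_{ref}/\eta_i}}).
#' @param weber Single chromatic Weber fraction (density_scaled mode).
#' @param weber_ref Name of the reference receptor (density_scaled mode);
#'   defaults to the longest-wavelength receptor.
#' @param achromatic List with `name`, `lambda_max` and `weber` describing
#'   the luminance channel (a receptor or a double cone).
#' @return An object of class `visual_system`.
#' @export
new_visual_system <- function(name, receptors, noise_mode = "per_receptor",
                              weber = NULL, weber_ref = NULL,
                              achromatic = NULL) {
  receptors <- as_tibble(receptors)
  if (nrow(receptors) < 2) abort("a visual system needs at least 2 receptors")
  if (any(receptors$density <= 0)) abort("receptor densities must be > 0")
  if (is.unsorted(receptors$lambda_max, strictly = TRUE)) {
    abort("receptors must be ordered short to long wavelength")
  }
  if (noise_mode == "per_receptor") {
    if (!"weber" %in% names(receptors) || anyNA(receptors$weber)) {
      abort("per_receptor mode requires a `weber` value for every receptor")
    }
  } else if (noise_mode == "density_scaled") {
    if (is.null(weber)) abort("density_scaled mode requires a single `weber`")
    if (is.null(weber_ref)) {
      weber_ref <- receptors$receptor[which.max(receptors$lambda_max)]
    }
    if (!weber_ref %in% receptors$receptor) {
      abort("`weber_ref` must name a receptor")
    }
  } else {
    abort("unknown `noise_mode`")
  }
  if (is.null(achromatic) ||
      !all(c("name", "lambda_max", "weber") %in% names(achromatic))) {
    abort("`achromatic` must supply name, lambda_max and weber")
  }
  structure(list(name = name, receptors = receptors, noise_mode = noise_mode,
                 weber = weber, weber_ref = weber_ref,
                 achromatic = achromatic),
            class = "visual_system")
}

#' Load a visual system from a YAML config file
#'
#' The file holds the fields of [new_visual_system()]: `name`, `receptors`
#' (a list of records with receptor/lambda_max/density and optional weber),
#' `noise_mode`, `weber`, `weber_ref` and `achromatic`.
#'
#' @param path Path to a YAML file.
#' @return A `visual_system`.
#' @export
read_visual_system <- function(path) {
  cfg <- yaml::read_yaml(path)
  new_visual_system(name = cfg$name %||% "custom",
                    receptors = bind_rows(lapply(cfg$receptors, as_tibble)),
                    noise_mode = cfg$noise_mode %||% "per_receptor",
                    weber = cfg$weber, weber_ref = cfg$weber_ref,
                    achromatic = cfg$achromatic)
}

#' @export
print.visual_system <- function(x, ...) {
  cat("Visual system:", x$name, "(", nrow(x$receptors), "receptors,",
      x$noise_mode, "noise )\n")
  print(x$receptors)
  cat(sprintf("achromatic channel: %s (%g nm), Weber %g\n",
              x$achromatic$name, x$achromatic$lambda_max, x$achromatic$weber))
  invisible(x)
}

#' Receptor noise vector
#'
#' The per-receptor noise standard deviations \eqn{e_i} entering the
#' receptor-noise-limited model. In `per_receptor` mode \eqn{e_i = \omega_i};
#' in `density_scaled` mode \eqn{e_i = \omega_{ref}\sqrt{\eta_{ref}/\eta_i}},
#' so scarcer receptor classes are noisier.
#'
#' @param vs A `visual_system`.
#' @return A named numeric vector, one entry per receptor.
#' @examples
#' noise_vector(visual_system("uv_bird"))
#' @export
noise_vector <- function(vs) {
  stopifnot(inherits(vs, "visual_system"))
  r <- vs$receptors
  e <- if (vs$noise_mode == "per_receptor") {
    r$weber
  } else {
    eta_ref <- r$density[r$receptor == vs$weber_ref]
    vs$weber * sqrt(eta_ref / r$density)
  }
  setNames(e, r$receptor)
}

#' Receptor spectral sensitivities of a visual system
#'
#' @param vs A `visual_system`.
#' @param grid Wavelength grid (nm).
#' @param include_achromatic Append the luminance channel (receptor name from
#'   the system definition, e.g. `"dc"` for a double cone)?
#' @return A long tibble (`receptor`, `lambda_max`, `wavelength`, `value`),
#'   each sensitivity peak-normalized.
#' @export
receptor_sensitivities <- function(vs, grid = default_grid(),
                                   include_achromatic = FALSE) {
  stopifnot(inherits(vs, "visual_system"))
  r <- vs$receptors[, c("receptor", "lambda_max")]
  if (include_achromatic && !vs$achromatic$name %in% r$receptor) {
    r <- bind_rows(r, tibble(receptor = vs$achromatic$name,
                             lambda_max = vs$achromatic$lambda_max))
  }
  purrr::pmap(r, function(receptor, lambda_max) {
    v <- template_values(lambda_max, grid, beta_band = lambda_max >= 400)
    tibble(receptor = receptor, lambda_max = lambda_max, wavelength = grid,
           value = v)
  }) |> bind_rows()
}

# trapezoidal rule on a possibly non-uniform grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Quantum catches and von Kries adapted receptor signals
#'
#' For each stimulus spectrum and each receptor, the quantum catch
#' \eqn{Q_i = \int R(\lambda) I(\lambda) S_i(\lambda) d\lambda}
#' (trapezoidal rule over the stimulus grid), the corresponding catch of the
#' adapting background, and the von Kries adapted log signal
#' \eqn{f_i = \ln(Q_i / Q_i^{bg})}. The achromatic (luminance) channel is
#' computed the same way from its own template and returned with
#' `channel = "achromatic"`.
#'
#' @param reflectance A spectra tibble of stimuli (columns `wavelength`,
#'   `value`, optional `label` and metadata; values are reflectance
#'   fractions).
#' @param vs A `visual_system`.
#' @param illuminant Illuminant spectrum tibble in photon units (default
#'   [d65_illuminant()] on the stimulus grid).
#' @param background Background reflectance spectrum tibble (the adapting
#'   surround, e.g. the mean brown wing spectrum); must be supplied when
#'   `adapt = TRUE`.
#' @param adapt Compute von Kries signals (default `TRUE`)? When `TRUE`, any
#'   zero stimulus or background catch is an error.
#' @return A tibble with one row per stimulus x channel: `label`, metadata
#'   columns, `receptor`, `lambda_max`, `channel`, `Q`, `Q_bg`, `f`.
#' @export
quantum_catch <- function(reflectance, vs, illuminant = NULL,
                          background = NULL, adapt = TRUE) {
  stopifnot(inherits(vs, "visual_system"))
  check_spectra(reflectance)
  if (adapt && is.null(background)) {
    abort("`background` is required for von Kries adaptation")
  }
  chans <- vs$receptors[, c("receptor", "lambda_max")]
  chans$channel <- "chromatic"
  chans <- bind_rows(chans, tibble(receptor = vs$achromatic$name,
                                   lambda_max = vs$achromatic$lambda_max,
                                   channel = "achromatic"))

  catch_one <- function(df) {
    wl <- df$wavelength
    illum <- if (is.null(illuminant)) {
      d65_illuminant(wl)$value
    } else {
      approx(illuminant$wavelength, illuminant$value, xout = wl)$y
    }
    if (anyNA(illum)) abort("illuminant does not cover the stimulus grid")
    q <- purrr::pmap_dbl(chans[, c("lambda_max", "channel")],
      function(lambda_max, channel) {
        s <- template_values(lambda_max, wl, beta_band = lambda_max >= 400)
        trapz(wl, df$value * illum * s)
      })
    meta <- df[1, setdiff(names(df), c("wavelength", "value", "kind")),
               drop = FALSE]
    out <- chans
    out$Q <- q
    bind_cols(meta[rep(1, nrow(out)), , drop = FALSE], out)
  }

  res <- per_spectrum(reflectance, catch_one)
  if (adapt) {
    bg <- catch_one(background[, c("wavelength", "value")])
    if (any(bg$Q <= 0)) abort("background quantum catch is zero")
    if (any(res$Q <= 0)) {
      abort("zero stimulus quantum catch; von Kries signal undefined")
    }
    res$Q_bg <- rep(bg$Q, length.out = nrow(res))
    res$f <- log(res$Q / res$Q_bg)
  }
  as_tibble(res)
}

# extract ordered chromatic f vector (or lum scalar) from a one-stimulus
# quantum_catch table, or pass a bare numeric vector through
catch_f <- function(x, vs, channel = "chromatic") {
  if (is.numeric(x)) return(x)
  if (!is.data.frame(x) || !"f" %in% names(x)) {
    abort("expected a numeric f vector or a quantum_catch table with `f`")
  }
  x <- x[x$channel == channel, ]
  if (channel == "chromatic") {
    ord <- match(vs$receptors$receptor, x$receptor)
    if (anyNA(ord)) abort("catch table is missing receptors of this system")
    x$f[ord]
  } else {
    x$f[1]
  }
}

#' Receptor-noise-limited chromatic distance
#'
#' The chromatic just-noticeable-difference between two stimuli with adapted
#' log signals \eqn{f^a, f^b}: the noise-weighted length of
#' \eqn{\Delta f = f^a - f^b} projected onto the chromatic
#' (intensity-invariant) subspace, via the closed forms for di-, tri- and
#' tetrachromatic systems. A uniform shift of all receptor signals (a pure
#' intensity change) gives distance 0.
#'
#' @param a,b Either numeric vectors of adapted log signals (ordered as the
#'   system's receptors) or single-stimulus [quantum_catch()] tables.
#' @param vs A `visual_system` (or a bare numeric noise vector \eqn{e_i}).
#' @return The chromatic distance in JND units (non-negative scalar).
#' @examples
#' vs <- visual_system("fessonia")
#' chromatic_distance(c(0, 0, 0.1), c(0, 0, 0), vs)
#' @export
chromatic_distance <- function(a, b, vs) {
  e <- if (inherits(vs, "visual_system")) noise_vector(vs) else vs
  fa <- if (inherits(vs, "visual_system")) catch_f(a, vs) else a
  fb <- if (inherits(vs, "visual_system")) catch_f(b, vs) else b
  if (length(fa) != length(e) || length(fb) != length(e)) {
    abort("signal vectors and noise vector must have equal length")
  }
  drop(delta_s(matrix(fa - fb, nrow = 1), e))
}

# vectorized RNL chromatic distance: rows of D are delta-f vectors
delta_s <- function(D, e) {
  e <- unname(e)
  k <- length(e)
  if (k == 2) {
    num <- (D[, 1] - D[, 2])^2
    den <- e[1]^2 + e[2]^2
  } else if (k == 3) {
    num <- e[1]^2 * (D[, 3] - D[, 2])^2 +
           e[2]^2 * (D[, 3] - D[, 1])^2 +
           e[3]^2 * (D[, 2] - D[, 1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  } else if (k == 4) {
    num <- (e[1] * e[2])^2 * (D[, 4] - D[, 3])^2 +
           (e[1] * e[3])^2 * (D[, 4] - D[, 2])^2 +
           (e[1] * e[4])^2 * (D[, 3] - D[, 2])^2 +
           (e[2] * e[3])^2 * (D[, 4] - D[, 1])^2 +
           (e[2] * e[4])^2 * (D[, 3] - D[, 1])^2 +
           (e[3] * e[4])^2 * (D[, 2] - D[, 1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
           (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  } else {
    abort("closed-form chromatic distance requires 2, 3 or 4 receptors")
  }
  sqrt(num / den)
}

#' Receptor-noise achromatic (luminance) distance
#'
#' \eqn{\Delta L = |f_A(a) - f_A(b)| / \omega_A} where \eqn{f_A} is the von
#' Kries log signal of the achromatic channel and \eqn{\omega_A} its Weber
#' fraction.
#'
#' @inheritParams chromatic_distance
#' @return The achromatic distance in JND units.
#' @export
achromatic_distance <- function(a, b, vs) {
  stopifnot(inherits(vs, "visual_system"))
  fa <- catch_f(a, vs, channel = "achromatic")
  fb <- catch_f(b, vs, channel = "achromatic")
  abs(fa - fb) / vs$achromatic$weber
}

# regular-simplex vertex matrices (rows = receptors, short to long)
simplex_vertices <- function(k) {
  if (k == 3) {
    rbind(c(0, 1),
          c(-sqrt(3) / 2, -1 / 2),
          c(sqrt(3) / 2, -1 / 2))
  } else if (k == 4) {
    rbind(c(0, 0, 0.75),
          c(-sqrt(3 / 8), -sqrt(1 / 8), -0.25),
          c(sqrt(3 / 8), -sqrt(1 / 8), -0.25),
          c(0, sqrt(1 / 2), -0.25))
  } else {
    abort("chromaticity coordinates are defined for 3 or 4 receptors")
  }
}

#' Chromaticity coordinates in the Maxwell triangle / tetrahedron
#'
#' Relative quantum catches \eqn{q_i = Q_i/\sum_j Q_j} are mapped to
#' \eqn{\sum_i q_i V_i} with \eqn{V_i} the vertices of a regular simplex
#' centered at the origin: for trichromats a triangle of unit circumradius
#' with the short-wavelength receptor at the top vertex; for tetrachromats a
#' regular tetrahedron of circumradius 0.75 with the shortest (UV/violet)
#' receptor on the +z axis. Coordinates are display conventions only and
#' never enter JND calculations.
#'
#' @param catches A [quantum_catch()] table (chromatic rows are used; may
#'   contain many labels) or a bare numeric catch vector.
#' @param vs The `visual_system` the catches were computed under.
#' @return A tibble with `label` (if present), `x`, `y` and for tetrachromats
#'   `z`.
#' @export
chromaticity_coords <- function(catches, vs) {
  stopifnot(inherits(vs, "visual_system"))
  k <- nrow(vs$receptors)
  V <- simplex_vertices(k)
  coords_one <- function(q) {
    if (sum(q) <= 0) abort("all-zero quantum catches have no chromaticity")
    rel <- q / sum(q)
    setNames(drop(rel %*% V), c("x", "y", "z")[seq_len(ncol(V))])
  }
  if (is.numeric(catches)) {
    return(as_tibble(as.list(coords_one(catches))))
  }
  if (!is.data.frame(catches) || !"Q" %in% names(catches)) {
    abort("`catches` must be a quantum_catch table or a numeric vector")
  }
  chrom <- catches[catches$channel == "chromatic", ]
  split_cols <- intersect("label", names(chrom))
  groups <- if (length(split_cols)) {
    dplyr::group_split(chrom, .data$label)
  } else {
    list(chrom)
  }
  purrr::map(groups, function(g) {
    ord <- match(vs$receptors$receptor, g$receptor)
    xyz <- as_tibble(as.list(coords_one(g$Q[ord])))
    if ("label" %in% names(g)) xyz <- bind_cols(label = g$label[1], xyz)
    xyz
  }) |> bind_rows()
}
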