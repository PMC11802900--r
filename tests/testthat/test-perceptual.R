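test_that("visual system presets carry the published parameters", {
  fess <- visual_system("fessonia")
  expect_equal(fess$receptors$lambda_max, c(355, 431, 530))
  expect_equal(fess$receptors$density, c(0.15, 0.13, 1))
  expect_equal(fess$receptors$weber, c(0.13, 0.06, 0.12))
  expect_equal(fess$achromatic$lambda_max, 530)
  expect_equal(fess$achromatic$weber, 0.16)

  uvb <- visual_system("uv_bird")
  expect_equal(uvb$receptors$lambda_max, c(372, 449, 502, 563))
  expect_equal(uvb$receptors$density, c(1, 2, 2, 4))
  expect_equal(uvb$weber, 0.1)
  expect_equal(uvb$achromatic$lambda_max, 563)
  expect_equal(uvb$achromatic$weber, 0.18)

  vb <- visual_system("violet_bird")
  expect_equal(vb$receptors$lambda_max, c(418, 453, 507, 571))
  expect_equal(vb$receptors$density, c(1, 2, 4, 4))
  expect_equal(vb$weber, 0.06)
  expect_equal(vb$achromatic$lambda_max, 571)
  expect_equal(vb$achromatic$weber, 0.22)

  expect_error(visual_system("pigeon"))
})

test_that("custom systems validate their definition", {
  rec <- tibble::tibble(receptor = c("a", "b"), lambda_max = c(400, 500),
                        density = c(1, 1), weber = c(0.1, NA))
  expect_error(new_visual_system("x", rec,
                                 achromatic = list(name = "b",
                                                   lambda_max = 500,
                                                   weber = 0.2)),
               "weber")
  rec$weber <- c(0.1, 0.1)
  vs <- new_visual_system("x", rec,
                          achromatic = list(name = "b", lambda_max = 500,
                                            weber = 0.2))
  expect_s3_class(vs, "visual_system")
  expect_error(new_visual_system("x", rec[1, ],
                                 achromatic = list(name = "a",
                                                   lambda_max = 400,
                                                   weber = 0.2)),
               "at least 2")
})

test_that("visual systems load from a YAML config", {
  f <- tempfile(fileext = ".yml")
  writeLines(c(
    "name: toy",
    "noise_mode: density_scaled",
    "weber: 0.1",
    "receptors:",
    "  - {receptor: u, lambda_max: 360, density: 1}",
    "  - {receptor: l, lambda_max: 560, density: 4}",
    "achromatic: {name: l, lambda_max: 560, weber: 0.2}"), f)
  vs <- read_visual_system(f)
  expect_equal(unname(noise_vector(vs)), c(0.2, 0.1))
})

test_that("noise vectors follow the per-receptor and density-scaled rules", {
  expect_equal(unname(noise_vector(visual_system("fessonia"))),
               c(0.13, 0.06, 0.12))
  # e_i = omega_ref * sqrt(eta_ref / eta_i): e_UV = 0.1 * sqrt(4/1) = 0.2
  expect_equal(unname(noise_vector(visual_system("uv_bird"))),
               c(0.2, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.1))
  # equal densities collapse to a constant noise vector
  rec <- tibble::tibble(receptor = c("a", "b", "c"),
                        lambda_max = c(400, 500, 600), density = c(2, 2, 2))
  vs <- new_visual_system("eq", rec, noise_mode = "density_scaled",
                          weber = 0.1,
                          achromatic = list(name = "c", lambda_max = 600,
                                            weber = 0.2))
  expect_equal(unname(noise_vector(vs)), rep(0.1, 3))
})

test_that("quantum catches are linear and von Kries signals vanish on the background", {
  vs <- visual_system("fessonia")
  grid <- seq(300, 700, 1)
  bg <- tibble::tibble(wavelength = grid, value = 0.1)
  r <- tibble::tibble(wavelength = grid, value = 0.3)

  q1 <- quantum_catch(r, vs, background = bg)
  r2 <- r
  r2$value <- 2 * r$value
  q2 <- quantum_catch(r2, vs, background = bg)
  expect_equal(q2$Q, 2 * q1$Q)

  qbg <- quantum_catch(bg, vs, background = bg)
  expect_equal(qbg$f, rep(0, 4), tolerance = 1e-12)

  zero <- tibble::tibble(wavelength = grid, value = 0)
  expect_error(quantum_catch(zero, vs, background = bg), "zero")
  qz <- quantum_catch(zero, vs, background = bg, adapt = FALSE)
  expect_equal(qz$Q, rep(0, 4))
})

test_that("chromatic distance has the receptor-noise null space and values", {
  vs <- visual_system("fessonia")
  expect_equal(chromatic_distance(c(0.2, 0.1, 0), c(0.2, 0.1, 0), vs), 0)
  # uniform intensity shifts are achromatic
  expect_equal(chromatic_distance(c(0.3, 0.3, 0.3), c(0, 0, 0), vs), 0,
               tolerance = 1e-12)
  # hand evaluation of the trichromat formula
  expect_equal(chromatic_distance(c(0, 0, 0.1), c(0, 0, 0),
                                  c(0.1, 0.1, 0.1)),
               sqrt(2 / 3), tolerance = 1e-12)
})

test_that("closed forms equal the brute-force noise-weighted line element", {
  set.seed(31)
  for (k in 2:4) {
    for (i in 1:1000) {
      d <- rnorm(k)
      e <- runif(k, 0.02, 0.4)
      expect_equal(rnlvis:::delta_s(matrix(d, 1), e)[1], rnl_oracle(d, e),
                   tolerance = 1e-9)
    }
  }
})

test_that("chromatic distance is a norm of delta-f (symmetry, triangle)", {
  set.seed(32)
  vs <- visual_system("uv_bird")
  for (i in 1:50) {
    a <- rnorm(4, sd = 0.3)
    b <- rnorm(4, sd = 0.3)
    cc <- rnorm(4, sd = 0.3)
    expect_equal(chromatic_distance(a, b, vs), chromatic_distance(b, a, vs))
    expect_lte(chromatic_distance(a, b, vs),
               chromatic_distance(a, cc, vs) +
                 chromatic_distance(cc, b, vs) + 1e-12)
  }
})

test_that("scaling both stimuli leaves the chromatic distance unchanged", {
  vs <- visual_system("violet_bird")
  grid <- seq(300, 700, 1)
  bg <- tibble::tibble(wavelength = grid, value = 0.1)
  suppressMessages({
    ra <- gen_wing_reflectance("orange_A", n = 1, seed = 1, noise_sd = 0)
    rb <- gen_wing_reflectance("orange_B", n = 1, seed = 1, noise_sd = 0)
  })
  qa <- quantum_catch(ra, vs, background = bg)
  qb <- quantum_catch(rb, vs, background = bg)
  ra2 <- ra; ra2$value <- 0.5 * ra$value
  rb2 <- rb; rb2$value <- 0.5 * rb$value
  qa2 <- quantum_catch(ra2, vs, background = bg)
  qb2 <- quantum_catch(rb2, vs, background = bg)
  expect_equal(chromatic_distance(qa, qb, vs),
               chromatic_distance(qa2, qb2, vs), tolerance = 1e-9)
})

test_that("the trichromat formula degenerates to the dichromat limit", {
  d <- c(0.12, -0.05, 0.3)
  e <- c(0.1, 0.15, 1e6)
  tri <- rnlvis:::delta_s(matrix(d, 1), e)[1]
  di <- abs(d[1] - d[2]) / sqrt(e[1]^2 + e[2]^2)
  expect_equal(tri, di, tolerance = 1e-6)
})

test_that("achromatic distance is the Weber-scaled log catch ratio", {
  vs <- visual_system("fessonia")
  expect_equal(achromatic_distance(log(2), 0, vs), log(2) / 0.16,
               tolerance = 1e-12)
  expect_equal(achromatic_distance(log(2), 0, visual_system("violet_bird")),
               log(2) / 0.22, tolerance = 1e-12)
  expect_equal(achromatic_distance(0.1, 0.1, vs), 0)
})

test_that("chromaticity coordinates map catches into the simplex", {
  vs3 <- visual_system("fessonia")
  # equal catches sit at the origin, a pure catch at its vertex
  expect_equal(unlist(chromaticity_coords(c(1, 1, 1), vs3)), c(x = 0, y = 0),
               tolerance = 1e-12)
  expect_equal(unlist(chromaticity_coords(c(1, 0, 0), vs3)), c(x = 0, y = 1))

  # swapping two receptors' catches reflects across the matching axis
  p <- chromaticity_coords(c(0.5, 0.3, 0.2), vs3)
  q <- chromaticity_coords(c(0.5, 0.2, 0.3), vs3)
  expect_equal(q$x, -p$x)
  expect_equal(q$y, p$y)

  vs4 <- visual_system("uv_bird")
  p4 <- chromaticity_coords(c(0.4, 0.3, 0.2, 0.1), vs4)
  q4 <- chromaticity_coords(c(0.4, 0.2, 0.3, 0.1), vs4)
  expect_equal(q4$x, -p4$x)
  expect_equal(q4$y, p4$y)
  expect_equal(q4$z, p4$z)
  expect_equal(unlist(chromaticity_coords(c(1, 0, 0, 0), vs4)),
               c(x = 0, y = 0, z = 0.75))

  # any catch vector stays inside the circumradius
  set.seed(41)
  for (i in 1:50) {
    co <- chromaticity_coords(runif(4), vs4)
    expect_lte(sqrt(co$x^2 + co$y^2 + co$z^2), 0.75 + 1e-12)
  }
  expect_error(chromaticity_coords(c(0, 0, 0), vs3), "zero")
})

test_that("receptor sensitivities are peak-normalized on the working grid", {
  sens <- receptor_sensitivities(visual_system("uv_bird"),
                                 include_achromatic = TRUE)
  peaks <- sens |> dplyr::group_by(receptor) |>
    dplyr::summarise(m = max(value))
  expect_true(all(abs(peaks$m - 1) < 1e-9))
  expect_true("dc" %in% sens$receptor)
})
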