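# shared fixtures and independent oracles

# build a quantum_catch-shaped table from an f matrix (members x receptors)
# and a luminance f vector, for a given visual system
make_catch_tbl <- function(F, lum, vs) {
  n <- nrow(F)
  k <- ncol(F)
  rec <- vs$receptors$receptor
  dplyr::bind_rows(
    tibble::tibble(label = rep(sprintf("m%03d", seq_len(n)), each = k),
                   receptor = rep(rec, n),
                   channel = "chromatic",
                   f = as.vector(t(F))),
    tibble::tibble(label = sprintf("m%03d", seq_len(n)),
                   receptor = vs$achromatic$name,
                   channel = "achromatic",
                   f = lum))
}

# independent receptor-noise oracle: the chromatic distance is the
# noise-weighted norm of delta-f after projecting out the uniform
# (intensity) direction -- minimize sum((d_i - c)^2 / e_i^2) over c
rnl_oracle <- function(d, e) {
  w <- 1 / e^2
  c_star <- sum(w * d) / sum(w)
  sqrt(sum(w * (d - c_star)^2))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
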