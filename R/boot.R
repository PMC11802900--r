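#' Bootstrapped color distances between two stimulus groups
#'
#' Resamples each group of measured spectra (their quantum catches) with
#' replacement at its original size, computes each group's centroid catch —
#' the geometric mean catch per receptor, i.e. the arithmetic mean of the von
#' Kries log signals — and the chromatic and achromatic receptor-noise
#' distances between the two centroids, for `n_boot` replicates. Reports the
#' mean of the replicate distribution and simple percentile confidence
#' bounds.
#'
#' Randomness protocol: with `seed` set the run is bit-reproducible. One
#' uniform draw stream is consumed replicate by replicate, group A's indices
#' first, then group B's (inverse-CDF mapping of uniforms to member indices).
#'
#' @param a,b [quantum_catch()] tables for the two groups; each `label` is
#'   one measured spectrum (group member). At least 2 members per group for a
#'   meaningful interval.
#' @param vs The `visual_system` the catches were computed under.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param alpha Interval level: the (`alpha/2`, `1 - alpha/2`) percentiles
#'   are reported (default 0.05, a 95% interval).
#' @param seed Integer seed; recorded in the output.
#' @param point `"mean"` (default) or `"median"` of the replicate
#'   distribution as the reported estimate.
#' @return A tibble of class `boot_coldist`, one row per channel
#'   (`chromatic`, `achromatic`): `mean_jnd`, `ci_low`, `ci_high`, `n_boot`,
#'   `alpha`, `seed`. The replicate distances are attached as attribute
#'   `replicates` (a two-column matrix).
#' @export
bootcoldist <- function(a, b, vs, n_boot = 1000, alpha = 0.05, seed = NULL,
                        point = c("mean", "median")) {
  stopifnot(inherits(vs, "visual_system"))
  point <- match.arg(point)
  if (n_boot < 1) abort("`n_boot` must be at least 1")
  fa <- group_f(a, vs)
  fb <- group_f(b, vs)
  na <- nrow(fa$chrom)
  nb <- nrow(fb$chrom)
  if (na < 1 || nb < 1) abort("both groups must contain at least one member")
  e <- noise_vector(vs)
  k <- length(e)

  if (!is.null(seed)) set.seed(seed)
  u <- runif(n_boot * (na + nb))
  # replicate-blocked, group A first within each block
  blocks <- matrix(u, nrow = na + nb)
  idx_a <- t(ceiling(blocks[seq_len(na), , drop = FALSE] * na))
  idx_b <- t(ceiling(blocks[na + seq_len(nb), , drop = FALSE] * nb))

  boot_means <- function(F, idx) {
    vapply(seq_len(ncol(F)), function(j) {
      rowMeans(matrix(F[, j][idx], nrow = nrow(idx)))
    }, numeric(nrow(idx)))
  }
  D <- boot_means(fa$chrom, idx_a) - boot_means(fb$chrom, idx_b)
  ds <- delta_s(matrix(D, ncol = k), e)
  dl <- abs(rowMeans(matrix(fa$lum[idx_a], nrow = n_boot)) -
              rowMeans(matrix(fb$lum[idx_b], nrow = n_boot))) /
    vs$achromatic$weber

  summarise_chan <- function(x, channel) {
    qs <- unname(quantile(x, c(alpha / 2, 1 - alpha / 2), type = 7))
    tibble(channel = channel,
           mean_jnd = if (point == "mean") mean(x) else stats::median(x),
           ci_low = qs[1], ci_high = qs[2],
           n_boot = n_boot, alpha = alpha,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }
  out <- bind_rows(summarise_chan(ds, "chromatic"),
                   summarise_chan(dl, "achromatic"))
  attr(out, "replicates") <- cbind(chromatic = ds, achromatic = dl)
  class(out) <- c("boot_coldist", class(out))
  out
}

# per-member f matrices: chromatic (members x receptors) and lum vector
group_f <- function(x, vs) {
  if (!is.data.frame(x) || !all(c("f", "channel", "receptor") %in% names(x))) {
    abort("groups must be quantum_catch tables with von Kries signals (`f`)")
  }
  if (!"label" %in% names(x)) x$label <- "member"
  labs <- unique(x$label)
  if (length(labs) == 0) {
    abort("both groups must contain at least one member")
  }
  chrom <- vapply(vs$receptors$receptor, function(r) {
    rows <- x[x$channel == "chromatic" & x$receptor == r, ]
    rows$f[match(labs, rows$label)]
  }, numeric(length(labs)))
  chrom <- matrix(chrom, nrow = length(labs),
                  dimnames = list(labs, vs$receptors$receptor))
  lumrows <- x[x$channel == "achromatic", ]
  lum <- lumrows$f[match(labs, lumrows$label)]
  if (anyNA(chrom) || anyNA(lum)) {
    abort("every group member needs an f value for every channel")
  }
  list(chrom = chrom, lum = lum)
}

#' Compare a bootstrapped distance to a discrimination threshold
#'
#' A JND threshold of 1 is the conventional laboratory discrimination
#' criterion; thresholds under natural conditions are typically higher.
#'
#' @param result A [bootcoldist()] result (or any data frame with `ci_low`
#'   and `ci_high` columns).
#' @param threshold Threshold in JND units (default 1).
#' @return Character vector, one per row: `"below"` if the whole interval is
#'   under the threshold, `"above"` if it is over, `"spans"` otherwise.
#' @export
threshold_assessment <- function(result, threshold = 1) {
  if (!all(c("ci_low", "ci_high") %in% names(result))) {
    abort("`result` must have `ci_low` and `ci_high` columns")
  }
  dplyr::case_when(result$ci_high < threshold ~ "below",
                   result$ci_low > threshold ~ "above",
                   TRUE ~ "spans")
}
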