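#' Boltzmann constant times temperature, kJ/mol
#' @param temperature Kelvin.
#' @return k_B T in kJ/mol (2.494 at 300 K).
#' @export
kT_kJmol <- function(temperature = 300) 0.0083144626 * temperature

#' Metropolis sampler for a 1-d potential
#'
#' Standard random-walk Metropolis chain targeting exp(-U/kT) on a bounded
#' interval with reflecting boundaries (mimicking a flat-bottom restraint
#' without implementing one). Fully seed-reproducible: the same seed yields a
#' bit-identical sample stream.
#'
#' @param potential function z (nm) -> potential energy (kJ/mol).
#' @param n number of samples.
#' @param step half-width of the uniform proposal, nm.
#' @param temperature Kelvin.
#' @param seed integer RNG seed.
#' @param start starting coordinate (default: centre of `bounds`).
#' @param bounds reflecting interval, nm.
#' @return object of class `IonSamples`: list with `z` (nm), `bias` (NULL),
#'   `temperature`, `seed`, `acceptance_rate`, `bounds`.
#' @export
metropolis_sample <- function(potential, n, step = 0.1, temperature = 300,
                              seed = 1L, start = NULL, bounds = c(-2, 2)) {
  stopifnot(n > 0, step > 0, bounds[1] < bounds[2])
  if (is.null(start)) start <- mean(bounds)
  u0 <- potential(start)
  if (!is.finite(u0)) stop("non-finite potential at the starting point")
  lo <- bounds[1]; hi <- bounds[2]; width <- hi - lo
  kT <- kT_kJmol(temperature)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  z <- numeric(n)
  cur <- start; ucur <- u0
  acc <- 0L
  prop_all <- runif(n, -step, step)
  uacc <- runif(n)
  for (i in seq_len(n)) {
    p <- cur + prop_all[i]
    # reflect into the interval (handles overshoot beyond one width too)
    while (p < lo || p > hi) {
      if (p < lo) p <- 2 * lo - p
      if (p > hi) p <- 2 * hi - p
    }
    up <- potential(p)
    if (up <= ucur || uacc[i] < exp(-(up - ucur) / kT)) {
      cur <- p; ucur <- up; acc <- acc + 1L
    }
    z[i] <- cur
  }
  structure(list(z = z, bias = NULL, temperature = temperature,
                 seed = as.integer(seed), acceptance_rate = acc / n,
                 bounds = bounds),
            class = "IonSamples")
}

#' Wrap raw coordinate samples as IonSamples
#' @param z numeric coordinate samples, nm.
#' @param bias optional per-sample bias potential, kJ/mol (removed by
#'   reweighting during inversion).
#' @param temperature Kelvin.
#' @param seed seed recorded for provenance.
#' @return an `IonSamples` object.
#' @export
ion_samples <- function(z, bias = NULL, temperature = 300, seed = NA_integer_) {
  stopifnot(all(is.finite(z)), is.null(bias) || length(bias) == length(z))
  structure(list(z = z, bias = bias, temperature = temperature,
                 seed = seed, acceptance_rate = NA_real_,
                 bounds = range(z)),
            class = "IonSamples")
}

#' Free-energy profile by Boltzmann inversion
#'
#' Histograms the coordinate samples (bias-reweighted with weights
#' exp(+bias/kT) when a bias is recorded) and inverts the density:
#' `F(z) = -kT log rho(z)`, offset so the minimum over the reference window
#' is zero. Bins with fewer than `min_count` raw counts are masked as gaps
#' rather than reported as unreliable values.
#'
#' @param samples an `IonSamples` object.
#' @param bin_width histogram bin width, nm.
#' @param reference_window length-2 z interval whose minimum is set to 0;
#'   default: the whole sampled range (global minimum at 0).
#' @param min_count minimum raw bin count below which a bin is masked.
#' @return object of class `PmfProfile`: data frame (z, free_energy, count,
#'   mask); attributes `temperature`, `reference_window`, `bin_width`.
#' @export
boltzmann_invert <- function(samples, bin_width = 0.05,
                             reference_window = NULL, min_count = 5L) {
  stopifnot(inherits(samples, "IonSamples"), bin_width > 0)
  z <- samples$z
  if (length(z) < 1000)
    stop("estimation error: need at least 1000 samples for inversion")
  kT <- kT_kJmol(samples$temperature)
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  bin <- findInterval(z, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  bin[bin < 1L] <- 1L; bin[bin > nb] <- nb
  counts <- tabulate(bin, nbins = nb)
  w <- if (is.null(samples$bias)) rep(1, length(z)) else exp(samples$bias / kT)
  wsum <- vapply(seq_len(nb), function(b) sum(w[bin == b]), numeric(1))
  rho <- wsum / (sum(w) * bin_width)
  fe <- ifelse(rho > 0, -kT * log(rho), NA_real_)
  mask <- counts < min_count
  fe[mask] <- NA_real_
  if (all(is.na(fe))) stop("estimation error: all histogram bins are empty")
  centres <- breaks[-length(breaks)] + bin_width / 2
  if (is.null(reference_window)) reference_window <- c(lo, hi)
  in_ref <- centres >= reference_window[1] & centres <= reference_window[2] &
    is.finite(fe)
  if (!any(in_ref)) stop("reference window contains no sampled bins")
  fe <- fe - min(fe[in_ref])
  structure(data.frame(z = centres, free_energy = fe, count = counts,
                       mask = mask),
            temperature = samples$temperature,
            reference_window = reference_window, bin_width = bin_width,
            class = c("PmfProfile", "data.frame"))
}

#' Wrap an externally computed free-energy curve as a PmfProfile
#' @param z axial coordinate, nm (extracellular to the left by convention,
#'   with the -2' gate at 0).
#' @param free_energy kJ/mol.
#' @param temperature Kelvin.
#' @return a `PmfProfile`.
#' @export
pmf_profile <- function(z, free_energy, temperature = 300) {
  stopifnot(length(z) == length(free_energy), !is.unsorted(z))
  structure(data.frame(z = z, free_energy = free_energy,
                       count = NA_integer_, mask = !is.finite(free_energy)),
            temperature = temperature, reference_window = range(z),
            bin_width = if (length(z) > 1) z[2] - z[1] else NA_real_,
            class = c("PmfProfile", "data.frame"))
}

#' Free-energy barrier within a gate window
#'
#' Height of the maximum of the profile inside the gate window above the
#' minimum over the flanking sampled regions (outside the window), together
#' with the position of the maximum.
#'
#' @param profile a `PmfProfile`.
#' @param gate_window length-2 z interval, nm.
#' @return list with `height` (kJ/mol) and `z_max` (nm).
#' @export
barrier_height <- function(profile, gate_window) {
  stopifnot(inherits(profile, "PmfProfile"), length(gate_window) == 2)
  fin <- is.finite(profile$free_energy)
  inw <- profile$z >= gate_window[1] & profile$z <= gate_window[2]
  if (!any(fin & inw))
    stop("gap error: gate window contains no sampled profile point")
  flank <- fin & !inw
  base <- if (any(flank)) min(profile$free_energy[flank])
          else min(profile$free_energy[fin])
  j <- which(fin & inw)[which.max(profile$free_energy[fin & inw])]
  list(height = profile$free_energy[j] - base, z_max = profile$z[j])
}

#' Named toy potentials for sampler validation
#'
#' `flat`: zero potential. `harmonic`: 0.5 k (z - z0)^2 with k = 100
#' kJ/mol/nm^2 about z0 = 0. `double_well`: quartic h ((z/w)^2 - 1)^2 with
#' minima at +/- w = 0.7 nm and programmed barrier h = 18 kJ/mol, echoing the
#' scale of the hydrophobic-gate barrier.
#'
#' @param name one of `"flat"`, `"harmonic"`, `"double_well"`.
#' @param ... overrides: `k`, `z0` (harmonic); `h`, `w` (double well).
#' @return function z -> kJ/mol with the parameters as attributes.
#' @export
toy_potential <- function(name = c("flat", "harmonic", "double_well"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  f <- switch(name,
    flat = function(z) 0 * z,
    harmonic = {
      k <- dots$k %||% 100; z0 <- dots$z0 %||% 0
      function(z) 0.5 * k * (z - z0)^2
    },
    double_well = {
      h <- dots$h %||% 18; w <- dots$w %||% 0.7
      function(z) h * ((z / w)^2 - 1)^2
    })
  attr(f, "name") <- name
  attr(f, "params") <- dots
  f
}

#' Curvature of a free-energy profile about its minimum
#'
#' Quadratic fit of F(z) over a window around the sampled minimum; for a
#' harmonic potential 0.5 k (z - z0)^2 the fitted curvature recovers k.
#'
#' @param profile a `PmfProfile`.
#' @param window half-width of the fit window, nm (default 0.25).
#' @return list with `k` (kJ/mol/nm^2) and `z_min` (nm).
#' @export
profile_curvature <- function(profile, window = 0.25) {
  fin <- which(is.finite(profile$free_energy))
  j <- fin[which.min(profile$free_energy[fin])]
  z0 <- profile$z[j]
  use <- fin[abs(profile$z[fin] - z0) <= window]
  if (length(use) < 4) stop("too few sampled bins around the minimum")
  fit <- stats::lm(profile$free_energy[use] ~ stats::poly(profile$z[use], 2,
                                                          raw = TRUE))
  list(k = 2 * unname(stats::coef(fit)[3]), z_min = z0)
}
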