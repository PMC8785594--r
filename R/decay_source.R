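# Source term of the Ru-106/Rh-106 pair in secular equilibrium: a continuous
# beta spectrum (the therapeutic component, endpoint ~3.54 MeV for the
# dominant branch) plus weak discrete gamma lines of the Rh-106 daughter.

FINE_STRUCTURE <- 1 / 137.035999

#' Allowed-shape Fermi beta spectrum
#'
#' Tabulates the allowed-transition beta spectrum
#' `p * E_tot * (Q - E)^2 * F(Z, E)` on an ascending energy grid and
#' normalizes it to unit integral (trapezoid rule).  The Fermi function uses
#' the standard non-relativistic screening approximation
#' `F = 2 pi eta / (1 - exp(-2 pi eta))` with `eta = alpha Z E_tot / (p c)`.
#'
#' @param endpoint_energy beta endpoint (Q value available to the branch), MeV.
#'   The default is the dominant Rh-106 branch.
#' @param daughter_z atomic number of the daughter nuclide (Pd-106: 46).
#' @param grid_size number of energy grid points (>= 200).
#' @param fermi logical; set `FALSE` to force the Fermi function to 1
#'   (pure statistical shape, mainly for validation against the analytic
#'   stationary point).
#' @return an object of class `beta_spectrum` with fields `energy_grid`
#'   (MeV), `density` (per decay per MeV) and `endpoint_energy`.
#' @export
build_beta_spectrum <- function(endpoint_energy = 3.541, daughter_z = 46,
                                grid_size = 400, fermi = TRUE) {
  if (!is.numeric(endpoint_energy) || endpoint_energy <= 0) {
    stop_invalid("endpoint energy must be positive (got %s)",
                 format(endpoint_energy))
  }
  if (grid_size < 200) {
    stop_invalid("energy grid too coarse: need >= 200 points, got %d",
                 grid_size)
  }
  e <- seq(endpoint_energy / grid_size, endpoint_energy,
           length.out = grid_size)
  dens <- beta_shape(e, endpoint_energy, daughter_z, fermi = fermi)
  dens <- dens / trapz(e, dens)
  structure(list(energy_grid = e, density = dens,
                 endpoint_energy = endpoint_energy,
                 daughter_z = daughter_z),
            class = "beta_spectrum")
}

# unnormalized allowed shape
beta_shape <- function(e, q, z, fermi = TRUE) {
  me <- ELECTRON_REST_MEV
  etot <- e + me
  pc <- sqrt(pmax(e * (e + 2 * me), 0))
  shape <- pc * etot * (q - e)^2
  if (fermi) {
    eta <- FINE_STRUCTURE * z * etot / pmax(pc, 1e-12)
    f <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
    shape <- shape * f
  }
  shape[e >= q] <- 0
  shape
}

#' Mean energy of a beta spectrum
#'
#' @param spectrum a `beta_spectrum`.
#' @return trapezoid integral of `E * p(E)`, MeV per beta decay.
#' @export
spectrum_mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  trapz(spectrum$energy_grid, spectrum$energy_grid * spectrum$density)
}

#' @export
print.beta_spectrum <- function(x, ...) {
  cat(sprintf("beta spectrum: endpoint %.3f MeV, mean %.3f MeV, %d grid points\n",
              x$endpoint_energy, spectrum_mean_energy(x),
              length(x$energy_grid)))
  invisible(x)
}

# cumulative distribution on the spectrum grid (starts at 0, ends at 1)
spectrum_cdf <- function(spectrum) {
  e <- spectrum$energy_grid
  d <- spectrum$density
  n <- length(e)
  cdf <- c(0, cumsum((e[-1] - e[-n]) * (d[-1] + d[-n]) / 2))
  cdf / cdf[n]
}

# inverse-CDF lookup table at n+1 uniform probability levels; shared by the
# R-level sampler and the C++ transport engine.
spectrum_quantile_table <- function(spectrum, n = 4096) {
  cdf <- spectrum_cdf(spectrum)
  e <- spectrum$energy_grid
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], e[keep], seq(0, 1, length.out = n + 1),
                rule = 2)$y
}

#' Rh-106 beta branches
#'
#' Endpoint energies and branching fractions of the main Rh-106 beta
#' transitions (evaluated-nuclear-data style values).  Only the dominant
#' 3.541 MeV branch is used by default; the minor branches can be folded in
#' through `ru106_source_term(multi_branch = TRUE)`.
#'
#' @return data.frame with columns `endpoint_MeV`, `fraction`.
#' @export
rh106_beta_branches <- function() {
  b <- data.frame(
    endpoint_MeV = c(3.541, 3.029, 2.407, 1.979, 1.511),
    fraction     = c(0.786, 0.081, 0.100, 0.018, 0.004)
  )
  b$fraction <- b$fraction / sum(b$fraction)
  b
}

#' Filter gamma lines by emission probability
#'
#' Keeps exactly the lines whose per-decay intensity is strictly greater
#' than the threshold; order is preserved.
#'
#' @param lines data.frame with columns `energy_MeV`, `intensity_per_decay`.
#' @param threshold minimum emission probability per decay (exclusive).
#' @return the retained rows.
#' @export
select_gamma_lines <- function(lines, threshold = 6e-4) {
  if (!is.numeric(threshold) || threshold < 0) {
    stop_invalid("gamma intensity threshold must be >= 0")
  }
  if (nrow(lines) == 0) return(lines)
  if (any(lines$energy_MeV <= 0)) stop_invalid("gamma line energies must be positive")
  if (any(lines$intensity_per_decay <= 0 | lines$intensity_per_decay > 1)) {
    stop_invalid("gamma line intensities must be in (0, 1]")
  }
  lines[lines$intensity_per_decay > threshold, , drop = FALSE]
}

#' Read a gamma-line table
#'
#' @param path TSV file with columns `energy_MeV`, `intensity_per_decay`;
#'   defaults to the bundled Rh-106 table.
#' @return data.frame of candidate lines (unfiltered).
#' @export
read_gamma_lines <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rh106_gammas.tsv", package = "ruplaque")
  }
  if (!file.exists(path)) stop_invalid("gamma line table not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Construct the Ru-106/Rh-106 source term
#'
#' Combines the beta spectrum with the gamma lines retained above the
#' intensity threshold (strictly greater than, default 0.06% per decay).
#'
#' @param gamma_threshold per-decay intensity cutoff (exclusive).
#' @param multi_branch fold the minor beta branches into a mixture spectrum
#'   (default uses only the dominant branch).
#' @param grid_size beta spectrum grid size.
#' @param gamma_file optional path to a custom gamma-line table.
#' @return an object of class `source_term` with fields `beta`, `gammas`,
#'   `gamma_threshold`.
#' @export
ru106_source_term <- function(gamma_threshold = 6e-4, multi_branch = FALSE,
                              grid_size = 400, gamma_file = NULL) {
  if (multi_branch) {
    br <- rh106_beta_branches()
    qmax <- max(br$endpoint_MeV)
    e <- seq(qmax / grid_size, qmax, length.out = grid_size)
    dens <- rep(0, grid_size)
    for (i in seq_len(nrow(br))) {
      sh <- beta_shape(e, br$endpoint_MeV[i], 46)
      sh[e > br$endpoint_MeV[i]] <- 0
      dens <- dens + br$fraction[i] * sh / trapz(e, sh)
    }
    dens <- dens / trapz(e, dens)
    beta <- structure(list(energy_grid = e, density = dens,
                           endpoint_energy = qmax, daughter_z = 46),
                      class = "beta_spectrum")
  } else {
    beta <- build_beta_spectrum(grid_size = grid_size)
  }
  gammas <- select_gamma_lines(read_gamma_lines(gamma_file), gamma_threshold)
  source_term(beta, gammas, gamma_threshold)
}

#' Assemble a source term from components
#'
#' @param beta a `beta_spectrum`.
#' @param gammas data.frame of retained gamma lines (may have zero rows).
#' @param gamma_threshold the intensity cutoff the lines were filtered with.
#' @return `source_term` object.
#' @export
source_term <- function(beta, gammas, gamma_threshold = 6e-4) {
  stopifnot(inherits(beta, "beta_spectrum"))
  if (nrow(gammas) > 0 && any(gammas$intensity_per_decay <= gamma_threshold)) {
    stop_invalid("source term contains gamma lines at or below the threshold")
  }
  structure(list(beta = beta, gammas = gammas,
                 gamma_threshold = gamma_threshold),
            class = "source_term")
}

#' @export
print.source_term <- function(x, ...) {
  cat(sprintf("Ru-106/Rh-106 source term: beta endpoint %.3f MeV, %d gamma line(s) > %.2f%%/decay\n",
              x$beta$endpoint_energy, nrow(x$gammas),
              100 * x$gamma_threshold))
  invisible(x)
}

#' Sample the emissions of one or more decays
#'
#' Each decay emits one beta (energy drawn by inverse CDF from the
#' spectrum) and each retained gamma line independently with its per-decay
#' intensity.  Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param source a `source_term`.
#' @param n_decays number of decays to sample.
#' @return data.frame with columns `decay`, `kind` ("beta"/"gamma"),
#'   `energy` (MeV).
#' @export
sample_emission <- function(source, n_decays = 1) {
  stopifnot(inherits(source, "source_term"))
  qt <- spectrum_quantile_table(source$beta)
  u <- stats::runif(n_decays)
  eb <- stats::approx(seq(0, 1, length.out = length(qt)), qt, u)$y
  out <- data.frame(decay = seq_len(n_decays), kind = "beta", energy = eb)
  if (nrow(source$gammas) > 0) {
    for (i in seq_len(nrow(source$gammas))) {
      hit <- which(stats::runif(n_decays) < source$gammas$intensity_per_decay[i])
      if (length(hit)) {
        out <- rbind(out, data.frame(decay = hit, kind = "gamma",
                                     energy = source$gammas$energy_MeV[i]))
      }
    }
  }
  out[order(out$decay, out$kind), , drop = FALSE]
}

#' Export a beta spectrum as a delimited table
#'
#' @param spectrum a `beta_spectrum`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(energy_MeV = spectrum$energy_grid,
               density_per_MeV = spectrum$density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabulated beta spectrum
#'
#' Entry point for user-supplied spectra (e.g. evaluated
#' tabulations); the density is renormalized to unit integral.
#'
#' @param path TSV with columns `energy_MeV`, `density_per_MeV`.
#' @return `beta_spectrum` object.
#' @export
read_spectrum <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.unsorted(t$energy_MeV, strictly = TRUE)) {
    stop_invalid("spectrum energies must be strictly ascending")
  }
  d <- t$density_per_MeV / trapz(t$energy_MeV, t$density_per_MeV)
  structure(list(energy_grid = t$energy_MeV, density = d,
                 endpoint_energy = max(t$energy_MeV), daughter_z = NA),
            class = "beta_spectrum")
}
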