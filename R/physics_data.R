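# Electron stopping powers, CSDA ranges, photon attenuation coefficients and
# the Rh-106 gamma-line table.
#
# The electron tables bundled under inst/extdata are generated by
# `write_physics_tables()` from the Moller collision stopping-power formula
# with the Sternheimer density-effect correction (mean excitation energies
# 75 eV for water, 470 eV for silver).  Radiative (bremsstrahlung) losses are
# excluded throughout: both dose engines treat collision losses only, so the
# shared tables keep them consistent.

ELECTRON_REST_MEV <- 0.51099895
RHO_SILVER <- 10.49  # g/cm^3
X0_WATER_MM <- 360.8 # radiation length of water, mm

.material_constants <- list(
  water = list(ZA = 0.555087, I_MeV = 75e-6, rho = 1.0,
               st = list(x0 = 0.2400, x1 = 2.8004, C = 3.5017,
                         a = 0.09116, m = 3.4773)),
  silver = list(ZA = 0.435698, I_MeV = 470e-6, rho = 10.49,
                st = list(x0 = 0.0657, x1 = 3.1074, C = 5.0630,
                          a = 0.24585, m = 2.6899))
)

#' Electron collision stopping power
#'
#' Moller collision stopping power with Sternheimer density-effect
#' correction.  Radiative losses are not included.
#'
#' @param energy kinetic energy in MeV (vectorized).
#' @param material `"water"` or `"silver"`.
#' @return mass collision stopping power in MeV cm^2/g.
#' @export
electron_stopping_power <- function(energy, material = c("water", "silver")) {
  material <- match.arg(material)
  mc <- .material_constants[[material]]
  me <- ELECTRON_REST_MEV
  tau <- energy / me
  gamma <- tau + 1
  beta2 <- 1 - 1 / gamma^2
  pc <- sqrt(energy * (energy + 2 * me))
  # density-effect correction
  x <- log10(pc / me)
  st <- mc$st
  delta <- ifelse(x < st$x0, 0,
                  ifelse(x < st$x1,
                         4.6052 * x - st$C + st$a * (st$x1 - x)^st$m,
                         4.6052 * x - st$C))
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  brack <- log(tau^2 * (tau + 2) / 2) - 2 * log(mc$I_MeV / me) + Fm - delta
  0.153536 / beta2 * mc$ZA * brack
}

#' Build an electron stopping-power / CSDA-range table
#'
#' @param material `"water"` or `"silver"`.
#' @param e_min,e_max table energy bounds, MeV.
#' @param n number of (log-spaced) rows.
#' @return data.frame with columns `energy_MeV`, `stopping_MeV_cm2_g`,
#'   `csda_range_g_cm2`.
#' @export
make_stopping_table <- function(material = c("water", "silver"),
                                e_min = 0.002, e_max = 4.0, n = 240) {
  material <- match.arg(material)
  # fine grid for the range quadrature, coarser grid for the shipped table
  ef <- exp(seq(log(5e-4), log(e_max), length.out = 2000))
  sf <- electron_stopping_power(ef, material)
  # cumulative CSDA range by trapezoid on 1/S
  inv <- 1 / sf
  r <- c(0, cumsum((ef[-1] - ef[-length(ef)]) * (inv[-1] + inv[-length(inv)]) / 2))
  r <- r + ef[1] * inv[1]  # short extrapolation to zero energy
  eg <- exp(seq(log(e_min), log(e_max), length.out = n))
  data.frame(
    energy_MeV = eg,
    stopping_MeV_cm2_g = electron_stopping_power(eg, material),
    csda_range_g_cm2 = stats::approx(ef, r, eg)$y
  )
}

# NIST-style photon mass attenuation / energy-absorption coefficients, water.
.photon_water <- data.frame(
  energy_MeV = c(0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.80,
                 1.00, 1.25, 1.50, 2.00, 3.00, 3.50),
  mu_cm2_g  = c(0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.09687, 0.08956,
                0.07865, 0.07072, 0.06323, 0.05754, 0.04942, 0.03969, 0.03640),
  muen_cm2_g = c(0.02546, 0.02764, 0.02967, 0.03192, 0.03279, 0.03299,
                 0.03284, 0.03206, 0.03103, 0.02965, 0.02833, 0.02608,
                 0.02281, 0.02161)
)

# Ratio of silver to water linear attenuation per geometric mm, used when a
# photon ray crosses the applicator shell (Compton-dominated regime, ratio of
# Z/A times density).
SILVER_PHOTON_WEQ <- 7.9

#' Write the bundled physics tables
#'
#' Regenerates the plain-text physics tables shipped under
#' `inst/extdata`.  Used at package-development time; the shipped files are
#' the ones read at run time.
#'
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_physics_tables <- function(dir) {
  paths <- character(0)
  for (m in c("water", "silver")) {
    tab <- make_stopping_table(m)
    p <- file.path(dir, sprintf("stopping_%s.tsv", m))
    utils::write.table(format(tab, digits = 8), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "photon_water.tsv")
  utils::write.table(.photon_water, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

.phys_cache <- new.env(parent = emptyenv())

physics_tables <- function() {
  if (!is.null(.phys_cache$tabs)) return(.phys_cache$tabs)
  read1 <- function(f) {
    p <- system.file("extdata", f, package = "ruplaque")
    if (!nzchar(p)) stop_invalid("bundled physics table %s not found", f)
    utils::read.table(p, header = TRUE, sep = "\t")
  }
  tabs <- list(water = read1("stopping_water.tsv"),
               silver = read1("stopping_silver.tsv"),
               photon = read1("photon_water.tsv"))
  .phys_cache$tabs <- tabs
  tabs
}

sp_water <- function(energy) {
  t <- physics_tables()$water
  exp(interp_strict(log(t$energy_MeV), log(t$stopping_MeV_cm2_g),
                    log(pmax(energy, min(t$energy_MeV))), "stopping power"))
}

sp_silver <- function(energy) {
  t <- physics_tables()$silver
  exp(interp_strict(log(t$energy_MeV), log(t$stopping_MeV_cm2_g),
                    log(pmax(energy, min(t$energy_MeV))), "stopping power"))
}

#' CSDA range of an electron in water
#'
#' @param energy kinetic energy, MeV.
#' @return continuous-slowing-down range in mm of water.
#' @export
csda_range_water_mm <- function(energy) {
  t <- physics_tables()$water
  10 * exp(interp_strict(log(t$energy_MeV), log(t$csda_range_g_cm2),
                         log(pmax(energy, min(t$energy_MeV))), "CSDA range"))
}

# inverse of csda_range_water_mm
energy_at_range_water_mm <- function(range_mm) {
  t <- physics_tables()$water
  exp(interp_strict(log(10 * t$csda_range_g_cm2), log(t$energy_MeV),
                    log(pmax(range_mm, 10 * min(t$csda_range_g_cm2))),
                    "CSDA range inverse"))
}

#' Water-equivalence factor of silver for electrons
#'
#' Water-equivalent path length per geometric path length in silver,
#' i.e. the ratio of linear collision stopping powers
#' (S_Ag * rho_Ag) / (S_w * rho_w).
#'
#' @param energy kinetic energy, MeV.
#' @return dimensionless factor (~8-9 over the therapeutic range).
#' @export
silver_weq_factor <- function(energy) {
  sp_silver(energy) * RHO_SILVER / sp_water(energy)
}

photon_mu_water_per_mm <- function(energy) {
  t <- physics_tables()$photon
  interp_strict(t$energy_MeV, t$mu_cm2_g, energy, "photon attenuation") * 0.1
}

photon_muen_water_per_mm <- function(energy) {
  t <- physics_tables()$photon
  interp_strict(t$energy_MeV, t$muen_cm2_g, energy, "photon absorption") * 0.1
}
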