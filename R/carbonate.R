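# Carbonate system: Gran alkalinity, freshwater equilibrium constants and
# DIC speciation.  All concentrations are mol L^-1, volumes L, temperature
# degrees Celsius.  Zero-ionic-strength (freshwater) constants are used
# throughout; the measured pH is treated as a free-proton-scale activity.

#' Carbonic-acid and water equilibrium constants for fresh water
#'
#' Temperature functions for the first and second dissociation constants of
#' carbonic acid (Plummer & Busenberg 1982 fits, zero ionic strength) and the
#' ion product of water (Millero 1995 refit of the Harned & Owen data).  All
#' constants are returned on the mol L^-1 concentration scale.
#'
#' @param temperature Water temperature in degrees C; must lie in 0--40.
#' @return A list with elements `K1`, `K2`, `Kw` (numeric), and the
#'   corresponding `pK1`, `pK2`, `pKw`.
#' @examples
#' equilibrium_constants(25)$pK1  # ~6.35
#' @export
equilibrium_constants <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (is.na(temperature) || temperature < 0 || temperature > 40) {
    stop("temperature must be between 0 and 40 degrees C")
  }
  TK <- temperature + 273.15
  log10_k1 <- -356.3094 - 0.06091964 * TK + 21834.37 / TK +
    126.8339 * log10(TK) - 1684915 / TK^2
  log10_k2 <- -107.8871 - 0.03252849 * TK + 5151.79 / TK +
    38.92561 * log10(TK) - 563713.9 / TK^2
  ln_kw <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK)
  list(
    K1 = 10^log10_k1, K2 = 10^log10_k2, Kw = exp(ln_kw),
    pK1 = -log10_k1, pK2 = -log10_k2, pKw = -ln_kw / log(10)
  )
}

#' Total alkalinity from a Gran titration
#'
#' Linearizes the acidimetric titration curve past the carbonic-acid
#' equivalence point with the Gran function F(Va) = (V0 + Va) * 10^(-pH) and
#' locates the equivalence volume as the x-intercept of an ordinary
#' least-squares line through the qualifying points.
#'
#' @param acid_volume Acid volumes added (L), strictly increasing.
#' @param ph Measured pH at each acid volume.
#' @param sample_volume Initial sample volume V0 (L).
#' @param acid_concentration Titrant acid concentration (mol L^-1).
#' @param ph_cutoff Points with pH below this value enter the Gran
#'   regression (default 4.5, i.e. past the carbonic-acid equivalence).
#' @return A list with `ta` (total alkalinity, mol L^-1), `ve` (equivalence
#'   volume, L), `r_squared` of the Gran line and `n_points` used.
#' @export
gran_alkalinity <- function(acid_volume, ph, sample_volume, acid_concentration,
                            ph_cutoff = 4.5) {
  stopifnot(length(acid_volume) == length(ph), sample_volume > 0,
            acid_concentration > 0)
  if (any(diff(acid_volume) <= 0)) {
    stop("acid_volume must be strictly increasing")
  }
  sel <- ph < ph_cutoff
  if (sum(sel) < 3L) {
    stop("need at least 3 titration points with pH below ", ph_cutoff)
  }
  va <- acid_volume[sel]
  f <- (sample_volume + va) * 10^(-ph[sel])
  fit <- stats::lm(f ~ va)
  slope <- stats::coef(fit)[["va"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  ve <- -intercept / slope
  if (!is.finite(ve) || ve <= 0) {
    stop("non-positive equivalence volume: over-acidified start or bad data")
  }
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(ta = ve * acid_concentration / sample_volume, ve = ve,
       r_squared = r2, n_points = sum(sel))
}

#' Dissolved inorganic carbon from temperature, pH and alkalinity
#'
#' Solves the freshwater carbonate system: carbonate alkalinity
#' CA = TA - Kw/h + h with h = 10^(-pH), then
#' DIC = CA * (1 + h/K1 + K2/h) / (1 + 2 K2/h), partitioned into
#' CO2* (dissolved CO2 + H2CO3), HCO3- and CO3^2-.
#'
#' @param temperature Degrees C.
#' @param ph Measured pH.
#' @param ta Total alkalinity (mol L^-1).
#' @return List with `dic`, `co2`, `hco3`, `co3` (mol L^-1) and the
#'   ionization fractions `alpha0`, `alpha1`, `alpha2`.
#' @export
dic_from_ta <- function(temperature, ph, ta) {
  k <- equilibrium_constants(temperature)
  h <- 10^(-ph)
  ca <- ta - k$Kw / h + h
  if (ca <= 0) stop("alkalinity inconsistent with pH: carbonate alkalinity <= 0")
  dic <- ca * (1 + h / k$K1 + k$K2 / h) / (1 + 2 * k$K2 / h)
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  alpha0 <- h^2 / denom
  alpha1 <- k$K1 * h / denom
  alpha2 <- k$K1 * k$K2 / denom
  list(dic = dic, co2 = alpha0 * dic, hco3 = alpha1 * dic, co3 = alpha2 * dic,
       alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2)
}

#' Total alkalinity implied by DIC and pH (forward model)
#'
#' Inverse companion of [dic_from_ta()]; used by the titration simulator.
#'
#' @inheritParams dic_from_ta
#' @param dic Dissolved inorganic carbon (mol L^-1).
#' @return Total alkalinity (mol L^-1).
#' @export
ta_from_dic <- function(temperature, ph, dic) {
  k <- equilibrium_constants(temperature)
  h <- 10^(-ph)
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  dic * (k$K1 * h + 2 * k$K1 * k$K2) / denom + k$Kw / h - h
}

#' pH of a solution of known DIC and total alkalinity
#'
#' Root-finds the proton balance; supports the Gran titration simulator.
#'
#' @inheritParams ta_from_dic
#' @param ta Total alkalinity (mol L^-1); may be negative past the
#'   equivalence point.
#' @return pH.
#' @export
carbonate_ph <- function(temperature, ta, dic) {
  f <- function(ph) ta_from_dic(temperature, ph, dic) - ta
  stats::uniroot(f, lower = 1.5, upper = 12.5, tol = 1e-12)$root
}

#' Simulate an ideal Gran titration curve
#'
#' Generates (acid volume, pH) points for the acidimetric titration of a
#' carbonate-buffered sample, accounting for dilution by the titrant and
#' conservation of DIC (no degassing).
#'
#' @param ta Initial total alkalinity (mol L^-1).
#' @param dic Initial DIC (mol L^-1).
#' @param temperature Degrees C.
#' @param sample_volume V0 (L).
#' @param acid_concentration Titrant strength (mol L^-1).
#' @param acid_volume Acid volumes to evaluate (L).
#' @return data.frame with columns `acid_volume` and `ph`.
#' @export
simulate_gran_titration <- function(ta, dic, temperature, sample_volume,
                                    acid_concentration, acid_volume) {
  ph <- vapply(acid_volume, function(va) {
    ta_v <- (ta * sample_volume - acid_concentration * va) / (sample_volume + va)
    dic_v <- dic * sample_volume / (sample_volume + va)
    carbonate_ph(temperature, ta_v, dic_v)
  }, numeric(1))
  data.frame(acid_volume = acid_volume, ph = ph)
}
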