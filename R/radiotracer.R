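# Radiotracer assimilation rates from scintillation DPM readings:
# 3H/14C-labelled organic monomers (TCA-killed control subtraction) and
# fractionated H14CO3- incorporation scaled by ambient DIC.

# carbons per molecule of each monomer substrate
CARBONS_PER_MOLECULE <- c(glucose = 6, pyruvate = 3, leucine = 6, thymidine = 10)

#' Convert a specific activity to DPM per nanomole
#'
#' 1 GBq mmol^-1 = 1e9 Bq mmol^-1 = 6e10 DPM mmol^-1 = 6e4 DPM nmol^-1.
#'
#' @param specific_activity Specific activity in GBq mmol^-1.
#' @return DPM nmol^-1.
#' @examples
#' sa_to_dpm_per_nmol(2220)  # 1.332e8
#' @export
sa_to_dpm_per_nmol <- function(specific_activity) {
  if (any(specific_activity <= 0)) stop("specific_activity must be positive")
  specific_activity * 6e4
}

#' Monomer assimilation rate from sample and killed-control DPM
#'
#' The killed-control activity is subtracted (floored at zero with a warning
#' when counting noise inverts a small signal), converted to nanomoles of
#' tracer through the specific activity, and normalized by sample volume and
#' incubation time.  By default the molar rate is multiplied by the number
#' of carbon atoms per molecule to report nmol C L^-1 h^-1.
#'
#' @param sample_dpm DPM of the live sample.
#' @param killed_dpm DPM of the TCA-killed control.
#' @param specific_activity GBq mmol^-1.
#' @param sample_volume Incubated volume (L), default 5 mL.
#' @param incubation_hours Incubation time (h), default 1.
#' @param carbons_per_molecule Carbon atoms per substrate molecule; used
#'   when `carbon_units` is TRUE.
#' @param carbon_units Report nmol C (TRUE, default) or nmol of substrate
#'   molecules (FALSE).
#' @return List with `value` (rate in the requested units), `molar_rate`
#'   (nmol substrate L^-1 h^-1) and `units`.
#' @export
monomer_rate <- function(sample_dpm, killed_dpm, specific_activity,
                         sample_volume = 5e-3, incubation_hours = 1,
                         carbons_per_molecule = 1, carbon_units = TRUE) {
  stopifnot(sample_dpm >= 0, killed_dpm >= 0, sample_volume > 0,
            incubation_hours > 0, carbons_per_molecule >= 1)
  delta <- sample_dpm - killed_dpm
  if (delta < 0) {
    # allow a few-sigma Poisson counting inversion quietly only if tiny
    if (-delta > 3 * sqrt(sample_dpm + killed_dpm + 1)) {
      warning("killed control exceeds sample DPM beyond counting noise; rate set to 0")
    }
    delta <- 0
  }
  molar <- delta / (sa_to_dpm_per_nmol(specific_activity) *
                      sample_volume * incubation_hours)
  value <- if (carbon_units) molar * carbons_per_molecule else molar
  list(value = value, molar_rate = molar,
       units = if (carbon_units) "nmol C L-1 h-1" else "nmol L-1 h-1")
}

#' Fractionated bicarbonate incorporation rates
#'
#' Converts DPM in the particulate and dissolved fractions of an H14CO3-
#' incubation into carbon fluxes: the fraction of the added label recovered
#' per litre of sample is scaled by the ambient DIC concentration and the
#' incubation time.  Differing filtration volumes per fraction (30 mL onto
#' the coarse filter, 5 mL refiltered, 1 mL total-activity aliquot) are
#' handled through per-fraction volume factors.
#'
#' @param fraction_dpm Named numeric vector of DPM per fraction, e.g.
#'   `c(particulate_gt2.5um = ..., particulate_0.17_2.5um = ..., doc_filtrate = ...)`.
#' @param total_added_dpm DPM measured in the total-activity aliquot.
#' @param dic Ambient dissolved inorganic carbon (mol L^-1).
#' @param incubation_hours Incubation time (h).
#' @param fraction_volumes Named vector of filtered volumes per fraction (L);
#'   defaults follow the standard protocol.
#' @param total_volume Volume of the total-activity aliquot (L), default 1 mL.
#' @return List with `rates` (named, umol C L^-1 h^-1), `total`
#'   (their sum) and `fraction_of_added` per fraction.
#' @export
bicarbonate_rates <- function(fraction_dpm, total_added_dpm, dic,
                              incubation_hours,
                              fraction_volumes = c(particulate_gt2.5um = 30e-3,
                                                   particulate_0.17_2.5um = 5e-3,
                                                   doc_filtrate = 5e-3),
                              total_volume = 1e-3) {
  stopifnot(total_added_dpm > 0, dic > 0, incubation_hours > 0)
  if (any(fraction_dpm < 0)) stop("fraction DPM must be non-negative")
  if (is.null(names(fraction_dpm)) || !all(names(fraction_dpm) %in% names(fraction_volumes))) {
    stop("fraction_dpm must be named and match fraction_volumes")
  }
  vols <- fraction_volumes[names(fraction_dpm)]
  added_per_l <- total_added_dpm / total_volume
  frac <- (fraction_dpm / vols) / added_per_l
  if (sum(frac) > 1 + 1e-9) {
    stop("mass balance violated: recovered label exceeds the added activity")
  }
  rates <- frac * dic * 1e6 / incubation_hours
  list(rates = rates, total = sum(rates), fraction_of_added = frac)
}

#' Bottle-level tracer rates from a scintillation table
#'
#' Pairs live samples with their killed controls (monomers) or sums label
#' fractions against the total-activity aliquot (bicarbonate) to produce one
#' rate per date, treatment and replicate.
#'
#' @param scintillation_table Long data.frame; monomer rows need columns
#'   `substrate`, `date`, `treatment`, `replicate`, `vial` (sample/killed),
#'   `dpm`, `specific_activity_gbq_mmol`, `sample_volume_l`,
#'   `incubation_hours`; bicarbonate rows carry `vial` =
#'   fraction name or `total_added`.
#' @param dic_table data.frame with `date` and `dic_mol_l`, required when
#'   bicarbonate rows are present.
#' @param carbon_units Passed to [monomer_rate()].
#' @return data.frame of rates: `analyte`, `date`, `treatment`, `replicate`,
#'   `value`, `units`, `incubation_hours`.  Monomer rates are
#'   nmol C L^-1 h^-1, bicarbonate totals umol C L^-1 h^-1 (analyte
#'   `CO2_fixation`).
#' @export
tracer_rates <- function(scintillation_table, dic_table = NULL,
                         carbon_units = TRUE) {
  st <- scintillation_table
  key <- interaction(st$substrate, st$date, st$treatment, st$replicate, drop = TRUE)
  rows <- lapply(split(st, key), function(g) {
    sub <- g$substrate[1]
    if (sub == "bicarbonate") {
      if (is.null(dic_table)) stop("dic_table required for bicarbonate assays")
      dic <- dic_table$dic_mol_l[match(as.character(g$date[1]),
                                       as.character(dic_table$date))]
      if (is.na(dic)) stop("no DIC value for date ", g$date[1])
      fr <- g[g$vial != "total_added", , drop = FALSE]
      tot <- g$dpm[g$vial == "total_added"]
      if (length(tot) != 1L) stop("bicarbonate assay needs one total_added vial")
      dpm <- stats::setNames(fr$dpm, fr$vial)
      r <- bicarbonate_rates(dpm, tot, dic, g$incubation_hours[1])
      data.frame(analyte = "CO2_fixation", date = g$date[1],
                 treatment = g$treatment[1], replicate = g$replicate[1],
                 value = r$total, units = "umol C L-1 h-1",
                 incubation_hours = g$incubation_hours[1])
    } else {
      smp <- g$dpm[g$vial == "sample"]
      kil <- g$dpm[g$vial == "killed"]
      if (length(smp) != 1L || length(kil) != 1L) {
        stop("monomer assay needs one sample and one killed vial per replicate")
      }
      r <- monomer_rate(smp, kil, g$specific_activity_gbq_mmol[1],
                        g$sample_volume_l[1], g$incubation_hours[1],
                        CARBONS_PER_MOLECULE[[sub]], carbon_units)
      data.frame(analyte = sub, date = g$date[1], treatment = g$treatment[1],
                 replicate = g$replicate[1], value = r$value, units = r$units,
                 incubation_hours = g$incubation_hours[1])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$analyte, out$date, out$treatment, out$replicate), ]
}
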