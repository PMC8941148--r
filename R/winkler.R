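# Winkler iodometric oxygen chemistry and bottle-incubation rate derivation.
# Stoichiometry: 1 mol O2 fixes iodine equivalent to 4 mol thiosulfate;
# 1 mol IO3- consumes 6 mol thiosulfate during standardization.

#' Standardize a thiosulfate titrant against a KIO3 standard
#'
#' Each replicate titration of a known amount of iodate yields a titrant
#' concentration via the iodate--iodide stoichiometry
#' (1 IO3- = 3 I2 = 6 S2O3^2-).
#'
#' @param kio3_moles Moles of KIO3 titrated in each replicate.
#' @param titrant_volume Thiosulfate volume used (L), same length.
#' @return List with `concentration` (the replicate mean, mol L^-1) and
#'   `replicates` (per-replicate concentrations).
#' @examples
#' standardize_thiosulfate(1e-6, 0.600e-3)$concentration  # 0.0100 mol/L
#' @export
standardize_thiosulfate <- function(kio3_moles, titrant_volume) {
  stopifnot(length(kio3_moles) == length(titrant_volume),
            length(kio3_moles) >= 1L)
  if (any(kio3_moles <= 0)) stop("kio3_moles must be positive")
  if (any(titrant_volume <= 0)) stop("invalid record: non-positive titrant volume")
  conc <- 6 * kio3_moles / titrant_volume
  list(concentration = mean(conc), replicates = conc)
}

#' Dissolved oxygen concentration from a Winkler titration
#'
#' Converts the thiosulfate volume at the endpoint into micromoles of O2 per
#' litre of original sample, correcting the effective bottle volume for the
#' sample displaced by the two fixing reagents (1 mol O2 = 4 mol S2O3^2-).
#'
#' @param titrant_volume Thiosulfate used (L); vectorized.
#' @param thiosulfate_concentration Titrant strength (mol L^-1), default 0.01.
#' @param bottle_volume Bottle capacity (L), default 0.115 (nominal 115 mL).
#' @param reagent_volume_displaced Sample displaced by fixing reagents (L),
#'   default 2.4 mL (2 x 1.2 mL).  Set to 0 to disable the correction.
#' @return O2 concentration in umol L^-1.
#' @examples
#' o2_concentration(1.2e-3)  # 26.64 umol/L
#' @export
o2_concentration <- function(titrant_volume,
                             thiosulfate_concentration = 0.01,
                             bottle_volume = 0.115,
                             reagent_volume_displaced = 2.4e-3) {
  if (any(titrant_volume < 0)) stop("titrant_volume must be non-negative")
  stopifnot(thiosulfate_concentration > 0)
  v_eff <- bottle_volume - reagent_volume_displaced
  if (any(v_eff <= 0)) stop("non-positive effective bottle volume")
  (titrant_volume * thiosulfate_concentration / 4) / v_eff * 1e6
}

# Welch difference-of-means interval, returned per hour of incubation.
welch_rate <- function(a, b, hours, analyte, conf_level = 0.95) {
  stopifnot(hours > 0)
  diff <- mean(a) - mean(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 > 1L && n2 > 1L) {
    v1 <- stats::var(a) / n1
    v2 <- stats::var(b) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    if (!is.finite(df) || se == 0) { df <- n1 + n2 - 2; }
    half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
  } else {
    se <- NA_real_; df <- NA_real_; half <- NA_real_
  }
  structure(list(analyte = analyte, value = diff / hours,
                 se = se / hours, df = df,
                 conf_int = c(diff - half, diff + half) / hours,
                 conf_level = conf_level,
                 incubation_hours = hours, n = c(n1, n2)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate: %.4g per hour (%.0f%% CI %.4g to %.4g), %g h incubation\n",
              x$analyte, x$value, 100 * x$conf_level,
              x$conf_int[1], x$conf_int[2], x$incubation_hours))
  invisible(x)
}

#' Community respiration rate from T0 and end-point oxygen concentrations
#'
#' Respiration is the O2 decline between the initial (T0) and the
#' dark/infrared end-point bottles divided by the incubation time; the 95%
#' interval is a Welch t-interval on the difference of bottle means.
#' Negative rates (net O2 increase in the dark) are retained with a warning.
#'
#' @param t0 O2 concentrations of the T0 bottles (umol L^-1).
#' @param end O2 concentrations at the end of the incubation (umol L^-1).
#' @param hours Incubation length (h), default 24.
#' @return A `rate_estimate` (umol O2 L^-1 h^-1).
#' @export
respiration_rate <- function(t0, end, hours = 24) {
  stopifnot(length(t0) >= 1L, length(end) >= 1L)
  out <- welch_rate(t0, end, hours, "respiration")
  if (out$value < 0) warning("negative respiration rate (O2 increased in the dark)")
  out
}

#' Net primary production rate from T0 and light-incubated bottles
#'
#' @param t0 O2 concentrations of the T0 bottles (umol L^-1).
#' @param end_light O2 concentrations after incubation in white light.
#' @param hours Incubation length (h), default 24.
#' @return A `rate_estimate` (umol O2 L^-1 h^-1), positive for net production.
#' @export
npp_rate <- function(t0, end_light, hours = 24) {
  stopifnot(length(t0) >= 1L, length(end_light) >= 1L)
  welch_rate(end_light, t0, hours, "NPP")
}

#' Per-bottle oxygen concentrations from a titration table
#'
#' @param titration_table data.frame with columns `bottle_id`, `date`,
#'   `treatment` (one of T0, dark, IR, light), `replicate`,
#'   `bottle_volume_l`, `reagent_volume_displaced_l`, `titrant_volume_l`.
#' @param standardization_table Optional data.frame with columns `date`,
#'   `kio3_moles`, `titrant_volume_l`; when given, the thiosulfate
#'   concentration is standardized per date, otherwise the table's
#'   `thiosulfate_mol_l` column (or 0.01) is used.
#' @return The input table with an `o2_umol_l` column appended.
#' @export
winkler_o2_table <- function(titration_table, standardization_table = NULL) {
  tt <- titration_table
  need <- c("bottle_id", "date", "treatment", "titrant_volume_l")
  if (!all(need %in% names(tt))) {
    stop("titration table missing columns: ",
         paste(setdiff(need, names(tt)), collapse = ", "))
  }
  if (!all(tt$treatment %in% c("T0", "dark", "IR", "light"))) {
    stop("treatment must be one of T0, dark, IR, light")
  }
  bv <- if ("bottle_volume_l" %in% names(tt)) tt$bottle_volume_l else 0.115
  rv <- if ("reagent_volume_displaced_l" %in% names(tt)) {
    tt$reagent_volume_displaced_l
  } else 2.4e-3
  if (!is.null(standardization_table)) {
    st <- standardization_table
    conc_by_date <- vapply(split(st, st$date), function(d) {
      standardize_thiosulfate(d$kio3_moles, d$titrant_volume_l)$concentration
    }, numeric(1))
    conc <- conc_by_date[as.character(tt$date)]
    if (anyNA(conc)) stop("standardization missing for some dates")
  } else if ("thiosulfate_mol_l" %in% names(tt)) {
    conc <- tt$thiosulfate_mol_l
  } else {
    conc <- 0.01
  }
  tt$o2_umol_l <- o2_concentration(tt$titrant_volume_l, conc, bv, rv)
  tt
}

#' Bottle-level activity rates from an oxygen table
#'
#' For every date, each dark or IR bottle yields a respiration rate against
#' the date's mean T0 concentration, and each light bottle a net primary
#' production rate.  Replicate bottles are kept as individual rows so that
#' downstream mixed models use the full number of independent measurements.
#'
#' @param o2_table Output of [winkler_o2_table()].
#' @param hours Incubation length (h), default 24.
#' @return data.frame with columns `analyte`, `date`, `treatment`,
#'   `replicate`, `value` (umol O2 L^-1 h^-1), `incubation_hours`.
#' @export
bottle_rates <- function(o2_table, hours = 24) {
  stopifnot(hours > 0)
  out <- lapply(split(o2_table, o2_table$date), function(d) {
    t0 <- d$o2_umol_l[d$treatment == "T0"]
    if (length(t0) == 0L) stop("date ", d$date[1], " has no T0 bottles")
    end <- d[d$treatment %in% c("dark", "IR", "light"), , drop = FALSE]
    data.frame(
      analyte = ifelse(end$treatment == "light", "NPP", "respiration"),
      date = end$date,
      treatment = end$treatment,
      replicate = end$replicate,
      value = ifelse(end$treatment == "light",
                     (end$o2_umol_l - mean(t0)) / hours,
                     (mean(t0) - end$o2_umol_l) / hours),
      incubation_hours = hours,
      row.names = NULL
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
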