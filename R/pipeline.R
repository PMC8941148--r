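# End-to-end pipeline: titration chemistry -> rates -> mixed-model light
# effects -> seasonal lake CO2 budget (-> community DistLM when counts are
# present).  Every stage consumes and produces plain tables so it can also
# be run standalone.

#' Per-date dissolved inorganic carbon from the Gran titration table
#'
#' @param gran_table Long table of titration points (`date`,
#'   `sample_volume_l`, `acid_concentration_mol_l`, `acid_volume_l`, `ph`).
#' @param station_table data.frame with `date`, `water_temperature`, `ph`.
#' @return data.frame with `date`, `ta_mol_l`, `dic_mol_l`, `gran_r_squared`.
#' @export
dic_table <- function(gran_table, station_table) {
  rows <- lapply(split(gran_table, gran_table$date), function(g) {
    fit <- gran_alkalinity(g$acid_volume_l, g$ph, g$sample_volume_l[1],
                           g$acid_concentration_mol_l[1])
    i <- match(as.character(g$date[1]), as.character(station_table$date))
    if (is.na(i)) stop("station metadata missing for date ", g$date[1])
    dic <- dic_from_ta(station_table$water_temperature[i],
                       station_table$ph[i], fit$ta)$dic
    data.frame(date = g$date[1], ta_mol_l = fit$ta, dic_mol_l = dic,
               gran_r_squared = fit$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$date), ]
}

#' Mixed-model light-effect summaries for every analyte
#'
#' For each analyte with dark and IR measurements, fits
#' `value ~ treatment` with a random date intercept by maximum likelihood,
#' tests the treatment term with a likelihood-ratio ANOVA against the
#' intercept-only model, and expresses the effect as a percent difference
#' relative to the dark (reference) mean.
#'
#' @param rates Long data.frame of bottle-level rates (`analyte`, `date`,
#'   `treatment` in dark/IR, `replicate`, `value`).
#' @return List with `summary` (data.frame: analyte, percent, ci_lo, ci_hi,
#'   direction, p_value, n, n_dates) and `fits` (named list of
#'   `mixed_fit`/`effect_summary` pairs).
#' @export
light_effect_summaries <- function(rates) {
  rates <- rates[rates$treatment %in% c("dark", "IR"), , drop = FALSE]
  rates$treatment <- factor(rates$treatment, levels = c("dark", "IR"))
  fits <- list()
  rows <- lapply(split(rates, rates$analyte), function(d) {
    full <- fit_lmm(value ~ treatment, d, group = "date")
    null <- fit_lmm(value ~ 1, d, group = "date")
    eff <- percent_difference(full, reduced = null)
    fits[[d$analyte[1]]] <<- list(fit = full, effect = eff)
    data.frame(analyte = d$analyte[1], percent = eff$percent,
               ci_lo = eff$conf_int[1], ci_hi = eff$conf_int[2],
               direction = eff$direction, p_value = eff$p_value,
               n = full$n, n_dates = full$n_groups)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, fits = fits)
}

#' Station-day table (per-date mean rates) for the budget chain
#'
#' @param rates Bottle-level rates including `respiration` (dark and IR)
#'   and `NPP` rows.
#' @param station_table data.frame with `date`, `water_temperature`,
#'   `light_hours`.
#' @return data.frame with one row per date: `date`, `npp_rate`,
#'   `resp_dark`, `resp_ir`, `light_hours`, `water_temperature`.
#' @export
station_days <- function(rates, station_table) {
  agg <- function(analyte, treatment) {
    d <- rates[rates$analyte == analyte & rates$treatment == treatment, ]
    tapply(d$value, as.character(d$date), mean)
  }
  resp_dark <- agg("respiration", "dark")
  resp_ir <- agg("respiration", "IR")
  npp <- agg("NPP", "light")
  dts <- sort(unique(as.character(rates$date)))
  i <- match(dts, as.character(station_table$date))
  if (anyNA(i)) stop("station metadata missing for some dates")
  data.frame(date = as.Date(dts),
             npp_rate = as.numeric(npp[dts]),
             resp_dark = as.numeric(resp_dark[dts]),
             resp_ir = as.numeric(resp_ir[dts]),
             light_hours = station_table$light_hours[i],
             water_temperature = station_table$water_temperature[i])
}

#' Run the full analysis pipeline on a study
#'
#' Executes the Winkler, carbonate, tracer, mixed-model and budget stages
#' (plus DistLM when a count table is present) and optionally writes every
#' intermediate table with provenance headers.
#'
#' @param study A `simulated_study` or a list holding the same tables read
#'   from disk.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @param seed Seed for the DistLM permutation stream (default 1).
#' @param n_perms Permutations for DistLM marginal/sequential tests.
#' @param budget_cfg A [season_config()].
#' @return List of class `pipeline_result`: `o2_table`, `rates`,
#'   `dic_table`, `effects` (percent-difference summary), `budgets`
#'   (per season-year `season_budget` plus `difference_total_g`),
#'   `community` (a `distlm_result` or NULL).
#' @export
run_pipeline <- function(study, out_dir = NULL, seed = 1, n_perms = 999,
                         budget_cfg = season_config()) {
  o2 <- winkler_o2_table(study$titration_table, study$standardization_table)
  oxy_rates <- bottle_rates(o2, hours = 24)
  dics <- dic_table(study$gran_table, study$station_table)
  trc <- tracer_rates(study$scintillation_table, dics)
  rates <- rbind(oxy_rates[, c("analyte", "date", "treatment", "replicate",
                               "value", "incubation_hours")],
                 trc[, c("analyte", "date", "treatment", "replicate",
                         "value", "incubation_hours")])
  eff <- light_effect_summaries(rates)
  sdays <- station_days(rates, study$station_table)
  year <- as.integer(format(sdays$date, "%Y"))
  budgets <- lapply(split(sdays, year), budget_difference, cfg = budget_cfg)
  diff_total <- sum(vapply(budgets, `[[`, numeric(1),
                           "difference_dark_minus_ir_g"))
  community <- NULL
  if (!is.null(study$count_table)) {
    filtered <- rare_filter(study$count_table)
    trans <- vst_transform(filtered)
    d <- suppressWarnings(bray_curtis(trans))
    community <- distlm(d, study$community_covariates, n_perms = n_perms,
                        seed = seed)
  }
  res <- structure(list(o2_table = o2, rates = rates, dic_table = dics,
                        effects = eff$summary, fits = eff$fits,
                        station_days = sdays, budgets = budgets,
                        difference_total_g = diff_total,
                        community = community, seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(stage = "pipeline", seed = seed,
              season_days = budget_cfg$season_days,
              lake_area_m2 = budget_cfg$lake_area,
              layer_depth_m = budget_cfg$layer_depth,
              respiratory_quotient = budget_cfg$respiratory_quotient)
    write_table_csv(o2, file.path(out_dir, "o2_concentrations.csv"), prov)
    write_table_csv(rates, file.path(out_dir, "rates.csv"), prov)
    write_table_csv(dics, file.path(out_dir, "dic.csv"), prov)
    write_table_csv(eff$summary, file.path(out_dir, "light_effects.csv"), prov)
    write_table_csv(sdays, file.path(out_dir, "station_days.csv"), prov)
    budget_rows <- do.call(rbind, lapply(names(budgets), function(y) {
      b <- budgets[[y]]
      data.frame(season = y, npp_g = b$npp_g, resp_dark_g = b$resp_dark_g,
                 resp_ir_g = b$resp_ir_g, excess_dark_g = b$excess_dark_g,
                 excess_ir_g = b$excess_ir_g,
                 difference_dark_minus_ir_g = b$difference_dark_minus_ir_g)
    }))
    write_table_csv(budget_rows, file.path(out_dir, "budget.csv"), prov)
    if (!is.null(community)) {
      write_table_csv(community$marginal,
                      file.path(out_dir, "distlm_marginal.csv"), prov)
    }
    jsonlite::write_json(
      list(seed = seed,
           effects = eff$summary,
           difference_total_g = diff_total),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat("Light-effect summaries (percent difference vs dark reference):\n")
  print(x$effects, digits = 3)
  cat(sprintf("Seasonal dark - IR CO2 difference: %.4g g over %d season(s)\n",
              x$difference_total_g, length(x$budgets)))
  if (!is.null(x$community)) {
    cat("Community DistLM marginal tests:\n")
    print(x$community$marginal, digits = 3)
  }
  invisible(x)
}
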