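## ---------------------------------------------------------------------------
## End-to-end convenience layer: from a dataset to adjusted trajectories
## and deaths for each country.  Thin orchestration over the module
## functions; everything here can also be called step by step.
## ---------------------------------------------------------------------------

#' Published global and regional summary estimates
#'
#' Loads the small bundled table of published inter-agency global and
#' regional child-mortality summary values (rates per 1000 for selected
#' years, death counts in thousands, live births in millions) used as
#' inputs to the worked-example metrics.
#'
#' @return data frame with columns `region`, `quantity`, `year`, `value`.
#' @export
reference_estimates <- function() {
  utils::read.csv(system.file("extdata", "published_summary_estimates.csv",
                              package = "childmort"),
                  stringsAsFactors = FALSE)
}

## convenience lookup into the reference table
ref_value <- function(ref, region, quantity, year) {
  v <- ref$value[ref$region == region & ref$quantity == quantity &
                   ref$year == year]
  stop_if(length(v) != 1, "reference value not found: ", region, "/",
          quantity, "/", year)
  v
}

## assemble extrapolated, ordered trajectories for one country from its
## fitted models (re-runs only the cheap stages, not the spline MCMC)
assemble_country <- function(fit_u5, fit_imr, obs_nmr, births, country_id,
                             config, ratio_cfg, global_arr) {
  tr_u5 <- as_trajectories(fit_u5, country_id, "U5MR")
  tr_u5 <- extrapolate_trajectories(tr_u5, fit_u5$last_data_year,
                                    global_arr, config)
  tr_imr <- NULL
  if (!is.null(fit_imr)) {
    tr_imr <- as_trajectories(fit_imr, country_id, "IMR")
    tr_imr <- extrapolate_trajectories(tr_imr, fit_imr$last_data_year,
                                       global_arr, config)
    tr_imr <- enforce_ordering(tr_imr, tr_u5)
  }
  nfit <- nmr_fit(obs_nmr, tr_u5, ratio_cfg)
  tr_nmr <- derive_nmr(tr_u5, ratio_trajectory(nfit, tr_u5))
  if (is.null(tr_imr)) {
    ## no infant data: geometric interpolant between NMR and U5MR
    mid <- sqrt(tr_nmr$draws * tr_u5$draws)
    tr_imr <- new_trajectories(country_id, "IMR", tr_u5$years, mid,
                               fitted = tr_u5$fitted)
  }
  tr_imr$draws <- pmax(tr_imr$draws, tr_nmr$draws)   # NMR <= IMR per draw
  list(u5mr = tr_u5, imr = tr_imr, nmr = tr_nmr,
       fits = list(u5mr = fit_u5, imr = fit_imr, nmr = nfit),
       births = births)
}

#' Fit one country end to end
#'
#' Fits U5MR and IMR with the penalized-spline model, extrapolates to the
#' reference year with the blended country/global trend, enforces the
#' NMR <= IMR <= U5MR ordering per draw, fits the neonatal ratio model,
#' and derives the NMR trajectories.
#'
#' @param dataset a flagged [read_dataset()] result.
#' @param country_id country to fit.
#' @param config a [b3_config()].
#' @param ratio_cfg a [ratio_config()].
#' @param global_arr global ARR used in extrapolation (0 for a
#'   single-country run; pass [compute_global_trend()] output for a
#'   multi-country run).
#' @return list with `u5mr`, `imr`, `nmr` trajectories, the `fits`, and
#'   the country's births.
#' @export
fit_country <- function(dataset, country_id, config = b3_config(),
                        ratio_cfg = ratio_config(), global_arr = 0) {
  obs_u5 <- country_observations(dataset, country_id, "U5MR")
  stop_if(nrow(obs_u5) == 0, "no included U5MR observations for ",
          country_id)
  years <- seq(floor(min(obs_u5$ref_year)), config$reference_year)
  fit_u5 <- b3_fit(obs_u5, config, years = years)
  obs_imr <- country_observations(dataset, country_id, "IMR")
  fit_imr <- if (nrow(obs_imr) > 0) b3_fit(obs_imr, config, years = years)
             else NULL
  obs_nmr <- country_observations(dataset, country_id, "NMR")
  births <- dataset$births[dataset$births$country_id == country_id, ]
  assemble_country(fit_u5, fit_imr, obs_nmr, births, country_id, config,
                   ratio_cfg, global_arr)
}

#' Crisis events recorded in a dataset for one country
#'
#' @param dataset a [read_dataset()] result.
#' @param country_id country id.
#' @return list of [crisis_event()] (one event per recorded year).
#' @export
dataset_crisis_events <- function(dataset, country_id) {
  cr <- dataset$crises[dataset$crises$country_id == country_id, ,
                       drop = FALSE]
  lapply(seq_len(nrow(cr)), function(i) {
    r <- cr[i, ]
    u5 <- r$frac_neonatal + r$frac_postneonatal + r$frac_child
    crisis_event(country_id, r$year, r$excess_deaths_total,
                 age_pattern = c(neonatal = r$frac_neonatal,
                                 postneonatal = r$frac_postneonatal,
                                 child = r$frac_child, older = 1 - u5))
  })
}

#' Run the estimation pipeline over a dataset
#'
#' Fits every country, computes the global trend from the first-pass
#' trajectories, re-extrapolates each country with the blended trend
#' (reusing the fitted posteriors), applies recorded crisis events, and
#' returns adjusted trajectories plus births per country.
#'
#' @param dataset a flagged [read_dataset()] result.
#' @param config a [b3_config()].
#' @param ratio_cfg a [ratio_config()].
#' @param apply_crises whether to add recorded crisis events back.
#' @return named list per country of [fit_country()]-shaped results, with
#'   the region map and global trend attached as attributes.
#' @export
run_pipeline <- function(dataset, config = b3_config(),
                         ratio_cfg = ratio_config(), apply_crises = TRUE) {
  ids <- sort(unique(dataset$observations$country_id))
  first <- lapply(ids, function(cid)
    fit_country(dataset, cid, config, ratio_cfg, global_arr = 0))
  names(first) <- ids
  gt <- compute_global_trend(lapply(first, `[[`, "u5mr"),
                             lapply(first, `[[`, "births"), config)
  out <- lapply(ids, function(cid) {
    res <- first[[cid]]
    res <- assemble_country(res$fits$u5mr, res$fits$imr,
                            country_observations(dataset, cid, "NMR"),
                            res$births, cid, config, ratio_cfg,
                            global_arr = gt$arr)
    if (apply_crises) {
      ev <- dataset_crisis_events(dataset, cid)
      if (length(ev) > 0) {
        adj <- apply_crisis_adjustment(res[c("nmr", "imr", "u5mr")], ev,
                                       res$births)
        res[c("nmr", "imr", "u5mr")] <- adj[c("nmr", "imr", "u5mr")]
      }
    }
    res
  })
  names(out) <- ids
  attr(out, "region_map") <- dataset$region_map
  attr(out, "global_trend") <- gt
  out
}
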