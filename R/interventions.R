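COVERAGE_GRID <- c(0.5, 0.8, 0.95)

# Per-protocol effect parameters shared by the catalog. Efficacy and test
# performance are synthetic defaults in the plausible range reported for
# these technologies; screening frequency follows the stated schedules
# (Pap every 3-5 years -> 4-year default; HPV test every 5 years;
# mammography every 2 years; VIA once per decade for ages 30-49).
default_effect_params <- function() {
  list(
    vaccine = list(efficacy = 0.95, age_at = 12L),
    via = list(interval = 10, age_lo = 30L, age_hi = 49L,
               sens_precancer = 0.55, sens_preclinical = 0.60,
               specificity = 0.85, treat_success = 0.90),
    pap = list(interval = 4, age_lo = 30L, age_hi = 49L,
               sens_precancer = 0.55, sens_preclinical = 0.65,
               specificity = 0.95, treat_success = 0.90),
    hpv_test = list(interval = 5, age_lo = 30L, age_hi = 49L,
                    sens_precancer = 0.90, sens_preclinical = 0.80,
                    specificity = 0.90, treat_success = 0.90),
    mammo = list(interval = 2, age_lo = 50L, age_hi = 69L,
                 sens_precancer = 0, sens_preclinical = 0.75,
                 specificity = 0.90, treat_success = 0),
    treatment = list(fatality_multiplier = c(I = 0.25, II = 0.45))
  )
}

effect_vaccination <- function(p) {
  list(type = "vaccination", group = "HPV_16_18", efficacy = p$efficacy,
       age_at = p$age_at, sex = "female")
}

effect_screening <- function(test, p) {
  c(list(type = "screening", test = test, sex = "female"), p)
}

effect_treatment <- function(p) {
  list(type = "treatment", stages = c("I", "II"),
       fatality_multiplier = p$fatality_multiplier)
}

effect_palliative <- function() list(type = "palliative")

#' The fourteen-intervention catalog
#'
#' Nine cervical, three breast and two colorectal cancer interventions:
#' HPV vaccination of 9-13-year-old girls, cervical screening by VIA, Pap
#' smear or HPV test for women 30-49 linked with treatment of
#' pre-cancerous lesions, vaccination-plus-screening combinations,
#' early-stage (I-II) treatment for each cancer, mammography screening for
#' women 50-69 linked with diagnosis and treatment, and basic palliative
#' care. Combination labels expand to the union of their components'
#' effects; screening "linked with treatment" carries the linked
#' technology in its `technologies` set, which the expansion-path
#' optimizer uses for coverage lock-in.
#'
#' @param params effect-size defaults, see source; override for
#'   sensitivity analyses.
#' @return tibble with one row per intervention: `label`, `cancer`,
#'   `description`, `technologies` (list), `effects` (list).
#' @export
build_catalog <- function(params = default_effect_params()) {
  pall_desc <- paste("Basic palliative care for cancer: home-based and",
                     "hospital care with multi-disciplinary team and",
                     "access to opiates and essential supportive medicines")
  vac_desc <- "Vaccination against human papillomavirus (two doses) of 9-13-year-old girls"
  scr_desc <- function(how) {
    sprintf("Prevention of cervical cancer by screening women aged 30-49 through %s linked with timely treatment of pre-cancerous lesions", how)
  }
  row <- function(label, cancer, description, technologies, effects) {
    tibble(label = label, cancer = cancer, description = description,
           technologies = list(technologies), effects = list(effects))
  }
  vac <- effect_vaccination(params$vaccine)
  via <- effect_screening("via", params$via)
  pap <- effect_screening("pap", params$pap)
  hpv <- effect_screening("hpv_test", params$hpv_test)
  treat <- effect_treatment(params$treatment)
  bind_rows(
    row("C1a", "cervical", vac_desc, "cvx_vaccine", list(vac)),
    row("C1b", "cervical", scr_desc("visual inspection with acetic acid"),
        "cvx_screen_via", list(via)),
    row("C1c", "cervical",
        scr_desc("Pap smear (cervical cytology) every 3-5 years"),
        "cvx_screen_pap", list(pap)),
    row("C1d", "cervical",
        scr_desc("human papillomavirus test every 5 years"),
        "cvx_screen_hpv", list(hpv)),
    row("C1e", "cervical",
        paste(vac_desc, "and prevention of cervical cancer by screening",
              "women aged 30-49 through visual inspection with acetic acid",
              "linked with timely treatment of pre-cancerous lesions"),
        c("cvx_vaccine", "cvx_screen_via"), list(vac, via)),
    row("C1f", "cervical",
        paste(vac_desc, "and prevention of cervical cancer by screening",
              "women aged 30-49 through Pap smear every 3-5 years linked",
              "with timely treatment of pre-cancerous lesions"),
        c("cvx_vaccine", "cvx_screen_pap"), list(vac, pap)),
    row("C1g", "cervical",
        paste(vac_desc, "and prevention of cervical cancer by screening",
              "women aged 30-49 through human papillomavirus test every 5",
              "years linked with timely treatment of pre-cancerous lesions"),
        c("cvx_vaccine", "cvx_screen_hpv"), list(vac, hpv)),
    row("C1h", "cervical",
        "Treatment of cervical cancer stages I and II with either surgery or radiotherapy +/- chemotherapy",
        "cvx_treat", list(treat)),
    row("C1i", "cervical", pall_desc, "cvx_palliative",
        list(effect_palliative())),
    row("C2a", "breast",
        "Treatment of breast cancer stages I and II with surgery +/- systemic therapy",
        "brc_treat", list(treat)),
    row("C2b", "breast",
        "Screening with mammography (once every 2 years for women aged 50-69 years) linked with timely diagnosis and treatment of breast cancer",
        c("brc_screen_mammo", "brc_treat"),
        list(effect_screening("mammo", params$mammo), treat)),
    row("C2c", "breast", pall_desc, "brc_palliative",
        list(effect_palliative())),
    row("C3a", "colorectal",
        "Treatment of colorectal cancer stages I and II with surgery +/- chemotherapy and radiotherapy",
        "crc_treat", list(treat)),
    row("C3b", "colorectal", pall_desc, "crc_palliative",
        list(effect_palliative()))
  )
}

#' Intervention scenarios
#'
#' A scenario is a set of catalog labels with coverage levels; the null
#' scenario has no interventions (equivalently, zero coverage everywhere)
#' and leaves rates and disability weights at their pure natural-history
#' values.
#'
#' @param labels catalog labels included.
#' @param coverage a single coverage shared by all labels, or one per
#'   label. Must lie in `{0, 0.5, 0.8, 0.95}` unless `strict = FALSE`.
#' @param region optional region tag.
#' @param strict enforce the standard coverage grid.
#' @return a `gcea_scenario` tibble (`label`, `coverage`) with attributes.
#' @export
scenario <- function(labels, coverage, region = NA_character_,
                     strict = TRUE) {
  coverage <- rep_len(coverage, length(labels))
  if (anyDuplicated(labels)) abort("at most one coverage per label")
  if (strict && !all(coverage %in% c(0, COVERAGE_GRID))) {
    abort("coverage must be one of 0, 0.5, 0.8, 0.95 (use strict = FALSE to override)")
  }
  if (any(coverage < 0 | coverage > 1)) abort("coverage must lie in [0, 1]")
  structure(tibble(label = labels, coverage = coverage),
            region = region, class = c("gcea_scenario", "tbl_df", "tbl",
                                       "data.frame"))
}

#' @rdname scenario
#' @export
null_scenario <- function(region = NA_character_) {
  scenario(character(), numeric(), region = region)
}

scenario_effects <- function(scn, catalog) {
  scn <- scn[scn$coverage > 0, , drop = FALSE]
  if (!nrow(scn)) return(list())
  miss <- setdiff(scn$label, catalog$label)
  if (length(miss)) {
    abort(paste0("unknown intervention label: ", paste(miss, collapse = ", ")))
  }
  purrr::pmap(scn, function(label, coverage) {
    i <- match(label, catalog$label)
    list(label = label, coverage = coverage, cancer = catalog$cancer[i],
         technologies = catalog$technologies[[i]],
         effects = catalog$effects[[i]])
  })
}

#' Apply an intervention scenario to natural-history inputs
#'
#' Translates (intervention, coverage) pairs into the modified transition
#' intensities, effective disability weights and engine-side settings that
#' define the scenario run. Coverage scales linearly: the covered fraction
#' experiences the full per-protocol effect.
#'
#' * Vaccination multiplies the healthy-to-HPV-16/18 hazard of vaccinated
#'   cohorts by `1 - coverage * efficacy` (applied inside the engine, where
#'   cohort eligibility is known); other HPV groups are untouched.
#' * Screening adds `coverage / interval * sensitivity` to the
#'   preclinical-to-clinical diagnosis intensities of the eligible band,
#'   and (for cervical tests) a screen-detect-and-treat regression
#'   intensity from CIN states back to HPV, split across subtype groups by
#'   attribution shares. Test specificity affects costing only, never
#'   state dynamics.
#' * Treatment multiplies the excess-mortality intensity of clinical
#'   stages I-II by `(1 - coverage) + coverage * multiplier`.
#' * Palliative care switches the terminal-state disability weight from
#'   "without medication" to "with medication" for the covered fraction.
#'
#' @param rates `gcea_rates` for one cancer's graph.
#' @param dws disability-weight table for that cancer, from
#'   [disability_weight_table()]: columns `state`, `dw_untreated`,
#'   `dw_treated`.
#' @param scn a `gcea_scenario` (labels may span several cancers; only
#'   effects matching `rates`' graph are applied).
#' @param catalog the intervention catalog.
#' @param hpv_shares attribution of screen-treated CIN regression across
#'   HPV subtype groups (defaults 70/20/10).
#' @return list with `rates` (modified schedule), `dw` (tibble `state`,
#'   `dw`: effective weights), `vaccination` (engine argument or `NULL`),
#'   and `meta` (per-intervention bookkeeping for the resource plan).
#' @export
apply_scenario <- function(rates, dws, scn, catalog = build_catalog(),
                           hpv_shares = c(HPV_16_18 = 0.70,
                                          HPV_high_risk = 0.20,
                                          HPV_low_risk = 0.10)) {
  effs <- scenario_effects(scn, catalog)
  cancer <- rates$graph_cancer
  treat_cov <- 0
  pall_cov <- 0
  vaccination <- NULL
  meta <- list()
  ages_all <- 0:rates$max_age

  for (iv in effs) {
    if (iv$cancer != cancer) next
    for (ef in iv$effects) {
      cov <- iv$coverage
      if (ef$type == "vaccination") {
        if (is.null(vaccination)) {
          vaccination <- list(coverage = cov, efficacy = ef$efficacy,
                              age_at = ef$age_at, sexes = ef$sex)
          meta <- c(meta, list(list(kind = "vaccination", label = iv$label,
                                    coverage = cov, age_at = ef$age_at)))
        }
      } else if (ef$type == "screening") {
        sigma <- cov / ef$interval
        band <- seq(ef$age_lo, min(ef$age_hi, rates$max_age))
        diag_ids <- edge_ids_of_kind(rates, "diagnosis")
        rates$rates[diag_ids, ef$sex, band + 1L] <-
          rates$rates[diag_ids, ef$sex, band + 1L] +
          sigma * ef$sens_preclinical
        if (ef$sens_precancer > 0 && ef$treat_success > 0) {
          for (g in names(hpv_shares)) {
            ids <- edge_ids_of_kind(rates, "regression",
                                    from = c("CIN1", "CIN2_3"), to = g)
            rates$rates[ids, ef$sex, band + 1L] <-
              rates$rates[ids, ef$sex, band + 1L] +
              sigma * ef$sens_precancer * ef$treat_success * hpv_shares[[g]]
          }
        }
        meta <- c(meta, list(c(list(kind = "screening", label = iv$label,
                                    coverage = cov), ef)))
      } else if (ef$type == "treatment") {
        treat_cov <- max(treat_cov, cov)
        for (stg in ef$stages) {
          id <- paste0("clinical_", stg, "->dead")
          m <- ef$fatality_multiplier[[stg]]
          rates$rates[id, , ] <- rates$rates[id, , ] * ((1 - cov) + cov * m)
        }
        meta <- c(meta, list(c(list(kind = "treatment", label = iv$label,
                                    coverage = cov), ef)))
      } else if (ef$type == "palliative") {
        pall_cov <- max(pall_cov, cov)
        meta <- c(meta, list(list(kind = "palliative", label = iv$label,
                                  coverage = cov)))
      }
    }
  }

  dw_eff <- dws %>%
    mutate(dw = case_when(
      .data$state == "clinical_IV" ~
        (1 - pall_cov) * .data$dw_untreated + pall_cov * .data$dw_treated,
      .data$state %in% c("clinical_CIS", "clinical_I", "clinical_II") ~
        (1 - treat_cov) * .data$dw_untreated + treat_cov * .data$dw_treated,
      TRUE ~ .data$dw_untreated
    )) %>%
    select("state", "dw")

  list(rates = rates, dw = dw_eff, vaccination = vaccination, meta = meta,
       treatment_coverage = treat_cov, palliative_coverage = pall_cov)
}

#' Resource-use plan implied by a simulated scenario
#'
#' Enumerates, per programme year, the vaccine doses, screens,
#' false-positive follow-ups, screen-positive diagnostic work-ups,
#' treatment courses, post-treatment surveillance years and palliative
#' episodes implied by the coverage levels and the trajectory.
#'
#' @param traj the `gcea_trajectory` simulated under the scenario.
#' @param applied result of [apply_scenario()] for the same scenario.
#' @return tibble (`component`, `item`, `year`, `quantity`).
#' @export
resource_plan <- function(traj, applied) {
  rows <- list()
  occ <- traj$occupancy
  st <- traj$states
  yrs <- seq_len(traj$horizon)
  occ_states_band <- function(states, sexes, ages) {
    idx <- match(intersect(states, st), st)
    apply(occ[idx, match(sexes, traj$sexes), ages + 1L, , drop = FALSE],
          4, sum)
  }

  for (m in applied$meta) {
    if (m$kind == "vaccination") {
      alive_at <- occ_states_band(st, "female", m$age_at)
      rows <- c(rows, list(tibble(
        component = "vaccination", item = "vaccine_dose", year = yrs,
        quantity = 2 * m$coverage * alive_at)))
    } else if (m$kind == "screening") {
      band <- seq(m$age_lo, min(m$age_hi, traj$max_age))
      sigma <- m$coverage / m$interval
      alive <- occ_states_band(st, m$sex, band)
      detectable <- intersect(
        c("CIN1", "CIN2_3", paste0("preclinical_", STAGE_CHAIN)), st)
      pos <- occ_states_band(detectable, m$sex, band)
      screens <- sigma * alive
      rows <- c(rows, list(
        tibble(component = "screening",
               item = paste0("screen_", m$test), year = yrs,
               quantity = screens),
        tibble(component = "screening", item = "fp_followup", year = yrs,
               quantity = sigma * (alive - pos) * (1 - m$specificity)),
        tibble(component = "screening", item = "diagnostic_workup",
               year = yrs,
               quantity = sigma * pos * m$sens_preclinical)))
    } else if (m$kind == "treatment") {
      diag_ids <- paste0("preclinical_", m$stages, "->clinical_", m$stages)
      e_idx <- match(diag_ids, traj$edge_ids)
      courses <- purrr::map(seq_along(m$stages), function(k) {
        apply(traj$events[e_idx[k], , , , drop = FALSE], 4, sum)
      })
      surv <- occ_states_band(paste0("clinical_", m$stages), traj$sexes,
                              0:traj$max_age)
      rows <- c(rows, purrr::map2(m$stages, courses, function(stg, q) {
        tibble(component = "treatment",
               item = paste0("treatment_course_", stg), year = yrs,
               quantity = m$coverage * q)
      }))
      rows <- c(rows, list(tibble(
        component = "treatment", item = "surveillance_year", year = yrs,
        quantity = m$coverage * surv)))
    } else if (m$kind == "palliative") {
      term <- purrr::map_dbl(yrs, function(t) {
        sum(occ[match("clinical_IV", st), , , t])
      })
      rows <- c(rows, list(tibble(
        component = "palliative", item = "palliative_year", year = yrs,
        quantity = m$coverage * term)))
    }
  }
  if (!length(rows)) {
    return(tibble(component = character(), item = character(),
                  year = integer(), quantity = numeric()))
  }
  bind_rows(rows) %>%
    group_by(.data$component, .data$item, .data$year) %>%
    summarise(quantity = sum(.data$quantity), .groups = "drop")
}
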