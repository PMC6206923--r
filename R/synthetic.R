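# Seeded draws are confined to this module: bundles are generated with a
# local RNG state so the simulation layer itself stays deterministic.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic region profile
#'
#' Everything region-specific the generator needs: GLOBOCAN-like
#' age-specific clinical incidence targets per cancer, the stage
#' distribution at diagnosis, HPV subtype-group attribution (default 70%
#' of cervical cancers to HPV 16/18), a regional price level, and the seed
#' for the profile's synthetic draws. All values are synthetic emulations
#' of the regional inputs such an analysis consumes.
#'
#' @param name region tag.
#' @param incidence tibble (`cancer`, `age_lo`, `age_hi`, `incidence`):
#'   clinical diagnoses per 100,000 of the at-risk population per year.
#' @param stage_distribution tibble (`cancer`, `stage`, `share`); shares
#'   sum to 1 within cancer.
#' @param hpv_shares attribution of cervical disease across subtype
#'   groups; sums to at most 1.
#' @param cost_level regional multiplier on the unit-cost table.
#' @param seed integer seed for the profile's synthetic draws.
#' @return a `gcea_region_profile`.
#' @export
region_profile <- function(name, incidence,
                           stage_distribution = default_stage_distribution(),
                           hpv_shares = c(HPV_16_18 = 0.70,
                                          HPV_high_risk = 0.20,
                                          HPV_low_risk = 0.10),
                           cost_level = 1, seed = 1L) {
  incidence <- as_tibble(incidence)
  stopifnot(all(incidence$incidence >= 0),
            all(incidence$cancer %in% CANCERS))
  sums <- stage_distribution %>%
    group_by(.data$cancer) %>%
    summarise(s = sum(.data$share), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("stage distribution must sum to 1 within each cancer")
  }
  if (sum(hpv_shares) > 1 + 1e-9 || any(hpv_shares < 0)) {
    abort("HPV attribution fractions must be >= 0 and sum to <= 1")
  }
  structure(list(name = name, incidence = incidence,
                 stage_distribution = as_tibble(stage_distribution),
                 hpv_shares = hpv_shares, cost_level = cost_level,
                 seed = as.integer(seed)),
            class = "gcea_region_profile")
}

#' @rdname region_profile
#' @export
default_stage_distribution <- function() {
  tidyr::expand_grid(cancer = CANCERS,
                     stage = c("CIS", "I", "II", "III", "IV")) %>%
    mutate(share = rep(c(0.05, 0.15, 0.30, 0.30, 0.20), times = 3))
}

# Gompertz-Makeham-style background mortality with an infant bump; life
# expectancy in the mid-60s, typical of the modelled settings.
synthetic_demography <- function(total = 1e7, max_age = 100) {
  ages <- 0:max_age
  mu <- 0.002 + 5e-5 * exp(0.082 * ages)
  mu[1] <- 0.04
  mu[2:5] <- 0.004
  mu[6:15] <- 0.0012
  bg <- bind_rows(
    tibble(sex = "female", age_lo = ages, age_hi = ages, rate = mu),
    tibble(sex = "male", age_lo = ages, age_hi = ages, rate = mu * 1.08)
  )
  dem <- demography(births = c(female = 100, male = 102), bg_mort = bg,
                    max_age = max_age)
  standardize_population(dem, total)
}

subset_demography <- function(dem, sexes) {
  demography(births = dem$births[sexes],
             bg_mort = purrr::map_dfr(sexes, function(s) {
               tibble(sex = s, age_lo = 0:dem$max_age,
                      age_hi = 0:dem$max_age, rate = dem$bg[s, ])
             }),
             sexes = sexes, max_age = dem$max_age)
}

# Natural progression/regression rates: cancer-specific, shared across
# regions. Onset edges are left at zero here and set by calibration.
cervical_base_rates <- function(graph, hpv_shares, max_age = 100) {
  all_ages <- function(from, to, sex, rate) {
    tibble(from = from, to = to, sex = sex, age_lo = 0, age_hi = max_age,
           rate = rate)
  }
  g <- names(hpv_shares)
  entries <- bind_rows(
    all_ages(g, "CIN1", "female", c(0.10, 0.05, 0.01)),
    all_ages("CIN1", "CIN2_3", "female", 0.10),
    all_ages("CIN2_3", "preclinical_CIS", "female", 0.06),
    all_ages("CIN2_3", "CIN1", "female", 0.15),
    all_ages("CIN1", g, "female", 0.35 * unname(hpv_shares)),
    all_ages("CIN2_3", g, "female", 0.05 * unname(hpv_shares)),
    all_ages(g, "immune", "both", c(0.35, 0.45, 0.55)),
    all_ages("immune", "healthy", "both", 1.0),
    stage_rate_entries("female",
                       progression = c(0.30, 0.40, 0.50, 0.60),
                       diagnosis = c(0.02, 0.08, 0.25, 0.60, 1.0),
                       fatality = c(0.01, 0.06, 0.15, 0.35, 0.70))
  )
  rate_schedule(graph, entries, sexes = c("female", "male"),
                max_age = max_age)
}

# Undiagnosed (preclinical) disease advances quickly through the stage
# chain; once diagnosed, the stage largely sticks (slow residual clinical
# progression) and prognosis is carried by stage-specific excess
# mortality. This keeps stage at diagnosis prognostic, which is what
# early-stage treatment and screening act on.
stage_rate_entries <- function(sex, progression, diagnosis, fatality,
                               clinical_progression = 0.05,
                               max_age = 100) {
  pre <- paste0("preclinical_", STAGE_CHAIN)
  cli <- paste0("clinical_", STAGE_CHAIN)
  bind_rows(
    tibble(from = pre[-5], to = pre[-1], sex = sex, age_lo = 0,
           age_hi = max_age, rate = progression),
    tibble(from = cli[-5], to = cli[-1], sex = sex, age_lo = 0,
           age_hi = max_age, rate = clinical_progression),
    tibble(from = pre, to = cli, sex = sex, age_lo = 0, age_hi = max_age,
           rate = diagnosis),
    tibble(from = pre, to = "dead", sex = sex, age_lo = 0,
           age_hi = max_age, rate = fatality),
    tibble(from = cli, to = "dead", sex = sex, age_lo = 0,
           age_hi = max_age, rate = fatality)
  )
}

breast_base_rates <- function(graph, max_age = 100) {
  rate_schedule(graph, stage_rate_entries(
    "female",
    progression = c(0.35, 0.45, 0.50, 0.55),
    diagnosis = c(0.03, 0.12, 0.30, 0.65, 1.0),
    fatality = c(0.005, 0.05, 0.12, 0.30, 0.60)
  ), sexes = "female", max_age = max_age)
}

colorectal_base_rates <- function(graph, max_age = 100) {
  polyp <- bind_rows(
    tibble(from = c("polyp_small", "polyp_medium", "polyp_large"),
           to = c("polyp_medium", "polyp_large", "preclinical_CIS"),
           sex = "both", age_lo = 0, age_hi = max_age,
           rate = c(0.12, 0.15, 0.06)),
    tibble(from = c("polyp_small", "polyp_medium"),
           to = c("healthy", "polyp_small"), sex = "both", age_lo = 0,
           age_hi = max_age, rate = c(0.30, 0.20))
  )
  rate_schedule(graph, bind_rows(
    polyp,
    stage_rate_entries("both",
                       progression = c(0.30, 0.40, 0.45, 0.55),
                       diagnosis = c(0.02, 0.10, 0.28, 0.60, 1.0),
                       fatality = c(0.005, 0.05, 0.13, 0.35, 0.65))
  ), sexes = c("female", "male"), max_age = max_age)
}

cancer_targets <- function(profile, cancer) {
  profile$incidence %>%
    filter(.data$cancer == !!cancer) %>%
    select("age_lo", "age_hi", "incidence")
}

#' Shared HPV transmission defaults
#'
#' Fixed, comfortably supercritical two-sex transmission parameters used
#' for every region: partner-change rates concentrated in ages 15-49,
#' per-partnership transmission probabilities and per-group clearance
#' giving endemic prevalence of a few percent per subtype group among
#' sexually active ages, and one-year mean duration of post-clearance
#' immunity. Keeping the contact process well above the epidemic
#' threshold makes the endemic state numerically stable; region-specific
#' cervical incidence is then calibrated through the HPV-to-CIN
#' progression intensities rather than by perturbing the infection
#' process itself.
#'
#' @return a `gcea_transmission`.
#' @export
default_cervical_transmission <- function() {
  partner <- tibble::tribble(
    ~sex,   ~age_lo, ~age_hi, ~rate,
    "both",       0,      14,   0,
    "both",      15,      19,   1.0,
    "both",      20,      29,   1.5,
    "both",      30,      39,   1.0,
    "both",      40,      49,   0.6,
    "both",      50,     100,   0.2
  )
  transmission_params(
    beta = c(HPV_16_18 = 0.70, HPV_high_risk = 0.95, HPV_low_risk = 1.10),
    partner_rate = partner,
    clearance = c(HPV_16_18 = 0.35, HPV_high_risk = 0.45,
                  HPV_low_risk = 0.55),
    immunity_waning = 1.0)
}

# Stationary all-healthy population with a small infected seed in the
# sexually active ages, for transmission burn-in.
seeded_hpv_init <- function(graph, dem, frac = 0.02, ages = 15:49) {
  n_s <- nrow(graph$states)
  hpv_i <- match(HPV_GROUPS, graph$states$name)
  pop <- stationary_population(dem)
  O <- array(0, dim = c(n_s, length(dem$sexes), dem$max_age + 1L))
  O[1, , ] <- matrix(pop$population, length(dem$sexes), dem$max_age + 1L,
                     byrow = TRUE)
  for (k in hpv_i) O[k, , ages + 1L] <- frac * O[1, , ages + 1L]
  O[1, , ages + 1L] <- O[1, , ages + 1L] * (1 - frac * length(hpv_i))
  O
}

#' Generate a complete region parameter bundle
#'
#' Produces everything a region's pipeline run needs, deterministically
#' given the profile's seed: standardized demography (10 million alive at
#' baseline), natural-history rate schedules for all three cancers with
#' onset intensities calibrated against the profile's incidence targets
#' ([calibrate_onset_rates()]), a fitted HPV transmission model whose
#' endemic equilibrium reproduces the calibrated cervical onset hazards
#' (with the equilibrium occupancy stored as the cervical initial state),
#' synthetic GBD-style disability-weight inputs, and regional costing
#' parameters.
#'
#' @param profile a `gcea_region_profile`.
#' @param max_age oldest modelled age.
#' @return a `gcea_bundle` list; `bundle$cancers[[cancer]]` holds `graph`,
#'   `rates`, `dem`, and for cervical also `transmission` and `init`.
#' @export
generate_region_params <- function(profile, max_age = 100) {
  stopifnot(inherits(profile, "gcea_region_profile"))
  dem <- synthetic_demography(1e7, max_age)
  dem_f <- subset_demography(dem, "female")

  gbd <- with_local_seed(profile$seed, gbd_dw_inputs(
    dw_diagnosis = stats::runif(1, 0.26, 0.32),
    dw_metastatic = stats::runif(1, 0.45, 0.52),
    dw_terminal_with_med = stats::runif(1, 0.48, 0.53),
    dw_terminal_without_med = stats::runif(1, 0.53, 0.57),
    dw_mastectomy = stats::runif(1, 0.03, 0.05),
    dw_stoma = stats::runif(1, 0.07, 0.10)
  ))
  dw_config <- list(frac_first_year = 0.3, frac_stoma = 0.05,
                    diag_weight_breast = 0.5)
  costing <- costing_params(cost_level = profile$cost_level)

  # breast: female-only static calibration; initial occupancy stored at
  # the calibrated equilibrium so scenario runs start from the standing
  # epidemiology rather than a disease-free population
  g_b <- build_breast_graph()
  r_b <- calibrate_onset_rates(g_b, breast_base_rates(g_b, max_age), dem_f,
                               cancer_targets(profile, "breast"))
  init_b <- simulate_cohort(g_b, r_b, dem_f, horizon = 80)$final_occupancy

  # colorectal: seed the two onset routes at the configured mass split,
  # then calibrate (uniform per-band scaling preserves the split)
  g_c <- build_colorectal_graph()
  r_c <- colorectal_base_rates(g_c, max_age)
  crc_t <- cancer_targets(profile, "colorectal")
  for (b in seq_len(nrow(crc_t))) {
    if (crc_t$incidence[b] > 0) {
      ages <- seq(crc_t$age_lo[b], min(max_age, crc_t$age_hi[b])) + 1L
      s <- crc_t$incidence[b] / 1e5
      r_c$rates["healthy->polyp_small", , ages] <- g_c$route_split[1] * s
      r_c$rates["healthy->preclinical_CIS", , ages] <- g_c$route_split[2] * s
    }
  }
  r_c <- calibrate_onset_rates(g_c, r_c, dem, crc_t)
  init_c <- simulate_cohort(g_c, r_c, dem, horizon = 80)$final_occupancy

  # cervical: fixed transmission burned in to its endemic state, then the
  # HPV->CIN1 progression intensities calibrated against the incidence
  # targets with the dynamic infection model in the loop
  g_v <- build_cervical_graph()
  r_v <- cervical_base_rates(g_v, profile$hpv_shares, max_age)
  cvx_t <- cancer_targets(profile, "cervical")
  tp <- default_cervical_transmission()
  burn <- simulate_cohort(g_v, r_v, dem, horizon = 150, transmission = tp,
                          init = seeded_hpv_init(g_v, dem))
  prog_edges <- paste(HPV_GROUPS, "CIN1", sep = "->")
  # coarse pass from the burn-in, then a pass whose measurement window
  # (years 111-130 from the settled state) coincides exactly with years
  # 11-30 after the stored initial occupancy, so the stationary incidence
  # seen by downstream runs is the calibrated one
  r_v <- calibrate_onset_rates(g_v, r_v, dem, cvx_t, onset_lag = 12,
                               edges = prog_edges, transmission = tp,
                               init = burn$final_occupancy,
                               incidence_sexes = "female",
                               settle = 50, measure = 20)
  init2 <- simulate_cohort(g_v, r_v, dem, horizon = 100,
                           transmission = tp,
                           init = burn$final_occupancy)$final_occupancy
  r_v <- calibrate_onset_rates(g_v, r_v, dem, cvx_t, onset_lag = 12,
                               edges = prog_edges, transmission = tp,
                               init = init2, incidence_sexes = "female",
                               settle = 110, measure = 20)
  init_v <- simulate_cohort(g_v, r_v, dem, horizon = 100,
                            transmission = tp,
                            init = init2)$final_occupancy

  structure(list(
    profile = profile, demography = dem,
    cancers = list(
      cervical = list(graph = g_v, rates = r_v, dem = dem,
                      transmission = tp, init = init_v),
      breast = list(graph = g_b, rates = r_b, dem = dem_f,
                    init = init_b),
      colorectal = list(graph = g_c, rates = r_c, dem = dem,
                        init = init_c)
    ),
    gbd = gbd, dw_config = dw_config, costing = costing,
    hpv_shares = profile$hpv_shares
  ), class = "gcea_bundle")
}

#' Two-region demonstration profiles
#'
#' A Southeast-Asia-like profile (moderate cervical incidence, higher
#' price level) and an eastern-sub-Saharan-Africa-like profile (high
#' cervical incidence, lower price level). Seeds are fixed so the
#' end-to-end demo is reproducible.
#'
#' @return named list of two `gcea_region_profile`s.
#' @export
make_two_region_demo <- function() {
  inc <- function(cancer, bands) {
    purrr::pmap_dfr(bands, function(age_lo, age_hi, incidence) {
      tibble(cancer = cancer, age_lo = age_lo, age_hi = age_hi,
             incidence = incidence)
    })
  }
  bands <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(age_lo = m[, 1], age_hi = m[, 2], incidence = m[, 3])
  }
  sea <- region_profile(
    "SEA-like",
    bind_rows(
      inc("cervical", bands(30, 44, 14, 45, 59, 28, 60, 74, 26, 75, 100, 14)),
      inc("breast", bands(30, 44, 22, 45, 59, 48, 60, 74, 52, 75, 100, 40)),
      inc("colorectal", bands(40, 59, 10, 60, 74, 22, 75, 100, 28))
    ),
    cost_level = 1.0, seed = 101L)
  essa <- region_profile(
    "ESSA-like",
    bind_rows(
      inc("cervical", bands(30, 44, 35, 45, 59, 70, 60, 74, 60, 75, 100, 30)),
      inc("breast", bands(30, 44, 18, 45, 59, 38, 60, 74, 40, 75, 100, 32)),
      inc("colorectal", bands(40, 59, 5, 60, 74, 12, 75, 100, 16))
    ),
    cost_level = 0.85, seed = 202L)
  list("SEA-like" = sea, "ESSA-like" = essa)
}

#' Published reference league tables (fixtures)
#'
#' Machine-readable copies of the published WHO-CHOICE league tables and
#' budget-allocation totals for Southeast Asia and eastern sub-Saharan
#' Africa (2010 I$ per 10 million population), packaged for
#' arithmetic-consistency tests of the CEA layer: recomputing ACERs,
#' ICERs, programme ratios and budget shares from the printed cost and
#' HLY columns.
#'
#' @return list of tibbles: `sea` and `essa` (label, coverage, cost in
#'   million I$, undiscounted HLY, printed ACER and ICER) and `budget`
#'   (per-cancer and total discounted costs in I$, HLY totals, programme
#'   ACERs, printed shares).
#' @export
fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "gcea",
                                  mustWork = TRUE)
  read <- function(f) {
    as_tibble(utils::read.csv(path(f), stringsAsFactors = FALSE)) %>%
      mutate(dplyr::across(dplyr::where(is.numeric), as.numeric))
  }
  list(sea = read("league_table_sea.csv"),
       essa = read("league_table_essa.csv"),
       budget = read("budget_allocation.csv"))
}
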