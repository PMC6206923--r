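#' Parameters of the two-sex HPV transmission sub-model
#'
#' A frequency-dependent, age-structured SIS-with-immunity formulation:
#' susceptibles acquire HPV of subtype group `g` at hazard
#' `partner_rate(sex, age) * sum_a' mixing(age, a') * beta_g *
#' prevalence(other_sex, a', g)`, clear infection at a per-group clearance
#' rate into a short-term immune state, and return to healthy as immunity
#' wanes. Clearance and waning intensities are carried on the
#' corresponding graph edges of the rate schedule; this object supplies
#' the force-of-infection ingredients.
#'
#' @param beta named per-partnership transmission probabilities per year,
#'   one per subtype group (`HPV_16_18`, `HPV_high_risk`, `HPV_low_risk`).
#' @param partner_rate tibble (`sex`, `age_lo`, `age_hi`, `rate`): mean new
#'   partners per year.
#' @param clearance named per-year natural clearance rates by group.
#' @param immunity_waning per-year immune-to-healthy rate.
#' @param mixing optional row-normalized age-mixing kernel (square matrix,
#'   rows = own age, columns = partner age). When `NULL` the engine uses
#'   proportionate mixing: partner ages weighted by opposite-sex partner
#'   supply (partner rate times stationary population).
#' @return a `gcea_transmission` object.
#' @export
transmission_params <- function(beta, partner_rate, clearance,
                                immunity_waning = 1, mixing = NULL) {
  stopifnot(all(HPV_GROUPS %in% names(beta)),
            all(HPV_GROUPS %in% names(clearance)))
  if (any(beta < 0) || any(clearance < 0) || immunity_waning < 0 ||
      any(partner_rate$rate < 0)) {
    abort("transmission parameters must be >= 0")
  }
  if (!is.null(mixing)) {
    if (any(abs(rowSums(mixing) - 1) > 1e-9)) {
      abort("mixing kernel rows must sum to 1")
    }
  }
  structure(list(beta = beta[HPV_GROUPS],
                 partner_rate = as_tibble(partner_rate),
                 clearance = clearance[HPV_GROUPS],
                 immunity_waning = immunity_waning, mixing = mixing),
            class = "gcea_transmission")
}

expand_partner_rate <- function(partner_rate, sexes, max_age) {
  out <- matrix(0, length(sexes), max_age + 1L,
                dimnames = list(sexes, 0:max_age))
  for (i in seq_len(nrow(partner_rate))) {
    e <- partner_rate[i, ]
    sx <- if (e$sex == "both") sexes else e$sex
    out[sx, seq(max(0L, e$age_lo), min(max_age, e$age_hi)) + 1L] <- e$rate
  }
  out
}

#' Per-year HPV infection hazard from a prevalence field
#'
#' The force of infection on susceptibles of one sex and age:
#' `hazard(g) = partner_rate(sex, age) * sum_a' mixing(age, a') * beta_g *
#' prevalence(other_sex, a', g)`. Zero whenever opposite-sex prevalence is
#' zero. With `mixing = NULL` partner ages are weighted uniformly across
#' the ages present in `prev` (the cohort engine itself uses proportionate
#' weights from the stationary population).
#'
#' @param prev prevalence field: tibble (`sex`, `age`, `group`,
#'   `prevalence`), entries in `[0, 1]`.
#' @param params a `gcea_transmission`.
#' @param sex,age the susceptible stratum to evaluate.
#' @return named per-year hazard per subtype group.
#' @export
#' @examples
#' pr <- tidyr::expand_grid(sex = c("female", "male"), age = 20,
#'                          group = c("HPV_16_18", "HPV_high_risk",
#'                                    "HPV_low_risk"))
#' pr$prevalence <- 0.1
#' tp <- transmission_params(
#'   beta = c(HPV_16_18 = 0.8, HPV_high_risk = 0.6, HPV_low_risk = 0.5),
#'   partner_rate = tibble::tibble(sex = "both", age_lo = 0, age_hi = 100,
#'                                 rate = 1),
#'   clearance = c(HPV_16_18 = 0.3, HPV_high_risk = 0.4,
#'                 HPV_low_risk = 0.5))
#' force_of_infection(pr, tp, "female", 20) # 1 * beta * 0.1 per group
force_of_infection <- function(prev, params, sex, age) {
  stopifnot(inherits(params, "gcea_transmission"))
  if (any(prev$prevalence < 0 | prev$prevalence > 1)) {
    abort("prevalence entries must lie in [0, 1]")
  }
  other <- setdiff(c("female", "male"), sex)
  opp <- prev %>% filter(.data$sex == other) %>% arrange(.data$age)
  ages <- sort(unique(opp$age))
  w <- if (is.null(params$mixing)) {
    rep(1 / length(ages), length(ages))
  } else {
    params$mixing[match(age, ages), ]
  }
  c_rate <- expand_partner_rate(params$partner_rate, c("female", "male"),
                                max(c(prev$age, age)))[sex, age + 1L]
  purrr::map_dbl(stats::setNames(HPV_GROUPS, HPV_GROUPS), function(g) {
    pg <- opp %>% filter(.data$group == g)
    p <- pg$prevalence[match(ages, pg$age)]
    p[is.na(p)] <- 0
    c_rate * params$beta[[g]] * sum(w * p)
  })
}

#' @describeIn force_of_infection per-cycle infection probabilities
#'   `1 - exp(-hazard * dt)` for every (sex, age) stratum of the
#'   prevalence field; this is the update the cohort engine applies to the
#'   healthy-to-HPV transition each cycle.
#' @param dt cycle length in years.
#' @export
step_infection <- function(prev, params, dt = 1) {
  stopifnot(dt > 0)
  strata <- prev %>% distinct(.data$sex, .data$age)
  purrr::pmap_dfr(strata, function(sex, age) {
    h <- force_of_infection(prev, params, sex, age)
    tibble(sex = sex, age = age, group = names(h), hazard = unname(h),
           probability = probability_from_rate(unname(h), dt))
  })
}

# Engine-facing context: precomputes indices and proportionate-mixing
# weights once per simulation; an environment so the per-cycle overall
# prevalence can be recorded in place.
transmission_context <- function(params, graph, rates, dem) {
  stopifnot(inherits(params, "gcea_transmission"))
  if (!all(c("female", "male") %in% dem$sexes)) {
    abort("the transmission sub-model needs both sexes in the demography")
  }
  st <- graph$states$name
  onset_edge_idx <- match(paste("healthy", HPV_GROUPS, sep = "->"),
                          rates$edge_ids)
  if (any(is.na(onset_edge_idx))) {
    abort("graph lacks healthy->HPV onset edges; transmission not applicable")
  }
  ctx <- new.env(parent = emptyenv())
  ctx$beta <- unlist(params$beta)
  ctx$onset_edge_idx <- onset_edge_idx
  ctx$hpv_idx <- match(HPV_GROUPS, st)
  ctx$sexes <- dem$sexes
  ctx$n_a <- dem$max_age + 1L
  ctx$partner <- expand_partner_rate(params$partner_rate, dem$sexes,
                                     dem$max_age)
  pop <- stationary_population(dem)
  N <- matrix(pop$population, length(dem$sexes), ctx$n_a, byrow = TRUE,
              dimnames = list(dem$sexes, NULL))
  if (is.null(params$mixing)) {
    w <- ctx$partner * N # partner supply by sex and age
    ctx$weights <- sweep(w, 1, rowSums(w), "/")
    ctx$mixing <- NULL
  } else {
    stopifnot(identical(dim(params$mixing), c(ctx$n_a, ctx$n_a)))
    ctx$mixing <- params$mixing
  }
  ctx$last_prev_overall <- matrix(0, length(HPV_GROUPS), length(dem$sexes),
                                  dimnames = list(HPV_GROUPS, dem$sexes))
  ctx$popN <- N
  ctx
}

# Hazards [group, sex, age] given current occupancy [state, sex, age].
transmission_foi <- function(ctx, O) {
  alive <- apply(O, c(2, 3), sum)
  prev <- O[ctx$hpv_idx, , , drop = FALSE]
  for (g in seq_along(ctx$hpv_idx)) {
    prev[g, , ] <- ifelse(alive > 0, prev[g, , ] / alive, 0)
  }
  n_sex <- length(ctx$sexes)
  foi <- array(0, dim = c(length(ctx$hpv_idx), n_sex, ctx$n_a))
  for (s in seq_len(n_sex)) {
    o <- if (ctx$sexes[s] == "female") match("male", ctx$sexes) else
      match("female", ctx$sexes)
    for (g in seq_along(ctx$hpv_idx)) {
      p_opp <- prev[g, o, ]
      mean_p <- if (is.null(ctx$mixing)) {
        sum(ctx$weights[o, ] * p_opp) # scalar: proportionate mixing
      } else {
        as.vector(ctx$mixing %*% p_opp)
      }
      foi[g, s, ] <- ctx$partner[s, ] * ctx$beta[g] * mean_p
      ctx$last_prev_overall[g, s] <-
        sum(prev[g, s, ] * alive[s, ]) / sum(alive[s, ])
    }
  }
  foi
}
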