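#' Convert an annual intensity to a per-cycle transition probability
#'
#' Uses the exponential conversion `1 - exp(-rate * dt)`. Within a cycle,
#' competing risks are resolved proportionally to their intensities; see
#' [competing_probabilities()].
#'
#' @param rate annual transition intensity (per person-year), vectorized.
#' @param dt cycle length in years.
#' @return per-cycle probability in `[0, 1)`.
#' @export
#' @examples
#' probability_from_rate(log(2), 1) # 0.5: half-life identity
probability_from_rate <- function(rate, dt = 1) {
  if (any(rate < 0)) abort("transition intensity must be >= 0")
  if (any(dt <= 0)) abort("cycle length dt must be > 0")
  -expm1(-rate * dt)
}

#' @describeIn probability_from_rate per-cause exit probabilities for
#'   several competing intensities acting on one state: total exit
#'   probability `1 - exp(-sum(rates) * dt)`, split across causes in
#'   proportion to their intensities.
#' @param rates numeric vector of competing intensities.
#' @export
competing_probabilities <- function(rates, dt = 1) {
  if (any(rates < 0)) abort("transition intensity must be >= 0")
  total <- sum(rates)
  if (total == 0) return(rep(0, length(rates)))
  probability_from_rate(total, dt) * rates / total
}

#' Deterministic annual-cycle cohort simulation
#'
#' Simulates an open population over `horizon` annual cycles on a
#' natural-history state graph. Each year, per-state exit intensities
#' (graph-edge rates plus background mortality, which applies in every
#' state) are converted to probabilities by exponential conversion with
#' proportional competing-risk allocation; occupants transition, everyone
#' ages one year (survivors past the maximum age exit and are counted as
#' deaths), and a new birth cohort enters the healthy state. Person-years
#' for a cycle are the state occupancy at the start of the cycle (no
#' half-cycle correction). The engine contains no randomness: identical
#' inputs give bit-identical trajectories.
#'
#' When `transmission` is supplied, the healthy-to-HPV onset intensities
#' are recomputed every cycle from the current opposite-sex HPV prevalence
#' (see [transmission_params()]), so prevalence and incidence co-evolve.
#' `vaccination` applies a susceptibility multiplier `1 - coverage *
#' efficacy` on the HPV 16/18 infection hazard of cohorts vaccinated at
#' `age_at` from programme start onwards (no catch-up cohorts).
#'
#' @param graph a validated `gcea_graph`.
#' @param rates a `gcea_rates` schedule for the graph.
#' @param dem a `gcea_demography`.
#' @param horizon number of annual cycles (programme years), >= 1.
#' @param transmission optional `gcea_transmission` parameters (cervical
#'   model only).
#' @param vaccination optional list with `coverage`, `efficacy`, and
#'   optionally `age_at` (default 12) and `sexes` (default `"female"`).
#' @param init optional initial occupancy array `[state, sex, age]`;
#'   default places the stationary population in the healthy state.
#' @return a `gcea_trajectory`: occupancy and edge-flow ("event") arrays by
#'   sex, age and year, deaths by year, and (with transmission) the HPV
#'   prevalence trajectory.
#' @export
simulate_cohort <- function(graph, rates, dem, horizon,
                            transmission = NULL, vaccination = NULL,
                            init = NULL) {
  viol <- validate_graph(graph)
  if (length(viol)) abort(c("invalid state graph", viol))
  stopifnot(horizon >= 1, identical(rates$max_age, dem$max_age))
  if (!identical(rates$sexes, dem$sexes)) {
    abort("rate schedule and demography must model the same sexes (see subset_rates())")
  }

  st <- graph$states$name
  n_s <- length(st)
  sexes <- dem$sexes
  n_sex <- length(sexes)
  n_a <- dem$max_age + 1L
  n_cell <- n_sex * n_a
  dead <- st[graph$states$category == "dead"]
  i_dead <- match(dead, st)
  i_healthy <- match("healthy", st)
  edges <- graph$edges
  n_e <- nrow(edges)
  e_from <- match(edges$from, st)
  e_to <- match(edges$to, st)

  # incidence matrices state x edge
  M_from <- matrix(0, n_s, n_e)
  M_from[cbind(e_from, seq_len(n_e))] <- 1
  M_to <- matrix(0, n_s, n_e)
  alive_target <- e_to != i_dead
  M_to[cbind(e_to[alive_target], which(alive_target))] <- 1

  R_base <- matrix(rates$rates, n_e, n_cell) # edge x (sex, age)
  bg <- as.vector(dem$bg) # (sex, age)

  if (is.null(init)) {
    pop <- stationary_population(dem)
    O <- array(0, dim = c(n_s, n_sex, n_a))
    O[i_healthy, , ] <- matrix(pop$population, n_sex, n_a, byrow = TRUE)
  } else {
    stopifnot(identical(as.integer(dim(init)),
                        as.integer(c(n_s, n_sex, n_a))))
    O <- init
  }
  init_total <- sum(O)

  tr_ctx <- if (!is.null(transmission)) {
    transmission_context(transmission, graph, rates, dem)
  }
  vax <- if (!is.null(vaccination)) {
    v <- vaccination
    v$age_at <- v$age_at %||% 12L
    v$sexes <- v$sexes %||% "female"
    v$edge <- which(edges$from == "healthy" & edges$to == "HPV_16_18")
    stopifnot(length(v$edge) == 1, v$coverage >= 0, v$coverage <= 1,
              v$efficacy >= 0, v$efficacy <= 1)
    v
  }

  occupancy <- array(0, dim = c(n_s, n_sex, n_a, horizon),
                     dimnames = list(st, sexes, 0:dem$max_age, NULL))
  events <- array(0, dim = c(n_e, n_sex, n_a, horizon))
  deaths <- numeric(horizon)
  births_in <- numeric(horizon)
  prev_traj <- if (!is.null(tr_ctx)) {
    array(0, dim = c(length(HPV_GROUPS), n_sex, horizon),
          dimnames = list(HPV_GROUPS, sexes, NULL))
  }

  for (t in seq_len(horizon)) {
    R_t <- R_base
    if (!is.null(tr_ctx)) {
      foi <- transmission_foi(tr_ctx, O) # [group, sex, age] hazard
      R_t[tr_ctx$onset_edge_idx, ] <- matrix(foi, length(tr_ctx$onset_edge_idx),
                                             n_cell)
      prev_traj[, , t] <- tr_ctx$last_prev_overall
    }
    if (!is.null(vax)) {
      protected_ages <- seq.int(vax$age_at,
                                min(dem$max_age, vax$age_at + t - 1L))
      s_idx <- match(vax$sexes, sexes)
      s_idx <- s_idx[!is.na(s_idx)]
      if (length(s_idx) && length(protected_ages)) {
        cells <- as.vector(outer(s_idx, protected_ages * n_sex, `+`))
        R_t[vax$edge, cells] <- R_t[vax$edge, cells] *
          (1 - vax$coverage * vax$efficacy)
      }
    }

    occupancy[, , , t] <- O

    O_mat <- matrix(O, n_s, n_cell)
    R_tot <- M_from %*% R_t + rep(bg, each = n_s) # state x cell
    if (any(R_tot < 0)) abort("negative total exit intensity (parameter pathology)")
    p_exit <- -expm1(-R_tot)
    frac <- ifelse(R_tot > 0, p_exit / R_tot, 0)
    W <- O_mat * frac # person-weight per unit intensity
    flows <- R_t * W[e_from, , drop = FALSE] # edge x cell
    bg_dead <- colSums(W) * bg # per cell
    events[, , , t] <- flows

    O_new <- O_mat - M_from %*% flows + M_to %*% flows
    O_new[i_dead, ] <- 0
    dead_flow <- sum(flows[e_to == i_dead, ]) + sum(bg_dead)
    # background deaths leave from every state proportionally
    O_new <- O_new - matrix(W * rep(bg, each = n_s), n_s, n_cell)

    O <- array(O_new, dim = c(n_s, n_sex, n_a))
    aged_out <- sum(O[, , n_a])
    O[, , 2:n_a] <- O[, , 1:(n_a - 1)]
    O[, , 1] <- 0
    O[i_healthy, , 1] <- dem$births
    births_in[t] <- sum(dem$births)
    deaths[t] <- dead_flow + aged_out
  }

  structure(list(
    graph = graph, sexes = sexes, max_age = dem$max_age, horizon = horizon,
    states = st, edge_ids = rates$edge_ids, edges = edges,
    occupancy = occupancy, events = events, deaths = deaths,
    births = births_in, init_total = init_total,
    final_occupancy = O, prevalence = prev_traj
  ), class = "gcea_trajectory")
}

#' @export
print.gcea_trajectory <- function(x, ...) {
  cat(sprintf(
    "<gcea_trajectory: %s> %d states, %d year(s), %s person-years\n",
    x$graph$cancer, length(x$states), x$horizon,
    format(sum(x$occupancy), big.mark = ",")))
  invisible(x)
}

#' Tidy views of a trajectory
#'
#' `as_tibble()` returns person-years by state, sex, age and year;
#' `trajectory_events()` the counted flows (diagnoses, deaths, ...) by
#' edge, sex, age and year; `prevalence_trajectory()` the HPV prevalence
#' path recorded when the transmission sub-model is active.
#'
#' @param x,traj a `gcea_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @method as_tibble gcea_trajectory
#' @export
as_tibble.gcea_trajectory <- function(x, ...) {
  grid <- tidyr::expand_grid(year = seq_len(x$horizon), age = 0:x$max_age,
                             sex = x$sexes, state = x$states)
  grid$person_years <- as.vector(x$occupancy)
  grid[, c("state", "sex", "age", "year", "person_years")]
}

#' @rdname as_tibble.gcea_trajectory
#' @export
trajectory_events <- function(traj) {
  grid <- tidyr::expand_grid(year = seq_len(traj$horizon),
                             age = 0:traj$max_age, sex = traj$sexes,
                             edge = traj$edge_ids)
  grid$kind <- traj$edges$kind[match(grid$edge, traj$edge_ids)]
  grid$count <- as.vector(traj$events)
  tidyr::separate_wider_delim(grid, "edge", "->",
                              names = c("from", "to"), cols_remove = FALSE)
}

#' @rdname as_tibble.gcea_trajectory
#' @export
prevalence_trajectory <- function(traj) {
  if (is.null(traj$prevalence)) {
    abort("trajectory was simulated without the transmission sub-model")
  }
  grid <- tidyr::expand_grid(year = seq_len(traj$horizon), sex = traj$sexes,
                             group = HPV_GROUPS)
  grid$prevalence <- as.vector(traj$prevalence)
  grid
}

#' Population-conservation error of a trajectory
#'
#' Every year, entrants (initial occupants plus cumulative births) must
#' equal current occupants plus cumulative deaths. Returns the maximum
#' relative discrepancy over the horizon; the engine keeps it at numerical
#' rounding level.
#'
#' @param traj a `gcea_trajectory`.
#' @return maximum relative conservation error (scalar).
#' @export
conservation_error <- function(traj) {
  alive <- apply(traj$occupancy, 4, sum)
  entrants <- traj$init_total + dplyr::lag(cumsum(traj$births), default = 0)
  accounted <- alive + dplyr::lag(cumsum(traj$deaths), default = 0)
  max(abs(entrants - accounted) / entrants)
}

total_person_years <- function(traj) sum(traj$occupancy)

# occupancy [state, sex, age] summed over states that hold living persons
alive_by_cell <- function(O) apply(O, c(2, 3), sum)
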