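#' Build an age- and sex-specific transition rate schedule
#'
#' A rate schedule attaches an annual transition intensity (per person-year)
#' to every edge of a state graph, for every modelled sex and single-year
#' age 0..`max_age`. Entries are supplied in coarse age bands and expanded
#' by step interpolation; edges not mentioned get intensity 0. Rates live
#' here rather than on graph edges so the same graph serves every region
#' and the null scenario.
#'
#' @param graph a `gcea_graph`.
#' @param entries tibble with columns `from`, `to`, `sex` (`"female"`,
#'   `"male"` or `"both"`), `age_lo`, `age_hi` (inclusive), `rate`.
#' @param sexes sexes modelled, subset of `c("female", "male")`.
#' @param max_age oldest single-year age modelled.
#' @return a `gcea_rates` object: internally a dense `[edge, sex, age]`
#'   intensity array with a tidy [tibble::as_tibble()] view.
#' @export
#' @examples
#' g <- build_breast_graph()
#' rs <- rate_schedule(g, tibble::tibble(
#'   from = "healthy", to = "preclinical_CIS", sex = "female",
#'   age_lo = 30, age_hi = 79, rate = 1e-4
#' ), sexes = "female")
rate_schedule <- function(graph, entries = NULL,
                          sexes = c("female", "male"), max_age = 100) {
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  edge_ids <- paste(graph$edges$from, graph$edges$to, sep = "->")
  n_a <- max_age + 1L
  arr <- array(0, dim = c(length(edge_ids), length(sexes), n_a),
               dimnames = list(edge_ids, sexes, 0:max_age))
  rs <- structure(
    list(graph_cancer = graph$cancer, edges = graph$edges,
         edge_ids = edge_ids, sexes = sexes, max_age = max_age, rates = arr),
    class = "gcea_rates"
  )
  if (!is.null(entries)) rs <- set_rates(rs, entries)
  rs
}

#' @describeIn rate_schedule add or overwrite banded entries; returns the
#'   updated schedule.
#' @param rs a `gcea_rates` object.
#' @export
set_rates <- function(rs, entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("from", "to", "sex", "age_lo", "age_hi", "rate")
                %in% names(entries)))
  if (any(entries$rate < 0)) abort("transition intensities must be >= 0")
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    id <- paste(e$from, e$to, sep = "->")
    if (!id %in% rs$edge_ids) {
      abort(sprintf("rate entry for unknown edge %s", id))
    }
    sx <- if (e$sex == "both") rs$sexes else e$sex
    if (!all(sx %in% rs$sexes)) {
      abort(sprintf("sex '%s' not modelled in this schedule", e$sex))
    }
    ages <- seq(max(0L, e$age_lo), min(rs$max_age, e$age_hi)) + 1L
    rs$rates[id, sx, ages] <- e$rate
  }
  rs
}

#' @describeIn rate_schedule restrict a schedule to a subset of its sexes
#'   (e.g. the female view of a two-sex cervical schedule, for static
#'   calibration against per-100,000-women incidence targets).
#' @export
subset_rates <- function(rs, sexes) {
  stopifnot(all(sexes %in% rs$sexes))
  rs$rates <- rs$rates[, sexes, , drop = FALSE]
  rs$sexes <- sexes
  rs
}

scale_edge_rates <- function(rs, edge_ids, ages, factor, sexes = rs$sexes) {
  rs$rates[edge_ids, sexes, ages + 1L] <-
    rs$rates[edge_ids, sexes, ages + 1L] * factor
  rs
}

edge_ids_of_kind <- function(rs, kind, from = NULL, to = NULL) {
  keep <- rs$edges$kind %in% kind
  if (!is.null(from)) keep <- keep & rs$edges$from %in% from
  if (!is.null(to)) keep <- keep & rs$edges$to %in% to
  rs$edge_ids[keep]
}

#' @method as_tibble gcea_rates
#' @export
as_tibble.gcea_rates <- function(x, ...) {
  grid <- tidyr::expand_grid(edge = x$edge_ids, sex = x$sexes,
                             age = 0:x$max_age)
  grid$rate <- x$rates[cbind(match(grid$edge, x$edge_ids),
                             match(grid$sex, x$sexes), grid$age + 1L)]
  tidyr::separate_wider_delim(grid, "edge", "->", names = c("from", "to"))
}

#' @export
print.gcea_rates <- function(x, ...) {
  cat(sprintf("<gcea_rates: %s> %d edges x %d sexes x ages 0-%d; %d non-zero cells\n",
              x$graph_cancer, length(x$edge_ids), length(x$sexes),
              x$max_age, sum(x$rates > 0)))
  invisible(x)
}

#' Validate a rate schedule against its graph
#'
#' @param graph the graph the schedule was built for.
#' @param rs a `gcea_rates`.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_rates <- function(graph, rs) {
  v <- character()
  if (any(rs$rates < 0)) v <- c(v, "negative transition intensity")
  want <- paste(graph$edges$from, graph$edges$to, sep = "->")
  if (!identical(sort(want), sort(rs$edge_ids))) {
    v <- c(v, "schedule edges do not match graph edges")
  }
  v
}

#' Demography of the simulated open population
#'
#' Describes the population the cohort engine simulates: steady annual
#' birth-cohort sizes by sex, background (all-cause, non-modelled)
#' mortality by sex and age, and the maximum age. By default the engine
#' initializes occupancy at the stationary age pyramid implied by these
#' inputs, all in the healthy state.
#'
#' @param births named numeric, annual births per modelled sex.
#' @param bg_mort tibble (`sex`, `age_lo`, `age_hi`, `rate`): background
#'   mortality intensities per person-year; `sex = "both"` allowed.
#' @param sexes modelled sexes.
#' @param max_age oldest single-year age (persons surviving past it exit
#'   the model and are counted as deaths).
#' @return a `gcea_demography` object.
#' @export
demography <- function(births, bg_mort, sexes = names(births),
                       max_age = 100) {
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  stopifnot(all(births >= 0), all(sexes %in% names(births)))
  n_a <- max_age + 1L
  bg <- matrix(0, length(sexes), n_a, dimnames = list(sexes, 0:max_age))
  bg_mort <- as_tibble(bg_mort)
  for (i in seq_len(nrow(bg_mort))) {
    e <- bg_mort[i, ]
    if (e$rate < 0) abort("background mortality must be >= 0")
    sx <- if (e$sex == "both") sexes else e$sex
    ages <- seq(max(0L, e$age_lo), min(max_age, e$age_hi)) + 1L
    bg[sx, ages] <- e$rate
  }
  structure(list(births = births[sexes], bg = bg, sexes = sexes,
                 max_age = max_age),
            class = "gcea_demography")
}

#' @describeIn demography stationary population (per sex and single-year
#'   age) implied by the births and background mortality, as a tibble.
#' @param dem a `gcea_demography`.
#' @export
stationary_population <- function(dem) {
  surv <- t(apply(exp(-dem$bg), 1, function(s) cumprod(c(1, s[-length(s)]))))
  purrr::map_dfr(seq_along(dem$sexes), function(i) {
    tibble(sex = dem$sexes[i], age = 0:dem$max_age,
           population = dem$births[i] * surv[i, ])
  })
}

#' @describeIn demography rescale birth cohorts so the stationary
#'   population alive at baseline equals `total` (reporting is standardized
#'   to "per 10 million population").
#' @param total target baseline population.
#' @export
standardize_population <- function(dem, total = 1e7) {
  cur <- sum(stationary_population(dem)$population)
  dem$births <- dem$births * total / cur
  dem
}
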