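#' Ingredients-based costing parameters
#'
#' Unit costs per ingredient in 2010 international dollars (I$), the
#' screening programme overhead fraction, screening-test specificities
#' (used for false-positive follow-up volumes) and the discount rate.
#' Default unit costs are synthetic, ingredients-style values at a
#' plausible 2010 I$ level; `cost_level` scales them all, so regions can
#' share one ingredient list at different price levels.
#'
#' @param unit_costs tibble (`item`, `unit_cost`); defaults cover every
#'   item the resource planner emits (vaccine doses, each screening test,
#'   false-positive follow-up, diagnostic work-up, stage-specific
#'   treatment courses, surveillance and palliative-care years).
#' @param overhead_screening programme-level share of total screening
#'   programme cost (administration, quality assurance, monitoring),
#'   default 20%.
#' @param discount_rate annual discount rate applied to all cost flows.
#' @param cost_level multiplicative regional price level.
#' @param currency label only.
#' @return a `gcea_costing` object.
#' @export
costing_params <- function(unit_costs = default_unit_costs(),
                           overhead_screening = 0.20, discount_rate = 0.03,
                           cost_level = 1, currency = "I$ 2010") {
  unit_costs <- as_tibble(unit_costs)
  stopifnot(all(c("item", "unit_cost") %in% names(unit_costs)))
  if (any(unit_costs$unit_cost < 0)) abort("unit costs must be >= 0")
  if (overhead_screening < 0 || overhead_screening >= 1) {
    abort("overhead fraction must lie in [0, 1)")
  }
  if (discount_rate < 0) abort("discount rate must be >= 0")
  structure(list(unit_costs = unit_costs,
                 overhead_screening = overhead_screening,
                 discount_rate = discount_rate, cost_level = cost_level,
                 currency = currency),
            class = "gcea_costing")
}

#' @rdname costing_params
#' @export
default_unit_costs <- function() {
  tibble::tribble(
    ~item,                  ~unit_cost,
    "vaccine_dose",               15,
    "screen_via",                  6,
    "screen_pap",                 18,
    "screen_hpv_test",            28,
    "screen_mammo",               45,
    "fp_followup",                60,
    "diagnostic_workup",         160,
    "treatment_course_I",       1200,
    "treatment_course_II",      3000,
    "surveillance_year",          45,
    "palliative_year",           350
  )
}

#' Cost a scenario's resource-use plan
#'
#' Patient-level cost is the sum over events of quantity times unit cost.
#' Screening programmes add a programme-level component (administration,
#' quality assurance, monitoring and evaluation) sized so that it makes up
#' the configured share (default 20%) of the screening programme's total
#' cost; false-positive follow-up is already enumerated in the plan.
#' Other components carry their own itemized costs without the overhead
#' rule. All flows are discounted from programme start.
#'
#' @param plan resource plan from [resource_plan()].
#' @param params a `gcea_costing`.
#' @return a `gcea_cost` list: `total` (discounted), `total_undiscounted`,
#'   and a `breakdown` tibble (`component`, `item`, `year`, `quantity`,
#'   `cost`, `cost_discounted`).
#' @export
scenario_cost <- function(plan, params) {
  stopifnot(inherits(params, "gcea_costing"))
  miss <- setdiff(unique(plan$item), params$unit_costs$item)
  if (length(miss)) {
    abort(paste0("missing unit cost for: ", paste(miss, collapse = ", ")))
  }
  br <- plan %>%
    left_join(params$unit_costs, by = "item") %>%
    mutate(cost = .data$quantity * .data$unit_cost * params$cost_level)
  oh <- params$overhead_screening
  if (oh > 0 && any(br$component == "screening")) {
    prog <- br %>%
      filter(.data$component == "screening") %>%
      group_by(.data$year) %>%
      summarise(cost = sum(.data$cost) * oh / (1 - oh), .groups = "drop") %>%
      mutate(component = "screening_programme",
             item = "programme_overhead", quantity = NA_real_,
             unit_cost = NA_real_)
    br <- bind_rows(br, prog)
  }
  r <- params$discount_rate
  br <- br %>%
    mutate(cost_discounted = .data$cost * (1 + r)^-(.data$year - 1)) %>%
    select("component", "item", "year", "quantity", "cost",
           "cost_discounted") %>%
    arrange(.data$component, .data$item, .data$year)
  structure(list(total = sum(br$cost_discounted),
                 total_undiscounted = sum(br$cost),
                 currency = params$currency, breakdown = br),
            class = "gcea_cost")
}

#' @export
print.gcea_cost <- function(x, ...) {
  cat(sprintf("<gcea_cost> total %s %s discounted (%s undiscounted)\n",
              format(round(x$total), big.mark = ","), x$currency,
              format(round(x$total_undiscounted), big.mark = ",")))
  invisible(x)
}
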