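test_that("disability-weight derivation follows the stated rules", {
  inp <- gbd_dw_inputs(dw_diagnosis = 0.3, dw_terminal_without_med = 0.6,
                       dw_terminal_with_med = 0.5, dw_mastectomy = 0.1,
                       dw_stoma = 0.1)
  # terminal: published estimates used directly
  expect_identical(derive_dw(inp, "breast", "terminal", treated = TRUE), 0.5)
  expect_identical(derive_dw(inp, "breast", "terminal", treated = FALSE), 0.6)
  # untreated pre-terminal: diagnosis weight inflated by the terminal ratio
  expect_equal(derive_dw(inp, "breast", "I", treated = FALSE), 0.3 * 0.6 / 0.5)
  # treated colorectal stage I with a 5% stoma fraction: independent
  # mixture oracle computed term by term
  got <- derive_dw(inp, "colorectal", "I", treated = TRUE,
                   frac_first_year = 0.5, frac_stoma = 0.05)
  oracle <- 0.95 * (0.3 * 0.5) + 0.05 * (0.1 + 0.3 * 0.5)
  expect_equal(got, oracle)
  expect_equal(got, 0.155)
  # cervical: first-year correction except stage III
  expect_equal(derive_dw(inp, "cervical", "I", TRUE, frac_first_year = 0.4),
               0.3 * 0.4)
  expect_identical(derive_dw(inp, "cervical", "III", TRUE), 0.3)
  # breast: diagnosis/mastectomy average, first-year corrected
  expect_equal(derive_dw(inp, "breast", "II", TRUE, frac_first_year = 0.4,
                         diag_weight_breast = 0.5), (0.5 * 0.3 + 0.5 * 0.1) * 0.4)
})

test_that("degenerate disability-weight inputs are rejected", {
  expect_error(gbd_dw_inputs(dw_terminal_with_med = 0), "> 0")
  expect_error(gbd_dw_inputs(dw_terminal_with_med = 0.6,
                             dw_terminal_without_med = 0.5), ">=")
  expect_error(gbd_dw_inputs(dw_diagnosis = 1.2), "\\[0, 1\\]")
})

test_that("treated weights never exceed untreated ones across random inputs", {
  set.seed(42)
  for (i in 1:25) {
    wm <- runif(1, 0.4, 0.55)
    inp <- gbd_dw_inputs(dw_diagnosis = runif(1, 0.2, 0.35),
                         dw_terminal_with_med = wm,
                         dw_terminal_without_med = wm + runif(1, 0, 0.1),
                         dw_mastectomy = runif(1, 0.02, 0.1),
                         dw_stoma = runif(1, 0.05, 0.12))
    for (g in list(build_cervical_graph(), build_breast_graph(),
                   build_colorectal_graph())) {
      tab <- disability_weight_table(g, inp,
                                     frac_first_year = runif(1, 0.1, 0.9))
      expect_true(all(tab$dw_treated <= tab$dw_untreated + 1e-12))
      expect_true(all(tab$dw_untreated >= 0 & tab$dw_untreated <= 1))
      # non-clinical states carry no cancer disability
      clinical <- g$states$name[g$states$category == "clinical_cancer"]
      expect_true(all(tab$dw_untreated[!tab$state %in% clinical] == 0))
    }
  }
})

test_that("healthy life years reduce to person-years at zero weights", {
  g <- build_breast_graph()
  dem <- toy_demography(max_age = 20, bg = 0.01, births = 5)
  rs <- rate_schedule(g, NULL, sexes = "female", max_age = 20)
  tr <- simulate_cohort(g, rs, dem, horizon = 10)
  dws0 <- tibble::tibble(state = tr$states, dw = 0)
  out <- healthy_life_years(tr, dws0, discount_rate = 0)
  expect_equal(out$hly, sum(tr$occupancy))
  expect_equal(out$hly, out$hly_discounted)
  dws1 <- tibble::tibble(state = tr$states, dw = 1)
  expect_equal(healthy_life_years(tr, dws1)$hly, 0)
  expect_error(healthy_life_years(tr, dws0[-1, ]), "missing disability")
})

test_that("discounted streams match the geometric-series closed form", {
  # constant one person-year per year for 100 years
  g <- build_breast_graph()
  dem <- toy_demography(max_age = 100, bg = 0, births = 0)
  rs <- rate_schedule(g, NULL, sexes = "female", max_age = 100)
  init <- array(0, dim = c(nrow(g$states), 1, 101))
  init[1, 1, 1] <- 1
  tr <- simulate_cohort(g, rs, dem, horizon = 100, init = init)
  dws <- tibble::tibble(state = tr$states, dw = 0)
  out <- healthy_life_years(tr, dws, discount_rate = 0.03)
  v <- 1 / 1.03
  closed_form <- (1 - v^100) / (1 - v)
  expect_equal(out$hly, 100)
  expect_equal(out$hly_discounted, closed_form, tolerance = 1e-9)
})

test_that("scenario costing applies unit costs, overhead and discounting", {
  params0 <- costing_params(discount_rate = 0)
  empty <- tibble::tibble(component = character(), item = character(),
                          year = integer(), quantity = numeric())
  expect_identical(scenario_cost(empty, params0)$total, 0)

  # false-positive follow-up arithmetic, overhead off for clean numbers
  p_noh <- costing_params(unit_costs = tibble::tibble(
    item = c("screen_via", "fp_followup"), unit_cost = c(0, 50)),
    overhead_screening = 0, discount_rate = 0)
  plan <- tibble::tibble(component = "screening",
                         item = c("screen_via", "fp_followup"), year = 1,
                         quantity = c(1e5, 1e5 * 0.1))
  expect_equal(scenario_cost(plan, p_noh)$total, 5e5)

  # a constant stream of C per year for 100 years discounts to C * 32.55
  pC <- costing_params(unit_costs = tibble::tibble(item = "palliative_year",
                                                   unit_cost = 7),
                       discount_rate = 0.03)
  stream <- tibble::tibble(component = "palliative",
                           item = "palliative_year", year = 1:100,
                           quantity = 1)
  v <- 1 / 1.03
  expect_equal(scenario_cost(stream, pC)$total, 7 * (1 - v^100) / (1 - v),
               tolerance = 1e-9)

  # screening overhead makes programme costs 20% of the programme total
  p_oh <- costing_params(unit_costs = tibble::tibble(item = "screen_via",
                                                     unit_cost = 10),
                         overhead_screening = 0.2, discount_rate = 0)
  sc <- scenario_cost(tibble::tibble(component = "screening",
                                     item = "screen_via", year = 1,
                                     quantity = 100), p_oh)
  oh <- sum(sc$breakdown$cost[sc$breakdown$component == "screening_programme"])
  expect_equal(oh / sc$total, 0.2)

  expect_error(scenario_cost(tibble::tibble(component = "x", item = "nope",
                                            year = 1, quantity = 1),
                             params0), "missing unit cost")
})

test_that("cost breakdowns add to the total and grow with coverage", {
  ev <- demo_evals("SEA-like")
  mono <- ev |>
    dplyr::arrange(.data$label, .data$coverage) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mono = all(diff(.data$cost) >= 0), .groups = "drop")
  expect_true(all(mono$mono))

  b <- demo_bundle()
  parts <- b$cancers$cervical
  dws <- disability_weight_table(parts$graph, b$gbd)
  mods <- apply_scenario(parts$rates, dws, scenario("C1e", 0.8))
  tr <- simulate_cohort(parts$graph, mods$rates, parts$dem, 10,
                        transmission = parts$transmission,
                        vaccination = mods$vaccination, init = parts$init)
  sc <- scenario_cost(resource_plan(tr, mods), b$costing)
  expect_equal(sum(sc$breakdown$cost_discounted), sc$total,
               tolerance = 1e-9)
  expect_equal(sum(sc$breakdown$cost), sc$total_undiscounted,
               tolerance = 1e-9)
})

test_that("zero discounting equates discounted and undiscounted totals", {
  b <- demo_bundle()
  parts <- b$cancers$breast
  dws <- disability_weight_table(parts$graph, b$gbd)
  mods <- apply_scenario(parts$rates, dws, scenario("C2a", 0.5))
  tr <- simulate_cohort(parts$graph, mods$rates, parts$dem, 10)
  hly <- healthy_life_years(tr, mods$dw, discount_rate = 0)
  expect_identical(hly$hly, hly$hly_discounted)
  costing0 <- b$costing
  costing0$discount_rate <- 0
  sc <- scenario_cost(resource_plan(tr, mods), costing0)
  expect_equal(sc$total, sc$total_undiscounted)
})
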