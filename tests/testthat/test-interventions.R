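test_that("the catalog holds 14 interventions partitioned 9/3/2", {
  cat14 <- build_catalog()
  expect_identical(nrow(cat14), 14L)
  expect_false(anyDuplicated(cat14$label) > 0)
  expect_equal(unname(table(cat14$cancer)[c("cervical", "breast",
                                            "colorectal")]),
               c(9L, 3L, 2L), ignore_attr = TRUE)
})

test_that("combination labels expand to the union of their components", {
  cat14 <- build_catalog()
  eff <- function(l) cat14$effects[[match(l, cat14$label)]]
  expect_identical(eff("C1e"), c(eff("C1a"), eff("C1b")))
  expect_identical(eff("C1f"), c(eff("C1a"), eff("C1c")))
  tech <- function(l) cat14$technologies[[match(l, cat14$label)]]
  expect_setequal(tech("C1e"), union(tech("C1a"), tech("C1b")))
  # mammography is linked with treatment, so it carries that technology
  expect_true(all(tech("C2a") %in% tech("C2b")))
})

test_that("vaccination targets girls aged 9-13 and only the 16/18 group", {
  cat14 <- build_catalog()
  vac <- cat14$effects[[match("C1a", cat14$label)]][[1]]
  expect_identical(vac$type, "vaccination")
  expect_identical(vac$sex, "female")
  expect_true(vac$age_at >= 9 && vac$age_at <= 13)
  expect_identical(vac$group, "HPV_16_18")
})

test_that("the null scenario is the identity on rates and weights", {
  b <- demo_bundle()
  parts <- b$cancers$cervical
  dws <- disability_weight_table(parts$graph, b$gbd)
  out <- apply_scenario(parts$rates, dws, null_scenario())
  expect_identical(out$rates$rates, parts$rates$rates)
  expect_identical(out$dw$dw, dws$dw_untreated)
  expect_null(out$vaccination)
  expect_length(out$meta, 0)
  # coverage zero everywhere reduces to the null as well
  out0 <- apply_scenario(parts$rates, dws,
                         scenario(c("C1a", "C1b", "C1h", "C1i"), 0))
  expect_identical(out0$rates$rates, parts$rates$rates)
  expect_identical(out0$dw$dw, dws$dw_untreated)
})

test_that("scenario validation rejects bad labels and coverages", {
  expect_error(scenario("C1a", 0.7), "coverage")
  expect_silent(scenario("C1a", 0.7, strict = FALSE))
  expect_error(scenario(c("C1a", "C1a"), 0.5), "one coverage")
  b <- demo_bundle()
  dws <- disability_weight_table(b$cancers$cervical$graph, b$gbd)
  expect_error(apply_scenario(b$cancers$cervical$rates, dws,
                              scenario("C9z", 0.5)), "unknown")
})

test_that("full-coverage vaccination silences only the 16/18 onset edge", {
  g <- build_cervical_graph()
  dem <- toy_demography(sexes = c("female", "male"), max_age = 40,
                        bg = 0, births = 10)
  rs <- rate_schedule(g, tibble::tibble(
    from = "healthy", to = c("HPV_16_18", "HPV_high_risk", "HPV_low_risk"),
    sex = "both", age_lo = 0, age_hi = 40, rate = 0.05), max_age = 40)
  tr <- simulate_cohort(g, rs, dem, horizon = 25,
                        vaccination = list(coverage = 1, efficacy = 1,
                                           age_at = 12))
  e16 <- match("healthy->HPV_16_18", tr$edge_ids)
  ehr <- match("healthy->HPV_high_risk", tr$edge_ids)
  fem <- match("female", tr$sexes)
  # cohorts vaccinated at 12: by year 25 all female ages 12..36 protected
  expect_identical(sum(tr$events[e16, fem, 13:37, 25]), 0)
  expect_gt(sum(tr$events[ehr, fem, 13:37, 25]), 0)
  # unvaccinated ages and men untouched
  expect_gt(sum(tr$events[e16, fem, 1:12, 25]), 0)
  expect_gt(sum(tr$events[e16, match("male", tr$sexes), , 25]), 0)
})

test_that("palliative coverage mixes the terminal disability weight", {
  b <- demo_bundle()
  parts <- b$cancers$colorectal
  dws <- disability_weight_table(parts$graph, b$gbd)
  out <- apply_scenario(parts$rates, dws, scenario("C3b", 0.95))
  with_med <- dws$dw_treated[dws$state == "clinical_IV"]
  without <- dws$dw_untreated[dws$state == "clinical_IV"]
  expect_equal(out$dw$dw[out$dw$state == "clinical_IV"],
               0.95 * with_med + 0.05 * without)
  # rates untouched by palliative care
  expect_identical(out$rates$rates, parts$rates$rates)
})

test_that("rate modifications scale linearly in coverage", {
  b <- demo_bundle()
  parts <- b$cancers$breast
  dws <- disability_weight_table(parts$graph, b$gbd)
  mod <- function(cov) {
    apply_scenario(parts$rates, dws,
                   scenario("C2b", cov, strict = FALSE))$rates$rates
  }
  r0 <- mod(0); r1 <- mod(1); r8 <- mod(0.8)
  expect_equal(r8, 0.2 * r0 + 0.8 * r1, tolerance = 1e-12)
})

test_that("a combination scenario equals its components applied jointly", {
  b <- demo_bundle()
  parts <- b$cancers$cervical
  dws <- disability_weight_table(parts$graph, b$gbd)
  combo <- apply_scenario(parts$rates, dws, scenario("C1e", 0.8))
  joint <- apply_scenario(parts$rates, dws,
                          scenario(c("C1a", "C1b"), 0.8))
  expect_identical(combo$rates$rates, joint$rates$rates)
  expect_identical(combo$dw, joint$dw)
  expect_identical(combo$vaccination, joint$vaccination)
})

test_that("screening adds diagnosis and screen-treat regression intensity", {
  b <- demo_bundle()
  parts <- b$cancers$cervical
  dws <- disability_weight_table(parts$graph, b$gbd)
  out <- apply_scenario(parts$rates, dws, scenario("C1b", 0.5))
  # VIA: annual screen probability = coverage / interval for women 30-49
  sigma <- 0.5 / 10
  d <- out$rates$rates["preclinical_I->clinical_I", "female", 36] -
    parts$rates$rates["preclinical_I->clinical_I", "female", 36]
  expect_equal(d, sigma * 0.60)
  reg <- out$rates$rates["CIN2_3->HPV_16_18", "female", 36] -
    parts$rates$rates["CIN2_3->HPV_16_18", "female", 36]
  expect_equal(reg, sigma * 0.55 * 0.90 * 0.70)
  # men and out-of-band ages untouched
  expect_identical(out$rates$rates[, "male", ],
                   parts$rates$rates[, "male", ])
  expect_identical(out$rates$rates["preclinical_I->clinical_I", "female", 20],
                   parts$rates$rates["preclinical_I->clinical_I", "female", 20])
})

test_that("HLY gains are non-decreasing in coverage for every intervention", {
  for (region in c("SEA-like", "ESSA-like")) {
    ev <- demo_evals(region)
    gaps <- ev |>
      dplyr::arrange(.data$label, .data$coverage) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(mono = all(diff(.data$hly) >= 0), .groups = "drop")
    expect_true(all(gaps$mono), label = region)
  }
})

test_that("the resource plan enumerates screens, doses and courses", {
  b <- demo_bundle()
  parts <- b$cancers$cervical
  dws <- disability_weight_table(parts$graph, b$gbd)
  mods <- apply_scenario(parts$rates, dws, scenario("C1e", 0.8))
  tr <- simulate_cohort(parts$graph, mods$rates, parts$dem, 5,
                        transmission = parts$transmission,
                        vaccination = mods$vaccination, init = parts$init)
  plan <- resource_plan(tr, mods)
  expect_setequal(unique(plan$component), c("vaccination", "screening"))
  doses <- plan |> dplyr::filter(item == "vaccine_dose", year == 1)
  girls12 <- sum(tr$occupancy[, match("female", tr$sexes), 13, 1])
  expect_equal(doses$quantity, 2 * 0.8 * girls12)
  screens <- plan |> dplyr::filter(item == "screen_via", year == 1)
  eligible <- sum(tr$occupancy[, match("female", tr$sexes), 31:50, 1])
  expect_equal(screens$quantity, 0.8 / 10 * eligible)
  fp <- plan |> dplyr::filter(item == "fp_followup")
  expect_true(all(fp$quantity > 0))
})
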