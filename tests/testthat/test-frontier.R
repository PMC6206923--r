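test_that("ACER reproduces the published worked ratios", {
  expect_identical(acer(396, 4541842), 87)
  expect_identical(acer(146, 5215136), 28)
  expect_identical(acer(0, 1000), 0)
  expect_error(acer(10, 0), "positive")
  expect_identical(acer(2601.476305, 8611060, digits = 2), 302.11)
})

test_that("ICER handles increments, degenerate nulls and dominance", {
  # first step versus the null coincides with the ACER
  expect_identical(icer(list(cost = 0, hly = 0),
                        list(cost = 396, hly = 4541842)), 87)
  # printed incremental pair: vaccination at 80% to combination at 80%
  expect_identical(icer(list(cost = 190, hly = 6773262),
                        list(cost = 1163, hly = 30421065)), 41)
  same <- icer(list(cost = 5, hly = 10), list(cost = 5, hly = 10))
  expect_true(is.infinite(same))
  expect_true(isTRUE(attr(same, "dominated")))
})

test_that("dominance_filter removes dominated and extended-dominated points", {
  one <- tibble::tibble(cost = 5, hly = 10)
  expect_identical(nrow(dominance_filter(one)$frontier), 1L)
  two <- tibble::tibble(label = c("A", "B"), cost = c(10, 20),
                        hly = c(100, 90))
  out <- dominance_filter(two)
  expect_identical(out$dominated$label, "B")
  expect_identical(out$dominated$reason, "dominated")

  set.seed(7)
  for (rep in 1:10) {
    pts <- tibble::tibble(cost = round(runif(20, 0, 100), 1),
                          hly = round(runif(20, 0, 100), 1))
    got <- dominance_filter(pts)$frontier |> dplyr::arrange(hly, cost)
    want <- oracle_frontier(pts) |> dplyr::arrange(hly, cost)
    expect_equal(got$cost, want$cost)
    expect_equal(got$hly, want$hly)
    ic <- diff(got$cost) / diff(got$hly)
    expect_true(all(diff(ic) >= -1e-12)) # non-decreasing ICERs
  }
})

test_that("a single technology walks its coverage ladder in order", {
  menu <- dplyr::bind_rows(
    menu_row("A", 0.5, 10, 100, "techA"),
    menu_row("A", 0.8, 18, 160, "techA"),
    menu_row("A", 0.95, 24, 190, "techA"))
  path <- expansion_path(menu)
  expect_identical(path$coverage, c(0.5, 0.8, 0.95))
  expect_true(all(diff(path$icer) >= 0))
})

test_that("the constrained path matches exhaustive search on small menus", {
  menu <- dplyr::bind_rows(
    menu_row("A", 0.5, 10, 100, "techA"),
    menu_row("A", 0.95, 24, 190, "techA"),
    menu_row("AB", 0.5, 40, 220, c("techA", "techB")),
    menu_row("AB", 0.95, 75, 340, c("techA", "techB")))
  got <- expansion_path(menu)[, c("label", "coverage")]
  want <- oracle_path(menu)
  expect_identical(as.data.frame(got), as.data.frame(want))

  # two independent disease arms interleave purely by ICER while each
  # arm still matches its own exhaustive search
  arm_t <- dplyr::bind_rows(
    menu_row("T", 0.5, 8, 50, "techT", cancer = "breast"),
    menu_row("T", 0.95, 15, 95, "techT", cancer = "breast"))
  path2 <- expansion_path(dplyr::bind_rows(menu, arm_t))
  expect_true(all(diff(path2$icer) >= 0)) # global ICER order
  got_cvx <- path2[path2$cancer == "cervical", c("label", "coverage")]
  got_brc <- path2[path2$cancer == "breast", c("label", "coverage")]
  expect_identical(as.data.frame(got_cvx), as.data.frame(oracle_path(menu)))
  expect_identical(as.data.frame(got_brc), as.data.frame(oracle_path(arm_t)))
})

test_that("budget shares reproduce the published allocations", {
  sea <- budget_allocation(c(cervical = 781881006, breast = 1454645503,
                             colorectal = 364949796))
  expect_identical(sea$share[match(c("breast", "cervical", "colorectal"),
                                   sea$cancer)], c(56, 30, 14))
  essa <- budget_allocation(c(cervical = 1522549019, breast = 1635269849,
                              colorectal = 248737875))
  expect_identical(essa$share[match(c("breast", "cervical", "colorectal"),
                                    essa$cancer)], c(48, 45, 7))
  eq <- budget_allocation(c(a = 1, b = 1, c = 1))
  expect_true(all(eq$share == 33))
  expect_identical(budget_allocation(c(breast = 5))$share, 100)
})

test_that("league tables keep path order and export the dominated set", {
  empty <- league_table(tibble::tibble(cancer = character(),
                                       label = character(),
                                       coverage = numeric(),
                                       cost = numeric(), hly = numeric(),
                                       technologies = list()))
  expect_identical(nrow(empty$path), 0L)

  ev <- demo_evals("SEA-like")
  path <- demo_path("SEA-like")
  lt <- league_table(ev, path)
  expect_identical(nrow(lt$path) + nrow(lt$dominated), nrow(ev))
  for (arm in unique(path$arm)) {
    expect_true(all(diff(path$icer[path$arm == arm]) >= 0))
  }
  gl <- glance(path)
  expect_identical(gl$n_steps, nrow(path))
  expect_gt(gl$programme_acer, 0)
})

test_that("printed league tables are arithmetically self-consistent", {
  fx <- fixture_tables()
  for (tab in list(fx$sea, fx$essa)) {
    recomputed <- acer(tab$cost_million, tab$hly)
    expect_true(all(abs(recomputed - tab$acer) / tab$acer < 0.005))
  }
  # programme-level ratios from the budget table
  bt <- fx$budget
  val <- function(region, q) bt$value[bt$region == region & bt$quantity == q]
  expect_identical(acer(val("SEA", "cost_total") / 1e6,
                        val("SEA", "hly_undiscounted"), digits = 2), 302.11)
  expect_identical(acer(val("ESSA", "cost_total") / 1e6,
                        val("ESSA", "hly_undiscounted"), digits = 2), 93.64)
})

test_that("autoplot and tidy work on a demo expansion path", {
  path <- demo_path("SEA-like")
  td <- tidy(path)
  expect_true(all(c("rank", "label", "acer", "icer") %in% names(td)))
  p <- ggplot2::ggplot_build(autoplot(path))
  expect_gt(length(p$data), 0)
})
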