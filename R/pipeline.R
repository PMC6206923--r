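#' Evaluate one scenario against the null
#'
#' Applies the scenario to the bundle's natural-history inputs for the
#' affected cancer, simulates the open population over the horizon,
#' accounts healthy life years with the scenario's effective disability
#' weights, enumerates and costs the resource plan, and reports
#' everything relative to the null run of the same cancer.
#'
#' @param bundle a `gcea_bundle` from [generate_region_params()].
#' @param scn a `gcea_scenario`; its labels must belong to one cancer.
#' @param catalog the intervention catalog.
#' @param horizon programme years (default 100).
#' @param cache optional environment memoizing null runs across calls.
#' @return one-row tibble: region, cancer, label(s), coverage,
#'   `cost` (discounted, million I$), `hly` and `hly_discounted` gains,
#'   `technologies` (list).
#' @export
evaluate_scenario <- function(bundle, scn, catalog = build_catalog(),
                              horizon = 100, cache = NULL) {
  stopifnot(inherits(bundle, "gcea_bundle"))
  effs <- scenario_effects(scn, catalog)
  cancer <- unique(purrr::map_chr(effs, "cancer"))
  if (length(cancer) != 1) {
    abort("a scenario evaluation must target exactly one cancer")
  }
  parts <- bundle$cancers[[cancer]]
  dws <- disability_weight_table(parts$graph, bundle$gbd,
                                 frac_first_year = bundle$dw_config$frac_first_year,
                                 frac_stoma = bundle$dw_config$frac_stoma,
                                 diag_weight_breast = bundle$dw_config$diag_weight_breast)
  null <- null_run(bundle, cancer, dws, horizon, cache)

  mods <- apply_scenario(parts$rates, dws, scn, catalog,
                         hpv_shares = bundle$hpv_shares)
  traj <- simulate_cohort(parts$graph, mods$rates, parts$dem, horizon,
                          transmission = parts$transmission,
                          vaccination = mods$vaccination,
                          init = parts$init)
  hly <- healthy_life_years(traj, mods$dw,
                            discount_rate = bundle$costing$discount_rate)
  cost <- scenario_cost(resource_plan(traj, mods), bundle$costing)
  techs <- sort(unique(unlist(purrr::map(effs, "technologies"))))
  gain <- hly$hly - null$hly$hly
  gain_disc <- hly$hly_discounted - null$hly$hly_discounted
  tibble(
    region = bundle$profile$name, cancer = cancer,
    label = paste(scn$label[scn$coverage > 0], collapse = "+"),
    coverage = max(scn$coverage, 0),
    cost = cost$total / 1e6,
    hly = gain, hly_discounted = gain_disc,
    technologies = list(techs)
  )
}

null_run <- function(bundle, cancer, dws, horizon, cache = NULL) {
  key <- paste(bundle$profile$name, cancer, horizon, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  parts <- bundle$cancers[[cancer]]
  null_dw <- dws %>% transmute(.data$state, dw = .data$dw_untreated)
  traj <- simulate_cohort(parts$graph, parts$rates, parts$dem, horizon,
                          transmission = parts$transmission,
                          init = parts$init)
  out <- list(traj = traj,
              hly = healthy_life_years(traj, null_dw,
                                       bundle$costing$discount_rate))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Evaluate the full intervention catalog for one region
#'
#' Runs the null once per cancer, then every catalog intervention at every
#' coverage level against it.
#'
#' @inheritParams evaluate_scenario
#' @param coverages coverage grid (default 50/80/95%).
#' @return evaluation tibble suitable for [expansion_path()] and
#'   [league_table()], with descriptions joined from the catalog.
#' @export
evaluate_interventions <- function(bundle, catalog = build_catalog(),
                                   coverages = COVERAGE_GRID,
                                   horizon = 100) {
  cache <- new.env(parent = emptyenv())
  grid <- tidyr::expand_grid(label = catalog$label, coverage = coverages)
  evals <- purrr::pmap_dfr(grid, function(label, coverage) {
    evaluate_scenario(bundle, scenario(label, coverage),
                      catalog = catalog, horizon = horizon, cache = cache)
  })
  evals %>%
    left_join(catalog %>% select("label", "description"), by = "label") %>%
    relocate("description", .after = "label")
}

#' Load a pipeline run configuration
#'
#' YAML with fields: `regions` (names of packaged demo profiles, see
#' [make_two_region_demo()]), `horizon` (default 100), `discount_rate`
#' (default 0.03), `coverages` (default 0.5/0.8/0.95), `seed`,
#' `output_dir` (optional; no files written when absent).
#'
#' @param path YAML file.
#' @return a validated `gcea_config` list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$regions <- cfg$regions %||% names(make_two_region_demo())
  cfg$horizon <- cfg$horizon %||% 100
  cfg$discount_rate <- cfg$discount_rate %||% 0.03
  cfg$coverages <- unlist(cfg$coverages %||% COVERAGE_GRID)
  cfg$seed <- cfg$seed %||% 1L
  problems <- c(
    if (cfg$horizon < 1) "horizon: must be >= 1",
    if (cfg$discount_rate < 0) "discount_rate: must be >= 0",
    if (any(cfg$coverages <= 0 | cfg$coverages > 1)) {
      "coverages: values must lie in (0, 1]"
    },
    if (!all(cfg$regions %in% names(make_two_region_demo()))) {
      "regions: unknown profile name"
    }
  )
  if (length(problems)) abort(c("invalid run configuration", problems))
  structure(cfg[c("regions", "horizon", "discount_rate", "coverages",
                  "seed", "output_dir")], class = "gcea_config")
}

#' @rdname load_config
#' @param cfg a `gcea_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!purrr::map_lgl(unclass(cfg), is.null)],
                   path)
  invisible(path)
}

#' Run the full GCEA pipeline
#'
#' For every configured region: generate the parameter bundle, evaluate
#' the null and all (intervention, coverage) scenarios, filter dominance,
#' build the constrained expansion path, league tables and the budget
#' allocation. With `output_dir` set, tidy CSVs (evaluations, path,
#' dominated interventions, budget) and a JSON provenance record (config,
#' seed, parameter digests) are written per region.
#'
#' @param config a `gcea_config` from [load_config()], or `NULL` for the
#'   packaged demo configuration.
#' @return list per region: `bundle`, `evals`, `path`, `league`,
#'   `budget`; plus `config`.
#' @export
run_pipeline <- function(config = NULL) {
  config <- config %||%
    load_config(system.file("extdata", "demo_config.yaml",
                            package = "gcea", mustWork = TRUE))
  profiles <- make_two_region_demo()[config$regions]
  catalog <- build_catalog()
  out <- purrr::map(profiles, function(pr) {
    pr$seed <- pr$seed + config$seed # run seed shifts the profile draws
    bundle <- generate_region_params(pr)
    bundle$costing$discount_rate <- config$discount_rate
    evals <- evaluate_interventions(bundle, catalog,
                                    coverages = config$coverages,
                                    horizon = config$horizon)
    path <- expansion_path(evals)
    league <- league_table(evals, path)
    budget <- budget_allocation(path, require_complete = FALSE)
    if (!is.null(config$output_dir)) {
      write_region_outputs(config, pr$name, evals, path, league, budget)
    }
    list(bundle = bundle, evals = evals, path = path, league = league,
         budget = budget)
  })
  c(out, list(config = config))
}

write_region_outputs <- function(config, region, evals, path, league,
                                 budget) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^A-Za-z0-9]+", "_", region)
  w <- function(df, name) {
    df <- df %>% mutate(dplyr::across(dplyr::where(is.list),
                                      ~ purrr::map_chr(.x, paste,
                                                       collapse = ";")))
    utils::write.csv(df, file.path(config$output_dir,
                                   paste0(slug, "_", name, ".csv")),
                     row.names = FALSE)
  }
  w(evals, "evaluations")
  w(tidy(path), "expansion_path")
  w(league$dominated, "dominated")
  w(budget, "budget_allocation")
  prov <- list(region = region, config = unclass(config),
               config_digest = rlang::hash(unclass(config)),
               r_version = as.character(getRversion()),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov,
                       file.path(config$output_dir,
                                 paste0(slug, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
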