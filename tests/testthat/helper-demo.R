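# Shared, lazily computed fixtures: the two-region demo pipeline is
# expensive (tens of seconds), so it is run once and reused across files.
.demo_cache <- new.env(parent = emptyenv())

demo_pipeline <- function() {
  if (is.null(.demo_cache$pipeline)) {
    .demo_cache$pipeline <- run_pipeline()
  }
  .demo_cache$pipeline
}

demo_bundle <- function(region = "SEA-like") {
  demo_pipeline()[[region]]$bundle
}

demo_evals <- function(region = "SEA-like") {
  demo_pipeline()[[region]]$evals
}

demo_path <- function(region = "SEA-like") {
  demo_pipeline()[[region]]$path
}

# Small deterministic demography for unit-scale engine tests.
toy_demography <- function(sexes = "female", max_age = 30, bg = 0,
                           births = 0) {
  demography(
    births = stats::setNames(rep(births, length(sexes)), sexes),
    bg_mort = tibble::tibble(sex = "both", age_lo = 0, age_hi = max_age,
                             rate = bg),
    sexes = sexes, max_age = max_age
  )
}

# Closed single cohort of a given size entering at age 0.
cohort_init <- function(graph, dem, n = 1000, state = "healthy") {
  O <- array(0, dim = c(nrow(graph$states), length(dem$sexes),
                        dem$max_age + 1L))
  O[match(state, graph$states$name), , 1] <- n / length(dem$sexes)
  O
}
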