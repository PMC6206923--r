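#' Calibrate onset intensities to age-specific clinical incidence targets
#'
#' Iteratively rescales the healthy-to-first-disease-state (onset-kind)
#' intensities of a schedule, age band by age band, until the simulated
#' clinical incidence (diagnosis-edge flows per 100,000 modelled population
#' per year, measured over a quasi-stationary window) matches the targets
#' within a relative tolerance. Progression, regression and diagnosis
#' rates are held fixed. This is a deliberately simple proportional-fitting
#' routine: it stands in for full population-specific rate estimation,
#' which is out of scope here.
#'
#' @param graph a `gcea_graph`.
#' @param rates a `gcea_rates`; its onset edges are the free parameters.
#' @param dem a `gcea_demography` restricted to the population whose
#'   incidence the targets describe (e.g. women only for cervical and
#'   breast targets).
#' @param targets tibble (`age_lo`, `age_hi`, `incidence`): clinical
#'   diagnoses per 100,000 per year by age band; bands with target 0 get
#'   onset intensity 0.
#' @param tol relative tolerance on every band (default 1%).
#' @param max_iter iteration cap (default 100); non-convergence is an
#'   error reporting the final residuals.
#' @param settle,measure years simulated before and inside the incidence
#'   measurement window.
#' @param onset_lag years between onset and clinical diagnosis assumed
#'   when mapping a target band to the onset ages that drive it: the band
#'   `[lo, hi]` controls onset at ages `[lo - onset_lag, hi - onset_lag]`.
#'   Use the typical preclinical (plus precancer) sojourn; e.g. around a
#'   decade for cervical disease, where the calibrated transition precedes
#'   diagnosis by many years.
#' @param edges edge ids (`"from->to"`) to rescale; defaults to the
#'   graph's onset-kind edges. The cervical generator passes the
#'   HPV-to-CIN1 progression edges here, because with a dynamic
#'   transmission model the entry into the cancer process is that
#'   transition rather than the (dynamically overridden) healthy-to-HPV
#'   edges.
#' @param transmission,init optional transmission parameters and initial
#'   occupancy forwarded to [simulate_cohort()], so calibration can run
#'   with the dynamic infection model in the loop from its endemic state.
#' @param incidence_sexes sexes whose diagnoses and person-years define
#'   the incidence (default: all modelled sexes); use `"female"` for
#'   targets quoted per 100,000 women.
#' @return the calibrated `gcea_rates`, with an attribute `calibration`
#'   (iterations, per-band achieved incidence and residuals).
#' @export
calibrate_onset_rates <- function(graph, rates, dem, targets, tol = 0.01,
                                  max_iter = 100, settle = 60, measure = 20,
                                  onset_lag = 0, edges = NULL,
                                  transmission = NULL, init = NULL,
                                  incidence_sexes = NULL) {
  targets <- as_tibble(targets)
  stopifnot(all(c("age_lo", "age_hi", "incidence") %in% names(targets)),
            all(targets$incidence >= 0))
  onset_ids <- edges %||% edge_ids_of_kind(rates, "onset")
  if (!length(onset_ids)) abort("no edges to calibrate")
  stopifnot(all(onset_ids %in% rates$edge_ids))
  diag_idx <- which(rates$edges$kind == "diagnosis")
  sex_idx <- match(incidence_sexes %||% rates$sexes, rates$sexes)
  win <- settle + seq_len(measure)

  band_ages <- purrr::map(seq_len(nrow(targets)), function(b) {
    seq(max(0L, targets$age_lo[b]), min(dem$max_age, targets$age_hi[b]))
  })
  onset_ages <- purrr::map(band_ages, function(a) {
    pmin(dem$max_age, pmax(0L, a - as.integer(onset_lag)))
  })
  pos <- targets$incidence > 0
  for (b in which(!pos)) {
    rates$rates[onset_ids, , onset_ages[[b]] + 1L] <- 0
  }
  # seed bands whose onset mass is all zero but whose target is positive
  for (b in which(pos)) {
    blk <- rates$rates[onset_ids, , onset_ages[[b]] + 1L, drop = FALSE]
    if (all(blk == 0)) {
      rates$rates[onset_ids, , onset_ages[[b]] + 1L] <-
        targets$incidence[b] / 1e5
    }
  }
  if (!any(pos)) {
    attr(rates, "calibration") <- list(iterations = 0L, converged = TRUE,
                                       achieved = targets$incidence,
                                       residuals = rep(0, nrow(targets)))
    return(rates)
  }

  achieved <- residuals <- rep(NA_real_, nrow(targets))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    traj <- simulate_cohort(graph, rates, dem, horizon = settle + measure,
                            transmission = transmission, init = init)
    diag_flows <- apply(traj$events[diag_idx, sex_idx, , win,
                                    drop = FALSE], 3, sum) # by age
    py <- apply(traj$occupancy[, sex_idx, , win, drop = FALSE], 3, sum)
    for (b in seq_len(nrow(targets))) {
      a <- band_ages[[b]] + 1L
      achieved[b] <- sum(diag_flows[a]) / sum(py[a]) * 1e5
    }
    residuals <- ifelse(targets$incidence > 0,
                        achieved / targets$incidence - 1, 0)
    if (max(abs(residuals)) <= tol) {
      converged <- TRUE
      break
    }
    if (any(achieved[pos] == 0)) {
      bad <- which(pos & achieved == 0)[1]
      abort(sprintf(
        "calibration target unreachable: band %d-%d has positive target but zero simulated incidence (are diagnosis rates zero?)",
        targets$age_lo[bad], targets$age_hi[bad]))
    }
    for (b in which(pos)) {
      scale <- min(10, max(0.1, targets$incidence[b] / achieved[b]))
      rates <- scale_edge_rates(rates, onset_ids, onset_ages[[b]], scale)
    }
  }
  if (!converged) {
    abort(c("onset-rate calibration did not converge",
            sprintf("band %d-%d: target %.3g, achieved %.3g (rel. %.2f%%)",
                    targets$age_lo, targets$age_hi, targets$incidence,
                    achieved, 100 * residuals)))
  }
  attr(rates, "calibration") <- list(iterations = it, converged = TRUE,
                                     achieved = achieved,
                                     residuals = residuals)
  rates
}
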