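#' GBD-2010-style disability-weight inputs
#'
#' The six published estimates the per-state weights are derived from:
#' "cancer: diagnosis and primary therapy", "cancer: metastatic",
#' "terminal phase: with medication", "terminal phase: without
#' medication", "mastectomy" and "stoma". Defaults are synthetic values in
#' the plausible GBD-2010 range.
#'
#' @param dw_diagnosis,dw_metastatic,dw_terminal_with_med,dw_terminal_without_med,dw_mastectomy,dw_stoma
#'   disability weights in `[0, 1]`; terminal-without-medication must be
#'   at least terminal-with-medication, and the latter positive (the
#'   untreated inflation rule divides by it).
#' @return a `gcea_dw_inputs` list.
#' @export
gbd_dw_inputs <- function(dw_diagnosis = 0.294, dw_metastatic = 0.484,
                          dw_terminal_with_med = 0.508,
                          dw_terminal_without_med = 0.519,
                          dw_mastectomy = 0.038, dw_stoma = 0.086) {
  vals <- c(dw_diagnosis, dw_metastatic, dw_terminal_with_med,
            dw_terminal_without_med, dw_mastectomy, dw_stoma)
  if (any(vals < 0 | vals > 1)) abort("disability weights must lie in [0, 1]")
  if (dw_terminal_with_med == 0) {
    abort("dw_terminal_with_med must be > 0: the untreated inflation ratio is undefined")
  }
  if (dw_terminal_without_med < dw_terminal_with_med) {
    abort("terminal-phase DW without medication must be >= with medication")
  }
  structure(list(dw_diagnosis = dw_diagnosis, dw_metastatic = dw_metastatic,
                 dw_terminal_with_med = dw_terminal_with_med,
                 dw_terminal_without_med = dw_terminal_without_med,
                 dw_mastectomy = dw_mastectomy, dw_stoma = dw_stoma),
            class = "gcea_dw_inputs")
}

#' Derive a single state disability weight
#'
#' Implements the derivation rules used throughout the model:
#'
#' * untreated, pre-terminal (any cancer, stages CIS-III): the "diagnosis
#'   and primary therapy" weight inflated by the ratio of the two
#'   terminal-phase weights (without / with medication), capped at 1;
#' * terminal stage (clinical IV, which doubles as the terminal phase):
#'   the published terminal estimate used directly - without medication if
#'   untreated, with medication under palliative care;
#' * treated cervical CIS-II: diagnosis weight times the fraction of cases
#'   in their first year of treatment; stage III uncorrected;
#' * treated breast CIS-II: weighted average of the diagnosis and
#'   mastectomy weights (equal weights by default), first-year-corrected;
#'   stage III: diagnosis weight times the first-year fraction in that
#'   stage;
#' * treated colorectal: for the `frac_stoma` of patients requiring a
#'   stoma, the stoma weight adds to the (first-year-corrected) diagnosis
#'   part; no first-year correction in stage III.
#'
#' @param inputs a `gcea_dw_inputs`.
#' @param cancer `"cervical"`, `"breast"` or `"colorectal"`.
#' @param stage one of `"CIS"`, `"I"`, `"II"`, `"III"`, `"terminal"`.
#' @param treated logical.
#' @param frac_first_year fraction of prevalent cases in their first year
#'   of treatment.
#' @param frac_stoma stoma fraction for colorectal (default 5%).
#' @param diag_weight_breast weight on the diagnosis estimate in the
#'   breast diagnosis/mastectomy average.
#' @param frac_first_year_stage3 first-year fraction within stage III
#'   (breast rule); defaults to `frac_first_year`.
#' @return a disability weight in `[0, 1]`.
#' @export
#' @examples
#' inp <- gbd_dw_inputs(dw_diagnosis = 0.3, dw_terminal_without_med = 0.6,
#'                      dw_terminal_with_med = 0.5)
#' derive_dw(inp, "breast", "I", treated = FALSE) # 0.3 * 0.6/0.5 = 0.36
derive_dw <- function(inputs, cancer, stage, treated,
                      frac_first_year = 0.5, frac_stoma = 0.05,
                      diag_weight_breast = 0.5,
                      frac_first_year_stage3 = frac_first_year) {
  stopifnot(inherits(inputs, "gcea_dw_inputs"),
            stage %in% c(STAGE_CHAIN[-5], "terminal"))
  if (stage == "terminal") {
    return(if (treated) inputs$dw_terminal_with_med
           else inputs$dw_terminal_without_med)
  }
  if (!treated) {
    ratio <- inputs$dw_terminal_without_med / inputs$dw_terminal_with_med
    return(min(1, inputs$dw_diagnosis * ratio))
  }
  dw <- switch(cancer,
    cervical = if (stage == "III") inputs$dw_diagnosis
               else inputs$dw_diagnosis * frac_first_year,
    breast = if (stage == "III") {
      inputs$dw_diagnosis * frac_first_year_stage3
    } else {
      (diag_weight_breast * inputs$dw_diagnosis +
         (1 - diag_weight_breast) * inputs$dw_mastectomy) * frac_first_year
    },
    colorectal = {
      f <- if (stage == "III") 1 else frac_first_year
      (1 - frac_stoma) * (inputs$dw_diagnosis * f) +
        frac_stoma * (inputs$dw_stoma + inputs$dw_diagnosis * f)
    },
    abort(sprintf("unknown cancer '%s'", cancer))
  )
  # treatment never worsens disability: the stoma add-on can nominally
  # exceed the untreated weight when the terminal-phase ratio is close
  # to 1, so treated weights are capped at the untreated derivation
  untreated <- min(1, inputs$dw_diagnosis *
                     inputs$dw_terminal_without_med /
                     inputs$dw_terminal_with_med)
  min(1, dw, untreated)
}

#' Disability-weight table for one cancer's states
#'
#' Expands the derivation rules over every state of a graph. States that
#' carry no cancer-related disability (healthy, immune, HPV infection,
#' precancer, undiagnosed preclinical disease) get weight 0; clinical
#' CIS-III are pre-terminal; clinical IV is the terminal phase.
#'
#' @param graph a `gcea_graph`.
#' @param inputs a `gcea_dw_inputs`.
#' @param ... derivation settings passed to [derive_dw()].
#' @return tibble (`state`, `dw_untreated`, `dw_treated`); treated weights
#'   never exceed untreated ones.
#' @export
disability_weight_table <- function(graph, inputs, ...) {
  cancer <- graph$cancer
  graph$states %>%
    filter(.data$category != "dead") %>%
    transmute(
      state = .data$name,
      stage = dplyr::if_else(.data$category == "clinical_cancer",
                             dplyr::if_else(.data$stage_label == "IV",
                                            "terminal", .data$stage_label),
                             NA_character_)
    ) %>%
    mutate(
      dw_untreated = purrr::map_dbl(.data$stage, function(s) {
        if (is.na(s)) 0 else derive_dw(inputs, cancer, s, FALSE, ...)
      }),
      dw_treated = purrr::map_dbl(.data$stage, function(s) {
        if (is.na(s)) 0 else derive_dw(inputs, cancer, s, TRUE, ...)
      })
    ) %>%
    select(-"stage")
}

#' Healthy life years of a trajectory
#'
#' HLYs are the sum of person-time in all states except death, each year
#' down-weighted by one minus the state's disability weight; the
#' discounted variant additionally multiplies year-`t` person-time by
#' `(1 + r)^-(t-1)` (programme year 1 is undiscounted). Totals are on the
#' scale of the simulated population (standardized to 10 million at
#' baseline by the region bundles).
#'
#' @param traj a `gcea_trajectory`.
#' @param dws effective weights: tibble (`state`, `dw`) covering every
#'   occupied non-dead state.
#' @param discount_rate annual discount rate (default 3%).
#' @return tibble with one row: `hly`, `hly_discounted`.
#' @export
healthy_life_years <- function(traj, dws, discount_rate = 0.03) {
  stopifnot(discount_rate >= 0)
  py <- apply(traj$occupancy, c(1, 4), sum) # state x year
  occupied <- traj$states[rowSums(py) > 0]
  miss <- setdiff(occupied, dws$state)
  if (length(miss)) {
    abort(paste0("missing disability weight for occupied state: ",
                 paste(miss, collapse = ", ")))
  }
  w <- dws$dw[match(traj$states, dws$state)]
  w[is.na(w)] <- 0
  if (any(w < 0 | w > 1)) abort("disability weights must lie in [0, 1]")
  healthy_py <- as.vector((1 - w) %*% py)
  disc <- (1 + discount_rate)^-(seq_len(traj$horizon) - 1)
  tibble(hly = sum(healthy_py), hly_discounted = sum(healthy_py * disc))
}
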