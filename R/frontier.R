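round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Average and incremental cost-effectiveness ratios
#'
#' League-table convention: costs are carried in million I$ and health
#' gains in HLYs, so `acer(cost, hly) = cost * 1e6 / hly`, rounded half-up
#' to an integer for league tables or to two decimals for programme
#' totals. The ICER divides incremental cost by incremental HLY relative
#' to the previous point on the expansion path; for the first step on an
#' arm it coincides with the ACER.
#'
#' @param cost_million total discounted cost in million I$.
#' @param hly healthy life years gained versus the null (undiscounted, the
#'   league-table convention).
#' @param digits rounding digits (0 for league tables, 2 for programme
#'   ACERs); `NA` skips rounding.
#' @return I$ per HLY gained.
#' @export
#' @examples
#' acer(396, 4541842) # 87
#' acer(146, 5215136) # 28
acer <- function(cost_million, hly, digits = 0) {
  if (any(hly <= 0)) abort("ACER needs a positive HLY gain")
  out <- cost_million * 1e6 / hly
  if (!is.na(digits)) out <- round_half_up(out, digits)
  out
}

#' @rdname acer
#' @param prev,next_ previous and next points: lists or one-row data
#'   frames with `cost` (million I$) and `hly` fields.
#' @return `icer()`: I$ per additional HLY; a non-positive incremental HLY
#'   returns `Inf` with a `dominated` attribute (dominance is handled by
#'   the caller, not an error).
#' @export
icer <- function(prev, next_, digits = 0) {
  d_cost <- next_$cost - prev$cost
  d_hly <- next_$hly - prev$hly
  if (d_hly <= 0) {
    return(structure(Inf, dominated = TRUE))
  }
  out <- d_cost * 1e6 / d_hly
  if (!is.na(digits)) out <- round_half_up(out, digits)
  out
}

#' Dominance filtering of (cost, effect) points
#'
#' Removes strictly dominated points (another point is at least as
#' effective and no more costly, with one inequality strict) and
#' extended-dominated points (a convex combination of two others
#' dominates), leaving the efficiency frontier sorted by effect with
#' non-decreasing ICERs.
#'
#' @param results tibble with `cost` (million I$) and `hly` columns; other
#'   columns are carried through.
#' @return list with `frontier` and `dominated` tibbles; `dominated`
#'   gains a `reason` column (`"dominated"` or `"extended"`).
#' @export
dominance_filter <- function(results) {
  results <- as_tibble(results)
  stopifnot(nrow(results) >= 1,
            all(c("cost", "hly") %in% names(results)))
  res <- results %>% mutate(.id = dplyr::row_number())
  strict <- purrr::map_lgl(seq_len(nrow(res)), function(i) {
    any(res$cost <= res$cost[i] & res$hly >= res$hly[i] &
          (res$cost < res$cost[i] | res$hly > res$hly[i]))
  })
  dominated <- res[strict, , drop = FALSE] %>% mutate(reason = "dominated")
  cand <- res[!strict, , drop = FALSE] %>%
    arrange(.data$hly, .data$cost)
  # iterative extended-dominance removal along the sorted candidates
  repeat {
    if (nrow(cand) < 3) break
    ic <- diff(cand$cost) / diff(cand$hly)
    bad <- which(diff(ic) < 0) + 1
    if (!length(bad)) break
    dominated <- bind_rows(dominated,
                           cand[bad[1], , drop = FALSE] %>%
                             mutate(reason = "extended"))
    cand <- cand[-bad[1], , drop = FALSE]
  }
  list(frontier = cand %>% select(-".id"),
       dominated = dominated %>% arrange(.data$.id) %>% select(-".id"))
}

# Technologies shared between menu items connect them into one "ladder"
# (e.g. vaccination alone and vaccination-plus-VIA); items on a ladder
# supersede each other under the lock-in rule, while separate ladders
# (treatment, palliative care) accumulate additively.
ladder_ids <- function(evals) {
  labs <- unique(evals$label)
  tech <- purrr::map(labs, function(l) {
    evals$technologies[[match(l, evals$label)]]
  })
  comp <- seq_along(labs)
  repeat {
    changed <- FALSE
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        if (comp[i] != comp[j] && length(intersect(tech[[i]], tech[[j]]))) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cancer <- evals$cancer[match(labs, evals$label)]
  stats::setNames(paste0(cancer, "_arm", match(comp, unique(comp))), labs)
}

#' Constrained expansion path over evaluated scenarios
#'
#' Walks the efficiency frontier under the programmatic lock-in
#' constraint: once a technology is adopted at some coverage, every later
#' point on its arm must retain it at the same or higher coverage. Within
#' an arm the walk greedily adopts the feasible menu item with the lowest
#' ICER versus the current point (ties broken towards the larger health
#' gain), then removes any step made extended-dominated by its successor
#' so ICERs are non-decreasing along each arm. Arms - connected groups of
#' interventions sharing a technology - are independent (disjoint states
#' and budgets) and are interleaved purely by ICER order.
#'
#' @param evals evaluation table: one row per (label, coverage) with
#'   columns `cancer`, `label`, `coverage`, `technologies` (list),
#'   `cost` (discounted million I$ vs null), `hly` (undiscounted HLY gain
#'   vs null); a null row is implicit at (0, 0).
#' @return a `gcea_path` tibble: ordered steps with incremental cost and
#'   HLY, ACER (vs null) and ICER (vs the previous point on the same
#'   arm).
#' @export
expansion_path <- function(evals) {
  evals <- as_tibble(evals) %>% filter(.data$hly > 0 | .data$cost > 0)
  if (!nrow(evals)) {
    return(structure(tibble(), class = c("gcea_path", "tbl_df", "tbl",
                                         "data.frame")))
  }
  arms <- ladder_ids(evals)
  evals$arm <- unname(arms[evals$label])

  arm_steps <- evals %>%
    group_by(.data$arm) %>%
    group_map(function(menu, key) {
      adopted <- stats::setNames(numeric(), character())
      cur <- list(cost = 0, hly = 0)
      steps <- list()
      repeat {
        feasible <- purrr::map_lgl(seq_len(nrow(menu)), function(i) {
          tech <- menu$technologies[[i]]
          all(names(adopted) %in% tech) &&
            (!length(adopted) || menu$coverage[i] >= max(adopted)) &&
            menu$hly[i] > cur$hly
        })
        if (!any(feasible)) break
        cand <- menu[feasible, , drop = FALSE]
        ic <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
          icer(cur, list(cost = cand$cost[i], hly = cand$hly[i]),
               digits = NA)
        })
        best <- which(ic <= min(ic) * 1.001 + 1e-12) # near-ties: largest gain
        best <- best[which.max(cand$hly[best])]
        pick <- cand[best, , drop = FALSE]
        steps <- c(steps, list(pick))
        adopted[pick$technologies[[1]]] <- pick$coverage
        cur <- list(cost = pick$cost, hly = pick$hly)
      }
      if (!length(steps)) return(NULL)
      out <- bind_rows(steps) %>% mutate(arm = key$arm)
      # drop steps made extended-dominated by their successor
      repeat {
        pts <- bind_rows(tibble(cost = 0, hly = 0),
                         out %>% select("cost", "hly"))
        ic <- diff(pts$cost) * 1e6 / diff(pts$hly)
        bad <- which(diff(ic) < 0)
        if (!length(bad)) break
        out <- out[-bad[1], , drop = FALSE]
      }
      out
    }) %>%
    purrr::compact() %>%
    bind_rows()

  if (!nrow(arm_steps)) {
    return(structure(tibble(), class = c("gcea_path", "tbl_df", "tbl",
                                         "data.frame")))
  }

  path <- arm_steps %>%
    group_by(.data$arm) %>%
    mutate(
      d_cost = .data$cost - dplyr::lag(.data$cost, default = 0),
      d_hly = .data$hly - dplyr::lag(.data$hly, default = 0),
      acer = acer(.data$cost, .data$hly),
      icer = round_half_up(.data$d_cost * 1e6 / .data$d_hly)
    ) %>%
    ungroup() %>%
    arrange(.data$icer, .data$arm) %>%
    mutate(rank = dplyr::row_number(), .before = 1)
  structure(path, class = c("gcea_path", "tbl_df", "tbl", "data.frame"))
}

#' Budget allocation across cancers at the end of the path
#'
#' Shares of total discounted cost by cancer once every arm has been
#' brought to full (95%) coverage. Each arm's final cost is its last
#' path step's scenario cost versus the null; arms within a cancer add.
#'
#' @param x a `gcea_path`, or a named numeric of total costs by cancer
#'   (any currency unit, e.g. the I$ totals of a published league table).
#' @param require_complete error unless every arm's final step is at 95%
#'   coverage.
#' @return tibble (`cancer`, `cost`, `share`): integer percent shares
#'   summing to 100 within rounding.
#' @export
budget_allocation <- function(x, require_complete = TRUE) {
  if (inherits(x, "gcea_path")) {
    finals <- x %>%
      group_by(.data$arm) %>%
      slice_tail(n = 1) %>%
      ungroup()
    if (require_complete && any(finals$coverage < 0.95)) {
      abort("expansion path incomplete: an arm ends below 95% coverage")
    }
    costs <- finals %>%
      group_by(.data$cancer) %>%
      summarise(cost = sum(.data$cost), .groups = "drop")
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    costs <- tibble(cancer = names(x), cost = unname(x))
  }
  costs %>%
    mutate(share = round_half_up(100 * .data$cost / sum(.data$cost)))
}

#' League tables in path order
#'
#' @param evals the evaluation table passed to [expansion_path()].
#' @param path the resulting `gcea_path`.
#' @return list of two tibbles: `path` rows (label, description if
#'   present, coverage, cost, HLY, ACER, ICER) in expansion-path order,
#'   and `dominated` - evaluated (label, coverage) points that never enter
#'   the path.
#' @export
league_table <- function(evals, path = expansion_path(evals)) {
  if (!nrow(path)) {
    return(list(path = tibble(), dominated = as_tibble(evals)))
  }
  keep <- intersect(c("rank", "cancer", "label", "description", "coverage",
                      "cost", "hly", "acer", "icer"), names(path))
  on_path <- paste(path$label, path$coverage)
  dominated <- as_tibble(evals) %>%
    filter(!paste(.data$label, .data$coverage) %in% on_path) %>%
    mutate(acer = dplyr::if_else(.data$hly > 0,
                                 round_half_up(.data$cost * 1e6 / .data$hly),
                                 NA_real_)) %>%
    select(dplyr::any_of(c("cancer", "label", "description", "coverage",
                           "cost", "hly", "acer")))
  list(path = path %>% select(dplyr::all_of(keep)), dominated = dominated)
}

#' @export
print.gcea_path <- function(x, ...) {
  cat(sprintf("<gcea_path> %d steps across %d arm(s)\n", nrow(x),
              dplyr::n_distinct(x$arm)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gcea_path
#' @export
tidy.gcea_path <- function(x, ...) {
  as_tibble(x) %>%
    select(dplyr::any_of(c("rank", "arm", "cancer", "label", "coverage",
                           "cost", "hly", "d_cost", "d_hly", "acer",
                           "icer")))
}

#' @method glance gcea_path
#' @export
glance.gcea_path <- function(x, ...) {
  finals <- as_tibble(x) %>%
    group_by(.data$arm) %>%
    slice_tail(n = 1) %>%
    ungroup()
  tibble(
    n_steps = nrow(x), n_arms = dplyr::n_distinct(x$arm),
    total_cost = sum(finals$cost), total_hly = sum(finals$hly),
    programme_acer = round_half_up(sum(finals$cost) * 1e6 /
                                     sum(finals$hly), 2)
  )
}

#' Expansion-path figure
#'
#' Cumulative discounted cost against cumulative healthy life years
#' gained, one point per adopted step, labelled by intervention and
#' coverage.
#'
#' @param object a `gcea_path`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gcea_path
#' @export
autoplot.gcea_path <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(cum_cost = cumsum(.data$d_cost), cum_hly = cumsum(.data$d_hly),
           step = paste0(.data$label, "@", 100 * .data$coverage, "%"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cum_hly, .data$cum_cost)) +
    ggplot2::geom_step(direction = "vh", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cancer), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$step), hjust = -0.1,
                       vjust = 1.1, size = 2.8, check_overlap = TRUE) +
    ggplot2::labs(x = "Healthy life years gained (cumulative)",
                  y = "Discounted cost, million I$ (cumulative)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
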