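#' @importFrom rlang .data %||% abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

CANCERS <- c("cervical", "breast", "colorectal")
STAGE_CHAIN <- c("CIS", "I", "II", "III", "IV")
HPV_GROUPS <- c("HPV_16_18", "HPV_high_risk", "HPV_low_risk")
STATE_CATEGORIES <- c(
  "healthy", "infection", "precancer", "preclinical_cancer",
  "clinical_cancer", "immune", "dead"
)
EDGE_KINDS <- c(
  "onset", "progression", "regression", "diagnosis", "mortality",
  "clearance", "waning_immunity"
)

new_state_graph <- function(cancer, states, edges, route_split = NULL) {
  states <- as_tibble(states)
  edges <- as_tibble(edges)
  stopifnot(
    all(c("name", "cancer", "category", "stage_label") %in% names(states)),
    all(c("from", "to", "kind") %in% names(edges))
  )
  structure(
    list(cancer = cancer, states = states, edges = edges,
         route_split = route_split),
    class = "gcea_graph"
  )
}

state_row <- function(name, cancer, category, stage_label = NA_character_) {
  tibble(name = name, cancer = cancer, category = category,
         stage_label = stage_label)
}

cancer_stage_states <- function(cancer) {
  bind_rows(
    tibble(name = paste0("preclinical_", STAGE_CHAIN), cancer = cancer,
           category = "preclinical_cancer", stage_label = STAGE_CHAIN),
    tibble(name = paste0("clinical_", STAGE_CHAIN), cancer = cancer,
           category = "clinical_cancer", stage_label = STAGE_CHAIN)
  )
}

stage_chain_edges <- function() {
  pre <- paste0("preclinical_", STAGE_CHAIN)
  cli <- paste0("clinical_", STAGE_CHAIN)
  bind_rows(
    tibble(from = pre[-5], to = pre[-1], kind = "progression"),
    tibble(from = cli[-5], to = cli[-1], kind = "progression"),
    tibble(from = pre, to = cli, kind = "diagnosis")
  )
}

mortality_edges <- function(states) {
  alive <- states$name[states$category != "dead"]
  tibble(from = alive, to = "dead", kind = "mortality")
}

#' Cervical cancer natural-history state graph
#'
#' Builds the full female cervical model: healthy, three HPV infection
#' groups (16/18, other high-risk, low-risk), CIN1 and CIN2-3 precancer
#' states, preclinical and clinical carcinoma stages CIS-IV, a short-term
#' immune state on the regression path, and an absorbing dead state.
#' Regression is modelled only for pre-cancerous states (CIN back to HPV,
#' HPV cleared to immune, immunity waning back to healthy); diagnosis edges
#' link each preclinical stage to its clinical twin. Men share this state
#' space structurally but their CIN-progression rates are zero (see
#' [build_male_hpv_graph()]), so they contribute to HPV transmission but
#' never to cancer incidence.
#'
#' @return A `gcea_graph` object with `$states` and `$edges` tibbles.
#' @seealso [validate_graph()], [build_breast_graph()],
#'   [build_colorectal_graph()]
#' @export
#' @examples
#' g <- build_cervical_graph()
#' validate_graph(g)
build_cervical_graph <- function() {
  states <- bind_rows(
    state_row("healthy", "shared", "healthy"),
    tibble(name = HPV_GROUPS, cancer = "cervical", category = "infection",
           stage_label = HPV_GROUPS),
    state_row("CIN1", "cervical", "precancer", "CIN1"),
    state_row("CIN2_3", "cervical", "precancer", "CIN2-3"),
    cancer_stage_states("cervical"),
    state_row("immune", "shared", "immune"),
    state_row("dead", "shared", "dead")
  )
  edges <- bind_rows(
    tibble(from = "healthy", to = HPV_GROUPS, kind = "onset"),
    tibble(from = HPV_GROUPS, to = "CIN1", kind = "progression"),
    tibble(from = "CIN1", to = "CIN2_3", kind = "progression"),
    tibble(from = "CIN2_3", to = "preclinical_CIS", kind = "progression"),
    stage_chain_edges(),
    tibble(from = "CIN2_3", to = "CIN1", kind = "regression"),
    tibble(from = "CIN1", to = HPV_GROUPS, kind = "regression"),
    tibble(from = "CIN2_3", to = HPV_GROUPS, kind = "regression"),
    tibble(from = HPV_GROUPS, to = "immune", kind = "clearance"),
    tibble(from = "immune", to = "healthy", kind = "waning_immunity"),
    mortality_edges(states)
  )
  new_state_graph("cervical", states, edges)
}

#' Male HPV-infection sub-model
#'
#' Reduced graph for men: healthy, the three HPV infection states, immune,
#' and dead, with infection (onset), natural clearance, waning immunity and
#' mortality edges only. HPV-related cancers are not modelled in men; the
#' male population matters solely as the opposite-sex reservoir of the
#' transmission model.
#'
#' @return A `gcea_graph`.
#' @export
build_male_hpv_graph <- function() {
  states <- bind_rows(
    state_row("healthy", "shared", "healthy"),
    tibble(name = HPV_GROUPS, cancer = "cervical", category = "infection",
           stage_label = HPV_GROUPS),
    state_row("immune", "shared", "immune"),
    state_row("dead", "shared", "dead")
  )
  edges <- bind_rows(
    tibble(from = "healthy", to = HPV_GROUPS, kind = "onset"),
    tibble(from = HPV_GROUPS, to = "immune", kind = "clearance"),
    tibble(from = "immune", to = "healthy", kind = "waning_immunity"),
    mortality_edges(states)
  )
  new_state_graph("cervical_male", states, edges)
}

#' Breast cancer natural-history state graph
#'
#' Breast cancer initiates directly as carcinoma in situ: healthy women
#' transition to preclinical CIS and progress through invasive stages I-IV,
#' with diagnosis edges from every preclinical stage to its clinical twin.
#' There are no precancer states and no regression out of cancer states.
#'
#' @return A `gcea_graph`.
#' @export
build_breast_graph <- function() {
  states <- bind_rows(
    state_row("healthy", "shared", "healthy"),
    cancer_stage_states("breast"),
    state_row("dead", "shared", "dead")
  )
  edges <- bind_rows(
    tibble(from = "healthy", to = "preclinical_CIS", kind = "onset"),
    stage_chain_edges(),
    mortality_edges(states)
  )
  new_state_graph("breast", states, edges)
}

#' Colorectal cancer natural-history state graph
#'
#' Two onset routes from healthy: an adenoma route through three polyp-size
#' precancer classes (<= 5 mm, 6-9 mm, >= 10 mm) culminating in preclinical
#' CIS, and a de-novo route directly to preclinical CIS. The split of onset
#' rate mass between the two routes is parameterized (default 77% adenoma /
#' 23% de novo). Small polyps may regress to healthy and medium polyps to
#' small (regression is allowed only for pre-cancerous states).
#'
#' @param route_split length-2 numeric summing to 1: fraction of onset rate
#'   mass entering via polyps vs de novo.
#' @return A `gcea_graph`; the split is stored in `$route_split` and used
#'   by the rate generator, since graph edges carry no rates.
#' @export
build_colorectal_graph <- function(route_split = c(0.77, 0.23)) {
  stopifnot(length(route_split) == 2, all(route_split >= 0),
            abs(sum(route_split) - 1) < 1e-9)
  polyps <- c("polyp_small", "polyp_medium", "polyp_large")
  states <- bind_rows(
    state_row("healthy", "shared", "healthy"),
    tibble(name = polyps, cancer = "colorectal", category = "precancer",
           stage_label = polyps),
    cancer_stage_states("colorectal"),
    state_row("dead", "shared", "dead")
  )
  edges <- bind_rows(
    tibble(from = "healthy", to = c("polyp_small", "preclinical_CIS"),
           kind = "onset"),
    tibble(from = polyps[-3], to = polyps[-1], kind = "progression"),
    tibble(from = "polyp_large", to = "preclinical_CIS", kind = "progression"),
    tibble(from = "polyp_medium", to = "polyp_small", kind = "regression"),
    tibble(from = "polyp_small", to = "healthy", kind = "regression"),
    stage_chain_edges(),
    mortality_edges(states)
  )
  new_state_graph("colorectal", states, edges, route_split = route_split)
}

#' Validate a natural-history state graph
#'
#' Checks the structural invariants every model graph must satisfy and
#' returns violations as messages rather than raising, so defective graphs
#' can be inspected.
#'
#' Invariants: exactly one absorbing dead state; stage labels present
#' exactly on infection/precancer/preclinical/clinical states; every
#' non-dead state has a mortality edge; diagnosis edges connect only a
#' preclinical stage to its clinical twin; regression never originates from
#' a preclinical or clinical cancer state; progression between carcinoma
#' stages moves exactly one step along CIS-I-II-III-IV; dead is reachable
#' from every state, and clinical stage IV from healthy (in graphs that
#' model cancer).
#'
#' @param graph a `gcea_graph`.
#' @return character vector of violation messages; empty if valid.
#' @export
validate_graph <- function(graph) {
  v <- character()
  st <- graph$states
  ed <- graph$edges

  bad_ref <- setdiff(unique(c(ed$from, ed$to)), st$name)
  if (length(bad_ref)) {
    v <- c(v, paste0("edge references unknown state: ",
                     paste(bad_ref, collapse = ", ")))
  }

  dead <- st$name[st$category == "dead"]
  if (length(dead) != 1) {
    v <- c(v, sprintf("graph must have exactly one dead state, found %d",
                      length(dead)))
  } else {
    out_of_dead <- ed %>% filter(.data$from == dead, .data$to != dead)
    if (nrow(out_of_dead)) {
      v <- c(v, sprintf("dead state is not absorbing: edge %s -> %s",
                        out_of_dead$from[1], out_of_dead$to[1]))
    }
  }

  need_label <- st$category %in% c("infection", "precancer",
                                   "preclinical_cancer", "clinical_cancer")
  miss <- st$name[need_label & is.na(st$stage_label)]
  extra <- st$name[!need_label & !is.na(st$stage_label)]
  if (length(miss)) {
    v <- c(v, paste0("missing stage_label: ", paste(miss, collapse = ", ")))
  }
  if (length(extra)) {
    v <- c(v, paste0("stage_label not allowed on: ",
                     paste(extra, collapse = ", ")))
  }

  alive <- st$name[st$category != "dead"]
  has_mort <- ed$from[ed$kind == "mortality"]
  no_mort <- setdiff(alive, has_mort)
  if (length(no_mort)) {
    v <- c(v, paste0("state lacks a mortality edge: ",
                     paste(no_mort, collapse = ", ")))
  }

  cat_of <- stats::setNames(st$category, st$name)
  lab_of <- stats::setNames(st$stage_label, st$name)
  diag <- ed %>% filter(.data$kind == "diagnosis")
  bad_diag <- diag %>% filter(
    cat_of[.data$from] != "preclinical_cancer" |
      cat_of[.data$to] != "clinical_cancer" |
      lab_of[.data$from] != lab_of[.data$to]
  )
  if (nrow(bad_diag)) {
    v <- c(v, sprintf(
      "diagnosis edge must link preclinical to clinical of the same stage: %s -> %s",
      bad_diag$from[1], bad_diag$to[1]))
  }

  regr <- ed %>% filter(.data$kind == "regression")
  bad_regr <- regr %>%
    filter(cat_of[.data$from] %in% c("preclinical_cancer", "clinical_cancer"))
  if (nrow(bad_regr)) {
    v <- c(v, sprintf("regression edge out of a cancer state: %s -> %s",
                      bad_regr$from[1], bad_regr$to[1]))
  }

  stage_idx <- stats::setNames(seq_along(STAGE_CHAIN), STAGE_CHAIN)
  prog <- ed %>% filter(.data$kind == "progression")
  both_staged <- prog %>% filter(
    cat_of[.data$from] %in% c("preclinical_cancer", "clinical_cancer"),
    cat_of[.data$to] %in% c("preclinical_cancer", "clinical_cancer")
  )
  if (nrow(both_staged)) {
    step <- stage_idx[lab_of[both_staged$to]] - stage_idx[lab_of[both_staged$from]]
    same_side <- cat_of[both_staged$from] == cat_of[both_staged$to]
    bad <- both_staged[!(same_side & step == 1), , drop = FALSE]
    if (nrow(bad)) {
      v <- c(v, sprintf("stage progression must advance one step: %s -> %s",
                        bad$from[1], bad$to[1]))
    }
  }

  if (length(dead) == 1) {
    reach_dead <- reachable_from(ed, dead, reverse = TRUE)
    cant_die <- setdiff(st$name, reach_dead)
    if (length(cant_die)) {
      v <- c(v, paste0("dead not reachable from: ",
                       paste(cant_die, collapse = ", ")))
    }
  }
  if ("clinical_IV" %in% st$name) {
    fwd <- reachable_from(ed, "healthy", reverse = FALSE)
    if (!"clinical_IV" %in% fwd) {
      v <- c(v, "clinical_IV not reachable from healthy")
    }
  }
  v
}

reachable_from <- function(edges, start, reverse = FALSE) {
  adj <- if (reverse) split(edges$from, edges$to) else split(edges$to, edges$from)
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' @export
print.gcea_graph <- function(x, ...) {
  cat(sprintf("<gcea_graph: %s>  %d states, %d edges\n",
              x$cancer, nrow(x$states), nrow(x$edges)))
  print(count(x$states, .data$category))
  invisible(x)
}

#' Tidy edge list of a state graph
#'
#' One row per edge, with the categories of both endpoints.
#' @param x a `gcea_graph`.
#' @param ... unused.
#' @method as_tibble gcea_graph
#' @export
as_tibble.gcea_graph <- function(x, ...) {
  cat_of <- stats::setNames(x$states$category, x$states$name)
  x$edges %>%
    mutate(from_category = unname(cat_of[.data$from]),
           to_category = unname(cat_of[.data$to]),
           cancer = x$cancer, .before = 1) %>%
    relocate("from", "to", "kind")
}

#' Serialize a state graph to structured text or DOT
#'
#' @param graph a `gcea_graph`.
#' @param path file to write; for `graph_to_dot` the DOT source is returned
#'   as a string.
#' @return `write_state_graph` returns `path` invisibly; `read_state_graph`
#'   a `gcea_graph`; `graph_to_dot` a character scalar.
#' @export
write_state_graph <- function(graph, path) {
  yaml::write_yaml(list(
    cancer = graph$cancer,
    route_split = graph$route_split,
    states = purrr::transpose(as.list(graph$states)),
    edges = purrr::transpose(as.list(graph$edges))
  ), path)
  invisible(path)
}

#' @rdname write_state_graph
#' @export
read_state_graph <- function(path) {
  doc <- yaml::read_yaml(path)
  tidy_rows <- function(rows) {
    bind_rows(lapply(rows, function(r) {
      as_tibble(lapply(r, function(f) if (is.null(f)) NA_character_ else f))
    }))
  }
  new_state_graph(doc$cancer, tidy_rows(doc$states), tidy_rows(doc$edges),
                  route_split = unlist(doc$route_split))
}

#' @rdname write_state_graph
#' @export
graph_to_dot <- function(graph) {
  shape <- c(healthy = "oval", infection = "box", precancer = "box",
             preclinical_cancer = "box", clinical_cancer = "box",
             immune = "oval", dead = "doublecircle")
  nodes <- sprintf('  "%s" [shape=%s];', graph$states$name,
                   shape[graph$states$category])
  arcs <- sprintf('  "%s" -> "%s" [label="%s"];',
                  graph$edges$from, graph$edges$to, graph$edges$kind)
  paste(c(sprintf("digraph %s {", graph$cancer), nodes, arcs, "}"),
        collapse = "\n")
}
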