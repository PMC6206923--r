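# Brute-force dominance oracle: strict dominance by pairwise comparison,
# extended dominance by the chord definition (a point is removed if some
# convex combination of two other undominated points is cheaper at its
# effectiveness level).
oracle_frontier <- function(pts) {
  n <- nrow(pts)
  strict <- sapply(seq_len(n), function(i) {
    any(pts$cost <= pts$cost[i] & pts$hly >= pts$hly[i] &
          (pts$cost < pts$cost[i] | pts$hly > pts$hly[i]))
  })
  cand <- pts[!strict, , drop = FALSE]
  m <- nrow(cand)
  ext <- sapply(seq_len(m), function(i) {
    for (j in seq_len(m)) {
      for (k in seq_len(m)) {
        if (j == i || k == i || cand$hly[j] >= cand$hly[k]) next
        if (cand$hly[j] <= cand$hly[i] && cand$hly[i] <= cand$hly[k]) {
          w <- (cand$hly[i] - cand$hly[j]) / (cand$hly[k] - cand$hly[j])
          mix_cost <- (1 - w) * cand$cost[j] + w * cand$cost[k]
          if (mix_cost < cand$cost[i] - 1e-9) return(TRUE)
        }
      }
    }
    FALSE
  })
  cand[!ext, , drop = FALSE]
}


menu_row <- function(label, coverage, cost, hly, tech, cancer = "cervical") {
  tibble::tibble(cancer = cancer, label = label, coverage = coverage,
                 cost = cost, hly = hly, technologies = list(tech))
}


# Exhaustive oracle: every maximal lock-in-respecting adoption sequence,
# keep those with non-decreasing ICERs, choose the lexicographically
# smallest ICER sequence.
oracle_path <- function(menu) {
  feasible <- function(adopted_tech, adopted_cov, cur_hly, i) {
    all(adopted_tech %in% menu$technologies[[i]]) &&
      (length(adopted_cov) == 0 || menu$coverage[i] >= max(adopted_cov)) &&
      menu$hly[i] > cur_hly
  }
  seqs <- list()
  recurse <- function(order, tech, cov, cost, hly, icers) {
    cand <- Filter(function(i) feasible(tech, cov, hly, i),
                   seq_len(nrow(menu)))
    if (!length(cand)) {
      seqs[[length(seqs) + 1]] <<- list(order = order, icers = icers)
      return(invisible())
    }
    for (i in cand) {
      recurse(c(order, i), union(tech, menu$technologies[[i]]),
              c(cov, menu$coverage[i]), menu$cost[i], menu$hly[i],
              c(icers, (menu$cost[i] - cost) * 1e6 / (menu$hly[i] - hly)))
    }
  }
  recurse(integer(), character(), numeric(), 0, 0, numeric())
  ok <- Filter(function(s) all(diff(s$icers) >= -1e-9), seqs)
  lex_less <- function(a, b) {
    for (i in seq_len(min(length(a), length(b)))) {
      if (a[i] < b[i] - 1e-9) return(TRUE)
      if (a[i] > b[i] + 1e-9) return(FALSE)
    }
    length(a) > length(b)
  }
  best <- ok[[1]]
  for (s in ok[-1]) if (lex_less(s$icers, best$icers)) best <- s
  menu[best$order, c("label", "coverage")]
}

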