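# Independent oracles and hand-computed reference values.

# Brute-force recursive evaluation of a network's rules: the state of
# (region, timepoint) is defined recursively from the initial condition,
# with no iteration, memoisation, or shared machinery with the engine.
oracle_state <- function(network, genotype, region, timepoint) {
  facs <- network$factors$factor
  ins <- network$factors$factor[network$factors$role == "input"]
  outs <- setdiff(facs, ins)
  clamped <- network$genotypes[[genotype]]
  sched <- function(t) {
    sub <- network$schedule[network$schedule$region == region &
                              network$schedule$timepoint == t, ]
    setNames(as.integer(sub$level), sub$factor)
  }
  if (timepoint == 0L) {
    s <- setNames(integer(length(facs)), facs)
    s[names(network$initial)] <- as.integer(network$initial)
    s[names(sched(0L))] <- sched(0L)[names(sched(0L))]
  } else {
    prev <- oracle_state(network, genotype, region, timepoint - 1L)
    s <- setNames(integer(length(facs)), facs)
    for (f in outs) s[[f]] <- as.integer(network$rules[[f]](prev))
    sc <- sched(timepoint)
    s[names(sc)] <- sc
  }
  s[intersect(clamped, facs)] <- 0L
  s
}

oracle_trajectory <- function(network, genotype) {
  R <- max(network$schedule$region)
  Tn <- max(network$schedule$timepoint) + 1L
  facs <- network$factors$factor
  do.call(rbind, lapply(seq_len(R), function(r) {
    do.call(rbind, lapply(0:(Tn - 1L), function(t) {
      s <- oracle_state(network, genotype, r, t)
      data.frame(genotype = genotype, region = r, timepoint = t,
                 factor = facs, level = unname(s[facs]),
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Random threshold-logic network over <= 3 output factors, for the
# engine-vs-oracle equivalence property.
random_network <- function(n_outputs = 2L, n_regions = 2L,
                           n_timepoints = 4L) {
  outs <- paste0("G", seq_len(n_outputs))
  facs <- c("In1", outs)
  max_lv <- setNames(sample(1:2, length(facs), replace = TRUE), facs)
  factors <- tibble::tibble(
    factor = facs,
    max_level = as.integer(max_lv[facs]),
    role = c("input", rep("output", n_outputs))
  )
  # Each output: thresholded sum of random signed inputs.
  rules <- setNames(lapply(outs, function(f) {
    w <- setNames(sample(-1:1, length(facs), replace = TRUE), facs)
    cap <- max_lv[[f]]
    function(s) {
      v <- sum(w * s[facs])
      as.integer(max(0L, min(cap, v)))
    }
  }), outs)
  schedule <- tidyr::expand_grid(factor = "In1",
                                 region = seq_len(n_regions),
                                 timepoint = 0:(n_timepoints - 1L))
  schedule$level <- sample(0:max_lv[["In1"]], nrow(schedule),
                           replace = TRUE)
  init <- setNames(sample(0:1, n_outputs, replace = TRUE), outs)
  new_network(
    factors = factors, rules = rules, schedule = schedule,
    initial = init,
    genotypes = list(wt = character(),
                     ko = sample(outs, 1L)),
    name = "random"
  )
}

# Hand-iterated level time courses for the canonical terminal network
# (worked by applying the reference rules on paper, independently of the
# engine). Rows: factor; columns t0..t3.
reference_series <- list(
  wt = list(
    `1` = list(Cad = c(1, 1, 0, 0), D = c(0, 2, 2, 0),
               Opa = c(0, 1, 2, 2), Fkh = c(0, 0, 0, 0),
               Wg = c(0, 0, 0, 0)),
    `2` = list(Cad = c(1, 1, 1, 1), D = c(0, 0, 0, 2),
               Opa = c(0, 0, 0, 1), Fkh = c(0, 0, 0, 0),
               Wg = c(0, 0, 0, 0)),
    `3` = list(Cad = c(1, 0, 0, 0), D = c(0, 0, 0, 0),
               Opa = c(0, 0, 0, 0), Fkh = c(0, 1, 1, 1),
               Wg = c(0, 0, 1, 1)),
    `4` = list(Cad = c(1, 0, 0, 0), D = c(0, 0, 0, 0),
               Opa = c(0, 0, 0, 0), Fkh = c(0, 1, 1, 1),
               Wg = c(0, 0, 0, 0))
  ),
  `D-` = list(
    `1` = list(Cad = c(1, 1, 1, 0), D = c(0, 0, 0, 0),
               Opa = c(0, 1, 2, 2))
  ),
  `opa-` = list(
    `1` = list(Cad = c(1, 1, 0, 0), D = c(0, 2, 2, 1))
  ),
  `cad-` = list(
    `1` = list(D = c(0, 1, 1, 0), Opa = c(0, 1, 2, 2))
  ),
  `tll-` = list(
    `3` = list(Cad = c(1, 1, 1, 0), D = c(0, 0, 0, 0),
               Opa = c(0, 1, 2, 2))
  ),
  `tll-opa-` = list(
    `3` = list(Cad = c(1, 1, 1, 1), D = c(0, 0, 0, 2))
  )
)

get_series <- function(trajectory, genotype, region, fac) {
  sub <- trajectory[trajectory$genotype == genotype &
                      trajectory$region == region &
                      as.character(trajectory$factor) == fac, ]
  sub$level[order(sub$timepoint)]
}
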