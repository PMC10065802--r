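#' Construct a logical network
#'
#' A `timer_network` bundles everything the synchronous simulator needs:
#' a factor registry, per-output update rules, hard-coded input schedules,
#' an initial condition, and a catalogue of genotypes defined by clamps.
#' Factors are ordinal logical variables taking levels `0..max_level`
#' (0 = off, 1 = weak/on, 2 = strong). Input factors follow their schedule
#' and have no rule; output factors have exactly one rule each.
#'
#' @param factors Tibble/data frame with columns `factor` (character),
#'   `max_level` (1 or 2), and `role` (`"input"` or `"output"`).
#' @param rules Named list of update functions, one per output factor.
#'   Each rule receives the complete predecessor state (a named integer
#'   vector over all factors) and returns a single level.
#' @param schedule Long tibble of hard-coded input levels with columns
#'   `factor`, `region`, `timepoint`, `level`. Regions are `1..R`,
#'   timepoints `0..T-1`; the grid must be complete for every input factor.
#' @param initial Named integer vector giving the level of every output
#'   factor at timepoint 0 (inputs take their scheduled t0 level).
#' @param genotypes Named list; each element is a character vector of
#'   factor names clamped to level 0 throughout the simulation. Must
#'   contain an entry for wild type (an empty clamp set).
#' @param interactions Optional tibble of annotated pairwise interactions
#'   (metadata; the rules encode the functional logic). May be `NULL`.
#' @param name Short identifier for the network, used in output headers.
#'
#' @return An object of class `timer_network`.
#' @seealso [terminal_network()], [simulate_genotype()], [validate_network()]
#' @export
new_network <- function(factors, rules, schedule, initial, genotypes,
                        interactions = NULL, name = "network") {
  net <- structure(
    list(
      factors      = tibble::as_tibble(factors),
      rules        = rules,
      schedule     = tibble::as_tibble(schedule),
      initial      = initial,
      genotypes    = genotypes,
      interactions = if (is.null(interactions)) NULL else tibble::as_tibble(interactions),
      name         = name
    ),
    class = "timer_network"
  )
  net
}

#' @export
print.timer_network <- function(x, ...) {
  n_in  <- sum(x$factors$role == "input")
  n_out <- sum(x$factors$role == "output")
  cat("<timer_network> ", x$name, "\n", sep = "")
  cat("  factors:   ", nrow(x$factors), " (", n_out, " output, ", n_in,
      " input)\n", sep = "")
  cat("  regions:   ", n_regions(x), "\n", sep = "")
  cat("  timepoints:", n_timepoints(x), "\n")
  cat("  genotypes: ", paste(names(x$genotypes), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$interactions)) {
    cat("  interactions:", nrow(x$interactions), "\n")
  }
  invisible(x)
}

input_factors <- function(network) {
  network$factors$factor[network$factors$role == "input"]
}

output_factors <- function(network) {
  network$factors$factor[network$factors$role == "output"]
}

n_regions <- function(network) {
  if (nrow(network$schedule) == 0L) 1L else max(network$schedule$region)
}

n_timepoints <- function(network) {
  if (nrow(network$schedule) == 0L) 1L else max(network$schedule$timepoint) + 1L
}

max_levels <- function(network) {
  setNames(as.integer(network$factors$max_level), network$factors$factor)
}

#' Look up clamped factors for a genotype
#' @noRd
genotype_clamps <- function(network, genotype) {
  if (!genotype %in% names(network$genotypes)) {
    abort(paste0(
      "Unknown genotype '", genotype, "'. Available genotypes: ",
      paste(names(network$genotypes), collapse = ", ")
    ))
  }
  network$genotypes[[genotype]]
}

#' Scheduled input levels for one region and timepoint
#' @noRd
scheduled_inputs <- function(network, region, timepoint) {
  sub <- network$schedule[network$schedule$region == region &
                            network$schedule$timepoint == timepoint, ]
  setNames(as.integer(sub$level), sub$factor)[input_factors(network)]
}

#' Advance a state by one synchronous update
#'
#' Applies every output factor's rule to the predecessor state, sets input
#' factors to their scheduled levels, and finally forces any clamped factor
#' to 0. Clamping wins over both rules and schedules, so a null mutant
#' never expresses the clamped factor at any timepoint.
#'
#' @param network A `timer_network`.
#' @param state Named integer vector with one level per registered factor
#'   (the predecessor state).
#' @param inputs Named integer vector of scheduled levels for every input
#'   factor at the target timepoint.
#' @param genotype Genotype name from the network's catalogue
#'   (default wild type, `"wt"`).
#'
#' @return Named integer vector: the successor state.
#' @examples
#' net <- terminal_network()
#' s0 <- c(Cad = 1L, D = 0L, Opa = 0L, Fkh = 0L, Wg = 0L, Tll = 0L, Hkb = 0L)
#' advance_state(net, s0, inputs = c(Tll = 0L, Hkb = 0L))
#' @export
advance_state <- function(network, state, inputs, genotype = "wt") {
  stopifnot(inherits(network, "timer_network"))
  facs <- network$factors$factor
  missing_state <- setdiff(facs, names(state))
  if (length(missing_state) > 0L) {
    abort(paste0("State is missing factor(s): ",
                 paste(missing_state, collapse = ", ")))
  }
  ins <- input_factors(network)
  missing_in <- setdiff(ins, names(inputs))
  if (length(missing_in) > 0L) {
    abort(paste0("Input schedule is missing factor(s): ",
                 paste(missing_in, collapse = ", ")))
  }
  clamped <- genotype_clamps(network, genotype)

  nxt <- setNames(integer(length(facs)), facs)
  for (f in output_factors(network)) {
    nxt[[f]] <- as.integer(network$rules[[f]](state))
  }
  for (f in ins) {
    nxt[[f]] <- as.integer(inputs[[f]])
  }
  nxt[intersect(clamped, facs)] <- 0L
  nxt
}

#' Initial state of a simulation
#' @noRd
initial_state <- function(network, region, genotype) {
  facs <- network$factors$factor
  s <- setNames(integer(length(facs)), facs)
  s[names(network$initial)] <- as.integer(network$initial)
  ins <- scheduled_inputs(network, region, 0L)
  s[names(ins)] <- ins
  s[intersect(genotype_clamps(network, genotype), facs)] <- 0L
  s
}

#' Human-readable label for an ordinal level
#'
#' Mirrors the off/weak/strong vocabulary used for ternary factors; binary
#' factors are labelled off/on.
#'
#' @param level Integer level(s), `0..max_level`.
#' @param max_level 1 (binary factor) or 2 (ternary factor); recycled.
#' @return Character vector of labels.
#' @examples
#' level_label(c(0, 1, 2), 2)
#' level_label(1, 1)
#' @export
level_label <- function(level, max_level) {
  n <- max(length(level), length(max_level))
  level <- rep_len(as.integer(level), n)
  max_level <- rep_len(as.integer(max_level), n)
  dplyr::case_when(
    level == 0L ~ "off",
    max_level == 1L ~ "on",
    level == 1L ~ "weak",
    TRUE ~ "strong"
  )
}

#' Simulate one genotype
#'
#' Runs the synchronous simulation for every region of the network:
#' timepoint 0 is the network's initial condition (with clamps applied),
#' and each later timepoint is derived from its predecessor by
#' [advance_state()] alone. Regions are independent; there is no spatial
#' coupling.
#'
#' @param network A `timer_network`.
#' @param genotype Genotype name from the network's catalogue.
#'
#' @return A tibble with columns `genotype`, `region`, `timepoint`,
#'   `factor`, `level`, `label`, one row per (region, timepoint, factor).
#' @examples
#' traj <- simulate_genotype(terminal_network(), "wt")
#' dplyr::filter(traj, region == 1, factor == "Cad")
#' @export
simulate_genotype <- function(network, genotype = "wt") {
  stopifnot(inherits(network, "timer_network"))
  genotype_clamps(network, genotype)  # validates the name
  R <- n_regions(network)
  Tn <- n_timepoints(network)
  facs <- network$factors$factor
  ml <- max_levels(network)

  rows <- vector("list", R)
  for (r in seq_len(R)) {
    states <- matrix(0L, nrow = Tn, ncol = length(facs),
                     dimnames = list(NULL, facs))
    s <- initial_state(network, r, genotype)
    states[1L, ] <- s[facs]
    if (Tn > 1L) {
      for (t in seq_len(Tn - 1L)) {
        s <- advance_state(network, s, scheduled_inputs(network, r, t),
                           genotype)
        states[t + 1L, ] <- s[facs]
      }
    }
    rows[[r]] <- tibble::tibble(
      genotype  = genotype,
      region    = r,
      timepoint = rep(0:(Tn - 1L), times = length(facs)),
      factor    = rep(facs, each = Tn),
      level     = as.integer(states[cbind(
        rep(seq_len(Tn), times = length(facs)),
        rep(seq_along(facs), each = Tn))])
    )
  }
  out <- dplyr::bind_rows(rows)
  out$label <- level_label(out$level, ml[out$factor])
  out$factor <- factor(out$factor, levels = facs)
  out
}

#' Simulate several genotypes into one tidy table
#'
#' @param network A `timer_network`.
#' @param genotypes Character vector of genotype names; defaults to the
#'   full catalogue.
#' @return A tibble in the same format as [simulate_genotype()], with all
#'   genotypes stacked.
#' @examples
#' all_traj <- simulate_genotypes(terminal_network())
#' dplyr::count(all_traj, genotype)
#' @export
simulate_genotypes <- function(network, genotypes = NULL) {
  genotypes <- genotypes %||% names(network$genotypes)
  purrr::map_dfr(genotypes, function(g) simulate_genotype(network, g))
}

#' Validate a network configuration
#'
#' Checks structural well-formedness: unique factor names, rules present
#' for exactly the output factors, a complete in-bounds input schedule,
#' an in-bounds initial condition, and genotypes that clamp only
#' registered factors. The canonical terminal network validates cleanly.
#'
#' @param network A `timer_network`.
#' @return A tibble of findings with columns `check` and `detail`;
#'   zero rows means the network is valid.
#' @examples
#' validate_network(terminal_network())  # zero rows
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "timer_network"))
  findings <- list()
  note <- function(check, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      check = check, detail = detail)
  }

  facs <- network$factors$factor
  dup <- unique(facs[duplicated(facs)])
  for (f in dup) note("duplicate_factor", f)

  if (!all(network$factors$max_level %in% c(1L, 2L))) {
    bad <- facs[!network$factors$max_level %in% c(1L, 2L)]
    for (f in bad) note("bad_max_level", f)
  }

  outs <- output_factors(network)
  ins <- input_factors(network)
  for (f in setdiff(outs, names(network$rules))) note("missing_rule", f)
  for (f in setdiff(names(network$rules), outs)) {
    note("rule_for_non_output", f)
  }

  ml <- max_levels(network)
  sch <- network$schedule
  for (f in setdiff(unique(sch$factor), facs)) {
    note("schedule_unknown_factor", f)
  }
  bad_lvl <- sch[sch$factor %in% facs &
                   (sch$level < 0L | sch$level > ml[sch$factor]), ]
  if (nrow(bad_lvl) > 0L) {
    for (i in seq_len(nrow(bad_lvl))) {
      note("schedule_level_out_of_bounds",
           paste0(bad_lvl$factor[i], " region ", bad_lvl$region[i],
                  " t", bad_lvl$timepoint[i], " = ", bad_lvl$level[i]))
    }
  }
  if (length(ins) > 0L && nrow(sch) > 0L) {
    grid <- tidyr::expand_grid(
      factor = ins,
      region = seq_len(max(sch$region)),
      timepoint = 0:max(sch$timepoint)
    )
    have <- paste(sch$factor, sch$region, sch$timepoint)
    want <- paste(grid$factor, grid$region, grid$timepoint)
    for (m in want[!want %in% have]) note("schedule_missing_cell", m)
  }

  init_bad <- setdiff(names(network$initial), outs)
  for (f in init_bad) note("initial_not_output", f)
  for (f in intersect(names(network$initial), outs)) {
    if (network$initial[[f]] < 0L || network$initial[[f]] > ml[[f]]) {
      note("initial_out_of_bounds", f)
    }
  }

  for (g in names(network$genotypes)) {
    unknown <- setdiff(network$genotypes[[g]], facs)
    for (f in unknown) {
      note("genotype_clamps_unknown_factor", paste0(g, ": ", f))
    }
  }

  if (length(findings) == 0L) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}
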