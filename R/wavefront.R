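#' Configuration for the sequential-segmentation variant
#'
#' The variant rewires the timer-gene network for a one-dimensional row of
#' cells with a posterior Wnt source, emulating a segment addition zone:
#' Cad becomes Wnt-dependent (on only where Wnt was present at the prior
#' step), D becomes strictly Cad-driven (strong under Cad, decaying
#' strong->weak->off without it, repressed by strong Opa), and Opa gains
#' cross-regulation from the other timer genes (repressed where Cad is on
#' or D is strong, and within the Wnt zone). Posterior growth appends
#' naive (all-off) cells that immediately fall inside the Wnt zone.
#'
#' Setting `wnt_range = 0` removes the Wnt source and reverts Cad to the
#' intrinsic default-on rule with the Cad-on initial condition; combined
#' with `opa_timer_repression = FALSE` and `growth_per_step = 0` every
#' cell then reproduces the trunk dynamics of the terminal network.
#'
#' @param n_cells Initial number of cells (>= 1).
#' @param n_steps Number of update steps to simulate (>= 1).
#' @param wnt_range Number of posterior-most cells receiving Wnt (0 to
#'   disable the Wnt source; otherwise must not exceed `n_cells`).
#' @param growth_per_step Cells appended at the posterior per step
#'   (0 or 1).
#' @param opa_timer_repression Should Opa be repressed by Cad >= 1, D = 2,
#'   or Wnt (the variant's extra cross-regulation)? Default `TRUE`.
#' @return A list of class `wavefront_config`.
#' @examples
#' wavefront_config()
#' @export
wavefront_config <- function(n_cells = 2L, n_steps = 20L, wnt_range = 2L,
                             growth_per_step = 1L,
                             opa_timer_repression = TRUE) {
  n_cells <- as.integer(n_cells)
  n_steps <- as.integer(n_steps)
  wnt_range <- as.integer(wnt_range)
  growth_per_step <- as.integer(growth_per_step)
  if (is.na(n_cells) || n_cells < 1L) {
    abort("`n_cells` must be a positive integer.")
  }
  if (is.na(n_steps) || n_steps < 1L) {
    abort("`n_steps` must be a positive integer.")
  }
  if (is.na(wnt_range) || wnt_range < 0L || wnt_range > n_cells) {
    abort("`wnt_range` must lie between 0 and `n_cells`.")
  }
  if (!growth_per_step %in% c(0L, 1L)) {
    abort("`growth_per_step` must be 0 or 1.")
  }
  structure(
    list(n_cells = n_cells, n_steps = n_steps, wnt_range = wnt_range,
         growth_per_step = growth_per_step,
         opa_timer_repression = isTRUE(opa_timer_repression)),
    class = "wavefront_config"
  )
}

#' @export
print.wavefront_config <- function(x, ...) {
  cat("<wavefront_config> ", x$n_cells, " cells (+", x$growth_per_step,
      "/step), ", x$n_steps, " steps, Wnt range ", x$wnt_range,
      if (x$opa_timer_repression) ", timer repression of Opa" else "",
      "\n", sep = "")
  invisible(x)
}

#' Ordered phase labels of the timer-gene succession
#'
#' @return Character vector of phase labels from least to most advanced:
#'   naive, cad, cad+D, D, D+opa, opa.
#' @examples
#' phase_levels()
#' @export
phase_levels <- function() {
  c("naive", "cad", "cad+D", "D", "D+opa", "opa")
}

#' Phase label of a cell state
#'
#' Discretises a cell's Cad/D/Opa levels into the timer-gene phase
#' sequence. Precedence follows the developmental succession: any Cad
#' without D is "cad"; Cad with D is "cad+D"; D without Cad is "D" or
#' "D+opa" depending on Opa; Opa alone is "opa"; all-off is "naive".
#' Total and deterministic over every level combination.
#'
#' @param cad,d,opa Integer levels (vectorised).
#' @return Factor with levels [phase_levels()].
#' @examples
#' phase_of(1, 0, 0)  # cad
#' phase_of(0, 2, 1)  # D+opa
#' @export
phase_of <- function(cad, d, opa) {
  lbl <- dplyr::case_when(
    cad == 0L & d == 0L & opa == 0L ~ "naive",
    cad >= 1L & d == 0L ~ "cad",
    cad >= 1L ~ "cad+D",
    d >= 1L & opa == 0L ~ "D",
    d >= 1L ~ "D+opa",
    TRUE ~ "opa"
  )
  factor(lbl, levels = phase_levels())
}

variant_update <- function(cad, d, opa, wnt, cfg) {
  wnt_driven <- cfg$wnt_range > 0L
  cad_next <- if (wnt_driven) {
    if (wnt >= 1L) 1L else 0L
  } else {
    # Intrinsic rule (terminal network trunk): default-on, repressed by
    # any D or strong Opa.
    if (d >= 1L || opa == 2L) 0L else 1L
  }
  d_next <- if (opa == 2L) {
    0L
  } else if (cad == 1L) {
    2L
  } else if (d >= 1L) {
    1L
  } else {
    0L
  }
  opa_repressed <- cfg$opa_timer_repression &&
    (cad >= 1L || d == 2L || wnt >= 1L)
  opa_next <- if (opa_repressed) 0L else min(opa + 1L, 2L)
  c(cad_next, d_next, opa_next)
}

#' Simulate the sequential-segmentation variant
#'
#' Runs the rewired timer-gene network on a growing one-dimensional cell
#' row with a posterior Wnt source. Updates are synchronous; Wnt is a
#' binary positional input occupying the `wnt_range` posterior-most cells
#' at each step; growth appends naive all-off cells at the posterior
#' after each update. Deterministic (no randomness anywhere).
#'
#' As cells are displaced out of the Wnt zone by growth they step through
#' the timer-gene succession cad -> cad+D -> D -> D+opa -> opa, producing
#' a posterior-to-anterior wavefront like that of a segment addition zone.
#'
#' @param config A [wavefront_config()].
#' @return Tidy tibble with one row per (step, cell, factor): columns
#'   `step` (0-based), `cell` (1 = anterior-most), `birth_step`, `wnt`
#'   (positional input at that step), `factor` (Cad/D/Opa), `level`, and
#'   `phase` (the cell's phase at that step).
#' @examples
#' rows <- simulate_wavefront(wavefront_config(n_steps = 8))
#' dplyr::filter(rows, step == 7, factor == "Cad")
#' @export
simulate_wavefront <- function(config = wavefront_config()) {
  stopifnot(inherits(config, "wavefront_config"))
  cfg <- config
  wnt_driven <- cfg$wnt_range > 0L

  # State per cell: levels of Cad, D, Opa plus birth step.
  n <- cfg$n_cells
  cad <- integer(n); d <- integer(n); opa <- integer(n)
  if (!wnt_driven) cad[] <- 1L  # intrinsic variant starts Cad-on
  birth <- integer(n)

  wnt_at <- function(n_now) {
    w <- integer(n_now)
    if (cfg$wnt_range > 0L) {
      w[seq.int(max(1L, n_now - cfg$wnt_range + 1L), n_now)] <- 1L
    }
    w
  }

  snapshot <- function(step, wnt) {
    tibble::tibble(
      step = step,
      cell = seq_along(cad),
      birth_step = birth,
      wnt = wnt,
      Cad = cad, D = d, Opa = opa
    )
  }

  wnt <- wnt_at(n)
  snaps <- vector("list", cfg$n_steps + 1L)
  snaps[[1L]] <- snapshot(0L, wnt)

  for (step in seq_len(cfg$n_steps)) {
    nxt <- vapply(seq_along(cad), function(i) {
      variant_update(cad[i], d[i], opa[i], wnt[i], cfg)
    }, integer(3L))
    cad <- nxt[1L, ]; d <- nxt[2L, ]; opa <- nxt[3L, ]
    if (cfg$growth_per_step > 0L) {
      cad <- c(cad, 0L); d <- c(d, 0L); opa <- c(opa, 0L)
      birth <- c(birth, step)
    }
    wnt <- wnt_at(length(cad))
    snaps[[step + 1L]] <- snapshot(step, wnt)
  }

  wide <- dplyr::bind_rows(snaps)
  wide$phase <- phase_of(wide$Cad, wide$D, wide$Opa)
  out <- tidyr::pivot_longer(wide, cols = c("Cad", "D", "Opa"),
                             names_to = "factor", values_to = "level")
  out$factor <- factor(out$factor, levels = c("Cad", "D", "Opa"))
  dplyr::select(out, "step", "cell", "birth_step", "wnt", "factor",
                "level", "phase")
}

#' Per-cell phase time courses
#'
#' Collapses a [simulate_wavefront()] table to one row per (step, cell)
#' with the phase and its rank in the succession (naive = 0 ... opa = 5).
#'
#' @param rows Output of [simulate_wavefront()].
#' @return Tibble with columns `step`, `cell`, `birth_step`, `wnt`,
#'   `phase`, `phase_rank`.
#' @examples
#' ph <- cell_phases(simulate_wavefront(wavefront_config(n_steps = 6)))
#' head(ph)
#' @export
cell_phases <- function(rows) {
  out <- dplyr::distinct(rows, .data$step, .data$cell, .data$birth_step,
                         .data$wnt, .data$phase)
  out$phase_rank <- as.integer(out$phase) - 1L
  out
}
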