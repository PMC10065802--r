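#' Factor registry of the posterior terminal network
#' @noRd
terminal_factors <- function() {
  tibble::tibble(
    factor    = c("Tll", "Hkb", "Cad", "D", "Opa", "Fkh", "Wg"),
    max_level = c(2L, 2L, 1L, 2L, 2L, 1L, 1L),
    role      = c("input", "input", rep("output", 5L))
  )
}

#' Annotated interaction table of the terminal network
#'
#' The 18 pairwise regulatory interactions encoded by the model, with
#' sign, presumed directness, provenance (newly inferred versus supported
#' by earlier literature), and the minimum source level at which the
#' effect applies (`threshold`; e.g. weak Tll suffices to repress D and
#' opa, but only strong Tll represses cad). Eleven interactions are newly
#' inferred; the `edge` column gives the identifier understood by
#' [terminal_rules()]'s `exclude` argument. Two edges (`Cad->Wg`,
#' `Tll->Wg`) are indirect net-effect summaries routed through Fkh and
#' carry no term of their own in the rule table.
#'
#' @return A tibble with columns `edge`, `source`, `target`, `sign`,
#'   `directness`, `provenance`, `threshold`, `functional`.
#' @examples
#' ints <- terminal_interactions()
#' nrow(ints)                                  # 18
#' sum(ints$provenance == "this_study")        # 11
#' @export
terminal_interactions <- function() {
  tibble::tribble(
    ~edge,       ~source, ~target, ~sign,        ~directness, ~provenance,  ~threshold, ~functional,
    "Cad->D",    "Cad",   "D",     "activation", "direct",    "this_study", 1L, TRUE,
    "D->Cad",    "D",     "Cad",   "repression", "direct",    "this_study", 1L, TRUE,
    "Opa->Cad",  "Opa",   "Cad",   "repression", "direct",    "this_study", 2L, TRUE,
    "Opa->D",    "Opa",   "D",     "repression", "direct",    "this_study", 2L, TRUE,
    "Tll->Cad",  "Tll",   "Cad",   "repression", "direct",    "this_study", 2L, TRUE,
    "Tll->D",    "Tll",   "D",     "repression", "direct",    "this_study", 1L, TRUE,
    "Tll->Opa",  "Tll",   "Opa",   "repression", "direct",    "this_study", 1L, TRUE,
    "Hkb->Cad",  "Hkb",   "Cad",   "repression", "direct",    "this_study", 2L, TRUE,
    "Hkb->D",    "Hkb",   "D",     "repression", "direct",    "this_study", 1L, TRUE,
    "Hkb->Opa",  "Hkb",   "Opa",   "repression", "direct",    "this_study", 2L, TRUE,
    "Hkb->Wg",   "Hkb",   "Wg",    "repression", "direct",    "this_study", 2L, TRUE,
    "Fkh->Wg",   "Fkh",   "Wg",    "activation", "direct",    "literature", 1L, TRUE,
    "Cad->Fkh",  "Cad",   "Fkh",   "activation", "direct",    "literature", 1L, TRUE,
    "Tll->Fkh",  "Tll",   "Fkh",   "activation", "indirect",  "literature", 2L, TRUE,
    "Hkb->Fkh",  "Hkb",   "Fkh",   "activation", "indirect",  "literature", 2L, TRUE,
    "Fkh->Fkh",  "Fkh",   "Fkh",   "activation", "direct",    "literature", 1L, TRUE,
    "Cad->Wg",   "Cad",   "Wg",    "activation", "indirect",  "literature", 1L, FALSE,
    "Tll->Wg",   "Tll",   "Wg",    "activation", "indirect",  "literature", 2L, FALSE
  )
}

#' Reference update rules of the terminal network
#'
#' Builds the per-factor logical update rules, optionally with individual
#' interactions deleted (for edge-necessity analyses). Each rule is a pure
#' function of the complete predecessor state:
#'
#' * **Cad** is default-on (maternal deposition; no activator modelled) and
#'   repressed by any D, strong Opa, strong Tll, or strong Hkb.
#' * **D** is repressed by any Tll, any Hkb, or strong Opa; otherwise it is
#'   strong when Cad is on and weak without Cad (basal activation).
#' * **Opa** ratchets up one level per timepoint unless repressed by any
#'   Tll or strong Hkb; repression resets it to off.
#' * **Fkh** switches on where Cad coincides with strong Tll or strong Hkb
#'   and is self-maintaining thereafter.
#' * **Wg** requires Fkh and is repressed by strong Hkb.
#'
#' @param exclude Character vector of edge identifiers (see
#'   [terminal_interactions()]) whose functional term is removed from the
#'   rules. Defaults to none.
#' @return Named list of rule functions for Cad, D, Opa, Fkh, Wg.
#' @examples
#' rules <- terminal_rules()
#' s <- c(Cad = 1L, D = 2L, Opa = 1L, Fkh = 0L, Wg = 0L, Tll = 0L, Hkb = 0L)
#' rules$Cad(s)  # 0: repressed by D
#' @export
terminal_rules <- function(exclude = character()) {
  known <- terminal_interactions()$edge
  bad <- setdiff(exclude, known)
  if (length(bad) > 0L) {
    abort(paste0("Unknown edge identifier(s): ",
                 paste(bad, collapse = ", ")))
  }
  on <- function(edge) !edge %in% exclude

  list(
    Cad = function(s) {
      repressed <-
        (on("D->Cad")   && s[["D"]] >= 1L)  ||
        (on("Opa->Cad") && s[["Opa"]] == 2L) ||
        (on("Tll->Cad") && s[["Tll"]] == 2L) ||
        (on("Hkb->Cad") && s[["Hkb"]] == 2L)
      if (repressed) 0L else 1L
    },
    D = function(s) {
      repressed <-
        (on("Tll->D") && s[["Tll"]] >= 1L) ||
        (on("Hkb->D") && s[["Hkb"]] >= 1L) ||
        (on("Opa->D") && s[["Opa"]] == 2L)
      if (repressed) {
        0L
      } else if (on("Cad->D") && s[["Cad"]] == 1L) {
        2L
      } else {
        1L
      }
    },
    Opa = function(s) {
      repressed <-
        (on("Tll->Opa") && s[["Tll"]] >= 1L) ||
        (on("Hkb->Opa") && s[["Hkb"]] == 2L)
      if (repressed) 0L else min(s[["Opa"]] + 1L, 2L)
    },
    Fkh = function(s) {
      maintained <- on("Fkh->Fkh") && s[["Fkh"]] == 1L
      induced <- on("Cad->Fkh") && s[["Cad"]] == 1L &&
        ((on("Tll->Fkh") && s[["Tll"]] == 2L) ||
           (on("Hkb->Fkh") && s[["Hkb"]] == 2L))
      if (maintained || induced) 1L else 0L
    },
    Wg = function(s) {
      if ((on("Fkh->Wg") && s[["Fkh"]] == 1L) &&
            !(on("Hkb->Wg") && s[["Hkb"]] == 2L)) 1L else 0L
    }
  )
}

#' Hard-coded Tll and Hkb input schedules
#'
#' The region-by-timepoint grids of terminal input levels that distinguish
#' the four modelled regions. The trunk (region 1) never sees terminal
#' input; the tail (region 2) sees transient weak Tll; the hindgut
#' (region 3) sees strong Tll that fades by the last timepoint plus
#' transient weak Hkb; the posterior midgut (region 4) sees strong Tll
#' and strong Hkb, the latter persisting weakly at the end.
#'
#' @return Long tibble with columns `factor`, `region`, `timepoint`,
#'   `level`.
#' @examples
#' sch <- terminal_schedule()
#' tidyr::pivot_wider(dplyr::filter(sch, factor == "Tll"),
#'                    names_from = timepoint, values_from = level)
#' @export
terminal_schedule <- function() {
  grids <- list(
    Tll = rbind(c(0L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L),
                c(2L, 2L, 2L, 0L),
                c(2L, 2L, 2L, 0L)),
    Hkb = rbind(c(0L, 0L, 0L, 0L),
                c(0L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L),
                c(2L, 2L, 2L, 1L))
  )
  purrr::map_dfr(names(grids), function(f) {
    g <- grids[[f]]
    tibble::tibble(
      factor    = f,
      region    = rep(seq_len(nrow(g)), times = ncol(g)),
      timepoint = rep(0:(ncol(g) - 1L), each = nrow(g)),
      level     = as.integer(g[cbind(rep(seq_len(nrow(g)), times = ncol(g)),
                                     rep(seq_len(ncol(g)), each = nrow(g)))])
    )
  })
}

#' Genotype catalogue of the terminal network
#'
#' Wild type plus the eight null mutants simulated by clamping: each
#' genotype lists the factors held at level 0 for all regions and
#' timepoints. `tor-` removes all terminal signalling and is simulated as
#' the `tll- hkb-` double clamp. `cad-` denotes the maternal-and-zygotic
#' null (germline clone derived).
#'
#' @return Named list of clamp sets.
#' @examples
#' names(terminal_genotypes())
#' @export
terminal_genotypes <- function() {
  list(
    "wt"       = character(),
    "fkh-"     = "Fkh",
    "cad-"     = "Cad",
    "D-"       = "D",
    "opa-"     = "Opa",
    "tor-"     = c("Tll", "Hkb"),
    "hkb-"     = "Hkb",
    "tll-"     = "Tll",
    "tll-opa-" = c("Tll", "Opa")
  )
}

#' The canonical posterior terminal network
#'
#' Assembles the seven-factor logical model of posterior terminal
#' patterning: Tll and Hkb as extrinsic inputs (ternary), the timer genes
#' Cad (binary), D and Opa (ternary), and the gut-specification genes Fkh
#' and Wg (binary), over four regions (trunk, tail, hindgut, posterior
#' midgut) and four timepoints. At timepoint 0, Cad is on in every region
#' and all other output factors are off.
#'
#' @param exclude Edge identifiers to delete from the rule table (passed
#'   to [terminal_rules()]); the interaction table is filtered to match.
#' @return A `timer_network`.
#' @examples
#' net <- terminal_network()
#' net
#' nrow(validate_network(net))  # 0
#' @export
terminal_network <- function(exclude = character()) {
  ints <- terminal_interactions()
  if (length(exclude) > 0L) {
    ints <- ints[!ints$edge %in% exclude, ]
  }
  new_network(
    factors      = terminal_factors(),
    rules        = terminal_rules(exclude),
    schedule     = terminal_schedule(),
    initial      = c(Cad = 1L, D = 0L, Opa = 0L, Fkh = 0L, Wg = 0L),
    genotypes    = terminal_genotypes(),
    interactions = ints,
    name         = if (length(exclude) == 0L) "terminal" else
      paste0("terminal[-", paste(exclude, collapse = ","), "]")
  )
}
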