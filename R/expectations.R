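exp_row <- function(id, genotype, type, description,
                    region = NA_integer_, factor = NA_character_,
                    timepoint = NA_integer_, relation = NA_character_,
                    level = NA_integer_, ref_genotype = NA_character_,
                    ref_region = NA_integer_, factors = list(NULL)) {
  tibble::tibble(
    id = id, genotype = genotype, type = type,
    region = as.integer(region), factor = factor,
    timepoint = as.integer(timepoint), relation = relation,
    level = as.integer(level), ref_genotype = ref_genotype,
    ref_region = as.integer(ref_region), factors = factors,
    description = description
  )
}

#' Machine-checkable phenotype expectations for the terminal network
#'
#' Encodes the qualitative genotype-by-genotype observations that the
#' model is required to reproduce, one row per check. Five predicate
#' types are used:
#'
#' * `level_at` — the factor's level at one (region, timepoint) satisfies
#'   a relation (`eq`, `ge`, `le`) against a stated level.
#' * `off_everywhere` — the factor is 0 at every timepoint of the region.
#' * `first_off_later_than` — the factor's first switch-off time (see
#'   [first_off_time()]) is strictly later than in the reference genotype
#'   at the same region; a factor that is expressed but never switches off
#'   sorts after every finite timepoint.
#' * `max_level_lower_than` — the factor's maximum level over the region's
#'   timepoints is strictly lower than in the reference genotype.
#' * `region_equals` — the full level time courses of the listed factors
#'   are identical between (genotype, region) and
#'   (ref_genotype, ref_region).
#'
#' Every expectation carries a plain-language description of the
#' developmental observation it operationalises. The suite covers all
#' nine genotypes and passes in full on the canonical network.
#'
#' @return A tibble of expectations (one row each; `factors` is a
#'   list-column used by `region_equals`).
#' @examples
#' suite <- expectation_suite()
#' nrow(suite)  # >= 25
#' dplyr::count(suite, genotype)
#' @export
expectation_suite <- function() {
  all_factors <- list(c("Tll", "Hkb", "Cad", "D", "Opa", "Fkh", "Wg"))
  dplyr::bind_rows(
    ## -- wild type ---------------------------------------------------
    exp_row("wt-cad-clears-trunk", "wt", "level_at",
            "Cad is repressed in the trunk by mid-blastoderm, before D",
            region = 1, factor = "Cad", timepoint = 2, relation = "eq",
            level = 0),
    exp_row("wt-d-outlasts-cad-trunk", "wt", "level_at",
            "D is still strong in the trunk when Cad has already gone off",
            region = 1, factor = "D", timepoint = 2, relation = "eq",
            level = 2),
    exp_row("wt-d-repressed-late-trunk", "wt", "level_at",
            "D is repressed in the trunk after Cad, once Opa is strong",
            region = 1, factor = "D", timepoint = 3, relation = "eq",
            level = 0),
    exp_row("wt-opa-strong-late-trunk", "wt", "level_at",
            "Opa builds up to strong expression in the trunk",
            region = 1, factor = "Opa", timepoint = 3, relation = "eq",
            level = 2),
    exp_row("wt-cad-persists-tail-t1", "wt", "level_at",
            "Cad expression is prolonged in the tail (still on at t1)",
            region = 2, factor = "Cad", timepoint = 1, relation = "eq",
            level = 1),
    exp_row("wt-cad-persists-tail-t2", "wt", "level_at",
            "Cad expression is prolonged in the tail (still on at t2)",
            region = 2, factor = "Cad", timepoint = 2, relation = "eq",
            level = 1),
    exp_row("wt-cad-persists-tail-t3", "wt", "level_at",
            "Cad expression is prolonged in the tail (still on at t3)",
            region = 2, factor = "Cad", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("wt-tail-d-delayed", "wt", "level_at",
            "Transient weak Tll delays D activation in the tail",
            region = 2, factor = "D", timepoint = 2, relation = "eq",
            level = 0),
    exp_row("wt-tail-late-d", "wt", "level_at",
            "D comes on strongly in the tail only at the last timepoint",
            region = 2, factor = "D", timepoint = 3, relation = "eq",
            level = 2),
    exp_row("wt-tail-opa-delayed", "wt", "level_at",
            "Transient weak Tll delays Opa activation in the tail",
            region = 2, factor = "Opa", timepoint = 2, relation = "eq",
            level = 0),
    exp_row("wt-wg-hindgut", "wt", "level_at",
            "Wg switches on in the hindgut region",
            region = 3, factor = "Wg", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("wt-wg-absent-trunk", "wt", "off_everywhere",
            "No posterior Wg in the trunk",
            region = 1, factor = "Wg"),
    exp_row("wt-wg-absent-tail", "wt", "off_everywhere",
            "No posterior Wg in the tail",
            region = 2, factor = "Wg"),
    exp_row("wt-wg-absent-midgut", "wt", "off_everywhere",
            "Strong Hkb keeps Wg off in the posterior midgut",
            region = 4, factor = "Wg"),
    exp_row("wt-fkh-hindgut", "wt", "level_at",
            "Fkh is activated in the hindgut region",
            region = 3, factor = "Fkh", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("wt-fkh-midgut", "wt", "level_at",
            "Fkh is activated in the posterior midgut region",
            region = 4, factor = "Fkh", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("wt-no-fkh-tail", "wt", "off_everywhere",
            "Weak Tll in the tail does not suffice to activate Fkh",
            region = 2, factor = "Fkh"),
    exp_row("wt-cad-clears-hindgut", "wt", "level_at",
            "Strong Tll represses Cad in the hindgut from the start",
            region = 3, factor = "Cad", timepoint = 1, relation = "eq",
            level = 0),
    ## -- fkh- --------------------------------------------------------
    exp_row("fkh-no-wg-hindgut", "fkh-", "off_everywhere",
            "Without Fkh, Wg is never activated in the hindgut region",
            region = 3, factor = "Wg"),
    ## -- D- ----------------------------------------------------------
    exp_row("D-cad-repression-delayed", "D-", "first_off_later_than",
            "Cad repression in the trunk is delayed without D",
            region = 1, factor = "Cad", ref_genotype = "wt"),
    exp_row("D-cad-eventually-off", "D-", "level_at",
            "Strong Opa still represses trunk Cad by the last timepoint",
            region = 1, factor = "Cad", timepoint = 3, relation = "eq",
            level = 0),
    ## -- opa- --------------------------------------------------------
    exp_row("opa-d-repression-delayed", "opa-", "first_off_later_than",
            "D repression in the trunk is delayed without Opa",
            region = 1, factor = "D", ref_genotype = "wt"),
    ## -- cad- --------------------------------------------------------
    exp_row("cad-no-fkh-hindgut", "cad-", "off_everywhere",
            "Fkh is not expressed in the hindgut without Cad",
            region = 3, factor = "Fkh"),
    exp_row("cad-no-wg-hindgut", "cad-", "off_everywhere",
            "Wg is (therefore) not expressed in the hindgut without Cad",
            region = 3, factor = "Wg"),
    exp_row("cad-no-fkh-midgut", "cad-", "off_everywhere",
            "Fkh is not expressed in the posterior midgut without Cad",
            region = 4, factor = "Fkh"),
    exp_row("cad-d-reduced-trunk", "cad-", "max_level_lower_than",
            "D activation in the trunk is reduced (weak, not strong)",
            region = 1, factor = "D", ref_genotype = "wt"),
    exp_row("cad-d-reduced-tail", "cad-", "max_level_lower_than",
            "D activation in the tail is reduced (weak, not strong)",
            region = 2, factor = "D", ref_genotype = "wt"),
    ## -- tor- --------------------------------------------------------
    exp_row("tor-tail-as-trunk", "tor-", "region_equals",
            "Loss of all terminal input transforms the tail into trunk",
            region = 2, ref_genotype = "wt", ref_region = 1,
            factors = all_factors),
    exp_row("tor-hindgut-as-trunk", "tor-", "region_equals",
            "Loss of all terminal input transforms the hindgut into trunk",
            region = 3, ref_genotype = "wt", ref_region = 1,
            factors = all_factors),
    exp_row("tor-midgut-as-trunk", "tor-", "region_equals",
            "Loss of all terminal input transforms the midgut into trunk",
            region = 4, ref_genotype = "wt", ref_region = 1,
            factors = all_factors),
    ## -- hkb- --------------------------------------------------------
    exp_row("hkb-midgut-as-hindgut", "hkb-", "region_equals",
            "Without Hkb the posterior midgut takes on hindgut identity",
            region = 4, ref_genotype = "hkb-", ref_region = 3,
            factors = all_factors),
    exp_row("hkb-wg-gained-midgut", "hkb-", "level_at",
            "Wg is eventually expressed in the transformed midgut region",
            region = 4, factor = "Wg", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("hkb-fkh-midgut", "hkb-", "level_at",
            "Fkh is eventually expressed in the transformed midgut region",
            region = 4, factor = "Fkh", timepoint = 3, relation = "eq",
            level = 1),
    ## -- tll- --------------------------------------------------------
    exp_row("tll-tail-as-trunk", "tll-", "region_equals",
            "Without Tll the tail is transformed into trunk",
            region = 2, ref_genotype = "tll-", ref_region = 1,
            factors = all_factors),
    exp_row("tll-transient-cad-hindgut-on", "tll-", "level_at",
            "A posteriorly shifted transient Cad stripe persists to t2",
            region = 3, factor = "Cad", timepoint = 2, relation = "eq",
            level = 1),
    exp_row("tll-transient-cad-hindgut-off", "tll-", "level_at",
            "The shifted Cad stripe decays by the last timepoint",
            region = 3, factor = "Cad", timepoint = 3, relation = "eq",
            level = 0),
    exp_row("tll-no-late-d-hindgut", "tll-", "off_everywhere",
            "Transient Hkb then unrepressed Opa preclude any late D",
            region = 3, factor = "D"),
    exp_row("tll-opa-unrepressed-hindgut", "tll-", "level_at",
            "Opa is not repressed in region 3 (unlike D)",
            region = 3, factor = "Opa", timepoint = 3, relation = "eq",
            level = 2),
    exp_row("tll-no-wg-hindgut", "tll-", "off_everywhere",
            "The posterior Wg domain is absent without Tll",
            region = 3, factor = "Wg"),
    exp_row("tll-fkh-retained-midgut", "tll-", "level_at",
            "Strong Hkb still drives Fkh in the posterior midgut",
            region = 4, factor = "Fkh", timepoint = 3, relation = "eq",
            level = 1),
    exp_row("tll-opa-absent-midgut", "tll-", "off_everywhere",
            "Strong Hkb keeps Opa off at the pole",
            region = 4, factor = "Opa"),
    exp_row("tll-cad-cleared-midgut", "tll-", "level_at",
            "Strong Hkb represses Cad at the pole (Cad abuts the Hkb domain)",
            region = 4, factor = "Cad", timepoint = 1, relation = "eq",
            level = 0),
    ## -- tll- opa- ---------------------------------------------------
    exp_row("tllopa-hindgut-as-tail", "tll-opa-", "region_equals",
            "Removing Opa repression fully transforms region 3 into tail",
            region = 3, ref_genotype = "wt", ref_region = 2,
            factors = list(c("Cad", "D")))
  )
}

#' First switch-off time of a factor
#'
#' The smallest timepoint at which the factor is 0 in the given region
#' after having been expressed (level >= 1) at some earlier timepoint.
#' Returns `NA` if the factor is never expressed, or is expressed but
#' never switches off within the simulated window.
#'
#' @param trajectory Tidy trajectory tibble from [simulate_genotype()] or
#'   [simulate_genotypes()].
#' @param region Region index.
#' @param factor Factor name.
#' @param genotype Genotype name; required when `trajectory` contains
#'   more than one genotype.
#' @return Integer timepoint or `NA`.
#' @examples
#' traj <- simulate_genotype(terminal_network(), "wt")
#' first_off_time(traj, region = 1, factor = "Cad")  # 2
#' first_off_time(traj, region = 2, factor = "Cad")  # NA (never off)
#' @export
first_off_time <- function(trajectory, region, factor, genotype = NULL) {
  if (is.null(genotype)) {
    gts <- unique(trajectory$genotype)
    if (length(gts) > 1L) {
      abort("Trajectory contains several genotypes; supply `genotype`.")
    }
    genotype <- gts
  }
  series <- level_series(trajectory, genotype, region, factor)
  ever_on <- which(series >= 1L)
  if (length(ever_on) == 0L) return(NA_integer_)
  offs <- which(series == 0L)
  offs <- offs[offs > min(ever_on)]
  if (length(offs) == 0L) return(NA_integer_)
  as.integer(min(offs) - 1L)  # positions are 1-based, timepoints 0-based
}

# Level time course for one (genotype, region, factor); errors on misses.
level_series <- function(trajectory, genotype, region, factor) {
  fac <- factor
  sub <- trajectory[trajectory$genotype == genotype &
                      trajectory$region == region &
                      as.character(trajectory$factor) == fac, ]
  if (nrow(sub) == 0L) {
    abort(paste0("No trajectory rows for genotype '", genotype,
                 "', region ", region, ", factor '", fac, "'."))
  }
  sub <- sub[order(sub$timepoint), ]
  setNames(sub$level, sub$timepoint)
}

eval_one_expectation <- function(row, trajectories) {
  gts_present <- unique(trajectories$genotype)
  needed <- stats::na.omit(c(row$genotype, row$ref_genotype))
  missing <- setdiff(needed, gts_present)
  if (length(missing) > 0L) {
    abort(paste0("Trajectories are missing genotype(s): ",
                 paste(missing, collapse = ", ")))
  }
  switch(
    row$type,
    level_at = {
      series <- level_series(trajectories, row$genotype, row$region,
                             row$factor)
      obs <- unname(series[as.character(row$timepoint)])
      ok <- switch(row$relation,
                   eq = obs == row$level,
                   ge = obs >= row$level,
                   le = obs <= row$level,
                   abort(paste0("Unknown relation '", row$relation, "'")))
      list(passed = ok, observed = paste0("level ", obs, " (", row$relation,
                                          " ", row$level, " required)"))
    },
    off_everywhere = {
      series <- level_series(trajectories, row$genotype, row$region,
                             row$factor)
      list(passed = all(series == 0L),
           observed = paste0("levels [", paste(series, collapse = ","), "]"))
    },
    first_off_later_than = {
      t_test <- first_off_time(trajectories, row$region, row$factor,
                               genotype = row$genotype)
      t_ref <- first_off_time(trajectories, row$region, row$factor,
                              genotype = row$ref_genotype)
      series <- level_series(trajectories, row$genotype, row$region,
                             row$factor)
      expressed <- any(series >= 1L)
      # Expressed-but-never-off sorts after every finite timepoint.
      t_test_cmp <- if (expressed && is.na(t_test)) Inf else t_test
      t_ref_cmp <- if (is.na(t_ref)) Inf else t_ref
      ok <- expressed && !is.na(t_test_cmp) && t_test_cmp > t_ref_cmp
      list(passed = isTRUE(ok),
           observed = paste0("first off t=", t_test_cmp, " vs reference t=",
                             t_ref_cmp))
    },
    max_level_lower_than = {
      m_test <- max(level_series(trajectories, row$genotype, row$region,
                                 row$factor))
      m_ref <- max(level_series(trajectories, row$ref_genotype, row$region,
                                row$factor))
      list(passed = m_test < m_ref,
           observed = paste0("max level ", m_test, " vs reference ", m_ref))
    },
    region_equals = {
      facs <- row$factors[[1L]]
      diffs <- character()
      for (f in facs) {
        a <- level_series(trajectories, row$genotype, row$region, f)
        b <- level_series(trajectories, row$ref_genotype, row$ref_region, f)
        if (!identical(unname(a), unname(b))) {
          diffs <- c(diffs, paste0(f, " [", paste(a, collapse = ","),
                                   "] vs [", paste(b, collapse = ","), "]"))
        }
      }
      list(passed = length(diffs) == 0L,
           observed = if (length(diffs) == 0L) {
             paste0("identical over {", paste(facs, collapse = ","), "}")
           } else {
             paste(diffs, collapse = "; ")
           })
    },
    abort(paste0("Unknown expectation type '", row$type, "'"))
  )
}

#' Evaluate phenotype expectations against simulated trajectories
#'
#' Deterministically checks every expectation in the suite against the
#' supplied trajectories and reports pass/fail together with the observed
#' levels that decided each verdict.
#'
#' @param trajectories Combined tidy trajectory tibble (see
#'   [simulate_genotypes()]) containing every genotype the suite refers to.
#' @param suite Expectation tibble; defaults to [expectation_suite()].
#' @return A `phenotype_report`: list with `results` (tibble: `id`,
#'   `genotype`, `type`, `description`, `passed`, `observed`), `n_pass`,
#'   and `n_fail`. Has [tidy()] and [glance()] methods.
#' @examples
#' traj <- simulate_genotypes(terminal_network())
#' rep <- evaluate_expectations(traj)
#' glance(rep)
#' @export
evaluate_expectations <- function(trajectories, suite = expectation_suite()) {
  if (nrow(suite) == 0L) {
    results <- tibble::tibble(
      id = character(), genotype = character(), type = character(),
      description = character(), passed = logical(), observed = character())
  } else {
    verdicts <- purrr::map(seq_len(nrow(suite)), function(i) {
      eval_one_expectation(suite[i, ], trajectories)
    })
    results <- tibble::tibble(
      id = suite$id,
      genotype = suite$genotype,
      type = suite$type,
      description = suite$description,
      passed = purrr::map_lgl(verdicts, "passed"),
      observed = purrr::map_chr(verdicts, "observed")
    )
  }
  structure(
    list(results = results,
         n_pass = sum(results$passed),
         n_fail = sum(!results$passed)),
    class = "phenotype_report"
  )
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report> ", x$n_pass, " passed, ", x$n_fail, " failed (",
      nrow(x$results), " expectations)\n", sep = "")
  if (x$n_fail > 0L) {
    bad <- x$results[!x$results$passed, ]
    for (i in seq_len(nrow(bad))) {
      cat("  FAIL ", bad$id[i], ": ", bad$observed[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @rdname evaluate_expectations
#' @param x A `phenotype_report`.
#' @param ... Unused.
#' @export
tidy.phenotype_report <- function(x, ...) {
  x$results
}

#' @rdname evaluate_expectations
#' @export
glance.phenotype_report <- function(x, ...) {
  tibble::tibble(
    n_expectations = nrow(x$results),
    n_pass = x$n_pass,
    n_fail = x$n_fail,
    pass_rate = if (nrow(x$results) == 0L) NA_real_ else
      x$n_pass / nrow(x$results)
  )
}
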