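#' Build a domain specification table
#'
#' Helper for describing smooth one-dimensional expression domains along
#' the anteroposterior axis. Positions are percent egg length measured
#' from the anterior pole. Each domain is the product of two logistic
#' shoulders: a rising edge at `anterior_edge` and a falling edge at
#' `posterior_edge`, each with half-maximum exactly at the edge parameter
#' and width set by `edge_sharpness`.
#'
#' @param gene Gene name.
#' @param anterior_edge,posterior_edge Domain edges in % egg length
#'   (`0 <= anterior_edge < posterior_edge <= 100`).
#' @param amplitude Plateau height above baseline, arbitrary intensity
#'   units (> 0).
#' @param edge_sharpness Logistic width in % egg length (> 0).
#' @param baseline Background intensity (>= 0).
#' @return One-row tibble usable with [synthesize_trace()] (bind rows for
#'   multiple domains/genes).
#' @examples
#' domain_spec("wg", 88, 93)
#' @export
domain_spec <- function(gene, anterior_edge, posterior_edge,
                        amplitude = 10, edge_sharpness = 1, baseline = 0) {
  tibble::tibble(
    gene = gene,
    anterior_edge = anterior_edge,
    posterior_edge = posterior_edge,
    amplitude = amplitude,
    edge_sharpness = edge_sharpness,
    baseline = baseline
  )
}

check_domains <- function(domains) {
  req <- c("gene", "anterior_edge", "posterior_edge", "amplitude",
           "edge_sharpness", "baseline")
  missing <- setdiff(req, names(domains))
  if (length(missing) > 0L) {
    abort(paste0("Domain table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    if (!(d$anterior_edge >= 0 && d$anterior_edge < d$posterior_edge &&
            d$posterior_edge <= 100)) {
      abort(paste0("Invalid domain edges for gene '", d$gene,
                   "': need 0 <= anterior_edge < posterior_edge <= 100."))
    }
    if (!(d$amplitude > 0)) {
      abort(paste0("Invalid amplitude for gene '", d$gene,
                   "': must be > 0."))
    }
    if (!(d$edge_sharpness > 0)) {
      abort(paste0("Invalid edge_sharpness for gene '", d$gene,
                   "': must be > 0."))
    }
    if (!(d$baseline >= 0)) {
      abort(paste0("Invalid baseline for gene '", d$gene,
                   "': must be >= 0."))
    }
  }
  invisible(domains)
}

new_trace <- function(tbl, normalized = FALSE,
                      degenerate = character()) {
  tbl <- tibble::as_tibble(tbl)
  structure(tbl,
            class = c("expression_trace", class(tbl)),
            normalized = normalized,
            degenerate = degenerate)
}

#' @export
print.expression_trace <- function(x, ...) {
  genes <- unique(x$gene)
  pos <- sort(unique(x$position))
  cat("<expression_trace> ", length(genes), " gene(s) [",
      paste(genes, collapse = ", "), "], ", length(pos),
      " positions in [", min(pos), ", ", max(pos), "] %EL",
      if (isTRUE(attr(x, "normalized"))) ", normalised" else "",
      "\n", sep = "")
  NextMethod()
}

#' Is a trace normalised?
#'
#' @param trace An `expression_trace`.
#' @return Logical.
#' @examples
#' tr <- synthesize_trace(domain_spec("cad", 70, 85))
#' is_normalized(tr)
#' is_normalized(normalize_trace(tr))
#' @export
is_normalized <- function(trace) {
  isTRUE(attr(trace, "normalized"))
}

#' Genes whose series collapsed to a constant during normalisation
#'
#' @param trace An `expression_trace`.
#' @return Character vector of gene names flagged degenerate (mapped to
#'   all-zero by [normalize_trace()]).
#' @export
degenerate_genes <- function(trace) {
  attr(trace, "degenerate") %||% character()
}

#' Synthesise one-dimensional expression intensity traces
#'
#' Generates per-gene intensity profiles over the anteroposterior axis
#' (percent egg length from the anterior pole): for each gene the sum over
#' its domains of
#' `baseline + amplitude * logistic((x - anterior_edge)/edge_sharpness)
#'  * logistic((posterior_edge - x)/edge_sharpness)`,
#' plus Gaussian noise with standard deviation `noise_sd`, floored at 0.
#' Reproducible for a given `seed` (the caller's RNG state is untouched).
#'
#' @param domains Domain table ([domain_spec()] rows; one or more genes).
#' @param n_points Number of evenly spaced sample positions (>= 10).
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param seed Integer seed for the noise (mandatory, with a fixed
#'   default so traces are reproducible by construction).
#' @param from,to Position range sampled, % egg length.
#' @return An `expression_trace`: tibble with columns `position`, `gene`,
#'   `intensity`.
#' @examples
#' tr <- synthesize_trace(domain_spec("wg", 88, 93), noise_sd = 0)
#' dplyr::slice_max(tr, intensity, n = 1)
#' @export
synthesize_trace <- function(domains, n_points = 301L, noise_sd = 0,
                             seed = 1L, from = 0, to = 100) {
  check_domains(domains)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 10L) {
    abort("`n_points` must be at least 10.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  positions <- seq(from, to, length.out = n_points)
  genes <- unique(domains$gene)

  out <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(genes, function(g) {
      dg <- domains[domains$gene == g, ]
      signal <- rep(0, n_points)
      for (i in seq_len(nrow(dg))) {
        d <- dg[i, ]
        signal <- signal + d$baseline +
          d$amplitude *
            plogis((positions - d$anterior_edge) / d$edge_sharpness) *
            plogis((d$posterior_edge - positions) / d$edge_sharpness)
      }
      if (noise_sd > 0) {
        signal <- signal + rnorm(n_points, sd = noise_sd)
      }
      tibble::tibble(position = positions, gene = g,
                     intensity = pmax(signal, 0))
    })
  })
  new_trace(out, normalized = FALSE)
}

#' Window a trace to an anteroposterior interval
#'
#' Restricts the trace to positions inside `[lo, hi]` (inclusive). The
#' defaults, 67.5–97.5 % egg length, are the standard posterior
#' quantification window used throughout the package.
#'
#' @param trace An `expression_trace`.
#' @param lo,hi Window bounds in % egg length (`lo < hi`).
#' @return The windowed `expression_trace`.
#' @examples
#' tr <- synthesize_trace(domain_spec("cad", 70, 85))
#' range(window_trace(tr)$position)
#' @export
window_trace <- function(trace, lo = 67.5, hi = 97.5) {
  if (!(lo < hi)) abort("Window is empty: `lo` must be < `hi`.")
  keep <- trace$position >= lo & trace$position <= hi
  if (!any(keep)) abort("Window contains no sampled positions.")
  new_trace(trace[keep, ], normalized = attr(trace, "normalized"),
            degenerate = degenerate_genes(trace))
}

#' Min-max normalise a trace per gene
#'
#' Rescales each gene's intensity series onto `[0, 1]` (minimum 0,
#' maximum 1). A constant series cannot be rescaled and maps to all-zero;
#' such genes are flagged (see [degenerate_genes()]). Idempotent.
#'
#' @param trace An `expression_trace`.
#' @return The normalised `expression_trace`.
#' @examples
#' tr <- normalize_trace(synthesize_trace(domain_spec("cad", 70, 85)))
#' range(tr$intensity)
#' @export
normalize_trace <- function(trace) {
  degen <- character()
  out <- dplyr::bind_rows(lapply(split(trace, trace$gene), function(sub) {
    rng <- range(sub$intensity)
    if (diff(rng) == 0) {
      degen <<- c(degen, sub$gene[1L])
      sub$intensity <- rep(0, nrow(sub))
    } else {
      sub$intensity <- (sub$intensity - rng[1L]) / diff(rng)
    }
    sub
  }))
  out <- out[order(match(out$gene, unique(trace$gene)), out$position), ]
  new_trace(out, normalized = TRUE,
            degenerate = union(degenerate_genes(trace), degen))
}

#' Threshold crossings of a normalised trace
#'
#' Finds every position at which a gene's normalised intensity crosses
#' the threshold, by linear interpolation between adjacent samples.
#' Crossings are labelled `rising` (intensity increasing through the
#' threshold) or `falling`. On a noise-free single-domain trace the
#' half-maximum crossings sit at the generating edge parameters.
#'
#' @param trace A normalised `expression_trace`.
#' @param gene Gene to analyse (must be present in the trace).
#' @param threshold Fraction of the normalised range (default 0.5,
#'   i.e. the half-maximum convention).
#' @return Tibble with columns `position`, `direction`; zero rows if the
#'   series never crosses the threshold.
#' @examples
#' tr <- normalize_trace(synthesize_trace(domain_spec("wg", 80, 95,
#'   edge_sharpness = 0.5)))
#' boundary_positions(tr, "wg")
#' @export
boundary_positions <- function(trace, gene, threshold = 0.5) {
  if (!is_normalized(trace)) {
    abort("`trace` must be normalised first (see normalize_trace()).")
  }
  g <- gene
  sub <- trace[trace$gene == g, ]
  if (nrow(sub) == 0L) {
    abort(paste0("Gene '", g, "' not present in the trace."))
  }
  sub <- sub[order(sub$position), ]
  y <- sub$intensity - threshold
  x <- sub$position
  cross <- which(y[-length(y)] * y[-1L] < 0 | (y[-length(y)] != 0 & y[-1L] == 0))
  if (length(cross) == 0L) {
    return(tibble::tibble(position = numeric(), direction = character()))
  }
  pos <- vapply(cross, function(i) {
    if (y[i + 1L] == 0) {
      x[i + 1L]
    } else {
      x[i] + (x[i + 1L] - x[i]) * (0 - y[i]) / (y[i + 1L] - y[i])
    }
  }, numeric(1L))
  dir <- ifelse(y[cross + 1L] > y[cross], "rising", "falling")
  tibble::tibble(position = pos, direction = dir)
}

#' Boundary shift between two traces
#'
#' Signed displacement (test minus reference, % egg length) of a gene's
#' threshold crossing between two normalised traces over the same window.
#' Negative values are anterior shifts. If either trace lacks the
#' requested crossing the shift is undefined and `NA` is returned.
#'
#' @param reference,test Normalised `expression_trace` objects sampled
#'   over the same window.
#' @param gene Gene to compare.
#' @param which `"rising"` or `"falling"`.
#' @param index Which crossing to use when a trace has several in the
#'   requested direction (both traces must then be indexable); without an
#'   index, multiple crossings are an error.
#' @param threshold Normalised threshold (default half-maximum).
#' @return Signed shift in % egg length, or `NA_real_`.
#' @examples
#' ref <- normalize_trace(synthesize_trace(domain_spec("cad", 70, 85)))
#' mut <- normalize_trace(synthesize_trace(domain_spec("cad", 70, 83)))
#' boundary_shift(ref, mut, "cad", "falling")  # about -2
#' @export
boundary_shift <- function(reference, test, gene,
                           which = c("falling", "rising"), index = NULL,
                           threshold = 0.5) {
  which <- match.arg(which)
  if (!is_normalized(reference) || !is_normalized(test)) {
    abort("Both traces must be normalised.")
  }
  r_rng <- range(reference$position)
  t_rng <- range(test$position)
  if (!isTRUE(all.equal(r_rng, t_rng))) {
    abort("Traces cover different windows; window them identically first.")
  }
  pick <- function(trace) {
    b <- boundary_positions(trace, gene, threshold)
    b <- b[b$direction == which, ]
    if (nrow(b) == 0L) return(NA_real_)
    if (nrow(b) > 1L && is.null(index)) {
      abort(paste0("Multiple ", which, " crossings for '", gene,
                   "'; supply `index`."))
    }
    i <- index %||% 1L
    if (i > nrow(b)) return(NA_real_)
    b$position[i]
  }
  p_ref <- pick(reference)
  p_test <- pick(test)
  if (is.na(p_ref) || is.na(p_test)) return(NA_real_)
  p_test - p_ref
}
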