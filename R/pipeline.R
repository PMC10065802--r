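#' Simulate genotypes and write trajectory tables
#'
#' Runs the simulation for the selected genotypes and writes one tidy TSV
#' per genotype plus a combined table (`trajectories.tsv`), each with a
#' header recording the package version and network config hash.
#' Optionally also writes a tile plot per genotype.
#'
#' @param out_dir Output directory (created if absent).
#' @param network A `timer_network`; default the canonical terminal
#'   network.
#' @param genotypes Genotype names; default the full catalogue.
#' @param plot Write `trajectories.pdf` with one page of tiles per
#'   genotype?
#' @return Invisibly, the combined trajectory tibble.
#' @export
run_simulate <- function(out_dir, network = terminal_network(),
                         genotypes = NULL, plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genotypes <- genotypes %||% names(network$genotypes)
  combined <- simulate_genotypes(network, genotypes)
  for (g in genotypes) {
    fname <- paste0("trajectory_", gsub("[^A-Za-z0-9]+", "_", g), ".tsv")
    write_trajectory(combined[combined$genotype == g, ],
                     file.path(out_dir, fname), network)
  }
  write_trajectory(combined, file.path(out_dir, "trajectories.tsv"),
                   network)
  if (isTRUE(plot)) {
    grDevices::pdf(file.path(out_dir, "trajectories.pdf"),
                   width = 8, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (g in genotypes) {
      print(plot_trajectory(combined[combined$genotype == g, ]) +
              ggplot2::ggtitle(g))
    }
  }
  invisible(combined)
}

#' Evaluate the phenotype checklist and write reports
#'
#' Simulates every genotype the suite references, evaluates the
#' expectations, and writes `check_report.json` (one entry per
#' expectation: id, genotype, verdict, observed, description) plus a
#' human-readable `check_report.txt`.
#'
#' @param out_dir Output directory (created if absent).
#' @param network A `timer_network`.
#' @param suite Expectation tibble; default [expectation_suite()].
#' @return Invisibly, the `phenotype_report`. Use
#'   `glance()` on it (or the return value's `n_fail`) for scripting;
#'   the shipped command-line wrapper exits non-zero on any failure.
#' @export
run_checklist <- function(out_dir, network = terminal_network(),
                          suite = expectation_suite()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  needed <- unique(stats::na.omit(c(suite$genotype, suite$ref_genotype)))
  trajectories <- simulate_genotypes(
    network, intersect(names(network$genotypes), needed))
  report <- evaluate_expectations(trajectories, suite)

  json <- lapply(seq_len(nrow(report$results)), function(i) {
    r <- report$results[i, ]
    list(id = r$id, genotype = r$genotype, verdict =
           if (r$passed) "pass" else "fail",
         observed = r$observed, description = r$description)
  })
  jsonlite::write_json(
    list(header = output_header(network), n_pass = report$n_pass,
         n_fail = report$n_fail, expectations = json),
    file.path(out_dir, "check_report.json"), auto_unbox = TRUE,
    pretty = TRUE)

  txt <- c(output_header(network),
           sprintf("%-32s %-9s %-6s %s", "id", "genotype", "verdict",
                   "observed"),
           sprintf("%-32s %-9s %-6s %s", report$results$id,
                   report$results$genotype,
                   ifelse(report$results$passed, "pass", "FAIL"),
                   report$results$observed),
           paste0(report$n_pass, " passed, ", report$n_fail, " failed"))
  writeLines(txt, file.path(out_dir, "check_report.txt"))
  invisible(report)
}

#' Run the sequential-segmentation variant and write outputs
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [wavefront_config()].
#' @param plot Write `kymograph.pdf`?
#' @return Invisibly, the tidy variant table.
#' @export
run_variant <- function(out_dir, config = wavefront_config(),
                        plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- simulate_wavefront(config)
  out <- rows
  out$factor <- as.character(out$factor)
  out$phase <- as.character(out$phase)
  path <- file.path(out_dir, "wavefront.tsv")
  writeLines(c(paste0("# timernet ",
                      as.character(utils::packageVersion("timernet"))),
               paste0("# config: ", config$n_cells, " cells (+",
                      config$growth_per_step, "/step), ",
                      config$n_steps, " steps, Wnt range ",
                      config$wnt_range)),
             path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  if (isTRUE(plot)) {
    grDevices::pdf(file.path(out_dir, "kymograph.pdf"),
                   width = 7, height = 5)
    print(plot_kymograph(rows))
    grDevices::dev.off()
  }
  invisible(rows)
}

#' Synthesise, window, normalise, and quantify a trace set
#'
#' Convenience pipeline for the synthetic-trace module: generates traces
#' from a domain table, windows them to the standard posterior window,
#' min-max normalises each gene, writes the trace table and the called
#' boundaries as TSVs.
#'
#' @param out_dir Output directory (created if absent).
#' @param domains Domain table ([domain_spec()] rows).
#' @param n_points,noise_sd,seed Passed to [synthesize_trace()].
#' @param lo,hi Window bounds, % egg length.
#' @param threshold Boundary threshold on the normalised scale.
#' @param plot Write `traces.pdf`?
#' @return Invisibly, a list with elements `trace` (the windowed,
#'   normalised trace) and `boundaries` (tibble: gene, position,
#'   direction).
#' @export
run_synth_trace <- function(out_dir, domains, n_points = 301L,
                            noise_sd = 0, seed = 1L, lo = 67.5, hi = 97.5,
                            threshold = 0.5, plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- synthesize_trace(domains, n_points = n_points,
                            noise_sd = noise_sd, seed = seed)
  trace <- normalize_trace(window_trace(trace, lo, hi))
  boundaries <- purrr::map_dfr(unique(trace$gene), function(g) {
    b <- boundary_positions(trace, g, threshold)
    if (nrow(b) == 0L) return(NULL)
    dplyr::mutate(b, gene = g, .before = 1L)
  })
  readr::write_tsv(tibble::as_tibble(trace),
                   file.path(out_dir, "traces.tsv"))
  readr::write_tsv(boundaries, file.path(out_dir, "boundaries.tsv"))
  if (isTRUE(plot)) {
    grDevices::pdf(file.path(out_dir, "traces.pdf"), width = 7,
                   height = 4)
    print(plot_trace(trace))
    grDevices::dev.off()
  }
  invisible(list(trace = trace, boundaries = boundaries))
}
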