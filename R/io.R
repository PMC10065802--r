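#' Write a network to a plain-text YAML config
#'
#' Serialises the factor registry, rule-set identifier, input schedule
#' grids (region x timepoint), initial condition, genotype catalogue, and
#' interaction table. Rules are referenced by identifier (functions are
#' not serialised); [read_network()] rebuilds them from the identifier.
#'
#' @param network A `timer_network` whose name matches a known rule set
#'   (currently `"terminal"`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "timer_network"))
  sch <- network$schedule
  grids <- lapply(split(sch, sch$factor), function(sub) {
    m <- tidyr::pivot_wider(sub[, c("region", "timepoint", "level")],
                            names_from = "timepoint",
                            values_from = "level")
    m <- m[order(m$region), ]
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, -1L]))
  })
  cfg <- list(
    name = network$name,
    rules = network$name,
    factors = lapply(seq_len(nrow(network$factors)), function(i) {
      list(factor = network$factors$factor[i],
           max_level = network$factors$max_level[i],
           role = network$factors$role[i])
    }),
    schedule = grids,
    initial = as.list(network$initial),
    genotypes = lapply(network$genotypes, as.list),
    interactions = if (is.null(network$interactions)) NULL else
      lapply(seq_len(nrow(network$interactions)), function(i) {
        as.list(network$interactions[i, ])
      })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a network from a YAML config
#'
#' Inverse of [write_network()]. The config's `rules` identifier selects
#' the rule set; `"terminal"` maps to [terminal_rules()]. The returned
#' network passes [validate_network()] if the config is well-formed.
#'
#' @param path Config file path; defaults to the canonical terminal
#'   network config shipped with the package.
#' @return A `timer_network`.
#' @examples
#' net <- read_network()
#' nrow(validate_network(net))  # 0
#' @export
read_network <- function(path = system.file("extdata",
                                            "terminal_network.yaml",
                                            package = "timernet")) {
  cfg <- yaml::read_yaml(path)
  rules <- switch(cfg$rules,
                  terminal = terminal_rules(),
                  abort(paste0("Unknown rule-set identifier '", cfg$rules,
                               "'.")))
  factors <- purrr::map_dfr(cfg$factors, tibble::as_tibble)
  factors$max_level <- as.integer(factors$max_level)
  schedule <- purrr::map_dfr(names(cfg$schedule), function(f) {
    grid <- cfg$schedule[[f]]
    purrr::map_dfr(seq_along(grid), function(r) {
      tibble::tibble(factor = f, region = r,
                     timepoint = seq_along(grid[[r]]) - 1L,
                     level = as.integer(grid[[r]]))
    })
  })
  genotypes <- lapply(cfg$genotypes, function(g) unlist(g) %||% character())
  interactions <- if (is.null(cfg$interactions)) NULL else
    purrr::map_dfr(cfg$interactions, tibble::as_tibble)
  new_network(
    factors = factors,
    rules = rules,
    schedule = schedule,
    initial = setNames(as.integer(unlist(cfg$initial)),
                       names(cfg$initial)),
    genotypes = genotypes,
    interactions = interactions,
    name = cfg$name %||% cfg$rules
  )
}

output_header <- function(network) {
  c(paste0("# timernet ", as.character(utils::packageVersion("timernet"))),
    paste0("# network: ", network$name, " (config hash ",
           rlang::hash(list(network$factors, network$schedule,
                            network$initial, network$genotypes,
                            network$interactions)), ")"))
}

#' Write a tidy trajectory TSV
#'
#' Writes the long-format trajectory table with a two-line comment header
#' recording the package version and the network configuration hash.
#'
#' @param trajectory Tibble from [simulate_genotype()] /
#'   [simulate_genotypes()].
#' @param path Output file path.
#' @param network The network the trajectory came from (for the header).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, network = NULL) {
  lines <- if (is.null(network)) character() else output_header(network)
  writeLines(lines, path)
  out <- trajectory
  out$factor <- as.character(out$factor)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return Tidy trajectory tibble.
#' @export
read_trajectory <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
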