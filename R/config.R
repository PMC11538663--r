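#' Write a network (plus stage options) to a YAML config
#'
#' Plain-text, diffable serialization: nodes with their kinetic rates,
#' edge list with Hill parameters, drug input levels, and optional extra
#' sections (phenotype rules, named drug conditions).  Numbers are
#' written with full double precision so that load -> dump -> load is the
#' identity.
#'
#' @param net a `cac_network`.
#' @param path output file.
#' @param extra optional named list merged into the config (e.g.
#'   `phenotype_rules`, `conditions`, `meta`).
#' @return `path`, invisibly.
#' @export
write_network_config <- function(net, path, extra = list()) {
  cfg <- c(list(
    nodes = lapply(seq_len(nrow(net$nodes)), function(i)
      list(name = net$nodes$name[i],
           g = net$nodes$g[i], k = net$nodes$k[i],
           is_input = net$nodes$is_input[i])),
    edges = lapply(seq_len(nrow(net$edges)), function(e)
      list(source = net$edges$source[e], target = net$edges$target[e],
           lambda = net$edges$lambda[e], S = net$edges$S[e],
           n = net$edges$n[e], side = net$edges$side[e])),
    inputs = as.list(net$inputs)),
    extra)
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' Load a network config
#'
#' Parses and validates a YAML config written by
#' [write_network_config()] (or by hand).  All structural invariants of
#' the network are checked at load time; schema violations produce an
#' error naming the offending node or key.
#'
#' @param path YAML file.
#' @return a list with `network` (a validated `cac_network`), `rules`
#'   (phenotype thresholds, when present) and `options` (all remaining
#'   sections).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("nodes", "edges"))
    if (is.null(cfg[[key]])) stop("config missing section: ", key)
  req_node <- c("name", "g", "k")
  nodes <- do.call(rbind, lapply(cfg$nodes, function(n) {
    miss <- setdiff(req_node, names(n))
    if (length(miss)) stop("node '", n$name %||% "?",
                           "' missing field(s): ", paste(miss, collapse = ", "))
    data.frame(name = n$name, g = n$g, k = n$k,
               is_input = isTRUE(n$is_input))
  }))
  req_edge <- c("source", "target", "lambda", "S", "n")
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    miss <- setdiff(req_edge, names(e))
    if (length(miss)) stop("edge ", e$source %||% "?", "->", e$target %||% "?",
                           " missing field(s): ", paste(miss, collapse = ", "))
    data.frame(source = e$source, target = e$target, lambda = e$lambda,
               S = e$S, n = e$n, side = e$side %||% "G")
  }))
  inputs <- unlist(cfg$inputs) %||% setNames(numeric(0), character(0))
  net <- network_spec(nodes, edges, inputs)
  rules <- if (!is.null(cfg$phenotype_rules))
    do.call(cac_marker_rules, cfg$phenotype_rules) else NULL
  opts <- cfg[setdiff(names(cfg), c("nodes", "edges", "inputs",
                                    "phenotype_rules"))]
  list(network = net, rules = rules, options = opts)
}

#' Export network parameters as TSV
#'
#' One row per free parameter with columns `parameter` (address),
#' `element` (node or edge), `value` and `units`.
#'
#' @param net a `cac_network`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_params_tsv <- function(net, path) {
  fp <- free_parameters(net)
  kind <- sub(":.*$", "", fp$param)
  elem <- sub("^[^:]*:", "", fp$param)
  units <- c(g = "concentration/time", k = "1/time", lambda = "dimensionless",
             S = "concentration", n = "dimensionless",
             input = "concentration")[kind]
  df <- data.frame(parameter = fp$param, element = elem,
                   value = fp$value, units = units)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import parameter values from a TSV
#'
#' Reads a table written by [export_params_tsv()] (columns `parameter`,
#' `value`) and applies the values to the network.
#'
#' @param net a `cac_network`.
#' @param path TSV file.
#' @return the updated `cac_network`.
#' @export
import_params_tsv <- function(net, path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(df)))
    stop("TSV must have 'parameter' and 'value' columns")
  set_params(net, setNames(df$value, df$parameter))
}
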