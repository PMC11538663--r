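#' The packaged cancer-adipose conversion network
#'
#' Loads the CAC regulatory circuit shipped with the package: the EMT
#' core (P53/MDM2, the p53-induced microRNAs miR-34/miR-145/miR-200, the
#' EMT transcription factors SNAIL1 and ZEB1), the metastasis module
#' (LIN28/LET7, BACH1, RKIP), the MAPK cascade (MEK/ERK) and the
#' adipogenic switch (PPARG/CEBPA), with three clamped drug input nodes:
#' TGFB (EMT inducer), MEKI (MEK inhibitor) and ROSI (rosiglitazone, a
#' PPARG agonist).
#'
#' The wiring follows the published circuit diagram of the conversion
#' model; the kinetic parameters are a synthetic reconstruction,
#' calibrated so that the drug conditions of [cac_conditions()] reproduce
#' the reported attractor structure (monostable E without drugs, E/M
#' bistability at moderate TGFB, five states under the full drug
#' combination, monostable M at high TGFB).
#'
#' @param config optional path to an alternative YAML config.
#' @param tgfb_autoregulation add the optional TGFB self-amplification
#'   variant? (robustness variant; off by default).  Because drug nodes
#'   are clamped this is modeled as a SNAIL1-mediated boost of ZEB1.
#' @return a `cac_network`.
#' @export
cac_network <- function(config = NULL, tgfb_autoregulation = FALSE) {
  path <- config %||% system.file("extdata", "cac_network.yml",
                                  package = "caclandscape")
  cfg <- load_config(path)
  net <- cfg$network
  if (tgfb_autoregulation) {
    extra <- data.frame(source = "SNAIL1", target = "ZEB1", lambda = 1.3,
                        S = 1.5, n = 2, side = "G")
    net$edges <- rbind(net$edges, extra)
    validate_network(net)
  }
  net
}

#' Calibrated phenotype thresholds for the packaged network
#' @return marker rules (see [cac_marker_rules()]) stored alongside the
#'   packaged config.
#' @export
cac_rules <- function() {
  cfg <- load_config(system.file("extdata", "cac_network.yml",
                                 package = "caclandscape"))
  cfg$rules %||% cac_marker_rules()
}

#' Set the drug input levels
#' @param net a `cac_network` with TGFB/MEKI/ROSI input nodes.
#' @param tgfb,meki,rosi levels; `NULL` leaves a level unchanged.
#' @return the updated network.
#' @export
set_drugs <- function(net, tgfb = NULL, meki = NULL, rosi = NULL) {
  v <- c(TGFB = tgfb, MEKI = meki, ROSI = rosi)
  if (length(v)) net$inputs[names(v)] <- v
  validate_network(net)
  net
}

#' Reported drug conditions for the CAC model
#'
#' The drug dose combinations used in the published landscape scans,
#' as named TGFB/MEKI/ROSI levels: `none` (baseline, monostable E),
#' `tgfb_mid` (E/M bistable), `tgfb_high` (monostable M), `tgfb_rosi`,
#' `tgfb_meki` (E/M/P1 tristable), `meki_rosi`, `full` (five states) and
#' `tgfb_high_full`.
#'
#' @return named list of length-3 numeric vectors.
#' @export
cac_conditions <- function() {
  list(
    none           = c(TGFB = 1,   MEKI = 0.001, ROSI = 0.1),
    tgfb_mid       = c(TGFB = 4.3, MEKI = 0.001, ROSI = 0.1),
    tgfb_high      = c(TGFB = 8,   MEKI = 0.001, ROSI = 0.1),
    tgfb_rosi      = c(TGFB = 4.3, MEKI = 0.001, ROSI = 1.5),
    tgfb_meki      = c(TGFB = 4.3, MEKI = 0.02,  ROSI = 0.1),
    meki_rosi      = c(TGFB = 1,   MEKI = 0.02,  ROSI = 1.5),
    full           = c(TGFB = 4.3, MEKI = 0.02,  ROSI = 1.5),
    tgfb_high_full = c(TGFB = 8,   MEKI = 0.02,  ROSI = 1.5))
}

#' Attractors of the packaged network under a named drug condition
#' @param condition name from [cac_conditions()].
#' @param net optional network (default [cac_network()]).
#' @param ... forwarded to [find_attractors()].
#' @return a labelled `attractor_set`.
#' @export
cac_attractors <- function(condition = "full", net = cac_network(), ...) {
  cond <- cac_conditions()[[condition]]
  if (is.null(cond)) stop("unknown condition: ", condition)
  net <- set_drugs(net, cond[["TGFB"]], cond[["MEKI"]], cond[["ROSI"]])
  classify_phenotype(find_attractors(net, ...), cac_rules())
}
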