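#' Default marker rules for the CAC phenotypes
#'
#' Threshold logic distilled from the expression patterns of the five
#' CAC cell states: the epithelial tumor state (E) has high P53 and
#' p53-induced microRNAs with the adipogenic program off; the mesenchymal
#' state (M) has high ZEB1/SNAIL1/MEK/ERK and low PPARG; the adipose
#' state (A) has by far the highest PPARG and CEBPA; the partial-EMT
#' states P1/P2 are intermediate in the EMT markers, P2 carrying more
#' PPARG than P1.  Thresholds are absolute marker levels (model
#' concentration units), fixed at calibration of the packaged network so
#' that classification also works for monostable attractor sets where
#' z-scoring across states is undefined.
#'
#' @param ppar_on PPARG level above which the adipogenic program counts
#'   as engaged (separates P2 from P1).
#' @param ppar_high PPARG level marking the fully adipose state A.
#' @param zeb_mid,zeb_high ZEB1 levels bounding the intermediate and
#'   mesenchymal EMT regimes.
#' @param p53_high P53 level marking the epithelial state.
#' @return a named list of thresholds usable by [classify_phenotype()].
#' @export
cac_marker_rules <- function(ppar_on = 1.7, ppar_high = 2.5,
                             zeb_mid = 0.35, zeb_high = 2.5,
                             p53_high = 0.55) {
  list(ppar_on = ppar_on, ppar_high = ppar_high,
       zeb_mid = zeb_mid, zeb_high = zeb_high, p53_high = p53_high)
}

#' Classify attractors into CAC phenotypes
#'
#' Assigns each fixed point one of E, M, A, P1, P2 or "unclassified" from
#' marker levels (see [cac_marker_rules()]).
#'
#' @param as an `attractor_set` over the CAC node set (needs the marker
#'   nodes PPARG, CEBPA, ZEB1, P53).
#' @param rules threshold list, default [cac_marker_rules()]; the packaged
#'   network ships its own calibrated copy.
#' @return the `attractor_set` with `labels` filled (unstable points keep
#'   `NA`).
#' @export
classify_phenotype <- function(as, rules = cac_marker_rules()) {
  need <- c("PPARG", "CEBPA", "ZEB1", "P53")
  missing <- setdiff(need, colnames(as$states))
  if (length(missing)) stop("marker node(s) absent from attractor states: ",
                            paste(missing, collapse = ", "))
  lab <- rep(NA_character_, length(as$stable))
  for (i in seq_along(as$stable)) {
    if (!as$stable[i]) next
    s <- as$states[i, ]
    lab[i] <-
      if (max(s) < 1e-6) "unclassified"
      else if (s["PPARG"] >= rules$ppar_high) "A"         # adipogenic program fully on
      else if (s["PPARG"] >= rules$ppar_on) "P2"          # partial EMT, adipo engaged
      else if (s["ZEB1"] >= rules$zeb_high) "M"           # mesenchymal, adipo off
      else if (s["ZEB1"] >= rules$zeb_mid) "P1"           # partial EMT, adipo off
      else if (s["P53"] >= rules$p53_high) "E"            # epithelial
      else "unclassified"
  }
  as$labels <- lab
  as
}

#' Extract the stable state carrying a given phenotype label
#' @param as a labelled `attractor_set`.
#' @param label phenotype label.
#' @return full state vector, or `NULL` if the label is absent.
#' @export
attractor_by_label <- function(as, label) {
  i <- which(as$labels == label & as$stable)
  if (!length(i)) return(NULL)
  as$states[i[1], ]
}
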