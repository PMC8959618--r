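#' Annotate signals as labeled, off-label, or undetermined
#'
#' A consensus signal whose PT is absent from the drug's product-label PT set
#' is off-label (unexpected) and deserves further scrutiny. Matching is exact
#' string equality on standardized PTs — synonym reconciliation belongs in
#' the term dictionary, not here. A drug absent from the label knowledge is
#' `undetermined`, never silently treated as labeled.
#'
#' @param signals data.frame with `generic_drug` and `pt` columns (typically
#'   [rank_signals()] output).
#' @param labels a `label_knowledge` object from [load_label_knowledge()].
#' @return `signals` with an added `offlabel` column in
#'   `{"labeled", "off-label", "undetermined"}`.
#' @export
flag_offlabel <- function(signals, labels) {
  stopifnot(inherits(labels, "label_knowledge"))
  known <- signals$generic_drug %in% names(labels)
  on_label <- as.logical(mapply(function(drug, pt) pt %in% labels[[drug]],
                                signals$generic_drug, signals$pt,
                                USE.NAMES = FALSE))
  signals$offlabel <- ifelse(!known, "undetermined",
                             ifelse(on_label, "labeled", "off-label"))
  signals
}
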