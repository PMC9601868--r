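#' Published mutant affinity panels
#'
#' The reported SPR dissociation constants of the Trim28 coiled-coil
#' mutant panels binding the ZFP932 KRAB domain, shipped as plain-text
#' tables: `"turns_faces"` holds the grouped turn/face alanine mutants of
#' the central eight coiled-coil turns, `"point"` the individual
#' alanine/serine/glutamate point mutants of the nine interface residues.
#' `kd` is in molar (`NA` = binding-deficient); `printedFold` is the
#' integer fold-decrease as published, which for a few rows was computed
#' from unrounded estimates and does not equal the ratio of the rounded
#' \eqn{K_d}s (see [foldChangeTable()]).
#'
#' @param which `"point"` (default) or `"turns_faces"`.
#' @return data.frame with columns `name`, `kd` (molar), `printedFold`.
#' @examples
#' panel <- mutantPanel("point")
#' wt <- panel$kd[panel$name == "Wild type"]
#' foldChangeTable(panel[panel$name != "Wild type", ], wt)
#' @export
mutantPanel <- function(which = c("point", "turns_faces")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("trim28_mutant_panel_", which, ".tsv"),
                      package = "coilface", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  data.frame(name = raw$name, kd = raw$kd_nM * 1e-9,
             printedFold = as.integer(raw$printed_fold),
             stringsAsFactors = FALSE)
}
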