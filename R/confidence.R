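#' Remove low-confidence residues from a predicted model
#'
#' Drops every residue whose pLDDT is strictly below `threshold` (the
#' standard pre-processing step for predicted models before interface
#' interpretation; residues exactly at the threshold are retained). Pruning
#' acts on whole residues — pLDDT is a per-residue score — and chains left
#' empty are dropped with the rest of the model order preserved.
#'
#' @param model a [StructureModel-class] whose B-factor column carries
#'   pLDDT.
#' @param threshold pLDDT cutoff, default 50.
#' @return the pruned [StructureModel-class].
#' @examples
#' # residues at 49.9 go, residues at 50.0 stay (strict "less than")
#' @export
pruneLowConfidence <- function(model, threshold = 50) {
  stopifnot(is(model, "StructureModel"))
  rt <- residueTable(model)
  if (any(is.na(rt$plddt)))
    stop("model has residues without a pLDDT value; predicted models ",
         "store pLDDT in the B-factor column - check the input source")
  keep_res <- rt[rt$plddt >= threshold, c("chain", "resno", "icode")]
  a <- model@atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  keepkey <- paste(keep_res$chain, keep_res$resno, keep_res$icode,
                   sep = "\r")
  out <- model
  out@atoms <- a[key %in% keepkey, , drop = FALSE]
  rownames(out@atoms) <- NULL
  if (nrow(out@atoms) == 0)
    stop("pruning at threshold ", threshold, " removed every residue")
  out
}

#' Per-residue confidence profile
#'
#' One row per residue in chain/residue (file) order with its pLDDT, the
#' tabular form of the per-residue confidence track plotted for predicted
#' models.
#'
#' @param model a [StructureModel-class].
#' @return data.frame with columns `chain`, `resno`, `plddt`.
#' @export
plddtProfile <- function(model) {
  stopifnot(is(model, "StructureModel"))
  rt <- residueTable(model)
  if (any(is.na(rt$plddt)))
    stop("model has residues without a pLDDT value")
  data.frame(chain = rt$chain, resno = rt$resno, plddt = rt$plddt,
             stringsAsFactors = FALSE)
}

# Resolve a SelectionSpec against a PAE residue index -> integer positions.
paeIndices <- function(pae, spec) {
  ri <- pae@residueIndex
  keep <- rep(TRUE, nrow(ri))
  if (length(spec@chainId) > 0) keep <- keep & ri$chain %in% spec@chainId
  if (length(spec@resRange) == 2)
    keep <- keep & ri$resno >= spec@resRange[1] &
      ri$resno <= spec@resRange[2]
  which(keep)
}

#' Summarize a rectangular PAE block
#'
#' Summary statistics of the PAE sub-matrix with rows/columns given by two
#' selections. AlphaFold PAE is asymmetric, so the directional (rows to
#' columns) mean is reported alongside the symmetrized mean — the average of
#' both directions — which is the headline statistic for judging the
#' confidence in the relative placement of two domains.
#'
#' @param pae a [PAEMatrix-class].
#' @param rows,cols [SelectionSpec-class] objects resolved against the PAE
#'   residue index.
#' @return list with `mean` (directional), `meanSym` (symmetrized), `min`,
#'   `max`, `nCells`, and the resolved index vectors.
#' @export
paeBlock <- function(pae, rows, cols) {
  stopifnot(is(pae, "PAEMatrix"))
  ri <- paeIndices(pae, rows)
  ci <- paeIndices(pae, cols)
  if (length(ri) == 0 || length(ci) == 0)
    stop("empty PAE block selection")
  block <- pae@values[ri, ci, drop = FALSE]
  blockT <- pae@values[ci, ri, drop = FALSE]
  list(mean = mean(block),
       meanSym = (mean(block) + mean(blockT)) / 2,
       min = min(block), max = max(block),
       nCells = length(block),
       rowIdx = ri, colIdx = ci)
}
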