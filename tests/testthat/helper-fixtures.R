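# Shared fixtures, all generated in code.

coordMatrixOf <- function(m) {
  unname(as.matrix(atomTable(m)[, c("x", "y", "z")]))
}

# minimal one-residue glycine PDB text
tinyGlyPdbLines <- function(b = 90) {
  c(sprintf("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00%6.2f           N", b),
    sprintf("ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00%6.2f           C", b),
    sprintf("ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00%6.2f           C", b),
    sprintf("ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00%6.2f           O", b),
    "END")
}

writeTinyGlyPdb <- function(path = tempfile(fileext = ".pdb"), b = 90) {
  writeLines(tinyGlyPdbLines(b), path)
  path
}

# small random multi-residue fixture for SASA cross-checks; the same
# deterministic construction is used by the frozen external-oracle values
randomSasaFixture <- function(seed) {
  set.seed(seed)
  nres <- 3
  rows <- list()
  for (r in seq_len(nres)) {
    natom <- sample(4:6, 1)
    centre <- stats::runif(3, 0, 8)
    for (k in seq_len(natom)) {
      el <- sample(c("C", "C", "N", "O", "S"), 1)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = r, resid = "UNK",
        elety = paste0(el, k), element = el,
        x = centre[1] + stats::rnorm(1, sd = 1.5),
        y = centre[2] + stats::rnorm(1, sd = 1.5),
        z = centre[3] + stats::rnorm(1, sd = 1.5),
        stringsAsFactors = FALSE)
    }
  }
  structureModel(do.call(rbind, rows), modelId = paste0("sasa_fix_", seed))
}

# default synthetic complex, built once and shared across test files
sharedComplex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildComplex(complexSpec())
    cache
  }
})

# a simple two-atom-per-molecule complex for BSA edge cases
twoCarbonModel <- function(d) {
  structureModel(data.frame(
    chain = c("A", "B"), resno = c(1, 1), resid = "UNK",
    elety = "C1", element = "C",
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
}
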