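test_that("a minimal PDB file reads into the expected hierarchy", {
  m <- readStructure(writeTinyGlyPdb())
  expect_s4_class(m, "StructureModel")
  expect_equal(chainIds(m), "A")
  expect_equal(nResidues(m), 1L)
  expect_equal(nAtoms(m), 4L)
  expect_equal(residueTable(m)$resid, "GLY")
})

test_that("per-residue pLDDT is taken from the CA B-factor", {
  m <- readStructure(writeTinyGlyPdb(b = 91.3))
  expect_equal(residueTable(m)$plddt, 91.3)
  # CA-less residue falls back to the mean atom B-factor
  atoms <- atomTable(m)
  atoms <- atoms[atoms$elety != "CA", ]
  atoms$b <- c(10, 20, 30)
  m2 <- structureModel(atoms)
  expect_equal(residueTable(m2)$plddt, 20)
})

test_that("write-then-read reproduces coordinates at PDB column precision", {
  h <- buildIdealHelix(20, sequence = "LEU")
  path <- tempfile(fileext = ".pdb")
  writeStructure(h, path)
  back <- readStructure(path)
  expect_equal(nAtoms(back), nAtoms(h))
  expect_equal(coordMatrixOf(back), round(coordMatrixOf(h), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  # idempotence: a second round trip is byte-stable
  path2 <- tempfile(fileext = ".pdb")
  writeStructure(back, path2)
  expect_equal(coordMatrixOf(readStructure(path2)), coordMatrixOf(back),
               ignore_attr = TRUE)
})

test_that("PDB fixed columns are enforced on write", {
  h <- buildIdealHelix(4)
  expect_error(writeStructure(selectAtoms(h, selectionSpec(chainId = "Z")),
                              tempfile()), "empty")
  big <- buildIdealHelix(4, startResno = 9996)
  expect_silent(writeStructure(big, tempfile(fileext = ".pdb")))
  huge <- buildIdealHelix(4, startResno = 99997)
  expect_error(writeStructure(huge, tempfile(fileext = ".pdb")), "column")
  far <- buildIdealHelix(4, axisPoint = c(99999, 0, 0))
  expect_error(writeStructure(far, tempfile(fileext = ".pdb")),
               "overflow")
})

test_that("a minimal mmCIF file reads equivalently", {
  lines <- c(
    "data_test", "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 91.30 ? 7 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 1.458 0.000 0.000 1.00 91.30 ? 7 GLY A CA 1",
    "#")
  f <- tempfile(fileext = ".cif")
  writeLines(lines, f)
  m <- readStructure(f)
  expect_equal(nAtoms(m), 2L)
  expect_equal(atomTable(m)$resno, c(7L, 7L))  # author numbering kept
  expect_equal(residueTable(m)$plddt, 91.3)
})

test_that("malformed input produces a parse error naming the file", {
  f <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", f)
  expect_error(readStructure(f), basename(f))
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
})

test_that("PAE JSON reading validates shape and sign", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error =
                              rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))),
                       f, digits = NA)
  p <- readPaeJson(f)
  expect_s4_class(p, "PAEMatrix")
  expect_equal(p@values, rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)),
               ignore_attr = TRUE)
  # AlphaFold-database array-of-objects layout
  f2 <- tempfile(fileext = ".json")
  writeLines(paste0('[{"predicted_aligned_error": [[0,1],[1,0]],',
                    '"max_predicted_aligned_error": 31.75}]'), f2)
  expect_equal(dim(readPaeJson(f2)@values), c(2L, 2L))
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error =
                              rbind(c(0, 1, 2), c(1, 0, 1))), f3,
                       digits = NA)
  expect_error(readPaeJson(f3), "square")
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error =
                              rbind(c(0, -1), c(1, 0))), f4, digits = NA)
  expect_error(readPaeJson(f4), "negative")
  f5 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(other_key = 1), f5)
  expect_error(readPaeJson(f5), "predicted_aligned_error")
})

test_that("selection filters chains, ranges, atom names and hydrogens", {
  built <- sharedComplex()
  m <- built$model
  sel <- selectAtoms(m, selectionSpec(chainId = "A",
                                      resRange = c(294, 321)))
  rt <- residueTable(sel)
  expect_true(all(rt$chain == "A"))
  expect_equal(range(rt$resno), c(294, 321))

  # hydrogens are dropped by heavyOnly
  withH <- atomTable(readStructure(writeTinyGlyPdb()))
  withH <- rbind(withH, transform(withH[1, ], elety = "H", element = "H",
                                  x = 5))
  mh <- structureModel(withH)
  noH <- selectAtoms(mh, selectionSpec(heavyOnly = TRUE))
  expect_false("H" %in% atomTable(noH)$element)

  # empty spec is the identity; selection is a projection
  expect_equal(atomTable(selectAtoms(m, selectionSpec())), atomTable(m))
  s <- selectionSpec(chainId = "C", resRange = c(1, 20),
                     atomNames = c("CA", "CB"))
  once <- selectAtoms(m, s)
  expect_equal(atomTable(selectAtoms(once, s)), atomTable(once))
})

test_that("equivalent-atom pairing is symmetric and drops unmatched atoms", {
  h <- buildIdealHelix(10, sequence = "LEU")
  map <- equivalentAtomMap(h, h)
  expect_equal(nrow(map), nAtoms(h))

  # remove one sidechain from the copy
  atoms <- atomTable(h)
  drop <- which(atoms$resno == 5 & atoms$elety %in% c("CB", "CD1"))
  h2 <- structureModel(atoms[-drop, ])
  map2 <- equivalentAtomMap(h, h2)
  expect_equal(nrow(map2), nAtoms(h) - 2L)
  expect_false(any(map2$resno == 5 & map2$elety == "CB"))

  # symmetry of the pairing
  map3 <- equivalentAtomMap(h2, h)
  expect_setequal(paste(map2$chain, map2$resno, map2$elety),
                  paste(map3$chain, map3$resno, map3$elety))

  # disjoint chains have nothing to compare
  hB <- buildIdealHelix(10, chainId = "B", sequence = "LEU")
  expect_error(equivalentAtomMap(h, hB), "no equivalent atoms")
})

test_that("altloc duplicates collapse to the highest-occupancy copy", {
  atoms <- atomTable(readStructure(writeTinyGlyPdb()))
  dup <- atoms[atoms$elety == "CA", ]
  atoms$altloc[atoms$elety == "CA"] <- "A"
  atoms$occ[atoms$elety == "CA"] <- 0.4
  dup$altloc <- "B"; dup$occ <- 0.6; dup$x <- dup$x + 1
  m <- structureModel(rbind(atoms, dup))
  path <- tempfile(fileext = ".pdb")
  writeStructure(m, path)
  back <- readStructure(path)
  ca <- atomTable(back)[atomTable(back)$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, round(dup$x, 3))  # the 0.6-occupancy altloc B wins
})
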