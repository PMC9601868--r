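chainPairModel <- function(dNZ_OE1) {
  # Lys sidechain N and Glu carboxylate O on different molecules,
  # collinear so the engineered pair is the only candidate contact
  structureModel(data.frame(
    chain = c("A", "A", "B", "B"),
    resno = 1L, resid = c("LYS", "LYS", "GLU", "GLU"),
    elety = c("CB", "NZ", "OE1", "CB"),
    element = c("C", "N", "O", "C"),
    x = c(0, 2.8, 2.8 + dNZ_OE1, 2.8 + dNZ_OE1 + 1.5),
    y = 0, z = 0, stringsAsFactors = FALSE))
}

g1 <- function() selectionSpec(chainId = c("A", "B"))
g2 <- function() selectionSpec(chainId = "C")

test_that("an engineered Lys-Glu pair classifies by distance", {
  cc <- classifyContacts(chainPairModel(3.40), selectionSpec(chainId = "A"),
                         selectionSpec(chainId = "B"))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$kind, "salt_bridge")
  expect_equal(cc$distance, 3.40, tolerance = 1e-9)
  # beyond both the salt-bridge and H-bond cutoffs: nothing
  cc2 <- classifyContacts(chainPairModel(4.10), selectionSpec(chainId = "A"),
                          selectionSpec(chainId = "B"))
  expect_equal(nrow(cc2), 0L)
  # within H-bond range but not a salt-bridge geometry: backbone O donor
  m <- chainPairModel(3.40)
  atoms <- atomTable(m)
  atoms$elety[atoms$elety == "OE1"] <- "O"   # backbone oxygen now
  cc3 <- classifyContacts(structureModel(atoms),
                          selectionSpec(chainId = "A"),
                          selectionSpec(chainId = "B"))
  expect_equal(cc3$kind, "hydrogen_bond")
})

test_that("synthetic designed contacts are recovered exactly", {
  built <- sharedComplex()
  cc <- classifyContacts(built$model, g1(), g2())
  keyGot <- with(cc, paste(kind, chainA, resnoA, atomA, resnoB, atomB))
  keyTruth <- with(built$truth$contacts,
                   paste(kind, chainA, resnoA, atomA, resnoB, atomB))
  expect_setequal(keyGot, keyTruth)
  expect_equal(cc$distance,
               built$truth$contacts$distance[
                 match(keyGot, keyTruth)], tolerance = 1e-9)
})

test_that("every reported contact satisfies its cutoff", {
  built <- sharedComplex()
  cut <- defaultContactCutoffs()
  cc <- classifyContacts(built$model, g1(), g2())
  lim <- c(salt_bridge = cut$saltBridge, hydrogen_bond = cut$hBond,
           hydrophobic = cut$hydrophobic)
  expect_true(all(cc$distance <= lim[cc$kind] + 1e-12))
})

test_that("contact classification is symmetric and rigid-motion invariant", {
  built <- sharedComplex()
  cc <- classifyContacts(built$model, g1(), g2())
  swapped <- classifyContacts(built$model, g2(), g1())
  expect_setequal(
    with(cc, paste(kind, chainA, resnoA, atomA, chainB, resnoB, atomB)),
    with(swapped, paste(kind, chainB, resnoB, atomB, chainA, resnoA,
                        atomA)))
  set.seed(8)
  rt <- randomRigidTransform()
  moved <- applyTransform(built$model,
                          new("RigidTransform", rotation = rt$R,
                              translation = rt$t))
  cc2 <- classifyContacts(moved, g1(), g2())
  expect_equal(table(cc2$kind), table(cc$kind))
})

test_that("interface residues and spans match the generator ground truth", {
  built <- sharedComplex()
  ir <- interfaceResidues(built$model, g1(), g2())
  expect_setequal(paste(ir$residues$chain, ir$residues$resno),
                  paste(built$truth$interfaceResidues$chain,
                        built$truth$interfaceResidues$resno))
  for (ch in unique(ir$spans$chain)) {
    sp <- ir$spans[ir$spans$chain == ch, ]
    tsp <- built$truth$spans[built$truth$spans$chain == ch, ]
    expect_equal(c(sp$start, sp$end), c(tsp$start, tsp$end))
    # span bounds equal min/max of the residue list
    resnos <- ir$residues$resno[ir$residues$chain == ch]
    expect_equal(c(sp$start, sp$end), range(resnos))
  }
})

test_that("separated molecules yield an empty interface", {
  m <- twoCarbonModel(100)
  ir <- interfaceResidues(m, selectionSpec(chainId = "A"),
                          selectionSpec(chainId = "B"))
  expect_equal(nrow(ir$residues), 0L)
  rep_ <- interfaceReport(m, selectionSpec(chainId = "A"),
                          selectionSpec(chainId = "B"))
  expect_equal(unname(rep_@bsa), c(0, 0), tolerance = 1e-9)
  expect_equal(nrow(rep_@contacts), 0L)
  expect_length(rep_@clusters, 0L)
  expect_equal(nrow(rep_@pins), 0L)
})

test_that("clusters recover the designed pockets and partition the nodes", {
  built <- sharedComplex()
  cc <- classifyContacts(built$model, g1(), g2())
  cl <- hydrophobicClusters(cc)
  expect_length(cl, 2L)
  got <- lapply(cl, function(x) sort(x$members$resno))
  truth <- lapply(built$truth$clusters, function(x) sort(x$members))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(truth, paste, collapse = ","))
  # partner pins are exactly the designed pin residues
  pins <- do.call(rbind, lapply(cl, function(x) x$partnerPins))
  expect_setequal(paste(pins$chain, pins$resno),
                  paste(built$truth$pins$chain, built$truth$pins$resno))
  # clusters partition the hydrophobic side-2 residues
  hp <- cc[cc$kind == "hydrophobic", ]
  nodes <- unique(paste(hp$chainB, hp$resnoB))
  memberKeys <- unlist(lapply(cl, function(x)
    paste(x$members$chain, x$members$resno)))
  expect_setequal(memberKeys, nodes)
  expect_equal(anyDuplicated(memberKeys), 0L)
  # no hydrophobic contacts: no clusters
  expect_length(hydrophobicClusters(cc[cc$kind != "hydrophobic", ]), 0L)
})

test_that("pin detection finds the designed pins and nothing else", {
  built <- sharedComplex()
  pins <- pinResidues(built$model, g1(), g2())
  expect_equal(paste(pins$chain, pins$resno),
               paste(built$truth$pins$chain, built$truth$pins$resno))
  expect_true(all(pins$buriedFraction >= 0.75))
  expect_true(all(pins$nPartners >= 4))
  # raising the partner requirement above the pocket size empties the list
  none <- pinResidues(built$model, g1(), g2(), partnerMin = 8)
  expect_equal(nrow(none), 0L)
})

test_that("the full report is consistent and flags the asymmetry", {
  built <- sharedComplex()
  rep_ <- interfaceReport(built$model, g1(), g2())
  expect_true(rep_@asymmetric)
  expect_equal(unname(rep_@bsa), unname(built$truth$bsa),
               tolerance = 1e-6)
  # every contact residue appears in the interface residue list
  irKeys <- paste(rep_@interfaceResidues$chain,
                  rep_@interfaceResidues$resno)
  expect_true(all(paste(rep_@contacts$chainA, rep_@contacts$resnoA)
                  %in% irKeys))
  expect_true(all(paste(rep_@contacts$chainB, rep_@contacts$resnoB)
                  %in% irKeys))
  # every pin's pocket is contained in some cluster's members
  memberSets <- lapply(rep_@clusters, function(cl)
    paste0("C:", cl$members$resid, cl$members$resno))
  for (k in seq_len(nrow(rep_@pins))) {
    pocket <- strsplit(rep_@pins$pocket[k], ",")[[1]]
    pocket <- sub("^C:", "C:", pocket)
    expect_true(any(vapply(memberSets, function(ms)
      all(pocket %in% ms), logical(1))))
  }
  # serialization round trip carries the headline numbers
  jpath <- tempfile(fileext = ".json")
  reportToJson(rep_, jpath)
  back <- jsonlite::fromJSON(jpath)
  expect_equal(unname(unlist(back$bsa))[1], unname(rep_@bsa[1]),
               tolerance = 1e-4)
  expect_equal(nrow(back$contacts), nrow(rep_@contacts))
  tpath <- tempfile(fileext = ".tsv")
  contactsToTsv(rep_, tpath)
  expect_equal(nrow(utils::read.delim(tpath)), nrow(rep_@contacts))
})
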