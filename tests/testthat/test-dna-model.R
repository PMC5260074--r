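test_that("duplex models have one base pair per input base", {
  m <- buildBDNA("GCGTGGGCG")
  a <- atoms(m)
  resA <- unique(a[a$chain == "A", c("resno", "resname")])
  resB <- unique(a[a$chain == "B", c("resno", "resname")])
  expect_equal(nrow(resA), 9L)
  expect_equal(nrow(resB), 9L)
  m27 <- buildBDNA(targetSequence(makeSynergisticTarget("GCG")))
  expect_equal(length(unique(atoms(m27)$resno[atoms(m27)$chain == "A"])), 27L)
  expect_error(buildBDNA("GCXG"), "invalid base")
  expect_error(buildBDNA(""), "non-empty")
})

test_that("per-base atom counts are constant", {
  m <- buildBDNA("ACGTACGT")
  a <- atoms(m)
  counts <- tapply(a$name, paste(a$chain, a$resno), length)
  res <- unique(a[, c("chain", "resno", "resname")])
  res$n <- as.integer(counts[paste(res$chain, res$resno)])
  expect_equal(unique(unname(res$n[res$resname == "DA"])), 21L)
  expect_equal(unique(unname(res$n[res$resname == "DG"])), 22L)
  expect_equal(unique(unname(res$n[res$resname == "DC"])), 19L)
  expect_equal(unique(unname(res$n[res$resname == "DT"])), 20L)
})

test_that("sequence is recovered from chain A and its reverse complement from chain B", {
  s <- "ATCGGGTACCGT"
  m <- buildBDNA(s)
  expect_equal(dnaSequence(m, "A"), s)
  expect_equal(dnaSequence(m, "B"), reverseComplement(s))
})

test_that("helical parameters round-trip through the built coordinates", {
  for (p in list(c(36, 3.38), c(34.3, 3.32))) {
    m <- buildBDNA("GACGTTTAC", twist = p[1], rise = p[2])
    hp <- helicalParameters(m)
    expect_equal(hp$twist, p[1], tolerance = 1e-6)
    expect_equal(hp$rise, p[2], tolerance = 1e-6)
    expect_true(all(abs(hp$twist_steps - p[1]) < 1e-6))
    expect_true(all(abs(hp$rise_steps - p[2]) < 1e-6))
  }
  ## invariant under rigid motion of the whole model
  m <- buildBDNA("GCGTGG")
  mt <- transformModel(m, randomRotation(11), c(-4, 9, 2))
  hp <- helicalParameters(mt)
  expect_equal(hp$twist, 36, tolerance = 1e-6)
  expect_equal(hp$rise, 3.38, tolerance = 1e-6)
})

test_that("paired Watson-Crick anchors sit at hydrogen-bonding distance", {
  m <- buildBDNA("ACGTACGTA")
  a <- atoms(m)
  n <- 9L
  for (i in seq_len(n)) {
    ra <- a[a$chain == "A" & a$resno == i, ]
    rb <- a[a$chain == "B" & a$resno == n + 1L - i, ]
    nmA <- if (ra$resname[1] %in% c("DA", "DG")) "N1" else "N3"
    nmB <- if (rb$resname[1] %in% c("DA", "DG")) "N1" else "N3"
    pa <- as.numeric(ra[ra$name == nmA, c("x", "y", "z")])
    pb <- as.numeric(rb[rb$name == nmB, c("x", "y", "z")])
    d <- sqrt(sum((pa - pb)^2))
    expect_gt(d, 2.7); expect_lt(d, 3.1)
  }
})

test_that("PDB write/read round-trips the model at format precision", {
  m <- buildBDNA("GCGTGGGCG")
  path <- tempfile(fileext = ".pdb")
  writePDB(m, path)
  m2 <- readPDB(path)
  expect_equal(nAtoms(m2), nAtoms(m))
  expect_equal(dnaSequence(m2, "A"), "GCGTGGGCG")
  xyz1 <- as.matrix(atoms(m)[, c("x", "y", "z")])
  xyz2 <- as.matrix(atoms(m2)[, c("x", "y", "z")])
  expect_lt(max(abs(xyz1 - xyz2)), 1e-3)
  ## empty model: error, no file written
  empty <- new("StructureModel", atoms = atoms(m)[0, ])
  p2 <- tempfile(fileext = ".pdb")
  expect_error(writePDB(empty, p2), "empty")
  expect_false(file.exists(p2))
})

test_that("batch export writes one PDB per target", {
  targets <- enumerateTargets("modular", "NNN")[seq_len(6)]
  dir <- tempfile()
  files <- writeTargetModels(targets, dir)
  expect_length(files, 6L)
  expect_true(all(file.exists(files)))
  expect_equal(basename(files[1]),
               paste0(targetId(targets[[1]]), ".pdb"))
})
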