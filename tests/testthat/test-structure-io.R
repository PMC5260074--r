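test_that("PDB parsing partitions protein and nucleotide residues", {
  fx <- makeFixture(data.frame(class = "N-O", d = 3.0, theta = 30))
  path <- tempfile(fileext = ".pdb")
  writePDB(fx$model, path)
  m <- readPDB(path)
  a <- atoms(m)
  expect_setequal(unique(a$kind), c("protein", "nucleotide"))
  expect_equal(sort(unique(a$resname[a$kind == "protein"])), "ARG")
  expect_equal(sort(unique(a$resname[a$kind == "nucleotide"])), "DG")
  ## parsing is idempotent: read(write(read(f))) == read(f)
  p2 <- tempfile(fileext = ".pdb")
  writePDB(m, p2)
  m2 <- readPDB(p2)
  expect_equal(atoms(m2), atoms(m))
  expect_error(readPDB(tempfile()), "no such file")
})

test_that("legacy one-letter DNA residue names are accepted", {
  lines <- c(
    "ATOM      1  N1    G A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O6    G A   1       1.300   1.000   0.000  1.00  0.00           O",
    "ATOM      3  CA  ARG B   1       2.000   0.000   2.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  a <- atoms(readPDB(path))
  expect_equal(a$resname[a$chain == "A"], c("DG", "DG"))
  expect_equal(unique(a$kind[a$chain == "A"]), "nucleotide")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  CA AARG A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BARG A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  N  AARG A   1       1.500   0.000   0.000  1.00  0.00           N",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  a <- atoms(readPDB(path))
  expect_equal(sum(a$name == "CA"), 1L)
  expect_equal(a$x[a$name == "CA"], 9.0)  # the 0.60-occupancy copy
})

test_that("donor/acceptor roles follow the chemistry table", {
  m <- makeFixture(data.frame(class = "N-O", d = 3.0, theta = 10))$model
  cl <- classifyDonorAcceptor(m)
  role_of <- function(res, atom) cl$role[cl$resname == res & cl$name == atom][1]
  expect_equal(role_of("ARG", "NH1"), "donor")
  expect_equal(role_of("DG", "O6"), "acceptor")
  expect_equal(role_of("ARG", "CZ"), "none")  # carbons never score
  ## backbone polar atoms are classified but excluded by default
  pep <- buildPeptide("AR", library = NULL)
  clp <- classifyDonorAcceptor(pep)
  expect_equal(clp$role[clp$name == "N"], c("none", "none"))
  clp2 <- classifyDonorAcceptor(pep, includeBackbone = TRUE)
  expect_equal(clp2$role[clp2$name == "N"], c("donor", "donor"))
})

test_that("chemistry table is total over polar atoms of standard residues", {
  ## every N/O/S atom the builders can produce has an explicit table entry
  pep <- buildPeptide("ARNDCQEGHILKMFPSTWYV")
  dna <- buildBDNA("ACGT")
  for (m in list(pep, dna)) {
    expect_silent(cl <- classifyDonorAcceptor(m))
    a <- atoms(m)
    tab <- donorAcceptorTable()
    polar <- a[a$element %in% c("N", "O", "S"), ]
    hit <- paste(polar$resname, polar$name) %in% paste(tab$resname, tab$atom)
    expect_true(all(hit))
  }
})

test_that("helix positions resolve by offset from the helix start", {
  pm <- list(chain = "A", helix_start = c(19L, 47L, 75L))
  expect_equal(resolveHelixPositions(pm, 1, c(-1L, 2L, 3L, 6L)),
               c(18L, 20L, 21L, 24L))
  expect_equal(resolveHelixPositions(pm, 3, 1L), 75L)
  expect_error(resolveHelixPositions(pm, 1, 7L), "invalid helix position")
  expect_error(resolveHelixPositions(pm, 1, 0L), "invalid helix position")
  expect_error(resolveHelixPositions(pm, 4, 1L), "finger 4")
})

test_that("interface selection returns the key residues and sub-site bases", {
  tc <- syntheticTemplateComplex(makeModularTarget("GCG", 1))
  sel <- selectInterfaceResidues(tc$model, tc$positionMap, 1,
                                 tc$windows[[1]], dnaChain = tc$dnaChain)
  expect_setequal(unique(sel$helix$resno), c(18L, 20L, 21L, 24L))
  expect_setequal(unique(sel$bases$resno), 1:3)
  ## a three-finger map yields 3 x 4 key residues in total
  nres <- 0L
  for (f in 1:3) {
    s <- selectInterfaceResidues(tc$model, tc$positionMap, f,
                                 tc$windows[[f]], dnaChain = tc$dnaChain)
    nres <- nres + length(unique(s$helix$resno))
  }
  expect_equal(nres, 12L)
  expect_error(
    selectInterfaceResidues(tc$model, tc$positionMap, 1, tc$windows[[1]],
                            dnaChain = tc$dnaChain, keyPositions = 7L),
    "invalid helix position")
})

test_that("position maps load from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("chain: P", "helix_start: [19, 47, 75]"), path)
  pm <- readPositionMap(path)
  expect_equal(pm$chain, "P")
  expect_equal(pm$helix_start, c(19L, 47L, 75L))
  bad <- tempfile(fileext = ".yaml")
  writeLines("chain: P", bad)
  expect_error(readPositionMap(bad), "helix_start")
})
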