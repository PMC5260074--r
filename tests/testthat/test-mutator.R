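test_that("rotamer library validates chemistry and frequencies", {
  lib <- defaultRotamerLibrary()
  expect_true(all(unique(lib$resname) %in%
                  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL")))
  expect_equal(length(unique(lib$resname)), 20L)
  sums <- tapply(lib$frequency, lib$resname, sum)
  expect_true(all(sums <= 1 + 1e-9))
  ## a row with the wrong chi count is rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("resname\tchi1\tchi2\tchi3\tchi4\tfrequency",
               "SER\t62\t180\tNA\tNA\t0.5"), bad)
  expect_error(readRotamerLibrary(bad), "expected 1")
})

test_that("glycine mutation strips the side chain entirely", {
  pep <- buildPeptide("KRK")
  m <- placeSidechain(pep, "P", 2, "G")
  a <- atoms(m)
  expect_setequal(a$name[a$resno == 2], c("N", "CA", "C", "O"))
  expect_equal(unique(a$resname[a$resno == 2]), "GLY")
})

test_that("identity mutation reproduces the input coordinates", {
  pep <- buildPeptide("AAA")
  m <- placeSidechain(pep, "P", 2, "A")  # Ala -> Ala, CB rebuilt
  expect_equal(nAtoms(m), nAtoms(pep))
  x1 <- atoms(pep); x2 <- atoms(m)
  key <- function(a) a[order(a$resno, a$name), c("x", "y", "z")]
  expect_equal(unname(as.matrix(key(x2))), unname(as.matrix(key(x1))),
               tolerance = 1e-9)
})

test_that("chi angles round-trip through placement for all residues", {
  lib <- defaultRotamerLibrary()
  pep <- buildPeptide("GGG", library = NULL)
  for (res in setdiff(unique(lib$resname), c("ALA", "GLY"))) {
    rows <- lib[lib$resname == res, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      chis <- as.numeric(rows[k, c("chi1", "chi2", "chi3", "chi4")])
      chis <- chis[!is.na(chis)]
      m <- placeSidechain(pep, "P", 2, res, chis)
      got <- measureChiAngles(m, "P", 2)
      expect_lt(max(angDiff(got, chis)), 1e-3)
      ## independent torsion measurement agrees
      defs <- zfscore:::.CHI_DEFS[[res]]
      ref <- vapply(defs, function(d) {
        refDihedral(atomCoord(m, "P", 2, d[1]), atomCoord(m, "P", 2, d[2]),
                    atomCoord(m, "P", 2, d[3]), atomCoord(m, "P", 2, d[4]))
      }, numeric(1))
      expect_lt(max(angDiff(ref, chis)), 1e-3)
    }
  }
})

test_that("backbone atoms are untouched by any mutation", {
  pep <- buildPeptide("RKQN")
  bb <- function(m) {
    a <- atoms(m)
    a <- a[a$name %in% c("N", "CA", "C", "O"), ]
    a <- a[order(a$resno, a$name), c("resno", "name", "x", "y", "z")]
    rownames(a) <- NULL
    a[, c("x", "y", "z")]
  }
  before <- bb(pep)
  m <- placeSidechain(pep, "P", 1, "W", c(-65, 95))
  expect_identical(bb(m), before)
  ch <- chooseRotamer(pep, "P", 3, "E")
  expect_identical(bb(ch$model), before)
})

test_that("rotamer choice equals an exhaustive clash scan", {
  ## crowd residue 2 with a neighbouring chain so clashes discriminate
  pep <- buildPeptide("AKA")
  wall <- buildBDNA("GGG")
  a <- atoms(pep)
  ca2 <- as.numeric(a[a$resno == 2 & a$name == "CA", c("x", "y", "z")])
  wall <- transformModel(wall, diag(3), ca2 + c(4.5, 1.0, 0))
  aw <- rbind(atoms(pep), atoms(wall))
  aw$serial <- seq_len(nrow(aw))
  crowded <- new("StructureModel", atoms = aw)
  lib <- defaultRotamerLibrary()
  for (aa in c("LYS", "ARG", "GLU", "MET")) {
    pick <- chooseRotamer(crowded, "P", 2, aa, lib)
    ## brute force: place every rotamer, count close heavy-atom pairs
    rows <- which(lib$resname == aa)
    best <- NULL
    for (k in seq_along(rows)) {
      chis <- as.numeric(lib[rows[k], c("chi1", "chi2", "chi3", "chi4")])
      chis <- chis[!is.na(chis)]
      cand <- placeSidechain(crowded, "P", 2, aa, chis)
      ac <- atoms(cand)
      sc <- ac[ac$resno == 2 & ac$chain == "P" &
               !ac$name %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
      oth <- ac[!(ac$resno == 2 & ac$chain == "P"), c("x", "y", "z")]
      dmat <- as.matrix(dist(rbind(sc, oth)))[seq_len(nrow(sc)),
                                              nrow(sc) + seq_len(nrow(oth))]
      ncl <- sum(dmat < 2.5)
      fr <- lib$frequency[rows[k]]
      if (is.null(best) || ncl < best$cl ||
          (ncl == best$cl && fr > best$fr))
        best <- list(k = k, cl = ncl, fr = fr)
    }
    expect_equal(pick$index, best$k)
    expect_equal(pick$clashes, best$cl)
  }
  ## isolated residue: clash counts all zero, highest frequency wins
  iso <- chooseRotamer(pep, "P", 2, "LEU", lib)
  leu <- lib[lib$resname == "LEU", ]
  expect_equal(iso$frequency, max(leu$frequency))
  ## single-rotamer library returns that rotamer
  single <- lib[lib$resname == "SER", ][2, , drop = FALSE]
  pick1 <- chooseRotamer(pep, "P", 2, "SER", single)
  expect_equal(pick1$chis, -65)
  expect_error(chooseRotamer(pep, "P", 2, "TRP", single), "no entry")
})

test_that("threading a helix is deterministic, idempotent and backbone-safe", {
  tc <- syntheticTemplateComplex(makeModularTarget("GAA", 2))
  h <- helixFromCode("QSGHLTK", 2)
  r1 <- applyHelix(tc$model, h, tc$positionMap)
  r2 <- applyHelix(tc$model, h, tc$positionMap)
  expect_identical(atoms(mutatedModel(r1)), atoms(mutatedModel(r2)))
  expect_lte(nrow(mutationSites(r1)), 3L)
  ## idempotence: re-applying the same helix changes nothing
  r3 <- applyHelix(mutatedModel(r1), h, tc$positionMap)
  expect_identical(atoms(mutatedModel(r3)), atoms(mutatedModel(r1)))
  expect_equal(nrow(mutationSites(r3)), 0L)
  ## backbone identical to the template's
  bb <- function(m) {
    a <- atoms(m)
    a <- a[a$kind == "protein" & a$name %in% c("N", "CA", "C", "O"), ]
    a[order(a$chain, a$resno, a$name), c("x", "y", "z")]
  }
  expect_equal(unname(as.matrix(bb(mutatedModel(r1)))),
               unname(as.matrix(bb(tc$model))))
})

test_that("placement errors are informative", {
  pep <- buildPeptide("AAA")
  expect_error(placeSidechain(pep, "P", 9, "R", c(0, 0, 0, 0)), "no residue")
  expect_error(placeSidechain(pep, "P", 2, "R", c(0, 0)), "4 chi")
  expect_error(placeSidechain(pep, "P", 2, "X"), "unknown amino acid")
  ## missing backbone atom
  a <- atoms(pep)
  a <- a[!(a$resno == 2 & a$name == "CA"), ]
  broken <- new("StructureModel", atoms = a)
  expect_error(placeSidechain(broken, "P", 2, "S", 62), "backbone atom")
})
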