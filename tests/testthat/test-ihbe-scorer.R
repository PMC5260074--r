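test_that("bond energy matches the closed form", {
  ## optimum geometry gives exactly -epsilon per class
  expect_identical(hbondEnergy(3.2, 0, "N-N"), -2.0)
  expect_identical(hbondEnergy(3.0, 0, "N-O"), -2.8)
  expect_identical(hbondEnergy(2.8, 0, "O-O"), -4.0)
  ## orthogonal geometry contributes nothing at any distance
  for (d in c(2.0, 2.8, 3.4)) expect_identical(hbondEnergy(d, 90, "O-O"), 0)
  ## direct numeric evaluation at an off-optimum geometry
  d <- 3.4; th <- 25
  byhand <- 2.8 * (3 * (3.0 / d)^8 - 4 * (3.0 / d)^6) * cos(th * pi / 180)^4
  expect_equal(hbondEnergy(d, th, "N-O"), byhand, tolerance = 1e-12)
  expect_error(hbondEnergy(3.0, 0, "N-S"), "unknown")
  ## |energy| non-increasing as theta goes 0 -> 90
  thetas <- seq(0, 90, by = 5)
  es <- abs(hbondEnergy(3.1, thetas, "N-O"))
  expect_true(all(diff(es) <= 1e-12))
})

test_that("interface pair screen applies cutoff and carbon exclusion", {
  fx <- makeFixture(data.frame(class = "N-O", d = 3.0, theta = 0))
  a <- atoms(fx$model)
  prot <- a[a$kind == "protein", ]; dna <- a[a$kind == "nucleotide", ]
  expect_equal(nrow(findInterfacePairs(prot, dna, 3.5)), 1L)
  expect_equal(findInterfacePairs(prot, dna, 3.5)$dist, 3.0, tolerance = 1e-12)
  ## same atoms placed at 3.6 A: outside the 350 pm screen
  dna2 <- dna; dna2$x <- dna2$x + 0.6
  expect_equal(nrow(findInterfacePairs(prot, dna2, 3.5)), 0L)
  ## a carbon at hydrogen-bonding distance is ignored
  carb <- dna; carb$name <- "C5'"; carb$element <- "C"
  expect_equal(nrow(findInterfacePairs(prot, carb, 3.5)), 0L)
})

test_that("pair resolution respects roles and idealized hydrogen geometry", {
  fx <- makeFixture(data.frame(class = "N-O", d = 2.9, theta = 30))
  a <- atoms(fx$model)
  pairs <- findInterfacePairs(a[a$kind == "protein", ],
                              a[a$kind == "nucleotide", ], 3.5)
  b <- resolveHBond(pairs[1, ], fx$model)
  expect_equal(b$class, "N-O")
  expect_match(b$donor, "ARG.*NH1")
  expect_match(b$acceptor, "DG.*O6")
  expect_equal(b$theta, 30, tolerance = 1e-6)
  ## acceptor-acceptor pair: rejected (no donor)
  rej <- data.frame(
    name = c("OD1", "O6"), resname = c("ASP", "DG"),
    chain = c("P", "D"), resno = c(1, 1),
    x = c(0, 2.9), y = 0, z = 0)
  m <- new("StructureModel", atoms = zfscore:::.makeAtomsDF(
    rej$name, rej$resname, rej$chain, rej$resno,
    as.matrix(rej[, c("x", "y", "z")])))
  a2 <- atoms(m)
  p2 <- findInterfacePairs(a2[a2$kind == "protein", ],
                           a2[a2$kind == "nucleotide", ], 3.5)
  expect_equal(nrow(p2), 1L)
  expect_null(resolveHBond(p2[1, ], m))
})

test_that("complex scores are additive over planted bonds", {
  fx <- makeFixture(data.frame(class = c("N-N", "N-O"), d = c(3.2, 3.0),
                               theta = c(0, 0)))
  rec <- scoreComplex(fx$model)
  expect_equal(totalEnergy(rec), -4.8, tolerance = 1e-12)
  expect_equal(bondScore(rec), 4.8, tolerance = 1e-12)
  expect_equal(nrow(hbonds(rec)), 2L)
  ## no qualifying pairs: zero total, zero score
  empty <- makeFixture(data.frame(class = "N-N", d = 3.2, theta = 0)[0, ],
                       decoys = 5L)
  rec0 <- scoreComplex(empty$model)
  expect_identical(totalEnergy(rec0), 0)
  expect_identical(bondScore(rec0), 0)
})

test_that("scores are invariant under rigid motion", {
  fx <- makeFixture(data.frame(class = c("N-O", "O-O", "N-N"),
                               d = c(3.1, 2.8, 3.3), theta = c(20, 0, 45)),
                    decoys = 4L)
  base <- totalEnergy(scoreComplex(fx$model))
  for (seed in 1:5) {
    R <- randomRotation(seed)
    set.seed(seed + 100)
    t <- runif(3, -20, 20)
    moved <- transformModel(fx$model, R, t)
    expect_equal(totalEnergy(scoreComplex(moved)), base, tolerance = 1e-9)
  }
})

test_that("pipeline total equals the exhaustive oracle on decoy structures", {
  for (seed in 1:40) {
    m <- randomFixture(30, seed)
    expect_equal(totalEnergy(scoreComplex(m)), oracleScore(m),
                 tolerance = 1e-12)
  }
})

test_that("strict hydrogen mode rejects donors without explicit hydrogens", {
  fx <- makeFixture(data.frame(class = "N-O", d = 3.0, theta = 0))
  strict <- hbondParams(hMode = "strict")
  rec <- scoreComplex(fx$model, strict)
  expect_identical(totalEnergy(rec), 0)
})

test_that("bond reports serialize as TSV", {
  fx <- makeFixture(data.frame(class = "O-O", d = 2.8, theta = 0))
  rec <- scoreComplex(fx$model)
  path <- tempfile(fileext = ".tsv")
  writeBondReport(rec, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 1L)
  expect_equal(df$energy, -4.0, tolerance = 1e-12)
})
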