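test_that("planted bonds are recovered exactly and decoys never score", {
  fx <- makeFixture(data.frame(class = c("N-N", "N-O", "O-O"),
                               d = c(3.25, 2.95, 2.8),
                               theta = c(10, 35, 0)),
                    decoys = 9L)
  rec <- scoreComplex(fx$model)
  expect_equal(nrow(hbonds(rec)), 3L)
  expect_equal(totalEnergy(rec), fx$expected, tolerance = 1e-9)
  ## every reported bond is a planted one (donor chain P, acceptor chain D,
  ## residue numbers within the planted range)
  b <- hbonds(rec)
  expect_true(all(grepl("^P:", b$donor)))
  expect_true(all(grepl("^D:", b$acceptor)))
  resno <- as.integer(sub(".*?(\\d+):.*", "\\1", b$acceptor))
  expect_true(all(resno <= 3L))
  ## zero bonds, many decoys: exact zero
  none <- makeFixture(data.frame(class = character(), d = numeric(),
                                 theta = numeric()), decoys = 100L)
  expect_identical(scoreComplex(none$model)@totalEnergy, 0)
})

test_that("closed-form expectations hold over a geometry grid", {
  grid <- expand.grid(class = c("N-N", "N-O", "O-O"),
                      d = c(2.8, 3.0, 3.2, 3.45),
                      theta = c(0, 15, 40), stringsAsFactors = FALSE)
  grid <- grid[grid$theta == 0 | grid$class != "O-O", ]
  for (i in seq_len(nrow(grid))) {
    fx <- makeFixture(grid[i, , drop = FALSE], decoys = 3L)
    expect_equal(totalEnergy(scoreComplex(fx$model)), fx$expected,
                 tolerance = 1e-9,
                 label = sprintf("%s d=%.2f theta=%g", grid$class[i],
                                 grid$d[i], grid$theta[i]))
  }
})

test_that("unrealizable planted geometry is refused", {
  expect_error(makeFixture(data.frame(class = "N-N", d = 1.0, theta = 0)),
               "unrealizable")
  expect_error(makeFixture(data.frame(class = "O-O", d = 2.8, theta = 20)),
               "rotatable donors")
  expect_error(makeFixture(data.frame(class = "N-O", d = 3.0, theta = 75)),
               "60 degrees")
  expect_error(makeFixture(data.frame(class = "X-X", d = 3.0, theta = 0)),
               "unknown bond class")
})

test_that("random fixtures are reproducible and rigid-invariant", {
  m1 <- randomFixture(40, seed = 123)
  m2 <- randomFixture(40, seed = 123)
  expect_identical(atoms(m1), atoms(m2))
  m3 <- randomFixture(40, seed = 124)
  expect_false(identical(atoms(m1), atoms(m3)))
  s <- totalEnergy(scoreComplex(m1))
  rot <- transformModel(m1, randomRotation(5), c(3, -8, 11))
  expect_equal(totalEnergy(scoreComplex(rot)), s, tolerance = 1e-9)
})

test_that("the synthetic template exposes three addressable finger interfaces", {
  tc <- syntheticTemplateComplex(makeSynergisticTarget("GCG"))
  expect_setequal(chainIds(tc$model), c("A", "B", "P"))
  a <- atoms(tc$model)
  expect_equal(sum(a$kind == "protein" & a$name == "CA"), 21L)  # 3 x 7 residues
  for (f in 1:3) {
    sel <- selectInterfaceResidues(tc$model, tc$positionMap, f,
                                   tc$windows[[f]], dnaChain = tc$dnaChain)
    expect_equal(length(unique(sel$bases$resno)), 3L)
  }
})
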