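# A hand-built template complex with one planted bond per finger: known
# per-finger energies (N-N 3.2 A -> 2.0; N-O 3.0 A -> 2.8; N-N 3.3 A)
# at the mapped key positions, so pipeline contracts can be checked
# against closed-form numbers without any threading.
plantedTemplate <- local({
  e3 <- 2.0 * (3 * (3.2 / 3.3)^8 - 4 * (3.2 / 3.3)^6)
  pm <- list(chain = "P", helix_start = c(19L, 47L, 75L))
  build <- function(ignored_target = NULL) {
    rows <- list()
    add <- function(name, res, chain, resno, p)
      rows[[length(rows) + 1L]] <<- data.frame(
        name = name, resname = res, chain = chain, resno = resno,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    donors <- data.frame(resno = c(18L, 46L, 74L), d = c(3.2, 3.0, 3.3),
                         acc = c("N7", "O6", "N7"), accres = c(1L, 4L, 7L))
    for (f in 1:3) {
      y0 <- 25 * f
      add("NZ", "LYS", "P", donors$resno[f], c(0, y0, 0))
      add(donors$acc[f], "DG", "A", donors$accres[f], c(donors$d[f], y0, 0))
      ## inert carbon placeholders at key positions +2, +3, +6
      for (k in seq_along(off <- c(2L, 3L, 6L)))
        add("CB", "ALA", "P", donors$resno[f] + off[k], c(-6, y0 + k, 0))
    }
    df <- do.call(rbind, rows)
    df <- unique(df)
    m <- new("StructureModel", atoms = zfscore:::.makeAtomsDF(
      df$name, df$resname, df$chain, df$resno,
      as.matrix(df[, c("x", "y", "z")])))
    list(model = m, positionMap = pm, dnaChain = "A",
         windows = list(1:3, 4:6, 7:9))
  }
  list(build = build, energies = c(2.0, 2.8, abs(e3)), e3 = e3,
       pool = aminoAcidPool("K", "A", "A"))
})

test_that("ranking is deterministic with the documented tie-breaks", {
  rec <- data.frame(
    helix = c("BSGALTA", "ASGALTA", "CSGALTA"),
    short_code = c("BAA", "AAA", "CAA"),
    triplet = "GGG", finger = 1L,
    total_energy = c(3.2, -5.0, 5.0),
    score = c(3.2, 5.0, 5.0),
    n_bonds = 1L, stringsAsFactors = FALSE)
  tab <- rankRecords(rec, key = "GGG/F1")
  r <- rankedRecords(tab)
  ## tie at 5.0: signed -5.0 ranks above +5.0; 3.2 last
  expect_equal(r$helix, c("ASGALTA", "CSGALTA", "BSGALTA"))
  expect_equal(r$rank, 1:3)
  ## permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    tab2 <- rankRecords(rec[perm, ], key = "GGG/F1")
    expect_identical(rankedRecords(tab2), r)
  }
  expect_warning(t0 <- rankRecords(rec[0, ]), "empty")
  expect_equal(nrow(rankedRecords(t0)), 0L)
})

test_that("modular scores are finger-dependent and combine additively", {
  tabs <- runModular("GGG", fingers = 1:3, pool = plantedTemplate$pool,
                     templateFn = plantedTemplate$build)
  expect_length(tabs, 3L)
  got <- vapply(1:3, function(f)
    rankedRecords(tabs[[sprintf("GGG/F%d", f)]])$score[1], numeric(1))
  expect_equal(got, plantedTemplate$energies, tolerance = 1e-9)
  ## same helix, different finger slots, different energies: positional
  ## dependence is non-degenerate on this geometry
  expect_gt(max(got) - min(got), 0.5)
  ## 9-bp query: per-slot winners concatenate, scores add exactly
  comb <- combineModular(tabs, "GGGGGGGGG")
  expect_equal(comb$total, sum(plantedTemplate$energies), tolerance = 1e-9)
  expect_equal(comb$scores, got, tolerance = 1e-12)
  expect_error(combineModular(tabs, "AAAGGGGGG"), "no ranking table")
  expect_error(combineModular(tabs, "GGGG"), "9 nt")
})

test_that("synergistic whole-complex score sums the planted finger bonds", {
  tabs <- runSynergistic("GGG", pool = plantedTemplate$pool,
                         templateFn = plantedTemplate$build)
  r <- rankedRecords(tabs[["GGGGGGGGG"]])
  expect_equal(nrow(r), 1L)
  expect_equal(r$total_energy, -2.0 - 2.8 + plantedTemplate$e3,
               tolerance = 1e-9)
  expect_equal(r$score, abs(r$total_energy))
  expect_equal(r$n_bonds, 3L)
})

test_that("every enumerated helix is scored, deterministically", {
  pool <- aminoAcidPool(c("K", "R"), c("A", "N"), "A")
  tc <- syntheticTemplateComplex(makeModularTarget("GCG", 1))
  tabs1 <- runModular("GCG", fingers = 1L, pool = pool,
                      templateFn = function(tg) tc)
  r1 <- rankedRecords(tabs1[["GCG/F1"]])
  expect_equal(nrow(r1), 4L)  # |records| = product of pool sizes
  expect_setequal(r1$short_code, c("KAA", "KNA", "RAA", "RNA"))
  ## byte-identical CSV across repeated runs
  tabs2 <- runModular("GCG", fingers = 1L, pool = pool,
                      templateFn = function(tg) tc)
  f1 <- tempfile(); f2 <- tempfile()
  writeRankingCsv(tabs1[["GCG/F1"]], f1)
  writeRankingCsv(tabs2[["GCG/F1"]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("propensity frequencies normalize per finger and position", {
  tabs <- runModular("GGG", fingers = 1:3, pool = plantedTemplate$pool,
                     templateFn = plantedTemplate$build)
  pr <- suppressWarnings(propensityReport(tabs, topK = 5L))
  ## single candidate helix: every frequency is 1
  expect_true(all(pr$frequency == 1))
  sums <- tapply(pr$frequency, paste(pr$finger, pr$position), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ## degenerate scores + full-table top-k: frequencies equal the pool's
  ## uniform composition (each residue appears equally often by symmetry)
  pool <- aminoAcidPool(c("K", "R"), c("A", "N"), c("A", "T"))
  hs <- enumerateHelices(pool, 1)
  rec <- do.call(rbind, lapply(hs, function(h) data.frame(
    helix = longCode(h), short_code = shortCode(h), triplet = "GGG",
    finger = 1L, total_energy = 0, score = 0, n_bonds = 0L,
    stringsAsFactors = FALSE)))
  tab <- rankRecords(rec, "GGG/F1")
  pr2 <- propensityReport(list(tab), topK = nrow(rec))
  expect_true(all(abs(pr2$frequency - 0.5) < 1e-12))
  ## top_k larger than the table warns and uses the full table
  expect_warning(propensityReport(list(tab), topK = 99L), "only")
})
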