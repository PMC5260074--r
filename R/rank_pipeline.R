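#' @include ihbe_scorer.R
NULL

## Pipeline orchestration: target enumeration -> helix enumeration ->
## threading -> scoring -> ranking, for the modular (per 3-bp sub-site)
## and synergistic (whole 27-bp target) binding models.

.emptyRecords <- function() {
  data.frame(helix = character(), short_code = character(),
             triplet = character(), finger = integer(),
             total_energy = numeric(), score = numeric(),
             n_bonds = integer(), stringsAsFactors = FALSE)
}

.recordRow <- function(rec, helix) {
  data.frame(helix = longCode(helix), short_code = shortCode(helix),
             triplet = rec@triplet, finger = rec@finger,
             total_energy = rec@totalEnergy, score = rec@score,
             n_bonds = nrow(rec@bonds), stringsAsFactors = FALSE)
}

#' Rank score records
#'
#' Orders records by descending absolute score; ties are broken by the
#' more negative signed energy first, then by helix code, so the ordering
#' is deterministic and independent of input order.
#'
#' @param records data.frame of score rows (columns `helix`,
#'   `short_code`, `triplet`, `finger`, `total_energy`, `score`,
#'   `n_bonds`).
#' @param key label for the resulting table.
#' @return a [RankingTable].
#' @export
rankRecords <- function(records, key = "") {
  if (!nrow(records)) {
    warning("ranking an empty record set", call. = FALSE)
    rr <- cbind(rank = integer(), .emptyRecords())
    return(new("RankingTable", key = key, records = rr))
  }
  ord <- order(-records$score, records$total_energy, records$helix)
  out <- records[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  new("RankingTable", key = key, records = out)
}

## Score one threaded complex restricted to one finger's interface.
.scoreFinger <- function(model, tmpl, finger, params, helix,
                         keyPositions = c(-1L, 2L, 3L, 6L)) {
  sel <- selectInterfaceResidues(model, tmpl$positionMap, finger,
                                 tmpl$windows[[finger]],
                                 dnaChain = tmpl$dnaChain,
                                 keyPositions = keyPositions)
  scoreComplex(model, params, helixAtoms = sel$helix, baseAtoms = sel$bases,
               helixId = longCode(helix),
               triplet = .tripletFromWindow(tmpl, finger),
               finger = finger)
}

## Triplet string of one finger read off the template DNA.
.tripletFromWindow <- function(tmpl, finger) {
  a <- atoms(tmpl$model)
  w <- tmpl$windows[[finger]]
  nuc <- a[a$chain == tmpl$dnaChain & a$resno %in% w &
           a$kind == "nucleotide", c("resno", "resname")]
  nuc <- unique(nuc[order(nuc$resno), ])
  paste(sub("^D", "", nuc$resname), collapse = "")
}

#' Score all candidate helices for modular binding
#'
#' For each requested (triplet, finger slot): builds the 9-bp modular
#' target complex, threads every candidate helix onto that finger
#' (fixed backbone, clash-minimizing rotamers), scores the finger's
#' interface with the triplet's bases, and ranks the candidates. Under
#' the modular model each finger binds independently, so a 9-bp
#' prediction is the concatenation of per-slot winners and its energy the
#' sum of the per-finger energies (see [combineModular]).
#'
#' @param triplets character vector of 3-bp sub-sites.
#' @param fingers finger slots to score (default all three).
#' @param pool an [AminoAcidPool] (approach 1 default; use
#'   `poolFromConfig(3)` for the all-20 space).
#' @param params an [HBondParams].
#' @param library rotamer library.
#' @param templateFn function mapping a [DnaTarget] to a template-complex
#'   list (`model`, `positionMap`, `dnaChain`, `windows`); default
#'   [syntheticTemplateComplex]. Supply a loader for a docked/crystal
#'   template to score real structures.
#' @param scaffold helix scaffold residues (positions 1, 2, 4, 5).
#' @param verbose print per-key progress.
#' @return named list of [RankingTable], keyed `"<triplet>/F<finger>"`.
#' @export
runModular <- function(triplets, fingers = 1:3, pool = poolFromConfig(1),
                       params = hbondParams(),
                       library = defaultRotamerLibrary(),
                       templateFn = syntheticTemplateComplex,
                       scaffold = .DEFAULT_SCAFFOLD, verbose = FALSE) {
  out <- list()
  for (trip in triplets) {
    for (f in fingers) {
      tmpl <- templateFn(makeModularTarget(trip, f))
      helices <- enumerateHelices(pool, finger = f, scaffold = scaffold)
      rows <- vector("list", length(helices))
      for (i in seq_along(helices)) {
        thr <- applyHelix(tmpl$model, helices[[i]], tmpl$positionMap,
                          library = library)
        rec <- .scoreFinger(mutatedModel(thr), tmpl, f, params, helices[[i]])
        rows[[i]] <- .recordRow(rec, helices[[i]])
      }
      key <- sprintf("%s/F%d", trip, f)
      out[[key]] <- rankRecords(do.call(rbind, rows), key = key)
      if (verbose)
        message(sprintf("%s: %d helices scored", key, length(helices)))
    }
  }
  out
}

#' Score all candidate helices for synergistic binding
#'
#' For each 3-bp target (classically the 16 GNN triplets): builds the
#' 27-bp repeated-triplet complex, applies the SAME candidate helix to
#' all three fingers simultaneously (collapsing the intractable 448^3
#' independent-finger space exactly as the synergistic design does) and
#' scores the whole complex in one pass.
#'
#' @param triplets 3-bp targets (default the 16 GNN triplets).
#' @param pool an [AminoAcidPool] (approach 2 default: 7/8/8).
#' @param params,library,templateFn,scaffold,verbose as in [runModular].
#' @return named list of [RankingTable], keyed by 9-bp repeated-triplet
#'   binding site.
#' @export
runSynergistic <- function(triplets = enumerateTriplets("GNN"),
                           pool = poolFromConfig(2),
                           params = hbondParams(),
                           library = defaultRotamerLibrary(),
                           templateFn = syntheticTemplateComplex,
                           scaffold = .DEFAULT_SCAFFOLD, verbose = FALSE) {
  out <- list()
  for (trip in triplets) {
    tmpl <- templateFn(makeSynergisticTarget(trip))
    helices <- enumerateHelices(pool, finger = 1L, scaffold = scaffold)
    rows <- vector("list", length(helices))
    for (i in seq_along(helices)) {
      h <- helices[[i]]
      cur <- tmpl$model
      for (f in 1:3) {
        hf <- new("RecognitionHelix", fingerIndex = as.integer(f),
                  residues = h@residues)
        cur <- mutatedModel(applyHelix(cur, hf, tmpl$positionMap,
                                       library = library))
      }
      ## whole-complex interface: all three fingers vs all three sub-sites
      sels <- lapply(1:3, function(f)
        selectInterfaceResidues(cur, tmpl$positionMap, f,
                                tmpl$windows[[f]], dnaChain = tmpl$dnaChain))
      helixAtoms <- do.call(rbind, lapply(sels, `[[`, "helix"))
      baseAtoms <- unique(do.call(rbind, lapply(sels, `[[`, "bases")))
      rec <- scoreComplex(cur, params, helixAtoms = helixAtoms,
                          baseAtoms = baseAtoms, helixId = longCode(h),
                          triplet = trip, finger = NA_integer_)
      rows[[i]] <- .recordRow(rec, h)
    }
    key <- strrep(trip, 3L)
    out[[key]] <- rankRecords(do.call(rbind, rows), key = key)
    if (verbose) message(sprintf("%s: %d helices scored", key, length(helices)))
  }
  out
}

#' Combine per-finger modular winners for a 9-bp query
#'
#' Under modular binding the net energy of a three-finger design is the
#' sum of the per-finger energies. Splits the query into its three 3-bp
#' sub-sites, takes each slot's top-ranked helix from the supplied tables
#' and reports the concatenated design with the summed score.
#'
#' @param tables named list of [RankingTable] from [runModular].
#' @param query 9-nt ACGT string.
#' @return list with `helices` (per-finger winner codes), `scores`
#'   (per-finger), `total` (summed score).
#' @export
combineModular <- function(tables, query) {
  query <- .checkDnaString(query, "query")
  if (nchar(query) != 9L) stop("query must be 9 nt", call. = FALSE)
  winners <- character(3L); scores <- numeric(3L)
  for (f in 1:3) {
    trip <- substr(query, 3L * f - 2L, 3L * f)
    key <- sprintf("%s/F%d", trip, f)
    if (!key %in% names(tables))
      stop(sprintf("no ranking table for %s", key), call. = FALSE)
    rec <- rankedRecords(tables[[key]])
    if (!nrow(rec)) stop(sprintf("empty ranking table for %s", key),
                         call. = FALSE)
    winners[f] <- rec$helix[1L]
    scores[f] <- rec$score[1L]
  }
  list(helices = winners, scores = scores, total = sum(scores))
}

#' Amino-acid propensities among top-ranked helices
#'
#' Frequency of each amino acid at the key positions -1, +3, +6 among the
#' top-k records of each table, aggregated per finger. Frequencies sum to
#' 1 per (finger, position).
#'
#' @param tables named list of [RankingTable] (modular runs; synergistic
#'   tables aggregate under finger `NA`).
#' @param topK records taken from the head of each table (capped at the
#'   table size, with a warning when smaller).
#' @return data.frame with columns `finger`, `position`, `residue`,
#'   `count`, `frequency`.
#' @export
propensityReport <- function(tables, topK = 20L) {
  counts <- list()
  for (tb in tables) {
    rec <- rankedRecords(tb)
    if (!nrow(rec)) next
    k <- min(topK, nrow(rec))
    if (k < topK)
      warning(sprintf("table %s has only %d records (top_k %d)",
                      tableKey(tb), nrow(rec), topK), call. = FALSE)
    top <- rec[seq_len(k), , drop = FALSE]
    for (i in seq_len(nrow(top))) {
      sc <- strsplit(top$short_code[i], "")[[1L]]
      for (j in 1:3) {
        pos <- c("-1", "3", "6")[j]
        kk <- paste(top$finger[i], pos, sc[j])
        counts[[kk]] <- (if (is.null(counts[[kk]])) 0L else counts[[kk]]) + 1L
      }
    }
  }
  if (!length(counts))
    return(data.frame(finger = integer(), position = character(),
                      residue = character(), count = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(counts), " "))
  df <- data.frame(finger = suppressWarnings(as.integer(parts[, 1L])),
                   position = parts[, 2L], residue = parts[, 3L],
                   count = unlist(counts, use.names = FALSE),
                   stringsAsFactors = FALSE)
  grp <- paste(df$finger, df$position)
  df$frequency <- df$count / ave(df$count, grp, FUN = sum)
  df <- df[order(df$finger, df$position, -df$frequency, df$residue), ]
  rownames(df) <- NULL
  df
}

#' Write a ranking table as CSV
#'
#' @param table a [RankingTable].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeRankingCsv <- function(table, path) {
  stopifnot(is(table, "RankingTable"))
  write.csv(rankedRecords(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
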