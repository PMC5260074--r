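#' @include AllClasses.R
NULL

## Candidate recognition-helix enumeration from per-position amino-acid
## pools. The scaffold positions +1, +2, +4, +5 stay fixed (default
## S, G, L, T, the ?SG?LT? pattern of the Zif-268 consensus frame);
## specificity positions -1, +3, +6 vary.

.DEFAULT_SCAFFOLD <- c("1" = "S", "2" = "G", "4" = "L", "5" = "T")

## Provisional consensus pools. The identities are an editable default
## drawn from the phage-display positional-preference literature; the set
## sizes (7 at -1, 7 at +3, 8 at +6) define the restricted design space,
## and the extended space adds glutamate at +3 (7 x 8 x 8).
.DEFAULT_POOLS <- list(
  "-1" = c("D", "K", "N", "Q", "R", "S", "T"),
  "3"  = c("A", "D", "H", "K", "N", "S", "T"),
  "6"  = c("A", "E", "K", "N", "Q", "R", "T", "V"))

#' Construct an amino-acid pool
#'
#' @param pos_m1,pos3,pos6 character vectors of one-letter residues allowed
#'   at helix positions -1, +3 and +6.
#' @param pos2 optional pool for position +2 (off by default: varying +2
#'   re-opens cross-strand contacts, which the scoring model excludes).
#' @return an [AminoAcidPool].
#' @export
aminoAcidPool <- function(pos_m1, pos3, pos6, pos2 = NULL) {
  pools <- list("-1" = sort(unique(pos_m1)), "3" = sort(unique(pos3)),
                "6" = sort(unique(pos6)))
  if (!is.null(pos2)) pools[["2"]] <- sort(unique(pos2))
  new("AminoAcidPool", pools = pools)
}

#' Per-approach default amino-acid pools
#'
#' Approach 1 (restricted consensus, modular binding) uses per-position
#' sets of sizes 7/7/8 at -1/+3/+6; approach 2 (synergistic binding) is
#' the same pool with glutamate added at +3 (7/8/8, 448 helices);
#' approach 3 allows all 20 amino acids at each key position (8000
#' helices). A YAML config can override the sets.
#'
#' @param approach 1, 2 or 3.
#' @param config optional list (or YAML path) with entries `pos_m1`,
#'   `pos3`, `pos6` replacing the defaults.
#' @return an [AminoAcidPool].
#' @examples
#' poolSizes(poolFromConfig(1))  # 7 7 8
#' poolSizes(poolFromConfig(2))  # 7 8 8
#' @export
poolFromConfig <- function(approach, config = NULL) {
  stopifnot(length(approach) == 1L, approach %in% 1:3)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    pools <- lapply(config[c("pos_m1", "pos3", "pos6")], function(x) {
      if (is.null(x)) stop("config must define pos_m1, pos3 and pos6",
                           call. = FALSE)
      toupper(unlist(x))
    })
    return(aminoAcidPool(pools$pos_m1, pools$pos3, pools$pos6))
  }
  if (approach == 3L)
    return(aminoAcidPool(.AA1, .AA1, .AA1))
  p3 <- .DEFAULT_POOLS[["3"]]
  if (approach == 2L) p3 <- sort(c(p3, "E"))
  aminoAcidPool(.DEFAULT_POOLS[["-1"]], p3, .DEFAULT_POOLS[["6"]])
}

#' Enumerate candidate recognition helices
#'
#' Cartesian product of the per-position pools, in lexicographic order over
#' (-1, +3, +6) codes; scaffold positions stay fixed. Position +2 is held
#' at the scaffold value unless the pool defines a set for it.
#'
#' @param pool an [AminoAcidPool].
#' @param finger finger index the helices are built for (1-3).
#' @param scaffold named character vector for positions 1, 2, 4, 5
#'   (default S, G, L, T).
#' @return list of [RecognitionHelix]; length = product of pool sizes.
#' @examples
#' length(enumerateHelices(poolFromConfig(2), 1))  # 448
#' @export
enumerateHelices <- function(pool, finger = 1L,
                             scaffold = .DEFAULT_SCAFFOLD) {
  stopifnot(is(pool, "AminoAcidPool"))
  if (!all(c("1", "2", "4", "5") %in% names(scaffold)))
    stop("scaffold must define positions 1, 2, 4 and 5", call. = FALSE)
  p <- pool@pools
  pos2 <- if ("2" %in% names(p)) p[["2"]] else scaffold[["2"]]
  grid <- expand.grid(p6 = p[["6"]], p3 = p[["3"]], p2 = pos2,
                      pm1 = p[["-1"]], stringsAsFactors = FALSE)
  ## lexicographic over (-1, 2, 3, 6)
  grid <- grid[order(grid$pm1, grid$p2, grid$p3, grid$p6), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    res <- c(grid$pm1[i], scaffold[["1"]], grid$p2[i], grid$p3[i],
             scaffold[["4"]], scaffold[["5"]], grid$p6[i])
    names(res) <- .HELIX_POSITIONS
    new("RecognitionHelix", fingerIndex = as.integer(finger), residues = res)
  })
}

#' Build a helix object from its 7-letter code
#'
#' @param code 7-letter helix string, positions -1, +1..+6.
#' @param finger finger index.
#' @return a [RecognitionHelix].
#' @export
helixFromCode <- function(code, finger = 1L) {
  code <- toupper(code)
  if (nchar(code) != 7L) stop("helix code must have 7 letters", call. = FALSE)
  res <- strsplit(code, "")[[1L]]
  names(res) <- .HELIX_POSITIONS
  new("RecognitionHelix", fingerIndex = as.integer(finger), residues = res)
}

#' Mutations needed to realize a helix on a template
#'
#' Compares the helix against the template residues at the mapped positions
#' and returns one record per differing site.
#'
#' @param helix a [RecognitionHelix].
#' @param model the template [StructureModel].
#' @param positionMap position map (see [defaultPositionMap]).
#' @param positions helix positions considered (default -1, +3, +6).
#' @return data.frame with columns `chain`, `resno`, `position`, `from`,
#'   `to` (three-letter residue names in `from`/`to_res`).
#' @export
helixToMutationSet <- function(helix, model, positionMap,
                               positions = c(-1L, 3L, 6L)) {
  stopifnot(is(helix, "RecognitionHelix"))
  a <- atoms(model)
  resnos <- resolveHelixPositions(positionMap, helix@fingerIndex, positions)
  out <- list()
  for (k in seq_along(positions)) {
    pos <- positions[k]
    want1 <- helix@residues[[as.character(pos)]]
    want3 <- .AA3_FROM_1[[want1]]
    cur <- a[a$chain == positionMap$chain & a$resno == resnos[k] &
             a$kind == "protein", , drop = FALSE]
    if (!nrow(cur))
      stop(sprintf("template has no residue %d (finger %d position %+d)",
                   resnos[k], helix@fingerIndex, pos), call. = FALSE)
    cur3 <- cur$resname[1L]
    if (cur3 != want3)
      out[[length(out) + 1L]] <- data.frame(
        chain = positionMap$chain, resno = resnos[k], position = pos,
        from = cur3, to = want3, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      position = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export a helix list as CSV
#'
#' @param helices list of [RecognitionHelix].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeHelicesCsv <- function(helices, path) {
  df <- data.frame(
    finger = vapply(helices, function(h) h@fingerIndex, integer(1)),
    short_code = vapply(helices, shortCode, character(1)),
    long_code = vapply(helices, longCode, character(1)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
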