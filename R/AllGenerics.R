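#' @include AllClasses.R
NULL

#' Atom table of a structure
#'
#' @param x a [StructureModel].
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @describeIn atoms atom table accessor
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' Number of atoms
#' @param x a [StructureModel].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn nAtoms atom count
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' Chain identifiers of a structure
#' @param x a [StructureModel].
#' @return character vector of chain ids, sorted.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @describeIn chainIds chain ids
setMethod("chainIds", "StructureModel", function(x) sort(unique(x@atoms$chain)))

#' Target sequence accessors
#'
#' @param x a [DnaTarget].
#' @return character scalar.
#' @export
setGeneric("targetSequence", function(x) standardGeneric("targetSequence"))

#' @describeIn targetSequence primary-strand 5'->3' sequence
setMethod("targetSequence", "DnaTarget", function(x) x@sequence)

#' @rdname targetSequence
#' @export
setGeneric("targetComplement", function(x) standardGeneric("targetComplement"))

#' @describeIn targetSequence reverse-complement strand
setMethod("targetComplement", "DnaTarget", function(x) x@complement)

#' @rdname targetSequence
#' @export
setGeneric("targetTriplet", function(x) standardGeneric("targetTriplet"))

#' @describeIn targetSequence variable 3-bp sub-site
setMethod("targetTriplet", "DnaTarget", function(x) x@triplet)

#' Helix codes
#'
#' `shortCode` is the 3-letter key-residue code (positions -1, +3, +6);
#' `longCode` the full 7-letter helix (positions -1, +1..+6).
#'
#' @param x a [RecognitionHelix].
#' @return character scalar.
#' @export
setGeneric("shortCode", function(x) standardGeneric("shortCode"))

#' @describeIn shortCode key residues at -1, +3, +6
setMethod("shortCode", "RecognitionHelix", function(x)
  paste0(x@residues[["-1"]], x@residues[["3"]], x@residues[["6"]]))

#' @rdname shortCode
#' @export
setGeneric("longCode", function(x) standardGeneric("longCode"))

#' @describeIn shortCode full 7-letter helix string
setMethod("longCode", "RecognitionHelix", function(x)
  paste(x@residues, collapse = ""))

#' Pool sizes per key position
#' @param x an [AminoAcidPool].
#' @return named integer vector of set sizes.
#' @export
setGeneric("poolSizes", function(x) standardGeneric("poolSizes"))

#' @describeIn poolSizes sizes of the per-position sets
setMethod("poolSizes", "AminoAcidPool", function(x)
  vapply(x@pools, length, integer(1)))

#' Score record accessors
#' @param x a [ScoreRecord].
#' @return see individual accessors.
#' @export
setGeneric("totalEnergy", function(x) standardGeneric("totalEnergy"))

#' @describeIn totalEnergy signed total interfacial energy (kcal/mol)
setMethod("totalEnergy", "ScoreRecord", function(x) x@totalEnergy)

#' @rdname totalEnergy
#' @export
setGeneric("bondScore", function(x) standardGeneric("bondScore"))

#' @describeIn totalEnergy absolute-value ranking score (kcal/mol)
setMethod("bondScore", "ScoreRecord", function(x) x@score)

#' @rdname totalEnergy
#' @export
setGeneric("hbonds", function(x) standardGeneric("hbonds"))

#' @describeIn totalEnergy resolved hydrogen-bond table
setMethod("hbonds", "ScoreRecord", function(x) x@bonds)

#' Ranking table accessors
#' @param x a [RankingTable].
#' @return data.frame of ranked records / character key.
#' @export
setGeneric("rankedRecords", function(x) standardGeneric("rankedRecords"))

#' @describeIn rankedRecords ordered record table
setMethod("rankedRecords", "RankingTable", function(x) x@records)

#' @rdname rankedRecords
#' @export
setGeneric("tableKey", function(x) standardGeneric("tableKey"))

#' @describeIn rankedRecords target key of the table
setMethod("tableKey", "RankingTable", function(x) x@key)

#' Mutation result accessors
#' @param x a [MutationResult].
#' @return see individual accessors.
#' @export
setGeneric("mutatedModel", function(x) standardGeneric("mutatedModel"))

#' @describeIn mutatedModel the threaded structure
setMethod("mutatedModel", "MutationResult", function(x) x@model)

#' @rdname mutatedModel
#' @export
setGeneric("mutationSites", function(x) standardGeneric("mutationSites"))

#' @describeIn mutatedModel per-site mutation report
setMethod("mutationSites", "MutationResult", function(x) x@sites)
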