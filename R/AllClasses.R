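#' @import methods
NULL

#' Gapped protein multiple sequence alignment
#'
#' A rectangular protein alignment over the 20 amino-acid letters plus the
#' gap character \code{-} and the unknown-residue character \code{X}. This is
#' the substrate of conservation scoring, domain delimitation, identity
#' statistics, column trimming and distance computation.
#'
#' @slot ids character vector of unique record identifiers.
#' @slot rows character vector of aligned rows, all of equal width.
#'
#' @seealso [ProteinMSA()], [readMsa()], [conservationProfile()]
#' @exportClass ProteinMSA
setClass("ProteinMSA", representation(ids = "character", rows = "character"))

setValidity("ProteinMSA", function(object) {
  if (length(object@ids) < 1L) return("alignment must contain at least one record")
  if (length(object@ids) != length(object@rows))
    return("ids and rows differ in length")
  if (anyDuplicated(object@ids)) return("record ids must be unique")
  w <- unique(nchar(object@rows))
  if (length(w) != 1L) return("all rows must have the same width")
  if (w < 1L) return("alignment width must be >= 1")
  bad <- grepl(sprintf("[^%sX-]", paste(AA_ALPHABET, collapse = "")), object@rows)
  if (any(bad))
    return(sprintf("illegal character in record '%s'", object@ids[which(bad)[1L]]))
  TRUE
})

#' Per-column conservation profile of an alignment
#'
#' Holds the raw property-conservation score (an integer between 0 and 10 per
#' column) and a moving-average smoothed version of it, together with the
#' smoothing window and step used.
#'
#' @slot raw numeric vector of per-column scores in \[0, 10\].
#' @slot smoothed numeric vector, same length as \code{raw}.
#' @slot window integer smoothing window (1 = no smoothing).
#' @slot step integer smoothing step.
#'
#' @seealso [conservationProfile()], [smoothProfile()], [delimitDomains()]
#' @exportClass ConservationProfile
setClass("ConservationProfile",
         representation(raw = "numeric", smoothed = "numeric",
                        window = "integer", step = "integer"))

setValidity("ConservationProfile", function(object) {
  if (length(object@raw) != length(object@smoothed))
    return("raw and smoothed must have equal length")
  if (any(object@raw < 0 | object@raw > 10)) return("raw scores must lie in [0, 10]")
  if (object@window < 1L) return("window must be >= 1")
  if (object@step < 1L) return("step must be >= 1")
  TRUE
})

#' Profile hidden Markov model of a protein domain
#'
#' A HMMER-like (not bit-compatible) profile HMM with match, insert and
#' delete states, uniform local entry over match states, length-balanced
#' local exit, and flanking self-loop states that emit background residues.
#' Scores are log2-odds (bits) against an i.i.d. background null.
#'
#' Transition slots are per-node probabilities; for node \code{k < M} the
#' match-state distribution is \code{MM + MI + MD + exit = 1}, and the final
#' match state exits with probability one.
#'
#' @slot M integer, number of match states.
#' @slot matchEmissions M x 20 matrix of match emission probabilities.
#' @slot insertEmissions (M+1) x 20 matrix of insert emission probabilities
#'   (background by construction).
#' @slot transitions M x 7 matrix with columns \code{MM, MI, MD, IM, II, DM, DD}.
#' @slot entry numeric length-M local entry distribution (uniform).
#' @slot exit numeric length-M local exit probabilities.
#' @slot background numeric length-20 background distribution.
#' @slot flankLoop numeric scalar, self-loop probability of the flanking
#'   background states.
#' @slot metadata list (seed ids, pseudocount matrix name, weighting).
#'
#' @seealso [buildProfile()], [viterbiScore()], [searchProfile()]
#' @exportClass ProfileHMM
setClass("ProfileHMM",
         representation(M = "integer", matchEmissions = "matrix",
                        insertEmissions = "matrix", transitions = "matrix",
                        entry = "numeric", exit = "numeric",
                        background = "numeric", flankLoop = "numeric",
                        metadata = "list"))

setValidity("ProfileHMM", function(object) {
  M <- object@M
  tol <- 1e-9
  if (M < 1L) return("M must be >= 1")
  if (!all(dim(object@matchEmissions) == c(M, 20L)))
    return("matchEmissions must be M x 20")
  if (!all(dim(object@insertEmissions) == c(M + 1L, 20L)))
    return("insertEmissions must be (M+1) x 20")
  if (any(abs(rowSums(object@matchEmissions) - 1) > tol))
    return("match emission rows must sum to 1")
  if (any(abs(rowSums(object@insertEmissions) - 1) > tol))
    return("insert emission rows must sum to 1")
  if (any(object@background <= 0) || abs(sum(object@background) - 1) > tol)
    return("background must be strictly positive and sum to 1")
  if (abs(sum(object@entry) - 1) > tol) return("entry distribution must sum to 1")
  tr <- object@transitions
  if (!all(dim(tr) == c(M, 7L))) return("transitions must be M x 7")
  s <- tr[, "MM"] + tr[, "MI"] + tr[, "MD"] + object@exit
  if (any(abs(s - 1) > tol)) return("match transition rows must sum to 1")
  if (M > 1L) {
    kk <- seq_len(M - 1L)
    if (any(abs(tr[kk, "IM"] + tr[kk, "II"] - 1) > tol))
      return("insert transition rows must sum to 1")
    if (any(abs(tr[kk, "DM"] + tr[kk, "DD"] - 1) > tol))
      return("delete transition rows must sum to 1")
  }
  if (object@flankLoop <= 0 || object@flankLoop >= 1)
    return("flankLoop must lie in (0, 1)")
  TRUE
})

#' Gumbel calibration of profile HMM bit scores
#'
#' Maximum-likelihood Gumbel fit to the Viterbi bit scores of background
#' decoy sequences, used to convert bit scores into E-values:
#' \eqn{E(s) = N (1 - \exp(-\exp(-\lambda (s - \mu))))} for a database of
#' \eqn{N} sequences.
#'
#' @slot lambda positive slope parameter.
#' @slot mu location parameter (bits).
#' @slot nDecoys number of decoy sequences used.
#' @slot decoyLen decoy sequence length.
#' @slot decoySeed RNG seed used to draw the decoys.
#'
#' @seealso [calibrateEvalues()], [evalueFromScore()]
#' @exportClass GumbelCalibration
setClass("GumbelCalibration",
         representation(lambda = "numeric", mu = "numeric", nDecoys = "integer",
                        decoyLen = "integer", decoySeed = "integer"))

setValidity("GumbelCalibration", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@nDecoys < 50L) return("nDecoys must be >= 50")
  TRUE
})

#' C-alpha trace of a protein structure
#'
#' Ordered C-alpha coordinates (in Angstrom) of one chain, one coordinate
#' triple per residue, with one-letter residue codes and author residue
#' numbers. Substrate of Kabsch superposition and normalized RMSD distances.
#'
#' @slot id character structure identifier.
#' @slot residues character vector of one-letter residue codes.
#' @slot resno integer vector of residue numbers.
#' @slot coords n x 3 numeric matrix of coordinates in Angstrom.
#'
#' @seealso [readCalpha()], [kabschSuperpose()], [structuralDistanceMatrix()]
#' @exportClass StructureModel
setClass("StructureModel",
         representation(id = "character", residues = "character",
                        resno = "integer", coords = "matrix"))

setValidity("StructureModel", function(object) {
  n <- length(object@residues)
  if (n < 3L) return("structure must contain at least 3 residues")
  if (!all(dim(object@coords) == c(n, 3L)))
    return("coords must be an n x 3 matrix matching residues")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@resno) != n) return("resno must match residues")
  TRUE
})
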