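#' Construct a protein multiple sequence alignment
#'
#' @param ids character vector of unique record identifiers.
#' @param rows character vector of aligned rows (equal width, letters from
#'   the 20 amino-acid codes plus \code{-} and \code{X}). If \code{rows} is
#'   named and \code{ids} missing, the names are used as identifiers.
#'
#' @return A [ProteinMSA-class] object.
#' @examples
#' msa <- ProteinMSA(c("a", "b"), c("AC-D", "ACAD"))
#' msaWidth(msa)
#' @export
ProteinMSA <- function(ids, rows) {
  if (missing(ids)) {
    ids <- names(rows)
    if (is.null(ids)) stop("ids are required when rows are unnamed")
  }
  new("ProteinMSA", ids = as.character(ids),
      rows = toupper(unname(as.character(rows))))
}

#' @describeIn ProteinMSA number of records.
#' @param x,msa a \code{ProteinMSA}.
#' @export
nSeq <- function(x) length(x@ids)

#' @describeIn ProteinMSA alignment width (number of columns).
#' @export
msaWidth <- function(x) nchar(x@rows[1L])

#' @describeIn ProteinMSA record identifiers.
#' @export
seqIds <- function(x) x@ids

#' @describeIn ProteinMSA aligned rows as a named character vector.
#' @export
alignedRows <- function(x) stats::setNames(x@rows, x@ids)

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d sequences x %d columns\n",
              nSeq(object), msaWidth(object)))
  n <- min(5L, nSeq(object))
  w <- min(60L, msaWidth(object))
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s%s\n", object@ids[i], substr(object@rows[i], 1L, w),
                if (msaWidth(object) > w) "..." else ""))
  if (nSeq(object) > n) cat(sprintf("  ... %d more\n", nSeq(object) - n))
})

#' Read an aligned FASTA file into a ProteinMSA
#'
#' Gaps may be encoded as \code{-} or \code{.} (dots are converted);
#' sequences are upper-cased.
#'
#' @param path path to an aligned FASTA file.
#' @return A [ProteinMSA-class].
#' @export
readMsa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  rows <- toupper(chartr(".", "-", as.character(ss)))
  ids <- sub("\\s.*$", "", names(ss))
  ProteinMSA(ids, rows)
}

#' Write a ProteinMSA (or named sequences) to FASTA
#'
#' @param msa a [ProteinMSA-class] or a named character vector of sequences.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeMsa <- function(msa, path) {
  seqs <- if (is(msa, "ProteinMSA")) alignedRows(msa) else msa
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Subset alignment columns
#'
#' @param msa a [ProteinMSA-class].
#' @param cols integer vector of 1-based column indices to keep.
#' @return A [ProteinMSA-class] restricted to \code{cols}.
#' @export
msaColumns <- function(msa, cols) {
  cols <- as.integer(cols)
  if (any(cols < 1L | cols > msaWidth(msa))) stop("column index out of range")
  m <- .msaMatrix(msa)[, cols, drop = FALSE]
  ProteinMSA(msa@ids, apply(m, 1L, paste, collapse = ""))
}

#' Subset alignment records
#'
#' @param msa a [ProteinMSA-class].
#' @param ids identifiers (or integer indices) of the records to keep.
#' @return A [ProteinMSA-class] restricted to the selected records.
#' @export
msaRecords <- function(msa, ids) {
  idx <- if (is.numeric(ids)) as.integer(ids) else match(ids, msa@ids)
  if (anyNA(idx)) stop("unknown record id")
  ProteinMSA(msa@ids[idx], msa@rows[idx])
}

#' Ungapped sequence of one alignment record
#'
#' @param msa a [ProteinMSA-class].
#' @param id record identifier.
#' @return Character scalar, the row with gap characters removed.
#' @export
ungappedSequence <- function(msa, id) {
  i <- match(id, msa@ids)
  if (is.na(i)) stop(sprintf("unknown record id '%s'", id))
  gsub("-", "", msa@rows[i], fixed = TRUE)
}

# character matrix view (rows = records)
.msaMatrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa@rows, "", fixed = TRUE))
  rownames(m) <- msa@ids
  m
}

# map from alignment column to 1-based residue position on a reference row;
# returns, per column, the number of non-gap reference characters in 1..col
.refResidueCount <- function(msa, referenceId) {
  i <- match(referenceId, msa@ids)
  if (is.na(i)) stop(sprintf("unknown reference id '%s'", referenceId))
  cumsum(.splitRow(msa@rows[i]) != "-")
}
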