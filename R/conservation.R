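#' The ten physicochemical residue property classes used for conservation
#'
#' The Taylor/Zvelebil property classification underlying the AMAS-style
#' alignment conservation score: a column's score is the number of these
#' classes whose membership status (all residues in, or all residues out) is
#' uniform down the column. The table is fixed package data.
#'
#' @return Named list of ten character vectors of one-letter residue codes.
#' @examples
#' names(conservationProperties())
#' @export
conservationProperties <- function() {
  list(
    hydrophobic = c("I", "L", "V", "C", "A", "G", "M", "F", "Y", "W", "H", "K", "T"),
    polar       = c("Y", "W", "H", "K", "R", "E", "Q", "D", "N", "S", "T", "C"),
    small       = c("V", "C", "A", "G", "D", "N", "S", "T", "P"),
    proline     = c("P"),
    tiny        = c("A", "G", "S"),
    aliphatic   = c("I", "L", "V"),
    aromatic    = c("F", "Y", "W", "H"),
    positive    = c("H", "K", "R"),
    negative    = c("D", "E"),
    charged     = c("H", "K", "R", "D", "E"))
}

#' Property-based conservation score of one alignment column
#'
#' Counts the property classes whose membership status is uniform across all
#' characters of the column. Gap (\code{-}) and unknown (\code{X}) characters
#' are treated as residues belonging to no property, so they break the
#' conservation of any property present in the column's residues while still
#' allowing "conserved absence" to count.
#'
#' @param column character vector of single characters (residues, \code{-}
#'   or \code{X}).
#' @param properties property table, see [conservationProperties()].
#' @return Integer score in \[0, 10\]; a column of identical residues scores 10.
#' @examples
#' columnConservation(c("V", "V", "V"))  # 10
#' columnConservation(c("K", "R"))
#' @export
columnConservation <- function(column, properties = conservationProperties()) {
  if (length(column) == 0L) stop("empty column")
  bad <- !(column %in% c(AA_ALPHABET, "-", "X"))
  if (any(bad))
    stop(sprintf("illegal character '%s' in column", column[which(bad)[1L]]))
  score <- 0L
  for (p in properties) {
    m <- column %in% p
    if (all(m) || !any(m)) score <- score + 1L
  }
  score
}

#' Per-column conservation profile of an alignment
#'
#' @param msa a [ProteinMSA-class].
#' @param properties property table, see [conservationProperties()].
#' @return A [ConservationProfile-class] with \code{smoothed} initialized to
#'   the raw scores (window 1).
#' @seealso [smoothProfile()], [delimitDomains()]
#' @export
conservationProfile <- function(msa, properties = conservationProperties()) {
  m <- .msaMatrix(msa)
  raw <- vapply(seq_len(ncol(m)), function(j) {
    tryCatch(as.numeric(columnConservation(m[, j], properties)),
             error = function(e) stop(sprintf("column %d: %s", j, conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(1))
  new("ConservationProfile", raw = raw, smoothed = raw,
      window = 1L, step = 1L)
}

#' Moving-average smoothing of a conservation profile
#'
#' Centered window with truncation at the profile edges; for even windows
#' the extra position is taken to the right. With \code{step = 1} the output
#' has the same length as the input; larger steps subsample window starts.
#'
#' @param profile a [ConservationProfile-class].
#' @param window window size in columns (default 10).
#' @param step step size (default 1).
#' @return A [ConservationProfile-class] with the \code{smoothed} slot filled.
#' @export
smoothProfile <- function(profile, window = 10L, step = 1L) {
  if (window < 1L) stop("window must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  raw <- profile@raw
  n <- length(raw)
  left <- (as.integer(window) - 1L) %/% 2L
  right <- as.integer(window) %/% 2L
  centers <- seq.int(1L, n, by = as.integer(step))
  sm <- vapply(centers, function(i)
    mean(raw[max(1L, i - left):min(n, i + right)]), numeric(1))
  if (step == 1L) {
    new("ConservationProfile", raw = raw, smoothed = sm,
        window = as.integer(window), step = 1L)
  } else {
    new("ConservationProfile", raw = raw[centers], smoothed = sm,
        window = as.integer(window), step = as.integer(step))
  }
}

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile: %d columns, window %d, step %d\n",
              length(object@raw), object@window, object@step))
  cat(sprintf("  raw mean %.2f, smoothed range [%.2f, %.2f]\n",
              mean(object@raw), min(object@smoothed), max(object@smoothed)))
})

#' @describeIn conservationProfile raw per-column scores.
#' @param x a \code{ConservationProfile}.
#' @export
rawScores <- function(x) x@raw

#' @describeIn conservationProfile smoothed per-column scores.
#' @export
smoothedScores <- function(x) x@smoothed

#' Delimit conserved domains on a smoothed conservation profile
#'
#' Extracts maximal runs of columns whose smoothed score is strictly above
#' \code{threshold}, merges runs separated by at most \code{mergeGap}
#' columns, discards runs shorter than \code{minLen} columns, and finally
#' extends segments minimally so that any anchor residue lying within
#' \code{mergeGap} columns of a segment boundary is included. Segment
#' coordinates are reported both in alignment columns and in residue
#' positions on a reference record (counting only its non-gap characters);
#' both coordinate systems are 1-based inclusive.
#'
#' @param profile a smoothed [ConservationProfile-class] with \code{step = 1}.
#' @param msa the source [ProteinMSA-class].
#' @param referenceId id of the reference record for residue coordinates.
#' @param threshold conservation threshold (default 4, score units).
#' @param minLen minimum segment length in columns (default 25).
#' @param mergeGap maximum gap between merged runs, in columns (default 10).
#' @param anchors integer vector of 1-based residue positions on the
#'   reference that must be included when close to a boundary.
#' @return A \code{data.frame} with columns \code{start_col}, \code{end_col},
#'   \code{start_res}, \code{end_res}, \code{length_res}; the reference id is
#'   attached as attribute \code{"reference"}.
#' @export
delimitDomains <- function(profile, msa, referenceId, threshold = 4,
                           minLen = 25L, mergeGap = 10L, anchors = integer(0)) {
  if (threshold < 0 || threshold > 10) stop("threshold must lie in [0, 10]")
  if (profile@step != 1L) stop("delimitation requires a step-1 profile")
  sm <- profile@smoothed
  if (length(sm) != msaWidth(msa))
    stop("profile length does not match alignment width")
  refcount <- .refResidueCount(msa, referenceId)
  reflen <- refcount[length(refcount)]
  anchors <- as.integer(anchors)
  if (any(anchors < 1L | anchors > reflen))
    stop(sprintf("anchor outside reference length (%d)", reflen))

  above <- sm > threshold
  if (!any(above)) return(.segmentFrame(integer(0), integer(0), msa, referenceId))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])

  # merge runs separated by <= mergeGap columns
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) for (i in 2L:nrow(seg)) {
    gap <- seg[i, 1L] - merged[nrow(merged), 2L] - 1L
    if (gap <= mergeGap) merged[nrow(merged), 2L] <- seg[i, 2L]
    else merged <- rbind(merged, seg[i, , drop = FALSE])
  }
  keep <- (merged[, 2L] - merged[, 1L] + 1L) >= minLen
  merged <- merged[keep, , drop = FALSE]

  # anchor extension: include anchors within mergeGap of a boundary
  if (length(anchors) && nrow(merged)) {
    anchorCols <- vapply(anchors, function(a)
      which(refcount == a & .splitRow(msa@rows[match(referenceId, msa@ids)]) != "-")[1L],
      integer(1))
    for (ac in anchorCols) {
      for (i in seq_len(nrow(merged))) {
        if (ac >= merged[i, 1L] && ac <= merged[i, 2L]) break
        if (ac < merged[i, 1L] && merged[i, 1L] - ac <= mergeGap) {
          merged[i, 1L] <- ac; break
        }
        if (ac > merged[i, 2L] && ac - merged[i, 2L] <= mergeGap) {
          merged[i, 2L] <- ac; break
        }
      }
    }
    # re-merge in case extensions created overlaps
    o <- order(merged[, 1L])
    merged <- merged[o, , drop = FALSE]
    out <- merged[1L, , drop = FALSE]
    if (nrow(merged) > 1L) for (i in 2L:nrow(merged)) {
      if (merged[i, 1L] <= out[nrow(out), 2L] + 1L)
        out[nrow(out), 2L] <- max(out[nrow(out), 2L], merged[i, 2L])
      else out <- rbind(out, merged[i, , drop = FALSE])
    }
    merged <- out
  }
  .segmentFrame(merged[, 1L], merged[, 2L], msa, referenceId)
}

.segmentFrame <- function(startCol, endCol, msa, referenceId) {
  refrow <- .splitRow(msa@rows[match(referenceId, msa@ids)])
  refcount <- cumsum(refrow != "-")
  nongapCols <- which(refrow != "-")
  startRes <- endRes <- integer(length(startCol))
  for (i in seq_along(startCol)) {
    inside <- nongapCols[nongapCols >= startCol[i] & nongapCols <= endCol[i]]
    if (!length(inside)) { startRes[i] <- NA_integer_; endRes[i] <- NA_integer_ }
    else { startRes[i] <- refcount[inside[1L]]; endRes[i] <- refcount[inside[length(inside)]] }
  }
  out <- data.frame(start_col = as.integer(startCol), end_col = as.integer(endCol),
                    start_res = startRes, end_res = endRes,
                    length_res = endRes - startRes + 1L)
  attr(out, "reference") <- referenceId
  out
}

#' Construct a domain segment record from known boundaries
#'
#' Convenience constructor for a delimited-segment row given reference
#' residue boundaries (1-based inclusive), e.g. to compute the residue span
#' of a domain whose boundaries are already known.
#'
#' @param startRes,endRes 1-based inclusive residue positions on the
#'   reference sequence.
#' @param startCol,endCol optional alignment-column coordinates.
#' @return One-row \code{data.frame} as returned by [delimitDomains()].
#' @examples
#' domainSegment(257, 449)$length_res  # 193
#' @export
domainSegment <- function(startRes, endRes, startCol = NA_integer_,
                          endCol = NA_integer_) {
  if (endRes < startRes) stop("endRes must be >= startRes")
  data.frame(start_col = as.integer(startCol), end_col = as.integer(endCol),
             start_res = as.integer(startRes), end_res = as.integer(endRes),
             length_res = as.integer(endRes) - as.integer(startRes) + 1L)
}

#' Mean pairwise percent identity of an alignment
#'
#' Identity of a pair is 100 times the number of identical positions divided
#' by the number of positions where both rows are non-gap; pairs with no
#' comparable positions are excluded from the mean.
#'
#' @param msa a [ProteinMSA-class] with at least two records.
#' @param colRange optional \code{c(start, end)} 1-based inclusive column
#'   range to restrict the computation to.
#' @return Mean percent identity over all unordered record pairs.
#' @export
meanPairwiseIdentity <- function(msa, colRange = NULL) {
  if (nSeq(msa) < 2L) stop("at least 2 records required")
  m <- .msaMatrix(msa)
  if (!is.null(colRange)) m <- m[, colRange[1L]:colRange[2L], drop = FALSE]
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    id <- .pairIdentity(m[i, ], m[j, ])
    if (!is.na(id)) vals <- c(vals, id)
  }
  if (!length(vals)) stop("no comparable positions in any pair")
  mean(vals)
}

#' Minimum percent identity of alignment records to a reference
#'
#' @param msa a [ProteinMSA-class] with at least two records.
#' @param referenceId id of the reference record.
#' @return Minimum over non-reference records of percent identity to the
#'   reference (same identity definition as [meanPairwiseIdentity()]).
#' @export
minIdentityToReference <- function(msa, referenceId) {
  if (nSeq(msa) < 2L) stop("at least 2 records required")
  i <- match(referenceId, msa@ids)
  if (is.na(i)) stop(sprintf("unknown reference id '%s'", referenceId))
  m <- .msaMatrix(msa)
  ids <- vapply(setdiff(seq_len(nrow(m)), i), function(j)
    .pairIdentity(m[i, ], m[j, ]), numeric(1))
  min(ids, na.rm = TRUE)
}

# percent identity of two aligned character rows; NA if no comparable position
.pairIdentity <- function(a, b) {
  comp <- a != "-" & b != "-"
  if (!any(comp)) return(NA_real_)
  100 * sum(a[comp] == b[comp]) / sum(comp)
}

#' Write a conservation profile as a two-column TSV
#'
#' @param profile a [ConservationProfile-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeProfileTsv <- function(profile, path) {
  utils::write.table(
    data.frame(column = seq_along(profile@raw), raw = profile@raw,
               smoothed = profile@smoothed),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write delimited segments as a TSV with both coordinate systems
#'
#' The header comment names the coordinate conventions (1-based inclusive
#' alignment columns and reference residue positions).
#'
#' @param segments segment \code{data.frame} from [delimitDomains()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSegmentsTsv <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# domain segments: start_col/end_col are 1-based inclusive alignment columns;",
    sprintf("# start_res/end_res are 1-based inclusive residue positions on reference '%s'",
            attr(segments, "reference") %||% "NA")), con)
  utils::write.table(segments, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
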