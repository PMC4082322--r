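#' Filter incomplete sequences against a model length
#'
#' Keeps records whose non-gap residue count covers at least
#' \code{minCoverage} of the model length.
#'
#' @param msa a [ProteinMSA-class].
#' @param modelLength reference model length in residues.
#' @param minCoverage minimum coverage fraction (default 0.7).
#' @return List with \code{msa} (kept records; may be empty, with a warning)
#'   and \code{report} (\code{data.frame} of id, coverage, kept).
#' @export
filterIncomplete <- function(msa, modelLength, minCoverage = 0.7) {
  if (modelLength < 1L) stop("modelLength must be >= 1")
  lens <- vapply(msa@rows, function(r) sum(.splitRow(r) != "-"), numeric(1))
  cov <- unname(lens) / modelLength
  keep <- cov >= minCoverage
  report <- data.frame(id = msa@ids, coverage = cov, kept = keep)
  if (!any(keep)) {
    warning("no sequence passes the coverage filter")
    return(list(msa = NULL, report = report))
  }
  list(msa = ProteinMSA(msa@ids[keep], msa@rows[keep]), report = report)
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Records are visited by descending ungapped length (ties: input order); a
#' record joins the first existing representative to which its pairwise
#' identity (computed on shared alignment columns) is at least
#' \code{identityThreshold}, otherwise it founds a new cluster. Deterministic.
#'
#' @param msa a [ProteinMSA-class].
#' @param identityThreshold identity fraction in (0, 1] (default 0.95).
#' @return List with \code{msa} (representatives, in input order) and
#'   \code{clusters} (named list: representative id -> member ids).
#' @export
removeRedundant <- function(msa, identityThreshold = 0.95) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must lie in (0, 1]")
  m <- .msaMatrix(msa)
  lens <- rowSums(m != "-")
  ord <- order(-lens)
  reps <- integer(0)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      id <- .pairIdentity(m[r, ], m[i, ])
      if (!is.na(id) && id / 100 >= identityThreshold) {
        clusters[[msa@ids[r]]] <- c(clusters[[msa@ids[r]]], msa@ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[msa@ids[i]]] <- msa@ids[i]
    }
  }
  reps <- sort(reps)
  list(msa = ProteinMSA(msa@ids[reps], msa@rows[reps]), clusters = clusters)
}

#' Trim alignment columns by gap fraction
#'
#' Keeps columns whose gap fraction is at most \code{maxGapFraction}.
#'
#' @param msa a [ProteinMSA-class].
#' @param maxGapFraction maximum tolerated gap fraction (default 0.2).
#' @return List with \code{msa} (trimmed) and \code{kept_columns} (original
#'   1-based column indices).
#' @export
trimColumns <- function(msa, maxGapFraction = 0.2) {
  m <- .msaMatrix(msa)
  gapfrac <- colMeans(m == "-")
  kept <- which(gapfrac <= maxGapFraction)
  if (!length(kept))
    stop("all columns removed; increase maxGapFraction")
  list(msa = msaColumns(msa, kept), kept_columns = kept)
}

#' Pairwise protein distance matrix of an alignment
#'
#' \code{p} distances are \eqn{1 - identity}; the \code{kimura} protein
#' correction is \eqn{d = -\ln(1 - p - 0.2 p^2)}. Identity uses positions
#' where both rows are non-gap. Kimura distances saturate: any pair with
#' \eqn{p \ge 0.85} raises an error.
#'
#' @param msa a [ProteinMSA-class] with at least 3 records.
#' @param model \code{"p"} or \code{"kimura"}.
#' @return Labeled symmetric numeric matrix with zero diagonal.
#' @export
pairwiseDistance <- function(msa, model = c("kimura", "p")) {
  model <- match.arg(model)
  n <- nSeq(msa)
  if (n < 3L) stop("at least 3 records required")
  m <- .msaMatrix(msa)
  d <- matrix(0, n, n, dimnames = list(msa@ids, msa@ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    id <- .pairIdentity(m[i, ], m[j, ])
    if (is.na(id)) stop(sprintf("no comparable positions between '%s' and '%s'",
                                msa@ids[i], msa@ids[j]))
    p <- 1 - id / 100
    if (model == "kimura") {
      if (p >= 0.85)
        stop(sprintf("saturated distance (p = %.2f) between '%s' and '%s'",
                     p, msa@ids[i], msa@ids[j]))
      d[i, j] <- d[j, i] <- -log(1 - p - 0.2 * p^2)
    } else {
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

.checkDistanceMatrix <- function(dm, minN = 3L) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (nrow(dm) < minN) stop(sprintf("at least %d taxa required", minN))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dm < 0)) stop("distances must be non-negative")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a message.
#'
#' @param dm labeled symmetric distance matrix (n >= 3).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(dm) {
  .checkDistanceMatrix(dm)
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    message(sprintf("clamped %d negative branch length(s) to 0",
                    sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the fraction of replicates containing it. Replicates whose distance
#' computation saturates are skipped and counted.
#'
#' @param msa a [ProteinMSA-class].
#' @param model distance model, see [pairwiseDistance()].
#' @param nReps number of bootstrap replicates (at least 10; default 100).
#' @param seed RNG seed.
#' @return List with \code{tree} (NJ tree whose \code{node.label} carries
#'   supports in \[0, 1\]), \code{supports}, \code{n_used} and
#'   \code{n_skipped}.
#' @export
bootstrapSupport <- function(msa, model = "kimura", nReps = 100L, seed = 1L) {
  if (nReps < 10L) stop("nReps must be >= 10")
  main <- njTree(pairwiseDistance(msa, model))
  w <- msaWidth(msa)
  boots <- withSeed(seed, {
    lapply(seq_len(nReps), function(b) {
      cols <- sample.int(w, w, replace = TRUE)
      tryCatch(njTree(suppressMessages(
        pairwiseDistance(msaColumns(msa, cols), model))),
        error = function(e) NULL)
    })
  })
  skipped <- sum(vapply(boots, is.null, logical(1)))
  if (skipped > 0L)
    warning(sprintf("%d replicate(s) skipped (saturated distances)", skipped))
  boots <- Filter(Negate(is.null), boots)
  if (!length(boots)) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- counts / length(boots)
  main$node.label <- sprintf("%.3f", supports)
  list(tree = main, supports = supports,
       n_used = length(boots), n_skipped = skipped)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm labeled symmetric distance matrix.
#' @param path output path.
#' @param strict if \code{TRUE}, use the classic fixed 10-character label
#'   field; otherwise labels are whitespace-separated (relaxed dialect).
#' @return Invisibly, \code{path}.
#' @export
writePhylipDist <- function(dm, path, strict = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    lab <- rownames(dm)[i]
    lab <- if (strict) sprintf("%-10s", substr(lab, 1L, 10L))
           else paste0(lab, " ")
    writeLines(paste0(lab, paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the classic 10-character-label dialect and relaxed
#' whitespace-separated labels; wrapped rows are handled by token counting.
#'
#' @param path input path.
#' @return Labeled symmetric numeric matrix.
#' @export
readPhylipDist <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  n <- as.integer(toks[1L])
  toks <- toks[-1L]
  labels <- character(n)
  dm <- matrix(0, n, n)
  pos <- 1L
  for (i in seq_len(n)) {
    labels[i] <- toks[pos]
    vals <- as.numeric(toks[pos + seq_len(n)])
    if (anyNA(vals)) stop("malformed PHYLIP matrix")
    dm[i, ] <- vals
    pos <- pos + n + 1L
  }
  dimnames(dm) <- list(labels, labels)
  dm
}
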