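#' Build a profile HMM from a seed domain alignment
#'
#' Alignment columns with more than 50\% gaps become insert columns, the
#' rest become match states. Match emissions are (optionally
#' Henikoff-position-weighted) residue counts mixed with substitution-matrix
#' pseudocounts: with observed frequency vector \eqn{f} and matrix
#' conditionals \eqn{g_a = \sum_b P(a|b) f_b}, the emission is
#' \eqn{(1-\alpha) f + \alpha g} with \eqn{\alpha = 20 / (20 + n_{eff})}.
#' Transitions are Laplace-smoothed counts of the per-sequence state paths.
#' Local entry is uniform over match states and the local exit probability of
#' match state \eqn{k} is \eqn{1 / (M - k + 1)}, which makes the model end
#' position approximately uniform a priori. The model is HMMER-like but not
#' bit-compatible with HMMER.
#'
#' @param seed a [ProteinMSA-class] with at least 2 records (ungapped or
#'   lightly gapped).
#' @param pseudocountMatrix \code{"BLOSUM62"}, \code{"BLOSUM90"}, or
#'   \code{"laplace"} for plus-one pseudocounts.
#' @param weighting \code{"position"} (Henikoff position-based) or
#'   \code{"none"}.
#' @param background background distribution: \code{"uniform"},
#'   \code{"blosum62"}, or a numeric vector of 20 frequencies.
#' @param flankLoop self-loop probability of the flanking background states.
#' @return A [ProfileHMM-class].
#' @examples
#' seed <- ProteinMSA(c("s1", "s2", "s3"), c("AC", "AC", "AG"))
#' hmm <- buildProfile(seed, "laplace", "none")
#' hmm@M
#' @export
buildProfile <- function(seed,
                         pseudocountMatrix = c("BLOSUM62", "BLOSUM90", "laplace"),
                         weighting = c("position", "none"),
                         background = "uniform", flankLoop = 350 / 351) {
  pseudocountMatrix <- match.arg(pseudocountMatrix)
  weighting <- match.arg(weighting)
  if (nSeq(seed) < 2L) stop("empty seed: at least 2 seed records required")
  bg <- .asBackground(background)
  m <- .msaMatrix(seed)
  n <- nrow(m)
  gapfrac <- colMeans(m == "-")
  isMatch <- gapfrac <= 0.5
  M <- sum(isMatch)
  if (M < 1L) stop("no match columns (all columns are >50% gaps)")

  w <- if (weighting == "position") .henikoffWeights(m) else rep(1, n)
  w <- w * n / sum(w)
  neff <- n

  matchCols <- which(isMatch)
  emis <- matrix(0, M, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (s in seq_len(M)) {
    col <- m[, matchCols[s]]
    ok <- col %in% AA_ALPHABET
    cnt <- vapply(AA_ALPHABET, function(a) sum(w[ok][col[ok] == a]), numeric(1))
    if (pseudocountMatrix == "laplace") {
      e <- cnt + 1
    } else {
      f <- if (sum(cnt) > 0) cnt / sum(cnt) else bg
      g <- as.numeric(.matrixConditional(pseudocountMatrix) %*% f)
      alpha <- 20 / (20 + neff)
      e <- (1 - alpha) * f + alpha * g
    }
    emis[s, ] <- e / sum(e)
  }

  tr <- .countTransitions(m, matchCols, w, M)
  exitp <- 1 / (M - seq_len(M) + 1)
  trans <- matrix(0, M, 7L,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (k in seq_len(M)) {
    if (k < M) {
      core <- tr$m[k, ] + 1  # Laplace over MM, MI, MD
      core <- core / sum(core)
      trans[k, c("MM", "MI", "MD")] <- (1 - exitp[k]) * core
      ins <- tr$i[k, ] + 1
      trans[k, c("IM", "II")] <- ins / sum(ins)
      del <- tr$d[k, ] + 1
      trans[k, c("DM", "DD")] <- del / sum(del)
    } else {
      trans[k, ] <- c(0, 0, 0, 1, 0, 1, 0)  # M_M and D_M exit with prob 1
    }
  }

  new("ProfileHMM", M = as.integer(M), matchEmissions = emis,
      insertEmissions = matrix(rep(bg, M + 1L), M + 1L, 20L, byrow = TRUE,
                               dimnames = list(NULL, AA_ALPHABET)),
      transitions = trans, entry = rep(1 / M, M), exit = exitp,
      background = bg, flankLoop = flankLoop,
      metadata = list(seedIds = seqIds(seed),
                      pseudocountMatrix = pseudocountMatrix,
                      weighting = weighting,
                      matchColumns = matchCols))
}

# Henikoff position-based sequence weights (gaps contribute nothing)
.henikoffWeights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- col %in% AA_ALPHABET
    if (!any(ok)) next
    tab <- table(col[ok])
    r <- length(tab)
    w[ok] <- w[ok] + 1 / (r * as.numeric(tab[col[ok]]))
  }
  if (all(w == 0)) rep(1, n) else pmax(w, 1e-8)
}

# weighted transition counts between consecutive match states; inserts that
# follow a delete state are skipped (Plan7 has no D->I / I->D transitions)
.countTransitions <- function(m, matchCols, w, M) {
  cm <- matrix(0, max(M - 1L, 1L), 3L, dimnames = list(NULL, c("MM", "MI", "MD")))
  ci <- matrix(0, max(M - 1L, 1L), 2L, dimnames = list(NULL, c("IM", "II")))
  cd <- matrix(0, max(M - 1L, 1L), 2L, dimnames = list(NULL, c("DM", "DD")))
  if (M < 2L) return(list(m = cm, i = ci, d = cd))
  allCols <- seq_len(ncol(m))
  for (s in seq_len(nrow(m))) {
    row <- m[s, ]
    occupied <- row[matchCols] != "-"
    if (!any(occupied)) next
    first <- which(occupied)[1L]
    last <- which(occupied)[length(which(occupied))]
    if (first == last) next
    for (k in first:(last - 1L)) {
      prevState <- if (row[matchCols[k]] != "-") "M" else "D"
      nextState <- if (row[matchCols[k + 1L]] != "-") "M" else "D"
      between <- allCols[allCols > matchCols[k] & allCols < matchCols[k + 1L]]
      nIns <- if (length(between)) sum(row[between] != "-") else 0L
      if (prevState == "M") {
        if (nIns > 0L) {
          cm[k, "MI"] <- cm[k, "MI"] + w[s]
          if (nIns > 1L) ci[k, "II"] <- ci[k, "II"] + w[s] * (nIns - 1L)
          if (nextState == "M") ci[k, "IM"] <- ci[k, "IM"] + w[s]
        } else {
          cm[k, if (nextState == "M") "MM" else "MD"] <-
            cm[k, if (nextState == "M") "MM" else "MD"] + w[s]
        }
      } else {
        cd[k, if (nextState == "M") "DM" else "DD"] <-
          cd[k, if (nextState == "M") "DM" else "DD"] + w[s]
      }
    }
  }
  list(m = cm, i = ci, d = cd)
}

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM: %d match states (%s pseudocounts, %s weighting)\n",
              object@M,
              object@metadata$pseudocountMatrix %||% "?",
              object@metadata$weighting %||% "?"))
  cat(sprintf("  built from %d seed sequences\n",
              length(object@metadata$seedIds %||% character(0))))
})

# log2 parameter pack handed to the C++ dynamic programming kernels
.hmmLogPack <- function(hmm) {
  lg <- function(x) ifelse(x > 0, log2(x), -Inf)
  tr <- hmm@transitions
  M <- hmm@M
  kk <- if (M > 1L) seq_len(M - 1L) else integer(0)
  list(me = log2(sweep(hmm@matchEmissions, 2L, hmm@background, "/")),
       lEntry = lg(hmm@entry), lExit = lg(hmm@exit),
       lMM = lg(tr[kk, "MM"]), lMI = lg(tr[kk, "MI"]), lMD = lg(tr[kk, "MD"]),
       lIM = lg(tr[kk, "IM"]), lII = lg(tr[kk, "II"]),
       lDM = lg(tr[kk, "DM"]), lDD = lg(tr[kk, "DD"]),
       lpLoop = log2(hmm@flankLoop), lpMove = log2(1 - hmm@flankLoop))
}

.seqToIdx <- function(seq) {
  chars <- .splitRow(toupper(seq))
  idx <- match(chars, AA_ALPHABET) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

#' Viterbi bit score, envelope and match-state path of a sequence
#'
#' Best local log2-odds alignment of \code{seq} to the model versus the
#' background null. The envelope is the target coordinate range spanned by
#' the first and last match state on the optimal path.
#'
#' @param hmm a [ProfileHMM-class].
#' @param seq character scalar amino-acid sequence.
#' @return List with \code{bits}, \code{envelope} (\code{c(start, end)},
#'   1-based inclusive) and \code{matchpos} (integer vector of length M: the
#'   target position matched by each match state, 0 if unused).
#' @export
viterbiScore <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  p <- .hmmLogPack(hmm)
  r <- cpp_hmm_viterbi(p$me, p$lEntry, p$lExit, p$lMM, p$lMI, p$lMD,
                       p$lIM, p$lII, p$lDM, p$lDD,
                       .seqToIdx(seq), p$lpLoop, p$lpMove)
  list(bits = r$bits, envelope = c(r$env_start, r$env_end),
       matchpos = r$matchpos)
}

#' Forward bit score of a sequence
#'
#' Log2-odds of the total model probability (sum over all local alignments)
#' versus the background null; always at least the Viterbi score.
#'
#' @inheritParams viterbiScore
#' @return Numeric bit score.
#' @export
forwardScore <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  p <- .hmmLogPack(hmm)
  cpp_hmm_forward(p$me, p$lEntry, p$lExit, p$lMM, p$lMI, p$lMD,
                  p$lIM, p$lII, p$lDM, p$lDD,
                  .seqToIdx(seq), p$lpLoop, p$lpMove)
}

#' Relative-entropy logo data of a profile HMM
#'
#' Per match position, the relative entropy (Kullback-Leibler divergence in
#' bits) of the match emission distribution against the background, the
#' per-letter heights (emission probability times position relative
#' entropy), and the insertion/deletion opening probabilities used to scale
#' logo column widths.
#'
#' @param hmm a [ProfileHMM-class].
#' @return List with a \code{positions} data.frame (\code{position},
#'   \code{relative_entropy}, \code{insert_open}, \code{delete_open}) and a
#'   \code{heights} M x 20 matrix in bits.
#' @export
relativeEntropyLogo <- function(hmm) {
  p <- hmm@matchEmissions
  q <- hmm@background
  rel <- vapply(seq_len(hmm@M), function(k) {
    pk <- p[k, ]
    sum(ifelse(pk > 0, pk * log2(pk / q), 0))
  }, numeric(1))
  heights <- p * rel
  tr <- hmm@transitions
  data_pos <- data.frame(position = seq_len(hmm@M), relative_entropy = rel,
                         insert_open = tr[, "MI"], delete_open = tr[, "MD"])
  list(positions = data_pos, heights = heights)
}

#' Calibrate bit-score E-values with background decoys
#'
#' Scores \code{nDecoys} i.i.d. background sequences with [viterbiScore()]
#' and fits a Gumbel distribution to the scores by maximum likelihood. The
#' E-value of a score \eqn{s} against a database of \eqn{N} sequences is
#' \eqn{N (1 - \exp(-\exp(-\lambda (s - \mu))))}.
#'
#' @param hmm a [ProfileHMM-class].
#' @param nDecoys number of decoys (at least 50; default 200).
#' @param decoyLen decoy length (default 350 residues).
#' @param seed RNG seed for decoy sampling.
#' @return A [GumbelCalibration-class].
#' @export
calibrateEvalues <- function(hmm, nDecoys = 200L, decoyLen = 350L, seed = 1L) {
  if (nDecoys < 50L) stop("nDecoys must be >= 50")
  scores <- withSeed(seed, {
    vapply(seq_len(nDecoys), function(i) {
      s <- paste(sample(AA_ALPHABET, decoyLen, replace = TRUE,
                        prob = hmm@background), collapse = "")
      viterbiScore(hmm, s)$bits
    }, numeric(1))
  })
  if (stats::sd(scores) < 1e-9)
    stop("degenerate decoy score variance; increase nDecoys or decoyLen")
  fit <- .gumbelML(scores)
  new("GumbelCalibration", lambda = fit$lambda, mu = fit$mu,
      nDecoys = as.integer(nDecoys), decoyLen = as.integer(decoyLen),
      decoySeed = as.integer(seed))
}

# maximum-likelihood Gumbel (max-value) fit
.gumbelML <- function(x) {
  xbar <- mean(x)
  f <- function(beta) {
    w <- exp(-(x - min(x)) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) / 20
  hi <- stats::sd(x) * 20
  # expand bracket if needed
  while (f(lo) * f(hi) > 0 && hi < 1e6) hi <- hi * 10
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  z <- -x / beta
  mu <- -beta * (max(z) + log(mean(exp(z - max(z)))))
  list(lambda = 1 / beta, mu = mu)
}

#' E-value of a bit score under a Gumbel calibration
#'
#' @param calibration a [GumbelCalibration-class].
#' @param bits numeric bit score(s).
#' @param N database size (number of sequences).
#' @return E-value(s), strictly decreasing in \code{bits}.
#' @export
evalueFromScore <- function(calibration, bits, N) {
  z <- exp(-calibration@lambda * (bits - calibration@mu))
  N * (-expm1(-z))
}

setMethod("show", "GumbelCalibration", function(object) {
  cat(sprintf("GumbelCalibration: lambda %.4f, mu %.2f bits (%d decoys of length %d, seed %d)\n",
              object@lambda, object@mu, object@nDecoys, object@decoyLen,
              object@decoySeed))
})

#' Search a sequence database with a profile HMM
#'
#' Scores every database sequence with [viterbiScore()], converts scores to
#' E-values with the given calibration and the database size, and returns
#' hits passing the cutoff sorted by increasing E-value then target id.
#'
#' @param hmm a [ProfileHMM-class].
#' @param database named character vector (or \code{AAStringSet}) of target
#'   sequences.
#' @param calibration a [GumbelCalibration-class].
#' @param evalueCutoff E-value cutoff (default 1e-10).
#' @param iteration iteration label stored in \code{iteration_found}.
#' @return \code{data.frame} with columns \code{target_id},
#'   \code{envelope_start}, \code{envelope_end}, \code{bit_score},
#'   \code{evalue}, \code{iteration_found}.
#' @export
searchProfile <- function(hmm, database, calibration, evalueCutoff = 1e-10,
                          iteration = 1L) {
  if (evalueCutoff <= 0) stop("evalueCutoff must be > 0")
  database <- .asDatabase(database)
  if (!length(database)) return(.emptyHits())
  res <- lapply(database, function(s) viterbiScore(hmm, s))
  bits <- vapply(res, `[[`, numeric(1), "bits")
  ev <- evalueFromScore(calibration, bits, length(database))
  hits <- data.frame(target_id = names(database),
                     envelope_start = vapply(res, function(r) r$envelope[1L], numeric(1)),
                     envelope_end = vapply(res, function(r) r$envelope[2L], numeric(1)),
                     bit_score = bits, evalue = ev,
                     iteration_found = as.integer(iteration),
                     row.names = NULL)
  hits <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  hits[order(hits$evalue, hits$target_id), , drop = FALSE]
}

.emptyHits <- function() {
  data.frame(target_id = character(0), envelope_start = numeric(0),
             envelope_end = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), iteration_found = integer(0))
}

.asDatabase <- function(database) {
  if (is(database, "AAStringSet")) {
    out <- as.character(database)
    names(out) <- sub("\\s.*$", "", names(database))
    return(out)
  }
  if (is.null(names(database)) && length(database))
    stop("database sequences must be named")
  database
}

#' Iterative (jackhmmer-style) profile HMM database search
#'
#' At each iteration a profile is built from the current seed alignment, the
#' database is searched, and the match-state-aligned envelopes of all hits
#' found so far are added to the seed for the next round. Iteration stops at
#' \code{maxIter} or as soon as the hit set stops growing. The E-value
#' calibration uses the same decoy seed at every iteration, making hit lists
#' monotone non-shrinking across iterations.
#'
#' @param seed a [ProteinMSA-class] seed alignment.
#' @param database named character vector (or \code{AAStringSet}).
#' @param evalueCutoff E-value cutoff (default 1e-10).
#' @param maxIter maximum number of iterations (default 3).
#' @param pseudocountMatrix pseudocount matrix name (default BLOSUM90).
#' @param weighting sequence weighting scheme, see [buildProfile()].
#' @param nDecoys decoys per calibration (default 200).
#' @param calibrationSeed RNG seed for decoy sampling.
#' @return List with the final \code{hmm}, \code{hits} (one data.frame per
#'   iteration, cumulative), the final \code{seed} alignment, the number of
#'   \code{iterations} run and a \code{converged} flag.
#' @export
iterativeSearch <- function(seed, database, evalueCutoff = 1e-10, maxIter = 3L,
                            pseudocountMatrix = "BLOSUM90",
                            weighting = "position", nDecoys = 200L,
                            calibrationSeed = 1L) {
  database <- .asDatabase(database)
  if (!length(database)) stop("database is empty")
  decoyLen <- max(10L, as.integer(round(mean(nchar(database)))))
  curSeed <- seed
  acc <- .emptyHits()
  hitsPerIter <- list()
  hmm <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    hmm <- buildProfile(curSeed, pseudocountMatrix, weighting)
    cal <- calibrateEvalues(hmm, nDecoys = nDecoys, decoyLen = decoyLen,
                            seed = calibrationSeed)
    hits <- searchProfile(hmm, database, cal, evalueCutoff, iteration = iter)
    # cumulative union; a re-found target keeps its original discovery iteration
    for (r in seq_len(nrow(hits))) {
      j <- match(hits$target_id[r], acc$target_id)
      if (is.na(j)) acc <- rbind(acc, hits[r, , drop = FALSE])
      else {
        it0 <- acc$iteration_found[j]
        acc[j, ] <- hits[r, , drop = FALSE]
        acc$iteration_found[j] <- it0
      }
    }
    acc <- acc[order(acc$evalue, acc$target_id), , drop = FALSE]
    rownames(acc) <- NULL
    hitsPerIter[[iter]] <- acc
    # grow the seed with match-aligned envelopes of new hits
    newIds <- setdiff(acc$target_id, seqIds(curSeed))
    if (!length(newIds)) { converged <- TRUE; break }
    rows <- vapply(newIds, function(id)
      .matchAlignedRow(hmm, database[[id]]), character(1))
    curSeed <- ProteinMSA(c(seqIds(curSeed), newIds),
                          c(.projectToMatch(hmm, curSeed), rows))
  }
  list(hmm = hmm, hits = hitsPerIter, seed = curSeed,
       iterations = iter, converged = converged)
}

# row of length M: the residue matched at each match state, '-' at deletions
.matchAlignedRow <- function(hmm, seq) {
  mp <- viterbiScore(hmm, seq)$matchpos
  chars <- rep("-", hmm@M)
  used <- mp > 0
  chars[used] <- .splitRow(toupper(seq))[mp[used]]
  paste(chars, collapse = "")
}

# project an existing seed alignment onto the current model's match columns
.projectToMatch <- function(hmm, seed) {
  mc <- hmm@metadata$matchColumns
  m <- .msaMatrix(seed)[, mc, drop = FALSE]
  apply(m, 1L, paste, collapse = "")
}

#' Serialize a profile HMM to a versioned plain-text file
#'
#' Writes all probabilities at full precision (\code{\%.12g}); the format
#' round-trips through [readProfileHmm()] to within 1e-9.
#'
#' @param hmm a [ProfileHMM-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeProfileHmm <- function(hmm, path) {
  fmt <- function(x) paste(sprintf("%.12g", x), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DomainScoutHMM 1",
               sprintf("M %d", hmm@M),
               sprintf("flankLoop %.12g", hmm@flankLoop),
               paste("background", fmt(hmm@background)),
               paste("entry", fmt(hmm@entry)),
               paste("exit", fmt(hmm@exit))), con)
  for (k in seq_len(hmm@M))
    writeLines(paste("MATCH", k, fmt(hmm@matchEmissions[k, ])), con)
  for (k in seq_len(hmm@M + 1L))
    writeLines(paste("INSERT", k, fmt(hmm@insertEmissions[k, ])), con)
  for (k in seq_len(hmm@M))
    writeLines(paste("TRANS", k, fmt(hmm@transitions[k, ])), con)
  writeLines(paste("METADATA", jsonlite::toJSON(hmm@metadata, auto_unbox = TRUE)),
             con)
  invisible(path)
}

#' Read a profile HMM written by [writeProfileHmm()]
#'
#' @param path input path.
#' @return A [ProfileHMM-class].
#' @export
readProfileHmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "DomainScoutHMM")) stop("not a DomainScout HMM file")
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1L]
    as.numeric(strsplit(sub(paste0("^", key, " "), "", ln), " +")[[1L]])
  }
  M <- as.integer(field("M"))
  grab <- function(key, n, ncol) {
    rows <- lines[startsWith(lines, paste0(key, " "))]
    m <- t(vapply(rows, function(ln) {
      v <- as.numeric(strsplit(ln, " +")[[1L]][-(1:2)])
      v
    }, numeric(ncol)))
    rownames(m) <- NULL
    m
  }
  me <- grab("MATCH", M, 20L); colnames(me) <- AA_ALPHABET
  ie <- grab("INSERT", M + 1L, 20L); colnames(ie) <- AA_ALPHABET
  tr <- grab("TRANS", M, 7L)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  mdLine <- lines[startsWith(lines, "METADATA ")][1L]
  md <- if (!is.na(mdLine))
    jsonlite::fromJSON(sub("^METADATA ", "", mdLine)) else list()
  new("ProfileHMM", M = M,
      matchEmissions = me / rowSums(me), insertEmissions = ie / rowSums(ie),
      transitions = tr, entry = field("entry"), exit = field("exit"),
      background = stats::setNames(field("background"), AA_ALPHABET),
      flankLoop = field("flankLoop"), metadata = as.list(md))
}

#' Write search hits as TSV
#'
#' @param hits hit \code{data.frame} from [searchProfile()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeHitsTsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
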