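# Independent oracles and small fixture builders used across the suite.

# --- property-based conservation: independent transcription of the
# Taylor/Zvelebil table and a direct enumeration scorer -----------------
ORACLE_PROPERTIES <- list(
  c("I","L","V","C","A","G","M","F","Y","W","H","K","T"),   # hydrophobic
  c("Y","W","H","K","R","E","Q","D","N","S","T","C"),       # polar
  c("V","C","A","G","D","N","S","T","P"),                   # small
  c("P"),                                                   # proline
  c("A","G","S"),                                           # tiny
  c("I","L","V"),                                           # aliphatic
  c("F","Y","W","H"),                                       # aromatic
  c("H","K","R"),                                           # positive
  c("D","E"),                                               # negative
  c("H","K","R","D","E"))                                   # charged

oracleColumnScore <- function(column) {
  s <- 0L
  for (p in ORACLE_PROPERTIES) {
    status <- vapply(column, function(ch) ch %in% p, logical(1))
    if (length(unique(status)) == 1L) s <- s + 1L
  }
  s
}

# TRUE if two residues have identical property membership vectors
samePropertyVector <- function(a, b) {
  all(vapply(ORACLE_PROPERTIES, function(p) (a %in% p) == (b %in% p), logical(1)))
}

# scalar-loop percent identity (both-non-gap denominator)
oraclePairIdentity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  nid <- 0L; ncomp <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] != "-" && cb[i] != "-") {
      ncomp <- ncomp + 1L
      if (ca[i] == cb[i]) nid <- nid + 1L
    }
  }
  if (ncomp == 0L) return(NA_real_)
  100 * nid / ncomp
}

# --- profile HMM: toy model builders and an exhaustive path-sum oracle ----
makeToyHmm <- function(emis, bg = rep(1 / 20, 20), flankLoop = 350 / 351,
                       coreProps = c(0.9, 0.05, 0.05)) {
  M <- nrow(emis)
  colnames(emis) <- DomainScout::AA_ALPHABET
  exitp <- 1 / (M - seq_len(M) + 1)
  trans <- matrix(0, M, 7,
                  dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (k in seq_len(M)) {
    if (k < M) {
      trans[k, 1:3] <- (1 - exitp[k]) * coreProps / sum(coreProps)
      trans[k, 4:5] <- c(0.9, 0.1)
      trans[k, 6:7] <- c(0.9, 0.1)
    } else trans[k, ] <- c(0, 0, 0, 1, 0, 1, 0)
  }
  methods::new("ProfileHMM", M = as.integer(M), matchEmissions = emis,
               insertEmissions = matrix(rep(bg, M + 1), M + 1, 20, byrow = TRUE,
                                        dimnames = list(NULL, DomainScout::AA_ALPHABET)),
               transitions = trans, entry = rep(1 / M, M), exit = exitp,
               background = stats::setNames(bg, DomainScout::AA_ALPHABET),
               flankLoop = flankLoop, metadata = list())
}

makeRandomHmm <- function(M, seed) {
  set.seed(seed)
  emis <- matrix(stats::runif(M * 20, 0.01, 1), M, 20)
  emis <- emis / rowSums(emis)
  core <- stats::runif(3, 0.05, 1)
  makeToyHmm(emis, coreProps = core)
}

# sharp model whose consensus path is forced
makeSharpHmm <- function(consensus, p = 0.96) {
  M <- nchar(consensus)
  chars <- strsplit(consensus, "")[[1]]
  emis <- matrix((1 - p) / 19, M, 20)
  for (k in seq_len(M)) emis[k, match(chars[k], DomainScout::AA_ALPHABET)] <- p
  makeToyHmm(emis)
}

# exhaustive sum over all legal state paths, straight from the generative
# definition of the model (probability-odds space, no dynamic programming
# sharing beyond plain recursion)
oracleForwardBits <- function(hmm, seq) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  ai <- match(x, DomainScout::AA_ALPHABET)
  q <- hmm@background
  tr <- hmm@transitions
  M <- hmm@M
  pL <- hmm@flankLoop
  valE <- function(i) pL^(L + 1 - i) * (1 - pL)
  valD <- function(k, i) {
    if (k == M) return(valE(i))
    tr[k, "DM"] * valM(k + 1, i) + tr[k, "DD"] * valD(k + 1, i)
  }
  valI <- function(k, i) {
    if (i > L) return(0)
    tr[k, "IM"] * valM(k + 1, i + 1) + tr[k, "II"] * valI(k, i + 1)
  }
  valM <- function(k, i) {
    if (i > L) return(0)
    e <- hmm@matchEmissions[k, ai[i]] / q[ai[i]]
    tot <- hmm@exit[k] * valE(i + 1)
    if (k < M)
      tot <- tot + tr[k, "MM"] * valM(k + 1, i + 1) +
        tr[k, "MI"] * valI(k, i + 1) + tr[k, "MD"] * valD(k + 1, i + 1)
    e * tot
  }
  valB <- function(i) sum(vapply(seq_len(M), function(k)
    hmm@entry[k] * valM(k, i), numeric(1)))
  total <- sum(vapply(0:L, function(a) pL^a * (1 - pL) * valB(a + 1), numeric(1)))
  log2(total)
}

randomSeq <- function(L) paste(sample(DomainScout::AA_ALPHABET, L, replace = TRUE),
                               collapse = "")

# --- architecture: brute-force max-weight non-overlapping subset ----------
oracleBestSubset <- function(hits) {
  n <- nrow(hits)
  feasible <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1L):length(idx)) {
      a <- hits[idx[i], ]; b <- hits[idx[j], ]
      ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
      shorter <- min(a$end - a$start + 1L, b$end - b$start + 1L)
      if (ov > max(10L, 0.2 * shorter)) return(FALSE)
    }
    TRUE
  }
  best <- 0
  for (m in 0:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
    if (feasible(idx)) best <- max(best, sum(hits$score[idx]))
  }
  best
}

# --- Fitch-Margoliash: exhaustive 5-taxon topology oracle ------------------
oracleEnum5 <- function() {
  quartets <- list(rbind(c(1,6),c(2,6),c(6,7),c(3,7),c(4,7)),
                   rbind(c(1,6),c(3,6),c(6,7),c(2,7),c(4,7)),
                   rbind(c(1,6),c(4,6),c(6,7),c(2,7),c(3,7)))
  out <- list()
  for (q in quartets) for (e in 1:5) {
    u <- q[e, 1]; v <- q[e, 2]
    out[[length(out) + 1L]] <- rbind(q[-e, , drop = FALSE],
                                     c(u, 8L), c(8L, v), c(5L, 8L))
  }
  out
}

oraclePathMatrix <- function(edges, leaves) {
  nodes <- sort(unique(as.integer(edges)))
  pairs <- t(utils::combn(leaves, 2L))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    # DFS path search between the two leaves
    target <- pairs[r, 2L]
    found <- FALSE
    walk <- function(node, from, path) {
      if (found) return()
      if (node == target) { A[r, path] <<- 1; found <<- TRUE; return() }
      for (e in seq_len(nrow(edges))) {
        if (e %in% path) next
        if (edges[e, 1L] == node) walk(edges[e, 2L], node, c(path, e))
        else if (edges[e, 2L] == node) walk(edges[e, 1L], node, c(path, e))
      }
    }
    walk(pairs[r, 1L], -1L, integer(0))
  }
  A
}

oracleFmBestE <- function(dm, power = 2) {
  pairs <- t(utils::combn(1:5, 2L))
  d <- dm[cbind(pairs[, 1L], pairs[, 2L])]
  w <- 1 / d^power
  best <- Inf
  for (edges in oracleEnum5()) {
    A <- oraclePathMatrix(edges, 1:5)
    obj <- function(b) sum(w * (d - as.numeric(A %*% b))^2)
    fit <- stats::optim(rep(mean(d) / 4, nrow(edges)), obj,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# --- misc ---------------------------------------------------------------
randomRotationMatrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# does the unrooted tree contain a bipartition separating `groupTips`?
hasBipartition <- function(tree, groupTips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  for (p in pp) {
    side <- labs[p]
    if (setequal(side, groupTips) || setequal(setdiff(labs, side), groupTips))
      return(TRUE)
  }
  FALSE
}
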