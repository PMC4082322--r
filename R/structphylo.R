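#' Read the C-alpha trace of a PDB file
#'
#' Extracts C-alpha \code{ATOM} records of one chain (alternate locations
#' \code{A} or blank only), ordered by residue number.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier (default \code{"A"}).
#' @return A [StructureModel-class].
#' @export
readCalpha <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  sel <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$chain) | at$chain == chain) &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[sel, , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha atoms found")
  if (anyDuplicated(at$resno))
    stop(sprintf("duplicate residue number %d after altloc filtering",
                 at$resno[duplicated(at$resno)][1L]))
  at <- at[order(at$resno), , drop = FALSE]
  res1 <- suppressWarnings(bio3d::aa321(at$resid))
  res1[is.na(res1) | res1 == "X"] <- "X"
  new("StructureModel", id = sub("\\.pdb$", "", basename(path)),
      residues = res1, resno = as.integer(at$resno),
      coords = unname(as.matrix(at[, c("x", "y", "z")])))
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' @param model a [StructureModel-class].
#' @param path output path.
#' @param chain chain identifier (default \code{"A"}).
#' @return Invisibly, \code{path}.
#' @export
writeCalpha <- function(model, path, chain = "A") {
  res3 <- bio3d::aa123(model@residues)
  res3[is.na(res3)] <- "UNK"
  lines <- sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_along(model@residues), res3, chain, model@resno,
                   model@coords[, 1L], model@coords[, 2L], model@coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel '%s': %d C-alpha residues\n",
              object@id, length(object@residues)))
})

#' Matched C-alpha coordinate pairs of two structures via a sequence MSA
#'
#' The alignment must contain rows for both structure ids whose ungapped
#' sequences equal the structures' residue sequences; coordinates are paired
#' at columns where both rows are non-gap.
#'
#' @param msa a [ProteinMSA-class] containing rows named after the structures.
#' @param a,b [StructureModel-class] objects.
#' @return List with \code{Xa}, \code{Xb} (matched n x 3 coordinate
#'   matrices) and \code{n_aligned}.
#' @export
pairedCoordinates <- function(msa, a, b) {
  rowFor <- function(s) {
    i <- match(s@id, msa@ids)
    if (is.na(i)) stop(sprintf("structure '%s' absent from alignment", s@id))
    chars <- .splitRow(msa@rows[i])
    ungapped <- chars[chars != "-"]
    if (length(ungapped) != length(s@residues))
      stop(sprintf("sequence/structure length mismatch for '%s' (%d vs %d)",
                   s@id, length(ungapped), length(s@residues)))
    mism <- which(ungapped != s@residues & ungapped != "X" & s@residues != "X")
    if (length(mism))
      stop(sprintf("sequence/structure mismatch for '%s' at residue %d ('%s' vs '%s')",
                   s@id, mism[1L], ungapped[mism[1L]], s@residues[mism[1L]]))
    chars
  }
  ra <- rowFor(a)
  rb <- rowFor(b)
  both <- ra != "-" & rb != "-"
  n <- sum(both)
  if (n < 3L) stop("fewer than 3 aligned residue pairs")
  ia <- cumsum(ra != "-")[both]
  ib <- cumsum(rb != "-")[both]
  list(Xa = a@coords[ia, , drop = FALSE], Xb = b@coords[ib, , drop = FALSE],
       n_aligned = n)
}

#' Kabsch least-squares superposition of two matched point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' \code{X} (mobile) and \code{Y} (fixed) via singular value decomposition
#' with determinant correction.
#'
#' @param X,Y n x 3 coordinate matrices of matched points (n >= 3, not all
#'   collinear).
#' @return List with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (so that \code{X \%*\% rotation + translation} superposes onto
#'   \code{Y}), \code{rmsd} (Angstrom) and \code{n_aligned}.
#' @export
kabschSuperpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L)
    stop("X and Y must be matched n x 3 matrices")
  n <- nrow(X)
  if (n < 3L) stop("at least 3 points required")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  svX <- svd(Xc)$d
  if (svX[2L] < 1e-8 * max(svX[1L], 1e-12))
    stop("degenerate (collinear) point set")
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  resid <- Xc %*% R - Yc
  rmsd <- sqrt(mean(rowSums(resid^2)))
  list(rotation = R, translation = as.numeric(cy - cx %*% R),
       rmsd = rmsd, n_aligned = n)
}

#' Length-normalized structural distance
#'
#' The distance used for structure-based trees:
#' \code{100 * rmsd / n_aligned}.
#'
#' @param rmsd RMSD in Angstrom.
#' @param nAligned number of aligned residues (>= 1).
#' @return Numeric distance.
#' @examples
#' normalizedStructuralDistance(2.5, 125)  # 2
#' @export
normalizedStructuralDistance <- function(rmsd, nAligned) {
  if (nAligned < 1L) stop("nAligned must be >= 1")
  if (rmsd < 0) stop("rmsd must be >= 0")
  100 * rmsd / nAligned
}

#' All-pairs normalized structural distance matrix
#'
#' For every structure pair: residue correspondence from the sequence MSA,
#' Kabsch superposition, and normalized RMSD distance. Each pair is computed
#' once, so the matrix is symmetric by construction.
#'
#' @param structs list of [StructureModel-class] objects (>= 3).
#' @param msa a [ProteinMSA-class] providing the residue correspondence.
#' @return List with \code{distance} (labeled symmetric matrix) and
#'   \code{report} (\code{data.frame} of pair, n_aligned, rmsd, distance).
#' @export
structuralDistanceMatrix <- function(structs, msa) {
  if (length(structs) < 3L) stop("at least 3 structures required")
  ids <- vapply(structs, function(s) s@id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  n <- length(structs)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  rep_rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pc <- pairedCoordinates(msa, structs[[i]], structs[[j]])
    sp <- kabschSuperpose(pc$Xa, pc$Xb)
    d <- normalizedStructuralDistance(sp$rmsd, pc$n_aligned)
    dm[i, j] <- dm[j, i] <- d
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(a = ids[i], b = ids[j], n_aligned = pc$n_aligned,
                 rmsd = sp$rmsd, distance = d)
  }
  list(distance = dm, report = do.call(rbind, rep_rows))
}

#' Fitch-Margoliash weighted least-squares tree
#'
#' Minimizes \eqn{E = \sum_{i<j} (d_{ij} - p_{ij})^2 / d_{ij}^{power}} over
#' tree path lengths \eqn{p_{ij}} by stepwise taxon addition in input order
#' followed by nearest-neighbor-interchange local search, with non-negative
#' weighted least-squares branch lengths at every step. \code{power = 2}
#' is the classic Fitch-Margoliash weighting; \code{power = 0} reduces to
#' unweighted least squares. Off-diagonal zero distances are replaced by
#' \code{1e-8} with a warning (the weight \eqn{1/d^2} is undefined at 0).
#'
#' @param dm labeled symmetric distance matrix (n >= 3).
#' @param power weighting exponent (default 2).
#' @return List with \code{tree} (unrooted \code{ape::phylo} with fitted
#'   branch lengths) and \code{error} (the final weighted least-squares
#'   criterion E).
#' @export
fitchMargoliashTree <- function(dm, power = 2.0) {
  .checkDistanceMatrix(dm)
  n <- nrow(dm)
  labels <- rownames(dm)
  off <- dm[upper.tri(dm)]
  if (any(off == 0)) {
    warning("replaced zero off-diagonal distance(s) by 1e-8")
    dm[dm == 0] <- 1e-8
    diag(dm) <- 0
  }

  # edges: 2-column matrix of node ids; leaves 1..n, internal nodes > n
  edges <- rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L))
  placed <- 3L
  nextInternal <- n + 2L
  for (t in seq_len(n)[-(1:3)]) {
    best <- NULL
    for (e in seq_len(nrow(edges))) {
      cand <- .fmAttach(edges, e, t, nextInternal)
      fit <- .fmEval(cand, dm, seq_len(t), power)
      if (is.null(best) || fit$E < best$E) best <- c(fit, list(edges = cand))
    }
    edges <- best$edges
    nextInternal <- nextInternal + 1L
    placed <- t
  }
  fit <- .fmEval(edges, dm, seq_len(n), power)
  # NNI local search
  repeat {
    improved <- FALSE
    internalEdges <- which(edges[, 1L] > n & edges[, 2L] > n)
    for (e in internalEdges) {
      for (swap in 1:2) {
        cand <- .fmNNI(edges, e, swap, n)
        if (is.null(cand)) next
        f2 <- .fmEval(cand, dm, seq_len(n), power)
        if (f2$E < fit$E - 1e-12) {
          edges <- cand
          fit <- f2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  tree <- .fmToPhylo(edges, fit$lengths, labels, n)
  list(tree = tree, error = fit$E)
}

# attach leaf `t` on edge e, subdividing it with internal node `x`
.fmAttach <- function(edges, e, t, x) {
  u <- edges[e, 1L]; v <- edges[e, 2L]
  rbind(edges[-e, , drop = FALSE],
        c(u, x), c(x, v), c(as.integer(t), x))
}

# nearest-neighbor interchange across internal edge e (two alternatives)
.fmNNI <- function(edges, e, swap, n) {
  u <- edges[e, 1L]; v <- edges[e, 2L]
  nbrU <- which((edges[, 1L] == u | edges[, 2L] == u) & seq_len(nrow(edges)) != e)
  nbrV <- which((edges[, 1L] == v | edges[, 2L] == v) & seq_len(nrow(edges)) != e)
  if (length(nbrU) < 2L || length(nbrV) < 2L) return(NULL)
  eu <- nbrU[2L]                       # subtree on u side to move
  ev <- nbrV[swap]                     # subtree on v side to move
  out <- edges
  # re-point the far endpoint of eu from u to v, and of ev from v to u
  out[eu, ] <- ifelse(out[eu, ] == u, v, out[eu, ])
  out[ev, ] <- ifelse(out[ev, ] == v, u, out[ev, ])
  out
}

# weighted non-negative least-squares branch lengths + criterion E
.fmEval <- function(edges, dm, leaves, power) {
  A <- .fmPathMatrix(edges, leaves)
  pairs <- t(utils::combn(leaves, 2L))
  d <- dm[cbind(pairs[, 1L], pairs[, 2L])]
  w <- 1 / d^power
  b <- .nnwls(A, d, w)
  resid <- d - as.numeric(A %*% b)
  list(E = sum(w * resid^2), lengths = b)
}

# pair x edge path-incidence matrix
.fmPathMatrix <- function(edges, leaves) {
  nodes <- sort(unique(as.integer(edges)))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1L]); b <- as.character(edges[e, 2L])
    adj[[a]] <- c(adj[[a]], e)
    adj[[b]] <- c(adj[[b]], e)
  }
  other <- function(e, node) {
    if (edges[e, 1L] == node) edges[e, 2L] else edges[e, 1L]
  }
  pairs <- t(utils::combn(leaves, 2L))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (lf in leaves) {
    # BFS from leaf lf recording the edge path to every node
    pathTo <- vector("list", max(nodes))
    visited <- rep(FALSE, max(nodes))
    queue <- lf
    visited[lf] <- TRUE
    pathTo[[lf]] <- integer(0)
    while (length(queue)) {
      nd <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[as.character(nd)]]) {
        nx <- other(e, nd)
        if (!visited[nx]) {
          visited[nx] <- TRUE
          pathTo[[nx]] <- c(pathTo[[nd]], e)
          queue <- c(queue, nx)
        }
      }
    }
    rows <- which(pairs[, 1L] == lf)
    for (r in rows) A[r, pathTo[[pairs[r, 2L]]]] <- 1
  }
  A
}

# non-negative weighted least squares by active-set clamping
.nnwls <- function(A, d, w) {
  p <- ncol(A)
  active <- rep(FALSE, p)
  b <- numeric(p)
  repeat {
    free <- which(!active)
    if (!length(free)) break
    Af <- A[, free, drop = FALSE]
    M <- t(Af) %*% (Af * w) + diag(1e-10, length(free))
    rhs <- t(Af) %*% (w * d)
    bf <- tryCatch(solve(M, rhs), error = function(e) rep(0, length(free)))
    if (all(bf >= -1e-10)) {
      b[free] <- pmax(as.numeric(bf), 0)
      break
    }
    active[free[which.min(bf)]] <- TRUE
  }
  b
}

# convert internal edge list to an ape::phylo via newick
.fmToPhylo <- function(edges, lengths, labels, n) {
  adj <- list()
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1L]); b <- as.character(edges[e, 2L])
    adj[[a]] <- rbind(adj[[a]], c(edges[e, 2L], e))
    adj[[b]] <- rbind(adj[[b]], c(edges[e, 1L], e))
  }
  nwk <- function(node, parent) {
    nb <- adj[[as.character(node)]]
    children <- nb[nb[, 1L] != parent, , drop = FALSE]
    if (node <= n && nrow(children) == 0L) return(labels[node])
    inner <- vapply(seq_len(nrow(children)), function(i) {
      paste0(nwk(children[i, 1L], node),
             sprintf(":%.10g", lengths[children[i, 2L]]))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  root <- n + 1L
  ape::read.tree(text = paste0(nwk(root, -1L), ";"))
}
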