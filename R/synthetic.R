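# Seeded generators of ground-truthed synthetic inputs. Every generator is
# a pure function of (parameters, seed): the caller's RNG state is left
# untouched and the same seed reproduces identical output.

#' Simulate a protein family sharing one conserved domain
#'
#' Draws a consensus domain from the background distribution; each family
#' member copies the consensus, substitutes every position independently
#' with probability \code{pSub} (replacement drawn from the background, so a
#' substitution can silently restore the consensus residue), and embeds the
#' domain between unrelated background flanks of uniform random length. The
#' true alignment is assembled column-wise from the known domain positions
#' (left flanks right-justified, right flanks left-justified).
#'
#' Under a uniform background the expected pairwise identity inside the
#' domain is \eqn{(1-p)^2 + p(2-p)/20}.
#'
#' @param n number of family members (default 14).
#' @param domainLen domain length in residues (default 193; at least 10).
#' @param flankLenRange \code{c(min, max)} flank length (default 50-150).
#' @param pSub per-site substitution probability in \[0, 0.5) (default 0.17).
#' @param background background distribution (name or 20 frequencies).
#' @param seed RNG seed.
#' @param prefix id prefix (default \code{"FAM"}).
#' @param consensus optional consensus domain sequence (character scalar);
#'   drawn from the background when \code{NULL}. Supplying the consensus of
#'   another simulated family produces homologous families, e.g. to plant
#'   searchable targets in a database.
#' @return List with \code{sequences} (named, unaligned), \code{alignment}
#'   (a [ProteinMSA-class]), \code{domain_coords} (\code{data.frame} of id,
#'   start, end, 1-based inclusive), \code{consensus} and \code{params}.
#' @export
simulateDomainFamily <- function(n = 14L, domainLen = 193L,
                                 flankLenRange = c(50L, 150L), pSub = 0.17,
                                 background = "uniform", seed = 1L,
                                 prefix = "FAM", consensus = NULL) {
  if (!is.null(consensus)) domainLen <- nchar(consensus)
  if (domainLen < 10L) stop("domainLen must be >= 10")
  if (pSub < 0 || pSub >= 0.5) stop("pSub must lie in [0, 0.5)")
  if (n < 1L) stop("n must be >= 1")
  bg <- .asBackground(background)
  withSeed(seed, {
    consensus <- if (is.null(consensus))
      sample(AA_ALPHABET, domainLen, replace = TRUE, prob = bg)
    else .splitRow(consensus)
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    left <- sample(seq.int(flankLenRange[1L], flankLenRange[2L]), n, replace = TRUE)
    right <- sample(seq.int(flankLenRange[1L], flankLenRange[2L]), n, replace = TRUE)
    doms <- lapply(seq_len(n), function(i) {
      sub <- stats::runif(domainLen) < pSub
      d <- consensus
      d[sub] <- sample(AA_ALPHABET, sum(sub), replace = TRUE, prob = bg)
      d
    })
    seqs <- vapply(seq_len(n), function(i) {
      paste(c(sample(AA_ALPHABET, left[i], replace = TRUE, prob = bg), doms[[i]],
              sample(AA_ALPHABET, right[i], replace = TRUE, prob = bg)),
            collapse = "")
    }, character(1))
    names(seqs) <- ids
    maxL <- max(left); maxR <- max(right)
    rows <- vapply(seq_len(n), function(i) {
      s <- .splitRow(seqs[i])
      paste(c(rep("-", maxL - left[i]), s[seq_len(left[i])],
              doms[[i]],
              s[left[i] + domainLen + seq_len(right[i])],
              rep("-", maxR - right[i])), collapse = "")
    }, character(1))
    list(sequences = seqs,
         alignment = ProteinMSA(ids, rows),
         domain_coords = data.frame(id = ids, start = left + 1L,
                                    end = left + domainLen),
         domain_cols = c(maxL + 1L, maxL + domainLen),
         consensus = paste(consensus, collapse = ""),
         params = list(n = n, domainLen = domainLen,
                       flankLenRange = flankLenRange, pSub = pSub, seed = seed))
  })
}

#' Simulate a VAD1-like reference homolog family
#'
#' An ungapped family of equal-length proteins evolved i.i.d. from one
#' consensus, with designated conserved blocks substituted at a low rate and
#' the remaining positions at a high background rate. This emulates a
#' seed-family alignment carrying a strongly conserved putative
#' lipid-binding (GRAM-like) block and a larger strongly conserved domain
#' block within otherwise weakly conserved sequence; since the family is
#' ungapped, alignment columns coincide with reference residue positions.
#'
#' @param n family size (default 14).
#' @param length protein length (default 550).
#' @param blocks \code{data.frame} of conserved blocks with columns
#'   \code{start}, \code{end}, \code{p_sub}; defaults to a 67-residue block
#'   at 116-182 and a 193-residue block at 257-449, both at \code{p_sub}
#'   0.17 (expected pairwise identity about 70\%).
#' @param pSubBackground substitution probability outside blocks (default
#'   0.30).
#' @param background background distribution.
#' @param seed RNG seed.
#' @param prefix id prefix (default \code{"HOM"}).
#' @return List with \code{alignment} (ungapped [ProteinMSA-class] whose
#'   first record is the reference), \code{reference_id}, \code{blocks} and
#'   \code{params}.
#' @export
simulateReferenceFamily <- function(n = 14L, length = 550L,
                                    blocks = data.frame(
                                      start = c(116L, 257L),
                                      end = c(182L, 449L),
                                      p_sub = c(0.17, 0.17)),
                                    pSubBackground = 0.30,
                                    background = "uniform", seed = 1L,
                                    prefix = "HOM") {
  bg <- .asBackground(background)
  prate <- rep(pSubBackground, length)
  for (b in seq_len(nrow(blocks))) prate[blocks$start[b]:blocks$end[b]] <- blocks$p_sub[b]
  withSeed(seed, {
    consensus <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    rows <- vapply(seq_len(n), function(i) {
      sub <- stats::runif(length) < prate
      s <- consensus
      s[sub] <- sample(AA_ALPHABET, sum(sub), replace = TRUE, prob = bg)
      paste(s, collapse = "")
    }, character(1))
    list(alignment = ProteinMSA(ids, rows), reference_id = ids[1L],
         blocks = blocks, consensus = paste(consensus, collapse = ""),
         params = list(n = n, length = length, pSubBackground = pSubBackground,
                       seed = seed))
  })
}

#' Default architecture catalogue for census simulations
#'
#' Frequencies are composed so that, among target-containing proteins, the
#' single-copy mass is 0.858, the target-only mass is 0.219 and the
#' GRAM-co-occurrence mass is 0.703 — the architecture spectrum observed for
#' VASt-containing proteins.
#'
#' @return \code{data.frame} with columns \code{architecture} and
#'   \code{frequency} (summing to 1).
#' @export
defaultArchitectureCatalogue <- function() {
  data.frame(
    architecture = c("VASt", "GRAM-VASt", "C2-VASt", "GRAM-VASt-VASt",
                     "VASt-VASt-Pex24p", "C2-VASt-C2-GRAM-VASt"),
    frequency = c(0.219, 0.573, 0.066, 0.100, 0.012, 0.030))
}

#' Simulate a protein set with known domain architectures
#'
#' Draws an architecture for each protein from the catalogue frequencies,
#' lays the domains out N-to-C with random linkers, and returns a truth
#' annotation table in the census TSV dialect.
#'
#' @param catalogue \code{data.frame} with columns \code{architecture} and
#'   \code{frequency} (must sum to 1); see
#'   [defaultArchitectureCatalogue()].
#' @param n number of proteins (>= 1).
#' @param seed RNG seed.
#' @param domainLengths named vector of domain lengths in residues.
#' @param linkerRange \code{c(min, max)} inter-domain linker length.
#' @return List with \code{hits} (truth table: protein_id, domain, start,
#'   end, score), \code{architectures} (named character) and \code{params}.
#' @export
simulateArchitectureSet <- function(catalogue = defaultArchitectureCatalogue(),
                                    n = 452L, seed = 1L,
                                    domainLengths = c(VASt = 190L, GRAM = 70L,
                                                      C2 = 90L, Pex24p = 80L,
                                                      FCH = 60L, PH = 100L),
                                    linkerRange = c(20L, 80L)) {
  if (n < 1L) stop("n must be >= 1")
  if (abs(sum(catalogue$frequency) - 1) > 1e-9)
    stop("catalogue frequencies must sum to 1")
  withSeed(seed, {
    archs <- sample(catalogue$architecture, n, replace = TRUE,
                    prob = catalogue$frequency)
    ids <- sprintf("PROT%04d", seq_len(n))
    rows <- lapply(seq_len(n), function(i) {
      doms <- strsplit(archs[i], "-(?=[A-Za-z])", perl = TRUE)[[1L]]
      pos <- sample(seq.int(linkerRange[1L], linkerRange[2L]), 1L)
      out <- vector("list", length(doms))
      for (k in seq_along(doms)) {
        len <- domainLengths[[doms[k]]]
        if (is.null(len)) stop(sprintf("unknown domain '%s' in catalogue", doms[k]))
        out[[k]] <- data.frame(protein_id = ids[i], domain = doms[k],
                               start = pos, end = pos + len - 1L,
                               score = round(stats::runif(1L, 25, 120), 1L))
        pos <- pos + len + sample(seq.int(linkerRange[1L], linkerRange[2L]), 1L)
      }
      do.call(rbind, out)
    })
    list(hits = do.call(rbind, rows),
         architectures = stats::setNames(archs, ids),
         params = list(n = n, seed = seed))
  })
}

#' Evolve an alignment along a tree (Jukes-Cantor-like on 20 letters)
#'
#' The root sequence is drawn from the background; along each branch of
#' length \eqn{t} every site substitutes independently with probability
#' \eqn{1 - e^{-rate \cdot t}}, the replacement drawn from the background.
#'
#' @param tree an \code{ape::phylo} with non-negative branch lengths.
#' @param length sequence length (default 125).
#' @param rate substitution rate per unit branch length (default 1).
#' @param seed RNG seed.
#' @param background background distribution.
#' @return Ungapped [ProteinMSA-class] with one row per leaf.
#' @export
evolveOnTree <- function(tree, length = 125L, rate = 1, seed = 1L,
                         background = "uniform") {
  if (!inherits(tree, "phylo")) stop("tree must be an ape::phylo")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  bg <- .asBackground(background)
  withSeed(seed, {
    nTips <- ape::Ntip(tree)
    root <- nTips + 1L
    seqs <- vector("list", nTips + tree$Nnode)
    seqs[[root]] <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
      p <- 1 - exp(-rate * ord$edge.length[e])
      s <- seqs[[from]]
      sub <- stats::runif(length) < p
      s[sub] <- sample(AA_ALPHABET, sum(sub), replace = TRUE, prob = bg)
      seqs[[to]] <- s
    }
    rows <- vapply(seq_len(nTips), function(i) paste(seqs[[i]], collapse = ""),
                   character(1))
    ProteinMSA(tree$tip.label, rows)
  })
}

#' Additive (path-length) distance matrix of a tree
#'
#' @param tree an \code{ape::phylo} with positive branch lengths and unique
#'   leaf labels.
#' @return Labeled symmetric matrix of leaf-to-leaf path lengths.
#' @export
additiveMatrix <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Simulate clustered C-alpha structures
#'
#' Per group, a smooth base trace is generated as a random walk with fixed
#' 3.8 Angstrom steps and bounded turning angle; each member adds i.i.d.
#' Gaussian noise (sd \code{sigma} per coordinate) to the base trace and is
#' then subjected to a random rigid motion. All structures share one random
#' residue sequence so that the accompanying trivial MSA pairs every
#' residue.
#'
#' @param nPerGroup structures per group (default 8).
#' @param nGroups number of groups (default 2).
#' @param sigma per-coordinate Gaussian noise in Angstrom (default 0.5).
#' @param nRes residues per structure (default 150).
#' @param maxTurn maximum turning angle between consecutive steps, radians.
#' @param seed RNG seed.
#' @return List with \code{structures} (list of [StructureModel-class]),
#'   \code{groups} (named group index), \code{msa} (trivial alignment) and
#'   \code{params}.
#' @export
simulateStructures <- function(nPerGroup = 8L, nGroups = 2L, sigma = 0.5,
                               nRes = 150L, maxTurn = 1.0, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  withSeed(seed, {
    seqChars <- sample(AA_ALPHABET, nRes, replace = TRUE)
    structures <- list()
    groups <- integer(0)
    for (g in seq_len(nGroups)) {
      base <- .randomTrace(nRes, maxTurn)
      for (m in seq_len(nPerGroup)) {
        id <- sprintf("G%dS%02d", g, m)
        x <- base + matrix(stats::rnorm(nRes * 3L, sd = sigma), nRes, 3L)
        R <- .randomRotation()
        x <- x %*% R + matrix(stats::runif(3L, -50, 50), nRes, 3L, byrow = TRUE)
        structures[[id]] <- new("StructureModel", id = id, residues = seqChars,
                                resno = seq_len(nRes), coords = x)
        groups[id] <- g
      }
    }
    seqStr <- paste(seqChars, collapse = "")
    msa <- ProteinMSA(names(structures), rep(seqStr, length(structures)))
    list(structures = unname(structures), groups = groups, msa = msa,
         params = list(nPerGroup = nPerGroup, nGroups = nGroups, sigma = sigma,
                       nRes = nRes, seed = seed))
  })
}

# smooth C-alpha-like random walk: 3.8 A steps, bounded turning angle
.randomTrace <- function(nRes, maxTurn) {
  step <- 3.8
  x <- matrix(0, nRes, 3L)
  dir <- .randomUnit()
  for (i in 2L:nRes) {
    # perturb the direction within maxTurn and renormalize
    repeat {
      nd <- dir + .randomUnit() * tan(stats::runif(1L, 0, maxTurn / 2))
      nd <- nd / sqrt(sum(nd^2))
      if (sum(nd * dir) >= cos(maxTurn)) break
    }
    dir <- nd
    x[i, ] <- x[i - 1L, ] + step * dir
  }
  x
}

.randomUnit <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

.randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
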