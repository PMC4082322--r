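test_that("C-alpha PDB reading extracts exact coordinates", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.100   2.200   3.300  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.400   5.500   6.600  1.00  0.00           C",
    "ATOM      4  CA  TRP A   3       7.700   8.800   9.900  1.00  0.00           C",
    "END"), p)
  m <- readCalpha(p)
  expect_identical(m@residues, c("A", "G", "W"))
  expect_equal(m@coords,
               matrix(c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6, 7.7, 8.8, 9.9),
                      3, 3, byrow = TRUE), tolerance = 1e-9)

  hetonly <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), hetonly)
  expect_error(readCalpha(hetonly), "C-alpha")
})

test_that("C-alpha writer/reader round-trips to PDB precision", {
  st <- simulateStructures(nPerGroup = 1, nGroups = 1, sigma = 0.3,
                           nRes = 40, seed = 6)$structures[[1]]
  p <- tempfile(fileext = ".pdb")
  writeCalpha(st, p)
  back <- readCalpha(p)
  expect_equal(back@coords, st@coords, tolerance = 1e-3)
  expect_identical(back@residues, st@residues)
})

test_that("paired coordinates follow the MSA and ignore record order", {
  st <- simulateStructures(nPerGroup = 2, nGroups = 1, sigma = 0.2,
                           nRes = 30, seed = 7)
  a <- st$structures[[1]]; b <- st$structures[[2]]
  pc <- pairedCoordinates(st$msa, a, b)
  expect_equal(pc$n_aligned, 30)

  # alignment with 2 gap columns in one row drops those pairs
  rows <- alignedRows(st$msa)[c(a@id, b@id)]
  seqchars <- strsplit(rows[[1]], "")[[1]]
  rowA <- paste(c(seqchars, "-", "-"), collapse = "")
  rowB <- paste(c("-", "-", strsplit(rows[[2]], "")[[1]]), collapse = "")
  # structure A misses last two residues, B misses first two
  msa2 <- ProteinMSA(c(a@id, b@id), c(rowA, rowB))
  a2 <- methods::new("StructureModel", id = a@id, residues = a@residues,
                     resno = a@resno, coords = a@coords)
  pc2 <- pairedCoordinates(msa2, a2, b)
  expect_equal(pc2$n_aligned, 28)

  # record order in the MSA does not matter
  msaR <- ProteinMSA(c(b@id, a@id), c(rows[[2]], rows[[1]]))
  pcR <- pairedCoordinates(msaR, a, b)
  expect_equal(pcR$Xa, pc$Xa)

  bad <- ProteinMSA(c(a@id, b@id),
                    c(sub("^.", if (substr(rows[[1]], 1, 1) == "A") "C" else "A",
                          rows[[1]]), rows[[2]]))
  expect_error(pairedCoordinates(bad, a, b), "mismatch")
})

test_that("Kabsch superposition is exact under rigid motions and symmetric", {
  set.seed(61)
  X <- matrix(rnorm(60), 20, 3)
  R <- randomRotationMatrix()
  Y <- X %*% R + matrix(c(5, -3, 8), 20, 3, byrow = TRUE)
  k <- kabschSuperpose(X, Y)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_equal(X %*% k$rotation + matrix(k$translation, 20, 3, byrow = TRUE),
               Y, tolerance = 1e-9)

  for (i in 1:10) {
    A <- matrix(rnorm(36), 12, 3)
    B <- matrix(rnorm(36), 12, 3)
    expect_equal(kabschSuperpose(A, B)$rmsd, kabschSuperpose(B, A)$rmsd,
                 tolerance = 1e-9)
  }
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("Kabsch RMSD matches a brute-force rotational minimization", {
  # unit square in a plane; one vertex displaced 1 A along z
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  Y <- X; Y[3, 3] <- 1
  got <- kabschSuperpose(X, Y)$rmsd
  cx <- sweep(X, 2, colMeans(X)); cy <- sweep(Y, 2, colMeans(Y))
  obj <- function(ang) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3)
    Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3)
    R <- Rz(ang[1]) %*% Ry(ang[2]) %*% Rx(ang[3])
    sqrt(mean(rowSums((cx %*% R - cy)^2)))
  }
  best <- Inf
  set.seed(67)
  for (s in 1:30) {
    fit <- stats::optim(runif(3, -pi, pi), obj)
    best <- min(best, fit$value)
  }
  expect_equal(got, best, tolerance = 1e-4)
  expect_lte(got, best + 1e-8)
})

test_that("normalized structural distance is the stated arithmetic", {
  expect_equal(normalizedStructuralDistance(2.5, 125), 2)
  expect_equal(normalizedStructuralDistance(0, 17), 0)
  expect_equal(normalizedStructuralDistance(3, 50),
               2 * normalizedStructuralDistance(3, 100))
  expect_error(normalizedStructuralDistance(1, 0), "nAligned")
})

test_that("structural distances vanish for rigid copies and respect clusters", {
  st <- simulateStructures(nPerGroup = 1, nGroups = 1, sigma = 0,
                           nRes = 50, seed = 8)
  base <- st$structures[[1]]
  copies <- lapply(1:3, function(i) {
    set.seed(80 + i)
    R <- randomRotationMatrix()
    methods::new("StructureModel", id = sprintf("copy%d", i),
                 residues = base@residues, resno = base@resno,
                 coords = base@coords %*% R +
                   matrix(runif(3, -20, 20), 50, 3, byrow = TRUE))
  })
  msa <- ProteinMSA(sprintf("copy%d", 1:3),
                    rep(paste(base@residues, collapse = ""), 3))
  sd0 <- structuralDistanceMatrix(copies, msa)
  expect_true(all(abs(sd0$distance) < 1e-9))

  st2 <- simulateStructures(nPerGroup = 4, nGroups = 2, sigma = 0.5, seed = 9)
  sd2 <- structuralDistanceMatrix(st2$structures, st2$msa)
  g <- st2$groups
  within <- sd2$distance[g == 1, g == 1]
  between <- sd2$distance[g == 1, g == 2]
  expect_lt(max(within[upper.tri(within)]), min(between))

  # rigid-motion invariance of the whole matrix
  moved <- st2$structures
  set.seed(10)
  R <- randomRotationMatrix()
  moved[[1]] <- methods::new("StructureModel", id = moved[[1]]@id,
                             residues = moved[[1]]@residues,
                             resno = moved[[1]]@resno,
                             coords = moved[[1]]@coords %*% R +
                               matrix(runif(3, -9, 9),
                                      nrow(moved[[1]]@coords), 3, byrow = TRUE))
  sd3 <- structuralDistanceMatrix(moved, st2$msa)
  expect_equal(sd3$distance, sd2$distance, tolerance = 1e-6)
})

test_that("Fitch-Margoliash fits additive matrices exactly", {
  dm <- additiveMatrix(ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);"))
  fm <- fitchMargoliashTree(dm, power = 2)
  expect_lt(fm$error, 1e-10)
  expect_equal(additiveMatrix(fm$tree)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-6)
  set.seed(71)
  for (n in 4:7) {
    t0 <- ape::rtree(n, br = function(k) runif(k, 0.3, 2))
    d0 <- additiveMatrix(t0)
    f0 <- fitchMargoliashTree(d0)
    expect_lt(f0$error, 1e-10)
    expect_equal(additiveMatrix(f0$tree)[rownames(d0), colnames(d0)], d0,
                 tolerance = 1e-5)
  }
})

test_that("Fitch-Margoliash matches the exhaustive 5-topology optimum", {
  set.seed(73)
  for (rep in 1:3) {
    t0 <- ape::rtree(5, br = function(k) runif(k, 0.5, 2))
    d0 <- additiveMatrix(t0)
    noise <- matrix(runif(25, -0.1, 0.1), 5)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d0 <- pmax(d0 + noise, 0.05)
    d0 <- (d0 + t(d0)) / 2; diag(d0) <- 0
    dimnames(d0) <- list(as.character(1:5), as.character(1:5))
    fm <- fitchMargoliashTree(d0, power = 2)
    best <- oracleFmBestE(d0, power = 2)
    expect_lte(fm$error, best + 1e-6)
  }
})

test_that("power zero reduces to unweighted least squares (3-taxon closed form)", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fm <- fitchMargoliashTree(d3, power = 0)
  # three equations, three unknowns: exact fit regardless of weights
  expect_lt(fm$error, 1e-12)
  el <- fm$tree$edge.length
  expect_equal(sort(el), sort(c(1, 2, 3)), tolerance = 1e-6)
})

test_that("zero distances are replaced with a warning", {
  d <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_warning(fm <- fitchMargoliashTree(d), "zero")
  expect_s3_class(fm$tree, "phylo")
})
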