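test_that("profile build maps columns to states and preserves count order", {
  seed5 <- ProteinMSA(sprintf("s%d", 1:5), rep("ACDEF", 5))
  hmm <- buildProfile(seed5, "laplace", "none")
  expect_identical(hmm@M, 5L)
  cons <- strsplit("ACDEF", "")[[1]]
  for (k in 1:5)
    expect_identical(AA_ALPHABET[which.max(hmm@matchEmissions[k, ])], cons[k])

  seed3 <- ProteinMSA(c("a", "b", "c"), c("AC", "AC", "AG"))
  for (pc in c("laplace", "BLOSUM62", "BLOSUM90")) {
    h <- buildProfile(seed3, pc, "none")
    e <- h@matchEmissions[2, ]
    expect_gt(e[["C"]], e[["G"]])
    expect_gt(e[["G"]], max(e[setdiff(AA_ALPHABET, c("C", "G"))]))
  }

  # 193-column ungapped seed gives a 193-state model
  fam <- simulateDomainFamily(n = 6, domainLen = 193, seed = 12)
  dc <- fam$domain_cols
  h193 <- buildProfile(msaColumns(fam$alignment, dc[1]:dc[2]), "BLOSUM90")
  expect_identical(h193@M, 193L)

  # normalization invariants (also enforced by class validity)
  expect_equal(unname(rowSums(h193@matchEmissions)), rep(1, 193))
  s <- h193@transitions[, "MM"] + h193@transitions[, "MI"] +
    h193@transitions[, "MD"] + h193@exit
  expect_equal(unname(s), rep(1, 193))
  expect_error(buildProfile(ProteinMSA("one", "ACD")), "seed")
})

test_that("columns with >50% gaps become insert columns", {
  seed <- ProteinMSA(c("a", "b", "c", "d"),
                     c("AC-E", "AC-E", "ACDE", "AC-E"))
  hmm <- buildProfile(seed, "laplace", "none")
  expect_identical(hmm@M, 3L)
  expect_identical(hmm@metadata$matchColumns, c(1L, 2L, 4L))
})

test_that("relative entropy logo matches the closed forms and direct sums", {
  bg <- rep(1 / 20, 20)
  # emission equal to background -> zero bits
  hmm0 <- makeToyHmm(matrix(bg, 2, 20, byrow = TRUE))
  logo0 <- relativeEntropyLogo(hmm0)
  expect_equal(logo0$positions$relative_entropy, c(0, 0), tolerance = 1e-12)
  # concentrated emission vs uniform background -> log2(20)
  e <- matrix(1e-12, 2, 20); e[, 1] <- 1 - 19e-12
  e <- e / rowSums(e)
  logo1 <- relativeEntropyLogo(makeToyHmm(e))
  expect_equal(logo1$positions$relative_entropy[1], log2(20), tolerance = 1e-6)
  # random emissions vs brute-force summation
  hmm <- makeRandomHmm(4, seed = 99)
  logo <- relativeEntropyLogo(hmm)
  for (k in 1:4) {
    direct <- sum(hmm@matchEmissions[k, ] *
                    log2(hmm@matchEmissions[k, ] / hmm@background))
    expect_equal(logo$positions$relative_entropy[k], direct, tolerance = 1e-12)
    expect_equal(sum(logo$heights[k, ]), direct, tolerance = 1e-9)
  }
  expect_true(all(logo$positions$relative_entropy >= 0))
})

test_that("Viterbi recovers a forced consensus path and planted envelopes", {
  cons <- paste(sample(AA_ALPHABET, 20, replace = TRUE), collapse = "")
  hmm <- makeSharpHmm(cons)
  v <- viterbiScore(hmm, cons)
  expect_equal(v$envelope, c(1, 20))
  expect_equal(v$matchpos, 1:20)

  set.seed(17)
  okEnv <- 0
  for (r in 1:20) {
    cons <- paste(sample(AA_ALPHABET, 20, replace = TRUE), collapse = "")
    hmm <- makeSharpHmm(cons)
    seq <- paste0(randomSeq(50), cons, randomSeq(50))
    env <- viterbiScore(hmm, seq)$envelope
    if (abs(env[1] - 51) <= 2 && abs(env[2] - 70) <= 2) okEnv <- okEnv + 1
  }
  expect_gte(okEnv, 19)
  expect_error(viterbiScore(hmm, ""), "empty sequence")
})

test_that("forward dominates Viterbi and equals the exhaustive path sum", {
  # one-path degenerate case: forward == viterbi
  e <- matrix(1e-12, 1, 20); e[1, 3] <- 1 - 19e-12; e <- e / rowSums(e)
  h1 <- makeToyHmm(e)
  expect_equal(forwardScore(h1, "D"), viterbiScore(h1, "D")$bits,
               tolerance = 1e-6)

  for (s in 1:6) {
    hmm <- makeRandomHmm(sample(2:5, 1), seed = 300 + s)
    seq <- randomSeq(sample(4:8, 1))
    expect_equal(forwardScore(hmm, seq), oracleForwardBits(hmm, seq),
                 tolerance = 1e-8)
  }

  set.seed(23)
  for (s in 1:40) {
    hmm <- makeRandomHmm(sample(2:6, 1), seed = 500 + s)
    seq <- randomSeq(sample(3:12, 1))
    expect_gte(forwardScore(hmm, seq) + 1e-9, viterbiScore(hmm, seq)$bits)
  }
})

test_that("Gumbel calibration yields the closed-form E-value family", {
  fam <- simulateDomainFamily(n = 8, domainLen = 40, seed = 3)
  hmm <- buildProfile(msaColumns(fam$alignment, fam$domain_cols[1]:fam$domain_cols[2]),
                      "BLOSUM62")
  cal <- calibrateEvalues(hmm, nDecoys = 60, decoyLen = 120, seed = 2)
  expect_equal(evalueFromScore(cal, cal@mu, 1), 1 - exp(-1), tolerance = 1e-12)
  # strictly decreasing wherever the double-precision tail is not saturated
  ss <- seq(cal@mu - 1, cal@mu + 15, by = 0.5)
  ev <- evalueFromScore(cal, ss, 100)
  expect_true(all(diff(ev) < 0))
  expect_error(calibrateEvalues(hmm, nDecoys = 10), "nDecoys")
  # same decoy seed reproduces the fit exactly
  cal2 <- calibrateEvalues(hmm, nDecoys = 60, decoyLen = 120, seed = 2)
  expect_identical(cal@lambda, cal2@lambda)

  # degenerate decoy scores are refused
  flat <- makeToyHmm(matrix(1 / 20, 1, 20))
  expect_error(calibrateEvalues(flat, nDecoys = 50, decoyLen = 30, seed = 1),
               "degenerate")
})

test_that("Gumbel ML fit recovers known parameters within 15%", {
  set.seed(41)
  u <- runif(2000)
  x <- 10 - log(-log(u)) / 0.7  # Gumbel(lambda = 0.7, mu = 10)
  fit <- DomainScout:::.gumbelML(x)
  expect_lt(abs(fit$lambda - 0.7) / 0.7, 0.15)
  expect_lt(abs(fit$mu - 10), 0.5)
})

test_that("database search filters, sorts and nests by cutoff", {
  fam <- simulateDomainFamily(n = 10, seed = 51)
  seedMsa <- msaColumns(fam$alignment, fam$domain_cols[1]:fam$domain_cols[2])
  hmm <- buildProfile(seedMsa, "BLOSUM90")
  cal <- calibrateEvalues(hmm, nDecoys = 60, decoyLen = 350, seed = 5)

  expect_identical(nrow(searchProfile(hmm, character(0), cal)), 0L)
  expect_error(searchProfile(hmm, character(0), cal, evalueCutoff = 0),
               "evalueCutoff")

  planted <- simulateDomainFamily(n = 10, seed = 52, prefix = "TGT",
                                  consensus = fam$consensus)
  set.seed(6)
  bg <- stats::setNames(replicate(30, randomSeq(300)), sprintf("BG%02d", 1:30))
  db <- c(planted$sequences, bg)
  hits <- searchProfile(hmm, db, cal, 1e-10)
  expect_setequal(hits$target_id, names(planted$sequences))
  expect_true(all(diff(hits$evalue) >= 0))

  strict <- searchProfile(hmm, db, cal, 1e-100)
  expect_true(all(strict$target_id %in% hits$target_id))

  # database order changes no score and no hit membership
  perm <- sample(length(db))
  hits2 <- searchProfile(hmm, db[perm], cal, 1e-10)
  expect_setequal(hits2$target_id, hits$target_id)
  expect_equal(hits2$bit_score[order(hits2$target_id)],
               hits$bit_score[order(hits$target_id)])
})

test_that("iterative search converges on a fixed point and never sheds hits", {
  fam <- simulateDomainFamily(n = 8, seed = 61, flankLenRange = c(0, 0))
  seedMsa <- fam$alignment  # ungapped: the domain itself
  db <- alignedRows(seedMsa)
  res <- iterativeSearch(seedMsa, db, nDecoys = 60, calibrationSeed = 3)
  expect_identical(res$iterations, 1L)
  expect_true(res$converged)
  expect_setequal(res$hits[[1]]$target_id, seqIds(seedMsa))

  expect_error(iterativeSearch(seedMsa, character(0)), "empty")
})

test_that("iterative search reaches chained remote homologs through intermediates", {
  gains <- t(vapply(1:6, function(s) {
    fam <- simulateDomainFamily(n = 8, domainLen = 60, seed = s)
    seedMsa <- msaColumns(fam$alignment, fam$domain_cols[1]:fam$domain_cols[2])
    close <- simulateDomainFamily(n = 10, seed = s + 1000, pSub = 0.05,
                                  prefix = "CLO", consensus = fam$consensus)
    midc <- simulateDomainFamily(n = 1, seed = s + 1500, pSub = 0.30,
                                 prefix = "MIDC", consensus = fam$consensus)
    midcons <- substr(midc$sequences[[1]], midc$domain_coords$start[1],
                      midc$domain_coords$end[1])
    mid <- simulateDomainFamily(n = 10, seed = s + 1600, pSub = 0.10,
                                prefix = "MID", consensus = midcons)
    remc <- simulateDomainFamily(n = 1, seed = s + 1700, pSub = 0.30,
                                 prefix = "REMC", consensus = midcons)
    remcons <- substr(remc$sequences[[1]], remc$domain_coords$start[1],
                      remc$domain_coords$end[1])
    remote <- simulateDomainFamily(n = 10, seed = s + 1800, pSub = 0.10,
                                   prefix = "REM", consensus = remcons)
    bg <- local({
      set.seed(s + 3000)
      stats::setNames(replicate(30, randomSeq(300)), sprintf("BG%02d", 1:30))
    })
    db <- c(close$sequences, mid$sequences, remote$sequences, bg)
    res <- iterativeSearch(seedMsa, db, nDecoys = 100, calibrationSeed = s,
                           maxIter = 3)
    first <- res$hits[[1]]$target_id
    final <- res$hits[[length(res$hits)]]$target_id
    # cumulative hit lists are monotone non-shrinking
    for (i in seq_along(res$hits)[-1])
      expect_true(all(res$hits[[i - 1]]$target_id %in% res$hits[[i]]$target_id))
    c(rem1 = sum(grepl("^REM", first)), remF = sum(grepl("^REM", final)),
      bgF = sum(grepl("^BG", final)))
  }, numeric(3)))
  # iteration extends reach into the remote tier without background leakage
  expect_gt(sum(gains[, "remF"]), sum(gains[, "rem1"]))
  expect_equal(sum(gains[, "bgF"]), 0)
})

test_that("profile HMM text serialization round-trips", {
  fam <- simulateDomainFamily(n = 6, domainLen = 35, seed = 71)
  hmm <- buildProfile(msaColumns(fam$alignment, fam$domain_cols[1]:fam$domain_cols[2]),
                      "BLOSUM90")
  path <- tempfile(fileext = ".hmm")
  writeProfileHmm(hmm, path)
  back <- readProfileHmm(path)
  expect_identical(back@M, hmm@M)
  expect_equal(back@matchEmissions, hmm@matchEmissions, tolerance = 1e-9)
  expect_equal(back@transitions, hmm@transitions, tolerance = 1e-9)
  expect_equal(back@exit, hmm@exit, tolerance = 1e-9)
  s <- randomSeq(60)
  expect_equal(viterbiScore(back, s)$bits, viterbiScore(hmm, s)$bits,
               tolerance = 1e-6)
})
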