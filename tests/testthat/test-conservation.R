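test_that("column conservation matches direct property enumeration", {
  expect_identical(columnConservation(c("V", "V", "V")), 10L)
  expect_identical(columnConservation(c("K", "R")), oracleColumnScore(c("K", "R")))
  expect_identical(columnConservation(c("K", "-")), oracleColumnScore(c("K", "-")))
  # only properties absent from K can be uniform in a K/gap column
  expect_identical(columnConservation(c("K", "-")),
                   sum(vapply(ORACLE_PROPERTIES, function(p) !("K" %in% p), logical(1))))
  set.seed(42)
  for (i in 1:200) {
    col <- sample(c(AA_ALPHABET, "-", "X"), sample(2:12, 1), replace = TRUE)
    expect_identical(columnConservation(col), oracleColumnScore(col))
  }
})

test_that("column conservation score bounds and identity maximum hold", {
  set.seed(7)
  for (i in 1:100) {
    col <- sample(c(AA_ALPHABET, "-", "X"), sample(2:10, 1), replace = TRUE)
    s <- columnConservation(col)
    expect_gte(s, 0L); expect_lte(s, 10L)
  }
  # identical residue columns always score 10
  for (a in AA_ALPHABET) expect_identical(columnConservation(rep(a, 5)), 10L)
  # columns of residues differing in at least one property score < 10;
  # residue pairs with identical property vectors (e.g. I/L) score 10
  for (i in 1:100) {
    pair <- sample(AA_ALPHABET, 2)
    s <- columnConservation(pair)
    if (samePropertyVector(pair[1], pair[2])) expect_identical(s, 10L)
    else expect_lt(s, 10L)
  }
})

test_that("column conservation rejects bad input", {
  expect_error(columnConservation(character(0)), "empty column")
  expect_error(columnConservation(c("A", "B")), "'B'")
})

test_that("conservation profile scores every column", {
  p1 <- conservationProfile(ProteinMSA("s", "VAST"))
  expect_equal(rawScores(p1), rep(10, 4))
  expect_equal(smoothedScores(p1), rep(10, 4))
  p2 <- conservationProfile(ProteinMSA(c("a", "b"), c("AA", "AG")))
  expect_equal(rawScores(p2), c(10, oracleColumnScore(c("A", "G"))))
  p3 <- conservationProfile(ProteinMSA(c("a", "b", "c"),
                                       rep(strrep("W", 50), 3)))
  expect_equal(rawScores(p3), rep(10, 50))
})

test_that("smoothing is a centered edge-truncated moving average", {
  mk <- function(raw) methods::new("ConservationProfile", raw = raw,
                                   smoothed = raw, window = 1L, step = 1L)
  expect_equal(smoothedScores(smoothProfile(mk(c(10, 10, 10, 10)), 1)),
               c(10, 10, 10, 10))
  expect_equal(smoothedScores(smoothProfile(mk(c(0, 10, 0)), 3)),
               c(5, 10 / 3, 5))
  expect_equal(smoothedScores(smoothProfile(mk(rep(7, 30)), 10)), rep(7, 30))
  expect_error(smoothProfile(mk(c(1, 2)), 0), "window")
  # contraction: smoothed stays within the raw range
  set.seed(3)
  for (w in c(2, 5, 10)) {
    raw <- round(runif(40, 0, 10), 2)
    sm <- smoothedScores(smoothProfile(mk(raw), w))
    expect_length(sm, 40)
    expect_true(all(sm >= min(raw) - 1e-12 & sm <= max(raw) + 1e-12))
  }
})

test_that("domain delimitation extracts, merges and anchors runs", {
  mk <- function(sm) methods::new("ConservationProfile",
                                  raw = pmin(pmax(sm, 0), 10), smoothed = sm,
                                  window = 1L, step = 1L)
  msa7 <- ProteinMSA("ref", strrep("A", 7))
  segs <- delimitDomains(mk(c(0, 0, 5, 5, 5, 0, 0)), msa7, "ref",
                         threshold = 4, minLen = 1, mergeGap = 0)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start_col, segs$end_col), c(3, 5))
  expect_equal(c(segs$start_res, segs$end_res, segs$length_res), c(3, 5, 3))

  msa5 <- ProteinMSA("ref", strrep("A", 5))
  merged <- delimitDomains(mk(c(5, 5, 0, 5, 5)), msa5, "ref",
                           threshold = 4, minLen = 1, mergeGap = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start_col, merged$end_col), c(1, 5))
  split <- delimitDomains(mk(c(5, 5, 0, 5, 5)), msa5, "ref",
                          threshold = 4, minLen = 1, mergeGap = 0)
  expect_equal(nrow(split), 2)
  expect_equal(split$start_col, c(1, 4))

  # a well-conserved anchor residue near the boundary extends the segment
  msa10 <- ProteinMSA("ref", strrep("A", 10))
  anch <- delimitDomains(mk(c(0, 0, 0, 5, 5, 5, 0, 0, 0, 0)), msa10, "ref",
                         threshold = 4, minLen = 1, mergeGap = 2,
                         anchors = c(2))
  expect_equal(anch$start_col, 2)
  expect_error(delimitDomains(mk(rep(5, 10)), msa10, "nope", threshold = 4),
               "unknown reference")
  expect_error(delimitDomains(mk(rep(5, 10)), msa10, "ref", anchors = 99),
               "anchor")
})

test_that("delimited segments are disjoint, sorted and above threshold inside", {
  set.seed(11)
  for (rep in 1:10) {
    raw <- round(runif(120, 0, 10), 1)
    prof <- smoothProfile(methods::new("ConservationProfile", raw = raw,
                                       smoothed = raw, window = 1L, step = 1L), 10)
    msa <- ProteinMSA("ref", strrep("C", 120))
    segs <- delimitDomains(prof, msa, "ref", threshold = 4, minLen = 5,
                           mergeGap = 3)
    if (nrow(segs) > 1) {
      expect_true(all(diff(segs$start_col) > 0))
      expect_true(all(segs$start_col[-1] > segs$end_col[-nrow(segs)]))
    }
  }
})

test_that("reference coordinates count only non-gap reference characters", {
  msa <- ProteinMSA(c("ref", "o"), c("--AC-DEF--", "AAACADEFAA"))
  prof <- methods::new("ConservationProfile",
                       raw = rep(0, 10),
                       smoothed = c(0, 0, 5, 5, 5, 5, 5, 5, 0, 0),
                       window = 1L, step = 1L)
  segs <- delimitDomains(prof, msa, "ref", threshold = 4, minLen = 1,
                         mergeGap = 0)
  expect_equal(c(segs$start_col, segs$end_col), c(3, 8))
  # reference residues within cols 3..8: A C D E F -> positions 1..5
  expect_equal(c(segs$start_res, segs$end_res, segs$length_res), c(1, 5, 5))
})

test_that("pairwise identity statistics follow the both-non-gap convention", {
  expect_equal(meanPairwiseIdentity(ProteinMSA(c("a", "b"), c("AAAA", "AAAA"))), 100)
  expect_equal(meanPairwiseIdentity(ProteinMSA(c("a", "b"), c("AAAA", "AAAT"))), 75)
  expect_equal(meanPairwiseIdentity(ProteinMSA(c("a", "b"), c("AA--", "AAAA"))), 100)
  expect_error(meanPairwiseIdentity(ProteinMSA("a", "AAAA")), "2 records")

  expect_equal(minIdentityToReference(
    ProteinMSA(c("r", "a", "b"), c("CCCC", "CCCC", "CCCC")), "r"), 100)
  expect_equal(minIdentityToReference(
    ProteinMSA(c("r", "a", "b"), c("AAAA", "AAAT", "TTTT")), "r"), 0)
  expect_error(minIdentityToReference(
    ProteinMSA(c("r", "a"), c("AAAA", "AAAT")), "zz"), "unknown reference")
})

test_that("mean pairwise identity equals the brute-force loop and is order-invariant", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:8, 1); L <- sample(10:50, 1)
    rows <- replicate(n, paste(sample(c(AA_ALPHABET, "-"), L, replace = TRUE,
                                      prob = c(rep(1, 20), 4)), collapse = ""))
    # ensure comparable positions exist
    rows <- vapply(rows, function(r) { substr(r, 1, 3) <- "ACD"; r }, character(1))
    msa <- ProteinMSA(sprintf("s%d", 1:n), rows)
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- oraclePairIdentity(rows[i], rows[j])
      if (!is.na(v)) vals <- c(vals, v)
    }
    expect_equal(meanPairwiseIdentity(msa), mean(vals))
    perm <- sample(n)
    expect_equal(meanPairwiseIdentity(ProteinMSA(sprintf("s%d", 1:n), rows[perm])),
                 meanPairwiseIdentity(msa))
  }
})

test_that("minimum identity of a simulated family sits in the binomial band", {
  fam <- simulateDomainFamily(n = 10, domainLen = 200, pSub = 0.2,
                              flankLenRange = c(0, 0), seed = 31)
  # expected pairwise identity under uniform background, exact form
  p <- 0.2
  eid <- (1 - p)^2 + p * (2 - p) / 20
  sd1 <- sqrt(eid * (1 - eid) / 200)
  minid <- minIdentityToReference(fam$alignment, seqIds(fam$alignment)[1])
  expect_gte(minid, 100 * (eid - 4 * sd1))
  expect_lte(minid, 100 * (eid + 2 * sd1))
})
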