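test_that("read enumeration honours linear and circular topology", {
  set.seed(201)
  s <- Biostrings::DNAStringSet(c(chr = oracle_random_seq(10)))

  lin <- enumerateReads(s, 4, circular = FALSE)
  expect_equal(nrow(lin), 7L)                     # L - k + 1
  expect_equal(lin$start, 1:7)
  expect_false(any(lin$wraps))

  circ <- enumerateReads(s, 4, circular = TRUE)
  expect_equal(nrow(circ), 10L)                   # one per position
  expect_equal(sum(circ$wraps), 3L)
  ext <- paste0(as.character(s[[1L]]), substr(as.character(s[[1L]]), 1, 3))
  expect_identical(circ$sequence, substring(ext, 1:10, 4:13))

  one <- enumerateReads(Biostrings::DNAStringSet(c(x = oracle_random_seq(150))),
                        150, circular = FALSE)
  expect_equal(nrow(one), 1L)

  expect_error(enumerateReads(s, 11, circular = TRUE), "exceeds")
})

test_that("canonicalKmers is strand-symmetric, idempotent, NA on non-ACGT", {
  expect_identical(canonicalKmers(c("AAAA", "TTTT", "ACGT")),
                   c("AAAA", "AAAA", "ACGT"))
  expect_true(is.na(canonicalKmers("ACNT")))
  set.seed(202)
  kmers <- vapply(1:50, function(i) oracle_random_seq(21), character(1))
  canon <- canonicalKmers(kmers)
  expect_identical(canon, canonicalKmers(rc_chr(kmers)))   # rc symmetry
  expect_identical(canon, canonicalKmers(canon))           # idempotent
  expect_true(all(canon <= kmers & canon <= rc_chr(kmers)))
})

test_that("KmerIndex counts loci strand-collapsed and excludes non-ACGT", {
  idx <- buildKmerIndex(Biostrings::DNAStringSet(c(g = "AAAAA")), k = 4,
                        circular = FALSE)
  expect_identical(idx@counts, c(AAAA = 2L))

  idxN <- buildKmerIndex(Biostrings::DNAStringSet(c(g = "ACGTNACGTA")),
                         k = 4, circular = FALSE)
  expect_equal(idxN@excludedLoci, 4L)   # every window covering the N
  expect_equal(sum(idxN@counts) + idxN@excludedLoci, 7L)

  # brute-force oracle on a random genome, both topologies
  set.seed(203)
  s <- oracle_random_seq(600)
  for (circ in c(TRUE, FALSE)) {
    idx <- buildKmerIndex(Biostrings::DNAStringSet(c(g = s)), k = 12,
                          circular = circ)
    wins <- oracle_windows(s, 12, circ)
    rc <- rc_chr(wins)
    expected <- vapply(seq_along(wins), function(i)
      sum(wins == wins[i] | rc == wins[i]), integer(1))
    got <- unname(kmerCount(idx, wins))
    expect_identical(got, expected)
  }
})

test_that("a planted duplicate with controlled flanks loses exactly its internal windows", {
  # unique1 + repeat + unique2 + repeat + unique3, flanks forced to differ
  set.seed(204)
  k <- 150L
  u1 <- oracle_random_seq(2000)
  u2 <- oracle_random_seq(1000)
  u3 <- oracle_random_seq(2000)
  rep300 <- oracle_random_seq(300)
  substr(u1, 2000, 2000) <- "A"; substr(u2, 1000, 1000) <- "C"
  substr(u2, 1, 1) <- "A"; substr(u3, 1, 1) <- "C"
  g <- paste0(u1, rep300, u2, rep300, u3)
  pool <- buildPool(list(org = Biostrings::DNAStringSet(c(chr = g))),
                    readLength = k, circular = FALSE)
  rep <- readLoss(pool)
  expect_equal(rep$ambiguous_intra, 302L)     # 151 internal windows per copy
  expect_equal(rep$ambiguous_inter, 0L)
  expect_equal(rep$total_reads, nchar(g) - k + 1L)
  # cross-check against the all-pairs oracle
  wins <- oracle_windows(g, k, FALSE)
  cls <- oracle_classify(wins, character(0))
  expect_equal(sum(cls == "intra"), 302L)
})

test_that("classification matches the brute-force oracle on a two-organism pool", {
  set.seed(205)
  k <- 30L
  a <- oracle_random_seq(1500)
  a <- oracle_plant_copy(a, 200, 120, 900)        # intra repeat in A
  b <- oracle_random_seq(1200)
  substr(b, 400, 479) <- substr(a, 50, 129)       # shared segment A<->B
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("chrA", "chrB"), k,
                        circular = c(TRUE, TRUE))
  rep <- readLoss(pool)
  winsA <- oracle_windows(a, k, TRUE)
  winsB <- oracle_windows(b, k, TRUE)
  for (org in c("A", "B")) {
    wins <- if (org == "A") winsA else winsB
    other <- if (org == "A") winsB else winsA
    cls <- oracle_classify(wins, other)
    row <- rep[rep$organism == org, ]
    expect_equal(row$ambiguous_intra, sum(cls == "intra"), info = org)
    expect_equal(row$ambiguous_inter, sum(cls == "inter"), info = org)
    expect_equal(row$unique_single,
                 sum(cls %in% c("unique", "inter")), info = org)
  }
})

test_that("reads containing non-ACGT are excluded but conserved in totals", {
  set.seed(206)
  a <- oracle_random_seq(800)
  substr(a, 400, 400) <- "N"
  pool <- buildPool(list(org = Biostrings::DNAStringSet(c(chr = a))),
                    readLength = 25, circular = FALSE)
  rep <- readLoss(pool)
  expect_equal(rep$excluded_reads, 25L)
  expect_equal(rep$unique_single + rep$ambiguous_intra + rep$excluded_reads,
               rep$total_reads)
})

test_that("self-pool identity: inter loss is everything not lost already", {
  set.seed(207)
  a <- oracle_random_seq(1000)
  a <- oracle_plant_copy(a, 100, 80, 700)
  substr(a, 500, 500) <- "N"
  pool <- make_pool_chr(c(a, a), c("one", "two"), c("c1", "c2"), 40,
                        circular = c(TRUE, TRUE))
  rep <- readLoss(pool)
  expect_equal(rep$ambiguous_inter, rep$unique_single)
  expect_equal(rep$inter_loss_pct,
               100 - rep$intra_loss_pct -
                 100 * rep$excluded_reads / rep$total_reads)
})

test_that("reverse-complementing one organism changes no counts", {
  set.seed(208)
  a <- oracle_random_seq(900)
  b <- oracle_random_seq(700)
  substr(b, 100, 159) <- substr(a, 300, 359)
  pool1 <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 35,
                         circular = c(TRUE, TRUE))
  pool2 <- make_pool_chr(c(a, rc_chr(b)), c("A", "B"), c("ca", "cb"), 35,
                         circular = c(TRUE, TRUE))
  r1 <- readLoss(pool1)
  r2 <- readLoss(pool2)
  expect_equal(r1[, -1], r2[, -1])
})

test_that("adding an organism never decreases inter-organism ambiguity", {
  set.seed(209)
  a <- oracle_random_seq(900)
  b <- oracle_random_seq(700)
  c2 <- oracle_random_seq(600)
  substr(c2, 50, 109) <- substr(a, 500, 559)
  p2 <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 30,
                      circular = rep(TRUE, 2))
  p3 <- make_pool_chr(c(a, b, c2), c("A", "B", "C"), c("ca", "cb", "cc"),
                      30, circular = rep(TRUE, 3))
  i2 <- readLoss(p2)
  i3 <- readLoss(p3)
  for (org in c("A", "B")) {
    expect_gte(i3$ambiguous_inter[i3$organism == org],
               i2$ambiguous_inter[i2$organism == org])
  }
  expect_gt(i3$ambiguous_inter[i3$organism == "A"], 0L)
})

test_that("pooled loss decomposition: single-unique minus pooled-unique equals inter", {
  set.seed(210)
  a <- oracle_random_seq(1000)
  b <- oracle_random_seq(800)
  substr(b, 200, 289) <- substr(a, 100, 189)
  single <- make_pool_chr(a, "A", "ca", 30, circular = TRUE)
  pooled <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 30,
                          circular = c(TRUE, TRUE))
  rs <- readLoss(single)
  rp <- readLoss(pooled)[1L, ]
  expect_equal(rs$unique_single, rp$unique_single)   # intra unaffected
  expect_equal(rs$unique_single - rp$unique_pooled, rp$ambiguous_inter)
})

test_that("minMismatchHits agrees with the exhaustive scan", {
  set.seed(211)
  g <- oracle_random_seq(1000)
  seqs <- Biostrings::DNAStringSet(c(chr = g))
  k <- 40L

  # unique substring: one exact locus
  q <- substr(g, 101, 140)
  h <- minMismatchHits(q, seqs, maxMismatch = 1, circular = TRUE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 101L)
  expect_equal(h$mismatches, 0L)

  # one substitution applied: min 1 at the original locus
  qm <- q
  substr(qm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                substr(qm, 20, 20))[1L]
  h <- minMismatchHits(qm, seqs, maxMismatch = 1, circular = TRUE)
  expect_true(any(h$start == 101L & h$mismatches == 1L))

  # 200 random queries (some mutated, some reverse-complemented, some
  # foreign) against the oracle, both topologies
  for (circ in c(TRUE, FALSE)) {
    for (i in 1:100) {
      pos <- sample.int(nchar(g) - k + 1L, 1L)
      q <- substr(g, pos, pos + k - 1L)
      if (i %% 2L == 0L) q <- injectErrors(q, fixed = sample(0:2, 1L))
      if (i %% 3L == 0L) q <- rc_chr(q)
      if (i %% 7L == 0L) q <- oracle_random_seq(k)
      got <- minMismatchHits(q, seqs, maxMismatch = 1, circular = circ)
      exp <- oracle_hits(q, g, k, circ, 1)
      expect_equal(got$start, exp$start)
      expect_equal(got$mismatches, exp$mismatches)
    }
  }
})

test_that("minMismatchHits matches Biostrings matchPattern on a larger genome", {
  set.seed(212)
  g <- oracle_random_seq(20000)
  g <- oracle_plant_copy(g, 1000, 500, 10000)
  seqs <- Biostrings::DNAStringSet(c(chr = g))
  subj <- Biostrings::DNAString(g)
  for (i in 1:20) {
    pos <- sample.int(nchar(g) - 150L, 1L)
    q <- injectErrors(substr(g, pos, pos + 149L), fixed = 1L)
    got <- minMismatchHits(q, seqs, maxMismatch = 1, circular = FALSE)
    fw <- BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString(q), subj, max.mismatch = 1))
    rv <- BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc_chr(q)), subj, max.mismatch = 1))
    expect_setequal(got$start, union(fw, rv))
  }
})

test_that("best-stratum resolution assigns, rejects and unmaps correctly", {
  set.seed(213)
  a <- oracle_random_seq(1200)
  b <- oracle_random_seq(1000)
  substr(b, 300, 379) <- substr(a, 100, 179)   # 80 bp shared block
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 40,
                        circular = c(TRUE, TRUE))

  # error-free read from a unique locus
  r <- substr(a, 600, 639)
  expect_identical(resolveBestStratum(r, pool)$organism, "A")

  # read present identically in both organisms
  shared <- substr(a, 120, 159)
  expect_identical(resolveBestStratum(shared, pool)$status, "ambiguous")

  # read matching nothing within 1 mismatch
  expect_identical(resolveBestStratum(oracle_random_seq(40), pool)$status,
                   "unmapped")

  # any-valid mode disqualifies on any second locus within the allowance
  r1 <- injectErrors(r, fixed = 1, seed = 5)
  bs <- resolveBestStratum(r1, pool, mode = "best-stratum")
  expect_identical(bs$status, "assigned")   # 1-mm own locus is unique best
})

test_that("an error can relocate a read to the organism carrying its neighbour", {
  # organism B contains exactly the 1-substitution neighbour of a unique A
  # read: with that error injected, the read's best match (0 mm) is in B
  set.seed(214)
  a <- oracle_random_seq(1000)
  read <- substr(a, 500, 549)
  mut <- read
  substr(mut, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 25, 25))[1L]
  b <- paste0(oracle_random_seq(400), mut, oracle_random_seq(400))
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 50,
                        circular = c(FALSE, FALSE))
  res <- resolveBestStratum(mut, pool)
  expect_identical(res$status, "assigned")
  expect_identical(res$organism, "B")
  expect_equal(res$mismatches, 0L)
  # cross-check with the oracle
  orc <- oracle_resolve(mut, c(a, b), c("A", "B"), c(FALSE, FALSE), 1)
  expect_identical(orc$organism, "B")
})
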