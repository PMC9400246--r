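make_genes <- function(replicon, starts, ends, ids) {
  GenomicRanges::GRanges(seqnames = replicon,
                         ranges = IRanges::IRanges(starts, ends),
                         strand = "+", gene_id = ids)
}

test_that("genes in repeat-free non-homologous regions lose nothing", {
  set.seed(301)
  a <- oracle_random_seq(2000)
  b <- oracle_random_seq(1500)
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), 40,
                        circular = c(TRUE, TRUE))
  genes <- make_genes("ca", c(101, 901), c(400, 1200), c("g1", "g2"))
  gl <- perGeneLoss(pool, "A", genes)
  expect_equal(gl$reads_ambiguous_intra, c(0L, 0L))
  expect_equal(gl$reads_ambiguous_inter, c(0L, 0L))
  expect_equal(gl$total_loss_pct, c(0, 0))
  # read attribution: >= 1 bp overlap, so (gene length) + k - 1 windows
  expect_equal(gl$reads_total, c(300L, 300L) + 40L - 1L)
})

test_that("a duplicated gene body loses exactly its internal windows", {
  set.seed(302)
  k <- 50L
  a <- oracle_random_seq(3000)
  # duplicate the gene body (unique flanks by construction check below)
  a <- oracle_plant_copy(a, 501, 200, 2101)
  # force the flanking bases to differ so the effective repeat cannot extend
  substr(a, 500, 500) <- "A"; substr(a, 2100, 2100) <- "C"
  substr(a, 701, 701) <- "A"; substr(a, 2301, 2301) <- "C"
  pool <- buildPool(list(A = Biostrings::DNAStringSet(c(ca = a))),
                    readLength = k, circular = FALSE)
  genes <- make_genes("ca", 501, 700, "dup_gene")
  gl <- perGeneLoss(pool, "A", genes)
  # oracle: overlapping windows classified by all-pairs comparison
  wins <- oracle_windows(a, k, FALSE)
  cls <- oracle_classify(wins, character(0))
  ovl <- oracle_gene_starts(501, 700, nchar(a), k, FALSE)
  expect_equal(gl$reads_total, length(ovl))
  expect_equal(gl$reads_ambiguous_intra, sum(cls[ovl] == "intra"))
  expect_equal(gl$reads_ambiguous_intra, 200L - k + 1L)  # internal windows
})

test_that("per-gene attribution matches the oracle on circular genomes, including junction genes", {
  set.seed(303)
  k <- 30L
  a <- oracle_random_seq(1200)
  a <- oracle_plant_copy(a, 101, 90, 601)
  b <- oracle_random_seq(1000)
  substr(b, 200, 299) <- substr(a, 401, 500)
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), k,
                        circular = c(TRUE, TRUE))
  genes <- make_genes("ca", c(81, 391, 1150), c(220, 520, 1200),
                      c("gRep", "gShared", "gEnd"))
  gl <- perGeneLoss(pool, "A", genes)
  winsA <- oracle_windows(a, k, TRUE)
  winsB <- oracle_windows(b, k, TRUE)
  cls <- oracle_classify(winsA, winsB)
  for (i in seq_len(nrow(gl))) {
    g <- genes[genes$gene_id == gl$gene_id[i]]
    ovl <- oracle_gene_starts(BiocGenerics::start(g), BiocGenerics::end(g),
                              nchar(a), k, TRUE)
    expect_equal(gl$reads_total[i], length(ovl), info = gl$gene_id[i])
    expect_equal(gl$reads_ambiguous_intra[i], sum(cls[ovl] == "intra"),
                 info = gl$gene_id[i])
    expect_equal(gl$reads_ambiguous_inter[i], sum(cls[ovl] == "inter"),
                 info = gl$gene_id[i])
  }
  expect_gt(gl$intra_loss_pct[gl$gene_id == "gRep"], 0)
  expect_gt(gl$inter_loss_pct[gl$gene_id == "gShared"], 0)
  # records sorted by total loss descending, ties by gene_id
  expect_equal(gl$total_loss_pct, sort(gl$total_loss_pct, decreasing = TRUE))
})

test_that("a fully shared gene in a self-pool is 100% lost", {
  set.seed(304)
  a <- oracle_random_seq(900)
  pool <- make_pool_chr(c(a, a), c("one", "two"), c("c1", "c2"), 30,
                        circular = c(TRUE, TRUE))
  genes <- make_genes("c1", 301, 500, "g")
  gl <- perGeneLoss(pool, "one", genes)
  expect_equal(gl$total_loss_pct, 100)
})

test_that("genic ambiguity never exceeds the organism-level genic totals", {
  set.seed(305)
  k <- 30L
  a <- oracle_random_seq(1500)
  a <- oracle_plant_copy(a, 101, 100, 801)
  b <- oracle_random_seq(1000)
  substr(b, 50, 149) <- substr(a, 401, 500)
  pool <- make_pool_chr(c(a, b), c("A", "B"), c("ca", "cb"), k,
                        circular = c(TRUE, TRUE))
  genes <- make_genes("ca", seq(1, 1401, by = 100),
                      pmin(seq(100, 1500, by = 100), 1500),
                      sprintf("g%02d", 1:15))
  gl <- perGeneLoss(pool, "A", genes)
  rep <- readLoss(pool)[1L, ]
  # union of per-gene ambiguous reads (each read counted once organism-wide)
  expect_lte(max(gl$reads_ambiguous_intra), rep$ambiguous_intra)
  expect_lte(max(gl$reads_ambiguous_inter), rep$ambiguous_inter)
  expect_true(all(gl$reads_total >=
                    gl$reads_ambiguous_intra + gl$reads_ambiguous_inter))
})

test_that("genes on foreign replicons are a hard error", {
  set.seed(306)
  pool <- make_pool_chr(c(oracle_random_seq(500), oracle_random_seq(500)),
                        c("A", "B"), c("ca", "cb"), 30,
                        circular = c(TRUE, TRUE))
  genes <- make_genes("cb", 10, 100, "wrong")
  expect_error(perGeneLoss(pool, "A", genes), "does not belong")
})

test_that("report writing is deterministic and complete", {
  set.seed(307)
  dir <- withr::local_tempdir()
  seqs <- lapply(1:3, function(i) oracle_random_seq(600))
  pool <- make_pool_chr(unlist(seqs), c("o1", "o2", "o3"),
                        c("c1", "c2", "c3"), 30, circular = rep(TRUE, 3))
  recs <- list(
    o1 = perGeneLoss(pool, "o1", make_genes("c1", 1, 200, "g1")),
    o2 = perGeneLoss(pool, "o2", make_genes("c2", 1, 200, "g2")),
    o3 = perGeneLoss(pool, "o3", NULL))   # empty gene list
  rep <- readLoss(pool)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  writeLossReports(recs, rep, out1)
  writeLossReports(recs, rep, out2)
  files <- list.files(out1)
  expect_length(files, 4L)     # 3 gene lists + 1 summary
  # header-only file for the organism without genes
  expect_length(readLines(file.path(out1, "o3_gene_loss.tsv")), 1L)
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
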