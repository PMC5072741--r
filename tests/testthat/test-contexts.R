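test_that("extract_context returns the strand-resolved adenine-centered window", {
  g <- toy_genome()
  expect_identical(extract_context(g, "c1", 4, "+", flank = 2), "CCACC")
  # minus strand: forward window "CCTCC" around the T, reverse-complemented
  expect_identical(extract_context(g, "c2", 4, "-", flank = 2), "GGAGG")
  expect_error(extract_context(g, "c3", 4, "+", flank = 2),
               "not adenine-centered")
  expect_error(extract_context(g, "c1", 4, "-", flank = 2),
               "not adenine-centered")  # forward A is not a minus-strand site
  expect_error(extract_context(g, "c1", 2, "+", flank = 2), "boundary")
  expect_error(extract_context(g, "nope", 4, "+", flank = 2), "contig")
})

test_that("extraction length and center invariants hold on random genomes", {
  set.seed(7)
  for (rep in 1:20) {
    g <- generate_genome(300L, seed = rep)
    s <- strsplit(g[[1]], "")[[1]]
    flank <- 5L
    ok <- which(s == "A")
    ok <- ok[ok > flank & ok <= length(s) - flank]
    if (!length(ok)) next
    pos <- sample(ok, 1L)
    ctx <- extract_context(g, "chr1", pos, "+", flank)
    expect_identical(nchar(ctx), 2L * flank + 1L)
    expect_identical(substr(ctx, flank + 1, flank + 1), "A")
    # the matching minus-strand site at a forward T is the reverse complement
    tpos <- which(s == "T")
    tpos <- tpos[tpos > flank & tpos <= length(s) - flank]
    if (length(tpos)) {
      tp <- sample(tpos, 1L)
      fwd_window <- substr(g[[1]], tp - flank, tp + flank)
      expect_identical(extract_context(g, "chr1", tp, "-", flank),
                       revcomp(fwd_window))
    }
  }
})

test_that("contexts with more than 20% N are rejected", {
  g <- c(ok = "CCNACCC", bad = "NNNANNN")
  expect_identical(extract_context(g, "ok", 4, "+", flank = 2), "CNACC")
  expect_error(extract_context(g, "bad", 4, "+", flank = 2), ">20% N")
})

test_that("negative sampling matches the binomial expectation and the seed contract", {
  g <- generate_genome(1000000L, seed = 11)
  neg <- sample_negative_sites(g, rate = 1e-4, flank = 20, seed = 3)
  # 2e6 Bernoulli draws at 1e-4, kept when center base suits the strand
  # (prob 1/4 each way at uniform composition)
  expected <- 2 * 1e6 * 1e-4 * 0.25
  sd4 <- 4 * sqrt(2 * 1e6 * 1e-4 * 0.25 * (1 - 1e-4 * 0.25))
  expect_gt(nrow(neg), expected - sd4)
  expect_lt(nrow(neg), expected + sd4)
  expect_true(all(substr(neg$seq, 21, 21) == "A"))
  again <- sample_negative_sites(g, rate = 1e-4, flank = 20, seed = 3)
  expect_identical(neg, again)
  expect_error(sample_negative_sites(g, rate = 0), "rate")
  expect_error(sample_negative_sites(g, rate = 1), "rate")
})

test_that("negative sampling excludes positive sequences exactly", {
  g <- c(c1 = "AAAAAAAAAAAAAAAAAAAA")
  # every context of this genome is "AAAAA"; excluding it leaves nothing
  neg <- sample_negative_sites(g, rate = 0.5, flank = 2,
                               exclude = "AAAAA", seed = 1)
  expect_identical(nrow(neg), 0L)
  kept <- sample_negative_sites(g, rate = 0.5, flank = 2, seed = 1)
  expect_true(all(kept$seq == "AAAAA"))
})

test_that("redundancy_filter implements greedy >threshold clustering", {
  r <- redundancy_filter(c("AAAAA", "AAAAA", "CCCCC"), 0.8)
  expect_identical(r$representatives, c("AAAAA", "CCCCC"))
  expect_identical(r$cluster, c(1L, 1L, 2L))

  # 41-mers differing at 7 of 41 positions: identity 34/41 > 0.8
  set.seed(5)
  a <- rand_context(1, 41)
  b <- mutate_context(a, 7)
  expect_identical(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), 7L)
  expect_length(redundancy_filter(c(a, b), 0.8)$representatives, 1L)

  # strict threshold 1.0: no identity can exceed it
  distinct <- rand_context(10, 21, seed = 8)
  expect_length(redundancy_filter(distinct, 1.0)$representatives, 10L)
  expect_error(redundancy_filter(c("AAA", "AAAA"), 0.8), "mixed lengths")
})

test_that("redundancy_filter sees reverse-complement identity and is idempotent", {
  set.seed(9)
  a <- rand_context(1, 41)
  r <- redundancy_filter(c(a, revcomp(a)), 0.8, both_strands = TRUE)
  expect_length(r$representatives, 1L)
  r2 <- redundancy_filter(c(a, revcomp(a)), 0.8, both_strands = FALSE)
  expect_length(r2$representatives, 2L)
  for (rep in 1:5) {
    seqs <- c(rand_context(15, 21, seed = rep),
              vapply(rand_context(5, 21, seed = rep + 100),
                     mutate_context, character(1), k = 1))
    reps <- redundancy_filter(seqs, 0.8)$representatives
    expect_identical(redundancy_filter(reps, 0.8)$representatives, reps)
  }
})

test_that("cross_set_similarity counts A-members similar to B", {
  A <- rand_context(8, 41, seed = 2)
  expect_identical(as.integer(cross_set_similarity(A, A, 0.8)), 8L)
  B <- rand_context(8, 41, seed = 99)  # random 41-mers: identity ~ 0.25
  expect_identical(as.integer(cross_set_similarity(A, B, 0.8)), 0L)
  expect_identical(as.integer(cross_set_similarity(A, c(B, A[3]), 0.8)), 1L)
})

test_that("site and genome files round-trip, BED is 0-based half-open", {
  tmp <- withr::local_tempdir()
  g <- generate_genome(500, seed = 1)
  fa <- file.path(tmp, "g.fa")
  write_genome(g, fa)
  expect_identical(read_genome(fa), g)
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tsv <- file.path(tmp, "s.tsv")
  write_sites(sites, tsv)
  expect_identical(read_sites(tsv), sites)
  bed <- file.path(tmp, "s.bed")
  write_sites_bed(sites, bed)
  b <- read.delim(bed, header = FALSE)
  expect_identical(b$V2, sites$pos - 1L)
  expect_identical(b$V3, sites$pos)
})
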