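test_that("enumerate_candidates finds every A/T with a full window", {
  cand <- enumerate_candidates(c(c1 = "CCACC"), L1 = 5L)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$pos, 3L)
  expect_identical(cand$strand, "+")
  expect_identical(cand$seq, "CCACC")
  cand <- enumerate_candidates(c(c1 = "CCTCC"), L1 = 5L)
  expect_identical(cand$strand, "-")
  expect_identical(cand$seq, "GGAGG")  # revcomp of the forward window
  # edge positions are skipped and counted
  cand <- enumerate_candidates(c(c1 = "ACCCA"), L1 = 5L)
  expect_identical(nrow(cand), 0L)
  expect_identical(attr(cand, "skipped"), 2L)
})

test_that("candidate density matches base composition", {
  g <- generate_genome(20000L, c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       seed = 51)
  L1 <- 21L
  cand <- enumerate_candidates(g, L1)
  usable <- 20000L - (L1 - 1L)
  expected <- 0.6 * usable
  expect_lt(abs(nrow(cand) - expected), 4 * sqrt(0.6 * 0.4 * usable))
})

test_that("every candidate context re-extracts identically (both strands)", {
  g <- generate_genome(3000L, seed = 52)
  cand <- enumerate_candidates(g, 21L)
  pick <- cand[sample(nrow(cand), 50), ]
  for (i in seq_len(nrow(pick)))
    expect_identical(
      extract_context(g, pick$chrom[i], pick$pos[i], pick$strand[i], 10L),
      pick$seq[i])
  expect_true(any(pick$strand == "-") || any(pick$strand == "+"))
})

test_that("seed_match recovers planted seeds at the right mismatch budget", {
  set.seed(53)
  g <- generate_genome(5000L, seed = 53)
  seed_ctx <- rand_context(1, 21)
  exact <- mutated <- g[[1]]
  substr(exact, 1001, 1021) <- seed_ctx
  m3 <- vapply(seed_ctx, mutate_context, character(1), k = 3)
  substr(mutated, 2001, 2021) <- m3
  g2 <- c(chr1 = paste0(substr(exact, 1, 1500), substr(mutated, 1501, 5000)))
  hits0 <- seed_match(seed_ctx, g2, max_mismatch = 0)
  expect_true(any(hits0$pos == 1011 & hits0$strand == "+"))
  hits2 <- seed_match(seed_ctx, g2, max_mismatch = 2)
  expect_false(any(hits2$pos == 2011))
  hits3 <- seed_match(seed_ctx, g2, max_mismatch = 3)
  expect_true(any(hits3$pos == 2011 & hits3$mismatches == 3))
  # monotone: the k-mismatch hit set is contained in the (k+1) set
  key <- function(h) paste(h$chrom, h$pos, h$strand)
  expect_true(all(key(hits0) %in% key(hits2)))
  expect_true(all(key(hits2) %in% key(hits3)))
})

test_that("seed_match finds reverse-complement placements as minus-strand hits", {
  set.seed(54)
  g <- generate_genome(2000L, seed = 54)
  seed_ctx <- rand_context(1, 21)
  s <- g[[1]]
  substr(s, 501, 521) <- revcomp(seed_ctx)
  g2 <- c(chr1 = s)
  hits <- seed_match(seed_ctx, g2, max_mismatch = 0)
  hit <- hits[hits$pos == 511, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "-")
  expect_identical(hit$seq, seed_ctx)
  # a minus hit re-extracts to the seed itself
  expect_identical(extract_context(g2, "chr1", 511, "-", 10L), seed_ctx)
})

test_that("overlapping seeds merge to the best (lowest-mismatch) seed", {
  g <- generate_genome(1000L, seed = 55)
  set.seed(55)
  a <- rand_context(1, 21)
  b <- mutate_context(a, 1)  # 1 mismatch from a
  s <- g[[1]]
  substr(s, 301, 321) <- a
  hits <- seed_match(c(b, a), c(chr1 = s), max_mismatch = 2)
  hit <- hits[hits$pos == 311, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$seed_id, 2L)      # exact seed beats the 1-off seed
  expect_identical(hit$mismatches, 0L)
})

test_that("two_stage_scan applies one-class then binary in order", {
  dp <- dist_params(w = 0.5, L1 = 21L, L2 = 11L)
  kp <- kernel_params(0.1)
  pos <- motif_contexts(60, L = 21, p = 0.05, seed = 56)
  neg <- rand_context(60, 21, seed = 57)
  oc <- train_one_class(pos, dp, kp, nu = 0.1)
  bin <- suppressWarnings(train_binary(pos, neg, dp, kp))
  cand <- data.frame(seq = c(pos, rand_context(40, 21, seed = 58)),
                     stringsAsFactors = FALSE)
  out <- suppressMessages(two_stage_scan(cand, oc, bin))
  expect_identical(nrow(out), nrow(cand))
  # at nu = 0.1 at most ~10% of training sequences are rejected
  expect_gte(mean(out$oneclass_pass[1:60]), 1 - 0.1 - 0.02)
  # unrelated random contexts mostly do not pass
  expect_lt(mean(out$oneclass_pass[61:100]), 0.5)
  # stage order: binary fields only populated for stage-1 survivors
  expect_true(all(is.na(out$binary_label[!out$oneclass_pass])))
  expect_true(all(!is.na(out$binary_label[out$oneclass_pass])))
  # final positives are a subset of stage-1 survivors
  expect_true(all(out$oneclass_pass[which(out$binary_label == 1L)]))
  # empty input passes through
  empty <- suppressMessages(two_stage_scan(cand[0, , drop = FALSE], oc, bin))
  expect_identical(nrow(empty), 0L)
  # parameter mismatch is an error
  bin2 <- suppressWarnings(
    train_binary(pos, neg, dist_params(w = 0.2, L1 = 21L, L2 = 11L), kp))
  expect_error(two_stage_scan(cand, oc, bin2), "disagree")
})

test_that("write_hits emits ordered TSV and 0-based BED with scaled scores", {
  tmp <- withr::local_tempdir()
  hits <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                     pos = c(5L, 9L, 3L), strand = c("+", "-", "+"),
                     seq = c("AAA", "CCC", "GGG"),
                     decision_value = c(0.5, -1, 2),
                     stringsAsFactors = FALSE)
  tsv <- file.path(tmp, "h.tsv")
  write_hits(hits, tsv, "tsv")
  back <- read.delim(tsv)
  expect_identical(back$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(back$pos, c(3L, 9L, 5L))
  bed <- file.path(tmp, "h.bed")
  write_hits(hits, bed, "bed")
  b <- read.delim(bed, header = FALSE)
  expect_identical(b$V2, c(2L, 8L, 4L))   # 0-based starts
  expect_identical(b$V3, c(3L, 9L, 5L))
  expect_true(all(b$V5 >= 0 & b$V5 <= 1000))
  expect_identical(b$V5[b$V3 == 9], 0L)   # lowest decision value
})
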