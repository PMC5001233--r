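test_that("split enumeration follows the max(0, L - 2*MS + 1) law", {
  r33 <- paste(sample(c("A", "C", "G", "T"), 33, TRUE), collapse = "")
  s <- split_read(c(rd = r33), MS = 8)
  expect_equal(nrow(s), 18L)
  expect_equal(s$splitOffset, 8:25)
  expect_equal(nrow(split_read(c(x = strrep("A", 16)), 8)), 1L)
  expect_equal(nrow(split_read(c(x = strrep("A", 15)), 8)), 0L)
  # property: random (L, MS), count law and reconstruction
  set.seed(99)
  for (i in 1:50) {
    L <- sample(6:80, 1)
    MS <- sample(1:30, 1)
    rd <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    s <- split_read(c(rd = rd), MS)
    expect_equal(nrow(s), max(0L, L - 2L * MS + 1L))
    if (nrow(s))
      expect_true(all(paste0(s$leftSeq, s$rightSeq) == rd))
    expect_true(all(nchar(s$leftSeq) >= MS & nchar(s$rightSeq) >= MS))
  }
})

test_that("split_reads emits both halves under the id convention", {
  halves <- split_reads(c(rd1 = strrep("ACGT", 5)), MS = 8)
  expect_length(halves, 10L)  # 5 offsets x 2 sides
  ids <- parse_half_ids(names(halves))
  expect_setequal(ids$readId, "rd1")
  expect_setequal(ids$splitOffset, 8:12)
})

test_that("matched pairs demand colinear same-chromosome placements with an admissible gap", {
  p <- rsr_params(MS = 8, MD = 40000, minCD = 2, BB = 5)
  half <- function(readId, off, side, chrom, strand, start, w)
    data.frame(queryId = paste0(readId, "/", off, "/", side),
               refName = chrom, strand = strand, start = start,
               end = start + w, mismatches = 0L, altCount = 0L,
               readId = readId, splitOffset = off, side = side,
               stringsAsFactors = FALSE)
  base <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
                half("r1", 10, "R", "chr1", "+", 136, 23))
  mp <- find_matched_pairs(base, p)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$leftEnd, 110L)
  expect_equal(mp$rightStart, 136L)
  expect_equal(mp$gap, 26L)

  # gap below minCD is rejected
  tight <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
                 half("r1", 10, "R", "chr1", "+", 111, 23))
  expect_equal(nrow(find_matched_pairs(tight, p)), 0L)
  # different chromosomes are rejected
  cross <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
                 half("r1", 10, "R", "chr2", "+", 136, 23))
  expect_equal(nrow(find_matched_pairs(cross, p)), 0L)
  # gap beyond MD is rejected, at MD it is kept
  far <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
               half("r1", 10, "R", "chr1", "+", 110 + 40001, 23))
  expect_equal(nrow(find_matched_pairs(far, p)), 0L)
  at <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
              half("r1", 10, "R", "chr1", "+", 110 + 40000, 23))
  expect_equal(find_matched_pairs(at, p)$gap, 40000L)
  # halves from different split offsets never pair
  mixed <- rbind(half("r1", 10, "L", "chr1", "+", 100, 10),
                 half("r1", 11, "R", "chr1", "+", 136, 22))
  expect_equal(nrow(find_matched_pairs(mixed, p)), 0L)
})

test_that("reverse-strand pairs report genomic-orientation coordinates", {
  p <- rsr_params()
  # on "-", the read-order left half sits at the larger genomic coordinate
  h <- data.frame(
    queryId = c("r1/10/L", "r1/10/R"), refName = "chr1", strand = "-",
    start = c(500L, 100L), end = c(510L, 123L), mismatches = 0L,
    altCount = 0L, readId = "r1", splitOffset = 10L,
    side = c("L", "R"), stringsAsFactors = FALSE)
  mp <- find_matched_pairs(h, p)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$leftEnd, 123L)
  expect_equal(mp$rightStart, 500L)
  expect_equal(mp$gap, 377L)
  # an inverted arrangement on "-" is rejected
  h2 <- h; h2$start <- rev(h2$start); h2$end <- rev(h2$end)
  expect_equal(nrow(find_matched_pairs(h2, p)), 0L)
})

test_that("matched-pair output is independent of input row order", {
  h <- random_half_alignments(5, nRowsMin = 300L)
  p <- rsr_params(MD = 5000)
  mp1 <- find_matched_pairs(h, p)
  mp2 <- find_matched_pairs(h[sample.int(nrow(h)), ], p)
  expect_equal(mp1, mp2)
})

test_that("clustering links within the buffer, separates lengths, and counts distinct reads", {
  mp <- data.frame(
    readId = c("a", "b", "c", "c", "d"), splitOffset = c(10, 12, 9, 11, 10),
    chrom = "chr1", strand = "+",
    leftEnd = c(110L, 113L, 110L, 111L, 300L),
    rightStart = c(136L, 139L, 136L, 137L, 327L),
    gap = c(26L, 26L, 26L, 26L, 27L), stringsAsFactors = FALSE)
  j <- cluster_junctions(mp, BB = 5)
  expect_equal(nrow(j), 2L)
  j26 <- j[j$length == 26L, ]
  # one read with two admissible offsets still counts once
  expect_equal(j26$supportCount, 3L)
  # modal leftEnd wins, smallest first on ties
  expect_equal(j26$leftEnd, 110L)
  expect_equal(j26$rightStart, 136L)
  # lengths 26 and 27 at the same locus stay separate junctions
  expect_equal(j[j$length == 27L, ]$supportCount, 1L)
  # at BB 1 the leftEnd-113 pair detaches (111 -> 113 step exceeds 1)
  j2 <- cluster_junctions(mp, BB = 1)
  expect_equal(nrow(j2[j2$length == 26L, ]), 2L)
})

test_that("clusters at a smaller buffer refine clusters at a larger one", {
  set.seed(11)
  mp <- data.frame(
    readId = sprintf("r%03d", 1:200), splitOffset = 10L, chrom = "chr1",
    strand = "+", leftEnd = sample.int(500L, 200L, replace = TRUE),
    stringsAsFactors = FALSE)
  mp$rightStart <- mp$leftEnd + 26L
  mp$gap <- 26L
  # oracle: single-linkage dendrogram cut just above the buffer
  oracle_k <- function(bb) {
    h <- hclust(dist(mp$leftEnd), method = "single")
    length(unique(cutree(h, h = bb + 0.5)))
  }
  buffers <- c(0L, 1L, 3L, 6L, 12L)
  ours <- vapply(buffers, function(bb) nrow(cluster_junctions(mp, bb)), 0L)
  expect_equal(ours, vapply(buffers, oracle_k, 0L))
  # refinement: cluster counts can only fall as the buffer grows
  expect_true(all(diff(ours) <= 0L))
  # distinct read ids per row: support is conserved under any buffer
  for (bb in buffers)
    expect_equal(sum(cluster_junctions(mp, bb)$supportCount), nrow(mp))
})

test_that("support filtering keeps the boundary and preserves order", {
  j <- data.frame(chrom = "chr1", strand = "+", leftEnd = c(1L, 2L, 3L),
                  rightStart = c(27L, 28L, 29L), length = 26L,
                  supportCount = c(1L, 2L, 5L),
                  supportingReadIds = c("a", "a,b", "a,b,c,d,e"),
                  status = NA_character_, stringsAsFactors = FALSE)
  f <- filter_junctions(j, 2)
  expect_equal(f$supportCount, c(2L, 5L))
  expect_equal(nrow(filter_junctions(j[0, ], 2)), 0L)
})

test_that("annotation tolerates BB but not BB+1, matching length exactly", {
  known <- data.frame(gene = "g", chrom = "chrA", leftEnd = 100L,
                      rightStart = 150L, length = 50L,
                      stringsAsFactors = FALSE)
  mk <- function(le, len) data.frame(
    chrom = "chrA", strand = "+", leftEnd = le, rightStart = le + len,
    length = len, supportCount = 3L, supportingReadIds = "a,b,c",
    status = NA_character_, stringsAsFactors = FALSE)
  expect_equal(annotate_known(mk(100L, 50L), known, 5)$status, "known")
  expect_equal(annotate_known(mk(105L, 50L), known, 5)$status, "known")
  expect_equal(annotate_known(mk(106L, 50L), known, 5)$status, "novel")
  # same locus, different spliced length -> novel
  expect_equal(annotate_known(mk(100L, 26L), known, 5)$status, "novel")
})

test_that("ranking orders by support then coordinate", {
  j <- data.frame(chrom = c("chr2", "chr1", "chr1"), strand = "+",
                  leftEnd = c(10L, 50L, 20L), rightStart = c(36L, 76L, 46L),
                  length = 26L, supportCount = c(2L, 5L, 2L),
                  supportingReadIds = "x", status = "novel",
                  stringsAsFactors = FALSE)
  r <- rank_junctions(j)
  expect_equal(r$supportCount, c(5L, 2L, 2L))
  expect_equal(r$chrom[2:3], c("chr1", "chr2"))
})

test_that("total junction support never exceeds the unmapped-read pool", {
  fx <- default_fixture()
  nUnmapped <- length(fx$hetFp$unmapped)
  expect_gt(nUnmapped, 0L)
  expect_lte(sum(fx$res$junctionsA$supportCount), nUnmapped)
})
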