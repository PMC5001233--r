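test_that("builtin aligner reports exact occurrences on both strands", {
  set.seed(7)
  g <- Biostrings::DNAStringSet(c(chr1 = rand_dna(200), chr2 = rand_dna(200)))
  q_fwd <- substr(as.character(g[["chr2"]]), 51, 62)
  q_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(as.character(g[["chr1"]]), 11, 20))))
  res <- builtin_align(c(a = q_fwd, b = q_rev, c = "GGGGGGGGGGGGGGGG"), g)
  a <- res$alignments[res$alignments$queryId == "a", ]
  expect_equal(a[c("refName", "strand", "start", "end")],
               data.frame(refName = "chr2", strand = "+", start = 50L,
                          end = 62L),
               ignore_attr = TRUE)
  b <- res$alignments[res$alignments$queryId == "b", ]
  expect_equal(b[c("refName", "strand", "start", "end")],
               data.frame(refName = "chr1", strand = "-", start = 10L,
                          end = 20L),
               ignore_attr = TRUE)
  expect_equal(res$unmapped, "c")
})

test_that("multi-mappers beyond the threshold are suppressed, not unmapped", {
  g <- Biostrings::DNAStringSet(c(
    chr1 = "AAACCCGGGTTTAACCCGGGTTTCCCGGGTTTAAACAT"))
  res <- builtin_align(c(m = "CCCGGGTTT"), g, maxHits = 2)
  expect_equal(res$suppressed, "m")
  expect_equal(res$unmapped, character())
  expect_equal(nrow(res$alignments), 0L)
  # three forward occurrences plus one reverse-complement occurrence
  res4 <- builtin_align(c(m = "CCCGGGTTT"), g, maxHits = 4)
  expect_equal(nrow(res4$alignments), 4L)
  expect_equal(sum(res4$alignments$strand == "-"), 1L)
  expect_equal(unique(res4$alignments$altCount), 3L)
})

test_that("first pass partitions every read into exactly one bin", {
  fx <- default_fixture()
  reads <- fx$hetReads
  fp <- fx$hetFp
  aligned <- unique(fp$alignments$queryId)
  expect_equal(sort(c(aligned, names(fp$unmapped), fp$suppressed)),
               sort(names(reads)))
  expect_length(intersect(aligned, names(fp$unmapped)), 0L)
  expect_length(intersect(aligned, fp$suppressed), 0L)
})

test_that("exonic and canonical-junction reads align in the first pass", {
  ref <- toy_ref()
  flanks <- build_junction_flanks(ref$genes, ref$genome, readLength = 33)
  xg <- build_expanded_genome(ref$genome, flanks)
  chromA <- as.character(ref$genome[["chrA"]])
  inside_exon <- substr(chromA, 61, 93)
  # 10 bases of exon 1, 23 of exon 2 (canonical junction at 100/150)
  spanning <- paste0(substr(chromA, 91, 100), substr(chromA, 151, 173))
  fp <- first_pass(c(e = inside_exon, s = spanning), xg, aligner_config())
  expect_length(fp$unmapped, 0L)
  expect_setequal(fp$alignments$queryId, c("e", "s"))
  sHit <- fp$alignments[fp$alignments$queryId == "s", ]
  expect_true(startsWith(sHit$refName, "|jct|"))
})

test_that("second pass recovers read id, offset and side from half ids", {
  ref <- toy_ref()
  chromB <- as.character(ref$genome[["chrB"]])
  halves <- c("rd1/10/L" = substr(chromB, 101, 110),
              "rd1/10/R" = substr(chromB, 141, 163))
  aln <- second_pass(halves, ref$genome, aligner_config())
  expect_setequal(aln$readId, "rd1")
  expect_setequal(aln$splitOffset, 10L)
  expect_setequal(aln$side, c("L", "R"))
  expect_equal(aln$start[aln$side == "L"], 100L)
  expect_equal(aln$end[aln$side == "L"], 110L)
  expect_error(parse_half_ids("rd1-10-L"), "unparseable half id")
})

test_that("bowtie-default and SAM encodings parse to the same alignments", {
  bowtie <- c(
    paste("r1", "+", "chr1", 100, paste(rep("A", 33), collapse = ""),
          paste(rep("I", 33), collapse = ""), 0, sep = "\t"),
    paste("r2", "-", "chr2", 100, paste(rep("C", 33), collapse = ""),
          paste(rep("I", 33), collapse = ""), 1, "10:A>G", sep = "\t"))
  b <- parse_bowtie_default(bowtie)
  sam <- c(
    "@HD\tVN:1.0",
    paste("r1", 0, "chr1", 101, 255, "33M", "*", 0, 0,
          paste(rep("A", 33), collapse = ""),
          paste(rep("I", 33), collapse = ""), "NM:i:0", sep = "\t"),
    paste("r2", 16, "chr2", 101, 255, "33M", "*", 0, 0,
          paste(rep("C", 33), collapse = ""),
          paste(rep("I", 33), collapse = ""), "NM:i:1", "NH:i:2",
          sep = "\t"))
  s <- parse_sam(sam)
  cols <- c("queryId", "refName", "strand", "start", "end", "mismatches")
  expect_equal(b[cols], s$alignments[cols], ignore_attr = TRUE)
  expect_equal(s$alignments$start, c(100L, 100L))
  expect_equal(s$alignments$end, c(133L, 133L))
})

test_that("SAM unmapped flags are routed out and truncation is an error", {
  s <- parse_sam(c(paste("r9", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII",
                         sep = "\t")))
  expect_equal(s$unmapped, "r9")
  expect_equal(nrow(s$alignments), 0L)
  expect_error(parse_sam("r1\t0\tchr1"), "truncated SAM record at line 1")
  expect_error(parse_bowtie_default("r1\t+\tchr1"),
               "truncated bowtie record at line 1")
})

test_that("external mode demands a resolvable aligner executable", {
  expect_error(aligner_config(mode = "external",
                              executablePath = "no-such-aligner-xyz"),
               "not found")
  expect_error(aligner_config(mode = "external"), "not found")
})
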