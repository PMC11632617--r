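test_that("CIGAR walk recovers junction coordinates and offsets", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  # read at 1-based position 101, 50M100N50M: intron [151, 250], offset 50
  write_toy_sam(sam, c(chr1 = 1000), list(
    list(chrom = "chr1", pos = 101, cigar = "50M100N50M"),
    list(chrom = "chr1", pos = 1, cigar = "100M")))
  recs <- extract_junctions(sam, "s1")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$start, 151)
  expect_equal(recs$end, 250)
  expect_identical(recs$offsets[[1]], c(`50` = 1L))
})

test_that("reads sharing a junction aggregate their offsets", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  write_toy_sam(sam, c(chr1 = 1000), list(
    list(chrom = "chr1", pos = 121, cigar = "30M100N70M"),
    list(chrom = "chr1", pos = 81, cigar = "70M100N30M")))
  recs <- extract_junctions(sam, "s1")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$count, 2)
  expect_identical(recs$offsets[[1]], c(`30` = 1L, `70` = 1L))
})

test_that("soft clips and insertions count towards the read offset, deletions do not", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  write_toy_sam(sam, c(chr1 = 1000), list(
    list(chrom = "chr1", pos = 101, cigar = "5S20M2I10M3D15M50N20M")))
  recs <- extract_junctions(sam, "s1")
  # reference consumed before N: 20+10+3+15 = 48 -> junction at 149
  expect_equal(recs$start, 149)
  expect_equal(recs$end, 198)
  # query consumed: 5+20+2+10+15 = 52
  expect_identical(names(recs$offsets[[1]]), "52")
})

test_that("multi-junction reads contribute one record per junction", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  write_toy_sam(sam, c(chr1 = 2000), list(
    list(chrom = "chr1", pos = 101, cigar = "30M100N40M200N30M")))
  recs <- extract_junctions(sam, "s1")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$start, c(131, 271))
  expect_equal(recs$end, c(230, 470))
  expect_equal(vapply(recs$offsets, names, character(1)), c("30", "70"))
})

test_that("extract_junctions agrees with an independent CIGAR oracle", {
  set.seed(99)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "r.sam")
  reads <- lapply(1:80, function(i) {
    m1 <- sample(10:60, 1); n1 <- sample(50:500, 1); m2 <- sample(10:60, 1)
    two <- runif(1) < 0.3
    cig <- if (two) {
      n2 <- sample(50:300, 1); m3 <- sample(10:40, 1)
      sprintf("%dM%dN%dM%dN%dM", m1, n1, m2, n2, m3)
    } else sprintf("%dM%dN%dM", m1, n1, m2)
    list(chrom = "chr1", pos = sample(1:5000, 1), cigar = cig)
  })
  write_toy_sam(sam, c(chr1 = 20000), reads)
  recs <- extract_junctions(sam, "s1")

  # oracle: independent regex walk
  oracle <- list()
  for (r in reads) {
    ops <- regmatches(r$cigar, gregexpr("[0-9]+[A-Z=]", r$cigar))[[1]]
    len <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    ref <- r$pos; q <- 0L
    for (j in seq_along(op)) {
      if (op[j] == "N") {
        key <- paste0(ref, "-", ref + len[j] - 1L)
        oracle[[key]] <- c(oracle[[key]], q)
        ref <- ref + len[j]
      } else if (op[j] %in% c("M", "=", "X")) {
        ref <- ref + len[j]; q <- q + len[j]
      } else if (op[j] %in% c("I", "S")) q <- q + len[j]
      else if (op[j] == "D") ref <- ref + len[j]
    }
  }
  got <- setNames(recs$offsets, paste0(recs$start, "-", recs$end))
  expect_setequal(names(got), names(oracle))
  for (k in names(oracle)) {
    want <- table(oracle[[k]])
    expect_identical(got[[k]][names(want)],
                     setNames(as.integer(want), names(want)))
  }
  # conservation of reads: every simulated N op is accounted for
  expect_equal(sum(recs$count),
               sum(lengths(regmatches(
                 vapply(reads, `[[`, character(1), "cigar"),
                 gregexpr("N", vapply(reads, `[[`, character(1), "cigar"))))))
})

test_that("malformed CIGARs are skipped with a message, reads below MAPQ ignored", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  write_toy_sam(sam, c(chr1 = 1000), list(
    list(chrom = "chr1", pos = 101, cigar = "50M100N50M"),
    list(chrom = "chr1", pos = 101, cigar = "50M100Q50M"),
    list(chrom = "chr1", pos = 101, cigar = "40M100N60M", mapq = 2)))
  expect_message(recs <- extract_junctions(sam, "s1", mapq_min = 10),
                 "malformed")
  expect_equal(recs$count, 1)
  expect_identical(names(recs$offsets[[1]]), "50")
})

test_that("offset entropy matches closed forms and its invariances", {
  expect_equal(offset_entropy(c(`10` = 4)), 0)
  expect_equal(offset_entropy(c(`5` = 2, `12` = 2)), 1)
  expect_equal(offset_entropy(c(`3` = 3, `7` = 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(round(offset_entropy(c(3, 1)), 3), 0.811)
  expect_error(offset_entropy(integer(0)), "positive")
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    v <- sample(1:20, k, replace = TRUE)
    expect_equal(offset_entropy(v), offset_entropy(sample(v)))
    expect_lte(offset_entropy(v), log2(k) + 1e-12)
    expect_equal(offset_entropy(rep(7, k)), log2(k))
  }
})

test_that("junction filter removes low-entropy and non-canonical junctions", {
  intron <- paste0("GT", rand_dna(96), "AG")
  chrom <- paste0(rand_dna(200), intron, rand_dna(200))
  g <- toy_genome(chr1 = chrom)
  rec <- function(offs) {
    r <- data.frame(sample = "s1", chrom = "chr1", start = 201L, end = 300L)
    r$offsets <- I(list(offs))
    r$count <- sum(offs)
    class(r) <- c("junction_records", "data.frame")
    r
  }
  # single offset: entropy 0, removed at the 1.5-bit default
  expect_equal(nrow(suppressMessages(
    filter_junctions(rec(c(`10` = 8)), g))), 0)
  # four equal offsets: exactly 2 bits, retained, strand assigned +
  jt <- filter_junctions(rec(c(`10` = 2, `20` = 2, `30` = 2, `40` = 2)), g)
  expect_equal(nrow(jt), 1)
  expect_equal(jt$entropy, 2)
  expect_equal(jt$strand, "+")
  # non-canonical boundaries: removed despite high entropy
  chrom2 <- chrom
  substr(chrom2, 201, 202) <- "AT"
  substr(chrom2, 299, 300) <- "AC"
  g2 <- toy_genome(chr1 = chrom2)
  jt2 <- suppressMessages(
    filter_junctions(rec(c(`10` = 2, `20` = 2, `30` = 2, `40` = 2)), g2))
  expect_equal(nrow(jt2), 0)
  expect_equal(unname(attr(jt2, "dropped")["noncanonical"]), 1L)
  # minus-strand junction: CT...AC assigned '-'
  chrom3 <- chrom
  substr(chrom3, 201, 202) <- "CT"
  substr(chrom3, 299, 300) <- "AC"
  jt3 <- filter_junctions(rec(c(`10` = 2, `20` = 2, `30` = 2, `40` = 2)),
                          toy_genome(chr1 = chrom3))
  expect_equal(jt3$strand, "-")
})

test_that("junction tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  r <- data.frame(sample = c("s1", "s1"), chrom = "chr1",
                  start = c(201L, 400L), end = c(300L, 500L),
                  strand = c("+", "-"), count = c(4, 3),
                  entropy = c(2, 1.5))
  r$offsets <- I(list(c(`10` = 2L, `20` = 2L), c(`5` = 3L)))
  class(r) <- c("junction_table", "data.frame")
  path <- file.path(dir, "j.tsv")
  write_junction_table(r, path)
  r2 <- read_junction_table(path)
  expect_equal(r2$count, r$count)
  expect_identical(r2$offsets[[1]], r$offsets[[1]])
  expect_equal(junction_count(r2, "chr1", 201, 300), 4)
  expect_equal(junction_count(r2, "chr1", 201, 300, samples = "s9"), 0)
})
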