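test_that("insertion builds the expected structure on the plus strand", {
  set.seed(51)
  loc <- make_boundary_locus(w2 = 50, stop_offset = 42)
  res <- insert_exon(loc$tx, loc$plant_start, loc$plant_end, loc$genome)
  expect_equal(res$status, "inserted")
  expect_equal(length(res$modified_starts), 4)
  expect_equal(res$intron_index, 1)
  # last junction: all exons but the last
  expect_equal(res$last_junction_mrna, 90 + 45 + 50)
  expect_equal(nchar(res$mrna), 90 + 45 + 50 + 90)
  expect_equal(res$exon_mrna_start, 91)
})

test_that("incompatible insertions are reported, not raised", {
  set.seed(52)
  loc <- make_boundary_locus(w2 = 50, stop_offset = 42)
  # upstream of the transcript span
  expect_equal(insert_exon(loc$tx, 1, 20, loc$genome)$status, "incompatible")
  # overlapping an exon
  expect_equal(insert_exon(loc$tx, 80, 120, loc$genome)$status,
               "incompatible")
  # touching an exon boundary (would extend, not insert)
  expect_equal(insert_exon(loc$tx, 91, 120, loc$genome)$status,
               "incompatible")
})

test_that("minus-strand mRNA equals the reverse-complement oracle", {
  set.seed(53)
  for (i in 1:10) {
    loc <- random_toy_locus()
    res <- insert_exon(loc$tx, loc$plant_start, loc$plant_end, loc$genome)
    expect_equal(res$status, "inserted")
    seqs <- substring(loc$chrom_seq, res$modified_starts, res$modified_ends)
    want <- paste(seqs, collapse = "")
    if (loc$strand == "-") want <- oracle_revcomp(want)
    expect_identical(res$mrna, want)
  }
})

test_that("the 50-nt rule boundary is inclusive at 50 and fails at 49", {
  set.seed(54)
  # distance = plant_len + w2 - stop_offset - 3 (in-frame: offset % 3 == 0)
  loc50 <- make_boundary_locus(w2 = 50, stop_offset = 42)
  res <- insert_exon(loc50$tx, loc50$plant_start, loc50$plant_end,
                     loc50$genome)
  cl <- classify_ptc(res)
  expect_equal(cl$verdict, "poison")
  expect_equal(cl$ptc_distance, 50)

  loc49 <- make_boundary_locus(w2 = 49, stop_offset = 42)
  cl49 <- classify_ptc(insert_exon(loc49$tx, loc49$plant_start,
                                   loc49$plant_end, loc49$genome))
  expect_equal(cl49$verdict, "coding")
  expect_equal(cl49$ptc_distance, 49)

  loc120 <- make_boundary_locus(w2 = 120, stop_offset = 42)
  cl120 <- classify_ptc(insert_exon(loc120$tx, loc120$plant_start,
                                    loc120$plant_end, loc120$genome))
  expect_equal(cl120$verdict, "poison")
  expect_equal(cl120$ptc_distance, 120)
})

test_that("classification agrees with the brute-force translation oracle", {
  set.seed(55)
  for (i in 1:100) {
    loc <- random_toy_locus()
    res <- insert_exon(loc$tx, loc$plant_start, loc$plant_end, loc$genome)
    expect_equal(res$status, "inserted")
    got <- classify_ptc(res)
    want <- oracle_classify(loc$chrom_seq, loc$strand,
                            res$modified_starts, res$modified_ends,
                            loc$tx$cds_start, loc$tx$cds_end)
    expect_identical(got$verdict, want$verdict)
    if (got$verdict == "poison")
      expect_equal(got$ptc_distance, want$distance)
  }
})

test_that("frame-preserving stop-free insertions into a clean ORF are never poison", {
  set.seed(56)
  for (i in 1:20) {
    # stop-free gene (T-free exons) with a T-free frame-preserving plant
    n_ex <- sample(3:5, 1)
    w <- sample(30:90, n_ex, replace = TRUE)
    iw <- sample(80:160, n_ex - 1, replace = TRUE)
    plant_len <- 3L * sample(7:20, 1)
    host <- sample(n_ex - 1, 1)
    pieces <- character(0); starts <- ends <- integer(n_ex); pos <- 1L
    for (k in seq_len(n_ex)) {
      starts[k] <- pos; ends[k] <- pos + w[k] - 1L
      pieces <- c(pieces, rand_dna(w[k], c("A", "C", "G")))
      pos <- pos + w[k]
      if (k < n_ex) {
        pieces <- c(pieces, paste0("GT", rand_dna(iw[k] - 4), "AG"))
        pos <- pos + iw[k]
      }
    }
    sense <- paste(pieces, collapse = "")
    p_start <- ends[host] + 10L
    p_end <- p_start + plant_len - 1L
    substr(sense, p_start, p_end) <- rand_dna(plant_len, c("A", "C", "G"))
    strand <- sample(c("+", "-"), 1)
    L <- nchar(sense)
    flip <- function(s, e) if (strand == "+") c(s, e)
                           else c(L - e + 1L, L - s + 1L)
    chrom_seq <- if (strand == "+") sense else oracle_revcomp(sense)
    gen <- t(vapply(seq_len(n_ex), function(k) flip(starts[k], ends[k]),
                    numeric(2)))
    gen <- gen[order(gen[, 1]), , drop = FALSE]
    cdsg <- flip(starts[1] + 5L, ends[n_ex] - 5L)
    tx <- transcript_model("fp.t1", "fp", "chrF", strand, gen[, 1],
                           gen[, 2], cds_start = min(cdsg),
                           cds_end = max(cdsg))
    pg <- flip(p_start, p_end)
    res <- insert_exon(tx, min(pg), max(pg),
                       toy_genome(chrF = chrom_seq))
    expect_equal(res$status, "inserted")
    cl <- classify_ptc(res)
    expect_false(identical(cl$verdict, "poison"))
  }
})

test_that("verdicts are strand-covariant under locus mirroring", {
  set.seed(57)
  for (i in 1:15) {
    loc <- random_toy_locus()
    res <- insert_exon(loc$tx, loc$plant_start, loc$plant_end, loc$genome)
    v1 <- classify_ptc(res)$verdict
    # mirror the whole chromosome
    L <- nchar(loc$chrom_seq)
    mir_seq <- oracle_revcomp(loc$chrom_seq)
    flip <- function(s, e) c(L - e + 1L, L - s + 1L)
    gen <- cbind(L - rev(loc$tx$exon_ends) + 1L,
                 L - rev(loc$tx$exon_starts) + 1L)
    cds <- flip(loc$tx$cds_start, loc$tx$cds_end)
    tx2 <- transcript_model("m", "m", "chrR",
                            if (loc$strand == "+") "-" else "+",
                            gen[, 1], gen[, 2],
                            cds_start = min(cds), cds_end = max(cds))
    pg <- flip(loc$plant_start, loc$plant_end)
    res2 <- insert_exon(tx2, min(pg), max(pg), toy_genome(chrR = mir_seq))
    expect_identical(classify_ptc(res2)$verdict, v1)
  }
})

test_that("UTR insertions and non-coding transcripts get UTR-type verdicts", {
  set.seed(58)
  # gene with long UTR exons: CDS confined to exon 2
  chrom <- paste0(rand_dna(100, c("A", "C", "G")), "GT",
                  rand_dna(96, c("A", "C", "G")), "AG",
                  rand_dna(120, c("A", "C", "G")), "GT",
                  rand_dna(96, c("A", "C", "G")), "AG",
                  rand_dna(100, c("A", "C", "G")))
  tx <- transcript_model("u.t1", "u", "cU", "+",
                         c(1, 201, 421), c(100, 320, 520),
                         cds_start = 211, cds_end = 300)
  g <- toy_genome(cU = chrom)
  # insertion into intron 1 ends before the CDS -> 5' UTR
  cl5 <- classify_ptc(insert_exon(tx, 140, 160, g))
  expect_equal(cl5$verdict, "utr_5prime")
  # insertion into intron 2 starts after the annotated stop -> 3' UTR
  cl3 <- classify_ptc(insert_exon(tx, 360, 380, g))
  expect_equal(cl3$verdict, "utr_3prime")
  # non-coding transcript
  txnc <- transcript_model("u.t2", "u", "cU", "+", c(1, 201, 421),
                           c(100, 320, 520))
  expect_equal(classify_ptc(insert_exon(txnc, 140, 160, g))$verdict,
               "noncoding")
})

test_that("frameshift calls follow length modulo three", {
  expect_true(is_frameshift(94))
  expect_false(is_frameshift(93))
  expect_true(is_frameshift(1))
  expect_error(is_frameshift(0), "positive")
})

test_that("APE/APC/MIX grouping spans the host gene's transcripts", {
  set.seed(59)
  # two coding transcripts differing in the terminal exon so the same stop
  # is >= 50 nt upstream of the last junction in tx long but not in tx short
  w1 <- 90; plant_len <- 45; i1 <- 100
  e1 <- rand_dna(w1, c("A", "C", "G"))
  plant <- rand_dna(plant_len, c("A", "C", "G"))
  substr(plant, 43, 45) <- "TAA"  # offset 42, in frame with I' = 60
  intr1 <- paste0("GT", rand_dna(i1 - 4), "AG")
  substr(intr1, 39, 38 + 2 + plant_len + 2) <- paste0("AG", plant, "GT")
  e2 <- rand_dna(80, c("A", "C", "G"))
  intr2 <- paste0("GT", rand_dna(96), "AG")
  e3 <- rand_dna(90, c("A", "C", "G"))
  chrom <- paste0(e1, intr1, e2, intr2, e3)
  g <- toy_genome(cG = chrom)
  s2 <- w1 + i1 + 1
  # long isoform: exon2 of 80 nt -> distance 45 + 80 - 42 - 3 = 80 >= 50
  tx_long <- transcript_model("g.long", "g", "cG", "+",
                              c(1, s2, s2 + 80 + 100),
                              c(w1, s2 + 79, s2 + 80 + 100 + 89),
                              cds_start = 31, cds_end = nchar(chrom) - 33)
  # short isoform: exon2 truncated to 40 nt -> distance 40 < 50
  tx_short <- transcript_model("g.short", "g", "cG", "+",
                               c(1, s2, s2 + 80 + 100),
                               c(w1, s2 + 39, s2 + 80 + 100 + 89),
                               cds_start = 31, cds_end = nchar(chrom) - 33)
  gene <- list(gene_id = "g", chrom = "cG", strand = "+",
               transcripts = list(g.long = tx_long, g.short = tx_short),
               representative_id = "g.long")
  ps <- w1 + 40 + 1
  cl <- classify_across_transcripts(gene, ps, ps + plant_len - 1, g)
  expect_equal(unname(cl$per_transcript["g.long"]), "poison")
  expect_equal(unname(cl$per_transcript["g.short"]), "coding")
  expect_equal(cl$group, "MIX")
  expect_equal(cl$mane_verdict, "poison")
  expect_false(cl$frameshift)  # 45 nt preserves the frame

  # all-poison across transcripts -> APE
  gene_ape <- gene; gene_ape$transcripts$g.short <- NULL
  expect_equal(classify_across_transcripts(gene_ape, ps,
                                           ps + plant_len - 1, g)$group,
               "APE")
})
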