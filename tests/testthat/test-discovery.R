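# small shared cohort for discovery tests
local_discovery_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    truth <- generate_locus_set(
      locus_config(n_genes = 12, n_cryptic = 5, n_false_positives = 1),
      seed = 21)
    cons <- generate_conservation(truth, seed = 21)
    design <- cohort_design(samples_per_tissue = 1, depth = 120)
    sim <- simulate_cohort(truth, design, seed = 21)
    jt <- bind_junctions(lapply(seq_len(nrow(design)), function(i)
      suppressMessages(filter_junctions(
        extract_junctions(sim$samples[[i]]$sam, design$sample[i]),
        truth$catalog$genome))))
    cache <<- list(truth = truth, cons = cons, design = design, sim = sim,
                   junctions = jt)
    cache
  }
})

test_that("cassette detection matches a quadratic brute-force matcher", {
  fx <- local_discovery_fixture()
  truth <- fx$truth
  for (i in seq_len(nrow(fx$design))) {
    models <- read_models_gtf(fx$sim$samples[[i]]$gtf)
    got <- find_cassette_exons(models, truth$catalog, fx$design$sample[i])
    # oracle: all (internal exon, annotated intron) pairs, checked pairwise
    ann <- as.data.frame(truth$catalog$annotated_introns)
    want <- list()
    for (tx in models) {
      n <- length(tx$exon_starts)
      if (n < 3) next
      for (k in 2:(n - 1)) {
        for (r in seq_len(nrow(ann))) {
          if (as.character(ann$seqnames[r]) == tx$chrom &&
              as.character(ann$strand[r]) == tx$strand &&
              ann$start[r] == tx$exon_ends[k - 1] + 1 &&
              ann$end[r] == tx$exon_starts[k + 1] - 1) {
            want[[length(want) + 1L]] <-
              c(tx$chrom, tx$exon_starts[k], tx$exon_ends[k],
                ann$start[r], ann$end[r])
          }
        }
      }
    }
    want_keys <- unique(vapply(want, paste, character(1), collapse = ":"))
    got_keys <- with(got, paste(chrom, exon_start, exon_end, skip_start,
                                skip_end, sep = ":"))
    expect_setequal(got_keys, want_keys)
  }
})

test_that("models with fewer than three exons contribute no candidates", {
  fx <- local_discovery_fixture()
  tx <- fx$truth$catalog$transcripts[[1]]
  two <- transcript_model("two", "g", tx$chrom, tx$strand,
                          tx$exon_starts[1:2], tx$exon_ends[1:2])
  expect_equal(nrow(find_cassette_exons(list(two), fx$truth$catalog, "s")), 0)
})

test_that("candidates without any annotated skip intron are not emitted", {
  g <- toy_genome(c1 = rand_dna(3000))
  # annotation: one two-exon transcript; its single intron is (1001..1999)
  ann <- transcript_model("a.t1", "a", "c1", "+", c(801, 2000),
                          c(1000, 2400))
  catalog <- nexon:::build_catalog(
    nexon:::models_to_granges(list(ann), "a.t1"), g)
  # model exon inside that intron -> candidate
  m <- transcript_model("m1", "a", "c1", "+", c(801, 1400, 2000),
                        c(1000, 1600, 2400))
  got <- find_cassette_exons(list(m), catalog, "s")
  expect_equal(got$exon_start, 1400)
  expect_equal(got$exon_end, 1600)
  expect_false(got$annotated)
  # same model against a catalog lacking the intron -> nothing
  ann2 <- transcript_model("a.t1", "a", "c1", "+", c(801, 2100),
                           c(1000, 2400))
  catalog2 <- nexon:::build_catalog(
    nexon:::models_to_granges(list(ann2), "a.t1"), g)
  expect_equal(nrow(find_cassette_exons(list(m), catalog2, "s")), 0)
})

test_that("split support is the minimum over the two flanking junctions", {
  cand <- data.frame(sample = "s1", chrom = "c1", strand = "+",
                     exon_start = 1400L, exon_end = 1600L,
                     skip_start = 1001L, skip_end = 1999L,
                     annotated = FALSE, cov = 7)
  jt <- data.frame(sample = "s1", chrom = "c1",
                   start = c(1001L, 1601L), end = c(1399L, 1999L),
                   count = c(12, 5))
  el <- GRanges("c1", IRanges(1400, 1600), score = 500)
  sc <- score_candidates(cand, el, jt)
  expect_equal(sc$split_support, 5)
  expect_equal(sc$conservation, 500)   # exon fully inside one element
  expect_equal(sc$coverage, 7)
  # one flank with no reads: support 0
  sc0 <- score_candidates(cand, el, jt[1, ])
  expect_equal(sc0$split_support, 0)
})

test_that("coverage falls back to the per-base track and errors when absent", {
  cand <- data.frame(sample = "s1", chrom = "c1", strand = "+",
                     exon_start = 11L, exon_end = 20L,
                     skip_start = 1L, skip_end = 30L,
                     annotated = FALSE, cov = NA_real_)
  jt <- data.frame(sample = "s1", chrom = "c1", start = 1L, end = 1L,
                   count = 0L)[0, ]
  el <- GRanges("c1", IRanges(1, 100), score = 100)
  track <- GRanges("c1", IRanges(11:20, 11:20), score = c(1:10))
  sc <- score_candidates(cand, el, jt, track = track)
  expect_equal(sc$coverage, 5.5)
  expect_error(score_candidates(cand, el, jt), "coverage source")
})

test_that("thresholds are nearest-rank lower quantiles of annotated metrics", {
  m <- data.frame(conservation = seq(10, 100, 10),
                  coverage = seq(1, 10), split_support = rep(7, 10))
  thr <- learn_thresholds(m, percentile = 0.10)
  expect_equal(thr$conservation_min, 10)
  expect_equal(thr$split_min, 7)       # constant distribution
  expect_error(learn_thresholds(m[1:9, ]), "fewer than 10")
  # oracle: sorted[ceiling(p*n)] on random draws
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    v <- round(runif(n, 0, 1000), 1)
    p <- sample(c(0.05, 0.1, 0.25, 0.5), 1)
    m2 <- data.frame(conservation = v, coverage = v, split_support = v)
    expect_equal(learn_thresholds(m2, p)$conservation_min,
                 sort(v)[ceiling(p * n)])
  }
})

test_that("selection drops annotated-overlapping and sub-threshold candidates", {
  g <- toy_genome(c1 = rand_dna(5000))
  ann <- transcript_model("a.t1", "a", "c1", "+", c(801, 2000),
                          c(1000, 2400))
  catalog <- nexon:::build_catalog(
    nexon:::models_to_granges(list(ann), "a.t1"), g)
  thr <- structure(list(conservation_min = 100, coverage_min = 5,
                        split_min = 3, percentile = 0.1, sample_id = "s1"),
                   class = "threshold_set")
  base <- data.frame(sample = "s1", chrom = "c1", strand = "+",
                     exon_start = 1400L, exon_end = 1600L,
                     skip_start = 1001L, skip_end = 1999L,
                     annotated = FALSE, cov = NA_real_,
                     conservation = 500, coverage = 10, split_support = 5)
  expect_equal(nrow(select_cryptic(base, thr, catalog)), 1)
  # 1-bp overlap with an annotated exon: dropped
  ov <- base; ov$exon_start <- 1000L
  expect_equal(nrow(select_cryptic(ov, thr, catalog)), 0)
  # opposite strand overlap kept unless strand_blind
  ov_minus <- ov; ov_minus$strand <- "-"
  expect_equal(nrow(select_cryptic(ov_minus, thr, catalog)), 1)
  expect_equal(nrow(select_cryptic(ov_minus, thr, catalog,
                                   strand_blind = TRUE)), 0)
  # below one threshold: dropped
  low <- base; low$conservation <- 99
  expect_equal(nrow(select_cryptic(low, thr, catalog)), 0)
  # annotated exons themselves are never cryptic
  annc <- base; annc$annotated <- TRUE
  expect_equal(nrow(select_cryptic(annc, thr, catalog)), 0)
})

test_that("aggregation picks the flanking pair with highest pooled support", {
  sel <- data.frame(sample = c("s1", "s2"), chrom = "c1", strand = "+",
                    exon_start = 1400L, exon_end = 1600L,
                    skip_start = c(1001L, 901L), skip_end = c(1999L, 1999L),
                    annotated = FALSE, cov = NA_real_)
  jt <- data.frame(sample = rep(c("s1", "s2"), each = 3), chrom = "c1",
                   start = c(1001, 1601, 901, 1001, 1601, 901),
                   end = c(1399, 1999, 1399, 1399, 1999, 1399),
                   count = c(5, 8, 1, 3, 4, 2))
  agg <- aggregate_catalog(sel, jt, c(s1 = "brain", s2 = "brain"))
  expect_equal(nrow(agg), 1)
  # pair P1 (1001,1999): pooled up = 8, down = 12 -> support 8
  # pair P2 (901,1999): pooled up = 3, down = 12 -> support 3
  expect_equal(agg$skip_start, 1001)
  expect_equal(agg$support, 8)
  expect_equal(agg$tissues, "brain")
  expect_equal(agg$n_samples, 2)
})

test_that("aggregation tie-breaks by shorter skip intron, then leftmost", {
  sel <- data.frame(sample = c("s1", "s1"), chrom = "c1", strand = "+",
                    exon_start = 1400L, exon_end = 1600L,
                    skip_start = c(1001L, 901L), skip_end = c(1999L, 2099L),
                    annotated = FALSE, cov = NA_real_)
  jt <- data.frame(sample = "s1", chrom = "c1",
                   start = c(1001, 1601, 901, 1601),
                   end = c(1399, 1999, 1399, 2099),
                   count = c(4, 4, 4, 4))
  agg <- aggregate_catalog(sel, jt, c(s1 = "brain"))
  expect_equal(agg$skip_start, 1001)  # shorter skip intron wins the tie
  # exact tie in length too: leftmost start
  sel2 <- sel; sel2$skip_end <- c(1999L, 2099L); sel2$skip_start <- c(1001L, 1101L)
  jt2 <- data.frame(sample = "s1", chrom = "c1",
                    start = c(1001, 1601, 1101, 1601),
                    end = c(1399, 1999, 1399, 2099),
                    count = 4)
  agg2 <- aggregate_catalog(sel2, jt2, c(s1 = "brain"))
  expect_equal(agg2$skip_start, 1001)
})

test_that("no catalog exon overlaps any annotated exon (exhaustive)", {
  fx <- local_discovery_fixture()
  truth <- fx$truth
  sel <- list()
  for (i in seq_len(nrow(fx$design))) {
    sid <- fx$design$sample[i]
    models <- read_models_gtf(fx$sim$samples[[i]]$gtf)
    cands <- find_cassette_exons(models, truth$catalog, sid)
    cands <- score_candidates(cands, fx$cons$elements, fx$junctions)
    ann <- cands[cands$annotated & cands$coverage > 0, ]
    thr <- learn_thresholds(ann, 0.10, sid)
    sel[[sid]] <- select_cryptic(cands, thr, truth$catalog)
  }
  agg <- aggregate_catalog(do.call(rbind, sel), fx$junctions,
                           setNames(fx$design$tissue, fx$design$sample))
  gr <- GRanges(agg$chrom, IRanges(agg$exon_start, agg$exon_end),
                strand = agg$strand)
  expect_equal(length(findOverlaps(gr, truth$catalog$annotated_exons)), 0)
})
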