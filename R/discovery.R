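#' Identify cassette exons in assembled transcript models
#'
#' An internal exon `[x, y]` of an assembled model is a cassette exon when its
#' flanking introns `[a, x-1]` and `[y+1, b]` skip-join an *annotated* intron
#' `[a, b]` — i.e. the exon sits inside an intron of the reference annotation
#' and is joined to the annotated flanking exons on both sides. Models with
#' fewer than three exons contribute nothing. Multi-exon skips and
#' alternative splice sites are excluded by construction.
#'
#' @param models list of [transcript_model()] objects for one sample (e.g.
#'   parsed from an assembler GTF with [read_models_gtf()]).
#' @param catalog an `annotation_catalog`.
#' @param sample_id sample label.
#' @return data.frame of class `cassette_candidates`, one row per distinct
#'   (exon, flanking pair): columns `sample`, `chrom`, `strand`,
#'   `exon_start`, `exon_end`, `skip_start`, `skip_end` (the matched
#'   annotated intron `[a, b]`), `annotated` (exact match to an annotated
#'   exon) and `cov` (assembler per-exon coverage, `NA` when absent).
#' @export
find_cassette_exons <- function(models, catalog, sample_id) {
  rows <- list()
  for (tx in models) {
    n <- length(tx$exon_starts)
    if (n < 3) next
    for (i in 2:(n - 1)) {
      a <- tx$exon_ends[i - 1] + 1L
      b <- tx$exon_starts[i + 1] - 1L
      x <- tx$exon_starts[i]; y <- tx$exon_ends[i]
      if (!interval_key(tx$chrom, tx$strand, a, b) %in% catalog$intron_keys)
        next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, chrom = tx$chrom, strand = tx$strand,
        exon_start = x, exon_end = y, skip_start = a, skip_end = b,
        annotated = interval_key(tx$chrom, tx$strand, x, y) %in%
          catalog$exon_keys,
        cov = if (!is.null(tx$cov)) tx$cov[i] else NA_real_)
    }
  }
  if (length(rows) == 0) {
    res <- data.frame(sample = character(0), chrom = character(0),
                      strand = character(0), exon_start = integer(0),
                      exon_end = integer(0), skip_start = integer(0),
                      skip_end = integer(0), annotated = logical(0),
                      cov = numeric(0))
  } else {
    res <- do.call(rbind, rows)
    # same exon+flank pair seen in several models of the sample: keep one,
    # with the largest reported coverage
    key <- with(res, paste(chrom, strand, exon_start, exon_end, skip_start,
                           skip_end))
    o <- order(key, -ifelse(is.na(res$cov), -Inf, res$cov))
    res <- res[o, ][!duplicated(key[o]), ]
    rownames(res) <- NULL
  }
  class(res) <- c("cassette_candidates", "data.frame")
  res
}

#' Parse an assembler-style GTF into transcript models
#'
#' Reads exon records (optionally with a per-exon `cov` attribute, as emitted
#' by StringTie-like assemblers) into [transcript_model()] objects. CDS
#' records, if present, are honoured.
#'
#' @param gtf_path path to the GTF.
#' @return named list of `transcript_model`.
#' @export
read_models_gtf <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  cds_by_tx <- split(cds, cds$transcript_id)
  out <- list()
  for (txid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == txid]
    cov <- if ("cov" %in% names(mcols(e))) as.numeric(e$cov) else NULL
    cs <- ce <- NA_integer_
    if (txid %in% names(cds_by_tx)) {
      cc <- cds_by_tx[[txid]]
      cs <- min(start(cc)); ce <- max(end(cc))
    }
    out[[txid]] <- transcript_model(
      transcript_id = txid, gene_id = e$gene_id[1],
      chrom = as.character(seqnames(e))[1],
      strand = as.character(strand(e))[1],
      exon_starts = start(e), exon_ends = end(e),
      cds_start = cs, cds_end = ce, cov = cov)
  }
  out
}

#' Score cassette candidates with the three metrics
#'
#' Attaches to each candidate: `conservation` — the element score weighted by
#' intersection length (see [weighted_element_score()]); `coverage` — the
#' assembler-reported per-exon coverage when present, otherwise the mean of a
#' per-base track over the exon; `split_support` — the minimum split-read
#' count over the two flanking (inclusion) junctions in the candidate's
#' sample.
#'
#' @param cands `cassette_candidates` frame.
#' @param elements `GRanges` of conserved elements with a `score` column
#'   (0-1000 scale).
#' @param junctions junction table covering the candidates' samples.
#' @param track optional per-base conservation `GRanges` (fallback coverage
#'   source). A candidate with neither a `cov` attribute nor a track is an
#'   error naming the exon.
#' @param cons_denominator see [weighted_element_score()].
#' @return the input frame with `conservation`, `coverage`, `split_support`
#'   columns added.
#' @export
score_candidates <- function(cands, elements, junctions, track = NULL,
                             cons_denominator = c("intersection", "exon")) {
  cons_denominator <- match.arg(cons_denominator)
  n <- nrow(cands)
  if (n == 0) {
    cands$conservation <- numeric(0)
    cands$coverage <- numeric(0)
    cands$split_support <- integer(0)
    return(cands)
  }
  gr <- GRanges(cands$chrom, IRanges(cands$exon_start, cands$exon_end),
                strand = cands$strand)
  cands$conservation <- weighted_element_scores(gr, elements,
                                                denominator = cons_denominator)
  coverage <- cands$cov
  need <- is.na(coverage)
  if (any(need)) {
    if (is.null(track))
      stop("no coverage source for exon ", cands$chrom[which(need)[1]], ":",
           cands$exon_start[which(need)[1]], "-",
           cands$exon_end[which(need)[1]],
           " (no assembler 'cov' attribute and no per-base track)")
    for (i in which(need)) {
      v <- track_values(track, cands$chrom[i], cands$exon_start[i],
                        cands$exon_end[i])
      coverage[i] <- mean(v, na.rm = TRUE)
    }
  }
  cands$coverage <- coverage
  up <- integer(n); dn <- integer(n)
  for (i in seq_len(n)) {
    s <- cands$sample[i]
    up[i] <- junction_count(junctions, cands$chrom[i], cands$skip_start[i],
                            cands$exon_start[i] - 1L, samples = s)
    dn[i] <- junction_count(junctions, cands$chrom[i],
                            cands$exon_end[i] + 1L, cands$skip_end[i],
                            samples = s)
  }
  cands$split_support <- pmin(up, dn)
  cands
}

nearest_rank_quantile <- function(v, p) {
  v <- sort(v)
  v[max(1L, ceiling(p * length(v)))]
}

#' Learn per-sample metric thresholds from annotated cassette exons
#'
#' Each threshold is the nearest-rank lower quantile (default the 10th
#' percentile) of the corresponding metric across the annotated cassette
#' exons of the sample. A sample with fewer than 10 scored annotated cassette
#' exons is unusable.
#'
#' @param annotated_metrics data.frame with columns `conservation`,
#'   `coverage`, `split_support` for annotated cassette exons of one sample.
#' @param percentile quantile level as a fraction (default 0.10).
#' @param sample_id optional sample label stored with the thresholds.
#' @return list of class `threshold_set`: `conservation_min`, `coverage_min`,
#'   `split_min`, `percentile`, `sample_id`.
#' @export
learn_thresholds <- function(annotated_metrics, percentile = 0.10,
                             sample_id = NA_character_) {
  if (nrow(annotated_metrics) < 10)
    stop("fewer than 10 annotated cassette exons (",
         nrow(annotated_metrics), "); sample unusable for thresholds")
  structure(list(
    conservation_min = nearest_rank_quantile(annotated_metrics$conservation,
                                             percentile),
    coverage_min = nearest_rank_quantile(annotated_metrics$coverage,
                                         percentile),
    split_min = nearest_rank_quantile(annotated_metrics$split_support,
                                      percentile),
    percentile = percentile, sample_id = sample_id),
    class = "threshold_set")
}

#' Select cryptic exons in one sample
#'
#' Keeps candidates whose three metrics all reach the sample's thresholds,
#' that are not annotated exons themselves, and that do not overlap (by at
#' least 1 bp, same strand unless `strand_blind`) any annotated exon.
#'
#' @param cands scored `cassette_candidates` for one sample.
#' @param thresholds a `threshold_set` learned on the same sample.
#' @param catalog the `annotation_catalog` (supplies the annotated exon
#'   index).
#' @param strand_blind when `TRUE` the overlap filter ignores strand.
#' @return the retained subset of `cands`.
#' @export
select_cryptic <- function(cands, thresholds, catalog, strand_blind = FALSE) {
  if (nrow(cands) == 0) return(cands)
  pass <- cands$conservation >= thresholds$conservation_min &
    cands$coverage >= thresholds$coverage_min &
    cands$split_support >= thresholds$split_min &
    !cands$annotated
  gr <- GRanges(cands$chrom, IRanges(cands$exon_start, cands$exon_end),
                strand = cands$strand)
  hits <- findOverlaps(gr, catalog$annotated_exons, minoverlap = 1L,
                       ignore.strand = strand_blind)
  pass[unique(queryHits(hits))] <- FALSE
  res <- cands[pass, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate per-sample cryptic lists into a catalog
#'
#' Deduplicates selected exons by coordinates across samples. When an exon
#' was detected with several flanking-intron pairs, the pair with the highest
#' pooled split-read support (minimum over the two junctions, pooled over all
#' samples) is chosen; ties go to the shorter skip intron, then the leftmost.
#' Supporting samples and tissues are recorded per exon.
#'
#' @param selected row-bound output of [select_cryptic()] across samples.
#' @param junctions pooled junction table over all samples.
#' @param sample_tissues named character vector mapping sample -> tissue.
#' @return data.frame of class `cryptic_catalog`: `chrom`, `strand`,
#'   `exon_start`, `exon_end`, `skip_start`, `skip_end`, `support` (pooled
#'   min-support of the chosen pair), `n_samples`, `samples`, `tissues`
#'   (comma-separated).
#' @export
aggregate_catalog <- function(selected, junctions, sample_tissues = NULL) {
  if (nrow(selected) == 0) {
    res <- data.frame(chrom = character(0), strand = character(0),
                      exon_start = integer(0), exon_end = integer(0),
                      skip_start = integer(0), skip_end = integer(0),
                      support = integer(0), n_samples = integer(0),
                      samples = character(0), tissues = character(0))
    class(res) <- c("cryptic_catalog", "data.frame")
    return(res)
  }
  exon_key <- with(selected, paste(chrom, strand, exon_start, exon_end))
  rows <- lapply(split(seq_len(nrow(selected)), exon_key), function(idx) {
    sub <- selected[idx, , drop = FALSE]
    pairs <- unique(sub[, c("chrom", "strand", "exon_start", "exon_end",
                            "skip_start", "skip_end")])
    support <- vapply(seq_len(nrow(pairs)), function(k) {
      up <- junction_count(junctions, pairs$chrom[k], pairs$skip_start[k],
                           pairs$exon_start[k] - 1L)
      dn <- junction_count(junctions, pairs$chrom[k], pairs$exon_end[k] + 1L,
                           pairs$skip_end[k])
      min(up, dn)
    }, numeric(1))
    skip_len <- pairs$skip_end - pairs$skip_start + 1L
    best <- order(-support, skip_len, pairs$skip_start)[1]
    smp <- sort(unique(sub$sample))
    tis <- if (!is.null(sample_tissues))
      sort(unique(sample_tissues[smp])) else character(0)
    data.frame(chrom = pairs$chrom[best], strand = pairs$strand[best],
               exon_start = pairs$exon_start[best],
               exon_end = pairs$exon_end[best],
               skip_start = pairs$skip_start[best],
               skip_end = pairs$skip_end[best],
               support = support[best], n_samples = length(smp),
               samples = paste(smp, collapse = ","),
               tissues = paste(tis, collapse = ","))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$exon_start, res$exon_end), ]
  rownames(res) <- NULL
  class(res) <- c("cryptic_catalog", "data.frame")
  res
}

#' Write a cryptic-exon catalog as BED12
#'
#' One BED12 line per catalog exon: the chromStart/chromEnd span covers the
#' skip intron's flanking boundaries, with a single block for the exon
#' itself. Scores are the pooled split-read support capped at 1000.
#'
#' @param catalog a `cryptic_catalog`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  if (nrow(catalog) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t1\t%d,\t0,",
    catalog$chrom, catalog$exon_start - 1L, catalog$exon_end,
    sprintf("nexon_%s_%d_%d", catalog$chrom, catalog$exon_start,
            catalog$exon_end),
    pmin(1000L, as.integer(catalog$support)), catalog$strand,
    catalog$exon_start - 1L, catalog$exon_end,
    catalog$exon_end - catalog$exon_start + 1L)
  writeLines(lines, path)
  invisible(path)
}
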