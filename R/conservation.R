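#' Element conservation score weighted by intersection length
#'
#' The score of an exon is the mean of the scores of the conserved elements
#' it intersects, weighted by the length of each intersection:
#' \eqn{\sum_i s_i |o_i| / \sum_i |o_i|}. With
#' `denominator = "exon"` the divisor is the exon length instead, so
#' uncovered bases count as score 0. An exon intersecting no element scores
#' 0 (the most conservative value for the conservation filter).
#'
#' @param exon a length-1 `GRanges` (or use [weighted_element_scores()] for a
#'   vectorised version).
#' @param elements `GRanges` with a numeric `score` column (0-1000,
#'   phastCons-element style).
#' @param denominator `"intersection"` (default) or `"exon"`.
#' @return a numeric score.
#' @export
weighted_element_score <- function(exon, elements,
                                   denominator = c("intersection", "exon")) {
  weighted_element_scores(exon, elements, match.arg(denominator))
}

#' @rdname weighted_element_score
#' @param exons a `GRanges` of exons.
#' @export
weighted_element_scores <- function(exons, elements,
                                    denominator = c("intersection", "exon")) {
  denominator <- match.arg(denominator)
  hits <- findOverlaps(exons, elements, ignore.strand = TRUE)
  out <- numeric(length(exons))
  if (length(hits) > 0) {
    ov <- width(pintersect(exons[queryHits(hits)], elements[subjectHits(hits)],
                           ignore.strand = TRUE))
    sc <- elements$score[subjectHits(hits)]
    num <- tapply(ov * sc, queryHits(hits), sum)
    den <- tapply(ov, queryHits(hits), sum)
    idx <- as.integer(names(num))
    if (denominator == "exon") den <- width(exons)[idx]
    out[idx] <- as.numeric(num) / as.numeric(den)
  }
  out
}

#' Per-base values of a conservation track over an interval
#'
#' @param track `GRanges` with a `score` column (bedGraph/wig style; each
#'   range carries one score for all its bases).
#' @param chrom,start,end 1-based closed interval.
#' @return numeric vector of length `end - start + 1` in genomic order, `NA`
#'   where the track has no value.
#' @export
track_values <- function(track, chrom, start, end) {
  q <- GRanges(chrom, IRanges(start, end))
  hits <- findOverlaps(q, track, ignore.strand = TRUE)
  v <- rep(NA_real_, end - start + 1L)
  for (h in seq_along(hits)) {
    t <- track[subjectHits(hits)[h]]
    lo <- max(start(t), start); hi <- min(end(t), end)
    v[(lo - start + 1L):(hi - start + 1L)] <- t$score
  }
  v
}

#' Mean conservation per codon position under a given phase
#'
#' Walks the exon in transcription order (reversed for minus-strand exons)
#' and averages the per-base scores at codon positions 1, 2 and 3. `phase`
#' follows the GFF convention: the number of bases at the exon 5' end that
#' belong to the previous codon, i.e. base `phase + 1` is the first codon
#' start. Missing per-base scores are excluded from the means; when fewer
#' than `min_cover` of the exon's positions have scores, the means are `NA`
#' and `ok = FALSE`.
#'
#' @param track per-base conservation `GRanges` (phyloP style).
#' @param chrom,start,end,strand the exon.
#' @param phase 0, 1 or 2 (GFF convention).
#' @param min_cover minimum fraction of scored positions (default 0.5).
#' @return list of class `codon_profile`: `means` (length-3 numeric),
#'   `phase`, `source` (`"annotation"`), `ok`.
#' @export
codon_position_profile <- function(track, chrom, start, end, strand, phase,
                                   min_cover = 0.5) {
  len <- end - start + 1L
  if (len < 3) stop("exon shorter than 3 nt")
  stopifnot(phase %in% 0:2)
  v <- track_values(track, chrom, start, end)
  if (strand == "-") v <- rev(v)
  ok <- mean(!is.na(v)) >= min_cover
  idx <- seq_len(len) - 1L                    # 0-based transcription order
  codon_pos <- ((idx - phase) %% 3) + 1L
  means <- if (ok) {
    vapply(1:3, function(p) mean(v[codon_pos == p], na.rm = TRUE), numeric(1))
  } else rep(NA_real_, 3)
  structure(list(means = means, phase = as.integer(phase),
                 source = "annotation", ok = ok),
            class = "codon_profile")
}

#' Infer the reading frame of an exon from conservation periodicity
#'
#' Evaluates the codon-position profile for all three phases and returns the
#' one whose third-position mean is lowest — protein-coding sequence shows
#' depressed conservation at wobble positions. Ties (e.g. flat tracks) go to
#' the lowest phase index.
#'
#' @inheritParams codon_position_profile
#' @return a `codon_profile` with `source = "inferred"`.
#' @export
infer_phase <- function(track, chrom, start, end, strand, min_cover = 0.5) {
  profs <- lapply(0:2, function(p)
    codon_position_profile(track, chrom, start, end, strand, p, min_cover))
  third <- vapply(profs, function(pr) pr$means[3], numeric(1))
  if (all(is.na(third))) {
    best <- profs[[1]]
  } else {
    best <- profs[[which.min(replace(third, is.na(third), Inf))]]
  }
  best$source <- "inferred"
  best
}

#' Reading frame of an inserted exon from the annotation
#'
#' Derives the phase of the exon's first base so that the annotated exon
#' following the insertion retains its annotated reading frame: if the
#' downstream coding sequence begins `I'` CDS nucleotides into the ORF in the
#' original transcript and the exon has length `L`, the exon's first base
#' sits at codon offset `(I' - L) mod 3`, i.e. GFF phase
#' `(3 - (I' - L)) mod 3`.
#'
#' @param tx the original (unmodified) [transcript_model()] with a CDS.
#' @param result an `insertion_result` for `tx` (supplies the host intron).
#' @return integer GFF phase in `0:2`.
#' @export
frame_from_insertion <- function(tx, result) {
  if (result$status != "inserted") stop("insertion was incompatible")
  if (is.na(tx$cds_start)) stop("transcript has no CDS; no frame is defined")
  i <- result$intron_index
  # host intron in the ORIGINAL transcript, genomic coordinates
  intron_start <- tx$exon_ends[i] + 1L
  intron_end <- tx$exon_starts[i + 1] - 1L
  if (intron_start <= tx$cds_start || intron_end >= tx$cds_end)
    stop("insertion point outside the CDS; no frame is defined")
  # CDS nucleotides transcriptionally upstream of the host intron
  cs <- pmax(tx$exon_starts, tx$cds_start)
  ce <- pmin(tx$exon_ends, tx$cds_end)
  w <- pmax(0L, ce - cs + 1L)
  upstream <- if (tx$strand == "+") which(tx$exon_ends < intron_start)
              else which(tx$exon_starts > intron_end)
  iprime <- sum(w[upstream])
  L <- result$exon_mrna_end - result$exon_mrna_start + 1L
  c0 <- ((iprime - L) %% 3L + 3L) %% 3L
  as.integer((3L - c0) %% 3L)
}
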