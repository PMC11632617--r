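# In-silico exon insertion, translation, 50-nt-rule PTC detection and the
# poison / protein-coding / UTR classification of cryptic exons.

# map a genomic position to the 1-based mRNA coordinate of a transcript with
# the given (sorted, genomic-order) exon structure
genomic_to_mrna <- function(exon_starts, exon_ends, strand, gpos) {
  w <- exon_ends - exon_starts + 1L
  idx <- which(exon_starts <= gpos & exon_ends >= gpos)
  if (length(idx) != 1) return(NA_integer_)
  if (strand == "+") {
    sum(w[seq_len(idx - 1L)]) + (gpos - exon_starts[idx]) + 1L
  } else {
    n <- length(w)
    # exons genomically after idx come first in transcription order
    sum(w[seq_len(n - idx) + idx]) + (exon_ends[idx] - gpos) + 1L
  }
}

# mRNA sequence of an exon structure (reverse-complemented, reverse-order
# concatenation on the minus strand)
build_mrna <- function(genome, chrom, strand, exon_starts, exon_ends) {
  seqs <- vapply(seq_along(exon_starts), function(i)
    genome_seq(genome, chrom, exon_starts[i], exon_ends[i]), character(1))
  s <- paste(seqs, collapse = "")
  if (strand == "-")
    s <- as.character(reverseComplement(DNAString(s)))
  s
}

#' Insert a cryptic exon into a transcript model
#'
#' The exon is accepted only when it lies strictly inside one intron of the
#' transcript (not touching either flanking exon); anything else — overlap
#' with an exon, a position outside the transcript span, a different
#' chromosome — yields `status = "incompatible"` rather than an error. On
#' insertion the mRNA is rebuilt from the genomic sequence
#' (reverse-complemented for minus-strand transcripts) and the CDS start and
#' final exon-exon junction positions are recomputed in mRNA coordinates.
#'
#' @param tx a [transcript_model()].
#' @param exon_start,exon_end genomic interval of the exon (same chromosome
#'   and strand as the transcript).
#' @param genome a `DNAStringSet`.
#' @return object of class `insertion_result`: `status` (`"inserted"` or
#'   `"incompatible"`), and when inserted: `mrna` (character),
#'   `cds_start_mrna`, `annotated_stop_end_mrna` (mRNA position of the last
#'   base of the annotated stop codon; `NA` for non-coding transcripts),
#'   `last_junction_mrna` (mRNA position of the last base before the final
#'   exon-exon junction), `exon_mrna_start`/`exon_mrna_end` (span of the
#'   inserted exon in mRNA coordinates), `modified_starts`/`modified_ends`,
#'   `intron_index` and `transcript_id`.
#' @export
insert_exon <- function(tx, exon_start, exon_end, genome) {
  incompatible <- structure(
    list(status = "incompatible", transcript_id = tx$transcript_id),
    class = "insertion_result")
  n <- length(tx$exon_starts)
  if (n < 2) return(incompatible)
  intron_index <- NA_integer_
  for (i in seq_len(n - 1)) {
    if (exon_start > tx$exon_ends[i] + 1L &&
        exon_end < tx$exon_starts[i + 1] - 1L) {
      intron_index <- i
      break
    }
  }
  if (is.na(intron_index)) return(incompatible)

  ms <- append(tx$exon_starts, exon_start, after = intron_index)
  me <- append(tx$exon_ends, exon_end, after = intron_index)
  mrna <- build_mrna(genome, tx$chrom, tx$strand, ms, me)
  w <- me - ms + 1L
  last_junction <- sum(w) - if (tx$strand == "+") w[length(w)] else w[1]

  g2m <- function(g) genomic_to_mrna(ms, me, tx$strand, g)
  cds_start_mrna <- annot_stop_end_mrna <- NA_integer_
  if (!is.na(tx$cds_start)) {
    cds_start_mrna <- g2m(if (tx$strand == "+") tx$cds_start else tx$cds_end)
    annot_stop_end_mrna <- g2m(if (tx$strand == "+") tx$cds_end else tx$cds_start)
  }
  exon_mrna_start <- g2m(if (tx$strand == "+") exon_start else exon_end)
  structure(
    list(status = "inserted", transcript_id = tx$transcript_id,
         strand = tx$strand, mrna = mrna,
         cds_start_mrna = cds_start_mrna,
         annotated_stop_end_mrna = annot_stop_end_mrna,
         last_junction_mrna = last_junction,
         exon_mrna_start = exon_mrna_start,
         exon_mrna_end = exon_mrna_start + (exon_end - exon_start),
         modified_starts = ms, modified_ends = me,
         intron_index = intron_index),
    class = "insertion_result")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# first in-frame stop codon at or after mRNA position `from`; returns the
# mRNA position of its last base, or NA
first_stop_end <- function(mrna, from) {
  len <- nchar(mrna)
  starts <- seq.int(from, len - 2L, by = 3L)
  if (length(starts) == 0) return(NA_integer_)
  codons <- substring(mrna, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0) return(NA_integer_)
  starts[hit[1]] + 2L
}

#' Classify an inserted exon under the 50-nt rule
#'
#' The modified mRNA is translated from the annotated CDS start; the first
#' in-frame stop codon is located. A stop is a premature termination codon
#' (PTC) when the distance from its 3' end to the last exon-exon junction is
#' at least `rule_nt` (default 50, inclusive), reflecting the downstream
#' exon-junction complexes that trigger NMD. The annotated stop codon is
#' never a PTC. Insertions outside the CDS are reported as `utr_5prime` /
#' `utr_3prime`; non-coding transcripts yield `noncoding`.
#'
#' @param result an `insertion_result` with `status = "inserted"`.
#' @param rule_nt PTC distance threshold in nucleotides.
#' @return list: `verdict` (one of `poison`, `coding`, `utr_5prime`,
#'   `utr_3prime`, `noncoding`, `incompatible`), `ptc_distance` (nt from the
#'   stop's 3' end to the last junction; `NA` unless a candidate stop was
#'   evaluated) and `nonstop` (`TRUE` when translation never reaches a stop).
#' @export
classify_ptc <- function(result, rule_nt = 50) {
  if (result$status != "inserted")
    return(list(verdict = "incompatible", ptc_distance = NA_real_,
                nonstop = FALSE))
  if (is.na(result$cds_start_mrna))
    return(list(verdict = "noncoding", ptc_distance = NA_real_,
                nonstop = FALSE))
  if (result$exon_mrna_end < result$cds_start_mrna)
    return(list(verdict = "utr_5prime", ptc_distance = NA_real_,
                nonstop = FALSE))
  if (result$exon_mrna_start > result$annotated_stop_end_mrna)
    return(list(verdict = "utr_3prime", ptc_distance = NA_real_,
                nonstop = FALSE))
  stop_end <- first_stop_end(result$mrna, result$cds_start_mrna)
  if (is.na(stop_end))
    return(list(verdict = "coding", ptc_distance = NA_real_, nonstop = TRUE))
  if (stop_end >= result$annotated_stop_end_mrna)
    return(list(verdict = "coding", ptc_distance = NA_real_,
                nonstop = FALSE))
  d <- result$last_junction_mrna - stop_end
  list(verdict = if (d >= rule_nt) "poison" else "coding",
       ptc_distance = d, nonstop = FALSE)
}

#' Is an exon length frame-shifting?
#'
#' @param exon_length exon length in nucleotides (>= 1).
#' @return `TRUE` iff the length is not a multiple of three.
#' @export
is_frameshift <- function(exon_length) {
  if (any(exon_length < 1)) stop("exon length must be positive")
  exon_length %% 3 != 0
}

#' Classify an exon across all transcripts of its host gene
#'
#' Runs [insert_exon()] + [classify_ptc()] against every transcript of the
#' gene. Over the coding transcripts where the insertion succeeded, the exon
#' is grouped as APE (a PTC in every such transcript), APC (a PTC in none)
#' or MIX (a PTC in some but not all). UTR insertions do not induce a PTC —
#' the exon lies outside the reading frame — and therefore count on the
#' non-poison side; insertions into transcripts without a CDS are recorded
#' but excluded. The verdict against the representative ("MANE-like")
#' transcript is reported separately.
#'
#' @param gene a gene entry from an `annotation_catalog` (`catalog$genes`).
#' @param exon_start,exon_end the exon's genomic interval.
#' @param genome a `DNAStringSet`.
#' @param rule_nt see [classify_ptc()].
#' @return list of class `exon_class`: `per_transcript` (named verdict
#'   vector), `mane_verdict`, `group` (`"APE"`, `"APC"`, `"MIX"` or `NA` when
#'   no transcript provides a coding context), `frameshift`, `ptc_distance`
#'   (against the representative transcript).
#' @export
classify_across_transcripts <- function(gene, exon_start, exon_end, genome,
                                        rule_nt = 50) {
  stopifnot(length(gene$transcripts) >= 1)
  verdicts <- character(0)
  mane_verdict <- NA_character_
  mane_distance <- NA_real_
  for (tx in gene$transcripts) {
    res <- insert_exon(tx, exon_start, exon_end, genome)
    cl <- classify_ptc(res, rule_nt = rule_nt)
    verdicts[tx$transcript_id] <- cl$verdict
    if (!is.na(gene$representative_id) &&
        tx$transcript_id == gene$representative_id) {
      mane_verdict <- cl$verdict
      mane_distance <- cl$ptc_distance
    }
  }
  n_poison <- sum(verdicts == "poison")
  n_nonpoison <- sum(verdicts %in% c("coding", "utr_5prime", "utr_3prime"))
  group <- if (n_poison + n_nonpoison == 0) NA_character_
  else if (n_nonpoison == 0) "APE"
  else if (n_poison == 0) "APC"
  else "MIX"
  structure(
    list(per_transcript = verdicts, mane_verdict = mane_verdict,
         group = group,
         frameshift = is_frameshift(exon_end - exon_start + 1L),
         ptc_distance = mane_distance),
    class = "exon_class")
}

#' @export
print.exon_class <- function(x, ...) {
  cat(sprintf("<exon_class> group=%s mane=%s frameshift=%s (%d transcripts)\n",
              x$group, x$mane_verdict, x$frameshift,
              length(x$per_transcript)))
  invisible(x)
}
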