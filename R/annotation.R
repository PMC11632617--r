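#' Construct a transcript model
#'
#' A transcript model holds the ordered exon structure of one transcript and,
#' for coding transcripts, the genomic span of its CDS. Exons are stored in
#' genomic order (ascending start); for minus-strand transcripts the
#' transcription order is the reverse. The CDS span includes the stop codon.
#'
#' @param transcript_id,gene_id character identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; strand-ambiguous transcripts are rejected.
#' @param exon_starts,exon_ends integer vectors of 1-based closed exon
#'   coordinates. Must be non-overlapping with at least 1 nt between
#'   consecutive exons.
#' @param cds_start,cds_end genomic span of the coding sequence (including the
#'   stop codon), or `NA` for non-coding transcripts.
#' @param cov optional numeric vector of per-exon read coverage (assembler
#'   "cov" attribute), parallel to the exons.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             cov = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-', got '",
         strand, "'")
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (!is.null(cov)) cov <- cov[o]
  if (any(exon_ends < exon_starts))
    stop("transcript ", transcript_id, ": exon end < start")
  n <- length(exon_starts)
  if (n > 1 && any(exon_starts[-1] - exon_ends[-n] < 2))
    stop("transcript ", transcript_id,
         ": overlapping or touching exons (introns must have length >= 1)")
  if (!is.na(cds_start)) {
    if (is.na(cds_end) || cds_end < cds_start)
      stop("transcript ", transcript_id, ": invalid CDS span")
    covers <- any(exon_starts <= cds_start & exon_ends >= cds_start) &&
      any(exon_starts <= cds_end & exon_ends >= cds_end)
    if (!covers)
      stop("transcript ", transcript_id, ": CDS boundaries outside exons")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exon_starts = exon_starts, exon_ends = exon_ends,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         cov = cov),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding"
         else paste0("CDS ", x$cds_start, "-", x$cds_end)
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exon_starts), cds))
  invisible(x)
}

#' Introns of a transcript model
#'
#' @param tx a [transcript_model()].
#' @return data.frame with columns `start`, `end` (1-based closed), one row
#'   per intron between consecutive exons; zero rows for single-exon models.
#' @export
transcript_introns <- function(tx) {
  n <- length(tx$exon_starts)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = tx$exon_ends[-n] + 1L, end = tx$exon_starts[-1] - 1L)
}

interval_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = ":")
}

#' Load a genome FASTA
#'
#' Sequence names are truncated at the first whitespace, matching common
#' aligner behaviour.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract genomic sequence
#'
#' @param genome a `DNAStringSet` as returned by [load_genome()].
#' @param chrom,start,end 1-based closed genomic interval.
#' @param strand when `"-"`, the reverse complement is returned.
#' @return a character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in the genome")
  len <- length(genome[[chrom]])
  if (start < 1 || end > len || start > end)
    stop("interval ", chrom, ":", start, "-", end,
         " outside sequence bounds (1-", len, ")")
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  as.character(s)
}

#' Test for canonical GT/AG splice-site dinucleotides
#'
#' An intron is canonical when its transcribed-strand sequence begins with GT
#' and ends with AG. On the minus strand the genomic (plus-strand) window
#' therefore reads CT...AC. Only GT/AG is accepted (GC/AG is rejected),
#' matching the splice-site setting used for split-read counting.
#'
#' @param genome a `DNAStringSet`.
#' @param chrom,start,end intron interval (1-based closed, length >= 4).
#' @param strand `"+"` or `"-"`.
#' @return `TRUE` or `FALSE`.
#' @export
is_canonical <- function(genome, chrom, start, end, strand) {
  if (end - start + 1 < 4)
    stop("intron ", chrom, ":", start, "-", end, " shorter than 4 nt")
  first2 <- genome_seq(genome, chrom, start, start + 1L)
  last2 <- genome_seq(genome, chrom, end - 1L, end)
  if (strand == "+") first2 == "GT" && last2 == "AG"
  else if (strand == "-") first2 == "CT" && last2 == "AC"
  else stop("strand must be '+' or '-'")
}

#' Load a reference annotation and genome into an annotation catalog
#'
#' Parses an Ensembl-dialect GTF (gene/transcript/exon/CDS features with
#' `gene_id`/`transcript_id` attributes) together with the genome FASTA, and
#' builds the gene models, the annotated intron catalog and the annotated
#' exon overlap index used by every downstream stage. The representative
#' ("MANE-like") transcript of each gene is recognised by a GTF `tag`
#' attribute value (default `"MANE_Select"`).
#'
#' @param gtf_path path to the annotation GTF (1-based closed coordinates).
#' @param genome_path path to the genome FASTA covering all referenced
#'   chromosomes (a missing chromosome is a hard error naming it).
#' @param representative_tag value of the `tag` attribute marking the
#'   representative transcript.
#' @return an object of class `annotation_catalog`: a list with `genes`
#'   (named list; each gene has `gene_id`, `chrom`, `strand`, `transcripts`
#'   (named list of [transcript_model()]), `representative_id`),
#'   `transcripts` (flat named list), `annotated_introns` /`annotated_exons`
#'   (`GRanges`), `intron_keys`/`exon_keys` (exact-match key sets) and
#'   `genome` (`DNAStringSet`).
#' @export
load_annotation <- function(gtf_path, genome_path,
                            representative_tag = "MANE_Select") {
  genome <- load_genome(genome_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  build_catalog(gr, genome, representative_tag)
}

build_catalog <- function(gr, genome, representative_tag = "MANE_Select") {
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (length(ex) == 0) stop("annotation contains no exon records")
  bad <- setdiff(unique(as.character(seqnames(ex))), names(genome))
  if (length(bad) > 0)
    stop("chromosome(s) absent from genome FASTA: ",
         paste(bad, collapse = ", "))
  tag <- if ("tag" %in% names(mcols(gr))) gr$tag else rep(NA_character_, length(gr))

  cds_by_tx <- split(cds, cds$transcript_id)
  exl <- split(ex, ex$transcript_id)
  transcripts <- list()
  rep_tx <- character(0)
  for (txid in names(exl)) {
    e <- exl[[txid]]
    strand <- as.character(strand(e))
    if (any(strand == "*"))
      stop("transcript ", txid, ": strand-ambiguous ('.') records rejected")
    if (length(unique(strand)) != 1 ||
        length(unique(as.character(seqnames(e)))) != 1)
      stop("transcript ", txid, ": exons on multiple chromosomes/strands")
    cs <- ce <- NA_integer_
    if (txid %in% names(cds_by_tx)) {
      cc <- cds_by_tx[[txid]]
      cs <- min(start(cc)); ce <- max(end(cc))
    }
    tx <- transcript_model(
      transcript_id = txid, gene_id = e$gene_id[1],
      chrom = as.character(seqnames(e))[1], strand = strand[1],
      exon_starts = start(e), exon_ends = end(e),
      cds_start = cs, cds_end = ce)
    transcripts[[txid]] <- tx
    gtag <- gr$transcript_id == txid & !is.na(tag) & tag == representative_tag
    if (any(gtag, na.rm = TRUE)) rep_tx <- c(rep_tx, txid)
  }

  gene_ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  genes <- list()
  for (gid in unique(gene_ids)) {
    txs <- transcripts[gene_ids == gid]
    chroms <- unique(vapply(txs, function(t) t$chrom, character(1)))
    strands <- unique(vapply(txs, function(t) t$strand, character(1)))
    if (length(chroms) != 1 || length(strands) != 1)
      stop("gene ", gid, ": transcripts disagree on chromosome or strand")
    rid <- intersect(names(txs), rep_tx)
    genes[[gid]] <- list(gene_id = gid, chrom = chroms, strand = strands,
                         transcripts = txs,
                         representative_id = if (length(rid)) rid[1] else NA_character_)
  }

  intr <- do.call(rbind, lapply(transcripts, function(t) {
    ii <- transcript_introns(t)
    if (nrow(ii) == 0) return(NULL)
    data.frame(chrom = t$chrom, strand = t$strand, start = ii$start,
               end = ii$end)
  }))
  if (is.null(intr))
    intr <- data.frame(chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0))
  intr <- unique(intr)
  annotated_introns <- GRanges(intr$chrom, IRanges(intr$start, intr$end),
                               strand = intr$strand)
  exu <- unique(data.frame(chrom = as.character(seqnames(ex)),
                           strand = as.character(strand(ex)),
                           start = start(ex), end = end(ex)))
  annotated_exons <- GRanges(exu$chrom, IRanges(exu$start, exu$end),
                             strand = exu$strand)
  structure(
    list(genes = genes, transcripts = transcripts,
         annotated_introns = annotated_introns,
         annotated_exons = annotated_exons,
         intron_keys = interval_key(intr$chrom, intr$strand, intr$start,
                                    intr$end),
         exon_keys = interval_key(exu$chrom, exu$strand, exu$start, exu$end),
         genome = genome, representative_tag = representative_tag),
    class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf(paste0("<annotation_catalog> %d gene(s), %d transcript(s), ",
                     "%d annotated intron(s), %d annotated exon(s)\n"),
              length(x$genes), length(x$transcripts),
              length(x$annotated_introns), length(x$annotated_exons)))
  invisible(x)
}

#' Write an annotation catalog back to GTF
#'
#' Emits transcript/exon/CDS records (and the representative-transcript `tag`
#' attribute) so that reloading with [load_annotation()] reproduces the same
#' interval sets.
#'
#' @param catalog an `annotation_catalog`.
#' @param gtf_path output path.
#' @return `gtf_path`, invisibly.
#' @export
write_annotation <- function(catalog, gtf_path) {
  rep_ids <- unlist(lapply(catalog$genes, function(g) g$representative_id))
  out <- models_to_granges(catalog$transcripts, rep_ids,
                           catalog$representative_tag)
  rtracklayer::export(sort(out), gtf_path, format = "gtf")
  invisible(gtf_path)
}

# transcript models -> GTF-style GRanges (exon + CDS rows, with cov and the
# representative tag where applicable)
models_to_granges <- function(transcripts, rep_ids = character(0),
                              representative_tag = "MANE_Select") {
  rep_ids <- rep_ids[!is.na(rep_ids)]
  rows <- list()
  for (tx in transcripts) {
    tagv <- if (tx$transcript_id %in% rep_ids) representative_tag
            else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = tx$chrom, start = tx$exon_starts, end = tx$exon_ends,
      strand = tx$strand, type = "exon", gene_id = tx$gene_id,
      transcript_id = tx$transcript_id, tag = tagv,
      cov = if (!is.null(tx$cov)) tx$cov else NA_real_,
      phase = NA_integer_)
    if (!is.na(tx$cds_start)) {
      cs <- pmax(tx$exon_starts, tx$cds_start)
      ce <- pmin(tx$exon_ends, tx$cds_end)
      keep <- which(cs <= ce)
      ord <- if (tx$strand == "+") keep else rev(keep)
      w <- ce[ord] - cs[ord] + 1L
      phase <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
      if (tx$strand == "-") phase <- rev(phase)  # back to genomic order
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = cs[keep], end = ce[keep],
        strand = tx$strand, type = "CDS", gene_id = tx$gene_id,
        transcript_id = tx$transcript_id, tag = tagv, cov = NA_real_,
        phase = phase)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df$phase)) df$phase <- NA_integer_
  out <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  out$type <- df$type
  out$source <- "nexon"
  out$gene_id <- df$gene_id
  out$transcript_id <- df$transcript_id
  out$phase <- df$phase
  if (any(!is.na(df$tag))) out$tag <- df$tag
  if (any(!is.na(df$cov))) out$cov <- df$cov
  out
}
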