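#' Extract splice junctions and read offsets from a SAM file
#'
#' Walks the CIGAR string of every aligned read and emits one record per
#' distinct (junction, sample): the intron spanned by each `N` operation,
#' together with the distribution of read offsets. The offset of a split read
#' is the number of read bases (query-consuming CIGAR operations, including
#' soft clips) preceding the junction, i.e. the distance from the read 5' end
#' to the last exonic base before the junction. Reads with several `N`
#' operations contribute one junction each, with its own offset.
#'
#' Reads whose CIGAR string is malformed are skipped (with a message); reads
#' below the MAPQ floor are ignored.
#'
#' @param sam_path path to a SAM file (sorted or unsorted) with a valid
#'   header.
#' @param sample_id sample label attached to every record.
#' @param mapq_min minimum mapping quality; reads below it are ignored
#'   (default 0 = count all; missing MAPQ counts as passing).
#' @return a data.frame of class `junction_records` with columns `sample`,
#'   `chrom`, `start`, `end` (the intron, 1-based closed), `count` (total
#'   split reads) and a list column `offsets` (named integer vector: offset
#'   -> read count). Zero junctions yield a zero-row frame.
#' @export
extract_junctions <- function(sam_path, sample_id, mapq_min = 0) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  lines <- readLines(sam_path)
  body <- !startsWith(lines, "@")
  cig_field <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                      function(f) if (length(f) >= 6) f[6] else "",
                      character(1))
  ok <- grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cig_field)
  if (any(!ok)) {
    message(sum(!ok), " read(s) with malformed CIGAR skipped")
    keep <- rep(TRUE, length(lines))
    keep[which(body)[!ok]] <- FALSE
    sam_path2 <- tempfile(fileext = ".sam")
    writeLines(lines[keep], sam_path2)
    sam_path <- sam_path2
  }
  bam <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "mapq"))
  mapq <- mcols(gal)$mapq
  keep <- is.na(mapq) | mapq >= mapq_min
  gal <- gal[keep]

  cig <- GenomicAlignments::cigar(gal)
  has_n <- grepl("N", cig, fixed = TRUE)
  gal <- gal[has_n]
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      count = integer(0))
  if (length(gal) == 0) {
    empty$offsets <- I(list())
    class(empty) <- c("junction_records", "data.frame")
    return(empty)
  }
  ops <- GenomicAlignments::explodeCigarOps(GenomicAlignments::cigar(gal))
  lens <- GenomicAlignments::explodeCigarOpLengths(GenomicAlignments::cigar(gal))
  pos <- start(gal)
  chrom <- as.character(seqnames(gal))

  recs <- vector("list", length(gal))
  for (i in seq_along(gal)) {
    op <- ops[[i]]; ln <- lens[[i]]
    refpos <- pos[i]; qpos <- 0L
    out <- list()
    for (j in seq_along(op)) {
      o <- op[j]; l <- ln[j]
      if (o == "N") {
        out[[length(out) + 1L]] <- c(refpos, refpos + l - 1L, qpos)
        refpos <- refpos + l
      } else if (o %in% c("M", "=", "X")) {
        refpos <- refpos + l; qpos <- qpos + l
      } else if (o %in% c("I", "S")) {
        qpos <- qpos + l
      } else if (o == "D") {
        refpos <- refpos + l
      } # H, P consume nothing relevant
    }
    recs[[i]] <- do.call(rbind, out)
  }
  nj <- vapply(recs, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  mat <- do.call(rbind, recs)
  df <- data.frame(chrom = rep(chrom, nj), start = mat[, 1], end = mat[, 2],
                   offset = mat[, 3])
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  offs <- lapply(split(df$offset, key), function(o) {
    t <- table(o)
    setNames(as.integer(t), names(t))
  })
  u <- df[!duplicated(key), c("chrom", "start", "end")]
  ukey <- paste(u$chrom, u$start, u$end, sep = ":")
  res <- data.frame(sample = sample_id, chrom = u$chrom,
                    start = as.integer(u$start), end = as.integer(u$end))
  res$offsets <- I(unname(offs[ukey]))
  res$count <- vapply(res$offsets, sum, numeric(1))
  res <- res[order(res$chrom, res$start, res$end),
             c("sample", "chrom", "start", "end", "count", "offsets")]
  rownames(res) <- NULL
  class(res) <- c("junction_records", "data.frame")
  res
}

#' Shannon entropy of a junction offset distribution
#'
#' \eqn{-\sum_i p_i \log_2 p_i} over the offset frequencies of a junction,
#' in bits. Single-offset junctions have entropy 0; `k` equally used offsets
#' have entropy `log2(k)`.
#'
#' @param offset_counts named or unnamed vector of positive read counts per
#'   offset.
#' @return entropy in bits.
#' @export
offset_entropy <- function(offset_counts) {
  offset_counts <- as.numeric(offset_counts)
  if (length(offset_counts) == 0 || sum(offset_counts) <= 0)
    stop("offset_counts must contain at least one positive count")
  p <- offset_counts / sum(offset_counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Filter junctions by offset entropy and canonical splice sites
#'
#' Retains junctions whose offset-distribution Shannon entropy is at least
#' `entropy_min` bits and whose boundary dinucleotides are canonical GT/AG on
#' one strand. Strand is assigned from the dinucleotides (GT...AG on the
#' genomic sequence gives `+`, CT...AC gives `-`), not from alignment flags;
#' junctions matching neither are dropped and counted in a message.
#'
#' @param records a `junction_records` frame from [extract_junctions()].
#' @param genome a `DNAStringSet` covering all junction chromosomes.
#' @param entropy_min entropy threshold in bits (default 1.5).
#' @return a data.frame of class `junction_table` with columns `sample`,
#'   `chrom`, `start`, `end`, `strand`, `count`, `entropy` and the `offsets`
#'   list column. The numbers of records dropped by each filter are stored in
#'   `attr(, "dropped")`.
#' @export
filter_junctions <- function(records, genome, entropy_min = 1.5) {
  n <- nrow(records)
  if (n == 0) {
    res <- records
    res$strand <- character(0)
    res$entropy <- numeric(0)
    class(res) <- c("junction_table", "data.frame")
    attr(res, "dropped") <- c(entropy = 0L, noncanonical = 0L)
    return(res)
  }
  ent <- vapply(records$offsets, offset_entropy, numeric(1))
  strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (records$end[i] - records$start[i] + 1 < 4) next
    if (is_canonical(genome, records$chrom[i], records$start[i],
                     records$end[i], "+")) strand[i] <- "+"
    else if (is_canonical(genome, records$chrom[i], records$start[i],
                          records$end[i], "-")) strand[i] <- "-"
  }
  keep_ent <- ent >= entropy_min
  keep_can <- !is.na(strand)
  dropped <- c(entropy = sum(!keep_ent),
               noncanonical = sum(keep_ent & !keep_can))
  if (sum(!(keep_ent & keep_can)) > 0)
    message(sum(!keep_ent), " junction(s) failed the entropy filter, ",
            sum(keep_ent & !keep_can), " further failed the GT/AG filter")
  res <- records[keep_ent & keep_can, , drop = FALSE]
  res$strand <- strand[keep_ent & keep_can]
  res$entropy <- ent[keep_ent & keep_can]
  res <- res[, c("sample", "chrom", "start", "end", "strand", "count",
                 "entropy", "offsets")]
  rownames(res) <- NULL
  class(res) <- c("junction_table", "data.frame")
  attr(res, "dropped") <- dropped
  res
}

#' Combine junction tables from several samples
#'
#' @param ... `junction_table` (or `junction_records`) frames.
#' @return a single frame with the union of rows.
#' @export
bind_junctions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Look up pooled split-read counts for a junction
#'
#' @param junctions a junction table/records frame.
#' @param chrom,start,end the intron interval.
#' @param samples optional character vector restricting the pooling to a set
#'   of samples.
#' @return total split-read count (0 when absent).
#' @export
junction_count <- function(junctions, chrom, start, end, samples = NULL) {
  sel <- junctions$chrom == chrom & junctions$start == start &
    junctions$end == end
  if (!is.null(samples)) sel <- sel & junctions$sample %in% samples
  sum(junctions$count[sel])
}

#' Write / read a junction table as TSV
#'
#' Columns: sample, chrom, start, end, strand, count, entropy, offsets
#' (encoded `offset:count` comma-separated).
#'
#' @param table a `junction_table` frame.
#' @param path output TSV path.
#' @return `path` (write) or the reconstructed `junction_table` (read).
#' @export
write_junction_table <- function(table, path) {
  df <- as.data.frame(table[, c("sample", "chrom", "start", "end")])
  df$strand <- if ("strand" %in% names(table)) table$strand else "."
  df$count <- table$count
  df$entropy <- if ("entropy" %in% names(table)) table$entropy
                else vapply(table$offsets, offset_entropy, numeric(1))
  df$offsets <- vapply(table$offsets, function(o)
    paste(names(o), o, sep = ":", collapse = ","), character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(sample = "character", chrom = "character",
                                  offsets = "character"))
  offs <- lapply(strsplit(df$offsets, ",", fixed = TRUE), function(x) {
    kv <- strsplit(x, ":", fixed = TRUE)
    setNames(vapply(kv, function(p) as.integer(p[2]), integer(1)),
             vapply(kv, `[`, character(1), 1))
  })
  res <- df[, c("sample", "chrom", "start", "end", "strand", "count",
                "entropy")]
  res$offsets <- I(offs)
  class(res) <- c("junction_table", "data.frame")
  res
}
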