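# Shared toy fixtures and independent oracles. Oracles here deliberately use
# plain string operations (chartr, substring) rather than the package's
# Biostrings-based code paths.

suppressPackageStartupMessages(library(GenomicRanges))

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# independent mRNA construction + first-stop scan + 50-nt rule
oracle_classify <- function(chrom_seq, strand, exon_starts, exon_ends,
                            cds_start, cds_end, rule_nt = 50) {
  seqs <- substring(chrom_seq, exon_starts, exon_ends)
  mrna <- paste(seqs, collapse = "")
  if (strand == "-") mrna <- oracle_revcomp(mrna)
  w <- exon_ends - exon_starts + 1L
  g2m <- function(g) {
    i <- which(exon_starts <= g & exon_ends >= g)
    if (strand == "+") sum(w[seq_len(i - 1)]) + g - exon_starts[i] + 1L
    else sum(w[-seq_len(i)]) + exon_ends[i] - g + 1L
  }
  cs <- g2m(if (strand == "+") cds_start else cds_end)
  stop_annot <- g2m(if (strand == "+") cds_end else cds_start)
  last_junction <- nchar(mrna) - (if (strand == "+") w[length(w)] else w[1])
  pos <- cs
  stop_end <- NA_integer_
  while (pos + 2 <= nchar(mrna)) {
    if (substring(mrna, pos, pos + 2) %in% c("TAA", "TAG", "TGA")) {
      stop_end <- pos + 2L
      break
    }
    pos <- pos + 3L
  }
  if (is.na(stop_end)) return(list(verdict = "coding", distance = NA))
  if (stop_end >= stop_annot) return(list(verdict = "coding", distance = NA))
  d <- last_junction - stop_end
  list(verdict = if (d >= rule_nt) "poison" else "coding", distance = d)
}

toy_genome <- function(...) {
  Biostrings::DNAStringSet(unlist(list(...)))
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a three-exon plus-strand toy gene with a cryptic exon planted in intron 1
# whose single stop codon sits at a controlled distance from the last
# junction: distance = plant_len + w2 - stop_offset - 3 (see test-nmd)
make_boundary_locus <- function(w2, stop_offset, w1 = 90, plant_len = 45,
                                w3 = 90, intron = 100) {
  e1 <- rand_dna(w1, c("A", "C", "G"))
  e2 <- rand_dna(w2, c("A", "C", "G"))
  e3 <- rand_dna(w3, c("A", "C", "G"))
  plant <- rand_dna(plant_len, c("A", "C", "G"))
  substr(plant, stop_offset + 1, stop_offset + 3) <- "TAA"
  i1 <- paste0("GT", rand_dna(intron - 4), "AG")
  i2 <- paste0("GT", rand_dna(intron - 4), "AG")
  # plant sits mid intron 1 with canonical AG / GT around it
  p_off <- 40L
  substr(i1, p_off - 1, p_off + plant_len + 2) <-
    paste0("AG", plant, "GT")
  chrom <- paste0(e1, i1, e2, i2, e3)
  tx <- transcript_model("toy.t1", "toy", "chrT", "+",
                         exon_starts = c(1, w1 + intron + 1,
                                         w1 + intron + w2 + intron + 1),
                         exon_ends = c(w1, w1 + intron + w2,
                                       w1 + intron + w2 + intron + w3),
                         cds_start = 31, cds_end = nchar(chrom) - 33)
  list(genome = toy_genome(chrT = chrom), tx = tx,
       plant_start = w1 + p_off + 1L,
       plant_end = w1 + p_off + plant_len)
}

# random toy locus for oracle cross-checks: random-content gene (both
# strands) with a random exon planted in a random intron
random_toy_locus <- function() {
  n_ex <- sample(3:5, 1)
  w <- sample(30:90, n_ex, replace = TRUE)
  iw <- sample(80:160, n_ex - 1, replace = TRUE)
  plant_len <- sample(20:70, 1)
  host <- sample(n_ex - 1, 1)
  pieces <- character(0)
  starts <- ends <- integer(n_ex)
  pos <- 1L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos; ends[i] <- pos + w[i] - 1L
    pieces <- c(pieces, rand_dna(w[i]))
    pos <- pos + w[i]
    if (i < n_ex) {
      pieces <- c(pieces, paste0("GT", rand_dna(iw[i] - 4), "AG"))
      pos <- pos + iw[i]
    }
  }
  sense <- paste(pieces, collapse = "")
  intron_s <- ends[host] + 1L
  p_off <- sample(10:(iw[host] - plant_len - 10), 1)
  p_start <- intron_s + p_off
  p_end <- p_start + plant_len - 1L
  substr(sense, p_start, p_end) <- rand_dna(plant_len)
  strand <- sample(c("+", "-"), 1)
  L <- nchar(sense)
  flip <- function(s, e) if (strand == "+") c(s, e) else c(L - e + 1L, L - s + 1L)
  chrom_seq <- if (strand == "+") sense else oracle_revcomp(sense)
  gen <- t(vapply(seq_len(n_ex), function(i) flip(starts[i], ends[i]),
                  numeric(2)))
  gen <- gen[order(gen[, 1]), , drop = FALSE]
  cds_sense <- c(starts[1] + 5L, ends[n_ex] - 5L)
  cdsg <- flip(cds_sense[1], cds_sense[2])
  pg <- flip(p_start, p_end)
  tx <- transcript_model("rt.t1", "rt", "chrR", strand, gen[, 1], gen[, 2],
                         cds_start = min(cdsg), cds_end = max(cdsg))
  list(genome = toy_genome(chrR = chrom_seq), tx = tx, strand = strand,
       chrom_seq = chrom_seq, plant_start = min(pg), plant_end = max(pg))
}

# write a minimal SAM file from read tuples (pos, cigar, seq optional)
write_toy_sam <- function(path, chrom_lens, reads, mapq = 60) {
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    qlen <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar,
                                   perl = TRUE))[[1]]))
    if (is.na(qlen) || qlen == 0) qlen <- 10L
    seq <- r$seq %||% strrep("A", qlen)
    lines <- c(lines, sprintf("r%03d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                              i, r$chrom, r$pos, r$mapq %||% mapq, r$cigar,
                              seq, strrep("I", nchar(seq))))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x
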