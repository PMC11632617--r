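# Ortholog filters for externally produced coordinate mappings (liftover is
# consumed as a table, never computed here) and expression support in another
# species' junction data.

#' Construct a mapped-exon record
#'
#' @param chrom,strand target-assembly location of the mapped exon.
#' @param exon_start,exon_end mapped exon interval.
#' @param up_start,up_end,down_start,down_end mapped flanking intron
#'   boundaries on the target assembly.
#' @param gap_free whether the mapping was gap-free.
#' @return list of class `mapped_exon`.
#' @export
mapped_exon <- function(chrom, strand, exon_start, exon_end,
                        up_start, up_end, down_start, down_end, gap_free) {
  structure(list(chrom = chrom, strand = strand,
                 exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end),
                 up_start = as.integer(up_start), up_end = as.integer(up_end),
                 down_start = as.integer(down_start),
                 down_end = as.integer(down_end),
                 gap_free = isTRUE(gap_free)),
            class = "mapped_exon")
}

#' Accept or reject a cross-species exon mapping
#'
#' A mapping is usable only when it is gap-free and both mapped flanking
#' introns carry canonical GT/AG dinucleotides on the target genome.
#'
#' @param m a [mapped_exon()].
#' @param target_genome `DNAStringSet` of the target assembly (a missing
#'   chromosome is an error).
#' @return `TRUE` or `FALSE`.
#' @export
accept_mapping <- function(m, target_genome) {
  if (!m$chrom %in% names(target_genome))
    stop("chromosome '", m$chrom, "' absent from target genome")
  m$gap_free &&
    is_canonical(target_genome, m$chrom, m$up_start, m$up_end, m$strand) &&
    is_canonical(target_genome, m$chrom, m$down_start, m$down_end, m$strand)
}

#' Is a mapped exon expressed in the target species?
#'
#' Under the default strict reading, the exon counts as expressed when some
#' single sample has at least one split read at *both* flanking junctions.
#' The laxer reading (`mode = "lax"`) requires each boundary to be supported
#' in at least one (possibly different) sample.
#'
#' @param m an accepted [mapped_exon()].
#' @param target_junctions junction table for the target species.
#' @param mode `"strict"` (default) or `"lax"`.
#' @return `TRUE` or `FALSE`.
#' @export
ortholog_expressed <- function(m, target_junctions,
                               mode = c("strict", "lax")) {
  mode <- match.arg(mode)
  samples <- unique(target_junctions$sample)
  per_sample <- vapply(samples, function(s) {
    up <- junction_count(target_junctions, m$chrom, m$up_start, m$up_end,
                         samples = s)
    dn <- junction_count(target_junctions, m$chrom, m$down_start, m$down_end,
                         samples = s)
    c(up = up, dn = dn)
  }, numeric(2))
  if (length(samples) == 0) return(FALSE)
  if (mode == "strict") any(per_sample["up", ] >= 1 & per_sample["dn", ] >= 1)
  else any(per_sample["up", ] >= 1) && any(per_sample["dn", ] >= 1)
}

#' Read a mapping table
#'
#' TSV columns: `chrom`, `strand`, `exon_start`, `exon_end`, `up_start`,
#' `up_end`, `down_start`, `down_end`, `gap_free` (logical/0-1), one row per
#' mapped exon, target-assembly coordinates.
#'
#' @param path TSV path.
#' @return list of [mapped_exon()] records.
#' @export
read_mapping_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character", strand = "character"))
  lapply(seq_len(nrow(df)), function(i)
    mapped_exon(df$chrom[i], df$strand[i], df$exon_start[i], df$exon_end[i],
                df$up_start[i], df$up_end[i], df$down_start[i],
                df$down_end[i], as.logical(df$gap_free[i])))
}
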