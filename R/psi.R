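#' Percent-spliced-in (PSI) of a cassette exon from pooled split reads
#'
#' For each group, the counts of the two inclusion junctions and of the skip
#' (exclusion) junction are pooled across the group's samples, and
#' \deqn{\Psi = \frac{inc_{up} + inc_{down}}{inc_{up} + inc_{down} + 2\,exc}.}
#' The factor 2 balances the read opportunities of the inclusion (two
#' junctions) and exclusion (one junction) isoforms. PSI values whose
#' denominator is below `denominator_min` (default 40) are reported missing.
#' Pooling happens before the ratio is taken, so PSI is invariant to how a
#' group's samples are partitioned.
#'
#' @param junctions a junction table covering all samples.
#' @param cand one cassette candidate / catalog row (list or single-row
#'   data.frame with `chrom`, `exon_start`, `exon_end`, `skip_start`,
#'   `skip_end`).
#' @param grouping named character vector mapping sample -> group (tissue,
#'   cohort, condition).
#' @param denominator_min minimum denominator for a defined PSI.
#' @return data.frame with one row per group: `group`, `inc_upstream`,
#'   `inc_downstream`, `exc`, `denominator`, `psi`.
#' @export
compute_psi <- function(junctions, cand, grouping, denominator_min = 40) {
  groups <- sort(unique(unname(grouping)))
  rows <- lapply(groups, function(g) {
    smp <- names(grouping)[grouping == g]
    iu <- junction_count(junctions, cand$chrom, cand$skip_start,
                         cand$exon_start - 1L, samples = smp)
    id <- junction_count(junctions, cand$chrom, cand$exon_end + 1L,
                         cand$skip_end, samples = smp)
    ex <- junction_count(junctions, cand$chrom, cand$skip_start,
                         cand$skip_end, samples = smp)
    den <- iu + id + 2 * ex
    data.frame(group = g, inc_upstream = iu, inc_downstream = id, exc = ex,
               denominator = den,
               psi = if (den >= denominator_min) (iu + id) / den else NA_real_)
  })
  res <- do.call(rbind, rows)
  res$exon <- paste0(cand$chrom, ":", cand$exon_start, "-", cand$exon_end)
  res
}

#' Exon response between two conditions
#'
#' `delta = psi_a - psi_b`; a missing PSI on either side propagates.
#'
#' @param a,b single rows from [compute_psi()] for the same exon (e.g. CHX
#'   treatment and control).
#' @return data.frame with `exon`, `group_a`, `group_b`, `delta`.
#' @export
delta_psi <- function(a, b) {
  if (!identical(a$exon, b$exon))
    stop("delta_psi: mismatched exons (", a$exon, " vs ", b$exon, ")")
  data.frame(exon = a$exon, group_a = a$group, group_b = b$group,
             delta = a$psi - b$psi)
}

#' Intron splicing index
#'
#' `I / (I + R)` where `I` and `R` are the numbers of reads supporting intron
#' splicing and retention; missing when both are zero.
#'
#' @param I,R non-negative read counts.
#' @return the splicing index, or `NA` when `I + R == 0`.
#' @export
splicing_index <- function(I, R) {
  if (any(I < 0) || any(R < 0)) stop("splicing_index: negative counts")
  ifelse(I + R > 0, I / (I + R), NA_real_)
}

#' Per-sample PSI matrix for a set of exons
#'
#' Computes PSI separately in every sample (each sample is its own pooling
#' group), as required for the tissue-specificity filter.
#'
#' @param junctions junction table.
#' @param catalog `cryptic_catalog` or `cassette_candidates` frame.
#' @param samples character vector of sample ids (default: all in
#'   `junctions`).
#' @param denominator_min see [compute_psi()].
#' @return numeric matrix exons x samples (rownames `chrom:start-end`).
#' @export
psi_by_sample <- function(junctions, catalog, samples = NULL,
                          denominator_min = 40) {
  if (is.null(samples)) samples <- sort(unique(junctions$sample))
  grouping <- setNames(samples, samples)
  m <- matrix(NA_real_, nrow = nrow(catalog), ncol = length(samples),
              dimnames = list(
                paste0(catalog$chrom, ":", catalog$exon_start, "-",
                       catalog$exon_end), samples))
  for (i in seq_len(nrow(catalog))) {
    p <- compute_psi(junctions, catalog[i, ], grouping, denominator_min)
    m[i, p$group] <- p$psi
  }
  m
}

#' Tissue-specific exons: per-tissue median PSI filter
#'
#' Flags exons whose per-tissue median PSI (median over the samples of the
#' tissue, missing values excluded) reaches `min_median` (inclusive) in at
#' least one tissue, and reports the qualifying tissues.
#'
#' @param psi_matrix exons x samples PSI matrix from [psi_by_sample()].
#' @param sample_tissues named character vector mapping sample -> tissue.
#' @param min_median median inclusion threshold (default 0.20).
#' @return data.frame: `exon`, `flagged`, `tissues` (comma-separated
#'   qualifying tissues), plus one `median_<tissue>` column per tissue.
#' @export
tissue_specific_exons <- function(psi_matrix, sample_tissues,
                                  min_median = 0.20) {
  tissues <- sort(unique(unname(sample_tissues)))
  med <- sapply(tissues, function(t) {
    smp <- intersect(colnames(psi_matrix),
                     names(sample_tissues)[sample_tissues == t])
    apply(psi_matrix[, smp, drop = FALSE], 1,
          function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  })
  med <- matrix(med, nrow = nrow(psi_matrix),
                dimnames = list(rownames(psi_matrix), tissues))
  qual <- !is.na(med) & med >= min_median
  res <- data.frame(exon = rownames(psi_matrix),
                    flagged = rowSums(qual) > 0,
                    tissues = apply(qual, 1, function(q)
                      paste(tissues[q], collapse = ",")))
  colnames(med) <- paste0("median_", tissues)
  cbind(res, as.data.frame(med), row.names = NULL)
}

#' Exons responsive to RBP perturbations, and their putative regulators
#'
#' Keeps exons whose strongest response across factors satisfies
#' `max |dPSI| >= exon_min`, and factors with strictly more than
#' `factor_floor` exons at `|dPSI| >= factor_min`.
#'
#' @param delta_matrix numeric matrix exons x factors of dPSI
#'   (perturbation - control); missing entries allowed.
#' @param exon_min minimum absolute response for an exon (default 0.10).
#' @param factor_min per-exon response counted towards a factor (default
#'   0.05).
#' @param factor_floor a factor must regulate strictly more than this many
#'   exons (default 10).
#' @return list with `exons`, `factors` (kept names) and `submatrix`.
#' @export
responsive_exons <- function(delta_matrix, exon_min = 0.10,
                             factor_min = 0.05, factor_floor = 10) {
  stopifnot(is.matrix(delta_matrix))
  amax <- apply(abs(delta_matrix), 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  keep_exon <- !is.na(amax) & amax >= exon_min
  nreg <- colSums(abs(delta_matrix) >= factor_min, na.rm = TRUE)
  keep_factor <- nreg > factor_floor
  list(exons = rownames(delta_matrix)[keep_exon],
       factors = colnames(delta_matrix)[keep_factor],
       submatrix = delta_matrix[keep_exon, keep_factor, drop = FALSE])
}

#' Select candidates for experimental validation
#'
#' Intersection of three filters under NMD inhibition: inclusion-rate change
#' `|dPSI| >= d_min`, host-gene expression increase of at least `fold_min`,
#' and exon boundaries supported by at least `reads_min` split reads. Exons
#' missing from any input are excluded with a message.
#'
#' @param delta named numeric vector exon -> dPSI (treatment - control).
#' @param gene_fold_change named numeric vector gene -> fold change.
#' @param split_support named numeric vector exon -> split reads (minimum
#'   over the two boundaries).
#' @param exon_gene named character vector exon -> host gene.
#' @param d_min,fold_min,reads_min thresholds (defaults 0.05, 4, 10; all
#'   inclusive).
#' @return character vector of exon ids passing all three filters.
#' @export
validation_candidates <- function(delta, gene_fold_change, split_support,
                                  exon_gene, d_min = 0.05, fold_min = 4,
                                  reads_min = 10) {
  exons <- names(delta)
  complete <- exons %in% names(exon_gene) &
    exons %in% names(split_support) &
    unname(exon_gene[exons]) %in% names(gene_fold_change)
  if (any(!complete))
    message(sum(!complete), " exon(s) missing from an input table, excluded")
  exons <- exons[complete]
  keep <- !is.na(delta[exons]) & abs(delta[exons]) >= d_min &
    gene_fold_change[exon_gene[exons]] >= fold_min &
    split_support[exons] >= reads_min
  exons[keep]
}
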