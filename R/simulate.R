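# Synthetic-data generator: self-contained toy genomes, annotations,
# conservation tracks, per-sample assembled models and spliced alignments
# with a planted ground-truth registry, so every pipeline stage is testable
# without external cohorts.

BASES <- c("A", "C", "G", "T")
NONSTOP_CODONS <- {
  all64 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                           paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

rand_seq <- function(n, alphabet = BASES)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

#' Synthetic locus-set configuration
#'
#' Defaults define the standard study conditions of the synthetic cohort: 20
#' multi-exon genes, 15 planted cryptic exons split 73% poison / 20% coding /
#' 7% UTR (echoing the predominance of poison exons among conserved cryptic
#' exons), four tissues, and conservation parameters that give coding
#' sequence a third-codon-position dip absent from poison exons.
#'
#' @param n_genes number of genes (one per synthetic chromosome).
#' @param n_cryptic number of planted cryptic exons.
#' @param class_fractions named fractions for `poison`, `coding`, `utr`.
#' @param exon_count range (min, max) of exons per gene.
#' @param internal_exon_len,flank_exon_len,intron_len length ranges (nt).
#' @param cryptic_len length range for planted exons (coding plants are
#'   rounded to multiples of 3).
#' @param utr5_len,utr3_len UTR lengths inside the terminal exons.
#' @param psi_home,psi_away,psi_annot inclusion-level ranges: planted exons
#'   in their home tissue, elsewhere, and annotated cassette exons.
#' @param chx_multiplier multiplicative effect of NMD inhibition on the
#'   inclusion odds of poison exons (default 3, giving dPSI of the magnitude
#'   seen for validated poison exons).
#' @param tissues tissue labels.
#' @param n_false_positives spurious assembled exons with no conservation.
#' @param fp_psi inclusion level of false-positive exons.
#' @param element_score_annotated,element_score_planted,element_score_background
#'   conserved-element score ranges (0-1000).
#' @param cons_high,cons_third_dip,cons_noise_sd,cons_background per-base
#'   track parameters: high level, third-position dip for coding sequence,
#'   Gaussian noise, and intergenic/unscored background.
#' @param read_len simulated read length (nt).
#' @param pad flanking sequence per chromosome (nt).
#' @return list of class `locus_config`.
#' @export
locus_config <- function(n_genes = 20, n_cryptic = 15,
                         class_fractions = c(poison = 0.73, coding = 0.20,
                                             utr = 0.07),
                         exon_count = c(5, 8),
                         internal_exon_len = c(81, 180),
                         flank_exon_len = c(150, 240),
                         intron_len = c(400, 650),
                         cryptic_len = c(60, 130),
                         utr5_len = 30, utr3_len = 30,
                         psi_home = c(0.3, 0.7), psi_away = c(0, 0.05),
                         psi_annot = c(0.05, 0.95),
                         chx_multiplier = 3,
                         tissues = c("brain", "liver", "muscle", "testis"),
                         n_false_positives = 3, fp_psi = 0.2,
                         element_score_annotated = c(300, 900),
                         element_score_planted = c(600, 950),
                         element_score_background = c(0, 150),
                         cons_high = 3, cons_third_dip = 1.5,
                         cons_noise_sd = 0.5, cons_background = 0.5,
                         read_len = 150, pad = 300) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(class_fractions) - 1) < 1e-6)
  structure(cfg, class = "locus_config")
}

# mRNA (transcription-order) position -> sense-gene position, given sense
# exon intervals in transcription order
mrna_to_sense <- function(exon_starts, exon_ends, mpos) {
  w <- exon_ends - exon_starts + 1L
  cum <- cumsum(w)
  idx <- findInterval(mpos - 1L, c(0L, cum), rightmost.closed = FALSE)
  exon_starts[idx] + (mpos - c(0L, cum)[idx] - 1L)
}

#' Generate a synthetic locus set with planted cryptic exons
#'
#' Builds one gene per synthetic chromosome: a representative multi-exon
#' coding transcript (tagged `MANE_Select`) with a valid ORF spanning its
#' exons, plus a second annotated isoform skipping one internal exon (the
#' annotated cassette exon used for threshold learning). Cryptic exons of
#' known class are planted strictly inside introns: poison plants carry an
#' in-frame stop codon placed so that, after insertion into the
#' representative transcript, its PTC lies at least 50 nt upstream of the
#' final exon junction; coding plants are frame-preserving and stop-free in
#' every frame (alphabet excludes T); UTR plants sit in 5'-UTR introns of
#' genes whose CDS starts downstream of the first intron. The generator
#' self-verifies every plant against [classify_ptc()] and errors on any
#' mismatch. Output is byte-deterministic given the seed.
#'
#' @param config a [locus_config()].
#' @param seed integer seed.
#' @param out_dir output directory for `genome.fa`, `annotation.gtf`,
#'   `truth.tsv` (created if needed).
#' @return list of class `synthetic_truth`: `plants` and `annotated`
#'   data.frames (genomic coordinates, classes, per-tissue psi columns,
#'   frames, CHX multipliers), `events` (all cassette events incl. false
#'   positives, with their three junctions), `catalog` (in-memory
#'   `annotation_catalog`), `config`, `seed` and file `paths`.
#' @export
generate_locus_set <- function(config = locus_config(), seed = 1,
                               out_dir = tempfile("nexon_locus_")) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nf <- config$class_fractions
  n_poison <- round(nf[["poison"]] * config$n_cryptic)
  n_coding <- round(nf[["coding"]] * config$n_cryptic)
  n_utr <- config$n_cryptic - n_poison - n_coding
  if (n_utr < 0) { n_coding <- n_coding + n_utr; n_utr <- 0 }
  if (n_utr > config$n_genes)
    stop("config infeasible: more UTR plants than genes")
  utr_gene_idx <- if (n_utr > 0) sort(sample(config$n_genes, n_utr))
                  else integer(0)

  genes <- vector("list", config$n_genes)
  for (gi in seq_len(config$n_genes)) {
    n_ex <- sample(config$exon_count[1]:config$exon_count[2], 1)
    w <- integer(n_ex)
    w[1] <- sample(config$flank_exon_len[1]:config$flank_exon_len[2], 1)
    w[n_ex] <- sample(config$flank_exon_len[1]:config$flank_exon_len[2], 1)
    if (n_ex > 2)
      w[2:(n_ex - 1)] <-
        sample(config$internal_exon_len[1]:config$internal_exon_len[2],
               n_ex - 2, replace = TRUE)
    utr_design <- gi %in% utr_gene_idx
    utr5 <- if (utr_design) w[1] + 10L else config$utr5_len
    total <- sum(w)
    cds_len <- total - utr5 - config$utr3_len
    cds_len <- cds_len - cds_len %% 3L
    if (cds_len < 60) stop("config infeasible: CDS too short in gene ", gi)
    utr3 <- total - utr5 - cds_len
    mrna <- paste0(rand_seq(utr5), "ATG",
                   paste(sample(NONSTOP_CODONS, cds_len / 3 - 2,
                                replace = TRUE), collapse = ""),
                   "TAA", rand_seq(utr3))
    intron_w <- sample(config$intron_len[1]:config$intron_len[2], n_ex - 1,
                       replace = TRUE)
    # sense-gene coordinates of exons
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- 1L; moff <- 0L
    pieces <- character(0)
    for (i in seq_len(n_ex)) {
      ex_start[i] <- pos
      ex_end[i] <- pos + w[i] - 1L
      pieces <- c(pieces, substring(mrna, moff + 1L, moff + w[i]))
      moff <- moff + w[i]
      pos <- pos + w[i]
      if (i < n_ex) {
        pieces <- c(pieces, paste0("GT", rand_seq(intron_w[i] - 4L), "AG"))
        pos <- pos + intron_w[i]
      }
    }
    sense <- paste(pieces, collapse = "")
    # the annotated cassette exon; for UTR-design genes keep intron 1 (the
    # UTR plant host) clear of its inclusion junctions
    cassette_k <- if (utr_design) sample(3:(n_ex - 1), 1)
                  else sample(2:(n_ex - 1), 1)
    genes[[gi]] <- list(
      gi = gi, n_ex = n_ex, w = w, ex_start = ex_start, ex_end = ex_end,
      intron_w = intron_w, utr_design = utr_design, utr5 = utr5,
      cds_len = cds_len, sense = sense,
      cds_sense = c(mrna_to_sense(ex_start, ex_end, utr5 + 1L),
                    mrna_to_sense(ex_start, ex_end, utr5 + cds_len)),
      cassette_k = cassette_k,
      strand = sample(c("+", "-"), 1))
  }

  # eligible plant slots: CDS introns i <= n_ex - 2 that are not the
  # inclusion junctions of the annotated cassette exon (i != k-1, k), so
  # that no two cassette events share a junction
  slots <- do.call(rbind, lapply(genes, function(g) {
    first_cds_intron <- if (g$utr_design) 2L else 1L
    i <- setdiff(first_cds_intron:(g$n_ex - 2L),
                 c(g$cassette_k - 1L, g$cassette_k))
    if (length(i) == 0) return(NULL)
    data.frame(gi = g$gi, intron = i)
  }))
  slots <- slots[sample(nrow(slots)), ]
  need <- n_poison + n_coding + config$n_false_positives
  if (need > nrow(slots))
    stop("config infeasible: ", need, " plant slots needed, ",
         nrow(slots), " available")
  classes <- c(rep("poison", n_poison), rep("coding", n_coding),
               rep("fp", config$n_false_positives))
  slots <- slots[seq_along(classes), ]
  slots$class <- classes
  if (n_utr > 0)
    slots <- rbind(slots, data.frame(gi = utr_gene_idx, intron = 1L,
                                     class = "utr"))

  plants <- list()
  for (r in seq_len(nrow(slots))) {
    g <- genes[[slots$gi[r]]]
    i <- slots$intron[r]
    cls <- slots$class[r]
    len <- switch(cls,
      coding = 3L * sample(ceiling(config$cryptic_len[1] / 3):
                           floor(config$cryptic_len[2] / 3), 1),
      sample(config$cryptic_len[1]:config$cryptic_len[2], 1))
    intron_start <- g$ex_end[i] + 1L
    intron_len <- g$intron_w[i]
    if (intron_len < len + 200L)
      stop("config infeasible: intron too short for plant")
    off <- sample(100:(intron_len - len - 100L), 1)
    p_start <- intron_start + off          # sense coordinates
    p_end <- p_start + len - 1L
    # CDS nucleotides upstream of the host intron
    iprime <- sum(g$w[seq_len(i)]) - g$utr5
    seqc <- switch(cls,
      poison = {
        s <- strsplit(paste0("CC", rand_seq(len - 2L, c("A", "C", "G"))),
                      "")[[1]]
        o <- 6L + ((3L - ((iprime + 6L) %% 3L)) %% 3L)  # codon-aligned
        s[(o + 1L):(o + 3L)] <- c("T", "A", "A")
        paste(s, collapse = "")
      },
      coding = paste0("CC", rand_seq(len - 2L, c("A", "C", "G"))),
      utr = rand_seq(len),
      fp = rand_seq(len))
    frame <- if (cls == "coding") (3L - (iprime %% 3L)) %% 3L else NA_integer_
    psi <- setNames(runif(length(config$tissues), config$psi_away[1],
                          config$psi_away[2]), config$tissues)
    home <- sample(config$tissues, 1)
    psi[home] <- runif(1, config$psi_home[1], config$psi_home[2])
    if (cls == "fp") psi[] <- config$fp_psi
    plants[[r]] <- list(gi = g$gi, intron = i, class = cls,
                        sense_start = p_start, sense_end = p_end,
                        seq = seqc, frame = frame, psi = psi,
                        home_tissue = if (cls == "fp") NA_character_ else home,
                        chx_multiplier = if (cls == "poison")
                          config$chx_multiplier else 1)
  }

  # write plant sequences into the sense strings, with canonical acceptor /
  # donor dinucleotides on the newly created flanking introns
  for (p in plants) {
    g <- genes[[p$gi]]
    substr(g$sense, p$sense_start, p$sense_end) <- p$seq
    substr(g$sense, p$sense_start - 2L, p$sense_start - 1L) <- "AG"
    substr(g$sense, p$sense_end + 1L, p$sense_end + 2L) <- "GT"
    genes[[p$gi]] <- g
  }

  # assemble chromosomes and genomic coordinates
  chrom_seqs <- character(config$n_genes)
  names(chrom_seqs) <- sprintf("chr%d", seq_len(config$n_genes))
  sense_to_genomic <- function(g, s, e) {
    glen <- nchar(g$sense) + 2L * config$pad
    if (g$strand == "+") c(s + config$pad, e + config$pad)
    else c(glen - (e + config$pad) + 1L, glen - (s + config$pad) + 1L)
  }
  transcripts <- list()
  rep_ids <- character(0)
  for (g in genes) {
    chrom <- sprintf("chr%d", g$gi)
    full <- paste0(rand_seq(config$pad), g$sense, rand_seq(config$pad))
    if (g$strand == "-")
      full <- as.character(reverseComplement(DNAString(full)))
    chrom_seqs[chrom] <- full
    gen <- t(vapply(seq_len(g$n_ex), function(i)
      sense_to_genomic(g, g$ex_start[i], g$ex_end[i]), numeric(2)))
    cdsg <- sense_to_genomic(g, g$cds_sense[1], g$cds_sense[2])
    gid <- sprintf("G%02d", g$gi)
    t1 <- sprintf("G%02d.t1", g$gi)
    t2 <- sprintf("G%02d.t2", g$gi)
    transcripts[[t1]] <- transcript_model(
      t1, gid, chrom, g$strand, gen[, 1], gen[, 2],
      cds_start = cdsg[1], cds_end = cdsg[2])
    keep <- setdiff(seq_len(g$n_ex), g$cassette_k)
    transcripts[[t2]] <- transcript_model(
      t2, gid, chrom, g$strand, gen[keep, 1], gen[keep, 2])
    rep_ids <- c(rep_ids, t1)
  }
  genome <- DNAStringSet(chrom_seqs)

  catalog <- build_catalog(models_to_granges(transcripts, rep_ids), genome)

  tissues <- config$tissues
  plant_rows <- lapply(plants, function(p) {
    g <- genes[[p$gi]]
    chrom <- sprintf("chr%d", p$gi)
    pe <- sense_to_genomic(g, p$sense_start, p$sense_end)
    skip <- sense_to_genomic(g, g$ex_end[p$intron] + 1L,
                             g$ex_start[p$intron + 1L] - 1L)
    df <- data.frame(gene_id = sprintf("G%02d", p$gi), chrom = chrom,
                     strand = g$strand, class = p$class,
                     exon_start = pe[1], exon_end = pe[2],
                     skip_start = skip[1], skip_end = skip[2],
                     frame = p$frame, home_tissue = p$home_tissue,
                     chx_multiplier = p$chx_multiplier)
    for (t in tissues) df[[paste0("psi_", t)]] <- unname(p$psi[t])
    df
  })
  plant_df <- do.call(rbind, plant_rows)
  annot_rows <- lapply(genes, function(g) {
    chrom <- sprintf("chr%d", g$gi)
    k <- g$cassette_k
    pe <- sense_to_genomic(g, g$ex_start[k], g$ex_end[k])
    skip <- sense_to_genomic(g, g$ex_end[k - 1L] + 1L,
                             g$ex_start[k + 1L] - 1L)
    df <- data.frame(gene_id = sprintf("G%02d", g$gi), chrom = chrom,
                     strand = g$strand, class = "annotated",
                     exon_start = pe[1], exon_end = pe[2],
                     skip_start = skip[1], skip_end = skip[2],
                     frame = NA_integer_, home_tissue = NA_character_,
                     chx_multiplier = 1)
    for (t in tissues) df[[paste0("psi_", t)]] <- runif(1,
      config$psi_annot[1], config$psi_annot[2])
    df
  })
  annot_df <- do.call(rbind, annot_rows)
  events <- rbind(annot_df, plant_df)
  events$event_id <- sprintf("E%03d", seq_len(nrow(events)))
  rownames(events) <- NULL

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                gtf = file.path(out_dir, "annotation.gtf"),
                truth = file.path(out_dir, "truth.tsv"))
  writeXStringSet(genome, paths$genome)
  write_annotation(catalog, paths$gtf)
  write.table(events, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- structure(
    list(plants = plant_df[plant_df$class != "fp", ],
         false_positives = plant_df[plant_df$class == "fp", ],
         annotated = annot_df, events = events, catalog = catalog,
         config = config, seed = seed, paths = paths),
    class = "synthetic_truth")
  verify_truth(truth)
  truth
}

# generator self-check: every plant must classify as planted against the
# representative transcript
verify_truth <- function(truth) {
  cat <- truth$catalog
  expected <- c(poison = "poison", coding = "coding", utr = "utr_5prime")
  for (r in seq_len(nrow(truth$plants))) {
    p <- truth$plants[r, ]
    gene <- cat$genes[[p$gene_id]]
    tx <- gene$transcripts[[gene$representative_id]]
    res <- insert_exon(tx, p$exon_start, p$exon_end, cat$genome)
    cl <- classify_ptc(res)
    if (!identical(cl$verdict, unname(expected[p$class])))
      stop("generator self-verification failed: plant ", p$chrom, ":",
           p$exon_start, "-", p$exon_end, " planted as ", p$class,
           " classified as ", cl$verdict)
  }
  invisible(TRUE)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d gene(s), %d plant(s) (%s), ",
                     "%d false positive(s), seed %d\n"),
              length(x$catalog$genes), nrow(x$plants),
              paste(names(table(x$plants$class)),
                    table(x$plants$class), sep = ":", collapse = ", "),
              nrow(x$false_positives), x$seed))
  invisible(x)
}

#' Generate synthetic conservation tracks
#'
#' Element track (BED-style `GRanges`, scores 0-1000): annotated exons and
#' planted cryptic exons are covered by high-score elements; introns carry
#' sparse low-score background; false-positive exons get none. Per-base
#' track (phyloP-style): coding sequence — annotated CDS and coding plants —
#' shows a third-codon-position dip of `cons_third_dip` below `cons_high`
#' (plus Gaussian noise), while poison and UTR plants are flat-high,
#' mirroring the codon-periodicity contrast between protein-coding and
#' poison exons.
#'
#' @param truth a `synthetic_truth`.
#' @param seed integer seed.
#' @param out_dir output directory for `elements.bed` and
#'   `conservation.bedGraph` (default: the locus set's directory).
#' @return list: `elements` (`GRanges` with score), `track` (per-base
#'   `GRanges`), `paths`.
#' @export
generate_conservation <- function(truth, seed = 1,
                                  out_dir = dirname(truth$paths$genome)) {
  set.seed(seed)
  config <- truth$config
  cat <- truth$catalog

  el <- list()
  for (g in cat$genes) {
    tx <- g$transcripts[[g$representative_id]]
    n <- length(tx$exon_starts)
    el[[length(el) + 1L]] <- data.frame(
      chrom = tx$chrom, start = tx$exon_starts, end = tx$exon_ends,
      score = runif(n, config$element_score_annotated[1],
                    config$element_score_annotated[2]))
    # one low-score background element in the last intron
    ii <- transcript_introns(tx)
    li <- nrow(ii)
    mid <- (ii$start[li] + ii$end[li]) %/% 2L
    el[[length(el) + 1L]] <- data.frame(
      chrom = tx$chrom, start = mid - 25L, end = mid + 24L,
      score = runif(1, config$element_score_background[1],
                    config$element_score_background[2]))
  }
  pl <- truth$plants
  if (nrow(pl) > 0)
    el[[length(el) + 1L]] <- data.frame(
      chrom = pl$chrom, start = pl$exon_start, end = pl$exon_end,
      score = runif(nrow(pl), config$element_score_planted[1],
                    config$element_score_planted[2]))
  eldf <- do.call(rbind, el)
  elements <- sort(GRanges(eldf$chrom, IRanges(eldf$start, eldf$end),
                           score = round(eldf$score, 1)))

  # per-base track over annotated CDS and all planted exons
  pos_chrom <- character(0); pos <- integer(0); val <- numeric(0)
  emit <- function(chrom, positions, values) {
    pos_chrom <<- c(pos_chrom, rep(chrom, length(positions)))
    pos <<- c(pos, positions)
    val <<- c(val, values)
  }
  coding_values <- function(n, offset0) {
    # offset0: codon offset (0 = codon start) of the first position
    off <- (offset0 + seq_len(n) - 1L) %% 3L
    base <- ifelse(off == 2L, config$cons_high - config$cons_third_dip,
                   config$cons_high)
    base + rnorm(n, 0, config$cons_noise_sd)
  }
  flat_values <- function(n, level = config$cons_high)
    level + rnorm(n, 0, config$cons_noise_sd)

  for (g in cat$genes) {
    tx <- g$transcripts[[g$representative_id]]
    cs <- pmax(tx$exon_starts, tx$cds_start)
    ce <- pmin(tx$exon_ends, tx$cds_end)
    keep <- which(cs <= ce)
    ord <- if (tx$strand == "+") keep else rev(keep)
    cds_idx <- 0L
    for (i in ord) {
      n <- ce[i] - cs[i] + 1L
      v <- coding_values(n, cds_idx %% 3L)
      if (tx$strand == "-") v <- rev(v)
      emit(tx$chrom, cs[i]:ce[i], v)
      cds_idx <- cds_idx + n
    }
    # UTR exon parts: flat high
    for (i in seq_along(tx$exon_starts)) {
      s <- tx$exon_starts[i]; e <- tx$exon_ends[i]
      left <- if (s < tx$cds_start) s:min(e, tx$cds_start - 1L) else NULL
      right <- if (e > tx$cds_end) max(s, tx$cds_end + 1L):e else NULL
      for (rng in list(left, right))
        if (!is.null(rng)) emit(tx$chrom, rng, flat_values(length(rng)))
    }
  }
  ev <- rbind(truth$plants, truth$false_positives)
  for (r in seq_len(nrow(ev))) {
    p <- ev[r, ]
    n <- p$exon_end - p$exon_start + 1L
    v <- if (p$class == "coding") {
      offset0 <- (3L - p$frame) %% 3L
      vv <- coding_values(n, offset0)
      if (p$strand == "-") rev(vv) else vv
    } else if (p$class == "fp") {
      flat_values(n, config$cons_background)
    } else {
      flat_values(n)
    }
    emit(p$chrom, p$exon_start:p$exon_end, v)
  }
  track <- sort(GRanges(pos_chrom, IRanges(pos, pos),
                        score = round(val, 4)))

  paths <- list(elements = file.path(out_dir, "elements.bed"),
                track = file.path(out_dir, "conservation.bedGraph"))
  bed <- elements
  names(bed) <- sprintf("el%04d", seq_along(bed))
  bed$score <- as.integer(round(bed$score))
  rtracklayer::export(bed, paths$elements, format = "bed")
  rtracklayer::export(track, paths$track, format = "bedGraph")
  list(elements = elements, track = track, paths = paths)
}

#' Cohort design for the synthetic study
#'
#' @param tissues tissue labels.
#' @param samples_per_tissue samples per tissue (per condition).
#' @param conditions e.g. `"control"` or `c("control", "CHX")`.
#' @param depth expected junction reads per cassette event.
#' @param noise beta overdispersion of per-sample inclusion levels (0 =
#'   plain binomial sampling).
#' @return data.frame with `sample`, `tissue`, `condition`, `depth`,
#'   `noise`.
#' @export
cohort_design <- function(tissues = c("brain", "liver", "muscle", "testis"),
                          samples_per_tissue = 2, conditions = "control",
                          depth = 100, noise = 0) {
  grid <- expand.grid(rep = seq_len(samples_per_tissue), tissue = tissues,
                      condition = conditions, stringsAsFactors = FALSE)
  data.frame(sample = sprintf("s%02d", seq_len(nrow(grid))),
             tissue = grid$tissue, condition = grid$condition,
             depth = depth, noise = noise)
}

# per-sample inclusion probability of an event: CHX raises the inclusion
# odds of poison exons by the multiplier
event_psi <- function(event, tissue, condition) {
  psi <- event[[paste0("psi_", tissue)]]
  if (condition == "CHX" && event$class == "poison" &&
      psi > 0 && psi < 1)
    psi <- plogis(qlogis(psi) + log(event$chx_multiplier))
  psi
}

#' Simulate junction counts for one sample
#'
#' For each cassette event (annotated cassette exons, planted cryptic exons
#' and false positives), inclusion-junction reads are drawn binomially with
#' the event's tissue inclusion level (odds-shifted for poison exons under
#' CHX) at the design depth, independently for the two inclusion junctions;
#' exclusion reads are drawn with the complementary probability. With
#' `noise > 0` the per-sample inclusion level is first drawn from a Beta
#' distribution with that overdispersion.
#'
#' @param truth a `synthetic_truth`.
#' @param design_row one row of [cohort_design()].
#' @param seed integer seed.
#' @return data.frame: `event_id`, `class`, `chrom`, `strand`, event
#'   coordinates, `iu`, `id`, `exc` (inclusion-up, inclusion-down,
#'   exclusion reads) and `sample`.
#' @export
simulate_junction_counts <- function(truth, design_row, seed) {
  set.seed(seed)
  ev <- truth$events
  n <- design_row$depth
  iu <- id <- exc <- integer(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    p <- event_psi(ev[r, ], design_row$tissue, design_row$condition)
    if (design_row$noise > 0 && p > 0 && p < 1) {
      k <- 1 / design_row$noise
      p <- stats::rbeta(1, p * k, (1 - p) * k)
    }
    iu[r] <- rbinom(1, n, p)
    id[r] <- rbinom(1, n, p)
    exc[r] <- rbinom(1, n, 1 - p)
  }
  out <- ev[, c("event_id", "class", "chrom", "strand", "exon_start",
                "exon_end", "skip_start", "skip_end")]
  out$iu <- iu; out$id <- id; out$exc <- exc
  out$sample <- design_row$sample
  rownames(out) <- NULL
  out
}

#' Convert simulated event counts to a junction table
#'
#' Expands each event into its two inclusion junctions and the skip
#' junction, summing counts for junctions shared between events. Offsets are
#' not simulated here (use [simulate_sample()] + [extract_junctions()] for
#' the alignment-level route); the table supports count-based operations
#' such as [compute_psi()].
#'
#' @param counts output of [simulate_junction_counts()] (possibly row-bound
#'   over samples).
#' @return a `junction_table`-like data.frame with `sample`, `chrom`,
#'   `start`, `end`, `strand`, `count`.
#' @export
counts_to_junction_table <- function(counts) {
  long <- rbind(
    data.frame(sample = counts$sample, chrom = counts$chrom,
               start = counts$skip_start, end = counts$exon_start - 1L,
               strand = counts$strand, count = counts$iu),
    data.frame(sample = counts$sample, chrom = counts$chrom,
               start = counts$exon_end + 1L, end = counts$skip_end,
               strand = counts$strand, count = counts$id),
    data.frame(sample = counts$sample, chrom = counts$chrom,
               start = counts$skip_start, end = counts$skip_end,
               strand = counts$strand, count = counts$exc))
  long <- long[long$count > 0, ]
  key <- with(long, paste(sample, chrom, start, end))
  agg <- long[!duplicated(key), ]
  agg$count <- as.integer(tapply(long$count, key, sum)[key[!duplicated(key)]])
  agg <- agg[order(agg$sample, agg$chrom, agg$start, agg$end), ]
  rownames(agg) <- NULL
  class(agg) <- c("junction_table", "data.frame")
  agg
}

#' Simulate one sample: spliced alignments and assembled models
#'
#' Emits single-end 150-nt split reads in SAM format for every junction read
#' drawn by [simulate_junction_counts()] (offsets uniform over 20-130 nt, so
#' the offset-entropy filter passes at modest depth), an assembled-model GTF
#' (the full and skip isoforms of each gene, plus an inclusion isoform for
#' every planted/false-positive exon observed with inclusion reads at both
#' junctions, each exon carrying a `cov` attribute), and a per-exon coverage
#' bedGraph.
#'
#' @param truth a `synthetic_truth`.
#' @param design_row one row of [cohort_design()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list: `sam`, `gtf`, `coverage` (paths) and `counts` (the event
#'   count table).
#' @export
simulate_sample <- function(truth, design_row, seed,
                            out_dir = dirname(truth$paths$genome)) {
  counts <- simulate_junction_counts(truth, design_row, seed)
  genome <- truth$catalog$genome
  config <- truth$config
  sample_id <- design_row$sample

  jt <- counts_to_junction_table(counts)
  read_len <- config$read_len
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)))
  qual <- strrep("I", read_len)
  blocks <- vector("list", nrow(jt))
  rid <- 0L
  for (r in seq_len(nrow(jt))) {
    a <- jt$start[r]; b <- jt$end[r]; chrom <- jt$chrom[r]
    w <- b - a + 1L
    k <- jt$count[r]
    if (k == 0) next
    offs <- sample(20:(read_len - 20L), k, replace = TRUE)
    seqs <- vapply(offs, function(o)
      paste0(genome_seq(genome, chrom, a - o, a - 1L),
             genome_seq(genome, chrom, b + 1L, b + read_len - o)),
      character(1))
    blocks[[r]] <- sprintf(
      "%s.r%06d\t0\t%s\t%d\t60\t%dM%dN%dM\t*\t0\t0\t%s\t%s",
      sample_id, rid + seq_len(k), chrom, a - offs, offs, w,
      read_len - offs, seqs, qual)
    rid <- rid + k
  }
  sam_lines <- c(header, unlist(blocks))
  paths <- list(
    sam = file.path(out_dir, paste0(sample_id, ".sam")),
    gtf = file.path(out_dir, paste0(sample_id, ".models.gtf")),
    coverage = file.path(out_dir, paste0(sample_id, ".coverage.bedGraph")))
  writeLines(sam_lines, paths$sam)

  # assembled models: full + skip isoform per gene, and one inclusion
  # isoform per observed planted / false-positive exon
  models <- list()
  covrows <- list()
  gene_cov <- list()   # per-gene exon coverage, shared by all isoform models
  ev_annot <- counts[counts$class == "annotated", ]
  for (g in truth$catalog$genes) {
    tx <- g$transcripts[[g$representative_id]]
    n <- length(tx$exon_starts)
    gene_ev <- ev_annot[ev_annot$chrom == tx$chrom, ]
    cov <- rep(as.numeric(design_row$depth), n)
    if (nrow(gene_ev) == 1) {
      k <- which(tx$exon_starts == gene_ev$exon_start)
      cov[k] <- (gene_ev$iu + gene_ev$id) / 2
    }
    gene_cov[[g$gene_id]] <- cov
    m1 <- tx; m1$cov <- cov
    m1$transcript_id <- paste0(g$gene_id, ".m1")
    m1$cds_start <- m1$cds_end <- NA_integer_
    models[[m1$transcript_id]] <- m1
    covrows[[length(covrows) + 1L]] <- data.frame(
      chrom = tx$chrom, start = tx$exon_starts, end = tx$exon_ends,
      score = cov)
    skip_tx <- g$transcripts[[setdiff(names(g$transcripts),
                                      g$representative_id)[1]]]
    m2 <- skip_tx
    m2$cov <- rep(as.numeric(design_row$depth),
                  length(skip_tx$exon_starts))
    m2$transcript_id <- paste0(g$gene_id, ".m2")
    models[[m2$transcript_id]] <- m2
  }
  ev_new <- counts[counts$class %in% c("poison", "coding", "utr", "fp") &
                   pmin(counts$iu, counts$id) > 0, ]
  for (r in seq_len(nrow(ev_new))) {
    e <- ev_new[r, ]
    gid <- truth$events$event_id == e$event_id
    gene_id <- truth$events$gene_id[gid]
    g <- truth$catalog$genes[[gene_id]]
    tx <- g$transcripts[[g$representative_id]]
    res <- insert_exon(tx, e$exon_start, e$exon_end, genome)
    if (res$status != "inserted") next
    exon_cov <- (e$iu + e$id) / 2
    m <- transcript_model(
      paste0(gene_id, ".x", sub("^E", "", e$event_id)), gene_id,
      tx$chrom, tx$strand, res$modified_starts, res$modified_ends,
      cov = append(gene_cov[[gene_id]], exon_cov,
                   after = res$intron_index))
    models[[m$transcript_id]] <- m
    covrows[[length(covrows) + 1L]] <- data.frame(
      chrom = tx$chrom, start = e$exon_start, end = e$exon_end,
      score = exon_cov)
  }
  gr <- models_to_granges(models)
  rtracklayer::export(sort(gr), paths$gtf, format = "gtf")

  covdf <- do.call(rbind, covrows)
  covgr <- sort(GRanges(covdf$chrom, IRanges(covdf$start, covdf$end),
                        score = covdf$score))
  rtracklayer::export(covgr, paths$coverage, format = "bedGraph")

  c(paths, list(counts = counts))
}

#' Simulate a whole cohort
#'
#' Runs [simulate_sample()] for every design row (per-sample seeds derived
#' deterministically from `seed`), writes `design.tsv`, and returns the
#' combined count table.
#'
#' @param truth a `synthetic_truth`.
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param write_files when `FALSE`, only junction counts are generated (no
#'   SAM/GTF), which is much faster for count-level analyses.
#' @return list: `design`, `counts` (all samples), `samples` (per-sample
#'   file paths when written), `paths`.
#' @export
simulate_cohort <- function(truth, design, seed = 1,
                            out_dir = dirname(truth$paths$genome),
                            write_files = TRUE) {
  samples <- list()
  counts <- list()
  for (i in seq_len(nrow(design))) {
    # per-sample seed, kept within the 32-bit integer range
    s_seed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    if (write_files) {
      out <- simulate_sample(truth, design[i, ], s_seed, out_dir)
      samples[[design$sample[i]]] <- out
      counts[[i]] <- out$counts
    } else {
      counts[[i]] <- simulate_junction_counts(truth, design[i, ], s_seed)
    }
  }
  design_path <- file.path(out_dir, "design.tsv")
  write.table(design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(design = design, counts = do.call(rbind, counts), samples = samples,
       paths = list(design = design_path, out_dir = out_dir))
}
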