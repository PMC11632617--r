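#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' discovery percentile (0.10), junction entropy floor (1.5 bits), PSI
#' denominator floor (40 reads), PTC rule distance (50 nt), tissue-specific
#' median PSI (0.20), RBP-response thresholds (0.10 per exon, 0.05 per
#' factor, strictly more than 10 exons per factor) and validation-candidate
#' thresholds (dPSI 0.05, 4-fold gene expression, 10 split reads).
#'
#' @param annotation,genome,elements,track input paths (GTF, FASTA, BED,
#'   bedGraph); `track` optional.
#' @param samples data.frame (or TSV path) with columns `sample`, `tissue`,
#'   `condition`, `sam`, `models` (paths per sample).
#' @param out_dir output directory.
#' @param percentile,entropy_min,psi_denominator_min,rule_nt,
#'   tissue_min_median,exon_response_min,factor_response_min,factor_floor,
#'   validation_dpsi_min,validation_fold_min,validation_reads_min,mapq_min,
#'   strand_blind,cons_denominator pipeline parameters (see module docs).
#' @param seed integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return list of class `nexon_config`.
#' @export
nexon_config <- function(annotation = NULL, genome = NULL, elements = NULL,
                         track = NULL, samples = NULL, out_dir = NULL,
                         percentile = 0.10, entropy_min = 1.5,
                         psi_denominator_min = 40, rule_nt = 50,
                         tissue_min_median = 0.20, exon_response_min = 0.10,
                         factor_response_min = 0.05, factor_floor = 10,
                         validation_dpsi_min = 0.05, validation_fold_min = 4,
                         validation_reads_min = 10, mapq_min = 0,
                         strand_blind = FALSE,
                         cons_denominator = "intersection", seed = 1) {
  cfg <- as.list(environment())
  stopifnot(percentile > 0, percentile < 1, entropy_min >= 0, rule_nt > 0,
            psi_denominator_min >= 0)
  structure(cfg, class = "nexon_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take the defaults of
#' [nexon_config()].
#'
#' @param path YAML file.
#' @return a `nexon_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(nexon_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(nexon_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the cryptic-exon pipeline end to end
#'
#' Stages: junction extraction and filtering per sample; cassette-exon
#' discovery with per-sample percentile thresholds and aggregation;
#' inclusion-level quantification (per-tissue pooled PSI, per-sample PSI,
#' tissue specificity, and dPSI between a `CHX` and `control` condition when
#' both are present); 50-nt-rule classification against all transcripts of
#' the host gene; conservation scoring with phase inference when a per-base
#' track is supplied. Writes `catalog.tsv`, `catalog.bed`, `verdicts.tsv`,
#' `psi_tissue.tsv`, `psi_sample.tsv`, `tissue_specific.tsv`, optionally
#' `delta_psi.tsv` and `conservation.tsv`, and a plain-text `report.txt`
#' with per-stage record counts and class proportions. The run is a pure
#' function of inputs and configuration (re-running yields byte-identical
#' outputs).
#'
#' @param config a [nexon_config()] or path to a YAML file.
#' @return invisibly, a list with the main result tables and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "nexon_config"))
  for (p in c("annotation", "genome", "elements"))
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("pipeline stage 'inputs' failed: missing ", p, " file")
  samples <- config$samples
  if (is.character(samples))
    samples <- read.table(samples, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (is.null(samples) || nrow(samples) == 0)
    stop("pipeline stage 'inputs' failed: no samples")
  for (f in c(samples$sam, samples$models))
    if (!file.exists(f))
      stop("pipeline stage 'inputs' failed: missing sample file ", f)
  out_dir <- config$out_dir %||% tempfile("nexon_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  catalog <- run_stage("annotation",
                       load_annotation(config$annotation, config$genome))
  elements <- run_stage("conservation-elements",
                        rtracklayer::import(config$elements, format = "bed"))
  track <- if (!is.null(config$track))
    run_stage("conservation-track",
              rtracklayer::import(config$track, format = "bedGraph"))
  else NULL

  log <- c(sprintf("genes\t%d", length(catalog$genes)),
           sprintf("annotated_introns\t%d", length(catalog$annotated_introns)))

  junctions <- run_stage("junctions", {
    jt <- lapply(seq_len(nrow(samples)), function(i) {
      recs <- extract_junctions(samples$sam[i], samples$sample[i],
                                mapq_min = config$mapq_min)
      filter_junctions(recs, catalog$genome,
                       entropy_min = config$entropy_min)
    })
    bind_junctions(jt)
  })
  log <- c(log, sprintf("junctions_retained\t%d", nrow(junctions)))

  sample_tissues <- setNames(samples$tissue, samples$sample)
  discovery <- run_stage("discovery", {
    selected <- list()
    n_cand <- n_annot <- 0L
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample[i]
      models <- read_models_gtf(samples$models[i])
      cands <- find_cassette_exons(models, catalog, sid)
      cands <- score_candidates(cands, elements, junctions, track = track,
                                cons_denominator = config$cons_denominator)
      ann <- cands[cands$annotated & cands$coverage > 0, ]
      n_cand <- n_cand + sum(!cands$annotated)
      n_annot <- n_annot + nrow(ann)
      thr <- learn_thresholds(ann, percentile = config$percentile,
                              sample_id = sid)
      selected[[sid]] <- select_cryptic(cands, thr, catalog,
                                        strand_blind = config$strand_blind)
    }
    selected <- do.call(rbind, selected)
    list(selected = selected,
         catalog = aggregate_catalog(selected, junctions, sample_tissues),
         n_cand = n_cand, n_annot = n_annot)
  })
  cryptic <- discovery$catalog
  log <- c(log,
           sprintf("candidate_exons_unannotated\t%d", discovery$n_cand),
           sprintf("annotated_cassette_exons_scored\t%d", discovery$n_annot),
           sprintf("selected_exon_records\t%d", nrow(discovery$selected)),
           sprintf("catalog_exons\t%d", nrow(cryptic)))

  quant <- run_stage("quantification", {
    tissue_groups <- sample_tissues
    psi_t <- lapply(seq_len(nrow(cryptic)), function(i)
      compute_psi(junctions, cryptic[i, ], tissue_groups,
                  denominator_min = config$psi_denominator_min))
    psi_tissue <- do.call(rbind, psi_t)
    psi_sample <- psi_by_sample(junctions, cryptic,
                                samples = samples$sample,
                                denominator_min = config$psi_denominator_min)
    ts <- if (nrow(cryptic) > 0)
      tissue_specific_exons(psi_sample, sample_tissues,
                            min_median = config$tissue_min_median)
    else NULL
    dpsi <- NULL
    if (all(c("CHX", "control") %in% samples$condition)) {
      cond <- setNames(samples$condition, samples$sample)
      dpsi <- do.call(rbind, lapply(seq_len(nrow(cryptic)), function(i) {
        p <- compute_psi(junctions, cryptic[i, ], cond,
                         denominator_min = config$psi_denominator_min)
        delta_psi(p[p$group == "CHX", ], p[p$group == "control", ])
      }))
    }
    list(psi_tissue = psi_tissue, psi_sample = psi_sample,
         tissue_specific = ts, dpsi = dpsi)
  })

  verdicts <- run_stage("classification", {
    rows <- lapply(seq_len(nrow(cryptic)), function(i) {
      gr <- GRanges(cryptic$chrom[i],
                    IRanges(cryptic$exon_start[i], cryptic$exon_end[i]),
                    strand = cryptic$strand[i])
      host <- NULL
      for (g in catalog$genes)
        if (g$chrom == cryptic$chrom[i] && g$strand == cryptic$strand[i]) {
          tx <- g$transcripts[[if (!is.na(g$representative_id))
            g$representative_id else names(g$transcripts)[1]]]
          if (cryptic$exon_start[i] >= min(tx$exon_starts) &&
              cryptic$exon_end[i] <= max(tx$exon_ends)) { host <- g; break }
        }
      if (is.null(host))
        return(data.frame(chrom = cryptic$chrom[i],
                          exon_start = cryptic$exon_start[i],
                          exon_end = cryptic$exon_end[i],
                          strand = cryptic$strand[i],
                          gene_id = NA_character_,
                          mane_verdict = "incompatible",
                          group = NA_character_, frameshift = NA,
                          ptc_distance = NA_real_))
      cl <- classify_across_transcripts(host, cryptic$exon_start[i],
                                        cryptic$exon_end[i],
                                        catalog$genome,
                                        rule_nt = config$rule_nt)
      data.frame(chrom = cryptic$chrom[i],
                 exon_start = cryptic$exon_start[i],
                 exon_end = cryptic$exon_end[i],
                 strand = cryptic$strand[i], gene_id = host$gene_id,
                 mane_verdict = cl$mane_verdict, group = cl$group,
                 frameshift = cl$frameshift,
                 ptc_distance = cl$ptc_distance)
    })
    do.call(rbind, rows)
  })

  conservation <- run_stage("conservation", {
    if (nrow(cryptic) == 0) return(NULL)
    gr <- GRanges(cryptic$chrom, IRanges(cryptic$exon_start,
                                         cryptic$exon_end),
                  strand = cryptic$strand)
    res <- data.frame(chrom = cryptic$chrom,
                      exon_start = cryptic$exon_start,
                      exon_end = cryptic$exon_end,
                      weighted_score = weighted_element_scores(
                        gr, elements,
                        denominator = config$cons_denominator))
    if (!is.null(track)) {
      prof <- lapply(seq_len(nrow(cryptic)), function(i)
        infer_phase(track, cryptic$chrom[i], cryptic$exon_start[i],
                    cryptic$exon_end[i], cryptic$strand[i]))
      res$phase <- vapply(prof, function(p) p$phase, integer(1))
      res$mean_pos1 <- vapply(prof, function(p) p$means[1], numeric(1))
      res$mean_pos2 <- vapply(prof, function(p) p$means[2], numeric(1))
      res$mean_pos3 <- vapply(prof, function(p) p$means[3], numeric(1))
    }
    res
  })

  # report: class proportions over the catalog
  nv <- if (is.null(verdicts)) 0L else nrow(verdicts)
  poison <- if (nv) sum(verdicts$mane_verdict == "poison") else 0L
  coding <- if (nv) sum(verdicts$mane_verdict == "coding") else 0L
  other <- nv - poison - coding
  prop <- if (nv > 0) c(poison, coding, other) / nv else c(0, 0, 0)
  groups <- table(factor(if (nv) verdicts$group else character(0),
                         levels = c("APE", "APC", "MIX")))
  log <- c(log,
           sprintf("class_poison\t%d\t%.4f", poison, prop[1]),
           sprintf("class_coding\t%d\t%.4f", coding, prop[2]),
           sprintf("class_other\t%d\t%.4f", other, prop[3]),
           sprintf("group_APE\t%d", groups[["APE"]]),
           sprintf("group_APC\t%d", groups[["APC"]]),
           sprintf("group_MIX\t%d", groups[["MIX"]]))

  wt <- function(x, f) if (!is.null(x))
    write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(cryptic, "catalog.tsv")
  write_catalog_bed(cryptic, file.path(out_dir, "catalog.bed"))
  wt(verdicts, "verdicts.tsv")
  wt(quant$psi_tissue, "psi_tissue.tsv")
  if (!is.null(quant$psi_sample))
    write.table(data.frame(exon = rownames(quant$psi_sample),
                           quant$psi_sample, check.names = FALSE),
                file.path(out_dir, "psi_sample.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  wt(quant$tissue_specific, "tissue_specific.tsv")
  wt(quant$dpsi, "delta_psi.tsv")
  wt(conservation, "conservation.tsv")
  writeLines(log, file.path(out_dir, "report.txt"))

  invisible(list(catalog = cryptic, verdicts = verdicts,
                 junctions = junctions, psi_tissue = quant$psi_tissue,
                 psi_sample = quant$psi_sample,
                 tissue_specific = quant$tissue_specific,
                 dpsi = quant$dpsi, conservation = conservation,
                 selected = discovery$selected, report = log,
                 out_dir = out_dir))
}
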