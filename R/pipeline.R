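## End-to-end orchestration: simulate (or read) inputs, run every
## analysis stage, and assemble summary report tables with their
## backing gene lists.

#' Pipeline configuration
#'
#' Either synthetic mode (a [sim_config()]) or real-input mode (paths to
#' the FASTA/GFF3/variant/expression/motif files written in the package
#' formats); exactly one must be provided.
#'
#' @param sim a [sim_config()] for synthetic mode, or NULL.
#' @param inputs named list of paths (fasta1, gff1, fasta2, gff2,
#'   variants, expression, motifs) for real mode, or NULL.
#' @param outdir optional output directory for report TSVs and gene
#'   lists.
#' @param detection_threshold,alpha analysis thresholds.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL, outdir = NULL,
                            detection_threshold = 25, alpha = 0.05) {
  if (is.null(sim) && is.null(inputs)) stop("either sim or inputs required")
  structure(list(sim = sim, inputs = inputs, outdir = outdir,
                 detection_threshold = detection_threshold, alpha = alpha),
            class = "PipelineConfig")
}

read_pipeline_inputs <- function(inputs) {
  need <- c("fasta1", "gff1", "fasta2", "gff2", "variants", "expression")
  for (k in need) if (is.null(inputs[[k]])) stop("missing input path: ", k)
  for (k in need) {
    if (!file.exists(inputs[[k]])) stop("input file not found: ", inputs[[k]])
  }
  list(
    genome1 = read_genome(inputs$fasta1, inputs$gff1),
    genome2 = read_genome(inputs$fasta2, inputs$gff2),
    variants = read_variants(inputs$variants),
    expr = read_expression(inputs$expression),
    motif_table = if (!is.null(inputs$motifs)) read_motifs(inputs$motifs) else
      default_motif_table(),
    truth = NULL
  )
}

#' Run the full two-variety analysis
#'
#' Stages: data (simulate or read), variant impact, Ka/Ks of
#' variety-1-vs-variety-2 coding sequences, duplication (families,
#' tandem, segmental), mobile elements (CACTA pairing, LTR scan, gene
#' capture), expression divergence, promoter/motif/methylation, and
#' duplication-mode enrichment among divergence classes. Deterministic
#' for a fixed seed; every reported count is backed by a gene list in
#' `$gene_lists`.
#'
#' @param config a [pipeline_config()].
#' @return a `ReportBundle` list of summary tables, the underlying
#'   objects, and `gene_lists`.
#' @export
run_pipeline <- function(config) {
  ds <- if (!is.null(config$inputs)) read_pipeline_inputs(config$inputs) else
    simulate_dataset(config$sim)
  genome1 <- ds$genome1
  genome2 <- ds$genome2
  gene_lists <- list()

  ## ---- variant impact ------------------------------------------------
  impacts <- classify_gene_impacts(genome1, genome2, ds$variants)
  burden <- overlap_counts(genome1, ds$variants)
  ps_genes <- impacts$gene_id[impacts$premature_stop]
  gene_lists$premature_stop <- ps_genes
  gene_lists$snp_genes <- burden$snp_genes
  gene_lists$indel_genes <- burden$indel_genes
  gene_lists$sv_genes <- burden$sv_genes
  gene_lists$deleted_or_cnv <- impacts$gene_id[impacts$deleted_or_cnv]
  variant_tab <- data.frame(
    metric = c("genes_with_snp", "genes_with_indel", "genes_with_sv",
               "premature_stop_genes", "deleted_or_cnv_genes"),
    count = c(length(burden$snp_genes), length(burden$indel_genes),
              length(burden$sv_genes), length(ps_genes),
              sum(impacts$deleted_or_cnv))
  )

  ## ---- Ka/Ks between varieties ---------------------------------------
  cand <- impacts$gene_id[!impacts$premature_stop & !impacts$deleted_or_cnv &
                            (impacts$n_snp > 0 | impacts$n_indel > 0)]
  kaks <- NULL
  if (length(cand) > 0) {
    cds1 <- setNames(vapply(cand, function(g) extract_cds(genome1, g), ""),
                     cand)
    cds2 <- setNames(impacts$variety2_cds[match(cand, impacts$gene_id)],
                     paste0(cand, "_v2"))
    ok <- !vapply(cds2, function(s) {
      p <- suppressWarnings(translate_dna(s))
      grepl("*", substr(p, 1, nchar(p) - 1), fixed = TRUE)
    }, logical(1))
    cand <- cand[ok]
    pairs <- data.frame(id1 = cand, id2 = paste0(cand, "_v2"))
    kaks <- kaks_pairs(pairs, c(cds1, cds2[ok]))
    kaks$gene_id <- kaks$id1
  }
  pos_genes <- if (is.null(kaks)) character(0) else
    kaks$gene_id[!is.na(kaks$ratio) & kaks$ratio > 1 &
                   !is.na(kaks$p_positive) & kaks$p_positive < config$alpha]
  gene_lists$kaks_positive <- pos_genes
  kaks_tab <- data.frame(
    metric = c("pairs_tested", "pairs_accepted", "ratio_gt1",
               "positive_selection"),
    count = c(if (is.null(kaks)) 0 else nrow(kaks),
              if (is.null(kaks)) 0 else sum(kaks$accepted),
              if (is.null(kaks)) 0 else sum(!is.na(kaks$ratio) & kaks$ratio > 1),
              length(pos_genes))
  )

  ## ---- duplication ---------------------------------------------------
  coding <- genome1$genes$gene_id[genome1$genes$coding & !genome1$genes$deleted]
  prots <- setNames(vapply(coding, function(g) {
    suppressWarnings(translate_dna(extract_cds(genome1, g)))
  }, ""), coding)
  hits <- all_vs_all_hits(prots)
  families <- cluster_families(hits)
  tandem <- score_tandem(genome1, families)
  blocks <- find_segmental_blocks(genome1, hits)
  tandem_genes <- unique(c(tandem$gene1, tandem$gene2))
  seg_genes <- segmental_genes(blocks)
  gene_lists$tandem <- tandem_genes
  gene_lists$segmental <- seg_genes
  dup_tab <- data.frame(
    metric = c("families", "tandem_pairs", "tandem_genes",
               "segmental_blocks", "segmental_genes"),
    count = c(length(unique(families$family_id)), nrow(tandem),
              length(tandem_genes), length(blocks), length(seg_genes))
  )

  ## ---- mobile elements -----------------------------------------------
  tir_seeds <- c(tir = if (!is.null(ds$config)) ds$config$tir_seed_seq else
    "CACTACAAGAAAATGGTGGG")
  term_hits <- find_terminal_hits(genome1, tir_seeds)
  cacta <- pair_cacta(genome1, term_hits)
  ltr <- naive_ltr_scan(genome1)
  cap <- capture_genes(rbind(cacta, ltr), genome1)
  rel <- cap$related_genes
  gene_lists$cacta_related <- unique(rel$gene_id[rel$class == "CACTA"])
  gene_lists$ltr_related <- unique(rel$gene_id[rel$class == "LTR"])
  elem_tab <- data.frame(
    metric = c("cacta_elements", "ltr_elements", "cacta_related_genes",
               "ltr_related_genes"),
    count = c(nrow(cacta), nrow(ltr), length(gene_lists$cacta_related),
              length(gene_lists$ltr_related))
  )

  ## ---- expression ----------------------------------------------------
  expr <- normalize_expression(ds$expr)
  det <- detect_expressed(expr, config$detection_threshold)
  div <- classify_divergence(expr, det)
  varieties <- attr(div, "varieties")
  profile_tab <- do.call(rbind, lapply(varieties, function(v) {
    cc <- det$condition_class[, v]
    data.frame(variety = v,
               normal_only = sum(cc == "normal_only"),
               treated_only = sum(cc == "treated_only"),
               both = sum(cc == "both"),
               expressed_total = sum(cc != "none"))
  }))
  six <- c("specific_v1", "specific_v2", "fold2_v1", "fold2_v2",
           "sucrose_only_v1", "sucrose_only_v2")
  class_gene_sets <- lapply(six, function(cl) {
    unique(div$gene_id[div[[cl]] & !is.na(div$gene_id)])
  })
  names(class_gene_sets) <- six
  gene_lists <- c(gene_lists, class_gene_sets)
  div_tab <- data.frame(
    class = c(six, "any_divergent_probes", "any_divergent_genes"),
    count = c(vapply(six, function(cl) sum(div[[cl]]), 0L),
              sum(div$divergent),
              length(unique(div$gene_id[div$divergent & !is.na(div$gene_id)])))
  )
  bins_tab <- do.call(rbind, lapply(seq_along(varieties), function(i) {
    b <- div[[paste0("abundance_bin_v", i)]]
    b <- b[!is.na(b)]
    data.frame(variety = varieties[i],
               bin = c("low", "middle", "high", "very_high"),
               fraction = as.numeric(table(factor(
                 b, levels = c("low", "middle", "high", "very_high"))) /
                 length(b)))
  }))

  ## ---- promoters / motifs / methylation ------------------------------
  proms <- extract_promoters(genome1, genome2, L = 1500)
  de_genes <- unique(unlist(class_gene_sets))
  frac_all <- variation_fractions(proms)
  frac_de <- if (sum(proms$gene_id %in% de_genes) > 0) {
    variation_fractions(proms, de_genes)
  } else c(with_variation = NA, without_variation = NA)
  prom_tab <- data.frame(
    subset = c("all_genes", "all_genes", "differentially_expressed",
               "differentially_expressed"),
    state = rep(c("with_variation", "without_variation"), 2),
    fraction = c(frac_all, frac_de)
  )
  proms1k <- extract_promoters(genome1, genome2, L = 1000)
  de1k <- proms1k[proms1k$gene_id %in% de_genes, , drop = FALSE]
  motif_tab <- NULL
  if (nrow(de1k) > 0) {
    s1 <- scan_motifs(setNames(de1k$seq_v1, de1k$gene_id), ds$motif_table)
    s2 <- scan_motifs(setNames(de1k$seq_v2, de1k$gene_id), ds$motif_table)
    motif_tab <- motif_overrepresentation(s1, s2)
  }
  meth_tab <- NULL
  if (!is.null(ds$bisulfite) && length(ds$bisulfite) > 0) {
    gids <- unique(vapply(ds$bisulfite, function(b) b$gene_id, ""))
    meth_tab <- do.call(rbind, lapply(gids, function(g) {
      b1 <- ds$bisulfite[[paste0(g, "_v1")]]
      b2 <- ds$bisulfite[[paste0(g, "_v2")]]
      mm <- call_methylation(b1$reference, b1$clones, b2$clones)
      data.frame(gene_id = g, n_sites = nrow(mm),
                 n_differential = sum(!is.na(mm$p_value) &
                                        mm$p_value < config$alpha))
    }))
  }

  ## ---- duplication modes vs expression divergence --------------------
  pairs_by_mode <- list(
    tandem = tandem[, c("gene1", "gene2")],
    segmental = do.call(rbind, lapply(blocks, function(b) b$anchors))
  )
  dup_div <- duplication_expression_divergence(pairs_by_mode, div, det)
  mode_map <- rbind(
    data.frame(gene_id = gene_lists$tandem, category_id = "tandem"),
    data.frame(gene_id = gene_lists$segmental, category_id = "segmental"),
    data.frame(gene_id = gene_lists$ltr_related, category_id = "LTR"),
    data.frame(gene_id = gene_lists$cacta_related, category_id = "CACTA")
  )
  background <- genome1$genes$gene_id
  enrich <- do.call(rbind, lapply(six, function(cl) {
    focal <- class_gene_sets[[cl]]
    if (length(focal) == 0) return(NULL)
    e <- overrepresentation(focal, mode_map, background)
    e$class <- cl
    e
  }))

  report <- structure(list(
    expression_profile = profile_tab,
    divergence_classes = div_tab,
    abundance_bins = bins_tab,
    variant_impact = variant_tab,
    kaks_summary = kaks_tab,
    duplication = dup_tab,
    elements = elem_tab,
    promoter_variation = prom_tab,
    motif_overrepresentation = motif_tab,
    methylation = meth_tab,
    dup_expression_divergence = dup_div,
    mode_enrichment = enrich,
    gene_lists = gene_lists,
    objects = list(impacts = impacts, kaks = kaks, families = families,
                   tandem = tandem, blocks = blocks, elements = cap$elements,
                   related_genes = rel, divergence = div, detection = det,
                   promoters = proms, truth = ds$truth)
  ), class = "ReportBundle")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Expression divergence of duplicate pairs, by duplication mode
#'
#' A pair is expression-divergent within a variety when its members
#' differ in detection call or differ by at least 2-fold in mean
#' normal-condition signal; divergence is sucrose-related when the
#' members differ only in their sucrose-response call.
#'
#' @param pairs_by_mode named list of data.frames(gene1, gene2).
#' @param div result of [classify_divergence()].
#' @param det result of [detect_expressed()].
#' @return data.frame(mode, variety, n_pairs, divergent, sucrose_only,
#'   fraction_divergent).
#' @export
duplication_expression_divergence <- function(pairs_by_mode, div, det) {
  varieties <- attr(div, "varieties")
  probe_of <- setNames(div$probe_id, div$gene_id)
  rows <- list()
  for (mode in names(pairs_by_mode)) {
    pp <- pairs_by_mode[[mode]]
    if (is.null(pp) || nrow(pp) == 0) next
    for (vi in seq_along(varieties)) {
      v <- varieties[vi]
      mcol <- paste0("mean_normal_v", vi)
      dcol <- paste0("sucrose_dir_v", vi)
      n <- divn <- sucn <- 0L
      for (r in seq_len(nrow(pp))) {
        p1 <- probe_of[pp$gene1[r]]
        p2 <- probe_of[pp$gene2[r]]
        if (is.na(p1) || is.na(p2)) next
        i1 <- match(p1, div$probe_id)
        i2 <- match(p2, div$probe_id)
        n <- n + 1L
        e1 <- det$per_variety[p1, v]
        e2 <- det$per_variety[p2, v]
        m1 <- div[[mcol]][i1]
        m2 <- div[[mcol]][i2]
        base_div <- (e1 != e2) ||
          (e1 && e2 && (m1 >= 2 * m2 || m2 >= 2 * m1))
        suc_div <- div[[dcol]][i1] != div[[dcol]][i2]
        if (base_div || suc_div) divn <- divn + 1L
        if (!base_div && suc_div) sucn <- sucn + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode, variety = v, n_pairs = n, divergent = divn,
        sucrose_only = sucn,
        fraction_divergent = if (n > 0) divn / n else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' One TSV per summary table plus one gene-list file per reported set,
#' so every count can be recomputed from the exports.
#'
#' @param report a `ReportBundle`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- setdiff(names(report), c("gene_lists", "objects"))
  for (nm in tabs) {
    if (is.null(report[[nm]])) next
    write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gl_dir <- file.path(dir, "gene_lists")
  if (!dir.exists(gl_dir)) dir.create(gl_dir)
  for (nm in names(report$gene_lists)) {
    writeLines(sort(report$gene_lists[[nm]]),
               file.path(gl_dir, paste0(nm, ".txt")))
  }
  invisible(dir)
}
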