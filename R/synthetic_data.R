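## Seeded two-variety synthetic dataset with full ground truth. The
## generator plants every structure the downstream analyses assume:
## tandem families, segmental blocks, CACTA/LTR elements with TSDs and
## captured genes, nonsense/frameshift premature stops, six expression
## divergence classes, promoter SNPs and motif gains/losses, and
## bisulfite clones with known per-cytosine methylation states.

DNA4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

sense_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE),
          c(STOP_CODONS, "ATG"))  # ATG reserved for the start
}

## ATG + random sense codons + one stop; no internal stops by construction
random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(sense_codons(), n_codons, replace = TRUE),
                      collapse = ""), sample(STOP_CODONS, 1))
}

## codon-level resampling keeps the copy in frame and stop-free
mutate_cds <- function(cds, rate = 0.03) {
  n <- nchar(cds) / 3
  cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, c(1L, n))
  cod[hit] <- sample(sense_codons(), length(hit), replace = TRUE)
  paste(cod, collapse = "")
}

default_motif_table <- function() {
  data.frame(
    motif_id = c("SEF4MOTIFGM7S", "TATABOX3", "SURE1STPAT21", "ABREZMRAB28"),
    pattern = c("GTTTTTA", "TATTAAT", "AATAGAAAA", "CCACGTGG"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: two
#' chromosomes, 1,000 genes, 2 varieties x 3 sucrose time points
#' (0/2/6 h) x 2 replicates, lognormal processed-signal scale, and
#' canonical element geometry (20-bp CACTA terminal inverted repeats
#' with 3-bp TSDs; ~300-bp LTR direct repeats with 5-bp TSDs).
#'
#' @param seed integer; fixes every stochastic draw.
#' @param n_chroms,chrom_len_bp genome shape.
#' @param n_genes total genes, including duplicate copies and captured
#'   genes.
#' @param frac_tandem_families fraction of genes seeding a 2-3 copy
#'   tandem family.
#' @param max_tandem_spacing_genes planted unrelated genes between
#'   tandem copies (0 to this value).
#' @param n_segmental_blocks,genes_per_block planted segmental blocks.
#' @param n_cacta,n_ltr planted element counts.
#' @param tir_seed_seq,subterminal_seq,tsd_len_cacta CACTA geometry.
#' @param ltr_len,tsd_len_ltr LTR geometry.
#' @param capture_frac fraction of elements that capture one gene.
#' @param snp_rate per-bp coding SNP rate (variety 2 vs variety 1).
#' @param indel_rate per-bp intergenic small-indel rate.
#' @param n_sv_del,n_sv_dup whole-gene structural deletions /
#'   copy-number records.
#' @param frac_premature_stop_genes fraction of coding genes given a
#'   planted premature stop (nonsense SNP or frameshift deletion).
#' @param expr_meanlog,expr_sdlog lognormal baseline of processed
#'   signals.
#' @param frac_variety_specific,frac_fold2,frac_sucrose_only,frac_silent
#'   expression-class fractions (each split over the two varieties).
#' @param replicate_cv replicate noise coefficient of variation.
#' @param frac_pair_divergent fraction of planted duplicate pairs whose
#'   members differ >= 2-fold in expression (pair expression divergence).
#' @param detection_threshold detection signal threshold.
#' @param n_est_probes EST-only probes without a gene id.
#' @param frac_promoter_variation fraction of genes with planted
#'   promoter variation.
#' @param frac_motif_gain_loss fraction of variation genes whose SNP
#'   creates/destroys a motif occurrence.
#' @param motif_table data.frame(motif_id, pattern).
#' @param meth_cg,meth_chg,meth_chh per-context methylation
#'   probabilities, length-2 (variety 1, variety 2).
#' @param n_meth_genes,meth_region_len,n_clones,conversion_error_rate
#'   bisulfite simulation shape.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_len_bp = 2e6, n_genes = 1000,
                       frac_tandem_families = 0.06,
                       max_tandem_spacing_genes = 2,
                       n_segmental_blocks = 2, genes_per_block = 8,
                       n_cacta = 6, n_ltr = 4,
                       tir_seed_seq = "CACTACAAGAAAATGGTGGG",
                       subterminal_seq = "GGTTTAAACC",
                       tsd_len_cacta = 3, ltr_len = 300, tsd_len_ltr = 5,
                       capture_frac = 0.5,
                       snp_rate = 5e-4, indel_rate = 5e-5,
                       n_sv_del = 3, n_sv_dup = 2,
                       frac_premature_stop_genes = 0.02,
                       expr_meanlog = log(400), expr_sdlog = 1.2,
                       frac_variety_specific = 0.06, frac_fold2 = 0.10,
                       frac_sucrose_only = 0.06, frac_silent = 0.12,
                       replicate_cv = 0.1, detection_threshold = 25,
                       n_est_probes = 50, frac_pair_divergent = 0.5,
                       frac_promoter_variation = 0.7,
                       frac_motif_gain_loss = 0.1,
                       motif_table = default_motif_table(),
                       meth_cg = c(0.8, 0.2), meth_chg = c(0.5, 0.1),
                       meth_chh = c(0.1, 0.05),
                       n_meth_genes = 3, meth_region_len = 300,
                       n_clones = 10, conversion_error_rate = 0.01) {
  cfg <- as.list(environment())
  fr <- c(frac_tandem_families, frac_premature_stop_genes, capture_frac,
          frac_variety_specific, frac_fold2, frac_sucrose_only, frac_silent,
          frac_promoter_variation, frac_motif_gain_loss,
          meth_cg, meth_chg, meth_chh)
  stopifnot(all(fr >= 0 & fr <= 1), snp_rate >= 0, indel_rate >= 0,
            n_genes > 0, startsWith(tir_seed_seq, "CACTA"))
  structure(cfg, class = "SimConfig")
}

## find a single-base change turning some middle codon into a stop;
## returns list(cds_pos [0-based within CDS], ref, alt) or NULL
nonsense_snp_for <- function(cds) {
  n <- nchar(cds) / 3
  for (ci in sample(2:(n - 1))) {
    codon <- substr(cds, ci * 3 - 2, ci * 3)
    for (p in sample(1:3)) {
      for (b in sample(setdiff(DNA4, substr(codon, p, p)))) {
        alt <- codon
        substr(alt, p, p) <- b
        if (alt %in% STOP_CODONS) {
          pos <- (ci - 1L) * 3L + (p - 1L)
          return(list(cds_pos = pos, ref = substr(codon, p, p), alt = b))
        }
      }
    }
  }
  NULL
}

## 1-bp deletion causing a frameshift with a verified earlier stop
frameshift_del_for <- function(cds) {
  n <- nchar(cds) / 3
  orig_stop <- n
  for (ci in sample(3:(n - 3), min(20, n - 5))) {
    pos <- (ci - 1L) * 3L  # delete first base of codon ci (0-based)
    mut <- paste0(substr(cds, 1, pos), substr(cds, pos + 2, nchar(cds)))
    st <- first_stop_codon(suppressWarnings(translate_dna(mut)))
    if (is.finite(st) && st < orig_stop) {
      return(list(cds_pos = pos, ref = substr(cds, pos + 1, pos + 1)))
    }
  }
  NULL
}

#' Simulate a two-variety dataset with ground truth
#'
#' Builds variety 1 de novo, derives a variant set (SNP/indel/SV) and
#' obtains variety 2 by [apply_variants()], so the closure property
#' (applying the returned variants to genome 1 reproduces genome 2)
#' holds by construction. See [sim_config()] for the planted structure.
#'
#' @param config a [sim_config()].
#' @return list with genome1, genome2, variants, expr
#'   (an [expression_matrix()]), motif_table, bisulfite (per-gene clone
#'   sets), and truth (a `GroundTruth` list of tables).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n_fam <- round(config$frac_tandem_families * config$n_genes)
  fam_extra <- n_fam  # one extra copy per family
  seg_copies <- config$n_segmental_blocks * config$genes_per_block
  n_cap_cacta <- round(config$capture_frac * config$n_cacta)
  n_cap_ltr <- round(config$capture_frac * config$n_ltr)
  captured <- n_cap_cacta + n_cap_ltr
  n_singles <- config$n_genes - 2L * n_fam - seg_copies - captured
  if (n_singles < seg_copies + 10) {
    stop("infeasible gene budget: ", n_singles, " singles left")
  }

  ## ---- gene records -------------------------------------------------
  gene_seq <- list()
  gene_role <- character(0)
  fam_of <- character(0)
  new_gene <- function(role, fam = NA_character_, seq = NULL) {
    gid <- sprintf("g%05d", length(gene_seq) + 1L)
    gene_seq[[gid]] <<- if (is.null(seq)) {
      random_cds(sample(80:160, 1))
    } else seq
    gene_role[gid] <<- role
    fam_of[gid] <<- fam
    gid
  }
  singles <- vapply(seq_len(n_singles), function(i) new_gene("single"),
                    character(1))
  fam_groups <- lapply(seq_len(n_fam), function(f) {
    fid <- sprintf("T%03d", f)
    seed_gid <- new_gene("tandem", fid)
    copy <- new_gene("tandem", fid,
                     seq = mutate_cds(gene_seq[[seed_gid]], 0.03))
    c(seed_gid, copy)
  })
  seg_sources <- split(singles[seq_len(seg_copies)],
                       rep(seq_len(config$n_segmental_blocks),
                           each = config$genes_per_block))
  seg_copy_ids <- lapply(seq_len(config$n_segmental_blocks), function(b) {
    vapply(seg_sources[[b]], function(src) {
      new_gene("segmental_copy", seq = mutate_cds(gene_seq[[src]], 0.03))
    }, character(1), USE.NAMES = FALSE)
  })
  cap_ids <- vapply(seq_len(captured), function(i) new_gene("captured"),
                    character(1))

  ## ---- element payloads ---------------------------------------------
  tir <- config$tir_seed_seq
  sub3 <- strrep(config$subterminal_seq, 3)
  make_cacta <- function(cap_gid) {
    tsd <- rand_dna(config$tsd_len_cacta)
    inner <- if (is.na(cap_gid)) rand_dna(sample(300:1500, 1)) else
      paste0(rand_dna(200), gene_seq[[cap_gid]], rand_dna(200))
    body <- paste0(tir, sub3, inner, revcomp(sub3), revcomp(tir))
    list(tsd = tsd, body = body, cap = cap_gid, class = "CACTA",
         gene_offset = if (is.na(cap_gid)) NA else
           nchar(tir) + nchar(sub3) + 200L)
  }
  make_ltr <- function(cap_gid) {
    tsd <- rand_dna(config$tsd_len_ltr)
    ltr <- rand_dna(config$ltr_len)
    inner <- if (is.na(cap_gid)) rand_dna(sample(1000:3000, 1)) else
      paste0(rand_dna(500), gene_seq[[cap_gid]], rand_dna(500))
    # block first-order repeat over-extension into flanks
    fix <- function(ch, avoid) if (ch == avoid) setdiff(DNA4, avoid)[1] else ch
    substr(inner, 1, 1) <- fix(substr(inner, 1, 1), substr(tsd, 1, 1))
    nlast <- nchar(inner)
    substr(inner, nlast, nlast) <- fix(substr(inner, nlast, nlast),
                                       substr(tsd, nchar(tsd), nchar(tsd)))
    body <- paste0(ltr, inner, ltr)
    list(tsd = tsd, body = body, cap = cap_gid, class = "LTR",
         gene_offset = if (is.na(cap_gid)) NA else config$ltr_len + 500L)
  }
  cacta_caps <- c(cap_ids[seq_len(n_cap_cacta)],
                  rep(NA, config$n_cacta - n_cap_cacta))
  ltr_caps <- c(cap_ids[n_cap_cacta + seq_len(n_cap_ltr)],
                rep(NA, config$n_ltr - n_cap_ltr))
  elements_payload <- c(lapply(cacta_caps, make_cacta),
                        lapply(ltr_caps, make_ltr))

  ## ---- layout plan ---------------------------------------------------
  # seg sources are placed as runs, not as free singles
  free_singles <- if (seg_copies > 0) singles[-seq_len(seg_copies)] else singles
  units <- c(
    lapply(free_singles, function(g) list(kind = "gene", ids = g)),
    lapply(fam_groups, function(gr) list(kind = "family", ids = gr)),
    lapply(seq_len(config$n_segmental_blocks),
           function(b) list(kind = "segrun", ids = seg_sources[[b]], block = b)),
    lapply(seq_len(config$n_segmental_blocks),
           function(b) list(kind = "segrun", ids = seg_copy_ids[[b]], block = b)),
    lapply(seq_along(elements_payload),
           function(i) list(kind = "element", payload = elements_payload[[i]],
                            eid = i))
  )
  units <- units[sample(length(units))]
  # spread across chromosomes; a segmental block's copy run goes to a
  # different chromosome than its source run when possible
  chrom_ids <- sprintf("chr%02d", seq_len(config$n_chroms))
  assign_chrom <- rep(chrom_ids, length.out = length(units))
  seg_idx <- which(vapply(units, function(u) u$kind == "segrun", logical(1)))
  if (config$n_chroms >= 2) {
    for (b in seq_len(config$n_segmental_blocks)) {
      ii <- seg_idx[vapply(units[seg_idx], function(u) u$block == b, logical(1))]
      assign_chrom[ii] <- chrom_ids[c(1, 2)][seq_along(ii)]
    }
  }

  ## ---- build chromosomes ---------------------------------------------
  genes_df <- list()
  cds_list <- list()
  elements_truth <- list()
  sequences <- setNames(character(config$n_chroms), chrom_ids)
  for (ch in chrom_ids) {
    pieces <- character(0)
    cursor <- 0L
    add <- function(seq) {
      pieces[[length(pieces) + 1L]] <<- seq
      start <- cursor
      cursor <<- cursor + nchar(seq)
      start
    }
    place_gene <- function(gid, start) {
      strand <- sample(c("+", "-"), 1)
      cds <- gene_seq[[gid]]
      genes_df[[gid]] <<- data.frame(
        gene_id = gid, chrom_id = ch, strand = strand,
        start = start, end = start + nchar(cds), coding = TRUE,
        deleted = FALSE, stringsAsFactors = FALSE
      )
      cds_list[[gid]] <<- cbind(start = start, end = start + nchar(cds))
      if (strand == "-") strand_rc[[gid]] <<- TRUE
      invisible(start)
    }
    strand_rc <- list()
    for (u in units[assign_chrom == ch]) {
      if (u$kind == "gene") {
        add(rand_dna(sample(3100:3300, 1)))
        place_gene(u$ids, cursor)
        add(gene_seq[[u$ids]])
      } else if (u$kind %in% c("family", "segrun")) {
        for (gid in u$ids) {
          add(rand_dna(sample(3100:3300, 1)))
          place_gene(gid, cursor)
          add(gene_seq[[gid]])
        }
      } else { # element
        pl <- u$payload
        add(rand_dna(sample(3100:3300, 1)))
        add(pl$tsd)
        el_start <- cursor
        if (!is.na(pl$cap)) place_gene(pl$cap, el_start + pl$gene_offset)
        add(pl$body)
        el_end <- cursor
        add(pl$tsd)
        elements_truth[[length(elements_truth) + 1L]] <- data.frame(
          element_id = sprintf("E%03d", u$eid), class = pl$class,
          chrom_id = ch, start = el_start, end = el_end, tsd = pl$tsd,
          captured_gene_ids = if (is.na(pl$cap)) "" else pl$cap,
          stringsAsFactors = FALSE
        )
      }
    }
    add(rand_dna(200))
    if (cursor > config$chrom_len_bp) {
      stop(sprintf("infeasible packing on %s: %d bp needed, %d available (%d genes placed)",
                   ch, cursor, config$chrom_len_bp, length(genes_df)))
    }
    pieces[[length(pieces) + 1L]] <- rand_dna(config$chrom_len_bp - cursor)
    sequences[[ch]] <- paste(pieces, collapse = "")
    # apply minus strands: genomic sequence holds revcomp(CDS)
    for (gid in names(strand_rc)) {
      g <- genes_df[[gid]]
      s <- sequences[[ch]]
      substr(s, g$start + 1L, g$end) <- revcomp(substring(s, g$start + 1L, g$end))
      sequences[[ch]] <- s
    }
  }
  genes <- do.call(rbind, genes_df)
  rownames(genes) <- NULL
  genome1 <- annotated_genome(sequences, genes, cds_list)
  elements_truth <- do.call(rbind, elements_truth)

  ## ---- variant plan (on genome-1 coordinates) ------------------------
  gs <- function(gid) genome1$genes[match(gid, genome1$genes$gene_id), ]
  variants <- list()
  add_var <- function(chrom, pos, vtype, ref, alt, sv_class = "") {
    variants[[length(variants) + 1L]] <<- data.frame(
      chrom_id = chrom, pos = as.integer(pos), vtype = vtype, ref = ref,
      alt = alt, sv_class = sv_class, stringsAsFactors = FALSE
    )
  }
  ## map a 0-based CDS offset to (genomic pos, forward-strand ref/alt)
  cds_to_genomic <- function(gid, cds_pos, ref, alt) {
    g <- gs(gid)
    if (g$strand == "+") {
      list(pos = g$start + cds_pos, ref = ref, alt = alt)
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      list(pos = g$end - 1L - cds_pos,
           ref = unname(comp[ref]), alt = unname(comp[alt]))
    }
  }
  pool <- if (seg_copies > 0) singles[-seq_len(seg_copies)] else singles
  ## structural deletions: whole genes removed in variety 2
  sv_del_genes <- sample(pool, config$n_sv_del)
  pool <- setdiff(pool, sv_del_genes)
  for (gid in sv_del_genes) {
    g <- gs(gid)
    s <- g$start - 100L
    e <- g$end + 100L
    add_var(g$chrom_id, s, "SV",
            seq_slice(genome1$sequences, g$chrom_id, s, e), "", "deletion")
  }
  ## copy-number records: flagged, sequence unchanged
  sv_dup_genes <- sample(pool, config$n_sv_dup)
  pool <- setdiff(pool, sv_dup_genes)
  for (gid in sv_dup_genes) {
    g <- gs(gid)
    add_var(g$chrom_id, g$start + 10L, "SV",
            seq_slice(genome1$sequences, g$chrom_id, g$start + 10L, g$start + 110L),
            "", "duplication")
  }
  ## premature stops: nonsense SNPs (70%) or frameshift deletions (30%)
  n_ps <- round(config$frac_premature_stop_genes * config$n_genes)
  ps_genes <- sample(pool, n_ps)
  pool <- setdiff(pool, ps_genes)
  ps_truth <- list()
  for (k in seq_along(ps_genes)) {
    gid <- ps_genes[k]
    cds <- gene_seq[[gid]]
    use_fs <- k > ceiling(0.7 * n_ps)
    fs <- if (use_fs) frameshift_del_for(cds) else NULL
    if (!is.null(fs)) {
      g <- gs(gid)
      pos <- if (g$strand == "+") g$start + fs$cds_pos else
        g$end - 1L - fs$cds_pos
      ref <- seq_slice(genome1$sequences, g$chrom_id, pos, pos + 1L)
      add_var(g$chrom_id, pos, "DEL", ref, "")
      ps_truth[[gid]] <- data.frame(gene_id = gid, cause = "DEL")
    } else {
      sn <- nonsense_snp_for(cds)
      m <- cds_to_genomic(gid, sn$cds_pos, sn$ref, sn$alt)
      g <- gs(gid)
      add_var(g$chrom_id, m$pos, "SNP", m$ref, m$alt)
      ps_truth[[gid]] <- data.frame(gene_id = gid, cause = "SNP")
    }
  }
  ps_truth <- do.call(rbind, ps_truth)
  ## background coding SNPs, never creating a stop
  bg_genes <- setdiff(genome1$genes$gene_id, c(ps_genes, sv_del_genes))
  for (gid in bg_genes) {
    cds <- gene_seq[[gid]]
    n_codons <- nchar(cds) / 3
    k <- rpois(1, nchar(cds) * config$snp_rate)
    if (k == 0) next
    done <- integer(0)
    for (i in seq_len(k)) {
      ci <- sample(2:(n_codons - 1), 1)
      if (ci %in% done) next
      codon <- substr(cds, ci * 3 - 2, ci * 3)
      p <- sample(1:3, 1)
      alts <- setdiff(DNA4, substr(codon, p, p))
      ok <- alts[vapply(alts, function(b) {
        cc <- codon
        substr(cc, p, p) <- b
        !(cc %in% STOP_CODONS)
      }, logical(1))]
      if (length(ok) == 0) next
      b <- if (length(ok) == 1) ok else sample(ok, 1)
      m <- cds_to_genomic(gid, (ci - 1L) * 3L + (p - 1L),
                          substr(codon, p, p), b)
      g <- gs(gid)
      add_var(g$chrom_id, m$pos, "SNP", m$ref, m$alt)
      done <- c(done, ci)
    }
  }
  ## promoter windows (genome-1 coordinates, transcript orientation)
  promoter_window <- function(gid, L = 1500L) {
    g <- gs(gid)
    if (g$strand == "+") c(g$start - L, g$start) else c(g$end, g$end + L)
  }
  prom_candidates <- setdiff(genome1$genes$gene_id,
                             c(sv_del_genes, cap_ids))
  n_pv <- round(config$frac_promoter_variation * length(prom_candidates))
  pv_genes <- sample(prom_candidates, n_pv)
  plus_pv <- pv_genes[vapply(pv_genes, function(g) gs(g)$strand == "+",
                             logical(1))]
  n_motif <- min(length(plus_pv), round(config$frac_motif_gain_loss * n_pv))
  motif_genes <- if (n_motif > 0) sample(plus_pv, n_motif) else character(0)
  motif <- config$motif_table$pattern[1]   # e.g. GTTTTTA
  motif_id <- config$motif_table$motif_id[1]
  mut_motif <- motif
  substr(mut_motif, 5, 5) <- if (substr(motif, 5, 5) == "T") "A" else "T"
  prom_truth <- list()
  for (gid in pv_genes) {
    w <- promoter_window(gid)
    change <- "none"
    if (gid %in% motif_genes) {
      loss <- runif(1) < 0.5
      planted <- if (loss) motif else mut_motif
      off <- sample(200:1200, 1)
      s <- sequences_overwrite_pos <- w[1] + off
      g <- gs(gid)
      str_ <- genome1$sequences[[g$chrom_id]]
      substr(str_, s + 1L, s + nchar(planted)) <- planted
      genome1$sequences[[g$chrom_id]] <- str_
      # SNP at motif position 5 flips presence in variety 2
      ref <- substr(planted, 5, 5)
      alt <- if (ref == "T") "A" else "T"
      add_var(g$chrom_id, s + 4L, "SNP", ref, alt)
      change <- if (loss) "loss_v2" else "gain_v2"
      n_snps <- 1L
    } else {
      g <- gs(gid)
      n_snps <- sample(1:3, 1)
      offs <- sample(50:1450, n_snps)
      for (off in offs) {
        pos <- w[1] + off
        ref <- seq_slice(genome1$sequences, g$chrom_id, pos, pos + 1L)
        add_var(g$chrom_id, pos, "SNP", ref, sample(setdiff(DNA4, ref), 1))
      }
    }
    prom_truth[[gid]] <- data.frame(gene_id = gid, has_variation = TRUE,
                                    n_snps = n_snps, motif_change = change,
                                    motif_id = if (change == "none") "" else motif_id)
  }
  no_pv <- setdiff(prom_candidates, pv_genes)
  prom_truth <- rbind(
    do.call(rbind, prom_truth),
    data.frame(gene_id = no_pv, has_variation = FALSE, n_snps = 0L,
               motif_change = "none", motif_id = "")
  )
  ## intergenic small indels, kept clear of promoter windows
  n_indel_bg <- rpois(1, config$n_chroms * config$chrom_len_bp *
                        config$indel_rate)
  gaps_mid <- list()
  for (ch in chrom_ids) {
    gg <- genome1$genes[genome1$genes$chrom_id == ch, ]
    gg <- gg[order(gg$start), ]
    bounds <- cbind(c(0L, gg$end), c(gg$start, nchar(sequences[[ch]])))
    wide <- bounds[, 2] - bounds[, 1] > 3080
    mids <- bounds[wide, , drop = FALSE]
    if (nrow(mids) > 0) {
      gaps_mid[[ch]] <- cbind(mids[, 1] + 1540L, mids[, 2] - 1540L)
    }
  }
  for (i in seq_len(n_indel_bg)) {
    ch <- sample(names(gaps_mid), 1)
    m <- gaps_mid[[ch]]
    r <- m[sample(nrow(m), 1), ]
    if (r[2] - r[1] < 10) next
    pos <- sample(seq(r[1], r[2] - 6L), 1)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)
      add_var(ch, pos, "DEL",
              seq_slice(genome1$sequences, ch, pos, pos + len), "")
    } else {
      add_var(ch, pos, "INS", "", rand_dna(sample(1:4, 1)))
    }
  }
  variants <- do.call(rbind, variants)
  variants <- variants[order(variants$chrom_id, variants$pos), ]
  rownames(variants) <- NULL
  ## drop rare collisions (same/overlapping positions)
  keep <- rep(TRUE, nrow(variants))
  last_end <- -1L
  last_ch <- ""
  for (i in seq_len(nrow(variants))) {
    vend <- variants$pos[i] + max(nchar(variants$ref[i]), 1L)
    if (variants$chrom_id[i] == last_ch && variants$pos[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- vend
      last_ch <- variants$chrom_id[i]
    }
  }
  variants <- variants[keep, , drop = FALSE]
  genome2 <- apply_variants(genome1, variants)

  ## ---- expression ----------------------------------------------------
  pair_df <- rbind(
    do.call(rbind, lapply(seq_along(fam_groups), function(f) {
      data.frame(gene1 = fam_groups[[f]][1], gene2 = fam_groups[[f]][2],
                 mode = "tandem")
    })),
    do.call(rbind, lapply(seq_len(config$n_segmental_blocks), function(b) {
      data.frame(gene1 = unname(seg_sources[[b]]),
                 gene2 = unname(seg_copy_ids[[b]]), mode = "segmental")
    }))
  )
  expr <- simulate_expression(config, genome1$genes$gene_id, sv_del_genes,
                              pair_df)

  ## ---- bisulfite -----------------------------------------------------
  meth_pool <- intersect(no_pv, pool)
  meth_genes <- sample(meth_pool, min(config$n_meth_genes, length(meth_pool)))
  bisulfite <- simulate_bisulfite(config, genome1, meth_genes)

  ## ---- ground truth --------------------------------------------------
  tandem_pairs <- do.call(rbind, lapply(seq_along(fam_groups), function(f) {
    gr <- sort(fam_groups[[f]])
    data.frame(gene1 = gr[1], gene2 = gr[2], family = sprintf("T%03d", f))
  }))
  segmental_pairs <- do.call(rbind, lapply(
    seq_len(config$n_segmental_blocks), function(b) {
      data.frame(block_id = sprintf("S%02d", b),
                 gene1 = unname(seg_sources[[b]]),
                 gene2 = unname(seg_copy_ids[[b]]))
    }))
  truth <- list(
    tandem_pairs = tandem_pairs,
    segmental_pairs = segmental_pairs,
    elements = elements_truth,
    premature_stop = ps_truth,
    sv_genes = data.frame(
      gene_id = c(sv_del_genes, sv_dup_genes),
      kind = rep(c("deleted", "duplicated"),
                 c(length(sv_del_genes), length(sv_dup_genes)))),
    expression_classes = expr$truth,
    pair_divergence = expr$pair_truth,
    promoter_variation = prom_truth[order(prom_truth$gene_id), ],
    methylation = bisulfite$truth
  )
  list(genome1 = genome1, genome2 = genome2, variants = variants,
       expr = expr$matrix, motif_table = config$motif_table,
       bisulfite = bisulfite$clones, truth = truth, config = config)
}

## planted six-class expression signals: 2 varieties x (0,2,6 h) x 2 reps;
## duplicate-pair members stay neutral with a controlled fraction of
## pairs made >= 2-fold divergent
simulate_expression <- function(config, gene_ids, sv_del_genes,
                                pair_df = NULL) {
  probes <- data.frame(
    probe_id = c(paste0("p_", gene_ids),
                 sprintf("est%04d", seq_len(config$n_est_probes))),
    gene_id = c(gene_ids, rep(NA_character_, config$n_est_probes)),
    stringsAsFactors = FALSE
  )
  np <- nrow(probes)
  classes <- rep("neutral", np)
  pair_genes <- if (is.null(pair_df)) character(0) else
    unique(c(pair_df$gene1, pair_df$gene2))
  assignable <- sample(which(!is.na(probes$gene_id) &
                               !(probes$gene_id %in% sv_del_genes) &
                               !(probes$gene_id %in% pair_genes)))
  take <- function(n) {
    out <- assignable[seq_len(n)]
    assignable <<- assignable[-seq_len(n)]
    out
  }
  n_spec <- round(config$frac_variety_specific * np / 2)
  n_fold <- round(config$frac_fold2 * np / 2)
  n_suc <- round(config$frac_sucrose_only * np / 2)
  n_sil <- round(config$frac_silent * np)
  classes[take(n_spec)] <- "specific_v1"
  classes[take(n_spec)] <- "specific_v2"
  classes[take(n_fold)] <- "fold2_v1"
  classes[take(n_fold)] <- "fold2_v2"
  classes[take(n_suc)] <- "sucrose_only_v1"
  classes[take(n_suc)] <- "sucrose_only_v2"
  classes[take(n_sil)] <- "silent"
  base <- pmin(pmax(exp(rnorm(np, config$expr_meanlog, config$expr_sdlog)),
                    60), 2e4)
  ## controlled duplicate-pair expression divergence
  pair_truth <- NULL
  if (!is.null(pair_df) && nrow(pair_df) > 0) {
    pi1 <- match(paste0("p_", pair_df$gene1), probes$probe_id)
    pi2 <- match(paste0("p_", pair_df$gene2), probes$probe_id)
    divergent <- runif(nrow(pair_df)) < config$frac_pair_divergent
    pfc <- 2^(runif(nrow(pair_df), 1.3, 2.2) *
                sample(c(-1, 1), nrow(pair_df), replace = TRUE))
    base[pi2] <- base[pi1] * ifelse(divergent, pfc, 1)
    pair_truth <- data.frame(pair_df, divergent = divergent)
  }
  fc <- 2^runif(np, 1.2, 2.5)
  suc_dir <- sample(c("up", "down"), np, replace = TRUE)
  mu <- array(0, dim = c(np, 2, 3),
              dimnames = list(NULL, c("v1", "v2"), c("0", "2", "6")))
  low <- function(n) runif(n, 0, 12)
  for (i in seq_len(np)) {
    m <- matrix(base[i], 2, 3)
    cl <- classes[i]
    if (cl == "silent") m[] <- low(6)
    if (cl == "specific_v1") m[2, ] <- low(3)
    if (cl == "specific_v2") m[1, ] <- low(3)
    if (cl == "fold2_v1") m[1, ] <- base[i] * fc[i]
    if (cl == "fold2_v2") m[2, ] <- base[i] * fc[i]
    if (cl == "sucrose_only_v1") {
      m[1, 2:3] <- base[i] * if (suc_dir[i] == "up") fc[i] else 1 / fc[i]
    }
    if (cl == "sucrose_only_v2") {
      m[2, 2:3] <- base[i] * if (suc_dir[i] == "up") fc[i] else 1 / fc[i]
    }
    mu[i, , ] <- m
  }
  samples <- expand.grid(replicate = 1:2, time = c(0, 2, 6),
                         variety = c("v1", "v2"),
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- paste(samples$variety, samples$time,
                             samples$replicate, sep = ":")
  signals <- matrix(0, np, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    v <- match(samples$variety[j], c("v1", "v2"))
    t <- as.character(samples$time[j])
    signals[, j] <- mu[, v, t] * exp(rnorm(np, 0, config$replicate_cv))
  }
  truth <- data.frame(
    probe_id = probes$probe_id, gene_id = probes$gene_id, class = classes,
    sucrose_direction = ifelse(startsWith(classes, "sucrose"), suc_dir, "none"),
    log2fc = ifelse(classes %in% c("fold2_v1", "fold2_v2"), log2(fc), 0),
    stringsAsFactors = FALSE
  )
  list(matrix = expression_matrix(signals, samples, probes), truth = truth,
       pair_truth = pair_truth)
}

## bisulfite clones over the proximal promoter of selected genes
simulate_bisulfite <- function(config, genome1, meth_genes) {
  clones <- list()
  truth <- list()
  for (v in 1:2) {
    for (gid in meth_genes) {
      i <- match(gid, genome1$genes$gene_id)
      g <- genome1$genes[i, ]
      L <- config$meth_region_len
      ref <- if (g$strand == "+") {
        seq_slice(genome1$sequences, g$chrom_id, g$start - L, g$start)
      } else {
        revcomp(seq_slice(genome1$sequences, g$chrom_id, g$end, g$end + L))
      }
      rc <- strsplit(ref, "")[[1]]
      c_pos <- which(rc == "C")
      ctx <- vapply(c_pos, function(p) methylation_context(rc, p), "")
      p_site <- setNames(
        ifelse(ctx == "CG", config$meth_cg[v],
               ifelse(ctx == "CHG", config$meth_chg[v], config$meth_chh[v])),
        c_pos)
      # one designated differential CG site per gene
      cg <- c_pos[ctx == "CG"]
      diff_site <- if (length(cg) > 0) cg[ceiling(length(cg) / 2)] else NA
      if (!is.na(diff_site)) {
        p_site[as.character(diff_site)] <- if (v == 1) 0.9 else 0.0
      }
      cl <- vapply(seq_len(config$n_clones), function(k) {
        out <- rc
        for (pi in seq_along(c_pos)) {
          meth <- runif(1) < p_site[pi]
          err <- runif(1) < config$conversion_error_rate
          out[c_pos[pi]] <- if (xor(meth, err)) "C" else "T"
        }
        paste(out, collapse = "")
      }, character(1))
      clones[[paste0(gid, "_v", v)]] <- list(gene_id = gid, variety = v,
                                             reference = ref, clones = cl)
      if (v == 1) {
        truth[[gid]] <- data.frame(
          gene_id = gid, position = -(L - c_pos + 1L), context = ctx,
          p_v1 = unname(p_site), p_v2 = NA_real_,
          differential = if (is.na(diff_site)) FALSE else c_pos == diff_site
        )
      } else {
        truth[[gid]]$p_v2 <- unname(p_site)
      }
    }
  }
  list(clones = clones, truth = do.call(rbind, truth))
}

#' Write / read ground-truth tables
#'
#' One TSV per truth table, named `truth_<table>.tsv`.
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory (write) or the truth list (read).
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(truth)) {
    if (is.null(truth[[nm]])) next
    write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  files <- list.files(dir, pattern = "^truth_.*\\.tsv$", full.names = TRUE)
  out <- lapply(files, read.delim, stringsAsFactors = FALSE)
  names(out) <- sub("^truth_(.*)\\.tsv$", "\\1", basename(files))
  out
}

#' Write a complete simulated dataset to disk
#'
#' FASTA/GFF3 per variety, the variant TSV, the expression TSV, the
#' motif TSV, bisulfite clone FASTAs and the ground-truth TSVs.
#'
#' @param ds result of [simulate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome(ds$genome1, file.path(dir, "variety1.fa"),
               file.path(dir, "variety1.gff3"))
  write_genome(ds$genome2, file.path(dir, "variety2.fa"),
               file.path(dir, "variety2.gff3"))
  write_variants(ds$variants, file.path(dir, "variants.tsv"))
  write_expression(ds$expr, file.path(dir, "expression.tsv"))
  write.table(ds$motif_table, file.path(dir, "motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(ds$bisulfite)) {
    b <- ds$bisulfite[[nm]]
    con <- file(file.path(dir, paste0("bisulfite_", nm, ".fa")), "w")
    writeLines(paste0(">reference_", b$gene_id, "\n", b$reference), con)
    for (k in seq_along(b$clones)) {
      writeLines(paste0(">", nm, "_clone", k, "\n", b$clones[k]), con)
    }
    close(con)
  }
  write_ground_truth(ds$truth, file.path(dir, "truth"))
  invisible(dir)
}
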