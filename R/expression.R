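## Detection calls, six expression-divergence classes, abundance bins,
## sucrose-response classification, Venn partitions and delta-delta-CT.

#' Construct an expression matrix
#'
#' @param signals numeric matrix, probes x samples, non-negative.
#' @param samples data.frame(sample_id, variety, time, replicate); `time`
#'   in hours with 0 = normal growth and 2/6 = sucrose-treated.
#' @param probes data.frame(probe_id, gene_id); `gene_id` NA for
#'   EST-only probes.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(signals, samples, probes) {
  stopifnot(ncol(signals) == nrow(samples), nrow(signals) == nrow(probes))
  stopifnot(all(signals >= 0))
  tab <- table(samples$variety, samples$time)
  if (any(tab < 2)) stop("need >= 2 replicates per (variety, time)")
  rownames(signals) <- probes$probe_id
  colnames(signals) <- samples$sample_id
  structure(list(signals = signals, samples = samples, probes = probes),
            class = "ExpressionMatrix")
}

#' Read / write the probe x sample signal TSV
#'
#' First column `probe_id`, optional `gene_id` column, remaining columns
#' named `variety:time:replicate` (e.g. `BTx:0:1`).
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_id <- if ("gene_id" %in% names(d)) d$gene_id else NA_character_
  sig_cols <- setdiff(names(d), c("probe_id", "gene_id"))
  parts <- strsplit(sig_cols, ":", fixed = TRUE)
  samples <- data.frame(
    sample_id = sig_cols,
    variety = vapply(parts, `[`, "", 1),
    time = as.numeric(vapply(parts, `[`, "", 2)),
    replicate = as.integer(vapply(parts, `[`, "", 3))
  )
  expression_matrix(as.matrix(d[, sig_cols]), samples,
                    data.frame(probe_id = d$probe_id, gene_id = gene_id))
}

#' @rdname read_expression
#' @param mat an [expression_matrix()].
#' @export
write_expression <- function(mat, path) {
  d <- data.frame(probe_id = mat$probes$probe_id,
                  gene_id = mat$probes$gene_id, mat$signals,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-array median normalization
#'
#' Scales each array (column) so its median equals the grand median of
#' all arrays; a simple, monotone stand-in for platform-specific array
#' processing.
#'
#' @param mat an [expression_matrix()].
#' @return the normalized [expression_matrix()].
#' @export
normalize_expression <- function(mat) {
  med <- apply(mat$signals, 2, median)
  mat$signals <- sweep(mat$signals, 2, median(mat$signals) / med, `*`)
  mat
}

#' Detection calls
#'
#' A probe is expressed in a (variety, time) when its signal reaches
#' `threshold` in ALL replicates; expressed in a variety when expressed
#' at >= 1 time point. Per variety the expressed probes partition into
#' condition classes: `normal_only` (0 h only), `treated_only`
#' (sucrose, 2 or 6 h, only) and `both`.
#'
#' @param mat an [expression_matrix()].
#' @param threshold detection signal threshold.
#' @return list with `per_time` (logical matrix probe x "variety:time"),
#'   `per_variety` (logical matrix probe x variety) and
#'   `condition_class` (character matrix probe x variety in
#'   none/normal_only/treated_only/both).
#' @export
detect_expressed <- function(mat, threshold = 25) {
  sm <- mat$samples
  keys <- sort(unique(paste(sm$variety, sm$time, sep = ":")))
  per_time <- sapply(keys, function(k) {
    cols <- which(paste(sm$variety, sm$time, sep = ":") == k)
    apply(mat$signals[, cols, drop = FALSE] >= threshold, 1, all)
  })
  varieties <- sort(unique(sm$variety))
  per_variety <- sapply(varieties, function(v) {
    cols <- grep(paste0("^", v, ":"), keys)
    apply(per_time[, cols, drop = FALSE], 1, any)
  })
  condition_class <- sapply(varieties, function(v) {
    normal <- per_time[, paste0(v, ":0")]
    treated_cols <- keys[grepl(paste0("^", v, ":"), keys) & !endsWith(keys, ":0")]
    treated <- apply(per_time[, treated_cols, drop = FALSE], 1, any)
    ifelse(normal & treated, "both",
           ifelse(normal, "normal_only",
                  ifelse(treated, "treated_only", "none")))
  })
  rownames(per_variety) <- rownames(condition_class) <- mat$probes$probe_id
  list(per_time = per_time, per_variety = per_variety,
       condition_class = condition_class, threshold = threshold)
}

#' Abundance bins for processed signals
#'
#' low: < 50; middle: 50-500; high: 500-5000; very_high: > 5000. The
#' bins partition the non-negative reals.
#'
#' @param signal numeric vector.
#' @return character vector of bins.
#' @export
bin_abundance <- function(signal) {
  ifelse(signal < 50, "low",
         ifelse(signal < 500, "middle",
                ifelse(signal <= 5000, "high", "very_high")))
}

#' Six-class expression-divergence calls
#'
#' Per probe and variety pair (`v1`, `v2` = first and second variety in
#' the sample table): `specific_vX` when expressed only in X;
#' `fold2_vX` when expressed in both and the mean normal-condition (0 h)
#' signal is at least twice higher in X; sucrose direction `up` when
#' expressed in the variety and mean treated / mean 0 h signal is >= 2
#' at >= 1 time point with no time point giving the opposite call
#' (`down` symmetric at <= 0.5); `sucrose_only_vX` when the direction is
#' non-none in X only. Abundance bins are the mean 0 h signal bins,
#' defined only for expressed probes.
#'
#' @param mat an [expression_matrix()].
#' @param det result of [detect_expressed()] on `mat`.
#' @return data.frame keyed by probe_id with the class flags, sucrose
#'   directions, abundance bins and mean normal signals.
#' @export
classify_divergence <- function(mat, det) {
  sm <- mat$samples
  varieties <- sort(unique(sm$variety))
  stopifnot(length(varieties) == 2)
  v1 <- varieties[1]
  v2 <- varieties[2]
  mean_at <- function(v, t) {
    cols <- which(sm$variety == v & sm$time == t)
    rowMeans(mat$signals[, cols, drop = FALSE])
  }
  m1 <- mean_at(v1, 0)
  m2 <- mean_at(v2, 0)
  e1 <- det$per_variety[, v1]
  e2 <- det$per_variety[, v2]
  sucrose_dir <- function(v) {
    m0 <- mean_at(v, 0)
    times <- setdiff(unique(sm$time), 0)
    ratios <- sapply(times, function(t) mean_at(v, t) / pmax(m0, 1e-9))
    up <- apply(ratios >= 2, 1, any) & !apply(ratios <= 0.5, 1, any)
    down <- apply(ratios <= 0.5, 1, any) & !apply(ratios >= 2, 1, any)
    ifelse(!det$per_variety[, v], "none",
           ifelse(up, "up", ifelse(down, "down", "none")))
  }
  d1 <- sucrose_dir(v1)
  d2 <- sucrose_dir(v2)
  out <- data.frame(
    probe_id = mat$probes$probe_id,
    gene_id = mat$probes$gene_id,
    specific_v1 = e1 & !e2,
    specific_v2 = e2 & !e1,
    fold2_v1 = e1 & e2 & m1 >= 2 * m2,
    fold2_v2 = e1 & e2 & m2 >= 2 * m1,
    sucrose_dir_v1 = d1,
    sucrose_dir_v2 = d2,
    sucrose_only_v1 = d1 != "none" & d2 == "none",
    sucrose_only_v2 = d2 != "none" & d1 == "none",
    mean_normal_v1 = m1,
    mean_normal_v2 = m2,
    abundance_bin_v1 = ifelse(e1, bin_abundance(m1), NA),
    abundance_bin_v2 = ifelse(e2, bin_abundance(m2), NA),
    stringsAsFactors = FALSE
  )
  out$divergent <- out$specific_v1 | out$specific_v2 | out$fold2_v1 |
    out$fold2_v2 | out$sucrose_only_v1 | out$sucrose_only_v2
  attr(out, "varieties") <- varieties
  out
}

#' Venn partition of named sets
#'
#' Counts every disjoint region of the Venn diagram over the union of
#' the sets; regions sum to the union size.
#'
#' @param sets named list of character vectors.
#' @return data.frame(region, count); region labels are
#'   "+"-joined member names.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "+"))
  counts <- table(key)
  data.frame(region = names(counts), count = as.integer(counts),
             row.names = NULL)
}

#' Relative expression by the delta-delta-CT method
#'
#' For each gene: per-replicate delta-CT = CT(target) - CT(reference);
#' delta-delta-CT = mean delta-CT(test) - mean delta-CT(calibrator);
#' relative amount = 2^-ddCT. A two-sample t test on the replicate
#' delta-CT values gives the p value.
#'
#' @param ct_table data.frame(gene, sample, replicate, C_T_target,
#'   C_T_reference).
#' @param test_sample,calibrator_sample sample labels.
#' @return data.frame(gene, delta_ct_test, delta_ct_calibrator, ddct,
#'   relative_amount, p_value).
#' @export
ddct <- function(ct_table, test_sample, calibrator_sample) {
  need <- c("gene", "sample", "replicate", "C_T_target", "C_T_reference")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  }
  rows <- lapply(unique(ct_table$gene), function(g) {
    d <- ct_table[ct_table$gene == g, , drop = FALSE]
    if (any(is.na(d$C_T_reference))) stop("missing reference gene CT for ", g)
    dct <- d$C_T_target - d$C_T_reference
    t_i <- d$sample == test_sample
    c_i <- d$sample == calibrator_sample
    if (sum(t_i) < 2 || sum(c_i) < 2) stop("need >= 2 replicates per sample")
    dd <- mean(dct[t_i]) - mean(dct[c_i])
    # degenerate (zero-variance) replicate sets: p from the mean difference
    p <- tryCatch(t.test(dct[t_i], dct[c_i])$p.value,
                  error = function(e) as.numeric(dd == 0))
    data.frame(gene = g, delta_ct_test = mean(dct[t_i]),
               delta_ct_calibrator = mean(dct[c_i]), ddct = dd,
               relative_amount = 2^(-dd), p_value = p)
  })
  do.call(rbind, rows)
}
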