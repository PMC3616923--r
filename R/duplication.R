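## Gene-family clustering by transitive closure and tandem/segmental
## duplicate identification.

#' All-versus-all protein similarity hits
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) for every
#' ordered protein pair; a hit is retained when identity over the
#' aligned region is at least `min_identity` and the aligned length
#' covers at least `min_coverage` of the query. A shared-k-mer prefilter
#' keeps large inputs tractable; `prefilter = FALSE` forces the exact
#' all-pairs scan.
#'
#' @param proteins named character vector of protein sequences (no
#'   trailing stop needed; `*` characters are stripped).
#' @param min_identity,min_coverage retention thresholds.
#' @param prefilter use the shared k-mer candidate filter.
#' @param kmer,min_shared prefilter parameters: candidate pairs must
#'   share at least `min_shared` distinct `kmer`-mers.
#' @return data.frame(query_id, subject_id, identity, query_coverage,
#'   score); no self-hits.
#' @export
all_vs_all_hits <- function(proteins, min_identity = 0.70,
                            min_coverage = 0.30, prefilter = TRUE,
                            kmer = 4, min_shared = 8) {
  stopifnot(length(proteins) >= 2, !is.null(names(proteins)))
  proteins <- gsub("*", "", proteins, fixed = TRUE)
  ids <- names(proteins)
  pairs <- if (prefilter) {
    kmer_candidate_pairs(proteins, kmer, min_shared)
  } else {
    t(combn(seq_along(ids), 2))
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      score = numeric(0)))
  }
  sub_mat <- blosum62()
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[i]]), Biostrings::AAString(proteins[[j]]),
      substitutionMatrix = sub_mat, gapOpening = 10, gapExtension = 0.5,
      type = "local"
    )
    ncols <- Biostrings::nchar(pa)
    if (ncols == 0) next
    ident <- Biostrings::nmatch(pa) / ncols
    alen_q <- Biostrings::width(Biostrings::pattern(pa))
    alen_s <- Biostrings::width(Biostrings::subject(pa))
    out <- list()
    if (ident >= min_identity && alen_q / nchar(proteins[[i]]) >= min_coverage) {
      out$fwd <- data.frame(query_id = ids[i], subject_id = ids[j],
                            identity = ident,
                            query_coverage = alen_q / nchar(proteins[[i]]),
                            score = Biostrings::score(pa))
    }
    if (ident >= min_identity && alen_s / nchar(proteins[[j]]) >= min_coverage) {
      out$rev <- data.frame(query_id = ids[j], subject_id = ids[i],
                            identity = ident,
                            query_coverage = alen_s / nchar(proteins[[j]]),
                            score = Biostrings::score(pa))
    }
    if (length(out) > 0) rows[[r]] <- do.call(rbind, out)
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## shared-distinct-k-mer counts per protein pair via a sparse indicator
## matrix; returns candidate index pairs sharing >= min_shared k-mers
kmer_candidate_pairs <- function(proteins, kmer, min_shared) {
  n <- length(proteins)
  km <- lapply(proteins, function(p) {
    L <- nchar(p)
    if (L < kmer) return(character(0))
    unique(substring(p, 1:(L - kmer + 1), kmer:L))
  })
  words <- unique(unlist(km))
  if (length(words) == 0) return(NULL)
  i <- rep(seq_len(n), lengths(km))
  j <- match(unlist(km), words)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n, length(words)))
  shared <- as.matrix(Matrix::tcrossprod(m))
  hit <- which(shared >= min_shared, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  unname(hit)
}

#' Cluster similarity hits into gene families by transitive closure
#'
#' A pair qualifies when either direction passed the hit filter; the
#' families are the connected components of the resulting graph (if
#' A = B and B = C then A = C). Family ids are deterministic: the
#' lexicographically smallest member prefixed with "F_". Singletons are
#' not families.
#'
#' @param hits data.frame from [all_vs_all_hits()].
#' @return data.frame(family_id, gene_id).
#' @export
cluster_families <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(family_id = character(0), gene_id = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = pmin(hits$query_id, hits$subject_id),
                      to = pmax(hits$query_id, hits$subject_id))),
    directed = FALSE
  )
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  rows <- lapply(member, function(ids) {
    ids <- sort(ids)
    data.frame(family_id = paste0("F_", ids[1]), gene_id = ids)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score tandemly duplicated gene pairs
#'
#' Two genes of the same family on the same chromosome form a tandem
#' pair when the number of intervening genes that do NOT belong to the
#' family is at most `max_spacing`. A gene may appear in several pairs
#' (tandem arrays).
#'
#' @param genome an [annotated_genome()] (provides gene order).
#' @param families data.frame from [cluster_families()].
#' @param max_spacing maximum number of unrelated intervening genes.
#' @return data.frame(gene1, gene2, family_id, n_intervening_unrelated).
#' @export
score_tandem <- function(genome, families, max_spacing = 10) {
  genes <- genome$genes[!genome$genes$deleted, , drop = FALSE]
  rows <- list()
  for (fid in unique(families$family_id)) {
    members <- families$gene_id[families$family_id == fid]
    gm <- genes[genes$gene_id %in% members, , drop = FALSE]
    for (ch in unique(gm$chrom_id)) {
      gc_ <- gm[gm$chrom_id == ch, , drop = FALSE]
      if (nrow(gc_) < 2) next
      gc_ <- gc_[order(gc_$order_index), , drop = FALSE]
      chrom_genes <- genes[genes$chrom_id == ch, , drop = FALSE]
      for (i in seq_len(nrow(gc_) - 1)) {
        for (j in seq(i + 1, nrow(gc_))) {
          between <- chrom_genes$order_index > gc_$order_index[i] &
            chrom_genes$order_index < gc_$order_index[j]
          n_unrel <- sum(between & !(chrom_genes$gene_id %in% members))
          if (n_unrel <= max_spacing) {
            rows[[length(rows) + 1]] <- data.frame(
              gene1 = gc_$gene_id[i], gene2 = gc_$gene_id[j],
              family_id = fid, n_intervening_unrelated = n_unrel
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      family_id = character(0),
                      n_intervening_unrelated = integer(0)))
  }
  do.call(rbind, rows)
}

#' Find segmental duplication blocks by collinear anchor chaining
#'
#' Homologous gene pairs (either hit direction) are chained by dynamic
#' programming into collinear blocks between chromosome regions: anchors
#' must advance strictly in gene rank on both chromosomes (same or
#' inverted orientation) with a per-step rank gap of at most
#' `max_gap_genes`; blocks need at least `min_anchors` anchors. Members
#' of a tandem array (same family, same chromosome, within
#' `tandem_spacing` unrelated genes) are collapsed to one representative
#' before chaining. This chain finder is a simple built-in stand-in for
#' curated segmental-pair resources; [load_segmental_pairs()] loads such
#' a resource directly.
#'
#' @param genome an [annotated_genome()].
#' @param hits data.frame from [all_vs_all_hits()].
#' @param min_anchors minimum collinear anchors per block.
#' @param max_gap_genes maximum gene-rank gap between consecutive anchors.
#' @param tandem_spacing array-collapsing spacing (as in [score_tandem()]).
#' @return list of blocks; each block is a list(block_id, chrom1, chrom2,
#'   orientation, anchors = data.frame(gene1, gene2)).
#' @export
find_segmental_blocks <- function(genome, hits, min_anchors = 5,
                                  max_gap_genes = 25, tandem_spacing = 10) {
  if (nrow(hits) == 0) return(list())
  genes <- genome$genes[!genome$genes$deleted, , drop = FALSE]
  fam <- cluster_families(hits)
  # representative per tandem array: lowest order_index member of a run
  rep_of <- setNames(genes$gene_id, genes$gene_id)
  for (fid in unique(fam$family_id)) {
    members <- fam$gene_id[fam$family_id == fid]
    gm <- genes[genes$gene_id %in% members, , drop = FALSE]
    for (ch in unique(gm$chrom_id)) {
      gc_ <- gm[gm$chrom_id == ch, , drop = FALSE]
      gc_ <- gc_[order(gc_$order_index), , drop = FALSE]
      if (nrow(gc_) < 2) next
      run_rep <- gc_$gene_id[1]
      for (k in seq(2, nrow(gc_))) {
        if (gc_$order_index[k] - gc_$order_index[k - 1] - 1 <= tandem_spacing) {
          rep_of[gc_$gene_id[k]] <- run_rep
        } else {
          run_rep <- gc_$gene_id[k]
        }
      }
    }
  }
  pr <- unique(data.frame(a = rep_of[pmin(hits$query_id, hits$subject_id)],
                          b = rep_of[pmax(hits$query_id, hits$subject_id)]))
  pr <- pr[pr$a != pr$b, , drop = FALSE]
  gi <- match(pr$a, genes$gene_id)
  gj <- match(pr$b, genes$gene_id)
  anchors <- data.frame(
    g1 = pr$a, g2 = pr$b,
    c1 = genes$chrom_id[gi], o1 = genes$order_index[gi],
    c2 = genes$chrom_id[gj], o2 = genes$order_index[gj]
  )
  # orient so (c1, o1) <= (c2, o2)
  swap <- anchors$c1 > anchors$c2 | (anchors$c1 == anchors$c2 & anchors$o1 > anchors$o2)
  anchors[swap, c("g1", "g2", "c1", "o1", "c2", "o2")] <-
    anchors[swap, c("g2", "g1", "c2", "o2", "c1", "o1")]
  # drop close same-chromosome pairs (tandem neighbourhood)
  anchors <- anchors[!(anchors$c1 == anchors$c2 &
                         abs(anchors$o1 - anchors$o2) <= tandem_spacing), ,
                     drop = FALSE]
  blocks <- list()
  for (key in unique(paste(anchors$c1, anchors$c2))) {
    aa <- anchors[paste(anchors$c1, anchors$c2) == key, , drop = FALSE]
    for (orient in c("same", "inverted")) {
      blocks <- c(blocks, chain_anchors(aa, orient, min_anchors, max_gap_genes))
    }
  }
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("B%03d", i)
  blocks
}

## longest chains of strictly collinear anchors with bounded rank gaps;
## used anchors are removed and chaining repeats for secondary blocks
chain_anchors <- function(aa, orient, min_anchors, max_gap_genes) {
  out <- list()
  repeat {
    if (nrow(aa) < min_anchors) break
    aa <- aa[order(aa$o1, if (orient == "same") aa$o2 else -aa$o2), , drop = FALSE]
    n <- nrow(aa)
    best <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        d1 <- aa$o1[i] - aa$o1[j]
        d2 <- if (orient == "same") aa$o2[i] - aa$o2[j] else aa$o2[j] - aa$o2[i]
        if (d1 >= 1 && d2 >= 1 && d1 <= max_gap_genes && d2 <= max_gap_genes &&
            best[j] + 1L > best[i]) {
          best[i] <- best[j] + 1L
          prev[i] <- j
        }
      }
    }
    if (max(best) < min_anchors) break
    i <- which.max(best)
    chain <- integer(0)
    while (!is.na(i)) {
      chain <- c(i, chain)
      i <- prev[i]
    }
    out[[length(out) + 1]] <- list(
      block_id = NA_character_,
      chrom1 = aa$c1[1], chrom2 = aa$c2[1], orientation = orient,
      anchors = data.frame(gene1 = aa$g1[chain], gene2 = aa$g2[chain])
    )
    aa <- aa[-chain, , drop = FALSE]
  }
  out
}

#' Load precomputed segmental pairs
#'
#' TSV with columns gene1, gene2 and optionally block_id; the canonical
#' route when a curated segmental-duplication resource is available.
#'
#' @param path file path.
#' @return list of blocks in the [find_segmental_blocks()] format.
#' @export
load_segmental_pairs <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene1", "gene2") %in% names(d)))
  if (is.null(d$block_id)) d$block_id <- "B001"
  lapply(unique(d$block_id), function(b) {
    list(block_id = b, chrom1 = NA, chrom2 = NA, orientation = NA,
         anchors = d[d$block_id == b, c("gene1", "gene2")])
  })
}

#' Gene ids involved in a set of segmental blocks
#' @param blocks list from [find_segmental_blocks()].
#' @return character vector of gene ids.
#' @export
segmental_genes <- function(blocks) {
  unique(unlist(lapply(blocks, function(b) c(b$anchors$gene1, b$anchors$gene2))))
}
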