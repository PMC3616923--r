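## Apply a variant set to a genome, detect premature stops and tabulate
## per-gene variant burden.
##
## Variant semantics: SNP (1 bp substitution), INS (alt inserted before
## pos, ref empty), DEL (ref deleted, alt empty), SV (sv_class "deletion"
## applied like DEL; "duplication"/"other" counted for burden and flagged
## but not applied to sequence).

applied_variant <- function(v) {
  v$vtype %in% c("SNP", "INS", "DEL") |
    (v$vtype == "SV" & v$sv_class == "deletion")
}

## half-open variant interval used for gene overlap (INS is a point)
variant_interval <- function(v) {
  len <- nchar(v$ref)
  cbind(start = v$pos, end = v$pos + pmax(len, 1L))
}

#' Apply a variant set to a genome
#'
#' Rebuilds every chromosome with the variants applied and lifts gene
#' models over the resulting coordinate changes. Genes whose span falls
#' entirely inside a deletion are marked `deleted` (their CDS is
#' removed); a CDS partially cut by a deletion is clamped to the
#' deletion edge.
#'
#' @param genome an [annotated_genome()] (variety 1).
#' @param variants variant data.frame (see [read_variants()]); ref
#'   alleles must match the reference, otherwise an error names the
#'   offending variant.
#' @return the variety-2 [annotated_genome()].
#' @export
apply_variants <- function(genome, variants) {
  validate_variants(variants)
  sequences <- genome$sequences
  genes <- genome$genes
  cds <- genome$cds
  for (ch in names(sequences)) {
    v <- variants[variants$chrom_id == ch, , drop = FALSE]
    if (nrow(v) == 0) next
    v <- v[order(v$pos), , drop = FALSE]
    obs <- substring(sequences[[ch]], v$pos + 1L, v$pos + nchar(v$ref))
    bad <- which(obs != v$ref)
    if (length(bad) > 0) {
      stop(sprintf("ref mismatch for %s variant at %s:%d (expected %s, found %s)",
                   v$vtype[bad[1]], ch, v$pos[bad[1]] + 1L,
                   v$ref[bad[1]], obs[bad[1]]))
    }
    a <- v[applied_variant(v), , drop = FALSE]
    if (nrow(a) > 0 && any(a$pos[-1] < (a$pos + nchar(a$ref))[-nrow(a)])) {
      stop("overlapping variants on ", ch)
    }
    ref_len <- nchar(a$ref)
    alt_len <- nchar(a$alt)
    vend <- a$pos + ref_len
    cumdelta <- cumsum(alt_len - ref_len)
    # rebuild sequence
    if (nrow(a) > 0) {
      prev <- c(0L, vend[-nrow(a)])
      keep <- substring(sequences[[ch]], prev + 1L, a$pos)
      tail_seq <- substring(sequences[[ch]], vend[nrow(a)] + 1L,
                            nchar(sequences[[ch]]))
      sequences[[ch]] <- paste(c(rbind(keep, a$alt), tail_seq), collapse = "")
    }
    # liftover of a boundary coordinate; positions inside a deleted span
    # clamp to the (lifted) deletion start
    lift <- function(x) {
      n <- findInterval(x, vend)
      shift <- c(0, cumdelta)[n + 1L]
      inside <- findInterval(x, a$pos) # variants starting at or before x
      out <- x + shift
      for (k in seq_along(x)) {
        j <- inside[k]
        if (j >= 1 && x[k] > a$pos[j] && x[k] < vend[j]) {
          # within variant j: clamp into its alt allele
          base <- a$pos[j] + c(0, cumdelta)[j]
          out[k] <- base + min(x[k] - a$pos[j], alt_len[j])
        }
      }
      out
    }
    gi <- which(genes$chrom_id == ch & !genes$deleted)
    if (length(gi) > 0) {
      del <- a[ref_len > 0 & alt_len == 0, , drop = FALSE]
      for (i in gi) {
        gid <- genes$gene_id[i]
        fully_deleted <- nrow(del) > 0 &&
          any(del$pos <= genes$start[i] &
              (del$pos + nchar(del$ref)) >= genes$end[i])
        if (fully_deleted) {
          genes$deleted[i] <- TRUE
          cds[[gid]] <- NULL
          next
        }
        genes$start[i] <- lift(genes$start[i])
        genes$end[i] <- lift(genes$end[i])
        if (genes$coding[i] && !is.null(cds[[gid]])) {
          m <- cds[[gid]]
          m[, 1] <- lift(m[, 1])
          m[, 2] <- lift(m[, 2])
          m <- m[m[, 2] > m[, 1], , drop = FALSE]
          if (nrow(m) == 0) {
            genes$deleted[i] <- TRUE
            cds[[gid]] <- NULL
          } else {
            cds[[gid]] <- m
          }
        }
      }
    }
  }
  annotated_genome(sequences, genes, cds)
}

#' Per-gene variant burden
#'
#' A gene is counted for a variant type when at least one variant of
#' that type intersects its span (half-open overlap; insertions are
#' points). INS and DEL are pooled as indels, matching the usual
#' SNP/indel/SV grouping.
#'
#' @param genome an [annotated_genome()].
#' @param variants variant data.frame.
#' @return list with character vectors `snp_genes`, `indel_genes`,
#'   `sv_genes`.
#' @export
overlap_counts <- function(genome, variants) {
  iv <- variant_interval(variants)
  hit_genes <- function(sel) {
    vs <- iv[sel, , drop = FALSE]
    vc <- variants$chrom_id[sel]
    g <- genome$genes
    out <- character(0)
    for (i in seq_len(nrow(g))) {
      same <- vc == g$chrom_id[i]
      if (any(same & vs[, "start"] < g$end[i] & vs[, "end"] > g$start[i])) {
        out <- c(out, g$gene_id[i])
      }
    }
    out
  }
  list(
    snp_genes = hit_genes(variants$vtype == "SNP"),
    indel_genes = hit_genes(variants$vtype %in% c("INS", "DEL")),
    sv_genes = hit_genes(variants$vtype == "SV")
  )
}

first_stop_codon <- function(protein) {
  i <- regexpr("*", protein, fixed = TRUE)
  if (i < 0) Inf else as.integer(i)
}

#' Classify per-gene variant impacts
#'
#' For each coding gene, compares the variety-1 and variety-2 CDS
#' translations. A premature stop is any in-frame stop strictly upstream
#' of the variety-1 stop position, including frameshift-induced stops; a
#' destroyed start codon is reported separately as `start_lost`, not as
#' a premature stop. Genes removed by deletions or overlapped by
#' copy-number SVs are flagged `deleted_or_cnv` and carry no variety-2
#' CDS.
#'
#' @param genome1 reference-variety genome.
#' @param genome2 result of [apply_variants()] on `genome1`.
#' @param variants the variant data.frame that produced `genome2`.
#' @return data.frame, one row per coding gene: gene_id, n_snp, n_indel,
#'   n_sv, premature_stop, cause, frameshift, start_lost,
#'   deleted_or_cnv, variety2_cds.
#' @export
classify_gene_impacts <- function(genome1, genome2, variants) {
  iv <- variant_interval(variants)
  g1 <- genome1$genes
  coding <- which(g1$coding)
  rows <- vector("list", length(coding))
  for (r in seq_along(coding)) {
    i <- coding[r]
    gid <- g1$gene_id[i]
    same <- variants$chrom_id == g1$chrom_id[i]
    ov <- same & iv[, "start"] < g1$end[i] & iv[, "end"] > g1$start[i]
    n_snp <- sum(ov & variants$vtype == "SNP")
    n_indel <- sum(ov & variants$vtype %in% c("INS", "DEL"))
    n_sv <- sum(ov & variants$vtype == "SV")
    j <- match(gid, genome2$genes$gene_id)
    deleted <- is.na(j) || genome2$genes$deleted[j]
    cnv <- any(ov & variants$vtype == "SV" & variants$sv_class == "duplication")
    m <- genome1$cds[[gid]]
    cds_ov <- rep(FALSE, nrow(variants))
    for (k in seq_len(nrow(m))) {
      cds_ov <- cds_ov | (same & iv[, "start"] < m[k, 2] & iv[, "end"] > m[k, 1])
    }
    premature <- FALSE
    frameshift <- FALSE
    start_lost <- FALSE
    v2_cds <- NA_character_
    if (!deleted && !cnv) {
      v2_cds <- extract_cds(genome2, gid)
      p1 <- suppressWarnings(translate_dna(extract_cds(genome1, gid)))
      p2 <- suppressWarnings(translate_dna(v2_cds))
      premature <- first_stop_codon(p2) < first_stop_codon(p1)
      indel_net <- sum((nchar(variants$alt) - nchar(variants$ref))[
        cds_ov & variants$vtype %in% c("INS", "DEL")])
      frameshift <- indel_net %% 3L != 0L
      start_lost <- substr(v2_cds, 1, 3) != "ATG"
    }
    cause <- if (premature) {
      paste(sort(unique(variants$vtype[cds_ov])), collapse = ",")
    } else ""
    rows[[r]] <- data.frame(
      gene_id = gid, n_snp = n_snp, n_indel = n_indel, n_sv = n_sv,
      premature_stop = premature, cause = cause, frameshift = frameshift,
      start_lost = start_lost, deleted_or_cnv = deleted || cnv,
      variety2_cds = v2_cds, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
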