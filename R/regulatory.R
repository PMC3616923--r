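## Promoter extraction and variation, IUPAC motif scanning and frequency
## comparison, bisulfite methylation calling.

#' Extract promoter pairs from two variety genomes
#'
#' The promoter is the `L` bases immediately 5' of the start codon in
#' transcript orientation (reverse-complemented for minus-strand genes),
#' truncated (and flagged) at contig edges. Variation between the two
#' varieties is called by direct comparison when the extracted sequences
#' have equal length and by global alignment otherwise. Genes missing or
#' deleted in either variety are skipped.
#'
#' @param genome1,genome2 [annotated_genome()] objects sharing gene ids.
#' @param L promoter length in bp (1500 for variation analysis, 1000
#'   for motif analysis).
#' @return data.frame(gene_id, seq_v1, seq_v2, truncated, has_variation,
#'   n_differences).
#' @export
extract_promoters <- function(genome1, genome2, L = 1500) {
  one <- function(genome, gid) {
    i <- match(gid, genome$genes$gene_id)
    if (is.na(i) || genome$genes$deleted[i]) return(NULL)
    ch <- genome$genes$chrom_id[i]
    n <- nchar(genome$sequences[[ch]])
    if (genome$genes$strand[i] == "+") {
      s <- max(0L, genome$genes$start[i] - L)
      e <- genome$genes$start[i]
      seq <- seq_slice(genome$sequences, ch, s, e)
    } else {
      s <- genome$genes$end[i]
      e <- min(n, genome$genes$end[i] + L)
      seq <- revcomp(seq_slice(genome$sequences, ch, s, e))
    }
    list(seq = seq, truncated = (e - s) < L)
  }
  rows <- lapply(genome1$genes$gene_id, function(gid) {
    p1 <- one(genome1, gid)
    p2 <- one(genome2, gid)
    if (is.null(p1) || is.null(p2)) return(NULL)
    if (nchar(p1$seq) == nchar(p2$seq)) {
      nd <- sum(strsplit(p1$seq, "")[[1]] != strsplit(p2$seq, "")[[1]])
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(p1$seq), Biostrings::DNAString(p2$seq),
        type = "global"
      )
      a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      nd <- sum(a != b)
    }
    data.frame(gene_id = gid, seq_v1 = p1$seq, seq_v2 = p2$seq,
               truncated = p1$truncated || p2$truncated,
               has_variation = nd > 0, n_differences = nd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Fractions of promoters with and without variation
#'
#' @param pairs data.frame from [extract_promoters()].
#' @param subset optional character vector of gene ids to restrict to.
#' @return named numeric c(with_variation, without_variation); sums to 1.
#' @export
variation_fractions <- function(pairs, subset = NULL) {
  if (!is.null(subset)) pairs <- pairs[pairs$gene_id %in% subset, , drop = FALSE]
  if (nrow(pairs) == 0) stop("empty promoter subset")
  w <- mean(pairs$has_variation)
  c(with_variation = w, without_variation = 1 - w)
}

#' Scan promoters for IUPAC motifs
#'
#' Degenerate IUPAC matching on both strands; overlapping occurrences
#' are counted. Presence means >= 1 occurrence on either strand.
#'
#' @param promoters named character vector (names = promoter/gene ids).
#' @param motifs data.frame(motif_id, pattern) as from [read_motifs()].
#' @return data.frame(promoter_id, motif_id, count, present).
#' @export
scan_motifs <- function(promoters, motifs) {
  ok <- grepl("^[ACGTUWSMKRYBDHVN]+$", motifs$pattern)
  if (!all(ok)) {
    stop("invalid IUPAC code in motif: ",
         paste(motifs$motif_id[!ok], collapse = ", "))
  }
  subj <- Biostrings::DNAStringSet(promoters)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    pat <- Biostrings::DNAString(motifs$pattern[i])
    fwd <- Biostrings::vcountPattern(pat, subj, fixed = FALSE)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                     subj, fixed = FALSE)
    data.frame(promoter_id = names(promoters), motif_id = motifs$motif_id[i],
               count = fwd + rev, present = fwd + rev > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif over-representation between two promoter sets
#'
#' Per motif, the presence fraction in set 1 is compared with set 2 by
#' the pooled two-proportion [u_test()], with Benjamini-Hochberg FDR
#' across motifs. The motif frequency of a set is its presence fraction
#' (occurrence counts are kept but not tested).
#'
#' @param scan1,scan2 [scan_motifs()] results for the two sets.
#' @return data.frame(motif_id, y1, n1, y2, n2, u, p_one_sided,
#'   p_two_sided, fdr).
#' @export
motif_overrepresentation <- function(scan1, scan2) {
  motifs <- union(unique(scan1$motif_id), unique(scan2$motif_id))
  n1 <- length(unique(scan1$promoter_id))
  n2 <- length(unique(scan2$promoter_id))
  rows <- lapply(motifs, function(m) {
    y1 <- sum(scan1$present[scan1$motif_id == m])
    y2 <- sum(scan2$present[scan2$motif_id == m])
    t <- u_test(y1, n1, y2, n2)
    data.frame(motif_id = m, y1 = y1, n1 = n1, y2 = y2, n2 = n2,
               u = t$u, p_one_sided = t$p_one_sided,
               p_two_sided = t$p_two_sided)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_two_sided, method = "BH")
  out[order(out$p_two_sided), , drop = FALSE]
}

methylation_context <- function(ref_chars, i) {
  n <- length(ref_chars)
  if (i + 1 <= n && ref_chars[i + 1] == "G") return("CG")
  if (i + 2 <= n && ref_chars[i + 2] == "G") return("CHG")
  "CHH"
}

#' Call cytosine methylation from bisulfite clone sequences
#'
#' Clones are bisulfite-converted Sanger reads aligned to the
#' transcript-strand reference promoter (equal length, ungapped). A
#' clone passes QC when its mismatch rate at non-cytosine reference
#' positions is at most `max_mismatch_frac`. At each reference C, a
#' clone C is a methylated observation, a clone T unmethylated, anything
#' else is ignored for that clone. Context (CG, CHG, CHH) comes from the
#' reference; per-site variety differences are tested with Fisher's
#' exact test (clone counts are small). Positions are reported 1-based
#' as negative offsets from the start codon, promoter-style.
#'
#' @param reference transcript-strand reference promoter sequence.
#' @param clones_v1,clones_v2 character vectors of clone sequences per
#'   variety.
#' @param max_mismatch_frac QC gate on non-C mismatch rate.
#' @return data.frame(position, context, meth_v1, total_v1, meth_v2,
#'   total_v2, p_value) with one row per reference cytosine, plus an
#'   attribute `excluded_clones` (count failing QC).
#' @export
call_methylation <- function(reference, clones_v1, clones_v2,
                             max_mismatch_frac = 0.02) {
  ref <- strsplit(reference, "")[[1]]
  L <- length(ref)
  non_c <- which(ref != "C")
  qc <- function(clones) {
    keep <- vapply(clones, function(cl) {
      cc <- strsplit(cl, "")[[1]]
      if (length(cc) != L) return(FALSE)
      mean(cc[non_c] != ref[non_c]) <= max_mismatch_frac
    }, logical(1), USE.NAMES = FALSE)
    clones[keep]
  }
  k1 <- qc(clones_v1)
  k2 <- qc(clones_v2)
  excluded <- (length(clones_v1) - length(k1)) + (length(clones_v2) - length(k2))
  c_pos <- which(ref == "C")
  count_site <- function(clones, i) {
    b <- vapply(clones, function(cl) substr(cl, i, i), "", USE.NAMES = FALSE)
    c(meth = sum(b == "C"), total = sum(b %in% c("C", "T")))
  }
  rows <- lapply(c_pos, function(i) {
    a <- count_site(k1, i)
    b <- count_site(k2, i)
    p <- if (a[["total"]] == 0 || b[["total"]] == 0) NA_real_ else
      fisher.test(matrix(c(a[["meth"]], a[["total"]] - a[["meth"]],
                           b[["meth"]], b[["total"]] - b[["meth"]]),
                         nrow = 2))$p.value
    data.frame(position = -(L - i + 1L),
               context = methylation_context(ref, i),
               meth_v1 = a[["meth"]], total_v1 = a[["total"]],
               meth_v2 = b[["meth"]], total_v2 = b[["total"]],
               p_value = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_clones") <- excluded
  out
}
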