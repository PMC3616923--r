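## Codon-aware pairwise alignment and NG86 Ka/Ks estimation.
##
## Sites are counted with the Nei-Gojobori (1986) fractions (changes to
## stop codons excluded from the per-position denominator, so S + N = 3
## per compared codon); multi-hit codons average observed synonymous /
## nonsynonymous differences over all minimal substitution pathways that
## avoid stop codons; distances are Jukes-Cantor corrected.

STOP_CODONS <- c("TAA", "TAG", "TGA")

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Codon-aware pairwise alignment
#'
#' Translates both coding sequences, aligns the proteins globally
#' (BLOSUM62, affine gaps) and threads the alignment back onto codons so
#' that gaps occur in whole-codon units. A trailing stop codon is removed
#' before alignment; internal stops are an error (premature-stop genes
#' are handled by the variant-impact step, not here).
#'
#' @param cds1,cds2 DNA character scalars, length divisible by 3.
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return list of class `CodonAlignment` with `seq1`, `seq2` (gap-aligned
#'   codon strings of equal length), `aligned_fraction` (fraction of
#'   `cds1` codons aligned to a subject codon) and `identity` (protein
#'   identity over mutually aligned columns).
#' @export
align_codons <- function(cds1, cds2, gap_opening = 10, gap_extension = 0.5) {
  if (nchar(cds1) == 0 || nchar(cds2) == 0) stop("empty sequence")
  strip <- function(cds) {
    p <- translate_dna(cds)
    if (substring(p, nchar(p)) == "*") {
      cds <- substr(cds, 1, nchar(cds) - 3)
      p <- substr(p, 1, nchar(p) - 1)
    }
    if (grepl("*", p, fixed = TRUE)) stop("internal stop codon in CDS")
    list(cds = cds, prot = p)
  }
  a <- strip(cds1)
  b <- strip(cds2)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$prot), Biostrings::AAString(b$prot),
    substitutionMatrix = blosum62(), gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global"
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cod1 <- substring(a$cds, seq(1, nchar(a$cds), 3), seq(3, nchar(a$cds), 3))
  cod2 <- substring(b$cds, seq(1, nchar(b$cds), 3), seq(3, nchar(b$cds), 3))
  i <- j <- 0L
  s1 <- s2 <- character(length(ap))
  for (k in seq_along(ap)) {
    if (ap[k] != "-") { i <- i + 1L; s1[k] <- cod1[i] } else s1[k] <- "---"
    if (as_[k] != "-") { j <- j + 1L; s2[k] <- cod2[j] } else s2[k] <- "---"
  }
  both <- ap != "-" & as_ != "-"
  structure(list(
    seq1 = paste(s1, collapse = ""), seq2 = paste(s2, collapse = ""),
    aligned_fraction = sum(both) / length(cod1),
    identity = if (any(both)) mean(ap[both] == as_[both]) else 0
  ), class = "CodonAlignment")
}

#' Alignment acceptance filter for Ka/Ks pairs
#'
#' Accept a pair when at least `min_aligned_fraction` of the query's
#' codons are aligned (inclusive) and the protein identity over the
#' aligned region is at least `min_identity`. The identity floor screens
#' out spurious pairings of unrelated proteins.
#'
#' @param aln a [align_codons()] result.
#' @param min_aligned_fraction minimum aligned fraction of the query.
#' @param min_identity minimum protein identity over the aligned region.
#' @return logical.
#' @export
pair_filter <- function(aln, min_aligned_fraction = 0.70, min_identity = 0.30) {
  aln$aligned_fraction >= min_aligned_fraction && aln$identity >= min_identity
}

## Fraction of synonymous changes at each position of a sense codon;
## changes to stop codons are excluded from the denominator.
ng86_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    base <- substr(codon, p, p)
    syn <- 0L
    valid <- 0L
    for (b in setdiff(c("A", "C", "G", "T"), base)) {
      alt <- codon
      substr(alt, p, p) <- b
      if (alt %in% STOP_CODONS) next
      valid <- valid + 1L
      if (gc[[alt]] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

## Observed synonymous/nonsynonymous differences for one codon pair,
## averaged over minimal substitution pathways avoiding stop codons.
ng86_pair_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(d)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(d) else {
    if (k == 2) list(d, rev(d)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) d[o])
    }
  }
  walk <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && nxt != c2) return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(res) == 0) {
    res <- lapply(perms, function(order) {  # all paths blocked: keep all
      cur <- c1; sd <- nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

.ng86_cache <- new.env(parent = emptyenv())

ng86_pair_diffs_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- ng86_pair_diffs(c1, c2)
    .ng86_cache[[key]] <- v
  }
  v
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

jc_variance <- function(p, L) {
  if (is.na(p) || p >= 0.75 || L <= 0) return(NA_real_)
  p * (1 - p) / (L * (1 - 4 * p / 3)^2)
}

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Codon columns containing a gap, an N, or a stop codon in either
#' sequence are excluded. Site counts are averaged over the two
#' sequences; p-distances are Jukes-Cantor corrected, with `saturated`
#' set (and the corresponding rate undefined) when a p-distance reaches
#' 3/4.
#'
#' @param aln a [align_codons()] result (or any list with gap-aligned
#'   `seq1`, `seq2`).
#' @return list of class `KaKsResult` with S, N, Sd, Nd, Ka, Ks, ratio,
#'   var_ka, var_ks, n_codons, saturated, p_positive.
#' @export
ng86_kaks <- function(aln) {
  cod1 <- substring(aln$seq1, seq(1, nchar(aln$seq1), 3),
                    seq(3, nchar(aln$seq1), 3))
  cod2 <- substring(aln$seq2, seq(1, nchar(aln$seq2), 3),
                    seq(3, nchar(aln$seq2), 3))
  ok <- !grepl("[-N]", cod1) & !grepl("[-N]", cod2) &
    !(cod1 %in% STOP_CODONS) & !(cod2 %in% STOP_CODONS)
  cod1 <- cod1[ok]
  cod2 <- cod2[ok]
  if (length(cod1) == 0) stop("no comparable codons")
  S <- 0
  Sd <- Nd <- 0
  for (i in seq_along(cod1)) {
    S <- S + (ng86_sites_cached(cod1[i]) + ng86_sites_cached(cod2[i])) / 2
    d <- ng86_pair_diffs_cached(cod1[i], cod2[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(cod1) - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  res <- structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, Ka = Ka, Ks = Ks,
    ratio = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
    var_ka = jc_variance(pn, N), var_ks = jc_variance(ps, S),
    n_codons = length(cod1),
    saturated = is.na(Ka) || is.na(Ks),
    p_positive = NA_real_
  ), class = "KaKsResult")
  res$p_positive <- test_positive_selection(res)
  res
}

.ng86_sites_cache <- new.env(parent = emptyenv())

ng86_sites_cached <- function(codon) {
  v <- .ng86_sites_cache[[codon]]
  if (is.null(v)) {
    v <- ng86_codon_sites(codon)
    .ng86_sites_cache[[codon]] <- v
  }
  v
}

#' One-sided test for Ka > Ks
#'
#' Normal test of (Ka - Ks)/sqrt(var_Ka + var_Ks) > 0 using the
#' large-sample Jukes-Cantor variances. Returns 0.5 when both variance
#' and Ka - Ks are zero; NA when either rate is undefined (saturation).
#'
#' @param r a [ng86_kaks()] result.
#' @return one-sided p value for positive selection.
#' @export
test_positive_selection <- function(r) {
  if (is.na(r$Ka) || is.na(r$Ks)) return(NA_real_)
  v <- sum(c(r$var_ka, r$var_ks), na.rm = TRUE)
  if (v <= 0) {
    if (r$Ka == r$Ks) return(0.5)
    return(if (r$Ka > r$Ks) 0 else 1)
  }
  pnorm((r$Ka - r$Ks) / sqrt(v), lower.tail = FALSE)
}

#' Ka/Ks for a set of gene pairs
#'
#' Convenience wrapper: aligns, filters and estimates for each pair of
#' CDSs, returning one row per pair.
#'
#' @param cds_pairs data.frame(id1, id2); `cds_by_id` named character
#'   vector of CDSs.
#' @param cds_by_id named character vector mapping ids to CDS sequences.
#' @param min_aligned_fraction,min_identity see [pair_filter()].
#' @return data.frame(id1, id2, S, N, Sd, Nd, Ka, Ks, ratio, p_positive,
#'   saturated, accepted, aligned_fraction).
#' @export
kaks_pairs <- function(cds_pairs, cds_by_id,
                       min_aligned_fraction = 0.70, min_identity = 0.30) {
  rows <- lapply(seq_len(nrow(cds_pairs)), function(i) {
    id1 <- cds_pairs$id1[i]
    id2 <- cds_pairs$id2[i]
    base <- data.frame(
      id1 = id1, id2 = id2, S = NA, N = NA, Sd = NA, Nd = NA,
      Ka = NA, Ks = NA, ratio = NA, p_positive = NA,
      saturated = NA, accepted = FALSE, aligned_fraction = NA
    )
    aln <- tryCatch(align_codons(cds_by_id[[id1]], cds_by_id[[id2]]),
                    error = function(e) NULL)
    if (is.null(aln)) return(base)
    base$aligned_fraction <- aln$aligned_fraction
    if (!pair_filter(aln, min_aligned_fraction, min_identity)) return(base)
    r <- tryCatch(ng86_kaks(aln), error = function(e) NULL)
    if (is.null(r)) return(base)
    base[c("S", "N", "Sd", "Nd", "Ka", "Ks", "ratio", "p_positive")] <-
      list(r$S, r$N, r$Sd, r$Nd, r$Ka, r$Ks, r$ratio, r$p_positive)
    base$saturated <- r$saturated
    base$accepted <- TRUE
    base
  })
  do.call(rbind, rows)
}
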