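## De novo CACTA detection by terminal-inverted-repeat pairing, a naive
## LTR direct-repeat scan, and element-gene capture.

#' Find approximate terminal-repeat hits
#'
#' Scans each chromosome for approximate occurrences of each terminal
#' seed and of its reverse complement (mismatch fraction at most
#' `max_mismatch_frac`, no indels). Forward-sense occurrences are 5'
#' terminals; reverse-complement occurrences are 3' terminals.
#' Overlapping hits of the same seed and sense keep the fewest
#' mismatches.
#'
#' @param genome an [annotated_genome()].
#' @param tir_seeds named character vector of seed sequences.
#' @param max_mismatch_frac maximum mismatch fraction per hit.
#' @return data.frame(chrom_id, start, end, sense, which_end,
#'   mismatches, seed_id); 0-based half-open spans.
#' @export
find_terminal_hits <- function(genome, tir_seeds, max_mismatch_frac = 0.1) {
  stopifnot(length(tir_seeds) > 0)
  if (is.null(names(tir_seeds))) names(tir_seeds) <- paste0("seed", seq_along(tir_seeds))
  rows <- list()
  for (ch in names(genome$sequences)) {
    subject <- Biostrings::DNAString(genome$sequences[[ch]])
    for (sid in names(tir_seeds)) {
      seed <- tir_seeds[[sid]]
      max_mm <- floor(max_mismatch_frac * nchar(seed))
      for (sense in c("forward", "reverse_complement")) {
        pat <- if (sense == "forward") seed else revcomp(seed)
        mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                       max.mismatch = max_mm)
        if (length(mt) == 0) next
        mm <- vapply(as.character(mt), function(s) {
          sum(strsplit(s, "")[[1]] != strsplit(pat, "")[[1]])
        }, integer(1), USE.NAMES = FALSE)
        d <- data.frame(
          chrom_id = ch,
          start = Biostrings::start(mt) - 1L,
          end = Biostrings::end(mt),
          sense = sense,
          which_end = if (sense == "forward") "five_prime" else "three_prime",
          mismatches = mm,
          seed_id = sid
        )
        rows[[length(rows) + 1]] <- merge_overlapping_hits(d)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom_id = character(0), start = integer(0),
                      end = integer(0), sense = character(0),
                      which_end = character(0), mismatches = integer(0),
                      seed_id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom_id, out$start), , drop = FALSE]
}

## overlapping same-seed/same-sense hits keep the fewest mismatches
merge_overlapping_hits <- function(d) {
  d <- d[order(d$mismatches), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(d)) > i)
    ov <- d$start[later] < d$end[i] & d$end[later] > d$start[i]
    keep[later[ov]] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' Pair CACTA terminals into full-length elements
#'
#' Pairs a forward-sense 5' terminal with a downstream
#' reverse-complement 3' terminal on the same chromosome. The element
#' span (5' start to 3' end) must lie within `[min_sep, max_sep]` and
#' both flanks must carry an identical `tsd_len`-bp target-site
#' duplication. Candidates are selected greedily by total mismatches
#' (ties: leftmost, then shortest); each terminal is used at most once.
#'
#' @param genome an [annotated_genome()].
#' @param hits data.frame from [find_terminal_hits()].
#' @param min_sep,max_sep allowed element length range in bp.
#' @param tsd_len target-site duplication length (3 is canonical for
#'   the CACTA superfamily).
#' @return data.frame(element_id, class, chrom_id, start, end, tsd,
#'   score).
#' @export
pair_cacta <- function(genome, hits, min_sep = 200, max_sep = 30000,
                       tsd_len = 3) {
  empty <- data.frame(element_id = character(0), class = character(0),
                      chrom_id = character(0), start = integer(0),
                      end = integer(0), tsd = character(0), score = numeric(0))
  h5 <- hits[hits$which_end == "five_prime", , drop = FALSE]
  h3 <- hits[hits$which_end == "three_prime", , drop = FALSE]
  if (nrow(h5) == 0 || nrow(h3) == 0) return(empty)
  cand <- list()
  for (i in seq_len(nrow(h5))) {
    for (j in seq_len(nrow(h3))) {
      if (h5$chrom_id[i] != h3$chrom_id[j]) next
      len <- h3$end[j] - h5$start[i]
      if (len < min_sep || len > max_sep) next
      if (h3$start[j] <= h5$end[i]) next
      ch <- h5$chrom_id[i]
      s <- h5$start[i]
      e <- h3$end[j]
      if (s - tsd_len < 0 || e + tsd_len > nchar(genome$sequences[[ch]])) next
      left <- seq_slice(genome$sequences, ch, s - tsd_len, s)
      right <- seq_slice(genome$sequences, ch, e, e + tsd_len)
      if (left != right) next
      cand[[length(cand) + 1]] <- data.frame(
        i = i, j = j, chrom_id = ch, start = s, end = e, tsd = left,
        score = h5$mismatches[i] + h3$mismatches[j]
      )
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$score, cand$start, cand$end - cand$start), , drop = FALSE]
  used5 <- used3 <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$i[r] %in% used5 || cand$j[r] %in% used3) next
    keep[r] <- TRUE
    used5 <- c(used5, cand$i[r])
    used3 <- c(used3, cand$j[r])
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$chrom_id, cand$start), , drop = FALSE]
  data.frame(
    element_id = sprintf("CACTA%03d", seq_len(nrow(cand))),
    class = "CACTA", chrom_id = cand$chrom_id, start = cand$start,
    end = cand$end, tsd = cand$tsd, score = cand$score
  )
}

#' Naive LTR retrotransposon scan
#'
#' Finds long terminal direct repeats: exact `seed_len`-mer matches in
#' direct orientation separated by a distance within `sep_range` are
#' grouped by diagonal and extended to maximal repeats; a candidate is
#' kept when the repeat is at least `min_ltr` bp at `min_ident`
#' identity and the outer flanks carry an identical 4-6 bp target-site
#' duplication. A deliberately simple stand-in for full LTR annotation
#' tools; [load_elements()] loads a precomputed element table instead.
#'
#' @param genome an [annotated_genome()].
#' @param min_ltr minimum terminal-repeat length (bp).
#' @param min_ident minimum identity between the two repeats.
#' @param sep_range allowed distance between repeat starts (bp).
#' @param seed_len exact seed length.
#' @return data.frame(element_id, class, chrom_id, start, end, tsd,
#'   score); span runs from the outer edge of the 5' repeat to the
#'   outer edge of the 3' repeat.
#' @export
naive_ltr_scan <- function(genome, min_ltr = 100, min_ident = 0.85,
                           sep_range = c(1000, 15000), seed_len = 20) {
  rows <- list()
  for (ch in names(genome$sequences)) {
    s <- genome$sequences[[ch]]
    n <- nchar(s)
    if (n < 2 * seed_len) next
    starts <- 1:(n - seed_len + 1)
    words <- substring(s, starts, starts + seed_len - 1L)
    dup <- words %in% words[duplicated(words)]
    pos_by_word <- split(starts[dup] - 1L, words[dup]) # 0-based
    diag_hits <- list()
    for (pp in pos_by_word) {
      if (length(pp) < 2 || length(pp) > 25) next
      for (a in seq_len(length(pp) - 1)) {
        for (b in seq(a + 1, length(pp))) {
          d <- pp[b] - pp[a]
          if (d >= sep_range[1] && d <= sep_range[2]) {
            diag_hits[[length(diag_hits) + 1]] <- c(pp[a], d)
          }
        }
      }
    }
    if (length(diag_hits) == 0) next
    dh <- do.call(rbind, diag_hits)
    for (d in unique(dh[, 2])) {
      p <- sort(dh[dh[, 2] == d, 1])
      # split into runs of nearby seeds on the same diagonal
      grp <- cumsum(c(1, diff(p) > 2 * min_ltr))
      for (g in unique(grp)) {
        q <- p[grp == g]
        r1s <- min(q)
        r1e <- max(q) + seed_len
        # maximal outward extension of the exact repeat
        while (r1s > 0 && r1s + d + 1L <= n &&
               substr(s, r1s, r1s) == substr(s, r1s + d, r1s + d)) {
          r1s <- r1s - 1L
        }
        while (r1e + d < n &&
               substr(s, r1e + 1L, r1e + 1L) == substr(s, r1e + d + 1L, r1e + d + 1L)) {
          r1e <- r1e + 1L
        }
        if (r1e - r1s < min_ltr) next
        rep1 <- substr(s, r1s + 1L, r1e)
        rep2 <- substr(s, r1s + d + 1L, r1e + d)
        ident <- mean(strsplit(rep1, "")[[1]] == strsplit(rep2, "")[[1]])
        if (ident < min_ident) next
        tsd <- ""
        for (tl in 6:4) {
          if (r1s - tl < 0 || r1e + d + tl > n) next
          left <- substr(s, r1s - tl + 1L, r1s)
          right <- substr(s, r1e + d + 1L, r1e + d + tl)
          if (left == right) { tsd <- left; break }
        }
        if (tsd == "") next
        rows[[length(rows) + 1]] <- data.frame(
          chrom_id = ch, start = r1s, end = r1e + d, tsd = tsd,
          score = ident
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(element_id = character(0), class = character(0),
                      chrom_id = character(0), start = integer(0),
                      end = integer(0), tsd = character(0),
                      score = numeric(0)))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$chrom_id, out$start), , drop = FALSE]
  data.frame(
    element_id = sprintf("LTR%03d", seq_len(nrow(out))),
    class = "LTR", chrom_id = out$chrom_id, start = out$start,
    end = out$end, tsd = out$tsd, score = out$score
  )
}

#' Assign captured genes to elements
#'
#' A gene is captured by an element when its span intersects the
#' element span by any amount (half-open overlap), i.e. genes fully or
#' partially located within the element.
#'
#' @param elements element data.frame ([pair_cacta()], [naive_ltr_scan()]
#'   or [load_elements()]).
#' @param genome an [annotated_genome()].
#' @return list(elements = input with a `captured_gene_ids` column
#'   (comma-separated), related_genes = data.frame(gene_id, element_id,
#'   class)).
#' @export
capture_genes <- function(elements, genome) {
  genes <- genome$genes[!genome$genes$deleted, , drop = FALSE]
  rel <- list()
  cap <- character(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    g <- genes[genes$chrom_id == elements$chrom_id[i] &
                 genes$start < elements$end[i] &
                 genes$end > elements$start[i], , drop = FALSE]
    cap[i] <- paste(g$gene_id, collapse = ",")
    if (nrow(g) > 0) {
      rel[[length(rel) + 1]] <- data.frame(
        gene_id = g$gene_id, element_id = elements$element_id[i],
        class = elements$class[i]
      )
    }
  }
  elements$captured_gene_ids <- cap
  list(
    elements = elements,
    related_genes = if (length(rel) > 0) do.call(rbind, rel) else
      data.frame(gene_id = character(0), element_id = character(0),
                 class = character(0))
  )
}

#' Write / load elements as GFF3
#'
#' Elements are written as `transposable_element` features with the
#' class and TSD in the attribute column.
#'
#' @param elements element data.frame.
#' @param path file path.
#' @export
write_elements_gff3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(elements))) {
    writeLines(sprintf(
      "%s\tdivaria\ttransposable_element\t%d\t%d\t.\t+\t.\tID=%s;class=%s;tsd=%s",
      elements$chrom_id[i], elements$start[i] + 1L, elements$end[i],
      elements$element_id[i], elements$class[i], elements$tsd[i]
    ), con)
  }
  invisible(path)
}

#' @rdname write_elements_gff3
#' @export
load_elements <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[gff$type == "transposable_element", , drop = FALSE]
  data.frame(
    element_id = as.character(gff$ID),
    class = if (!is.null(gff$class)) as.character(gff$class) else NA_character_,
    chrom_id = as.character(gff$seqid),
    start = gff$start - 1L,
    end = gff$end,
    tsd = if (!is.null(gff$tsd)) as.character(gff$tsd) else "",
    score = NA_real_
  )
}
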