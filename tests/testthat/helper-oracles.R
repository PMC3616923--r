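# Independent oracles, written deliberately apart from the package code
# paths they check.

GC_TABLE <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC_TABLE)[GC_TABLE == "*"]

# all permutations of a small vector (recursive, no dependency)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# brute-force NG86 with Jukes-Cantor, one codon pair at a time
ng86_oracle <- function(s1, s2) {
  cod <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- cod(s1)
  c2 <- cod(s2)
  keep <- !grepl("[-N]", c1) & !grepl("[-N]", c2) &
    !(c1 %in% ORACLE_STOPS) & !(c2 %in% ORACLE_STOPS)
  c1 <- c1[keep]
  c2 <- c2[keep]
  site_count <- function(codon) {
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
      variants <- vapply(alts, function(b) {
        x <- codon
        substr(x, p, p) <- b
        x
      }, "")
      variants <- variants[!(variants %in% ORACLE_STOPS)]
      if (length(variants) > 0) {
        s <- s + mean(GC_TABLE[variants] == GC_TABLE[[codon]])
      }
    }
    s
  }
  diffs <- function(a, b) {
    d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(d) == 0) return(c(0, 0))
    paths <- perms_of(d)
    counted <- list()
    for (ord in paths) {
      cur <- a
      sd <- nd <- 0
      bad <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (nxt %in% ORACLE_STOPS && nxt != b) { bad <- TRUE; break }
        if (GC_TABLE[[cur]] == GC_TABLE[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!bad) counted[[length(counted) + 1]] <- c(sd, nd)
    }
    if (length(counted) == 0) {  # every route hits a stop: count them all
      for (ord in paths) {
        cur <- a
        sd <- nd <- 0
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(b, p, p)
          if (GC_TABLE[[cur]] == GC_TABLE[[nxt]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        counted[[length(counted) + 1]] <- c(sd, nd)
      }
    }
    colMeans(do.call(rbind, counted))
  }
  S <- sum((vapply(c1, site_count, 0) + vapply(c2, site_count, 0)) / 2)
  N <- 3 * length(c1) - S
  dd <- rowSums(vapply(seq_along(c1), function(i) diffs(c1[i], c2[i]),
                       numeric(2)))
  ps <- dd[1] / S
  pn <- dd[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = dd[1], Nd = dd[2], Ks = jc(ps), Ka = jc(pn))
}

# union-find connected components
unionfind_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges[i, 1])
    b <- find(edges[i, 2])
    if (a != b) parent[[a]] <- b
  }
  split(nodes, vapply(nodes, find, ""))
}

# permutation (hypergeometric) p for a two-proportion comparison
perm_two_prop_p <- function(y1, n1, y2, n2, n_draws = 1e5) {
  obs <- abs(y1 / n1 - y2 / n2)
  k <- y1 + y2
  draw <- rhyper(n_draws, k, n1 + n2 - k, n1)
  sim <- abs(draw / n1 - (k - draw) / n2)
  mean(sim >= obs - 1e-12)
}

# sliding-window Hamming scan for approximate occurrences
hamming_scan_oracle <- function(sequence, pattern, max_mm) {
  n <- nchar(sequence)
  w <- nchar(pattern)
  pc <- strsplit(pattern, "")[[1]]
  hits <- list()
  for (s in 0:(n - w)) {
    mm <- sum(strsplit(substr(sequence, s + 1, s + w), "")[[1]] != pc)
    if (mm <= max_mm) hits[[length(hits) + 1]] <- c(start = s, mm = mm)
  }
  if (length(hits) == 0) return(data.frame(start = integer(0), mm = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

random_cds_oracle <- function(n_codons) {
  sense <- setdiff(names(GC_TABLE), c(ORACLE_STOPS, "ATG"))
  paste0("ATG", paste(sample(sense, n_codons, TRUE), collapse = ""), "TAA")
}

# one small shared dataset per session (generation is seeded)
small_sim_config <- function(seed = 42) {
  sim_config(seed = seed, n_genes = 80, chrom_len_bp = 4e5, n_cacta = 3,
             n_ltr = 2, n_segmental_blocks = 1, genes_per_block = 6,
             n_sv_del = 2, n_sv_dup = 1, n_meth_genes = 2)
}

.fixture_env <- new.env()
shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- simulate_dataset(small_sim_config())
  .fixture_env$ds
}

# tiny hand-built genome: linear genes on one or two chromosomes
toy_genome <- function(gene_starts, cds_len = 9, chrom = "c1",
                       chrom_len = max(gene_starts) + 200,
                       strand = "+", cds_seq = NULL) {
  n <- length(gene_starts)
  strand <- rep(strand, length.out = n)
  seqs <- setNames(paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE),
                         collapse = ""), chrom)
  genes <- data.frame(
    gene_id = sprintf("t%02d", seq_len(n)), chrom_id = chrom,
    strand = strand, start = gene_starts, end = gene_starts + cds_len,
    coding = TRUE, deleted = FALSE
  )
  cds <- list()
  s <- seqs[[chrom]]
  for (i in seq_len(n)) {
    body <- if (is.null(cds_seq)) random_cds_oracle(cds_len / 3 - 2) else cds_seq[i]
    genomic <- if (strand[i] == "+") body else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(body)))
    substr(s, gene_starts[i] + 1, gene_starts[i] + cds_len) <- genomic
    cds[[genes$gene_id[i]]] <- cbind(start = gene_starts[i],
                                     end = gene_starts[i] + cds_len)
  }
  seqs[[chrom]] <- s
  annotated_genome(seqs, genes, cds)
}
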