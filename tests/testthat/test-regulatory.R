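test_that("promoter extraction takes L bases 5' of the start codon in transcript orientation", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  genes <- data.frame(gene_id = c("p", "m"), chrom_id = "c1",
                      strand = c("+", "-"), start = c(2000L, 200L),
                      end = c(2030L, 230L), coding = TRUE, deleted = FALSE)
  cds <- list(p = cbind(start = 2000L, end = 2030L),
              m = cbind(start = 200L, end = 230L))
  g <- annotated_genome(c(c1 = s), genes, cds)
  pp <- extract_promoters(g, g, L = 1500)
  # plus strand gene starting at 2000 with L=1500: reference [500, 2000)
  expect_equal(pp$seq_v1[pp$gene_id == "p"], substr(s, 501, 2000))
  # minus strand: downstream window, reverse-complemented
  expect_equal(pp$seq_v1[pp$gene_id == "m"], revcomp(substr(s, 231, 1730)))
  expect_false(any(pp$has_variation))   # identical genomes
  expect_true(all(pp$n_differences == 0))
  # truncation at the contig edge is flagged
  g2 <- annotated_genome(c(c1 = s), transform(genes, start = c(900L, 200L),
                                              end = c(930L, 230L)),
                         list(p = cbind(start = 900L, end = 930L),
                              m = cbind(start = 200L, end = 230L)))
  pp2 <- extract_promoters(g2, g2, L = 1500)
  expect_true(pp2$truncated[pp2$gene_id == "p"])
  expect_equal(nchar(pp2$seq_v1[pp2$gene_id == "p"]), 900)
})

test_that("variation fractions sum to one and recover the planted fraction", {
  ds <- shared_dataset()
  pp <- extract_promoters(ds$genome1, ds$genome2, L = 1500)
  fr <- variation_fractions(pp)
  expect_equal(unname(sum(fr)), 1, tolerance = 1e-12)
  truth <- ds$truth$promoter_variation
  m <- merge(pp[, c("gene_id", "has_variation")], truth, by = "gene_id")
  expect_true(all(m$has_variation.x == m$has_variation.y))
  # subsets also sum to 1; empty subsets error
  sub <- sample(pp$gene_id, 10)
  expect_equal(unname(sum(variation_fractions(pp, sub))), 1)
  expect_error(variation_fractions(pp, "no_such_gene"), "empty")
})

test_that("IUPAC motif scanning counts both strands and matches a sliding oracle", {
  proms <- c(a = "AAAGTTTTTACCC",              # forward hit
             b = paste0("GGG", revcomp("GTTTTTA"), "TTT"),  # reverse only
             c = "AAAGTTTATACCC")              # mutated: no hit
  motifs <- data.frame(motif_id = "SEF4MOTIFGM7S", pattern = "GTTTTTA")
  sc <- scan_motifs(proms, motifs)
  expect_true(sc$present[sc$promoter_id == "a"])
  expect_true(sc$present[sc$promoter_id == "b"])
  expect_false(sc$present[sc$promoter_id == "c"])
  expect_error(scan_motifs(proms, data.frame(motif_id = "bad", pattern = "QQ")),
               "invalid IUPAC")
  # degenerate pattern vs brute-force sliding count on random sequence
  set.seed(73)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  pat <- "WTTSSA"
  iupac <- list(W = c("A", "T"), S = c("C", "G"))
  match_at <- function(seq, pat, i) {
    all(vapply(seq_len(nchar(pat)), function(k) {
      pc <- substr(pat, k, k)
      sc_ <- substr(seq, i + k - 1, i + k - 1)
      if (pc %in% names(iupac)) sc_ %in% iupac[[pc]] else sc_ == pc
    }, TRUE))
  }
  brute <- function(seq, pat) {
    sum(vapply(1:(nchar(seq) - nchar(pat) + 1),
               function(i) match_at(seq, pat, i), TRUE))
  }
  want <- brute(s, pat) + brute(revcomp(s), pat)
  got <- scan_motifs(c(x = s), data.frame(motif_id = "m", pattern = pat))
  expect_equal(got$count, want)
  # strand symmetry: reverse-complementing promoters preserves presence
  sc_rc <- scan_motifs(vapply(proms, revcomp, ""), motifs)
  expect_equal(sc_rc$present, sc$present)
})

test_that("motif over-representation flags a planted frequency difference and is antisymmetric", {
  set.seed(79)
  mk_set <- function(n, frac_with) {
    has <- runif(n) < frac_with
    seqs <- vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G"), 60, TRUE), collapse = "")
      if (has[i]) substr(s, 20, 26) <- "GTTTTTA"
      s
    }, "")
    setNames(seqs, sprintf("g%03d", seq_len(n)))
  }
  motifs <- data.frame(motif_id = "SEF4MOTIFGM7S", pattern = "GTTTTTA")
  s1 <- scan_motifs(mk_set(200, 0.6), motifs)
  s2 <- scan_motifs(mk_set(200, 0.1), motifs)
  r <- motif_overrepresentation(s1, s2)
  expect_gt(r$u, 0)
  expect_lt(r$fdr, 0.05)
  r_swapped <- motif_overrepresentation(s2, s1)
  expect_equal(r_swapped$u, -r$u, tolerance = 1e-12)
  r_equal <- motif_overrepresentation(s1, s1)
  expect_equal(r_equal$u, 0)
})

test_that("methylation calling assigns contexts from the reference and counts C/T observations", {
  ref <- "ACGTACGGACTTACCC"
  # cytosines at 1-based 2 (CG), 6 (CGG -> CG), 9? positions enumerated below
  clones_meth <- rep(ref, 5)                      # all C retained
  clones_unmeth <- rep(gsub("C", "T", ref), 5)    # fully converted
  calls <- call_methylation(ref, clones_meth, clones_unmeth)
  expect_equal(nrow(calls), sum(strsplit(ref, "")[[1]] == "C"))
  expect_true(all(calls$meth_v1 == 5))
  expect_true(all(calls$meth_v2 == 0))
  # contexts: position 2 is CG; last three C's before end are CHH/CC cases
  cg_rows <- calls$context[calls$position == -(nchar(ref) - 2 + 1)]
  expect_equal(cg_rows, "CG")
  # fully converted clones yield zero methylated calls
  calls0 <- call_methylation(ref, clones_unmeth, clones_unmeth)
  expect_true(all(calls0$meth_v1 == 0))
  # clones failing the non-cytosine QC gate are excluded
  bad <- paste(rev(strsplit(ref, "")[[1]]), collapse = "")
  calls_qc <- call_methylation(ref, c(clones_meth, bad), clones_unmeth)
  expect_equal(attr(calls_qc, "excluded_clones"), 1)
})

test_that("planted methylation proportions and the differential site are recovered", {
  ds <- shared_dataset()
  truth <- ds$truth$methylation
  for (gid in unique(truth$gene_id)) {
    b1 <- ds$bisulfite[[paste0(gid, "_v1")]]
    b2 <- ds$bisulfite[[paste0(gid, "_v2")]]
    calls <- call_methylation(b1$reference, b1$clones, b2$clones)
    tr <- truth[truth$gene_id == gid, ]
    m <- merge(calls, tr, by = "position")
    # binomial 99% CI check on per-site proportions (n = 10 clones)
    ok <- mapply(function(meth, tot, p) {
      ci <- qbinom(c(0.005, 0.995), tot, p)
      meth >= ci[1] && meth <= ci[2]
    }, m$meth_v1, m$total_v1, m$p_v1)
    expect_true(mean(ok) > 0.9)
    dpos <- tr$position[tr$differential]
    drow <- calls[calls$position == dpos, ]
    expect_lt(drow$p_value, 0.05)   # 0.9 vs 0.0 planted difference
  }
})
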