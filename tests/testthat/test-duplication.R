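random_protein <- function(n) {
  aa <- setdiff(rownames(divaria:::blosum62()), c("B", "Z", "X", "*"))
  paste(sample(aa, n, TRUE), collapse = "")
}

test_that("identical proteins give a retained identity-1 hit; 60%-identical proteins are discarded", {
  set.seed(13)
  p <- random_protein(120)
  idx <- sample(120, 48)  # 60% identity
  qq <- strsplit(p, "")[[1]]
  aa <- setdiff(rownames(divaria:::blosum62()), c("B", "Z", "X", "*"))
  for (i in idx) qq[i] <- sample(setdiff(aa, qq[i]), 1)
  prots <- c(a = p, b = p, c = paste(qq, collapse = ""))
  hits <- all_vs_all_hits(prots, prefilter = FALSE)
  ab <- hits[hits$query_id == "a" & hits$subject_id == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$identity, 1)
  expect_equal(ab$query_coverage, 1)
  expect_false(any(hits$subject_id == "c" | hits$query_id == "c"))
  expect_false(any(hits$query_id == hits$subject_id))
})

test_that("the k-mer prefilter reproduces the exact all-pairs hit set on random families", {
  set.seed(19)
  base <- replicate(6, random_protein(100))
  prots <- character(0)
  for (b in base) {
    fam_size <- sample(1:4, 1)
    for (k in seq_len(fam_size)) {
      v <- strsplit(b, "")[[1]]
      flip <- sample(100, 10)
      aa <- setdiff(rownames(divaria:::blosum62()), c("B", "Z", "X", "*"))
      v[flip] <- sample(aa, 10, TRUE)
      prots <- c(prots, paste(v, collapse = ""))
    }
  }
  names(prots) <- sprintf("p%02d", seq_along(prots))
  h_fast <- all_vs_all_hits(prots, prefilter = TRUE)
  h_exact <- all_vs_all_hits(prots, prefilter = FALSE)
  key <- function(h) sort(paste(h$query_id, h$subject_id))
  expect_equal(key(h_fast), key(h_exact))
})

test_that("transitive closure merges A=B, B=C into one family and matches a union-find oracle", {
  hits <- data.frame(query_id = c("A", "B"), subject_id = c("B", "C"),
                     identity = 1, query_coverage = 1, score = 1)
  fam <- cluster_families(hits)
  expect_equal(sort(fam$gene_id[fam$family_id == "F_A"]), c("A", "B", "C"))
  empty <- hits[0, ]
  expect_equal(nrow(cluster_families(empty)), 0)
  set.seed(23)
  for (trial in 1:15) {
    nodes <- sprintf("n%02d", 1:20)
    m <- sample(5:25, 1)
    edges <- cbind(sample(nodes, m, TRUE), sample(nodes, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) == 0) next
    hits <- data.frame(query_id = edges[, 1], subject_id = edges[, 2],
                       identity = 1, query_coverage = 1, score = 1)
    fam <- cluster_families(hits)
    comp <- unionfind_components(unique(c(edges)), edges)
    comp <- lapply(comp, sort)
    got <- lapply(split(fam$gene_id, fam$family_id), sort)
    expect_equal(sort(unname(vapply(got, paste, "", collapse = ","))),
                 sort(unname(vapply(comp, paste, "", collapse = ","))))
    # and ordering of the hit table does not matter
    fam2 <- cluster_families(hits[sample(nrow(hits)), ])
    expect_equal(fam, fam2)
  }
})

test_that("tandem scoring counts unrelated intervening genes with the inclusive max-spacing rule", {
  set.seed(29)
  # 14 genes in a row; family members at ranks 1, 4 and at ranks 1, 13
  starts <- seq(100, by = 1000, length.out = 14)
  g <- toy_genome(starts, cds_len = 9)
  fam <- data.frame(family_id = "F_t01",
                    gene_id = c("t01", "t04", "t13"))
  tp <- score_tandem(g, fam, max_spacing = 10)
  # t01-t04: 2 unrelated between; t04-t13: 8; t01-t13: 10 (t04 excluded)
  key <- paste(tp$gene1, tp$gene2)
  expect_setequal(key, c("t01 t04", "t04 t13", "t01 t13"))
  expect_equal(tp$n_intervening_unrelated[match("t01 t04", key)], 2)
  expect_equal(tp$n_intervening_unrelated[match("t04 t13", key)], 8)
  expect_equal(tp$n_intervening_unrelated[match("t01 t13", key)], 10)
  # 11 unrelated genes between: not tandem
  fam2 <- data.frame(family_id = "F_t01", gene_id = c("t01", "t13"))
  expect_equal(nrow(score_tandem(g, fam2, max_spacing = 10)), 0)
})

test_that("tandem arrays enumerate all within-family pairs (spacings 2,2 give 2,2,5)", {
  starts <- seq(100, by = 1000, length.out = 9)
  g <- toy_genome(starts, cds_len = 9)
  # array members at ranks 1, 4, 7 with two unrelated genes between each
  fam <- data.frame(family_id = "F_t01", gene_id = c("t01", "t04", "t07"))
  tp <- score_tandem(g, fam)
  key <- paste(tp$gene1, tp$gene2)
  expect_equal(tp$n_intervening_unrelated[match("t01 t04", key)], 2)
  expect_equal(tp$n_intervening_unrelated[match("t04 t07", key)], 2)
  expect_equal(tp$n_intervening_unrelated[match("t01 t07", key)], 4)
})

test_that("planted tandem and segmental duplications are recovered exactly", {
  ds <- shared_dataset()
  g1 <- ds$genome1
  coding <- g1$genes$gene_id[g1$genes$coding & !g1$genes$deleted]
  prots <- setNames(vapply(coding, function(g) {
    suppressWarnings(translate_dna(extract_cds(g1, g)))
  }, ""), coding)
  hits <- all_vs_all_hits(prots)
  fam <- cluster_families(hits)
  tan <- score_tandem(g1, fam)
  got <- sort(paste(pmin(tan$gene1, tan$gene2), pmax(tan$gene1, tan$gene2)))
  want <- sort(paste(pmin(ds$truth$tandem_pairs$gene1, ds$truth$tandem_pairs$gene2),
                     pmax(ds$truth$tandem_pairs$gene1, ds$truth$tandem_pairs$gene2)))
  expect_equal(got, want)   # precision = recall = 1
  expect_true(all(g1$genes$chrom_id[match(tan$gene1, g1$genes$gene_id)] ==
                    g1$genes$chrom_id[match(tan$gene2, g1$genes$gene_id)]))
  blocks <- find_segmental_blocks(g1, hits)
  anchors <- do.call(rbind, lapply(blocks, function(b) b$anchors))
  gota <- sort(paste(pmin(anchors$gene1, anchors$gene2),
                     pmax(anchors$gene1, anchors$gene2)))
  wanta <- sort(paste(pmin(ds$truth$segmental_pairs$gene1, ds$truth$segmental_pairs$gene2),
                      pmax(ds$truth$segmental_pairs$gene1, ds$truth$segmental_pairs$gene2)))
  expect_equal(gota, wanta)
})

test_that("segmental chaining needs min_anchors collinear anchors and rejects shuffled homologs", {
  set.seed(37)
  # two chromosomes with 4 collinear homolog pairs only: below threshold
  starts <- seq(100, by = 1000, length.out = 8)
  cds <- vapply(1:4, function(i) random_cds_oracle(40), "")
  g1 <- toy_genome(starts[1:4], cds_len = 126, chrom = "cA", cds_seq = cds)
  stopifnot(all(nchar(cds) == 126))
  seqs <- c(g1$sequences,
            cB = paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""))
  genes2 <- data.frame(gene_id = sprintf("u%02d", 1:4), chrom_id = "cB",
                       strand = "+", start = starts[1:4],
                       end = starts[1:4] + 126, coding = TRUE, deleted = FALSE,
                       order_index = NA_integer_)
  s <- seqs[["cB"]]
  cds2 <- list()
  for (i in 1:4) {
    substr(s, starts[i] + 1, starts[i] + 126) <- cds[i]
    cds2[[genes2$gene_id[i]]] <- cbind(start = starts[i], end = starts[i] + 126)
  }
  seqs[["cB"]] <- s
  g <- annotated_genome(seqs, rbind(g1$genes[1:4, ], genes2), c(g1$cds[1:4], cds2))
  prots <- setNames(vapply(g$genes$gene_id, function(gid) {
    suppressWarnings(translate_dna(extract_cds(g, gid)))
  }, ""), g$genes$gene_id)
  hits <- all_vs_all_hits(prots, prefilter = FALSE)
  expect_equal(length(find_segmental_blocks(g, hits, min_anchors = 5)), 0)
  expect_gt(length(find_segmental_blocks(g, hits, min_anchors = 4)), 0)
  # shuffled (non-collinear) homologs chain neither forward nor inverted
  g_sh <- g
  sh <- c(3, 1, 4, 2)
  g_sh$genes$start[5:8] <- starts[sh]
  g_sh$genes$end[5:8] <- starts[sh] + 126
  g_sh$genes <- divaria:::assign_order_index(g_sh$genes)
  expect_equal(length(find_segmental_blocks(g_sh, hits, min_anchors = 4,
                                            max_gap_genes = 25)), 0)
})
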