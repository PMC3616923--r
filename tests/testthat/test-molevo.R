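test_that("NG86 reproduces the hand-computed single-substitution example", {
  aln <- list(seq1 = "TTTGGGAAA", seq2 = "TTCGGGAAA")
  r <- ng86_kaks(aln)
  expect_equal(r$S, 5 / 3, tolerance = 1e-12)
  expect_equal(r$N, 9 - 5 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 4 / 3 * (1 / (5 / 3))), tolerance = 1e-9)
  expect_equal(r$Ka, 0)
})

test_that("identical sequences give Ka = Ks = 0 with undefined ratio; estimator is symmetric", {
  cds <- "ATGAAATGGCTT"
  r <- ng86_kaks(list(seq1 = cds, seq2 = cds))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  set.seed(2)
  for (i in 1:20) {
    a <- random_cds_oracle(30)
    b <- random_cds_oracle(30)
    r1 <- ng86_kaks(list(seq1 = a, seq2 = b))
    r2 <- ng86_kaks(list(seq1 = b, seq2 = a))
    expect_equal(r1$Ka, r2$Ka, tolerance = 1e-12)
    expect_equal(r1$Ks, r2$Ks, tolerance = 1e-12)
  }
})

test_that("NG86 agrees with the brute-force pathway-enumeration oracle on random pairs", {
  set.seed(31)
  for (i in 1:40) {
    a <- random_cds_oracle(60)
    # derive b by random in-frame codon replacements
    cod <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    sense <- setdiff(names(GC_TABLE), c(ORACLE_STOPS, "ATG"))
    hit <- sample(2:(length(cod) - 1), 12)
    cod[hit] <- sample(sense, length(hit), TRUE)
    b <- paste(cod, collapse = "")
    r <- ng86_kaks(list(seq1 = a, seq2 = b))
    o <- ng86_oracle(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(r$Ks, o$Ks, tolerance = 1e-9)
    expect_equal(r$Ka, o$Ka, tolerance = 1e-9)
  }
})

test_that("adding one more nonsynonymous difference never decreases Ka", {
  set.seed(5)
  a <- random_cds_oracle(100)
  cod_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  b_cod <- cod_a
  kas <- c()
  for (step in 1:12) {
    # introduce one nonsynonymous change at an untouched codon
    repeat {
      i <- sample(2:(length(cod_a) - 1), 1)
      if (b_cod[i] != cod_a[i]) next
      cand <- sample(setdiff(names(GC_TABLE), c(ORACLE_STOPS, "ATG")), 1)
      d <- sum(strsplit(cand, "")[[1]] != strsplit(cod_a[i], "")[[1]])
      if (d == 1 && GC_TABLE[[cand]] != GC_TABLE[[cod_a[i]]]) {
        b_cod[i] <- cand
        break
      }
    }
    r <- ng86_kaks(list(seq1 = a, seq2 = paste(b_cod, collapse = "")))
    kas <- c(kas, r$Ka)
  }
  expect_true(all(diff(kas) > -1e-12))
})

test_that("codon alignment threads protein gaps onto whole codons", {
  a <- "ATGAAACCCGGGTTTTAA"
  b <- "ATGAAAGGGTTTTAA"   # one codon removed
  aln <- align_codons(a, b)
  expect_equal(nchar(aln$seq1), nchar(aln$seq2))
  expect_equal(nchar(aln$seq1) %% 3, 0)
  gaps <- gregexpr("-+", aln$seq2)[[1]]
  expect_equal(attr(gaps, "match.length"), 3L)
  ident <- align_codons(a, a)
  expect_equal(ident$aligned_fraction, 1)
  expect_false(grepl("-", ident$seq1))
  expect_error(align_codons("", a), "empty")
  expect_error(align_codons("ATGTAATGA", a), "internal stop")
})

test_that("pair filter applies the 70% aligned-fraction rule inclusively plus an identity floor", {
  expect_false(pair_filter(list(aligned_fraction = 0.69, identity = 1)))
  expect_true(pair_filter(list(aligned_fraction = 0.70, identity = 1)))
  expect_true(pair_filter(list(aligned_fraction = 1, identity = 1)))
  expect_false(pair_filter(list(aligned_fraction = 1, identity = 0.1)))
})

test_that("the Ka>Ks test is 0.5 at equality, >0.5 for Ka<Ks, and significant for strong excess", {
  r_eq <- list(Ka = 0.1, Ks = 0.1, var_ka = 0, var_ks = 0)
  expect_equal(test_positive_selection(r_eq), 0.5)
  set.seed(8)
  # purifying pair: many synonymous, no nonsynonymous changes
  a <- random_cds_oracle(200)
  cod <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  b_cod <- cod
  for (i in sample(2:199, 60)) {
    syn <- names(GC_TABLE)[GC_TABLE == GC_TABLE[[cod[i]]]]
    syn <- setdiff(syn, cod[i])
    if (length(syn) > 0) b_cod[i] <- sample(syn, 1)
  }
  r_low <- ng86_kaks(list(seq1 = a, seq2 = paste(b_cod, collapse = "")))
  expect_gt(r_low$p_positive, 0.5)
  # strongly nonsynonymous pair: single-base amino-acid-changing edits
  sense <- setdiff(names(GC_TABLE), c(ORACLE_STOPS, "ATG"))
  one_step_nonsyn <- function(codon) {
    for (p in sample(1:3)) {
      for (b in sample(setdiff(c("A", "C", "G", "T"), substr(codon, p, p)))) {
        cand <- codon
        substr(cand, p, p) <- b
        if (!(cand %in% ORACLE_STOPS) && cand != "ATG" &&
            GC_TABLE[[cand]] != GC_TABLE[[codon]]) return(cand)
      }
    }
    codon
  }
  c_cod <- cod
  for (i in sample(2:199, 60)) c_cod[i] <- one_step_nonsyn(cod[i])
  r_hi <- ng86_kaks(list(seq1 = a, seq2 = paste(c_cod, collapse = "")))
  expect_lt(r_hi$p_positive, 0.05)
})

test_that("neutral evolution gives mean Ka/Ks near 1 and a controlled positive-selection rate", {
  set.seed(77)
  n_pairs <- 120
  ratios <- numeric(0)
  flagged <- 0L
  tested <- 0L
  for (i in seq_len(n_pairs)) {
    a <- random_cds_oracle(300)
    b <- a
    # neutral: accept every non-stop point mutation regardless of effect
    m <- 0L
    while (m < 60L) {
      p <- sample(4:(nchar(a) - 3), 1)
      base <- substr(b, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      cand <- b
      substr(cand, p, p) <- alt
      ci <- (p - 1) %/% 3 + 1
      codon <- substr(cand, ci * 3 - 2, ci * 3)
      if (codon %in% ORACLE_STOPS) next
      b <- cand
      m <- m + 1L
    }
    r <- ng86_kaks(list(seq1 = a, seq2 = b))
    if (!is.na(r$ratio)) ratios <- c(ratios, r$ratio)
    if (!is.na(r$p_positive)) {
      tested <- tested + 1L
      if (!is.na(r$ratio) && r$ratio > 1 && r$p_positive < 0.05) flagged <- flagged + 1L
    }
  }
  expect_gt(mean(ratios), 0.85)
  expect_lt(mean(ratios), 1.15)
  # the large-sample z test runs slightly anti-conservative (~6% at
  # alpha = 0.05); bound the empirical rate rather than the nominal one
  expect_lte(flagged / tested, 0.10)
})
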