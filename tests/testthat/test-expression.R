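make_expr <- function(signal_list) {
  # signal_list: named list probe -> numeric vector over the 12 samples
  samples <- expand.grid(replicate = 1:2, time = c(0, 2, 6),
                         variety = c("v1", "v2"), stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- paste(samples$variety, samples$time, samples$replicate,
                             sep = ":")
  m <- do.call(rbind, signal_list)
  probes <- data.frame(probe_id = names(signal_list),
                       gene_id = names(signal_list))
  expression_matrix(m, samples, probes)
}

# column order: v1:0:1 v1:0:2 v1:2:1 v1:2:2 v1:6:1 v1:6:2 then v2 same
flat <- function(v1, v2) c(rep(v1, 6), rep(v2, 6))

test_that("detection needs the threshold in ALL replicates and any time point per variety", {
  mat <- make_expr(list(
    ok = c(30, 40, rep(100, 4), rep(100, 6)),
    half = c(30, 20, rep(100, 4), rep(100, 6)),  # one 0h replicate below
    off = flat(10, 100)
  ))
  det <- detect_expressed(mat, threshold = 25)
  expect_true(det$per_time["ok", "v1:0"])
  expect_false(det$per_time["half", "v1:0"])
  expect_true(det$per_variety["half", "v1"])    # treated times carry it
  expect_false(det$per_variety["off", "v1"])
  expect_true(det$per_variety["off", "v2"])
  # condition classes partition the expressed set
  cc <- det$condition_class[, "v1"]
  expect_equal(sum(cc %in% c("normal_only", "treated_only", "both")),
               sum(det$per_variety[, "v1"]))
})

test_that("abundance bins partition the signal axis at 50/500/5000", {
  expect_equal(bin_abundance(c(0, 49, 50, 499.9, 500, 5000, 5001)),
               c("low", "low", "middle", "middle", "high", "high", "very_high"))
  set.seed(59)
  s <- runif(500, 0, 10000)
  b <- bin_abundance(s)
  expect_true(all(b %in% c("low", "middle", "high", "very_high")))
  expect_equal(length(b), 500)
})

test_that("two-fold calls are inclusive at exactly 2.0 and mutually exclusive; specific calls need absence", {
  mat <- make_expr(list(
    twice = flat(400, 200),     # exactly 2-fold in v1
    under = flat(390, 200),     # 1.95-fold: no call
    only1 = flat(300, 5),
    only2 = flat(5, 300)
  ))
  det <- detect_expressed(mat)
  div <- classify_divergence(mat, det)
  expect_true(div$fold2_v1[div$probe_id == "twice"])
  expect_false(div$fold2_v2[div$probe_id == "twice"])
  expect_false(any(div$fold2_v1 & div$fold2_v2))
  expect_false(div$fold2_v1[div$probe_id == "under"])
  expect_true(div$specific_v1[div$probe_id == "only1"])
  expect_true(div$specific_v2[div$probe_id == "only2"])
  expect_false(any(div$specific_v1 & div$specific_v2))
  expect_false(any((div$specific_v1 | div$specific_v2) &
                     (div$fold2_v1 | div$fold2_v2)))
})

test_that("sucrose direction uses any-time-point 2-fold with no contradiction", {
  mat <- make_expr(list(
    up2h = c(100, 100, 250, 250, 110, 110, rep(100, 6)),
    down6h = c(100, 100, 100, 100, 40, 40, rep(100, 6)),
    mixed = c(100, 100, 250, 250, 40, 40, rep(100, 6)),
    both_up = c(100, 100, 300, 300, 300, 300, 100, 100, 260, 260, 100, 100)
  ))
  det <- detect_expressed(mat)
  div <- classify_divergence(mat, det)
  expect_equal(div$sucrose_dir_v1[div$probe_id == "up2h"], "up")
  expect_equal(div$sucrose_dir_v1[div$probe_id == "down6h"], "down")
  expect_equal(div$sucrose_dir_v1[div$probe_id == "mixed"], "none")
  expect_true(div$sucrose_only_v1[div$probe_id == "up2h"])
  # direction in both varieties is not variety-specific sucrose regulation
  expect_false(div$sucrose_only_v1[div$probe_id == "both_up"])
})

test_that("classification is invariant to sample column order", {
  set.seed(61)
  mat <- make_expr(list(a = flat(300, 100), b = flat(50, 400),
                        c = c(100, 100, 250, 250, 240, 240, rep(80, 6))))
  det <- classify_divergence(mat, detect_expressed(mat))
  perm <- sample(12)
  mat2 <- mat
  mat2$signals <- mat$signals[, perm]
  mat2$samples <- mat$samples[perm, ]
  det2 <- classify_divergence(mat2, detect_expressed(mat2))
  expect_equal(det, det2, ignore_attr = TRUE)
})

test_that("venn partition counts every disjoint region and sums to the union", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"), C = c("q"))
  vp <- venn_partition(sets)
  expect_equal(vp$count[vp$region == "A"], 1)        # x
  expect_equal(vp$count[vp$region == "A+B"], 2)      # y, z
  expect_equal(vp$count[vp$region == "C"], 1)
  expect_equal(sum(vp$count), length(unique(unlist(sets))))
  # disjoint sets and subset relations
  vp2 <- venn_partition(list(A = c("a", "b"), B = c("c")))
  expect_false("A+B" %in% vp2$region)
  vp3 <- venn_partition(list(A = c("a"), B = c("a", "b")))
  expect_false("A" %in% vp3$region)  # A alone is empty since A is a subset of B
  # random sets equal an element-wise membership oracle
  set.seed(67)
  for (i in 1:10) {
    u <- sprintf("e%02d", 1:30)
    ss <- list(A = sample(u, 12), B = sample(u, 8), C = sample(u, 15))
    vp <- venn_partition(ss)
    oracle <- table(vapply(unique(unlist(ss)), function(e) {
      paste(names(ss)[vapply(ss, function(s) e %in% s, TRUE)], collapse = "+")
    }, ""))
    expect_equal(setNames(vp$count, vp$region), unlist(as.list(oracle))[vp$region])
  }
})

test_that("delta-delta-CT follows the textbook identities", {
  tbl <- data.frame(
    gene = "gX",
    sample = rep(c("test", "cal"), each = 2),
    replicate = c(1, 2, 1, 2),
    C_T_target = c(25, 25, 23, 23),
    C_T_reference = c(20, 20, 20, 20)
  )
  r <- ddct(tbl, "test", "cal")
  expect_equal(r$ddct, 2)                 # 5 - 3
  expect_equal(r$relative_amount, 0.25)   # 2^-2
  # ddCT of 0 gives relative amount 1 and equal replicates give p = 1
  tbl0 <- transform(tbl, C_T_target = c(23, 23, 23, 23))
  r0 <- ddct(tbl0, "test", "cal")
  expect_equal(r0$ddct, 0)
  expect_equal(r0$relative_amount, 1)
  expect_equal(r0$p_value, 1)
  expect_error(ddct(tbl[, -5], "test", "cal"), "must have columns")
})

test_that("planted expression classes are recovered on synthetic data", {
  ds <- shared_dataset()
  det <- detect_expressed(ds$expr)
  div <- classify_divergence(ds$expr, det)
  truth <- ds$truth$expression_classes
  six <- c("specific_v1", "specific_v2", "fold2_v1", "fold2_v2",
           "sucrose_only_v1", "sucrose_only_v2")
  acc <- vapply(six, function(cl) {
    planted <- truth$probe_id[truth$class == cl]
    called <- div$probe_id[div[[cl]]]
    length(intersect(planted, called)) / max(length(planted), 1)
  }, 0)
  expect_true(all(acc >= 0.95))
  # per-variety expressed totals partition into the three condition classes
  for (v in c("v1", "v2")) {
    cc <- det$condition_class[, v]
    expect_equal(sum(cc == "normal_only") + sum(cc == "treated_only") +
                   sum(cc == "both"), sum(det$per_variety[, v]))
  }
})
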