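lib3 <- manual_library(c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG"))

test_that("counts-per-million normalisation scales each sample to 1e6", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(lib3$hairpin_id, "s1"))
  sc <- manual_counts(m, "ctrl", lib3)
  norm <- normalize_counts(sc)
  expect_equal(unname(norm[, 1]), c(250000, 250000, 500000))

  m2 <- cbind(s1 = c(1, 1, 2), s2 = c(10, 10, 20))
  rownames(m2) <- lib3$hairpin_id
  sc2 <- manual_counts(m2, c("ctrl", "ctrl"), lib3)
  norm2 <- normalize_counts(sc2)
  expect_equal(unname(norm2[, 1]), unname(norm2[, 2]))  # scale invariance

  m3 <- cbind(s1 = c(1, 1, 2), s2 = c(0, 0, 0))
  rownames(m3) <- lib3$hairpin_id
  sc3 <- manual_counts(m3, c("ctrl", "ctrl"), lib3)
  expect_error(normalize_counts(sc3), "s2")
})

test_that("the control-abundance filter partitions on the mean raw count", {
  m <- cbind(c1 = c(150, 0, 100), c2 = c(150, 0, 100), c3 = c(150, 0, 103))
  rownames(m) <- lib3$hairpin_id
  sc <- manual_counts(m, rep("untreated", 3), lib3)
  flt <- filter_low_abundance(sc, "untreated", min_raw = 100)
  expect_identical(flt$kept, c("sh001", "sh003"))  # 101 > 100 strict
  expect_identical(flt$filtered, "sh002")
  flt0 <- filter_low_abundance(sc, "untreated", min_raw = 0)
  expect_identical(flt0$filtered, "sh002")  # zero-signal hairpin stays out
})

test_that("t statistics match stats::t.test to 1e-10 on 3-vs-3 fixtures", {
  set.seed(101)
  lib <- generate_library(20, 1, seq_len = 12, seed = 101)
  counts <- matrix(rpois(20 * 6, 500), 20, 6,
                   dimnames = list(lib$hairpin_id,
                                   paste0("s", 1:6)))
  sc <- manual_counts(counts, rep(c("untreated", "drug"), each = 3), lib)
  for (ve in c(TRUE, FALSE)) {
    ht <- call_hits(sc, "drug", "untreated", min_raw = 0, var_equal = ve)
    norm <- normalize_counts(sc)
    for (i in seq_len(20)) {
      ref <- stats::t.test(norm[i, 4:6], norm[i, 1:3], var.equal = ve)
      expect_equal(ht$t[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ht$p_value[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("identical arms yield no depleted or enriched calls", {
  lib <- generate_library(50, 1, seq_len = 12, seed = 7)
  p <- generate_abundance(lib, 0.5, seed = 7)
  sc <- simulate_screen_counts(lib, p, effect_spec(condition = "drug"),
                               depth = 1e5, seed = 8)
  counts <- sc$counts
  counts[, 4:6] <- counts[, 1:3]  # treated arm literally equals control
  sc2 <- screen_counts(counts, sc$samples, lib)
  ht <- call_hits(sc2, "drug", "untreated", min_raw = 0)
  expect_equal(sum(ht$class %in% c("depleted", "enriched")), 0)
  expect_true(all(ht$p_value == 1))
})

test_that("planted depletion is recovered and classes form a partition", {
  lib <- generate_library(400, 1, seq_len = 15, seed = 21)
  p <- generate_abundance(lib, 0.3, seed = 22)
  planted <- lib$hairpin_id[1:20]
  eff <- effect_spec(planted, multiplier = 1 / 8, condition = "drug")
  sc <- simulate_screen_counts(lib, p, eff, depth = 4e5, rep_cv = 0.05,
                               seed = 23)
  ht <- call_hits(sc, "drug", "untreated")
  expect_true(all(ht$class[1:20] %in% c("depleted", "lost")))
  expect_true(all(table(ht$hairpin_id) == 1))
  expect_false(any(is.na(ht$class)))
  expect_equal(sum(table(ht$class)), 400)
  # depleted calls respect both rules
  dep <- ht$class == "depleted"
  expect_true(all(ht$log2_ratio[dep] <= -1))
  expect_true(all(ht$p_value[dep] < 0.01))
})

test_that("a strong but sub-two-fold shift stays unchanged", {
  # log2 ratio of -0.8 with a tiny p-value fails the fold rule
  target_c <- c(100000L, 100100L, 99900L)
  target_t <- as.integer(round(target_c * 2^-0.8) + c(0L, 40L, -40L))
  m <- rbind(c(target_c, target_t),
             as.integer(1e6 - c(target_c, target_t)))
  lib <- manual_library(c("AAAAAAAAAAAA", "CCCCCCCCCCCC"))
  dimnames(m) <- list(lib$hairpin_id, paste0("s", 1:6))
  sc <- manual_counts(m, rep(c("untreated", "drug"), each = 3), lib)
  ht <- call_hits(sc, "drug", "untreated")
  expect_lt(ht$p_value[1], 0.001)
  expect_gt(ht$log2_ratio[1], -1)
  expect_identical(as.character(ht$class[1]), "unchanged")
})

test_that("lost detection precedes the ratio rule", {
  lib <- generate_library(100, 1, seq_len = 12, seed = 31)
  p <- generate_abundance(lib, 0, seed = 31)
  eff <- effect_spec(lib$hairpin_id[1], lost = TRUE, condition = "drug")
  sc <- simulate_screen_counts(lib, p, eff, depth = 1e5, seed = 32)
  ht <- call_hits(sc, "drug", "untreated")
  expect_identical(as.character(ht$class[1]), "lost")
  # raw treated counts are all zero, control passed the filter
  t_cols <- sc$samples$sample_id[sc$samples$condition == "drug"]
  expect_true(all(sc$counts[1, t_cols] == 0))
})

test_that("call_hits validates its contract", {
  lib <- generate_library(10, 1, seq_len = 12, seed = 41)
  m <- matrix(rpois(30, 200), 10, 3,
              dimnames = list(lib$hairpin_id, paste0("s", 1:3)))
  sc <- manual_counts(m, c("untreated", "untreated", "drug"), lib)
  expect_error(call_hits(sc, "drug", "untreated"), ">= 2 replicates")
  m6 <- cbind(m, m)
  colnames(m6) <- paste0("s", 1:6)
  sc6 <- manual_counts(m6, rep(c("untreated", "drug"), each = 3), lib)
  expect_error(call_hits(sc6, "drug", "untreated", alpha = 2), "alpha")
  expect_error(call_hits(sc6, "drug", "untreated", fold = 1), "fold")
  expect_error(call_hits(sc6, "drug", "nope"), "sample sheet")
})

test_that("hit intersection is idempotent and respects planted structure", {
  lib <- generate_library(150, 2, seq_len = 15, seed = 51)
  p <- generate_abundance(lib, 0.3, seed = 52)
  genes <- unique(lib$gene_symbol)
  shared <- genes[1:4]
  priv <- list(genes[5:8], genes[9:12], genes[13:16])
  tables <- lapply(1:3, function(k) {
    hp <- lib$hairpin_id[lib$gene_symbol %in% c(shared, priv[[k]])]
    eff <- effect_spec(hp, multiplier = 1 / 8,
                       condition = paste0("drug", k))
    sc <- simulate_screen_counts(lib, p, eff, depth = 1e6, rep_cv = 0.05,
                                 seed = 60 + k)
    call_hits(sc, paste0("drug", k), "untreated")
  })
  ov <- intersect_hits(tables, "depleted")
  expect_setequal(ov$gene_symbol, shared)

  self <- intersect_hits(tables[1], "depleted")
  dep1 <- tables[[1]]$hairpin_id[tables[[1]]$class %in% c("depleted", "lost")]
  expect_setequal(self$hairpin_id, dep1)

  other <- generate_library(150, n_hairpins = 380, seq_len = 15, seed = 99)
  p2 <- generate_abundance(other, 0.3, seed = 99)
  sc2 <- simulate_screen_counts(other, p2, effect_spec(condition = "x"),
                                depth = 1e5, seed = 99)
  ht2 <- call_hits(sc2, "x", "untreated")
  expect_error(intersect_hits(list(tables[[1]], ht2)), "different libraries")
})

test_that("contrasts with disjoint planted effects share no hits", {
  lib <- generate_library(120, 1, seq_len = 15, seed = 71)
  p <- generate_abundance(lib, 0.3, seed = 72)
  effA <- effect_spec(lib$hairpin_id[1:10], multiplier = 1 / 8,
                      condition = "drugA")
  effB <- effect_spec(lib$hairpin_id[51:60], multiplier = 1 / 8,
                      condition = "drugB")
  sc <- simulate_screen_counts(lib, p, list(effA, effB), depth = 3e5,
                               rep_cv = 0.05, seed = 73)
  ta <- call_hits(sc, "drugA", "untreated")
  tb <- call_hits(sc, "drugB", "untreated")
  ov <- intersect_hits(list(ta, tb), "depleted")
  expect_length(ov$hairpin_id, 0)
})
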