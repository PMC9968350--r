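make_probe_table <- function(expr, gene_of, above = NULL, samples = NULL) {
  n <- ncol(expr)
  if (is.null(above)) above <- matrix(TRUE, nrow(expr), n)
  if (is.null(samples))
    samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                          donor = "d1", region = "r1", hemisphere = "left",
                          structure = "cortex", x = 0, y = 0, z = 0)
  probe_table(data.frame(probe_id = rownames(expr), gene_id = gene_of),
              expr, above, samples)
}

test_that("intensity filter applies the at-least-50-percent rule inclusively", {
  n <- 100
  expr <- matrix(0, 3, n, dimnames = list(c("p1", "p2", "p3"), NULL))
  above <- rbind(rep(c(TRUE, FALSE), c(51, 49)),
                 rep(c(TRUE, FALSE), c(49, 51)),
                 rep(c(TRUE, FALSE), c(50, 50)))
  rownames(above) <- rownames(expr)
  pt <- make_probe_table(expr, c("g1", "g2", "g3"), above)
  kept <- filter_probes_intensity(pt, 0.5)
  expect_setequal(kept$probe_info$probe_id, c("p1", "p3"))
})

test_that("RNA-seq-guided selection keeps the best correlated probe per gene", {
  set.seed(31)
  n <- 40
  ref <- rnorm(n)
  # gene gA: one noisy probe (low r), one faithful probe (high r)
  pA1 <- rnorm(n)
  pA2 <- ref + rnorm(n, 0, 0.3)
  # gene gB: all probes uncorrelated
  pB1 <- rnorm(n); pB2 <- rnorm(n)
  # gene gC: probe identical to the reference
  pC1 <- ref
  expr <- rbind(pA1 = pA1, pA2 = pA2, pB1 = pB1, pB2 = pB2, pC1 = pC1)
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  rnaseq <- rbind(gA = ref, gB = rnorm(n), gC = ref)
  colnames(rnaseq) <- colnames(expr)
  pt <- make_probe_table(expr, c("gA", "gA", "gB", "gB", "gC"))
  out <- select_probes_rnaseq(pt, rnaseq, min_r = 0.2)
  pm <- attr(out, "probe_map")
  expect_equal(pm$probe_id[pm$gene_id == "gA"], "pA2")
  expect_false("gB" %in% colnames(out$expr))
  expect_equal(pm$r[pm$gene_id == "gC"], 1)
  # genes absent from the reference are dropped
  expect_true(all(colnames(out$expr) %in% rownames(rnaseq)))
  # too few matched samples: nothing selectable
  expect_warning(
    out2 <- select_probes_rnaseq(pt, rnaseq[, 1:2, drop = FALSE]),
    "matched")
  expect_equal(ncol(out2$expr), 0)
})

test_that("sample filter keeps left-cortex in-mask samples only", {
  grid <- gen_brain_grid(toy_brain_spec(c(10, 10, 10), 2, "ellipsoid"))
  samples <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    donor = "d1", region = "r1",
    hemisphere = c("left", "right", "left", "left"),
    structure = c("cortex", "cortex", "subcortex", "cortex"),
    x = c(0, 0, 0, -9), y = c(0, 0, 0, -9), z = c(0, 0, 0, -9))
  expr <- matrix(rnorm(4 * 3), 4, 3,
                 dimnames = list(samples$sample_id, c("g1", "g2", "g3")))
  b <- expression_bundle(expr, samples)
  out <- filter_samples(b, grid)
  expect_equal(rownames(out$expr), "a")   # b: right; c: subcortex; d: off-mask

  allin <- expression_bundle(expr[c(1, 1, 1, 1), , drop = FALSE],
                             transform(samples, hemisphere = "left",
                                       structure = "cortex", x = 0, y = 0, z = 0))
  expect_equal(nrow(filter_samples(allin, grid)$expr), 4)
})

test_that("scaled robust sigmoid matches hand values and is rank/affine stable", {
  s <- scaled_robust_sigmoid(c(1, 2, 3))
  raw <- 1 / (1 + exp(-(c(1, 2, 3) - 2) / (1 / 1.35)))
  expect_equal(raw, c(0.2059, 0.5, 0.7941), tolerance = 1e-4)
  expect_equal(s, c(0, 0.5, 1), tolerance = 1e-9)

  set.seed(41)
  x <- rnorm(30)
  expect_equal(order(scaled_robust_sigmoid(x)), order(x))   # monotone
  # affine invariance
  expect_equal(scaled_robust_sigmoid(3 * x - 7), scaled_robust_sigmoid(x),
               tolerance = 1e-9)
  # one extreme outlier leaves the other ranks untouched
  xo <- c(x, 1e6)
  so <- scaled_robust_sigmoid(xo)
  expect_equal(order(so[1:30]), order(x))

  w <- testthat::capture_warnings(srs_normalize(matrix(1, 5, 4)))
  expect_true(any(grepl("zero IQR", w)))
})

test_that("two-stage SRS normalization bounds values and removes donor offsets", {
  set.seed(42)
  n <- 24; G <- 8
  donors <- rep(c("d1", "d2"), each = n / 2)
  signal <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, paste0("g", 1:G)))
  shifted <- signal + ifelse(donors == "d1", 5, -5)   # strong donor offset
  out <- srs_normalize(shifted, donors)
  expect_true(all(out >= 0 & out <= 1))
  expect_false(anyNA(out))
  # donor offset removed: per-donor means comparable after normalization
  expect_lt(abs(mean(out[donors == "d1", ]) - mean(out[donors == "d2", ])), 0.1)
})

test_that("differential stability measures cross-donor profile agreement", {
  G <- 5; R <- 8
  prof <- matrix(rnorm(R * G), R, G, dimnames = list(NULL, paste0("g", 1:G)))
  samples <- data.frame(sample_id = sprintf("s%02d", 1:(2 * R)),
                        donor = rep(c("d1", "d2"), each = R),
                        region = rep(sprintf("r%02d", 1:R), 2),
                        hemisphere = "left", structure = "cortex",
                        x = 0, y = 0, z = 0)
  # identical regional profiles -> DS = 1
  b <- expression_bundle(rbind(prof, prof), samples)
  expect_true(all(differential_stability(b)$ds == 1))
  # reverse-ranked profiles (any anti-monotone transform) -> DS = -1
  b2 <- expression_bundle(rbind(prof, -prof), samples)
  expect_true(all(abs(differential_stability(b2)$ds + 1) < 1e-12))

  # independent profiles across 6 donors, 30 regions: DS centred on 0
  set.seed(52)
  nd <- 6; nr <- 30; G2 <- 40
  sam <- data.frame(sample_id = sprintf("s%03d", 1:(nd * nr)),
                    donor = rep(sprintf("d%d", 1:nd), each = nr),
                    region = rep(sprintf("r%02d", 1:nr), nd),
                    hemisphere = "left", structure = "cortex",
                    x = 0, y = 0, z = 0)
  b3 <- expression_bundle(matrix(rnorm(nd * nr * G2), nd * nr, G2,
                                 dimnames = list(NULL, sprintf("g%02d", 1:G2))),
                          sam)
  expect_lt(abs(mean(differential_stability(b3)$ds)), 0.1)

  # no donor pair with >= 3 shared regions: DS undefined
  sam2 <- samples
  sam2$region <- c(sprintf("a%02d", 1:R), sprintf("b%02d", 1:R))
  expect_warning(ds_na <- differential_stability(expression_bundle(rbind(prof, prof), sam2)),
                 "undefined")
  expect_true(all(is.na(ds_na$ds)))
})

test_that("DS gene filter keeps the top fraction with nested thresholds", {
  G <- 10
  samples <- data.frame(sample_id = c("a", "b", "c"), donor = "d1",
                        region = c("r1", "r2", "r3"), hemisphere = "left",
                        structure = "cortex", x = 0, y = 0, z = 0)
  b <- expression_bundle(matrix(0, 3, G, dimnames = list(NULL, sprintf("g%02d", 1:G))),
                         samples)
  b$ds <- setNames(seq(0.1, 1, length.out = G), colnames(b$expr))
  expect_equal(ncol(filter_genes_ds(b, 0.5)$expr), 5)
  k4 <- colnames(filter_genes_ds(b, 0.4)$expr)
  k5 <- colnames(filter_genes_ds(b, 0.5)$expr)
  k6 <- colnames(filter_genes_ds(b, 0.6)$expr)
  expect_true(all(k4 %in% k5) && all(k5 %in% k6))
  # all-equal DS: lexicographically smallest ids kept
  b$ds[] <- 0.5
  expect_equal(colnames(filter_genes_ds(b, 0.5)$expr), sprintf("g%02d", 1:5))
})

test_that("the full preprocessing chain yields a clean bounded matrix", {
  grid <- small_grid()
  target <- smooth_target(grid)
  truth <- demo_truth(n_true = 6)
  ds <- gen_expression_dataset(grid, target, n_donors = 4,
                               n_samples_per_donor = 25, n_genes = 40,
                               probes_per_gene = 2, truth = truth, seed = 61)
  suppressMessages(out <- process_expression(ds$probes, ds$rnaseq, grid))
  expect_true(all(out$expr >= 0 & out$expr <= 1))
  expect_false(anyNA(out$expr))
  expect_equal(ncol(out$expr), ceiling(0.5 * attr(out, "log")[["genes_selected"]]))
  # every retained gene has exactly one representative probe
  expect_false(anyDuplicated(colnames(out$expr)) > 0)
  # decoy samples removed
  expect_true(all(out$samples$hemisphere == "left" &
                  out$samples$structure == "cortex"))
  lg <- attr(out, "log")
  expect_true(lg[["probes_intensity"]] < lg[["probes_in"]])
})
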