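test_that("TSS-mode occupancy handles empty, full and half coverage", {
  mk <- function(track) mk_panel(flank_up = 1000, flank_down = 1000,
                                 L = 500, tracks = list("c|m" = track))
  empty <- lapply(1:4, function(i) mk(rel_track(numeric(0), numeric(0))[0, , drop = FALSE]))
  full <- lapply(1:4, function(i) mk(rel_track(-1000, 1500)))
  expect_equal(average_feature_profile(empty, "c|m", "tss", bin_size = 100)$values,
               rep(0, 20))
  expect_equal(average_feature_profile(full, "c|m", "tss", bin_size = 100)$values,
               rep(1, 20))
  half <- c(lapply(1:2, function(i) mk(rel_track(-50, 50))),
            lapply(1:2, function(i) mk(rel_track(900, 950))))
  v <- average_feature_profile(half, "c|m", "tss", bin_size = 100)$values
  # bins tile [-1000, 1000); [-100,0) and [0,100) carry the [-50,50) interval
  expect_equal(v[10], 0.5)
  expect_equal(v[11], 0.5)
  expect_equal(v[20], 0.5)   # the [900,1000) bin carries [900,950)
  expect_equal(sum(v), 1.5)
})

test_that("profiles match per-base brute-force coverage binning", {
  for (seed in 1:6) {
    inst <- mk_instance(seed, n_genes = 8, tracks = 1, rate = 30,
                        flank_up = 2000, flank_down = 2000)
    key <- names(inst$panels[[1]]$tracks)[1]
    got <- average_feature_profile(inst$panels, key, "tss", bin_size = 250)
    expect_equal(got$values, bf_profile_tss(inst$panels, key, 250))
    expect_true(all(got$values >= 0 & got$values <= 1))
    expect_equal(length(got$values), length(got$bin_edges) - 1)
  }
})

test_that("gene-body scaling is length-invariant: tiled bodies give 1", {
  panels <- lapply(c(700, 5000, 12345, 40000), function(L)
    mk_panel(L = L, tracks = list("c|m" = rel_track(0, L))))
  pr <- average_feature_profile(panels, "c|m", "genebody", n_bins = 100)
  expect_equal(pr$values, rep(1, 100))
  expect_equal(pr$bin_edges, seq(0, 100, 1))
  # flank-only peaks never touch a body bin
  flank_only <- lapply(c(900, 3000), function(L)
    mk_panel(L = L, tracks = list("c|m" = rel_track(-5000, -10))))
  expect_equal(average_feature_profile(flank_only, "c|m", "genebody")$values,
               rep(0, 100))
  # an interval over the first half of every body fills the first 50 bins
  halves <- lapply(c(1000, 9000), function(L)
    mk_panel(L = L, tracks = list("c|m" = rel_track(0, L / 2))))
  vh <- average_feature_profile(halves, "c|m", "genebody")$values
  expect_equal(vh[1:50], rep(1, 50))
  expect_equal(vh[51:100], rep(0, 50))
})

test_that("aggregates honour the show flag", {
  shown <- mk_panel(gene_id = "A", tracks = list("c|m" = rel_track(-100, 100)),
                    expression = c(X = 1, Y = 2))
  hidden <- mk_panel(gene_id = "B", tracks = list("c|m" = rel_track(-100, 100)),
                     expression = c(X = 3, Y = 4), show = FALSE)
  panels <- list(shown, hidden)
  expect_equal(average_feature_profile(panels, "c|m", "tss")$n_genes, 1)
  expect_equal(average_feature_profile(panels, "c|m", "tss",
                                       shown_only = FALSE)$n_genes, 2)
  expect_equal(nrow(expression_scatter(panels, "X", "Y")$points), 1)
  expect_equal(nrow(gene_table(panels, filtered_only = TRUE)), 1)
  expect_equal(nrow(gene_table(panels, filtered_only = FALSE)), 2)
  expect_error(average_feature_profile(list(hidden), "c|m", "tss"),
               "no contributing")
})

test_that("feature histograms count right-open bins plus overflow exactly", {
  df <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30),
                   end = c(100, 110, 320, 4030), name = letters[1:4],
                   score = c(5, 200, 400, 1200), strand = ".",
                   signal_value = NA_real_, p_value = NA_real_,
                   q_value = NA_real_, summit_offset = -1,
                   stringsAsFactors = FALSE)
  ps <- epipanel:::new_peak_set(df, key = track_key("c", "m"))
  h <- feature_histogram(ps, "size", c(0, 200, 400))
  expect_equal(h$counts, c(2, 1))     # sizes 100,100,300,4000
  expect_equal(h$overflow, 1)
  expect_equal(sum(h$counts) + h$underflow + h$overflow, nrow(df))
  hs <- feature_histogram(ps, "score", c(100, 500, 1000))
  expect_equal(hs$counts, c(2, 0))
  expect_equal(hs$underflow, 1)
  expect_equal(hs$overflow, 1)
  empty <- apply_cutoffs(ps, min_score = 1e9)
  expect_equal(feature_histogram(empty, "size", c(0, 100, 200))$counts, c(0, 0))
})

test_that("expression display scale is the 5th-95th percentile band", {
  v <- 1:100
  got <- expression_scale(v)
  expect_equal(unname(got), c(bf_percentile(v, 0.05), bf_percentile(v, 0.95)))
  for (seed in 1:10) {
    x <- with_seed(seed, stats::rlnorm(with_seed(seed, sample(2:50, 1))))
    got <- expression_scale(x, 10, 90)
    expect_equal(unname(got), c(bf_percentile(x, 0.1), bf_percentile(x, 0.9)))
  }
  # degenerate inputs widen by a small epsilon
  flat <- expression_scale(rep(7, 5))
  expect_lt(flat[1], 7); expect_gt(flat[2], 7)
  one <- expression_scale(3)
  expect_lt(one[1], 3); expect_gt(one[2], 3)
  expect_error(expression_scale(numeric()), "no expression")
})

test_that("expression scatter pairs values and reports missing genes", {
  panels <- list(
    mk_panel(gene_id = "A", expression = c(X = 2, Y = 8)),
    mk_panel(gene_id = "B", expression = c(X = 1, Y = NA)),
    mk_panel(gene_id = "C", expression = c(X = 4, Y = 0)))
  sc <- expression_scatter(panels, "X", "Y")
  expect_equal(sc$points$gene_id, c("A", "C"))
  expect_equal(sc$points$x, c(2, 4))
  expect_equal(sc$points$y, c(8, 0))
  expect_equal(sc$missing, "B")
  expect_equal(nrow(sc$points) + length(sc$missing), length(panels))
  expect_error(expression_scatter(panels, "X", "Z"), "Z")
})

test_that("the gene table carries spans, per-track counts and expression", {
  p <- mk_panel(gene_id = "A", L = 9000,
                tracks = list("c|m1" = rel_track(-10, 10, 50, 80, 200, 400),
                              "c|m2" = rel_track(numeric(0), numeric(0))[0, , drop = FALSE]),
                expression = c(X = 2.5))
  tb <- gene_table(list(p))
  expect_equal(tb$gene_id, "A")
  expect_equal(tb$gene_length, 9000)
  expect_equal(tb$n_c_m1, 3)
  expect_equal(tb$n_c_m2, 0)
  expect_equal(tb$expr_X, 2.5)
  # sorting is a permutation
  inst <- mk_instance(6, n_genes = 9)
  tb2 <- gene_table(inst$panels)
  srt <- tb2[order(tb2$gene_length), ]
  expect_setequal(srt$gene_id, tb2$gene_id)
  expect_equal(nrow(gene_table(list())), 0)
})
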