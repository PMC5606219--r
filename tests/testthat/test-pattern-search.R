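test_that("interval gap: overlap and abutment are 0, separation counts bases", {
  expect_equal(interval_gap(c(0, 10), c(5, 15)), 0)
  expect_equal(interval_gap(c(0, 10), c(10, 20)), 0)    # half-open abutment
  expect_equal(interval_gap(c(0, 10), c(510, 520)), 500)
  expect_equal(interval_gap(c(510, 520), c(0, 10)), 500) # symmetric
  # agrees with base enumeration on random pairs
  for (seed in 1:30) {
    x <- with_seed(seed, sort(sample(0:2000, 4)))
    a <- x[c(1, 2)]; b <- x[c(3, 4)]
    if (a[1] == a[2] || b[1] == b[2]) next
    expect_equal(interval_gap(a, b), bf_gap(a, b))
    expect_equal(interval_gap(b, a), bf_gap(b, a))
  }
})

test_that("overlapping activating+repressive marks near the TSS are detected", {
  p <- mk_panel(tracks = list(
    "H1|H3K4me3" = rel_track(-100, 300),
    "H1|H3K27me3" = rel_track(0, 500)))
  f <- filter_feature_overlap("H1", "H3K4me3", target = "H3K27me3",
                              relation = "near", max_distance = 0,
                              window_rel = c(-5000, 2000))
  expect_true(eval_filter(f, p))
  # only one of the marks present -> no bivalency
  p2 <- mk_panel(tracks = list(
    "H1|H3K4me3" = rel_track(-100, 300),
    "H1|H3K27me3" = rel_track(15000, 15500)))  # outside the window
  expect_false(eval_filter(f, p2))
})

test_that("exon proximity within 0.5 kb is detected via the exons target", {
  # exon body [0, 10000); peak 400 bp past the end of the gene body
  p <- mk_panel(L = 10000,
                tracks = list("H1|H3K36me3" = rel_track(10400, 10900)))
  f <- filter_feature_overlap("H1", "H3K36me3", target = "exons",
                              relation = "near", max_distance = 500)
  expect_true(eval_filter(f, p))
  f2 <- filter_feature_overlap("H1", "H3K36me3", target = "exons",
                               relation = "near", max_distance = 300)
  expect_false(eval_filter(f2, p))
})

test_that("upstream/downstream juxtaposition relations are directional", {
  p <- mk_panel(tracks = list(
    "H1|A" = rel_track(-1000, -600),
    "H1|B" = rel_track(-500, 0)))
  up <- filter_feature_overlap("H1", "A", target = "B",
                               relation = "a_upstream_of_b",
                               max_distance = 200)
  down <- filter_feature_overlap("H1", "A", target = "B",
                                 relation = "a_downstream_of_b",
                                 max_distance = 200)
  expect_true(eval_filter(up, p))
  expect_false(eval_filter(down, p))
  tight <- filter_feature_overlap("H1", "A", target = "B",
                                  relation = "a_upstream_of_b",
                                  max_distance = 50)
  expect_false(eval_filter(tight, p))
})

test_that("count, name, size, chrom and expression predicates behave", {
  p <- mk_panel(gene_id = "Nanog", L = 8000,
                tracks = list("H1|K4" = rel_track(-100, 100, 3000, 3400)),
                expression = c(H1 = 5, K562 = NA))
  expect_true(eval_filter(filter_feature_count("H1", "K4", c(-5000, 2000),
                                               "=", 1), p))
  expect_true(eval_filter(filter_feature_count("H1", "K4", op = "=",
                                               count = 2), p))
  expect_false(eval_filter(filter_feature_count("H1", "K4", c(-5000, 2000),
                                                "=", 0), p))
  expect_true(eval_filter(filter_name(names = "NANOG"), p))
  expect_true(eval_filter(filter_name(pattern = "^Na"), p))
  expect_true(eval_filter(filter_gene_size(">=", 8000), p))
  expect_false(eval_filter(filter_gene_size("<", 8000), p))
  expect_true(eval_filter(filter_chrom("chr1"), p))
  expect_true(eval_filter(filter_expression("H1", ">", 3.2), p))
  # an absent expression value fails the filter rather than acting as zero
  expect_false(eval_filter(filter_expression("K562", "<", 100), p))
  expect_error(eval_filter(filter_expression("HeLa", ">", 1), p), "HeLa")
  expect_error(eval_filter(filter_feature_count("H1", "K27"), p), "H1|K27")
})

test_that("overlap and count filters agree with brute-force oracles", {
  checked <- 0L
  for (seed in 1:25) {
    inst <- mk_instance(seed, n_genes = 25, tracks = 2, rate = 6)
    wins <- list(NULL, c(-5000, 2000), c(-20000, 0), c(1000, 30000))
    for (p in inst$panels) {
      w <- wins[[(checked %% 4L) + 1L]]
      d <- c(0, 500, 5000)[(checked %% 3L) + 1L]
      rel <- c("near", "a_upstream_of_b",
               "a_downstream_of_b")[(checked %% 3L) + 1L]
      fo <- filter_feature_overlap("cellA", inst$marks[1],
                                   target = inst$marks[2], relation = rel,
                                   max_distance = d, window_rel = w)
      expect_identical(eval_filter(fo, p),
                       bf_overlap(p, "cellA", inst$marks[1], inst$marks[2],
                                  rel, d, w))
      fe <- filter_feature_overlap("cellA", inst$marks[1], target = "exons",
                                   relation = rel, max_distance = d,
                                   window_rel = w)
      expect_identical(eval_filter(fe, p),
                       bf_overlap(p, "cellA", inst$marks[1], "exons",
                                  rel, d, w))
      n <- bf_count(p, "cellA", inst$marks[2], w)
      expect_true(eval_filter(filter_feature_count("cellA", inst$marks[2],
                                                   w, "=", n), p))
      expect_false(eval_filter(filter_feature_count("cellA", inst$marks[2],
                                                    w, ">", n), p))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 500L)
})

test_that("chaining equals intersection; the final set is order-invariant", {
  for (seed in 1:10) {
    inst <- mk_instance(seed, n_genes = 20, tracks = 2, rate = 4)
    f1 <- filter_feature_count("cellA", inst$marks[1], c(-5000, 5000), ">=", 1)
    f2 <- filter_feature_count("cellA", inst$marks[2], NULL, ">=", 2)
    f3 <- filter_gene_size(">", 8000)
    a <- apply_chain(filter_chain(f1, f2, f3), inst$panels)
    b <- apply_chain(filter_chain(f3, f1, f2), inst$panels)
    solo <- lapply(list(f1, f2, f3), function(f)
      vapply(Filter(function(p) eval_filter(f, p), inst$panels),
             function(p) p$gene$gene_id, ""))
    expect_setequal(a$surviving, Reduce(intersect, solo))
    expect_setequal(a$surviving, b$surviving)
    expect_true(all(diff(a$trace) <= 0))
    expect_equal(a$trace[length(a$trace)], length(a$surviving))
    # show flags mirror survival and nothing else changed
    for (i in seq_along(inst$panels)) {
      expect_equal(a$panels[[i]]$show,
                   inst$panels[[i]]$gene$gene_id %in% a$surviving)
      keep <- a$panels[[i]]; keep$show <- inst$panels[[i]]$show
      expect_equal(keep, inst$panels[[i]])
    }
  }
})

test_that("an empty chain keeps every gene shown", {
  inst <- mk_instance(2, n_genes = 6)
  res <- apply_chain(filter_chain(), inst$panels)
  expect_length(res$surviving, 6)
  expect_true(all(vapply(res$panels, `[[`, TRUE, "show")))
  expect_length(res$trace, 0)
})

test_that("filter chains round-trip through their JSON document form", {
  ch <- filter_chain(
    filter_name(names = c("G1", "G2")),
    filter_gene_size(">=", 5000),
    filter_chrom(c("chr1", "chr2")),
    filter_expression("H1-hESC", ">=", 3.2),
    filter_feature_count("H1-hESC", "H3K9ac", c(-5000, 2000), "=", 0),
    filter_feature_overlap("H1-hESC", "H3K4me3", target = "H3K27me3",
                           relation = "near", max_distance = 0,
                           window_rel = c(-5000, 2000)))
  f <- tempfile(fileext = ".json")
  filters_to_json(ch, f)
  back <- filters_from_json(f)
  expect_equal(back$filters, ch$filters)
  expect_identical(filters_to_json(back), filters_to_json(ch))
})
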