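mk_session <- function(seed = 1, n_genes = 8) {
  inst <- mk_instance(seed, n_genes = n_genes, tracks = 2, rate = 3)
  et <- make_expression(inst$ann, "cellA", seed = seed + 50)
  panels <- build_panels(lapply(inst$panels, `[[`, "gene"), inst$peaksets,
                         list(et), inst$settings, inst$ann)
  ch <- filter_chain(filter_feature_count("cellA", inst$marks[1],
                                          c(-5000, 2000), ">=", 1))
  res <- apply_chain(ch, panels)
  session_state(res$panels, inst$settings, res$chain,
                genome_label = "synthetic-demo",
                file_manifest = list("cellA_a.bed" = c("cellA", inst$marks[1])))
}

test_that("save -> load -> save is byte-identical and deep-equal", {
  st <- mk_session()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_session(st, f1)
  st2 <- load_session(f1)
  save_session(st2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(st2$panels, st$panels)
  expect_equal(st2$settings, st$settings)
  expect_equal(st2$chain$filters, st$chain$filters)
  expect_equal(st2$chain$trace, st$chain$trace)
})

test_that("a session is self-contained: raw inputs are not needed again", {
  dir <- tempfile(); dir.create(dir)
  sim <- run_simulate(dir, n_genes = 12, seed = 3)
  sess <- file.path(dir, "session.json")
  run_map(gene_list = sim$gene_list, annotation = sim$annotation,
          id_map = sim$id_map, features = sim$features,
          expression = sim$expression, session = sess)
  chain <- filter_chain(filter_feature_count("cellA", "H3K4me3",
                                             c(-5000, 2000), ">=", 1))
  before <- apply_chain(chain, load_session(sess)$panels)
  tbl_before <- gene_table(before$panels, filtered_only = TRUE)
  prof_before <- average_feature_profile(before$panels, "cellA|H3K4me3",
                                         "tss", shown_only = FALSE)
  # delete every raw input; only the session file remains
  file.remove(unlist(sim[c("annotation", "id_map", "gene_list",
                           "features", "expression")]))
  after <- apply_chain(chain, load_session(sess)$panels)
  expect_identical(after$surviving, before$surviving)
  expect_equal(gene_table(after$panels, filtered_only = TRUE), tbl_before)
  expect_equal(average_feature_profile(after$panels, "cellA|H3K4me3",
                                       "tss", shown_only = FALSE),
               prof_before)
})

test_that("schema violations and future versions are explicit errors", {
  st <- mk_session()
  f <- tempfile(fileext = ".json")
  save_session(st, f)
  # truncation
  txt <- readLines(f)
  bad <- tempfile(fileext = ".json")
  writeLines(substr(txt, 1, nchar(txt) %/% 2), bad)
  expect_error(load_session(bad), "JSON")
  # missing required keys
  writeLines('{"format_version":"1.0"}', bad)
  expect_error(load_session(bad), "schema.*panels")
  # unsupported future version
  l <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  l$format_version <- "99.0"
  writeLines(epipanel:::canonical_json(l), bad)
  expect_error(load_session(bad), "99\\.0")
})

test_that("summary text reports filters, traces and a parseable gene list", {
  st <- mk_session(seed = 4, n_genes = 10)
  f <- tempfile(fileext = ".txt")
  export_summary(st, f)
  txt <- readLines(f)
  expect_true(any(grepl("flank_up: 20000", txt)))
  expect_true(any(grepl(sprintf("-> %d gene", st$chain$trace[1]), txt)))
  shown <- vapply(Filter(function(p) p$show, st$panels),
                  function(p) p$gene$gene_id, "")
  expect_identical(read_summary_genes(f), shown)
  # a two-stage trace appears in order
  inst <- mk_instance(5, n_genes = 10)
  ch <- filter_chain(filter_gene_size(">", 0),
                     filter_feature_count("cellA", inst$marks[1],
                                          c(-2000, 2000), ">=", 1))
  res <- apply_chain(ch, inst$panels)
  st2 <- session_state(res$panels, inst$settings, res$chain)
  export_summary(st2, f)
  txt <- readLines(f)
  l1 <- grep(sprintf("^1\\..*-> %d gene", res$trace[1]), txt)
  l2 <- grep(sprintf("^2\\..*-> %d gene", res$trace[2]), txt)
  expect_length(l1, 1); expect_length(l2, 1)
  expect_lt(l1, l2)
  # empty chain: every gene listed as passing
  st3 <- session_state(inst$panels, inst$settings)
  export_summary(st3, f)
  expect_length(read_summary_genes(f), 10)
})

test_that("SVG export is well-formed and renders exactly the shown content", {
  p1 <- mk_panel(gene_id = "A",
                 tracks = list("c|m" = rel_track(-100, 100, 500, 900)),
                 expression = c(c = 5))
  p2 <- mk_panel(gene_id = "B",
                 tracks = list("c|m" = rel_track(0, 50)),
                 expression = c(c = 1), show = FALSE)
  f <- tempfile(fileext = ".svg")
  export_svg(list(p1, p2), panel_settings(), f)
  doc <- xml2::read_xml(f)   # throws if not well-formed XML
  ns <- function(x) sprintf("//*[local-name()='%s']", x)
  expect_length(xml2::xml_find_all(doc, "//*[@class='gene-panel']"), 1)
  expect_length(xml2::xml_find_all(doc, "//*[@class='peak']"), 2)
  expect_length(xml2::xml_find_all(doc, "//*[@class='gene-body']"), 1)
  expect_length(xml2::xml_find_all(doc, "//*[@class='scale']"), 1)
  # zero-peak panel still renders the gene bar and scale
  p0 <- mk_panel(gene_id = "C", tracks = list(
    "c|m" = rel_track(numeric(0), numeric(0))[0, , drop = FALSE]))
  export_svg(list(p0), panel_settings(), f)
  doc0 <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc0, "//*[@class='peak']"), 0)
  expect_length(xml2::xml_find_all(doc0, "//*[@class='gene-body']"), 1)
  expect_error(export_svg(list(p2), panel_settings(), f), "no shown")
})

test_that("peak bar opacity is linear in score between floor and 1", {
  p <- mk_panel(tracks = list("c|m" = matrix(c(-100, 100, 10,
                                               4000, 4200, 510,
                                               8000, 8100, 1010),
                                             ncol = 3, byrow = TRUE)))
  f <- tempfile(fileext = ".svg")
  export_svg(list(p), panel_settings(), f)
  doc <- xml2::read_xml(f)
  op <- as.numeric(xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[@class='peak']"), "fill-opacity"))
  expect_equal(sort(op), c(0.3, 0.65, 1.0), tolerance = 1e-3)
  # element count is affine in the content: panels x (fixed parts) + peaks
  inst <- mk_instance(7, n_genes = 6, tracks = 2, rate = 3)
  export_svg(inst$panels, inst$settings, f)
  doc2 <- xml2::read_xml(f)
  n_peaks <- sum(vapply(inst$panels, function(p)
    sum(vapply(p$tracks, nrow, 0L)), 0L))
  expect_length(xml2::xml_find_all(doc2, "//*[@class='peak']"), n_peaks)
  expect_length(xml2::xml_find_all(doc2, "//*[@class='gene-panel']"), 6)
})
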