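# Hand-built classified tables for the metric contracts. Only the columns a
# given metric consumes need to be realistic.
classified_stub <- function(category, resection_offset = NA_integer_,
                            structure_kind = "direct", structure_length = 0L,
                            out_of_range = FALSE, prey_end_type = NA_character_,
                            stad = NA_character_,
                            translocation_class = NA_character_,
                            Rname = "chrA", Strand = "+", Junction = 1000L,
                            B_Junction = 6001L) {
  data.frame(category = category, resection_offset = resection_offset,
             structure_kind = structure_kind,
             structure_length = structure_length,
             out_of_range = out_of_range, prey_end_type = prey_end_type,
             stad = stad, translocation_class = translocation_class,
             Rname = Rname, Strand = Strand, Junction = Junction,
             B_Junction = B_Junction, stringsAsFactors = FALSE)
}

test_that("resection enrichment is the inner-window count fraction", {
  cl <- classified_stub("V_J", resection_offset = c(0L, 3L, -5L, 50L, -80L))
  r <- resection_enrichment(cl)
  expect_equal(r$enrichment, 3 / 5)
  expect_equal(r$n_inner, 3L)
  expect_equal(r$n_window, 5L)
  # offsets beyond the outer window do not enter the denominator
  cl <- classified_stub("V_J", resection_offset = c(0L, 101L, -150L))
  expect_equal(resection_enrichment(cl)$n_window, 1L)
  # every junction at the cut: enrichment is exactly 1
  cl <- classified_stub("V_J", resection_offset = rep(0L, 7))
  expect_identical(resection_enrichment(cl)$enrichment, 1)
  # no V-J junctions in window: NA, not 0/0
  r <- resection_enrichment(classified_stub("rejoin"))
  expect_true(is.na(r$enrichment))
  expect_equal(r$n_window, 0L)
})

test_that("CE/SE ratio is undefined (NA) without signal ends", {
  cl <- classified_stub("V_J", prey_end_type = c("CE", "CE", "SE"))
  r <- ce_se_ratio(cl)
  expect_equal(r$ratio, 2)
  cl <- classified_stub("V_J", prey_end_type = c("CE", "CE"))
  r <- ce_se_ratio(cl)
  expect_equal(r$ce_count, 2L)
  expect_equal(r$se_count, 0L)
  expect_true(is.na(r$ratio))
})

test_that("V-J efficiency contracts", {
  cl <- classified_stub(c("V_J", "V_J", "rejoin", "translocation"))
  expect_equal(vj_efficiency(cl, 100L), 0.02)
  expect_equal(vj_efficiency(classified_stub("rejoin"), 100L), 0)
  expect_error(vj_efficiency(cl, 0L), "total_reads must be positive")
})

test_that("structure distribution bins, MMEJ definition and range flag", {
  cl <- classified_stub("V_J",
                        structure_kind = c("direct", "MH", "MH", "MH",
                                           "insertion", "MH"),
                        structure_length = c(0L, 1L, 2L, 3L, 2L, 25L),
                        out_of_range = c(rep(FALSE, 5), TRUE))
  d <- structure_distribution(cl, "V_region")
  expect_equal(d$n, 5L)
  expect_equal(d$n_out_of_range, 1L)
  expect_equal(sum(d$counts), 5L)
  expect_equal(unname(d$counts[c("MH2", "MH1", "direct", "INS2")]),
               c(1L, 1L, 1L, 1L))
  # MMEJ counts MH > 1 only: MH2 and MH3 of the 5 in-range junctions
  expect_equal(d$mmej_fraction, 2 / 5)
  expect_equal(d$direct_fraction, 1 / 5)
  # a pure-direct library is a point mass on the direct bin
  cl <- classified_stub(rep("V_J", 4))
  d <- structure_distribution(cl, "V_region")
  expect_equal(unname(d$counts[["direct"]]), 4L)
  expect_equal(d$direct_fraction, 1)
  expect_equal(d$mmej_fraction, 0)
  expect_equal(length(d$counts), 41L)
})

test_that("translocation frequency: relative scales, absolute deduplicates", {
  # 10 distinct junctions, each present in 3 identical copies
  uniq <- classified_stub(rep("translocation", 10),
                          translocation_class = rep(c("receptor_locus",
                                                      "spontaneous"), 5),
                          Rname = "chrX", Strand = "+",
                          Junction = seq(100L, 1000L, by = 100L))
  cl <- rbind(uniq, uniq, uniq)
  rel <- translocation_frequency(cl, total_reads = 500000L, mode = "relative")
  expect_equal(rel$frequency, 30)
  expect_equal(rel$n, 30L)
  expect_equal(unname(rel$by_class), c(15, 15))
  abs_ <- translocation_frequency(cl, total_reads = 500000L, mode = "absolute")
  expect_equal(abs_$frequency, 10)
  expect_equal(abs_$n, 10L)
  expect_equal(unname(abs_$by_class), c(5, 5))
  # relative mode rescales to events per 500k reads
  rel2 <- translocation_frequency(cl, total_reads = 250000L, mode = "relative")
  expect_equal(rel2$frequency, 60)
})

test_that("duplicates differing in any key field survive deduplication", {
  a <- classified_stub("translocation", Junction = 100L, Strand = "+")
  b <- classified_stub("translocation", Junction = 100L, Strand = "-")
  c_ <- classified_stub("translocation", Junction = 100L, Strand = "+",
                        B_Junction = 5999L)
  abs_ <- translocation_frequency(rbind(a, b, c_, a), 500000L, "absolute")
  expect_equal(abs_$frequency, 3)
})

test_that("downsample is reproducible and warns when short", {
  ids <- sprintf("id%04d", 1:2000)
  s1 <- downsample(ids, n = 100L, seed = 7L)
  s2 <- downsample(ids, n = 100L, seed = 7L)
  expect_identical(s1, s2)
  expect_length(s1, 100L)
  expect_false(identical(s1, downsample(ids, n = 100L, seed = 8L)))
  expect_warning(out <- downsample(ids, n = 5000L), "using all of them")
  expect_identical(out, ids)
})

test_that("stad distribution fractions sum to one over assigned V-Js", {
  spec <- small_locus_spec()
  cl <- classified_stub(rep("V_J", 10), stad = c(rep("s1", 7), rep("s2", 3)))
  d <- stad_distribution(cl, spec)
  expect_equal(d$stad, c("s1", "s2"))
  expect_equal(d$count, c(7L, 3L))
  expect_equal(sum(d$fraction), 1)
})

test_that("category counts partition the classified junctions", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 4000L, seed = 31, error_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  called <- call_junctions(sim, genome, spec, "BCE")$tlx
  cl <- classify_junctions(called, spec, "BCE")
  m <- compute_metrics(cl, spec, nrow(sim$reads))
  expect_equal(sum(m$category_counts), nrow(cl))
  expect_equal(m$n_junctions, nrow(cl))
  expect_true(all(names(m$category_counts) %in%
                    c("V_J", "rejoin", "intra_locus_other", "translocation")))
})

test_that("write_metrics emits the three plain-text tables", {
  spec <- small_locus_spec()
  cl <- classified_stub(c("V_J", "V_J", "rejoin"),
                        resection_offset = c(0L, 2L, NA),
                        prey_end_type = c("CE", "SE", NA),
                        stad = c("s1", "s2", NA))
  m <- compute_metrics(cl, spec, 1000L)
  prefix <- tempfile()
  paths <- write_metrics(m, prefix)
  expect_true(all(file.exists(paths)))
  summ <- utils::read.delim(paths[1])
  expect_true("vj_efficiency" %in% summ$key)
  expect_equal(summ$value[summ$key == "vj_efficiency"], 2 / 1000)
  hist <- utils::read.delim(paths[2])
  expect_equal(nrow(hist), 41L)
})
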