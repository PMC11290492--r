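# Minimal tlx row builder for structure/category tests. Defaults describe a
# 100 bp read whose bait alignment ends at query base 50.
tlx_row <- function(Junction = 1700L, Strand = "-", Rname = "chrA",
                    Rstart = Junction - 40L, Rend = Junction,
                    B_Qend = 50L, Qstart = 51L, Seq = strrep("A", 100)) {
  data.frame(Qname = "q1", JuncID = 1L, Rname = Rname, Junction = Junction,
             Strand = Strand, Rstart = Rstart, Rend = Rend,
             B_Rname = "chrA", B_Rstart = 6001L, B_Rend = 6050L,
             B_Strand = "-", B_Junction = 6001L, B_Qstart = 1L,
             B_Qend = B_Qend, Qstart = Qstart, Qend = 100L, Qlen = 100L,
             Seq = Seq, stringsAsFactors = FALSE)
}

test_that("query overlap maps to MH / direct / insertion", {
  expect_equal(joint_structure(tlx_row(B_Qend = 50L, Qstart = 48L))$structure_kind,
               "MH")
  expect_equal(joint_structure(tlx_row(B_Qend = 50L, Qstart = 48L))$structure_length,
               3L)
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 51L))
  expect_equal(st$structure_kind, "direct")
  expect_equal(st$structure_length, 0L)
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 53L))
  expect_equal(st$structure_kind, "insertion")
  expect_equal(st$structure_length, 2L)
})

test_that("palindromic insertions are recognised from the read sequence", {
  # bait-proximal bases 49-50 are "AC"; insertion "GT" = revcomp("AC")
  seq <- paste0(strrep("A", 48), "AC", "GT", strrep("C", 48))
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 53L, Seq = seq))
  expect_true(st$palindromic)
  # prey-proximal match also counts: insertion "GG" before prey "CC"
  seq <- paste0(strrep("A", 50), "GG", strrep("C", 48))
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 53L, Seq = seq))
  expect_true(st$palindromic)
  # unrelated insertion is not palindromic
  seq <- paste0(strrep("A", 50), "GT", strrep("T", 48))
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 53L, Seq = seq))
  expect_false(st$palindromic)
})

test_that("structures beyond max_len are flagged out of range", {
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 29L))  # MH-22
  expect_true(st$out_of_range)
  expect_equal(st$structure_length, 22L)
  st <- joint_structure(tlx_row(B_Qend = 50L, Qstart = 72L))  # INS-21
  expect_true(st$out_of_range)
  expect_false(joint_structure(tlx_row(Qstart = 31L))$out_of_range)  # MH-20
})

test_that("categorize applies inclusive +/- pad windows around V cuts", {
  spec <- small_locus_spec()
  # V1 cut at 0-based 1699; window [1499, 1899] inclusive
  at <- function(j0) tlx_row(Junction = j0 + 1L)
  expect_equal(categorize(at(1499L), spec, "BCE")$category, "V_J")
  expect_equal(categorize(at(1899L), spec, "BCE")$category, "V_J")
  expect_equal(categorize(at(1498L), spec, "BCE")$category,
               "intra_locus_other")
  expect_equal(categorize(at(1900L), spec, "BCE")$category,
               "intra_locus_other")
  expect_equal(categorize(at(1499L), spec, "BCE")$prey_segment, "V1")
})

test_that("categorize separates rejoins, locus background and translocations", {
  spec <- small_locus_spec()
  # bait region [5850, 6150): inside -> rejoin, boundary 6150 -> not
  expect_equal(categorize(tlx_row(Junction = 5851L), spec, "BCE")$category,
               "rejoin")
  expect_equal(categorize(tlx_row(Junction = 6150L), spec, "BCE")$category,
               "rejoin")
  expect_equal(categorize(tlx_row(Junction = 6151L), spec, "BCE")$category,
               "intra_locus_other")
  # off the bait chromosome: translocation, split by receptor loci
  rec <- categorize(tlx_row(Junction = 2100L, Rname = "chrX"), spec, "BCE")
  expect_equal(rec$category, "translocation")
  expect_equal(rec$translocation_class, "receptor_locus")
  sp <- categorize(tlx_row(Junction = 4000L, Rname = "chrX"), spec, "BCE")
  expect_equal(sp$translocation_class, "spontaneous")
  sp <- categorize(tlx_row(Junction = 2100L, Rname = "chrB"), spec, "BCE")
  expect_equal(sp$translocation_class, "spontaneous")
  # on the bait chromosome but outside the locus interval [500, 7000)
  far <- categorize(tlx_row(Junction = 9000L), spec, "BCE")
  expect_equal(far$category, "translocation")
  expect_equal(far$translocation_class, "spontaneous")
})

test_that("end type follows the majority of aligned prey bases", {
  spec <- small_locus_spec()
  # V1 '+' cut 1699: coding side is offset <= 0, i.e. positions <= 1699
  ce <- tlx_row(Junction = 1700L, Strand = "-", Rstart = 1660L, Rend = 1700L)
  cat <- categorize(ce, spec, "BCE")
  et <- assign_end_type(ce, cat, spec)
  expect_equal(et$prey_end_type, "CE")
  expect_false(et$end_ambiguous)
  expect_equal(et$configuration, "DEL")

  se <- tlx_row(Junction = 1701L, Strand = "+", Rstart = 1701L, Rend = 1741L)
  et <- assign_end_type(se, categorize(se, spec, "BCE"), spec)
  expect_equal(et$prey_end_type, "SE")
  expect_false(et$end_ambiguous)

  # majority on the coding side despite crossing the cut
  mix <- tlx_row(Junction = 1660L, Strand = "+", Rstart = 1660L, Rend = 1705L)
  et <- assign_end_type(mix, categorize(mix, spec, "BCE"), spec)
  expect_equal(et$prey_end_type, "CE")
  expect_true(et$end_ambiguous)

  # exact tie: 20 bases each side, junction base decides (offset 0 -> CE)
  tie <- tlx_row(Junction = 1700L, Strand = "-", Rstart = 1681L, Rend = 1720L)
  et <- assign_end_type(tie, categorize(tie, spec, "BCE"), spec)
  expect_equal(sum(seq(1680L, 1719L) <= 1699L), 20L)  # fixture sanity
  expect_equal(et$prey_end_type, "CE")
  expect_true(et$end_ambiguous)
})

test_that("resection offset is strand-normalised around the assigned cut", {
  spec <- small_locus_spec()
  # V1 '+': junction 5 bp into the coding body -> offset -5
  r <- classify_junctions(tlx_row(Junction = 1695L, Strand = "-",
                                  Rstart = 1655L, Rend = 1695L),
                          spec, "BCE")
  expect_equal(r$resection_offset, -5L)
  expect_equal(r$stad, "s1")
  # V2 '-' cut 2200: genomic position 2205 is 5 bp into the coding body
  r <- classify_junctions(tlx_row(Junction = 2206L, Strand = "+",
                                  Rstart = 2206L, Rend = 2246L),
                          spec, "BCE")
  expect_equal(r$resection_offset, -5L)
  expect_equal(r$prey_segment, "V2")
  expect_equal(r$configuration, "INV")
  # non-V junctions carry NA offset and stad
  r <- classify_junctions(tlx_row(Junction = 5900L), spec, "BCE")
  expect_true(is.na(r$resection_offset))
  expect_true(is.na(r$stad))
})

test_that("stad assignment comes from the assigned segment's cut site", {
  spec <- small_locus_spec()
  r <- classify_junctions(tlx_row(Junction = 3700L, Strand = "-",
                                  Rstart = 3660L, Rend = 3700L),
                          spec, "BCE")
  expect_equal(r$prey_segment, "V3")
  expect_equal(r$stad, "s2")
})

test_that("classify_junctions on empty input returns typed columns", {
  spec <- small_locus_spec()
  r <- classify_junctions(tlx_row()[integer(0), ], spec, "BCE")
  expect_equal(nrow(r), 0)
  expect_type(r$resection_offset, "integer")
  expect_type(r$palindromic, "logical")
  expect_true(all(c("category", "stad", "structure_kind") %in% names(r)))
})
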