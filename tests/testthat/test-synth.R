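test_that("flank guard removes every suffix/prefix identity and block", {
  spec <- small_locus_spec()
  genome <- small_genome()
  pairs <- baitjoin:::guard_pairs(spec)
  viol <- lapply(pairs, function(p) {
    baitjoin:::flank_pair_violations(genome, p$bg, p$pg)
  })
  expect_true(all(lengths(viol) == 0))
})

test_that("an unguarded genome contains chance violations", {
  spec <- small_locus_spec()
  genome <- build_toy_genome(spec, seed = 11, flank_guard = "off")
  pairs <- baitjoin:::guard_pairs(spec)
  viol <- lapply(pairs, function(p) {
    baitjoin:::flank_pair_violations(genome, p$bg, p$pg)
  })
  # 16 pairs x 3 single-base conditions, each ~1/4: some violation is
  # essentially certain (and holds at this fixed seed)
  expect_gt(sum(lengths(viol)), 0)
})

test_that("simulation is deterministic for a fixed config", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 200L, seed = 5, error_rate = 0.002)
  s1 <- simulate_library(cfg, spec, genome)
  s2 <- simulate_library(cfg, spec, genome)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("event class frequencies match the configuration within 3 sigma", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 20000L, seed = 6, error_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  n <- nrow(sim$truth)
  for (cls in c("V_J", "rejoin", "translocation")) {
    p <- switch(cls, V_J = cfg$vj_rate, rejoin = cfg$rejoin_rate,
                translocation = cfg$translocation_rate)
    obs <- sum(sim$truth$event_class == cls) / n
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("emergent read structure equals intended structure", {
  # the MH/direct/insertion structure read back from the sequence itself must
  # equal the simulator's intent for every joined read (noiseless, guarded)
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 1500L, seed = 7, error_rate = 0,
                      regime = "NHEJ")
  sim <- simulate_library(cfg, spec, genome)
  tlx <- emit_truth_tlx(sim, spec)
  st <- joint_structure(tlx)
  truth <- sim$truth[match(tlx$Qname, sim$truth$qname), ]
  expect_identical(st$structure_kind, truth$structure_kind)
  expect_identical(st$structure_length, truth$structure_length)
  expect_identical(st$palindromic, truth$palindromic)
})

test_that("hybrid_rate = 0 yields only cognate ends", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 2000L, seed = 8, hybrid_rate = 0,
                      error_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  v <- sim$truth[sim$truth$event_class == "V_J", ]
  expect_gt(nrow(v), 0)
  expect_true(all(v$prey_end_type == "CE"))
})

test_that("resection_w0 = 1 pins every end at the cut", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 1000L, seed = 9, resection_w0 = 1,
                      error_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  v <- sim$truth[sim$truth$event_class == "V_J", ]
  expect_gt(nrow(v), 0)
  expect_true(all(v$bait_resection == 0L))
  expect_true(all(v$prey_resection == 0L))
  # with no resection a religated bait DSB is seamless: every rejoin is
  # perfect, carries no junction, and emits no truth tlx record
  rj <- sim$truth[sim$truth$event_class == "rejoin", ]
  expect_gt(nrow(rj), 0)
  expect_true(all(rj$structure_kind == "none"))
  expect_true(all(is.na(rj$bait_resection)))
  tlx <- emit_truth_tlx(sim, spec)
  expect_length(intersect(tlx$Qname, rj$qname), 0)
  # and those reads are literally the unbroken allele, so the caller is
  # silent on them
  called <- call_junctions(sim, genome, spec, "BCE")$tlx
  expect_length(intersect(called$Qname, rj$qname), 0)
  expect_setequal(called$Qname, tlx$Qname)
})

test_that("prey resections follow the closed-form mixture (insertion joints)", {
  # insertion junctions sample their resections straight from the mixture
  # (the admissibility retry depends on the random inserted bases, not on the
  # site), so their marginal CDF matches the closed form; MH and direct
  # joints are conditioned on sequence availability and frontier blocks and
  # are checked by the pipeline-vs-truth equality tests instead
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 4000L, seed = 10, error_rate = 0,
                      vj_rate = 0.5, rejoin_rate = 0.1,
                      structure_weights = c(INS3 = 1),
                      palindromic_insertion_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  v <- sim$truth[sim$truth$event_class == "V_J", ]
  n <- nrow(v)
  for (x in c(0, 5, 20, 60)) {
    p <- resection_cdf(x, cfg$resection_w0, cfg$resection_mean,
                       cfg$resection_max)
    obs <- mean(v$prey_resection <= x)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 0.02)
  }
})

test_that("duplicate injection appends exact copies", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 500L, seed = 12, duplicate_rate = 0.2,
                      error_rate = 0)
  sim <- simulate_library(cfg, spec, genome)
  dups <- grepl(":dup$", sim$reads$qname)
  expect_gt(sum(dups), 0)
  orig <- sub(":dup$", "", sim$reads$qname[dups])
  expect_identical(sim$reads$seq[dups],
                   sim$reads$seq[match(orig, sim$reads$qname)])
  expect_true(all(sim$truth$is_duplicate[dups]))
})

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(sim_config(vj_rate = 0.7, rejoin_rate = 0.5), "<= 1")
  expect_error(sim_config(structure_weights = c(direct = 0.5, MH25 = 0.5)),
               "unknown structure weight")
  expect_error(sim_config(v_usage = c("sTAD1-2" = 0.5)), "sum to 1")
  expect_error(sim_config(resection_max = 300), "<= 200")
  expect_error(sim_config(hybrid_rate = 1.5), "hybrid_rate")
  expect_error(sim_config(read_length = 60) |> (\(cfg) {
    simulate_library(cfg, default_locus_spec(), big_genome())
  })(), "read_length too short")
})

test_that("resection pmf is a probability mass with the right point mass", {
  pmf <- resection_pmf(0.8, 30, 100)
  expect_equal(sum(pmf), 1)
  expect_equal(pmf[1], 0.8)
  expect_equal(resection_cdf(100, 0.8, 30, 100), 1)
  expect_equal(resection_cdf(0, 0.8, 30, 100), 0.8)
})

test_that("fastq output is deterministic and well-formed", {
  spec <- small_locus_spec()
  genome <- small_genome()
  cfg <- small_config(n_read_pairs = 50L, seed = 13)
  sim <- simulate_library(cfg, spec, genome)
  f1 <- tempfile(fileext = ".fastq"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fastq"); t2 <- tempfile(fileext = ".tsv")
  write_library(sim, f1, t1)
  write_library(sim, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  fq <- readLines(f1)
  expect_equal(length(fq), 4 * nrow(sim$reads))
  expect_true(all(startsWith(fq[seq(1, length(fq), 4)], "@rd")))
})
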