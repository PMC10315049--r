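test_that("a random sequence with no repeated 30-mer yields no repeats", {
  set.seed(40)
  s <- rand_dna(2000)
  expect_equal(nrow(repeat_oracle(s, 30)), 0)   # construction verified
  r <- find_repeats(s, 30, circular = FALSE)
  expect_equal(nrow(r$pairs), 0)
  expect_equal(r$n_units, 0)
  expect_equal(r$content, 0)
})

test_that("maximal repeat enumeration equals the quadratic oracle on small genomes", {
  for (seed in 41:43) {
    set.seed(seed)
    core <- rand_dna(3000)
    rep1 <- rand_dna(150); rep2 <- rand_dna(60)
    g <- paste0(substr(core, 1, 700), rep1,
                substr(core, 701, 1500), rep2,
                substr(core, 1501, 2200), rep1,
                substr(core, 2201, 2700),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(rep2))),
                substr(core, 2701, 3000))
    want <- repeat_oracle(g, 30)
    got <- find_repeats(g, 30, circular = FALSE)$pairs
    got <- got[order(got$relation, got$start1, got$start2), ]
    expect_equal(nrow(got), nrow(want), info = seed)
    expect_equal(got$start1, want$start1)
    expect_equal(got$start2, want$start2)
    expect_equal(got$length, want$len)
    expect_equal(got$relation, want$relation)
  }
})

test_that("raising min_len never increases the unit count; content is rotation-invariant", {
  set.seed(44)
  core <- rand_dna(4000)
  rep1 <- rand_dna(300)
  g <- paste0(substr(core, 1, 1000), rep1, substr(core, 1001, 2500), rep1,
              substr(core, 2501, 4000))
  r30 <- find_repeats(g, 30, circular = TRUE)
  r100 <- find_repeats(g, 100, circular = TRUE)
  r400 <- find_repeats(g, 400, circular = TRUE)
  expect_gte(r30$n_units, r100$n_units)
  expect_gte(r100$n_units, r400$n_units)
  for (off in c(500, 1100, 4000)) {
    rr <- find_repeats(rotate_seq(g, off), 30, circular = TRUE)
    expect_equal(sort(rr$pairs$length), sort(r30$pairs$length), info = off)
    expect_equal(rr$content, r30$content)
    expect_equal(rr$n_units, r30$n_units)
  }
})

test_that("recombination assay counts conformations and validates preconditions", {
  set.seed(45)
  core <- rand_dna(6000)
  rep1 <- rand_dna(300)
  g <- paste0(substr(core, 1, 1500), rep1, substr(core, 1501, 3500), rep1,
              substr(core, 3501, 6000))
  rp <- list(start1 = 1501, end1 = 1800, start2 = 3801, end2 = 4100,
             relation = "direct")
  reads <- c(
    substr(g, 1300, 2100),                        # parental 1
    substr(g, 3600, 4400),                        # parental 2
    paste0(substr(g, 1300, 1800), substr(g, 4101, 4400)),  # recombinant 1
    paste0(substr(g, 3600, 3800), substr(g, 1501, 2100)))  # recombinant 2
  a <- recombination_frequency(g, rp, reads, flank = 100)
  expect_equal(unname(a$counts[c("parental_1", "parental_2",
                                 "recombinant_1", "recombinant_2")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(a$frequency, 0.5)
  ## parental-only reads: frequency 0
  a0 <- recombination_frequency(g, rp, reads[1:2], flank = 100)
  expect_equal(a0$frequency, 0)
  ## reads shorter than repeat + 2 x flank never span: undefined
  a_short <- recombination_frequency(g, rp,
                                     substring(g, 1:5 * 100, 1:5 * 100 + 300))
  expect_equal(a_short$total, 0)
  expect_true(is.na(a_short$frequency))
  ## order invariance
  a_rev <- recombination_frequency(g, rp, rev(reads), flank = 100)
  expect_equal(a_rev$counts, a$counts)
  expect_error(
    recombination_frequency(g, list(start1 = 1501, end1 = 1580,
                                    start2 = 3801, end2 = 3880,
                                    relation = "direct"), reads),
    "larger than 100")
  close_rp <- list(start1 = 1501, end1 = 1800, start2 = 1900, end2 = 2199,
                   relation = "direct")
  expect_error(recombination_frequency(g, close_rp, reads, flank = 100),
               "overlap")
})

test_that("simulated recombinant reads are recovered at the planted fraction", {
  set.seed(46)
  core <- rand_dna(8000)
  rep1 <- rand_dna(300)
  g <- annotated_genome("g", paste0(substr(core, 1, 2000), rep1,
                                    substr(core, 2001, 5000), rep1,
                                    substr(core, 5001, 8000)), "circular")
  rp <- data.frame(start1 = 2001, end1 = 2300, start2 = 5301, end2 = 5600,
                   relation = "direct")
  cfg <- sim_config(seed = 47, read_len_mean = 900, read_len_sd = 60,
                    read_error_rate = 0.02,
                    recombinant_read_fraction = 0.25)
  rd <- simulate_long_reads(g, rp, cfg, n_reads = 300,
                            start_window = c(1500, 1900))
  spanning <- !is.na(rd$truth$repeat_idx)
  expect_gt(sum(spanning), 50)
  a <- recombination_frequency(g, rp[1, ], rd$reads[spanning])
  planted <- mean(rd$truth$conformation[spanning] != "parental")
  expect_gt(a$total, 0.9 * sum(spanning))
  expect_lt(abs(a$frequency - planted), 0.02)
})
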