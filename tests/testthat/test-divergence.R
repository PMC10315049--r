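test_that("Kimura two-parameter distance follows the two-logarithm formula", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1))
  expect_equal(round(k2p_distance(0.1, 0.05), 5), 0.17018)
  expect_error(k2p_distance(0.3, 0.4), "saturation")
  ## the correction never shrinks the observed proportion
  for (i in 1:20) {
    set.seed(i)
    P <- runif(1, 0, 0.2); Q <- runif(1, 0, 0.2)
    expect_gte(k2p_distance(P, Q), P + Q - 1e-12)
  }
})

test_that("substitution and indel tabulation matches the simulation ledger exactly", {
  sim <- shared_sim()
  A <- sim$genomes$C; B <- sim$genomes$S
  blocks <- build_blocks(local_search(A, B$seq, circular_subject = TRUE))
  td <- tabulate_differences(blocks, A)
  led <- sim$ledger$substitutions
  exp_subs <- sum(led$genome == "C" & led$branch == "C") +
    sum(led$genome == "S" & led$branch == "S")
  ind <- sim$ledger$indels
  exp_ind <- sum(ind$genome == "C" & ind$branch == "C") +
    sum(ind$genome == "S" & ind$branch == "S")
  expect_equal(nrow(td$substitutions), exp_subs)
  expect_equal(nrow(td$indels), exp_ind)
  expect_true(all(td$indels$length >= 1 & td$indels$length <= 8))
  ## identical inputs: nothing to report
  b0 <- build_blocks(local_search(A, A$seq))
  td0 <- tabulate_differences(b0, A)
  expect_equal(nrow(td0$substitutions), 0)
  expect_equal(nrow(td0$indels), 0)
})

test_that("a single A/G mismatch is one transition record with codon effect", {
  set.seed(50)
  orf <- mitocomp:::.make_orf(300)
  flank <- rand_dna(500)
  seq1 <- paste0(flank, orf, rand_dna(500))
  g <- annotated_genome("g", seq1, "linear",
                        data.frame(type = "CDS", start = 501, end = 800,
                                   strand = "+", name = "gene1"))
  v <- strsplit(seq1, "")[[1]]
  pos <- 501 + 3 * 10   # first base of codon 11
  v[pos] <- c(A = "G", G = "A", C = "T", T = "C")[[v[pos]]]
  seq2 <- paste(v, collapse = "")
  td <- tabulate_differences(build_blocks(local_search(g, seq2)), g)
  expect_equal(nrow(td$substitutions), 1)
  expect_equal(td$substitutions$pos, pos)
  expect_equal(td$substitutions$class, "transition")
  expect_equal(td$substitutions$context, "CDS")
  expect_true(td$substitutions$codon_effect %in%
                c("synonymous", "nonsynonymous"))
})

test_that("Ks/Ka counting agrees with the brute-force pathway oracle", {
  expect_equal(ks_ka("ATGAAA", "ATGAAA")$Ks, 0)
  expect_equal(ks_ka("ATGAAA", "ATGAAA")$Ka, 0)
  ## a single synonymous third-position change in a long CDS
  set.seed(51)
  orf <- mitocomp:::.make_orf(900)
  v <- strsplit(orf, "")[[1]]; v2 <- v
  v[88:90] <- c("G", "G", "A"); v2[88:90] <- c("G", "G", "G")
  r <- ks_ka(paste(v, collapse = ""), paste(v2, collapse = ""))
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  ## enumerable two-codon toys, including a two-step pathway; identical
  ## context codons are appended so the correction stays defined
  ctx <- paste(rep("ATGGGG", 30), collapse = "")
  for (toy in list(c("ATGAAA", "ATGAAG"), c("ATGTTT", "ATGTAC"),
                   c("TTAAGA", "CTGAGC"))) {
    r <- ks_ka(paste0(ctx, toy[1]), paste0(ctx, toy[2]))
    want_syn <- want_nonsyn <- 0
    for (k in 1:2) {
      o <- codon_pathway_oracle(substr(toy[1], 3 * k - 2, 3 * k),
                                substr(toy[2], 3 * k - 2, 3 * k))
      want_syn <- want_syn + o["syn"]; want_nonsyn <- want_nonsyn + o["nonsyn"]
    }
    expect_equal(r$S_diffs, unname(want_syn), info = toy[1])
    expect_equal(r$N_diffs, unname(want_nonsyn), info = toy[1])
  }
  expect_error(ks_ka("ATGTAAAAA", "ATGTAAAAG"), "internal stop")
})

test_that("column polarisation assigns lineages and conserves counts", {
  ## definition cases
  p <- polarize(c("GAA", "AAA", "AAA"))
  expect_equal(unname(p$counts["lineage1"]), 1L)
  p2 <- polarize(c("ACG", "ACG", "ACG"))
  expect_equal(unname(p2$counts["total"]), 0L)
  p3 <- polarize(c("GAA", "CAA", "TAA"))   # three states
  expect_equal(unname(p3$counts["unpolarized"]), 1L)
  ## ledgered simulation: terminal-branch recovery is exact
  cfg <- sim_config(seed = 52, event_counts = c(), indel_rate = 0,
                    rotate = FALSE)
  s <- simulate_genomes(cfg)
  pz <- polarize(c(s$genomes$C$seq, s$genomes$S$seq, s$genomes$D$seq))
  led <- s$ledger$substitutions
  expect_equal(unname(pz$counts["lineage1"]),
               sum(led$genome == "C" & led$branch == "C"))
  expect_equal(unname(pz$counts["lineage2"]),
               sum(led$genome == "S" & led$branch == "S"))
  expect_equal(unname(pz$counts["lineage1"] + pz$counts["lineage2"] +
                        pz$counts["unpolarized"]),
               unname(pz$counts["total"]))
})

test_that("clock arithmetic reproduces the calibration identities", {
  ## query equal to calibration distance dates to the calibration time
  expect_equal(clock(0.05, 0.05, 88e6)$time, 88e6)
  cl <- clock(1.33e-3, 6.28e-2, 88e6)
  expect_equal(cl$time / 1e6, 1.86, tolerance = 0.01 / 1.86)
  expect_equal(clock_rate(1.33e-3, 1.86e6), 7.15e-10, tolerance = 1e-3)
  expect_equal(clock_rate(4.45e-3, 1.86e6), 2.39e-9, tolerance = 1e-3)
  ## scale invariance: multiplying all distances by c leaves T unchanged
  for (c_ in c(0.1, 3, 10))
    expect_equal(clock(c_ * 1.33e-3, c_ * 6.28e-2, 88e6)$time, cl$time)
  ## per-lineage convention halves the rate but not the time
  cl2 <- clock(1.33e-3, 6.28e-2, 88e6, per_lineage = TRUE)
  expect_equal(cl2$rate, cl$rate / 2)
  expect_equal(cl2$time, cl$time)
  expect_error(clock(0, 1, 1), "query_distance")
})
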