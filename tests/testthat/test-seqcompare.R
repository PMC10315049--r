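test_that("self-search returns a full-length identity hit", {
  set.seed(10)
  g <- rand_dna(3000)
  h <- local_search(g, g)
  expect_true(any(h$qstart == 1 & h$qend == 3000 & h$identity == 1))
  expect_error(local_search("ACGTX", g), "outside")
})

test_that("a planted 500 bp insert at 95% identity yields exactly one covering hit", {
  for (seed in 1:3) {
    set.seed(seed)
    ins <- rand_dna(500)
    subj <- paste0(rand_dna(1000), mutate_seq(ins, 25), rand_dna(1000))
    query <- paste0(rand_dna(200), ins, rand_dna(200))
    h <- local_search(query, subj)
    expect_equal(nrow(h), 1)
    expect_gte(h$qend - h$qstart + 1, 0.9 * 500)
    expect_gte(h$identity, 0.85)
  }
})

test_that("unrelated random sequences yield no hits, matching the DP oracle", {
  for (seed in 4:6) {
    set.seed(seed)
    q <- rand_dna(1000); s <- rand_dna(1000)
    h <- local_search(q, s, min_identity = 0.85, min_hit_len = 90)
    expect_equal(nrow(h), 0)
    o <- sw_oracle(q, s)
    ## the optimal local alignment itself fails the reporting thresholds
    expect_true(o$q_end - o$q_start + 1 < 90 || o$identity < 0.85)
  }
})

test_that("every qualifying DP-oracle alignment is recovered by the seeded search", {
  for (seed in 7:11) {
    set.seed(seed)
    core <- rand_dna(400)
    q <- paste0(rand_dna(300), core, rand_dna(300))
    s <- paste0(rand_dna(500), mutate_seq(core, 20), rand_dna(700))
    o <- sw_oracle(q, s)
    expect_gte(o$identity, 0.85)   # oracle finds the planted similarity
    h <- local_search(q, s)
    expect_gt(nrow(h), 0)
    ov <- pmin(h$qend, o$q_end) - pmax(h$qstart, o$q_start) + 1
    expect_gte(max(ov) / (o$q_end - o$q_start + 1), 0.9)
  }
})

test_that("identical genomes chain into a single full-coverage block", {
  set.seed(12)
  g <- rand_dna(5000)
  b <- build_blocks(local_search(g, g))
  expect_equal(nrow(b), 1)
  expect_equal(b$q_start, 1); expect_equal(b$q_end, 5000)
})

test_that("an inversion appears as one minus-strand block at the planted interval", {
  set.seed(13)
  left <- rand_dna(4000); mid <- rand_dna(2000); right <- rand_dna(4000)
  gA <- paste0(left, mid, right)
  gB <- paste0(left, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mid))), right)
  b <- build_blocks(local_search(gA, gB))
  inv <- detect_inversions(b)
  expect_equal(nrow(inv), 1)
  expect_lt(abs(inv$q_start - 4001), 50)
  expect_lt(abs(inv$q_end - 6000), 50)
  expect_equal(nrow(detect_inversions(build_blocks(local_search(gA, gA)))),
               0)
})

test_that("a planted insertion splits the chain and is reported as a region", {
  set.seed(14)
  left <- rand_dna(4000); right <- rand_dna(4000)
  gain <- rand_dna(2712)
  A <- annotated_genome("Aa", paste0(left, gain, right), "linear")
  B <- annotated_genome("Bb", paste0(left, right), "linear")
  b <- build_blocks(local_search(A, B$seq))
  nar <- nonalignable_regions(A, B, b)
  expect_equal(nrow(nar$Aa), 1)
  expect_lt(abs(nar$Aa$length - 2712), 50)
  expect_equal(nrow(nar$Bb), 0)
  ## role swap: comparing (B, A) attributes the same region to A
  b2 <- build_blocks(local_search(B, A$seq))
  nar2 <- nonalignable_regions(B, A, b2)
  expect_equal(nrow(nar2$Bb), 0)
  expect_equal(nrow(nar2$Aa), 1)
  expect_lt(abs(nar2$Aa$length - nar$Aa$length), 30)
})

test_that("block + region + sub-threshold gap coverage conserves genome length", {
  sim <- shared_sim()
  A <- sim$genomes$C; B <- sim$genomes$S
  b <- build_blocks(local_search(A, B$seq, circular_subject = TRUE))
  nar <- nonalignable_regions(A, B, b, merge_slack = 0)
  cov_blocks <- IRanges::reduce(IRanges::IRanges(b$q_start, b$q_end))
  gaps <- IRanges::gaps(cov_blocks, start = 1, end = nchar(A$seq))
  small <- sum(IRanges::width(gaps)[IRanges::width(gaps) < 90])
  expect_equal(sum(IRanges::width(cov_blocks)) + sum(nar$C$length) + small,
               nchar(A$seq))
})

test_that("rotating a circular genome preserves the multiset of region lengths", {
  sim <- shared_sim()
  A <- sim$genomes$C; B <- sim$genomes$S
  rotB <- annotated_genome("S", rotate_seq(B$seq, 20000), "circular")
  lens <- function(bb, a, b) {
    nar <- nonalignable_regions(a, b, bb)
    sort(unlist(lapply(nar, function(x) x$length)))
  }
  l1 <- lens(build_blocks(local_search(A, B$seq, circular_subject = TRUE)),
             A, B)
  l2 <- lens(build_blocks(local_search(A, rotB$seq, circular_subject = TRUE)),
             A, rotB)
  expect_equal(length(l1), length(l2))
  expect_lt(max(abs(l1 - l2)), 60)   # boundary jitter only
})
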