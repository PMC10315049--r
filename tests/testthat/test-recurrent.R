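# a small deterministic alignment-set builder: mt consensus vs a cp
# sequence differing at planted diagnostic sites
make_set <- function(n_col = 600, n_diag = 60, seed = 1,
                     breakpoint = NULL, query = c("mt", "cp", "chimera")) {
  set.seed(seed)
  query <- match.arg(query)
  mt <- strsplit(rand_dna(n_col), "")[[1]]
  cp <- mt
  diag_pos <- sort(sample(n_col, n_diag))
  for (p in diag_pos) cp[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              cp[p]), 1)
  mts <- c(m1 = paste(mt, collapse = ""), m2 = paste(mt, collapse = ""),
           m3 = paste(mt, collapse = ""))
  q <- switch(query,
              mt = mt,
              cp = cp,
              chimera = c(cp[seq_len(breakpoint)],
                          mt[(breakpoint + 1):n_col]))
  list(set = region_alignment_set(paste(q, collapse = ""), mts,
                                  c(cp = paste(cp, collapse = ""))),
       diag = diag_pos)
}

test_that("single-segment queries get no-chimera verdicts", {
  s <- make_set(query = "mt")
  call <- scan_breakpoint(s$set)
  expect_equal(call$verdict, "all_mt")
  s2 <- make_set(query = "cp")
  expect_equal(scan_breakpoint(s2$set)$verdict, "all_cp")
  nosig <- region_alignment_set("ACGT", c(m1 = "ACGT", m2 = "ACGT"),
                                c(cp = "ACGT"))
  expect_error(scan_breakpoint(nosig), "diagnostic")
})

test_that("the scan equals the exhaustive boundary oracle and localises planted breakpoints", {
  for (seed in 1:20) {
    bp <- sample(150:450, 1)
    s <- make_set(seed = seed, breakpoint = bp, query = "chimera")
    call <- scan_breakpoint(s$set)
    want <- breakpoint_oracle(s$set)
    expect_equal(call$verdict, "chimera")
    expect_equal(call$verdict, want$verdict)
    expect_equal(call$score, want$score)
    expect_equal(call$orientation, want$orientation)
    ## localisation within the flanking diagnostic-site gap
    lo <- max(s$diag[s$diag <= bp])
    hi <- min(s$diag[s$diag > bp])
    expect_gte(call$boundary, lo)
    expect_lt(call$boundary, hi)
  }
})

test_that("reversing the alignment mirrors the boundary and orientation", {
  s <- make_set(seed = 77, breakpoint = 300, query = "chimera")
  call <- scan_breakpoint(s$set)
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  rset <- region_alignment_set(
    rev_str(paste(s$set$query, collapse = "")),
    vapply(seq_len(nrow(s$set$mts)), function(i)
      rev_str(paste(s$set$mts[i, ], collapse = "")), ""),
    rev_str(paste(s$set$cps[1, ], collapse = "")))
  rcall <- scan_breakpoint(rset)
  expect_equal(rcall$verdict, "chimera")
  expect_equal(rcall$score, call$score)
  expect_false(rcall$orientation == call$orientation)
  ## the mirrored boundary lies on the same inter-diagnostic plateau
  ## (leftmost tie-breaking picks opposite plateau ends)
  lo <- max(s$diag[s$diag <= 300]); hi <- min(s$diag[s$diag > 300])
  expect_gte(s$set$n_col - rcall$boundary, lo)
  expect_lt(s$set$n_col - rcall$boundary, hi)
})

test_that("indel columns are excluded from diagnostics but reported", {
  q <- "ACG-TTGA"
  mts <- c(m1 = "ACGATTGA", m2 = "ACGATTGA", m3 = "ACG-TTGA")
  cps <- c(cp = "TCGATTGA")
  set <- region_alignment_set(q, mts, cps)
  expect_equal(set$indel_columns, 4L)
  expect_equal(set$diagnostic, 1L)
})

test_that("neighbor joining recovers the topology from additive distances", {
  ## additive tree: ((a,b),(c,d)) with internal edge 3
  D <- matrix(c(0, 4, 9, 10,
                4, 0, 9, 10,
                9, 9, 0, 5,
                10, 10, 5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  phy <- ape::nj(as.dist(D))
  expect_true(ape::is.monophyletic(phy, c("a", "b")))
  expect_true(ape::is.monophyletic(phy, c("c", "d")))
})

test_that("partition trees place the carrier with the chloroplast clade only on the overwritten side", {
  sim <- shared_sim()
  tmpl <- sim$ledger$recurrent
  ev <- sim$ledger$events
  reg_of <- function(g) {
    e <- ev[ev$genome == g & ev$event_id == tmpl$host_event, ]
    substr(sim$genomes[[g]]$seq, e$start, e$end)
  }
  mts <- c(C = reg_of("C"), S = reg_of("S"), D = reg_of("D"))
  cps <- c(cp = substr(sim$cp$seq, tmpl$donor_start, tmpl$donor_end))
  pop <- simulate_population(sim, 6, carrier_fraction = 0.5)
  qcar <- as.character(pop$sequences[[which(pop$carrier)[1]]])
  set <- region_alignment_set(qcar, mts, cps)
  call <- scan_breakpoint(set)
  expect_equal(call$verdict, "chimera")
  pt <- partition_trees(set, call, bootstrap = 200, seed = 5)
  expect_true(pt$left$query_with_cp)
  expect_false(pt$right$query_with_cp)
  expect_gte(pt$left$support, 95)
  ## a non-carrier stays inside the mitochondrial clade on both sides
  qnon <- as.character(pop$sequences[[which(!pop$carrier)[1]]])
  set0 <- region_alignment_set(qnon, mts, cps)
  expect_equal(scan_breakpoint(set0)$verdict, "all_mt")
  ptn <- partition_trees(set0, call, bootstrap = 100, seed = 5)
  expect_false(ptn$left$query_with_cp)
  expect_false(ptn$right$query_with_cp)
  ## degenerate partitions are refused
  shallow <- call; shallow$boundary <- 10L
  expect_error(partition_trees(set, shallow, bootstrap = 10),
               "too short|at least 50")
})

test_that("the fixation survey reproduces population presence patterns", {
  sim <- shared_sim()
  tmpl <- sim$ledger$recurrent
  ev <- sim$ledger$events
  reg_of <- function(g) {
    e <- ev[ev$genome == g & ev$event_id == tmpl$host_event, ]
    substr(sim$genomes[[g]]$seq, e$start, e$end)
  }
  mts <- c(C = reg_of("C"), S = reg_of("S"), D = reg_of("D"))
  cps <- c(cp = substr(sim$cp$seq, tmpl$donor_start, tmpl$donor_end))
  popA <- simulate_population(sim, 5, carrier_fraction = 1, seed = 101)
  popB <- simulate_population(sim, 5, carrier_fraction = 0, seed = 102)
  popC <- simulate_population(sim, 5, carrier_fraction = 0, seed = 103)
  tb <- scan_breakpoint(region_alignment_set(
    as.character(popA$sequences[[1]]), mts, cps))$boundary
  fs <- fixation_survey(list(one = as.character(popA$sequences),
                             two = as.character(popB$sequences),
                             three = as.character(popC$sequences)),
                        mts, cps, template_boundary = tb)
  expect_equal(fs$carriers, c(5L, 0L, 0L))
  expect_equal(fs$fixed, c(TRUE, FALSE, FALSE))
  expect_false(attr(fs, "species_fixed"))
  expect_true(attr(fs, "present"))
  ## all carriers: species-wide fixation; none: absent
  all_fix <- fixation_survey(list(one = as.character(popA$sequences)),
                             mts, cps, template_boundary = tb)
  expect_true(attr(all_fix, "species_fixed"))
  none <- fixation_survey(list(two = as.character(popB$sequences)),
                          mts, cps, template_boundary = tb)
  expect_false(attr(none, "present"))
})
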