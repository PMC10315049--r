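test_that("per-base attribution matches the ledger on a full simulated trio", {
  sim <- shared_sim()
  panel <- reference_panel(sim$genomes, cp = sim$cp, nuclear = sim$nuclear,
                           external = sim$external,
                           external_meta = sim$external_meta)
  pair <- c("C", "D")
  A <- sim$genomes$C; B <- sim$genomes$D
  blocks <- build_blocks(local_search(A, B$seq, circular_subject = TRUE))
  nar <- nonalignable_regions(A, B, blocks, pair_label = "CD")
  expected <- ledger_expected_origins(sim, pair)
  expect_setequal(unique(expected$expected),
                  c("GL", "ID", "CP", "PH", "NU"))
  correct <- 0; total <- 0
  for (side in pair) {
    regs <- nar[[side]]
    calls <- classify_regions(regs, panel, pair)
    for (cl in calls) {
      expect_equal(sum(cl$bp), cl$length)   # exact conservation
    }
    exp_side <- expected[expected$genome == side, ]
    for (i in seq_len(nrow(exp_side))) {
      e <- exp_side[i, ]
      total <- total + (e$end - e$start + 1)
      for (cl in calls) {
        ev <- cl$evidence[cl$evidence$category == e$expected, , drop = FALSE]
        if (nrow(ev))
          correct <- correct +
            sum(pmax(0, pmin(ev$end, e$end) - pmax(ev$start, e$start) + 1))
      }
    }
  }
  expect_gte(correct / total, 0.9)
})

test_that("a region with no hits anywhere is fully ND", {
  set.seed(30)
  junk <- rand_dna(600)
  A <- annotated_genome("A", paste0(rand_dna(2000), junk, rand_dna(2000)),
                        "linear")
  B <- annotated_genome("B", rand_dna(4000), "linear")
  C <- annotated_genome("C", rand_dna(4000), "linear")
  panel <- reference_panel(list(A = A, B = B, C = C))
  reg <- data.frame(code = "ABA1", genome = "A", start = 2001, end = 2600)
  call <- classify_region(reg, panel, c("A", "B"))
  expect_equal(unname(call$bp["ND"]), 600)
  expect_error(
    classify_region(data.frame(code = "x", genome = "A", start = 4800,
                               end = 5200), panel, c("A", "B")),
    "not extractable")
})

test_that("removing the external collection moves PH into ND only", {
  sim <- shared_sim()
  panel_full <- reference_panel(sim$genomes, cp = sim$cp,
                                nuclear = sim$nuclear,
                                external = sim$external,
                                external_meta = sim$external_meta)
  panel_noext <- reference_panel(sim$genomes, cp = sim$cp,
                                 nuclear = sim$nuclear)
  ev <- sim$ledger$events
  hdt <- ev[ev$genome == "D" & ev$kind == "hdt", ][1, ]
  reg <- data.frame(code = "CDD1", genome = "D", start = hdt$start,
                    end = hdt$end)
  full <- classify_region(reg, panel_full, c("C", "D"))
  noext <- classify_region(reg, panel_noext, c("C", "D"))
  expect_gt(full$bp[["PH"]], 0.9 * full$length)
  expect_equal(noext$bp[["PH"]], 0L)
  expect_equal(noext$bp[["ND"]] - full$bp[["ND"]], full$bp[["PH"]])
  expect_equal(noext$bp[["CP"]], full$bp[["CP"]])
  expect_equal(noext$bp[["GL"]], full$bp[["GL"]])
})

test_that("pair summaries format per-category accounting and reject mixed pairs", {
  sim <- shared_sim()
  panel <- reference_panel(sim$genomes, cp = sim$cp,
                           nuclear = sim$nuclear,
                           external = sim$external,
                           external_meta = sim$external_meta)
  ev <- sim$ledger$events
  gain <- ev[ev$genome == "C" & ev$kind == "gain", ][1, ]
  reg <- data.frame(code = "CDC1", genome = "C", start = gain$start,
                    end = gain$end)
  call <- classify_region(reg, panel, c("C", "D"))
  summ <- summarize_pair(list(call))
  expect_match(summ$table$GL[1], "bp \\(100\\.00%\\)")
  expect_match(summ$table$total[1], "bp \\(100%\\)")
  expect_equal(sum(summ$long$bp), call$length)
  other <- call; other$pair <- "C-S"
  expect_error(summarize_pair(list(call, other)), "mixed")
})

test_that("parsimony polarity equals the exhaustive oracle on all 8 patterns", {
  pats <- expand.grid(C = c(TRUE, FALSE), S = c(TRUE, FALSE),
                      D = c(TRUE, FALSE))
  for (i in seq_len(nrow(pats))) {
    p <- unlist(pats[i, ])
    got <- parsimony_polarity(p)
    want <- parsimony_oracle(p)
    expect_equal(got$call, want$call, info = paste(p, collapse = ","))
    expect_equal(got$events, want$events, info = paste(p, collapse = ","))
    if (got$call %in% c("gain_in", "loss_in"))
      expect_equal(got$where, want$where)
  }
})
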