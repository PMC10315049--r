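test_that("degenerate configuration yields three identical genomes and an empty ledger", {
  cfg <- sim_config(seed = 3, event_counts = c(),
                    branch_lengths = c(C = 0, S = 0, CS = 0, D = 0),
                    indel_rate = 0)
  s <- simulate_genomes(cfg)
  expect_identical(s$genomes$C$seq, s$genomes$S$seq)
  expect_identical(s$genomes$C$seq, s$genomes$D$seq)
  expect_equal(nrow(s$ledger$events), 0)
  expect_equal(nrow(s$ledger$substitutions), 0)
})

test_that("same seed reproduces byte-identical FASTA and ledger", {
  s1 <- simulate_genomes(sim_config(seed = 9))
  s2 <- simulate_genomes(sim_config(seed = 9))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("ledger intervals return the planted sequence up to planted substitutions", {
  sim <- shared_sim()
  ev <- sim$ledger$events
  led <- sim$ledger$substitutions
  ins <- ev[!ev$deleted & !is.na(ev$inserted_seq), ]
  expect_gt(nrow(ins), 5)
  for (i in seq_len(nrow(ins))) {
    g <- sim$genomes[[ins$genome[i]]]
    got <- substr(g$seq, ins$start[i], ins$end[i])
    exp <- ins$inserted_seq[i]
    if (ins$strand[i] == "-")
      exp <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(exp)))
    expect_equal(nchar(got), nchar(exp), info = ins$event_id[i])
    n_diff <- sum(strsplit(got, "")[[1]] != strsplit(exp, "")[[1]])
    n_subs <- sum(led$genome == ins$genome[i] & led$pos >= ins$start[i] &
                    led$pos <= ins$end[i])
    expect_lte(n_diff, n_subs)
  }
})

test_that("planted ancestral transfer is recoverable from all three genomes", {
  sim <- shared_sim()
  ev <- sim$ledger$events
  host <- ev[ev$kind == "idt_ancestral", ]
  expect_setequal(host$genome, c("C", "S", "D"))
  for (i in seq_len(nrow(host))) {
    seg <- substr(sim$genomes[[host$genome[i]]]$seq, host$start[i],
                  host$end[i])
    h <- local_search(seg, sim$cp$seq)
    expect_gt(nrow(h), 0)
    expect_gte(max(h$identity), 0.85)
    expect_gte(max(h$length), 0.9 * nchar(seg))
  }
})

test_that("structural-event and substitution clocks scale as configured", {
  ## long branches, no structural events: observed distance tracks 2t and
  ## coding sites are slower by the configured factor
  cfg <- sim_config(seed = 21, mt_ancestor_len = 30000, event_counts = c(),
                    indel_rate = 0,
                    branch_lengths = c(C = 0.01, S = 0.01, CS = 0, D = 0),
                    rotate = FALSE)
  s <- simulate_genomes(cfg)
  vC <- strsplit(s$genomes$C$seq, "")[[1]]
  vS <- strsplit(s$genomes$S$seq, "")[[1]]
  cds <- s$genomes$C$features
  coding <- rep(FALSE, length(vC))
  for (i in which(cds$type == "CDS")) coding[cds$start[i]:cds$end[i]] <- TRUE
  p_nc <- mean(vC[!coding] != vS[!coding])
  p_cd <- mean(vC[coding] != vS[coding])
  t2 <- 2 * 0.01
  se <- sqrt(t2 * (1 - t2) / sum(!coding))
  expect_lt(abs(p_nc - t2), 3 * se + t2^2)      # small back-mutation slack
  expect_lt(abs(p_cd - t2 / 3), 4 * sqrt(t2 / 3 / sum(coding)) + t2^2)
})

test_that("population sampling honours the carrier fraction exactly", {
  sim <- shared_sim()
  expect_error(simulate_population(sim, 0), ">= 1")
  p0 <- simulate_population(sim, 10, carrier_fraction = 0)
  expect_equal(sum(p0$carrier), 0)
  p1 <- simulate_population(sim, 5, carrier_fraction = 1)
  expect_equal(sum(p1$carrier), 5)
  expect_equal(length(unique(as.character(p1$sequences))), 1)
  p13 <- simulate_population(sim, 15, carrier_fraction = 1 / 3)
  expect_equal(sum(p13$carrier), 5)
  ## carrier sequences are chloroplast-identical left of the breakpoint
  ## and mitochondrial right of it
  tmpl <- sim$ledger$recurrent
  cp_seg <- substr(sim$cp$seq, tmpl$donor_start, tmpl$donor_end)
  mt_seg <- substr(sim$genomes$C$seq, tmpl$region_start, tmpl$region_end)
  car <- as.character(p1$sequences[[1]])
  b <- p1$breakpoint
  expect_identical(substr(car, 1, b), substr(cp_seg, 1, b))
  expect_identical(substr(car, b + 1, nchar(car)),
                   substr(mt_seg, b + 1, nchar(mt_seg)))
})

test_that("error-free reads are exact circular substrings; labels are consistent", {
  sim <- shared_sim()
  g <- sim$genomes$C
  cfg <- sim_config(seed = 6, read_error_rate = 0,
                    recombinant_read_fraction = 0)
  rd <- simulate_long_reads(g, NULL, cfg, n_reads = 25)
  SS <- paste0(g$seq, g$seq)
  for (i in seq_len(25)) {
    r <- as.character(rd$reads[[i]])
    if (rd$truth$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    expect_true(grepl(r, SS, fixed = TRUE))
  }
})

test_that("read-length and repeat preconditions are enforced", {
  sim <- shared_sim()
  short_rp <- data.frame(start1 = 200, end1 = 280, start2 = 900, end2 = 980,
                         relation = "direct")
  expect_error(simulate_long_reads(sim$genomes$C, short_rp, sim$config),
               "> 100 bp")
  lin <- annotated_genome("lin", substr(sim$genomes$C$seq, 1, 3000),
                          "linear")
  edge_rp <- data.frame(start1 = 20, end1 = 220, start2 = 900, end2 = 1100,
                        relation = "direct")
  expect_error(simulate_long_reads(lin, edge_rp, sim$config),
               "sequence end")
})
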