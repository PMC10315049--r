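# reduced-scale trio so the end-to-end stages stay quick
pipe_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_genomes(small_sim_config(99))
    cache
  }
})

test_that("the pipeline runs end to end and its manifest is complete", {
  sim <- pipe_sim()
  out <- file.path(withr::local_tempdir(), "run1")
  cfg <- pipeline_config(mt = sim$genomes, cp = sim$cp,
                         nuclear = sim$nuclear, external = sim$external,
                         external_meta = sim$external_meta, outdir = out,
                         seed = 5, calibration_distance = 6.28e-2,
                         calibration_time = 88e6)
  res <- run_pipeline(cfg)
  expect_s3_class(res, "pipeline_result")
  expect_true(all(file.exists(file.path(out, res$manifest$file))))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  expect_equal(nrow(res$summary), 3)
  expect_true(all(res$summary$gc_pct > 30 & res$summary$gc_pct < 70))
  expect_true(!is.null(res$clock))
  expect_gt(res$distances$d_k2p_noncoding, 0)
  ## per-pair origin tables conserve region totals
  for (key in names(res$origin_tables)) {
    lg <- res$origin_tables[[key]]$long
    for (g in unique(lg$genome))
      expect_equal(sum(lg$pct[lg$genome == g]), 100, tolerance = 1e-6)
  }
  ## every output declares its coordinate convention or is JSON
  for (f in res$manifest$file) {
    if (grepl("\\.tsv$", f)) {
      first <- readLines(file.path(out, f), n = 3)
      expect_true(any(grepl("1-based inclusive", first)), info = f)
    }
  }
})

test_that("rerunning with the same seed reproduces identical checksums", {
  sim <- pipe_sim()
  out <- file.path(withr::local_tempdir(), "rerun")
  cfg <- pipeline_config(mt = sim$genomes, cp = sim$cp,
                         nuclear = sim$nuclear, external = sim$external,
                         external_meta = sim$external_meta, outdir = out,
                         seed = 5)
  m1 <- run_pipeline(cfg)$manifest
  m2 <- run_pipeline(cfg)$manifest
  expect_identical(m1, m2)
})

test_that("a missing chloroplast genome degrades gracefully and says so", {
  sim <- pipe_sim()
  out <- file.path(withr::local_tempdir(), "nocp")
  cfg <- pipeline_config(mt = sim$genomes, outdir = out, seed = 5)
  res <- run_pipeline(cfg)
  expect_true(any(grepl("CP arm disabled", res$notes)))
  expect_true(file.exists(file.path(out, "notes.txt")))
  expect_null(res$idt)
  ## classification still ran, with CP never assigned
  for (key in names(res$origin_tables)) {
    lg <- res$origin_tables[[key]]$long
    expect_equal(sum(lg$bp[lg$category == "CP"]), 0)
  }
})

test_that("pipeline inputs load from FASTA paths as well as objects", {
  sim <- pipe_sim()
  d <- withr::local_tempdir()
  paths <- list()
  for (g in names(sim$genomes)) {
    p <- file.path(d, paste0(g, ".fa"))
    write_fasta(sim$genomes[[g]], p)
    paths[[g]] <- p
  }
  g2 <- mitocomp:::.load_genome(paths$C, "C")
  expect_identical(g2$seq, sim$genomes$C$seq)
})

test_that("the command-line dispatcher wires subcommands to the functions", {
  expect_equal(mitocomp_cli(character()), 2L)
  expect_equal(mitocomp_cli("nonsense"), 2L)
  out <- capture.output(
    code <- mitocomp_cli(c("clock", "--query", "1.33e-3", "--cal-distance",
                           "6.28e-2", "--cal-time", "88e6")))
  expect_equal(code, 0L)
  expect_match(paste(out, collapse = ""), "1863")
  expect_equal(mitocomp_cli(c("clock", "--query", "1")), 2L)
  ## simulate subcommand writes a trio
  d <- file.path(withr::local_tempdir(), "simout")
  code <- suppressMessages(
    mitocomp_cli(c("simulate", "--outdir", d, "--seed", "3",
                   "--config", {
                     cfgp <- withr::local_tempfile(fileext = ".json")
                     jsonlite::write_json(
                       list(mt_ancestor_len = 8000, cp_len = 3000,
                            nuclear_len = 2000, foreign_len = 2000,
                            n_genes = 4, gene_len = 600,
                            event_counts = list(idt_ancestral = 1),
                            event_sizes = list(idt_ancestral = 800,
                                               recurrent_idt = 300)),
                       cfgp, auto_unbox = TRUE)
                     cfgp
                   })))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(d, "mt_C.fasta")))
  expect_true(file.exists(file.path(d, "ledger.json")))
  gff <- read_gff3(file.path(d, "mt_C.gff3"))
  expect_true(any(gff$type == "idt_ancestral"))
})
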