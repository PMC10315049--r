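#' Pipeline configuration
#'
#' Collects inputs, thresholds and convention flags for [run_pipeline()].
#' Every run writes the resolved configuration and seed beside its
#' outputs, and the configuration serialises to JSON losslessly.
#'
#' @param mt named list of three mitogenomes: `annotated_genome` objects
#'   or FASTA paths
#' @param cp chloroplast genome (`annotated_genome` or path), or NULL to
#'   run with the CP arm disabled
#' @param nuclear nuclear genome, or NULL
#' @param external external mitochondrial collection (`DNAStringSet` or
#'   path), or NULL
#' @param external_meta data.frame (`id`, `taxon`, `relatedness`) for
#'   `external`
#' @param outdir output directory
#' @param seed seed for any stochastic step (bootstrap)
#' @param min_identity,min_len local-search thresholds
#' @param repeat_min minimal repeat size
#' @param assay_flank recombination assay flank (bp)
#' @param min_region_len,merge_slack non-alignable region extraction
#' @param max_gap anchor-chaining gap limit
#' @param bootstrap bootstrap replicates for partition trees
#' @param remove_ir drop one chloroplast IR copy before transfer search
#' @param per_lineage report clock rates per lineage (distance / 2T)
#' @param calibration_distance,calibration_time optional molecular-clock
#'   calibration (substitutions/site, years)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(mt, cp = NULL, nuclear = NULL, external = NULL,
                            external_meta = NULL, outdir = "mitocomp_out",
                            seed = 1L, min_identity = 0.85, min_len = 90,
                            repeat_min = 30, assay_flank = 100,
                            min_region_len = 90, merge_slack = 50,
                            max_gap = 1000, bootstrap = 1000,
                            remove_ir = TRUE, per_lineage = FALSE,
                            calibration_distance = NULL,
                            calibration_time = NULL) {
  stopifnot(length(mt) == 3, !is.null(names(mt)))
  structure(list(mt = mt, cp = cp, nuclear = nuclear, external = external,
                 external_meta = external_meta, outdir = outdir,
                 seed = as.integer(seed), min_identity = min_identity,
                 min_len = min_len, repeat_min = repeat_min,
                 assay_flank = assay_flank,
                 min_region_len = min_region_len,
                 merge_slack = merge_slack, max_gap = max_gap,
                 bootstrap = bootstrap, remove_ir = remove_ir,
                 per_lineage = per_lineage,
                 calibration_distance = calibration_distance,
                 calibration_time = calibration_time),
            class = "pipeline_config")
}

.load_genome <- function(x, id) {
  if (is(x, "annotated_genome")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- read_fasta(x)
    return(annotated_genome(id, as.character(ss[[1]]), "circular"))
  }
  annotated_genome(id, x, "circular")
}

#' Run the comparative mitogenome pipeline
#'
#' Executes the full analysis on a trio of mitogenomes: chloroplast
#' transfer detection, pairwise comparison (blocks, inversions,
#' non-alignable regions), per-base origin classification with a per-pair
#' accounting table, dispersed-repeat census, substitution/indel
#' tabulation with noncoding Kimura two-parameter distance between the
#' first two genomes, and calibrated clock dating when a calibration is
#' supplied. All outputs are plain text with declared coordinate
#' conventions; a manifest lists every file with its checksum. Rerunning
#' with the same inputs and seed reproduces identical checksums.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result`: `summary` (per-genome table),
#'   `pairs`, `origin_tables`, `distances`, `clock`, `manifest`,
#'   `outdir`, `notes`
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  set.seed(config$seed)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mts <- stage("load", {
    out <- list()
    for (id in names(config$mt)) out[[id]] <- .load_genome(config$mt[[id]], id)
    out
  })
  cp <- if (!is.null(config$cp)) .load_genome(config$cp, "cp") else NULL
  nuclear <- if (!is.null(config$nuclear))
    .load_genome(config$nuclear, "nuclear") else NULL
  external <- config$external
  if (is.character(external) && length(external) == 1 &&
      file.exists(external)) external <- read_fasta(external)
  ids <- names(mts)
  files <- character()
  emit <- function(path) files <<- c(files, path)

  ## transfer detection
  idt <- NULL
  if (!is.null(cp)) {
    idt <- stage("idt", lapply(mts, function(g)
      detect_idt(g, cp, min_identity = config$min_identity,
                 min_len = config$min_len, remove_ir = config$remove_ir)))
    for (id in ids) {
      p <- file.path(outdir, paste0("idt_links_", id, ".tsv"))
      export_links(idt[[id]], p); emit(p)
      gp <- file.path(outdir, paste0("idt_genes_", id, ".tsv"))
      write_tsv(idt[[id]]$genes, gp,
                comments = "transferred gene copies and status"); emit(gp)
    }
    sj <- file.path(outdir, "idt_summary.json")
    jsonlite::write_json(lapply(idt, function(s)
      list(total_bp = s$total_bp, fraction = s$fraction,
           n_regions = nrow(s$regions), n_intact = s$n_intact,
           n_pseudo = s$n_pseudo)), sj, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    emit(sj)
  } else {
    notes <- c(notes,
               "no chloroplast genome supplied: CP arm disabled, transfer stage skipped")
  }

  ## pairwise comparison + classification
  pair_list <- list(ids[c(1, 2)], ids[c(1, 3)], ids[c(2, 3)])
  panel <- reference_panel(mts, cp = cp, nuclear = nuclear,
                           external = external,
                           external_meta = config$external_meta)
  pairs <- list(); origin_tables <- list()
  for (pr in pair_list) {
    key <- paste(pr, collapse = "-")
    res <- stage(paste0("compare:", key), {
      A <- mts[[pr[1]]]; B <- mts[[pr[2]]]
      hits <- local_search(A, B$seq, min_identity = config$min_identity,
                           min_hit_len = config$min_len,
                           circular_subject = TRUE)
      blocks <- build_blocks(hits, max_gap = config$max_gap)
      nar <- nonalignable_regions(A, B, blocks,
                                  min_region_len = config$min_region_len,
                                  merge_slack = config$merge_slack,
                                  pair_label = paste0(pr[1], pr[2]))
      inv <- detect_inversions(blocks)
      list(hits = hits, blocks = blocks, regions = nar, inversions = inv)
    })
    bp <- file.path(outdir, paste0("blocks_", key, ".tsv"))
    write_tsv(as.data.frame(res$blocks), bp,
              comments = paste("collinear blocks", key)); emit(bp)
    ip <- file.path(outdir, paste0("inversions_", key, ".tsv"))
    write_tsv(res$inversions, ip, comments = paste("inversions", key))
    emit(ip)
    rp <- file.path(outdir, paste0("regions_", key, ".tsv"))
    write_tsv(do.call(rbind, res$regions), rp,
              comments = paste("non-alignable regions", key)); emit(rp)
    calls <- stage(paste0("classify:", key), {
      out <- list()
      for (side in pr) {
        regs <- res$regions[[side]]
        if (nrow(regs))
          out <- c(out, classify_regions(regs, panel, pr,
                                         min_identity = config$min_identity,
                                         min_len = config$min_len))
      }
      out
    })
    if (length(calls)) {
      summ <- summarize_pair(calls)
      tp <- file.path(outdir, paste0("origins_", key, ".tsv"))
      write_tsv(summ$table, tp,
                comments = c(paste("inferred origins", key),
                             "cells: N bp (percent of total non-alignable bp)"))
      emit(tp)
      lp <- file.path(outdir, paste0("origins_long_", key, ".tsv"))
      write_tsv(summ$long, lp, comments = "machine-readable origins")
      emit(lp)
      origin_tables[[key]] <- summ
    }
    pairs[[key]] <- res
  }

  ## repeats and per-genome summary
  reps <- stage("repeats", lapply(mts, find_repeats,
                                  min_len = config$repeat_min))
  summary_df <- data.frame(
    genome = ids,
    size_bp = vapply(mts, function(g) nchar(g$seq), 0),
    gc_pct = vapply(mts, function(g) round(100 * gc_content(g$seq), 2), 0),
    repeat_units = vapply(reps, function(r) as.integer(r$n_units), 0L),
    largest_repeat = vapply(reps, function(r) as.integer(r$largest), 0L),
    repeat_content_pct = vapply(reps, function(r)
      round(100 * r$content, 2), 0),
    cp_derived_pct = if (!is.null(idt))
      vapply(idt, function(s) round(100 * s$fraction, 2), 0) else NA)
  sp <- file.path(outdir, "genome_summary.tsv")
  write_tsv(summary_df, sp, comments = "per-genome summary"); emit(sp)
  for (id in ids) {
    rp <- file.path(outdir, paste0("repeats_", id, ".tsv"))
    export_repeats(reps[[id]], rp); emit(rp)
  }

  ## divergence between the first two genomes, third as outgroup
  key12 <- paste(ids[1:2], collapse = "-")
  distances <- stage("divergence", {
    td <- tabulate_differences(pairs[[key12]]$blocks, mts[[1]])
    subs <- td$substitutions
    nc <- subs[subs$context != "CDS", , drop = FALSE]
    h12 <- pairs[[key12]]$hits
    cov <- IRanges::reduce(IRanges::IRanges(h12$qstart, h12$qend))
    cds1 <- mts[[1]]$features
    cds1 <- cds1[cds1$type == "CDS", , drop = FALSE]
    coding_cov <- if (nrow(cds1))
      sum(IRanges::width(IRanges::intersect(cov, as_iranges(cds1)))) else 0L
    aligned <- sum(IRanges::width(cov))
    nc_aligned <- aligned - coding_cov
    P <- sum(nc$class == "transition") / nc_aligned
    Q <- sum(nc$class == "transversion") / nc_aligned
    list(pair = key12, n_substitutions = nrow(subs),
         n_transitions = sum(subs$class == "transition"),
         n_transversions = sum(subs$class == "transversion"),
         n_indels = nrow(td$indels),
         indel_size_range = if (nrow(td$indels))
           range(td$indels$length) else c(NA, NA),
         aligned_bp = aligned, noncoding_aligned_bp = nc_aligned,
         P = P, Q = Q,
         d_k2p_noncoding = k2p_distance(P, Q),
         tabulated = td)
  })
  dj <- file.path(outdir, "distances.json")
  jsonlite::write_json(distances[setdiff(names(distances), "tabulated")],
                       dj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(dj)

  clock_out <- NULL
  if (!is.null(config$calibration_distance) &&
      !is.null(config$calibration_time)) {
    clock_out <- stage("clock", clock(distances$d_k2p_noncoding,
                                      config$calibration_distance,
                                      config$calibration_time,
                                      per_lineage = config$per_lineage))
    cj <- file.path(outdir, "clock.json")
    jsonlite::write_json(clock_out, cj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    emit(cj)
  }

  ## resolved config + manifest
  cfgj <- file.path(outdir, "config.json")
  cfg_ser <- config
  cfg_ser$mt <- lapply(cfg_ser$mt, function(x)
    if (is.character(x)) x else paste0("<in-memory:", x$id, ">"))
  for (f in c("cp", "nuclear", "external")) {
    if (!is.null(cfg_ser[[f]]) && !is.character(cfg_ser[[f]]))
      cfg_ser[[f]] <- "<in-memory>"
  }
  jsonlite::write_json(unclass(cfg_ser), cfgj, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  emit(cfgj)
  if (length(notes)) {
    np <- file.path(outdir, "notes.txt")
    writeLines(notes, np); emit(np)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  mp <- file.path(outdir, "manifest.tsv")
  write_tsv(manifest, mp, comments = "output manifest (md5 checksums)")

  structure(list(summary = summary_df, pairs = pairs,
                 origin_tables = origin_tables, distances = distances,
                 clock = clock_out, idt = idt, repeats = reps,
                 manifest = manifest, outdir = outdir, notes = notes),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> outputs in", x$outdir, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("noncoding K2P distance (%s): %.4g over %d aligned bp\n",
              x$distances$pair, x$distances$d_k2p_noncoding,
              x$distances$aligned_bp))
  if (!is.null(x$clock))
    cat(sprintf("clock: rate %.4g /site/yr, time %.4g yr\n",
                x$clock$rate, x$clock$time))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Align sequences with MAFFT
#'
#' Thin wrapper over the `mafft` binary for the multiple alignments used
#' by the chimera scan on real (indel-bearing) regions.
#'
#' @param seqs named character vector or `DNAStringSet`
#' @return `DNAStringSet` of aligned sequences (equal width)
#' @export
align_mafft <- function(seqs) {
  inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inf, outf)))
  write_fasta(seqs, inf)
  system2(find_tool("mafft"), c("--auto", "--quiet", inf),
          stdout = outf, stderr = FALSE)
  toupper_set <- Biostrings::readBStringSet(outf)
  Biostrings::DNAStringSet(toupper(as.character(toupper_set)))
}
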