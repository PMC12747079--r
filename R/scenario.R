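# A single YAML scenario declares a full synthetic dataset (host genome with
# implanted elements, a giant-virus-like reference with a coverage island, a
# survey table, growth replicates). run_scenario() generates the data,
# writes the files, runs the whole analysis chain and returns results next
# to the truth, so the pipeline is exercised end to end with no download.

#' Read a scenario description from YAML
#'
#' @param path YAML file path.
#' @return The scenario as a nested list.
#' @export
read_scenario <- function(path) {
  yaml::read_yaml(path)
}

scenario_host <- function(sc, seed) {
  h <- sc$host
  gen_host_genome(
    n_contigs = h$n_contigs,
    length_range = unlist(h$length_range),
    gc = h$gc %||% 0.52,
    telomere_motif = h$telomere_motif %||% "TTAGGG",
    end_plan = unlist(h$end_plan),
    seed = seed)
}

scenario_implants <- function(sg, sc, seed) {
  for (i in seq_along(sc$eves)) {
    e <- sc$eves[[i]]
    spec <- element_spec(
      length = e$length, gc = e$gc %||% 0.35,
      repeat_kind = e$repeat_kind %||% "TIR",
      repeat_len = e$repeat_len %||% 488L,
      tsd_len = e$tsd_len %||% 0L,
      anchor_peptides = unlist(e$anchors %||% "MAGWNDKTHQLV"),
      anchor_strand = e$anchor_strand %||% "+")
    sg <- implant_eve(sg, e$contig, e$pos, spec, seed = seed + i)
  }
  sg
}

#' Run a full synthetic scenario end to end
#'
#' Generates every dataset the scenario declares, optionally writes them to
#' `outdir` (FASTA, GFF3 truth, alignment TSV + SAM, survey and growth
#' TSV), then runs the analysis chain: element calling and classification,
#' telomere scan and chromosome accounting, assembly statistics, read
#' recruitment with island detection, survey summary and correlation
#' screen, growth fits and collapse detection.
#'
#' @param scenario A YAML path or scenario list (see
#'   `system.file("extdata", "scenario-demo.yaml", package = "evekit")`).
#' @param seed Integer master seed; every generator derives from it.
#' @param outdir Optional output directory for the generated files.
#' @return A list of class `scenario_run` with `truth`, `data` and
#'   `results` components.
#' @export
run_scenario <- function(scenario, seed = 1L, outdir = NULL) {
  sc <- if (is.character(scenario)) read_scenario(scenario) else scenario
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  truth <- list(); data <- list(); results <- list()

  # --- host genome with implanted elements ---------------------------------
  if (!is.null(sc$host)) {
    sg <- scenario_host(sc, seed)
    if (!is.null(sc$eves)) sg <- scenario_implants(sg, sc, seed)
    data$genome <- sg$genome
    truth$telomeres <- sg$truth$telomeres
    truth$eves <- sg$truth$eves
    if (!is.null(outdir)) {
      write_fasta(sg$genome, file.path(outdir, "host_genome.fasta"))
      write_truth_gff3(sg, file.path(outdir, "truth_elements.gff3"))
    }
    peptides <- unique(unlist(lapply(sc$eves, function(e) {
      unlist(e$anchors %||% "MAGWNDKTHQLV")
    })))
    ep <- do.call(eve_params, sc$eve_params %||% list())
    calls <- call_eves(sg, anchors = peptides, params = ep)
    if (!is.null(sc$eves) && nrow(calls)) {
      intg <- vapply(sc$eves, function(e) e$integrase %||% "rve-INT",
                     character(1))
      key <- vapply(sc$eves, function(e) e$contig, character(1))
      ann <- tibble(contig_id = truth$eves$contig_id,
                    start = truth$eves$start + 1L,
                    integrase = intg[match(truth$eves$contig_id, key)])
      calls <- suppressWarnings(classify_eves(calls, ann))
    }
    results$eve_calls <- calls
    results$eve_summary <- summarize_eves(calls)
    results$telomeres <- scan_telomeres(
      sg, motif = sc$host$telomere_motif %||% "TTAGGG")
    tel_counts <- table(factor(results$telomeres$status,
                               c("both", "one", "none")))
    results$min_chromosomes <- min_chromosomes(tel_counts[["both"]],
                                               tel_counts[["one"]])
    results$asm_stats <- asm_stats(sg)
  }

  # --- giant-virus-like reference with a coverage island -------------------
  if (!is.null(sc$gv)) {
    gv <- sc$gv
    set.seed(seed + 1000L)
    ref_len <- as.integer(gv$length)
    ref <- Biostrings::DNAStringSet(random_dna(ref_len, gv$gc %||% 0.3))
    names(ref) <- gv$name %||% "GV1"
    island <- tibble(start = as.integer(gv$island[[1]]),
                     end = as.integer(gv$island[[2]]))
    aln <- gen_alignments(ref, n_reads = gv$n_reads, read_len = gv$read_len,
                          excluded = island, seed = seed + 1001L)
    truth$islands <- island
    data$gv_reference <- ref
    data$alignments <- aln
    if (!is.null(outdir)) {
      write_fasta(ref, file.path(outdir, "gv_reference.fasta"))
      write_alignment_tsv(aln, file.path(outdir, "gv_alignments.tsv"))
      write_sam(aln, setNames(ref_len, names(ref)),
                file.path(outdir, "gv_alignments.sam"))
    }
    track <- coverage_track(aln, ref_len, bin = gv$bin %||% 100L)
    results$coverage <- track
    results$recruitment <- recruit(ref, aln,
                                   library_size = gv$library_size %||% 1e6)
    results$islands <- detect_islands(track,
                                      max_depth = gv$max_depth %||% 0,
                                      min_len = gv$island_min_len %||% 5000L)
    if (!is.null(outdir) && nrow(results$islands)) {
      write_islands_bed(results$islands, names(ref),
                        file.path(outdir, "gv_islands.bed"))
    }
  }

  # --- survey table --------------------------------------------------------
  if (!is.null(sc$survey)) {
    sv <- sc$survey
    samples <- gen_survey(
      n_samples = sv$n_samples %||% 263L,
      hnf_mean = sv$hnf_mean %||% 1500,
      cry1a_beta = unlist(sv$cry1a_beta %||% c(0.73, 3.69)),
      seed = seed + 2000L)
    data$survey <- samples
    if (!is.null(outdir)) {
      readr::write_tsv(samples, file.path(outdir, "survey.tsv"))
    }
    results$survey_summary <- summarize_survey(samples)
    results$correlation_screen <- correlation_screen(
      samples, threshold = sv$threshold %||% 0.5)
  }

  # --- growth replicates ---------------------------------------------------
  if (!is.null(sc$growth)) {
    gw <- sc$growth
    reps <- list()
    for (i in seq_len(gw$replicates %||% 3L)) {
      coll <- if (!is.null(gw$collapse_replicates) &&
                  i %in% unlist(gw$collapse_replicates)) {
        list(t = gw$t_collapse %||% 480, frac = gw$collapse_frac %||% 0.8)
      } else {
        list(t = Inf, frac = 0)
      }
      reps[[i]] <- gen_growth(
        inoculum = gw$inoculum %||% 200, lag = gw$lag %||% 168,
        mu = gw$mu %||% (log(2) / 29),
        t_collapse = coll$t, collapse_frac = coll$frac,
        cv = gw$cv %||% 0.1,
        timepoints = unlist(gw$timepoints %||% seq(0, 600, by = 24)),
        replicate_id = sprintf("rep%d", i), seed = seed + 3000L + i)
    }
    growth <- bind_rows(reps)
    truth$growth_params <- list(mu = gw$mu %||% (log(2) / 29),
                                lag = gw$lag %||% 168,
                                t_collapse = gw$t_collapse %||% NA,
                                collapse_frac = gw$collapse_frac %||% 0)
    data$growth <- growth
    if (!is.null(outdir)) {
      readr::write_tsv(growth, file.path(outdir, "growth.tsv"))
    }
    results$growth_fits <- fit_growth_curves(growth)
    results$collapses <- map_dfr(split(growth, growth$replicate_id),
                                 function(d) {
      ev <- detect_collapse(d)
      if (nrow(ev)) ev$replicate_id <- d$replicate_id[1]
      ev
    })
  }

  structure(list(truth = truth, data = data, results = results,
                 scenario = sc, seed = seed),
            class = "scenario_run")
}
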