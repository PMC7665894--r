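#' Orchestrate the full synthetic analysis from one YAML config
#'
#' Runs the configured stages in dependency order — simulate, arrays,
#' assign, occupancy, conjugation, boxa, assays — writing each stage's
#' outputs under `out_dir` and returning a manifest with parameters,
#' derived seeds, and md5 hashes of every written file.  Rerunning with
#' the same config reproduces the outputs bit-for-bit.
#'
#' @param config path to a YAML file, or an equivalent named list.
#'   Recognized top-level fields: `seed` (master seed), `out_dir`,
#'   `stages` (character subset of the stage names above), plus optional
#'   per-stage parameter blocks (`simulate`, `assign`, `conjugation`,
#'   `boxa`).
#' @param out_dir output directory (overrides the config field).
#' @return manifest list: `config`, `stages` (per stage: status and
#'   output files), `hashes` (md5 per file).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% stop_input("out_dir required")
  stages <- config$stages %||% c("simulate", "arrays", "assign",
                                 "occupancy", "conjugation", "boxa",
                                 "assays")
  known <- c("simulate", "arrays", "assign", "occupancy", "conjugation",
             "boxa", "assays")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_input("unknown stage(s): %s",
                              paste(bad, collapse = ", "))
  for (f in c(config$inputs %||% character(0)))
    if (!file.exists(f)) stop_input("input file missing: %s", f)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list())
  files <- character(0)
  done <- function(stage, out) {
    manifest$stages[[stage]] <<- list(status = "ok", files = out)
    files <<- c(files, out)
  }

  sim <- NULL; tracks <- NULL; peaks <- NULL
  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(list(seed = seed),
                                config$simulate %||% list()))
    sim <- make_crispr_genome(sc)
    f1 <- file.path(out_dir, "genome.fa")
    write_fasta(c(chr = sim$genome), f1)
    f2 <- file.path(out_dir, "sites.tsv")
    write_tsv(sim$sites, f2)
    f3 <- file.path(out_dir, "spacers.tsv")
    write_tsv(sim$spacers, f3)
    done("simulate", c(f1, f2, f3))
  }
  if ("arrays" %in% stages) {
    if (is.null(sim)) stop_input("stage 'arrays' needs stage 'simulate'")
    rows <- do.call(rbind, lapply(sim$arrays, function(a)
      data.frame(array_id = a$array_id, chrom = "chr", strand = a$strand,
                 repeat_seq = a$repeat_seq,
                 spacer_index = a$spacers$index,
                 spacer_seq = a$spacers$seq,
                 start = a$spacers$start, end = a$spacers$end)))
    f <- file.path(out_dir, "arrays.tsv")
    write_tsv(rows, f)
    done("arrays", f)
  }
  if ("assign" %in% stages) {
    if (is.null(sim)) stop_input("stage 'assign' needs stage 'simulate'")
    regions <- build_regions(sim$sites$center,
                             width = config$assign$width %||% 101L,
                             contig_length = nchar(sim$genome))
    peaks <- assign_peaks(regions, sim$genome, sim$spacers)
    f <- file.path(out_dir, "assignments.tsv")
    write_tsv(peaks, f)
    done("assign", f)
  }
  if ("occupancy" %in% stages) {
    if (is.null(peaks)) stop_input("stage 'occupancy' needs stage 'assign'")
    n_sp <- vapply(sim$arrays, function(a) nrow(a$spacers), 0L)
    rho <- config$occupancy$rho %||% 0.05
    ab <- unlist(lapply(names(sim$arrays), function(id) {
      m <- termination_model(rep(rho, n_sp[[id]]))
      stats::setNames(simulate_crrna_abundance(m),
                      paste0(id, ":", seq_len(n_sp[[id]])))
    }))
    tracks <- list(
      rep1 = simulate_chip_coverage(sim, ab, seed = seed),
      rep2 = simulate_chip_coverage(sim, ab, seed = seed + 1L))
    occ <- occupancy_matrix(peaks$center, tracks)
    occ[, 2L] <- scale_replicates(occ[, 1L], occ[, 2L])$scaled
    f1 <- file.path(out_dir, "coverage_rep1_fwd.bedgraph")
    write_bedgraph(tracks$rep1$fwd, f1)
    f2 <- file.path(out_dir, "coverage_rep1_rev.bedgraph")
    write_bedgraph(tracks$rep1$rev, f2)
    f3 <- file.path(out_dir, "occupancy.tsv")
    write_tsv(cbind(peaks[, c("start", "end", "center", "status")],
                    as.data.frame(occ)), f3)
    done("occupancy", c(f1, f2, f3))
  }
  if ("conjugation" %in% stages) {
    n_ps <- config$conjugation$n_protospacers %||% 12L
    set.seed(derive_seed(seed, 10L))
    eff <- stats::setNames(stats::runif(n_ps),
                           sprintf("ps%02d", seq_len(n_ps)))
    cnt <- simulate_conjugation_counts(
      eff, depth = config$conjugation$depth %||% 1e5, seed = seed)
    flt <- filter_low(cnt)
    effout <- normalize_efficiency(flt$counts)
    f1 <- file.path(out_dir, "conjugation_counts.tsv")
    write_tsv(cnt, f1)
    f2 <- file.path(out_dir, "conjugation_efficiency.tsv")
    write_tsv(effout, f2)
    done("conjugation", c(f1, f2))
  }
  if ("boxa" %in% stages) {
    flanks <- make_cas2_flank_set(
      n = config$boxa$n %||% 60L,
      planting_fraction = config$boxa$planting_fraction %||% 0.3,
      seed = seed)
    scr <- screen_boxa(flanks, n_starts = config$boxa$n_starts %||% 8L,
                       seed = seed)
    f1 <- file.path(out_dir, "boxa_report.tsv")
    write_tsv(scr$report, f1)
    f2 <- file.path(out_dir, "boxa_motif.meme")
    write_meme(scr$model, f2)
    done("boxa", c(f1, f2))
  }
  if ("assays" %in% stages) {
    demo <- data.frame(sample = c("wt", "boxAmut"),
                       a420 = c(0.5, 0.25), a600 = c(0.5, 0.5),
                       time_min = c(10, 10), volume_ml = c(0.1, 0.1))
    demo$miller_units <- miller_units(demo$a420, demo$a600, demo$time_min,
                                      demo$volume_ml)
    f <- file.path(out_dir, "assays.tsv")
    write_tsv(demo, f)
    done("assays", f)
  }
  manifest$hashes <- as.list(tools::md5sum(files))
  f <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = seed, stages = names(manifest$stages),
                        hashes = manifest$hashes), f)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
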