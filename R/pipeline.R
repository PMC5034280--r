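#' Assemble and validate an end-to-end run configuration
#'
#' One mandatory seed governs every stage; per-stage sub-seeds are derived
#' deterministically from it. Unknown parameters are rejected.
#'
#' @param sim a \code{\link{sim_config}} describing the synthetic
#'   experiment (carries the seed).
#' @param bandwidth Gaussian smoothing sd for the occupancy track, bp.
#' @param normalization track normalization mode.
#' @param min_spacing,min_height nucleosome caller parameters.
#' @param rescue_bp +1 assignment rescue window, bp.
#' @param pseudocount ratio pseudocount.
#' @param fold_log2 significance fold filter (|log2 ratio| threshold).
#' @param q_max q-value ceiling for significance calls; must lie in (0, 1].
#' @param decile_fraction high/low occupancy class size.
#' @param qpcr_replicates,qpcr_noise_sd synthetic Ct table settings.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim, bandwidth = 20, normalization = "genome_mean_one",
                       min_spacing = 147L, min_height = 0.25,
                       rescue_bp = 200L, pseudocount = 0.5,
                       fold_log2 = 1.0, q_max = 1e-30,
                       decile_fraction = 0.1,
                       qpcr_replicates = 3, qpcr_noise_sd = 0.15) {
  cfg <- list(sim = sim, bandwidth = bandwidth, normalization = normalization,
              min_spacing = as.integer(min_spacing), min_height = min_height,
              rescue_bp = as.integer(rescue_bp), pseudocount = pseudocount,
              fold_log2 = fold_log2, q_max = q_max,
              decile_fraction = decile_fraction,
              qpcr_replicates = as.integer(qpcr_replicates),
              qpcr_noise_sd = qpcr_noise_sd)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg$sim, "sim_config"))
    stop_config("run_config: 'sim' must be a sim_config")
  if (cfg$bandwidth <= 0) stop_config("run_config: 'bandwidth' must be > 0")
  if (!cfg$normalization %in% c("genome_mean_one", "per_million"))
    stop_config("run_config: unknown normalization '%s'", cfg$normalization)
  if (cfg$min_spacing <= 0) stop_config("run_config: 'min_spacing' must be > 0")
  if (cfg$min_height < 0) stop_config("run_config: 'min_height' must be >= 0")
  if (cfg$q_max <= 0 || cfg$q_max > 1)
    stop_config("run_config: 'q_max' must lie in (0, 1], got %g", cfg$q_max)
  if (cfg$fold_log2 < 0) stop_config("run_config: 'fold_log2' must be >= 0")
  if (cfg$pseudocount < 0) stop_config("run_config: 'pseudocount' must be >= 0")
  if (cfg$decile_fraction <= 0 || cfg$decile_fraction > 0.5)
    stop_config("run_config: 'decile_fraction' must lie in (0, 0.5]")
  invisible(cfg)
}

#' Read a run configuration from a flat key=value file
#'
#' Simulation parameters take a \code{sim.} prefix (e.g. \code{sim.n_genes});
#' \code{sim.seed} is mandatory. Unknown keys are rejected.
#'
#' @param path text file of key=value lines; '#' starts a comment.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop_config("read_run_config: malformed line '%s'", lines[lengths(kv) != 2][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  sim_keys <- startsWith(keys, "sim.")
  sim_args <- as.list(vals[sim_keys])
  names(sim_args) <- substring(keys[sim_keys], 5)
  run_args <- as.list(vals[!sim_keys])
  names(run_args) <- keys[!sim_keys]

  coerce <- function(args, fml) {
    unknown <- setdiff(names(args), names(fml))
    if (length(unknown))
      stop_config("read_run_config: unknown key '%s'", unknown[1])
    lapply(stats::setNames(names(args), names(args)), function(k) {
      v <- args[[k]]
      if (k == "conditions") strsplit(v, ",")[[1]]
      else if (suppressWarnings(!is.na(as.numeric(v)))) as.numeric(v)
      else v
    })
  }
  sim_args <- coerce(sim_args, formals(sim_config))
  run_args <- coerce(run_args, formals(run_config)[-1])
  cfg_sim <- do.call(sim_config, sim_args)
  do.call(run_config, c(list(sim = cfg_sim), run_args))
}

run_stage <- function(run_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(run_dir, sprintf("FAILED_%s", stage)))
    stop_config("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full pipeline: simulate, occupancy, call, metagene, diff, qpcr
#'
#' Executes every stage into \code{run_dir} and writes a manifest
#' (parameters, seed, package version, md5 checksum of every output)
#' sufficient to verify byte-identical reproduction. Any stage failure
#' aborts with the stage name; partial outputs stay behind a FAILED_<stage>
#' marker file.
#'
#' @param config a \code{\link{run_config}}.
#' @param run_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config, run_dir, quiet = FALSE) {
  validate_run_config(config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message(sprintf(...))
  ref <- config$sim$conditions[1]
  cmps <- setdiff(config$sim$conditions, ref)

  note("[simulate] %d genes, %d condition(s), seed %d",
       config$sim$n_genes, length(config$sim$conditions), config$sim$seed)
  sim <- run_stage(run_dir, "simulate", {
    s <- simulate_mnase(config$sim)
    write_simulation(s, file.path(run_dir, "sim"))
    s
  })

  note("[occupancy] bandwidth %g bp, %s", config$bandwidth,
       config$normalization)
  tracks <- run_stage(run_dir, "occupancy", {
    tr <- lapply(config$sim$conditions, function(cond) {
      t <- compute_occupancy(sim$fragments[[cond]], sim$chrom_sizes,
                             bandwidth = config$bandwidth, condition = cond)
      t <- normalize_track(t, config$normalization)
      write_bedgraph(t, file.path(run_dir,
                                  sprintf("track_%s.bedGraph", cond_slug(cond))))
      t
    })
    stats::setNames(tr, config$sim$conditions)
  })

  note("[call] min_spacing %d bp, min_height %g", config$min_spacing,
       config$min_height)
  calls <- run_stage(run_dir, "call", {
    cl <- lapply(config$sim$conditions, function(cond) {
      x <- call_nucleosomes(tracks[[cond]], config$min_spacing,
                            config$min_height)
      data.table::fwrite(x, file.path(run_dir,
                                      sprintf("calls_%s.tsv", cond_slug(cond))),
                         sep = "\t")
      bed <- data.frame(chrom = x$chrom, start = x$dyad - HALF_CORE,
                        end = x$dyad + HALF_CORE + 1L,
                        name = sprintf("nuc%06d", seq_len(nrow(x))),
                        score = as.integer(round(x$occupancy_score * 100)),
                        strand = ".")
      data.table::fwrite(bed, file.path(run_dir,
                                        sprintf("calls_%s.bed", cond_slug(cond))),
                         sep = "\t", col.names = FALSE)
      x
    })
    stats::setNames(cl, config$sim$conditions)
  })

  note("[architecture] reference condition: %s", ref)
  arch <- run_stage(run_dir, "architecture", {
    a <- build_gene_architecture(sim$genes, calls[[ref]], sim$fragments,
                                 rescue_bp = config$rescue_bp)
    data.table::fwrite(a, file.path(run_dir, "architecture.tsv"), sep = "\t")
    a
  })

  note("[metagene] +/-1000 bp at TSS and stop codon, TATA strata")
  run_stage(run_dir, "metagene", {
    profs <- list()
    for (cond in config$sim$conditions)
      for (anchor in c("tss", "stop_codon"))
        for (stratum in c("all", "tata1", "tata0")) {
          if (stratum != "all" &&
              !any(sim$genes$tata == (stratum == "tata1"))) next
          profs[[length(profs) + 1L]] <-
            metagene(tracks[[cond]], sim$genes, anchor, stratum)
        }
    tbl <- metagene_table(profs)
    data.table::fwrite(tbl, file.path(run_dir, "metagene.tsv"), sep = "\t")
    tbl
  })

  note("[diff] %s vs %s; fold filter %g, q < %g", ref,
       paste(cmps, collapse = "/"), config$fold_log2, config$q_max)
  diffs <- run_stage(run_dir, "diff", {
    out <- list()
    for (cmp in cmps) {
      res <- diff_nfr(arch, ref, cmp, pseudocount = config$pseudocount,
                      fold_log2 = config$fold_log2, q_max = config$q_max)
      data.table::fwrite(res, file.path(run_dir,
                                        sprintf("diff_%s_vs_%s.tsv",
                                                cond_slug(ref), cond_slug(cmp))),
                         sep = "\t")
      out[[cmp]] <- res
    }
    summ <- lapply(out, function(r) as.list(table(factor(
      r$call, levels = c("activated", "repressed", "NS")))))
    jsonlite::write_json(summ, file.path(run_dir, "diff_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    ok <- !is.na(arch[[paste0(ref, "_NFR")]])
    cls <- decile_classes(arch[[paste0(ref, "_NFR")]][ok],
                          arch$gene_id[ok], config$decile_fraction)
    data.table::fwrite(cls, file.path(run_dir, "deciles.tsv"), sep = "\t")
    ct_tab <- class_tata_table(cls, sim$genes)
    utils::write.table(as.data.frame.matrix(ct_tab),
                       file.path(run_dir, "decile_tata_table.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    out
  })

  run_stage(run_dir, "qpcr", {
    has_effects <- !is.null(config$sim$effect_genes) &&
      nrow(config$sim$effect_genes) > 0
    if (!has_effects) {
      note("[qpcr] no effect genes designated; stage skipped")
      return(invisible(NULL))
    }
    note("[qpcr] 2^-ddCt vs %s, reference gene ACT1", ref)
    ct <- simulate_ct_table(sim$truth, control = ref,
                            replicates = config$qpcr_replicates,
                            ct_noise_sd = config$qpcr_noise_sd,
                            seed = config$sim$seed)
    data.table::fwrite(ct, file.path(run_dir, "qpcr_ct.tsv"), sep = "\t")
    conc <- list()
    for (cmp in cmps) {
      fc <- fold_change_table(ct, cmp, ref)
      data.table::fwrite(fc, file.path(run_dir,
                                       sprintf("qpcr_folds_%s.tsv",
                                               cond_slug(cmp))), sep = "\t")
      sig <- significant_calls(diffs[[cmp]], config$fold_log2, config$q_max)
      if (nrow(sig) && nrow(fc))
        conc[[cmp]] <- tryCatch({
          cc <- concordance(fc, sig)
          list(table = as.list(as.data.frame(as.table(cc$table))),
               concordance_activated = cc$concordance_activated,
               concordance_repressed = cc$concordance_repressed,
               n_boundary = cc$n_boundary, n = cc$n)
        }, error = function(e) list(note = conditionMessage(e)))
    }
    jsonlite::write_json(conc, file.path(run_dir, "qpcr_concordance.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  manifest <- list(
    package = "nucdyn",
    version = as.character(utils::packageVersion("nucdyn")),
    seed = config$sim$seed,
    parameters = c(config[setdiff(names(config), "sim")],
                   list(sim = config$sim[setdiff(names(config$sim),
                                                 "effect_genes")]),
                   list(effect_genes = config$sim$effect_genes)),
    checksums = manifest_checksums(run_dir))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  note("[done] %s", run_dir)
  invisible(run_dir)
}

manifest_checksums <- function(run_dir) {
  files <- sort(list.files(run_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("manifest.json", "report.md"))
  sums <- tools::md5sum(file.path(run_dir, files))
  stats::setNames(as.list(unname(sums)), files)
}

#' Render a plain-text summary report for a completed run
#'
#' Sections: simulation, occupancy tracks, nucleosome calls, metagene
#' profiles, decile x TATA table, differential summary, qPCR concordance.
#' Missing stage outputs are reported as absent; the report still renders,
#' and regeneration is idempotent.
#'
#' @param run_dir directory produced by \code{\link{run_pipeline}}.
#' @return invisibly, the report path.
#' @export
render_report <- function(run_dir) {
  out <- c("# nucleosome dynamics run report", "")
  sec <- function(title, body) c(paste("##", title), "", body, "")
  have <- function(f) file.exists(file.path(run_dir, f))

  out <- c(out, sec("Simulation", if (have("sim/truth_genes.tsv")) {
    tg <- data.table::fread(file.path(run_dir, "sim/truth_genes.tsv"))
    sprintf("%d genes simulated; %d TATA-containing.", nrow(tg), sum(tg$tata))
  } else "absent"))

  tracks <- list.files(run_dir, "^track_.*\\.bedGraph$")
  out <- c(out, sec("Occupancy tracks", if (length(tracks))
    paste("-", tracks) else "absent"))

  callf <- list.files(run_dir, "^calls_.*\\.tsv$")
  out <- c(out, sec("Nucleosome calls", if (length(callf)) {
    vapply(callf, function(f) {
      sprintf("%s: %d calls", f,
              nrow(data.table::fread(file.path(run_dir, f))))
    }, character(1))
  } else "absent"))

  out <- c(out, sec("Metagene profiles", if (have("metagene.tsv")) {
    mg <- data.table::fread(file.path(run_dir, "metagene.tsv"))
    sprintf("%d profile rows over %d condition(s), anchors: %s.",
            nrow(mg), length(unique(mg$condition)),
            paste(unique(mg$anchor), collapse = ", "))
  } else "absent"))

  out <- c(out, sec("Decile occupancy x TATA",
                    if (have("decile_tata_table.tsv"))
                      readLines(file.path(run_dir, "decile_tata_table.tsv"))
                    else "absent"))

  out <- c(out, sec("Differential NFR occupancy",
                    if (have("diff_summary.json"))
                      paste(readLines(file.path(run_dir, "diff_summary.json")),
                            collapse = "")
                    else "absent"))

  out <- c(out, sec("qPCR concordance",
                    if (have("qpcr_concordance.json"))
                      paste(readLines(file.path(run_dir,
                                                "qpcr_concordance.json")),
                            collapse = "")
                    else "absent (no qRT-PCR inputs for this run)"))

  path <- file.path(run_dir, "report.md")
  writeLines(out, path)
  invisible(path)
}
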