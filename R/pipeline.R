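#' @include AllClasses.R trim.R filter.R strategy.R recruit.R assemble.R
#'   annotate.R ini.R
NULL

#' Parse the project configuration file
#'
#' INI dialect. Sections: `[project]` (`name`, `output_dir`), `[input]`
#' (`sample_name`, `reads_1`, `reads_2`, optional `transcriptomes`),
#' `[filter]` (label = reference FASTA path, any number), optional
#' `[filter_sources]` (label = nucleus|plastid|mitochondrion), and the
#' per-stage parameter blocks `[trim]`, `[classify]`, `[seed]`,
#' `[enrich]`, `[assembly]` whose keys are the snake_case parameter names
#' of the corresponding `*Params()` constructors. SRA accessions are
#' recognized in `reads_*` and rejected: retrieval from the archive is
#' out of scope, fetch FASTQ files externally first.
#'
#' @param path configuration file path.
#' @return a `ProjectConfig` list.
#' @export
readProjectConfig <- function(path) {
  ini <- .read_ini(path)
  known <- c("project", "input", "filter", "filter_sources", "trim",
             "classify", "seed", "enrich", "assembly")
  unknown <- setdiff(names(ini), known)
  if (length(unknown))
    stop("unknown section(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  pr <- ini[["project"]]
  if (is.null(pr) || is.na(pr["output_dir"]))
    stop("config must provide [project] output_dir")
  inp <- ini[["input"]]
  if (is.null(inp)) stop("config must provide an [input] section")
  for (key in c("reads_1", "reads_2")) {
    v <- inp[key]
    if (!is.na(v) && grepl("^[SED]RR[0-9]+$", v))
      stop("'", v, "' looks like an SRA accession; archive retrieval is ",
           "not supported here - fetch the FASTQ files first (e.g. with ",
           "prefetch/fasterq-dump) and provide local paths")
  }
  if (is.na(inp["reads_1"]) && is.na(inp["transcriptomes"]))
    stop("config must provide at least one sample input ",
         "(reads_1 or transcriptomes)")
  getnum <- function(sec, key, default) {
    v <- ini[[sec]][key]
    if (is.null(v) || is.na(v)) default else as.numeric(v)
  }
  adapters <- character(0)
  adpath <- ini[["trim"]]["adapters"]
  if (!is.null(adpath) && !is.na(adpath))
    adapters <- as.character(readFasta(adpath, "DNA"))
  trim <- trimParams(
    window = getnum("trim", "window", 4),
    windowMinq = getnum("trim", "window_minq", 20),
    leadQ = getnum("trim", "lead_q", 3),
    trailQ = getnum("trim", "trail_q", 3),
    minLen = getnum("trim", "min_len", 36), adapters = adapters,
    adapterMinOverlap = getnum("trim", "adapter_min_overlap", 8),
    adapterMaxMismatch = getnum("trim", "adapter_max_mismatch", 1))
  refs <- ini[["filter"]]
  sources <- ini[["filter_sources"]]
  list(
    name = if (!is.na(pr["name"])) unname(pr["name"]) else "project",
    outputDir = unname(pr["output_dir"]),
    sampleName = if (!is.na(inp["sample_name"])) unname(inp["sample_name"])
                 else "sample",
    reads1 = if (!is.na(inp["reads_1"])) unname(inp["reads_1"]) else NULL,
    reads2 = if (!is.na(inp["reads_2"])) unname(inp["reads_2"]) else NULL,
    transcriptomes = if (!is.na(inp["transcriptomes"]))
      .ini_paths(inp["transcriptomes"]) else character(0),
    refs = if (length(refs)) setNames(unname(refs), names(refs))
           else character(0),
    sources = if (length(sources)) setNames(unname(sources), names(sources))
              else character(0),
    trim = trim,
    classifyK = as.integer(getnum("classify", "k", 31)),
    classify = classifyParams(getnum("classify", "min_frac", 0.25)),
    seed = seedParams(getnum("seed", "aa_word", 4),
                      getnum("seed", "min_score", 50),
                      getnum("seed", "x_drop", 20)),
    enrich = enrichParams(getnum("enrich", "nt_k", 25),
                          getnum("enrich", "min_shared", 2)),
    assembly = assemblyParams(getnum("assembly", "k", 31),
                              getnum("assembly", "min_count", 2),
                              getnum("assembly", "tip_len",
                                     2 * getnum("assembly", "k", 31)),
                              getnum("assembly", "bubble_identity", 0.95),
                              getnum("assembly", "min_contig_len", 200)))
}

#' Deterministic output-directory layout
#'
#' Filtered reads live under `01-global/05-filtered-fq-data/[SAMPLE]`,
#' per-gene results under `02-strategies/[STRATEGY]/`.
#'
#' @param outputDir project output directory.
#' @param sample,strategy names (optional).
#' @return list of paths.
#' @export
layoutPaths <- function(outputDir, sample = NULL, strategy = NULL) {
  l <- list(globalDir = file.path(outputDir, "01-global"),
            strategiesDir = file.path(outputDir, "02-strategies"),
            manifest = file.path(outputDir, "run_manifest.json"),
            log = file.path(outputDir, "run.log"))
  if (!is.null(sample)) {
    l$trimmedDir <- file.path(l$globalDir, "02-trimmed-fq-data", sample)
    l$filteredDir <- file.path(l$globalDir, "05-filtered-fq-data", sample)
  }
  if (!is.null(strategy))
    l$strategyDir <- file.path(l$strategiesDir, strategy)
  l
}

.hash_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.read_manifest <- function(path) {
  if (file.exists(path)) read_json(path, simplifyVector = FALSE)
  else list(stages = list())
}

.stage_done <- function(manifest, key, param_hash, input_files) {
  e <- manifest$stages[[key]]
  if (is.null(e)) return(FALSE)
  if (!identical(e$param_hash, param_hash)) return(FALSE)
  if (!all(file.exists(unlist(e$outputs)))) return(FALSE)
  cur <- .hash_files(input_files)
  identical(cur[sort(names(cur))], e$input_hashes[sort(names(e$input_hashes))])
}

.check_collision <- function(manifest, key, outputs) {
  e <- manifest$stages[[key]]
  known <- unlist(e$outputs)
  clash <- outputs[file.exists(outputs) & !(outputs %in% known)]
  if (length(clash))
    stop("refusing to overwrite existing file(s) not created by this ",
         "pipeline: ", paste(clash, collapse = ", "))
}

#' Run the targeted assembly pipeline
#'
#' Stage order: trim, filter (optional `stopAfterFilter` exit), then per
#' search strategy: query-set build, two-stage read recruitment, targeted
#' assembly, annotation. All parameters are logged to `run.log` in the
#' output directory. Completed stages are detected through the run
#' manifest (parameter hash + input file hashes + outputs present) and
#' skipped, so re-running an unchanged project performs no stage work;
#' `force` reruns everything. Any stage error aborts with a message
#' naming the sample, strategy and stage.
#'
#' @param cfgPath project configuration file (see [readProjectConfig()]).
#' @param ssPath search-strategies file; when absent the pipeline runs
#'   through filtering only.
#' @param stopAfterFilter terminate after the read-filtering stage,
#'   leaving the per-reference FASTQ bins as the final output.
#' @param force rerun stages even when up to date.
#' @param quiet suppress console messages (the run log is always written).
#' @return invisibly, a list with per-stage status ("ran"/"skipped") and
#'   key output paths.
#' @export
runPipeline <- function(cfgPath, ssPath = NULL, stopAfterFilter = FALSE,
                        force = FALSE, quiet = FALSE) {
  cfg <- readProjectConfig(cfgPath)
  sample <- cfg$sampleName
  lay <- layoutPaths(cfg$outputDir, sample)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(line, "\n", file = lay$log, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  manifest <- .read_manifest(lay$manifest)
  save_manifest <- function() {
    write_json(manifest, lay$manifest, auto_unbox = TRUE, digits = NA)
  }
  status <- list()
  run_stage <- function(key, label, param_obj, input_files, outputs, body) {
    ph <- .hash_obj(param_obj)
    if (!force && .stage_done(manifest, key, ph, input_files)) {
      log("skip ", label, " (up to date)")
      status[[key]] <<- "skipped"
      return(invisible(NULL))
    }
    .check_collision(manifest, key, outputs)
    log("run ", label)
    tryCatch(body(), error = function(e) {
      stop("stage '", label, "' failed for sample '", sample, "': ",
           conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[key]] <<- list(
      param_hash = ph, input_hashes = .hash_files(input_files),
      outputs = as.list(outputs),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    save_manifest()
    status[[key]] <<- "ran"
  }
  log("pipeline start: project '", cfg$name, "', sample '", sample,
      "', targasm ", as.character(packageVersion("targasm")))
  log("config: ", cfgPath, if (!is.null(ssPath)) paste0(", strategies: ",
      ssPath) else "", "; parameters logged below")
  log("trim params: ", jsonlite::toJSON(unclass(cfg$trim), auto_unbox = TRUE))
  log("classify k=", cfg$classifyK, " min_frac=", cfg$classify$minFrac)

  paired <- !is.null(cfg$reads2)
  trimmed <- c(
    p1 = file.path(lay$trimmedDir, paste0(sample, "_paired_1.fastq.gz")),
    p2 = file.path(lay$trimmedDir, paste0(sample, "_paired_2.fastq.gz")),
    orphans = file.path(lay$trimmedDir,
                        paste0(sample, "_orphans.fastq.gz")))
  if (!is.null(cfg$reads1)) {
    run_stage(paste0("trim:", sample), "trim", unclass(cfg$trim),
              c(cfg$reads1, cfg$reads2), trimmed, function() {
      dir.create(lay$trimmedDir, recursive = TRUE, showWarnings = FALSE)
      r1 <- readFastq(cfg$reads1)
      if (paired) {
        r2 <- readFastq(cfg$reads2)
        t <- trimPairs(r1, r2, cfg$trim)
        writeFastq(t$paired1, trimmed[["p1"]])
        writeFastq(t$paired2, trimmed[["p2"]])
        writeFastq(t$orphans, trimmed[["orphans"]])
        log("trim: ", length(t$paired1), " pairs kept, ",
            length(t$orphans), " orphans, ", length(t$discardedIds),
            " reads discarded")
      } else {
        t <- trimReads(r1, cfg$trim)
        writeFastq(t$kept, trimmed[["p1"]])
        writeFastq(t$kept[0], trimmed[["p2"]])
        writeFastq(t$kept[0], trimmed[["orphans"]])
        log("trim: ", length(t$kept), " reads kept, ",
            length(t$discardedIds), " discarded")
      }
    })

    unclass_bins <- c(
      file.path(lay$filteredDir,
                paste0(sample, "_unclassified_1.fastq.gz")),
      file.path(lay$filteredDir,
                paste0(sample, "_unclassified_2.fastq.gz")))
    filter_params <- list(k = cfg$classifyK, minFrac = cfg$classify$minFrac,
                          refs = as.list(cfg$refs))
    run_stage(paste0("filter:", sample), "filter", filter_params,
              unname(trimmed[c("p1", "p2")]), unclass_bins, function() {
      dir.create(lay$filteredDir, recursive = TRUE, showWarnings = FALSE)
      r1 <- readFastq(trimmed[["p1"]])
      r2 <- if (paired) readFastq(trimmed[["p2"]]) else NULL
      if (length(cfg$refs)) {
        idx <- buildKmerIndex(cfg$refs, cfg$classifyK)
        res <- splitReads(r1, r2, idx, cfg$classify, lay$filteredDir,
                          prefix = sample)
        for (i in seq_len(nrow(res$summary)))
          log("filter: ", res$summary$label[i], " ", res$summary$count[i],
              " (", round(100 * res$summary$fraction[i], 2), "%)")
      } else {
        writeFastq(r1, unclass_bins[1])
        if (paired) writeFastq(r2, unclass_bins[2])
        log("filter: no references configured; all ", length(r1),
            " pairs pass through unclassified")
      }
    })
  }

  if (stopAfterFilter) {
    log("stop-after-filter: filtered read set at ", lay$filteredDir)
    save_manifest()
    return(invisible(list(status = status, filteredDir = lay$filteredDir)))
  }
  if (is.null(ssPath)) {
    log("no search-strategies file; pipeline ends after filtering")
    return(invisible(list(status = status, filteredDir = lay$filteredDir)))
  }

  strategies <- readSearchStrategies(ssPath)
  unclass1 <- file.path(lay$filteredDir,
                        paste0(sample, "_unclassified_1.fastq.gz"))
  unclass2 <- file.path(lay$filteredDir,
                        paste0(sample, "_unclassified_2.fastq.gz"))
  for (s in strategies) {
    slay <- layoutPaths(cfg$outputDir, sample, s@name)
    sdir <- slay$strategyDir
    outs <- c(file.path(sdir, "queries.fasta"),
              file.path(sdir, "recruited_1.fastq.gz"),
              file.path(sdir, "recruited_2.fastq.gz"),
              file.path(sdir, "all_contigs.fasta"),
              file.path(sdir, "transcripts.fasta"),
              file.path(sdir, "transcripts.gff3"),
              file.path(sdir, "orfs_nt.fasta"),
              file.path(sdir, "orfs_aa.fasta"))
    sparams <- list(strategy = .strategy_fields(s),
                    seed = unclass(cfg$seed), enrich = unclass(cfg$enrich),
                    assembly = unclass(cfg$assembly))
    inputs <- c(if (!is.null(cfg$reads1)) c(unclass1, unclass2),
                s@queryFastaPaths, cfg$transcriptomes)
    run_stage(paste0("strategy:", s@name),
              paste0("strategy '", s@name, "'"), sparams, inputs,
              outs, function() {
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      queries <- buildQuerySet(s)
      writeFasta(queries, outs[1])
      log("strategy ", s@name, ": ", length(queries),
          " queries after pruning")
      contigs <- DNAStringSet()
      if (!is.null(cfg$reads1)) {
        r1 <- readFastq(unclass1)
        r2 <- if (paired) readFastq(unclass2) else NULL
        stage1 <- recruitSeed(r1, r2, queries, cfg$seed)
        rec <- enrichReads(r1, r2, stage1, cfg$enrich)
        log("strategy ", s@name, ": recruited ", length(rec@reads1),
            " pairs (", sum(rec@provenance == "seed"), " seed, ",
            sum(rec@provenance == "enrich"), " enrich)")
        writeFastq(rec@reads1, outs[2])
        if (paired) writeFastq(rec@reads2, outs[3]) else
          writeFastq(rec@reads1[0], outs[3])
        contigs <- assembleTargeted(rec, cfg$assembly)
      }
      asm <- contigs
      if (length(asm)) {
        hdr <- paste0(names(asm), " cov=", round(mcols(asm)$cov, 1))
        writeFasta(setNames(as.character(asm), hdr), outs[4])
      } else writeFasta(DNAStringSet(), outs[4])
      for (tp in cfg$transcriptomes) {
        user <- readFasta(tp, "DNA")
        names(user) <- paste0("user_", names(user))
        contigs <- c(contigs, user)
      }
      log("strategy ", s@name, ": ", length(contigs),
          " candidate transcripts")
      if (length(contigs) == 0) {
        .write_empty_annotation(sdir)
      } else {
        ann <- annotateContigs(contigs, queries, s,
                               code = geneticCodeFor("nucleus"))
        log("strategy ", s@name, ": ", nrow(ann$matches),
            " matched transcripts, ",
            if (is.null(ann$cds)) 0 else nrow(ann$cds), " with CDS")
        writeAnnotation(contigs, ann$matches, ann$cds, sdir)
      }
    })
  }
  log("pipeline complete")
  invisible(list(status = status, outputDir = cfg$outputDir))
}

.strategy_fields <- function(s) {
  sapply(slotNames(s), function(sl) slot(s, sl), simplify = FALSE)
}

.write_empty_annotation <- function(outDir) {
  writeFasta(DNAStringSet(), file.path(outDir, "transcripts.fasta"))
  writeLines("##gff-version 3", file.path(outDir, "transcripts.gff3"))
  writeFasta(DNAStringSet(), file.path(outDir, "orfs_nt.fasta"))
  writeFasta(AAStringSet(), file.path(outDir, "orfs_aa.fasta"))
}
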