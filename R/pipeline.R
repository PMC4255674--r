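# End-to-end orchestration: genome -> TA sites -> tags -> mapping -> saturation
# stats -> HMM decode -> gene classes -> report bundle. The pipeline is a pure
# function of (inputs, config): no stage uses randomness, so reruns are
# byte-identical.

#' Pipeline configuration
#'
#' @param genome Path to the genome FASTA.
#' @param annotation Path to the gene annotation GFF3.
#' @param reads Path to the raw reads FASTQ.
#' @param out_dir Output directory (created if absent).
#' @param structure A [read_structure()].
#' @param ir_mismatches Mismatches tolerated locating the inverted repeat.
#' @param feature_type GFF3 feature type to classify (default `"gene"`).
#' @param hmm_overrides Optional [hmm_params()] applied to every replicon in
#'   place of per-replicon fitting (rarely wanted; fitting per replicon
#'   cancels copy-number depth differences).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, reads, out_dir,
                            structure = read_structure(),
                            ir_mismatches = 0L,
                            feature_type = "gene",
                            hmm_overrides = NULL) {
  for (f in c(genome, annotation, reads)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(genome = genome, annotation = annotation, reads = reads,
                 out_dir = out_dir, structure = structure,
                 ir_mismatches = as.integer(ir_mismatches),
                 feature_type = feature_type, hmm_overrides = hmm_overrides),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline config file
#'
#' Recognized keys: `genome`, `annotation`, `reads`, `out_dir`,
#' `ir_sequence`, `ir_mismatches`, `quality_floor`, `feature_type`.
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) trimws(x[2]), character(1)),
                          vapply(kv, function(x) trimws(x[1]), character(1)))
  struct_args <- list()
  if ("ir_sequence" %in% names(vals)) struct_args$ir_sequence <- vals[["ir_sequence"]]
  if ("quality_floor" %in% names(vals)) {
    struct_args$quality_floor <- as.integer(vals[["quality_floor"]])
  }
  pipeline_config(
    genome = vals[["genome"]],
    annotation = vals[["annotation"]],
    reads = vals[["reads"]],
    out_dir = vals[["out_dir"]],
    structure = do.call(read_structure, struct_args),
    ir_mismatches = if ("ir_mismatches" %in% names(vals)) {
      as.integer(vals[["ir_mismatches"]])
    } else 0L,
    feature_type = if ("feature_type" %in% names(vals)) {
      vals[["feature_type"]]
    } else "gene"
  )
}

#' Run the full INSeq analysis pipeline
#'
#' Executes TA-site enumeration, read processing, tag mapping, saturation
#' statistics, HMM decoding and gene classification, writing every stage's
#' outputs plus a run log with the attrition counts into `out_dir`.
#'
#' Output files: `ta_sites.tsv`, `ta_sites.bed`, `tags.tsv`,
#' `processing_stats.tsv`, `mapping_stats.tsv`, `profile.wig`,
#' `replicon_summary.tsv`/`.json`, `gene_classes.tsv`, `class_summary.tsv`,
#' `site_states.wig`, `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genome <- stage("load-genome", load_genome(config$genome))
  info <- replicon_info(genome)
  note("loaded %d replicon(s), %d bp total", nrow(info), sum(info$length))

  ta <- stage("ta-sites", ta_site_index(genome))
  note("potential insertion sites: %d", sum(lengths(ta)))
  write_ta_tsv(ta, file.path(config$out_dir, "ta_sites.tsv"))
  write_ta_bed(ta, file.path(config$out_dir, "ta_sites.bed"))

  ann <- stage("load-annotation",
               load_annotation(config$annotation,
                               stats::setNames(info$length, info$replicon_id),
                               feature_type = config$feature_type))
  note("annotated genes: %d", nrow(ann))

  proc <- stage("process-reads",
                process_fastq(config$reads, config$structure,
                              config$ir_mismatches))
  s <- proc$stats
  note(paste0("reads: %d in; %d quality-failed; %d without IR; ",
              "%d bad length; %d without leading TA; %d tags"),
       s$n_input, s$n_quality_fail, s$n_no_ir, s$n_bad_length, s$n_no_ta,
       s$n_tags)
  write_tags_tsv(proc$tags, file.path(config$out_dir, "tags.tsv"))
  data.table::fwrite(as.data.frame(unclass(s)),
                     file.path(config$out_dir, "processing_stats.tsv"),
                     sep = "\t")

  index <- stage("map", build_tag_index(genome, ta))
  hits <- stage("map", map_tags(proc$tags$tag, index))
  acc <- stage("map", accumulate_profile(hits, ta))
  ms <- acc$stats
  note("mapped: %d unique; %d multi-aligned omitted; %d failed to align",
       ms$n_unique, ms$n_multi, ms$n_unmapped)
  data.table::fwrite(as.data.frame(unclass(ms)),
                     file.path(config$out_dir, "mapping_stats.tsv"),
                     sep = "\t")
  write_wig(acc$profiles, ta, file.path(config$out_dir, "profile.wig"))

  summaries <- stage("stats", {
    rows <- lapply(info$replicon_id, function(r) {
      summarize_replicon(acc$profiles[[r]], ta[[r]], r,
                         genes = ann[ann$replicon_id == r, , drop = FALSE],
                         size_bp = info$length[info$replicon_id == r],
                         gc_percent = 100 * info$gc_fraction[info$replicon_id == r])
    })
    per_rep <- do.call(rbind, rows)
    gen <- summarize_genome(per_rep)
    per_rep$mean_read_count_pooled <- per_rep$mean_read_count
    rbind(per_rep, gen)
  })
  write_replicon_summary(summaries,
                         file.path(config$out_dir, "replicon_summary.tsv"),
                         file.path(config$out_dir, "replicon_summary.json"))
  note("overall insertion density: %.2f",
       summaries$insertion_density[nrow(summaries)])

  cls <- stage("classify",
               classify_genome_with_overrides(acc$profiles, ta, ann,
                                              config$hmm_overrides))
  gt <- merge(cls$gene_table, ann[, c("locus", "product")], by = "locus",
              all.x = TRUE, sort = FALSE)
  write_gene_table(gt, file.path(config$out_dir, "gene_classes.tsv"))
  write_class_summary(cls$class_summary,
                      file.path(config$out_dir, "class_summary.tsv"))
  write_state_wig(cls$states, ta, file.path(config$out_dir, "site_states.wig"))
  tab <- table(factor(cls$gene_table$phenotypic_class,
                      levels = c(HMM_STATES, "NoData")))
  note("gene classes: ES %d | GD %d | NE %d | GA %d | NoData %d",
       tab["ES"], tab["GD"], tab["NE"], tab["GA"], tab["NoData"])

  writeLines(log_lines, log_path)
  invisible(list(genome = genome, ta = ta, annotation = ann,
                 processing = proc, mapping = acc, summaries = summaries,
                 classification = cls))
}

classify_genome_with_overrides <- function(profiles, ta, ann, overrides) {
  if (is.null(overrides)) return(classify_genome(profiles, ta, ann))
  tables <- list(); summaries <- list(); states <- list()
  for (r in names(profiles)) {
    genes_r <- ann[ann$replicon_id == r, , drop = FALSE]
    res <- classify_replicon(profiles[[r]], ta[[r]], genes_r,
                             params = overrides)
    tab <- res$gene_table
    if (nrow(tab)) tab <- cbind(replicon_id = r, tab)
    tables[[r]] <- tab
    summaries[[r]] <- cbind(replicon_id = r, res$class_summary)
    states[[r]] <- res$states
  }
  list(gene_table = as.data.frame(data.table::rbindlist(tables)),
       class_summary = as.data.frame(data.table::rbindlist(summaries)),
       states = states)
}
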