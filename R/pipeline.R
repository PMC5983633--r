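## End-to-end pipeline orchestration: filter -> map -> annotate -> novel ->
## quantify -> differential expression -> targets -> degradome, with TSV
## report bundles and a reproducibility manifest.

#' Pipeline configuration
#'
#' Inputs may be given as file paths (FASTA/FASTQ) or as in-memory
#' data.frames with the same columns the readers produce.
#'
#' @param genome genome FASTA path or data.frame (`id`, `sequence`).
#' @param mature_ref,hairpin_ref known-miRNA reference sets (miRBase-style).
#' @param samples sample sheet data.frame: `library_id`, `tissue`,
#'   `treatment`, `replicate`, `fastq`.
#' @param transcripts optional transcript set for target prediction.
#' @param degradome optional degradome FASTQ path (reads are expected
#'   adapter-trimmed).
#' @param class_refs named list of per-class annotation reference sets, in
#'   hierarchy order.
#' @param filter a [filter_params()] object.
#' @param penalty a [penalty_params()] object.
#' @param comparisons list of `list(a =, b =, label =)` library-id groups;
#'   `NULL` builds all within-tissue treatment contrasts (short vs control,
#'   long vs control, long vs short).
#' @param min_stack_count novel-candidate stack threshold (default 10).
#' @param outdir output directory for the report bundle.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, mature_ref, hairpin_ref, samples,
                            transcripts = NULL, degradome = NULL,
                            class_refs = list(),
                            filter = filter_params(),
                            penalty = penalty_params(),
                            comparisons = NULL, min_stack_count = 10L,
                            outdir = tempfile("mirstalk_run_"), seed = 1L) {
  load_fasta <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) stop("missing ", what, " file: ", x)
      return(read_fasta(x))
    }
    stopifnot(is.data.frame(x))
    x
  }
  stopifnot(all(c("library_id", "tissue", "treatment", "replicate",
                  "fastq") %in% names(samples)))
  missing_fq <- !file.exists(samples$fastq)
  if (any(missing_fq)) {
    stop("missing FASTQ for library ", samples$library_id[missing_fq][1L])
  }
  if (!is.null(degradome) && !file.exists(degradome)) {
    stop("missing degradome file: ", degradome)
  }
  if (is.null(comparisons)) {
    comparisons <- list()
    for (ti in unique(samples$tissue)) {
      tt <- samples[samples$tissue == ti, ]
      trt <- unique(tt$treatment)
      pairs <- list(c("S", "C"), c("L", "C"), c("L", "S"))
      for (p in pairs) {
        if (!all(p %in% trt)) next
        lab <- paste0(p[1L], ti, " vs ", p[2L], ti)
        comparisons[[lab]] <- list(
          a = tt$library_id[tt$treatment == p[2L]],
          b = tt$library_id[tt$treatment == p[1L]],
          label = lab, tissue = ti)
      }
    }
  }
  for (cmp in comparisons) {
    if (!all(c(cmp$a, cmp$b) %in% samples$library_id)) {
      stop("comparison references an undeclared library")
    }
  }
  structure(list(genome = load_fasta(genome, "genome"),
                 mature_ref = load_fasta(mature_ref, "mature reference"),
                 hairpin_ref = load_fasta(hairpin_ref, "hairpin reference"),
                 samples = samples,
                 transcripts = load_fasta(transcripts, "transcript"),
                 degradome = degradome, class_refs = class_refs,
                 filter = filter, penalty = penalty,
                 comparisons = comparisons,
                 min_stack_count = as.integer(min_stack_count),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Process one sRNA library: quality, adapter, filters, collapse
#'
#' @param fastq FASTQ path.
#' @param filter a [filter_params()] object.
#' @return list with `raw_reads`, `clean_reads`, `length_filtered_reads`,
#'   `tally` (rejection reasons) and `collapsed` (sequence/count
#'   data.frame).
#' @export
process_library <- function(fastq, filter) {
  fq <- read_fastq(fastq)
  raw_n <- nrow(fq)
  seqs <- fq$sequence
  if (!is.na(filter$min_mean_quality)) {
    mq <- vapply(fq$quality,
                 function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                 USE.NAMES = FALSE)
    seqs <- seqs[mq >= filter$min_mean_quality]
  }
  tr <- trim_adapter3(seqs, filter)
  inserts <- tr$insert[!is.na(tr$insert)]
  clean_n <- length(inserts)
  fl <- filter_reads(inserts, filter)
  tally <- c(no_adapter = tr$n_no_adapter +
               (raw_n - length(seqs)) * 0L, fl$tally)
  list(raw_reads = raw_n, clean_reads = clean_n,
       length_filtered_reads = length(fl$kept), tally = tally,
       collapsed = collapse_unique(fl$kept))
}

#' Run the full analysis pipeline
#'
#' Stages: filter -> map -> annotate -> novel -> quantify -> differential
#' expression -> targets -> degradome. All stage outputs are written to
#' `config$outdir` as TSV, with a JSON manifest recording parameters, seed
#' and md5 checksums.
#'
#' @param config a [pipeline_config()].
#' @return list with `stats`, `stats_table`, `size_dist`, `class_counts`,
#'   `catalog` (miRNA id/sequence/type), `cm` (a [count_matrix()]), `tpm`,
#'   `novel` (all candidates), `de` (list of [de_test()] results),
#'   `summaries` (per tissue), `targets`, `cleavage`, `profile`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  samples <- config$samples
  libs <- samples$library_id

  ## ---- filter + collapse ------------------------------------------------
  per_lib <- lapply(seq_len(nrow(samples)), function(i) {
    process_library(samples$fastq[i], config$filter)
  })
  names(per_lib) <- libs
  long <- rbindlist(lapply(libs, function(l) {
    d <- as.data.table(per_lib[[l]]$collapsed)
    if (nrow(d)) d[, library_id := l]
    d
  }))
  if (nrow(long) == 0L) stop("stage filter: no reads passed the filters")
  wide <- data.table::dcast(long, sequence ~ library_id,
                            value.var = "count", fill = 0L)
  for (m in setdiff(libs, names(wide))) wide[, (m) := 0L]
  data.table::setcolorder(wide, c("sequence", libs))
  wide[, total := rowSums(.SD), .SDcols = libs]
  setkey(wide, sequence)

  ## ---- map + annotate ---------------------------------------------------
  index <- build_index(config$genome)
  aln <- map_exact(wide$sequence, index)
  mapped <- wide$sequence %in% unique(aln$read)
  known <- annotate_known(wide$sequence, config$mature_ref,
                          config$hairpin_ref)
  cls <- classify_read(wide$sequence, mapped, known, config$class_refs)
  class_counts <- as.data.frame(table(class = cls))

  stats <- lapply(libs, function(l) {
    cn <- wide[[l]]
    ms <- mapping_stats(wide$sequence, cn, mapped)
    library_stats(per_lib[[l]]$raw_reads, per_lib[[l]]$clean_reads,
                  ms$length_filtered_reads, ms$mapped_reads,
                  ms$length_filtered_unique, ms$mapped_unique)
  })
  names(stats) <- libs
  size_dist <- lapply(libs, function(l) {
    keep <- wide[[l]] > 0L
    size_distribution(wide$sequence[keep], wide[[l]][keep])
  })
  names(size_dist) <- libs

  ## ---- known counts -----------------------------------------------------
  kn <- as.data.table(known)
  kn <- wide[kn, on = c(sequence = "read")]
  known_counts <- matrix(0L, nrow(config$mature_ref), length(libs),
                         dimnames = list(config$mature_ref$id, libs))
  if (nrow(kn)) {
    for (l in libs) known_counts[kn$mature_id, l] <- kn[[l]]
  }

  ## ---- novel discovery --------------------------------------------------
  cand_seq <- wide$sequence[cls == "novel_candidate"]
  cand_aln <- aln[aln$read %in% cand_seq, , drop = FALSE]
  stacks <- detect_stacks(cand_aln, as.data.frame(wide), libs,
                          min_stack_count = config$min_stack_count)
  novel <- find_novel_mirnas(stacks, config$genome, libs)
  novel_acc <- novel[novel$accepted, , drop = FALSE]
  novel_counts <- if (nrow(novel_acc)) {
    m <- as.matrix(novel_acc[, libs, drop = FALSE])
    rownames(m) <- novel_acc$mirna_id
    storage.mode(m) <- "integer"
    m
  } else {
    matrix(integer(0), 0L, length(libs), dimnames = list(NULL, libs))
  }

  catalog <- rbind(
    data.frame(mirna_id = config$mature_ref$id,
               sequence = norm_seq(config$mature_ref$sequence),
               type = "known", stringsAsFactors = FALSE),
    data.frame(mirna_id = novel_acc$mirna_id,
               sequence = novel_acc$mature_seq,
               type = "novel", stringsAsFactors = FALSE))

  ## ---- quantification + DE ---------------------------------------------
  sm <- samples
  sm$total_clean_reads <- vapply(per_lib, function(x) x$clean_reads,
                                 numeric(1))[libs]
  cm <- count_matrix(rbind(known_counts, novel_counts), sm)
  tpm_m <- tpm_matrix(cm)
  de <- lapply(config$comparisons, function(cmp) {
    de_test(cm, cmp$a, cmp$b, comparison = cmp$label)
  })
  summaries <- list()
  tissues <- unique(vapply(config$comparisons, function(x) x$tissue %||% "",
                           character(1)))
  for (ti in tissues[nzchar(tissues)]) {
    sel <- vapply(config$comparisons, function(x) identical(x$tissue, ti),
                  logical(1))
    if (any(sel)) summaries[[ti]] <- comparison_summary(de[sel])
  }

  ## ---- targets + degradome ---------------------------------------------
  targets <- NULL; cleavage <- NULL; profile <- NULL
  if (!is.null(config$transcripts)) {
    trs <- setNames(config$transcripts$sequence, config$transcripts$id)
    hits <- list()
    for (i in seq_len(nrow(catalog))) {
      for (tr in names(trs)) {
        h <- suppressWarnings(
          scan_transcript(catalog$sequence[i], trs[[tr]], config$penalty))
        if (nrow(h)) {
          h$mirna_id <- catalog$mirna_id[i]
          h$transcript <- tr
          hits[[length(hits) + 1L]] <- h
        }
      }
    }
    targets <- if (length(hits)) as.data.frame(rbindlist(hits)) else
      data.frame(start = integer(0), end = integer(0), score = numeric(0),
                 pairing = character(0), mirna_id = character(0),
                 transcript = character(0))
    if (!is.null(config$degradome)) {
      deg <- read_fastq(config$degradome)
      profile <- map_degradome(deg$sequence, config$transcripts)
      cleavage <- call_cleavage(targets, profile)
    }
  }

  res <- list(stats = stats, stats_table = format_stats_table(stats),
              size_dist = size_dist, class_counts = class_counts,
              catalog = catalog, cm = cm, tpm = tpm_m, novel = novel,
              de = de, summaries = summaries, targets = targets,
              cleavage = cleavage, profile = profile)
  res$files <- write_bundle(res, config)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## write the TSV report bundle + JSON manifest; returns file paths
write_bundle <- function(res, config) {
  out <- config$outdir
  tsv <- function(d, name) {
    p <- file.path(out, name)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    stats = tsv(res$stats_table, "library_stats.tsv"),
    class_counts = tsv(res$class_counts, "class_counts.tsv"),
    counts = tsv(data.frame(mirna_id = rownames(res$cm$counts),
                            res$cm$counts, check.names = FALSE),
                 "counts.tsv"),
    tpm = tsv(data.frame(mirna_id = rownames(res$tpm), res$tpm,
                         check.names = FALSE), "tpm.tsv"),
    novel = tsv(format_novel_table(res$novel[res$novel$accepted, ,
                                             drop = FALSE]),
                "novel_mirnas.tsv"),
    de = tsv(do.call(rbind, res$de), "de_results.tsv"))
  sd <- rbindlist(lapply(names(res$size_dist), function(l) {
    d <- res$size_dist[[l]]; d$library_id <- l; d
  }))
  files["size_dist"] <- tsv(as.data.frame(sd), "size_distribution.tsv")
  if (!is.null(res$targets)) {
    files["targets"] <- tsv(res$targets, "target_sites.tsv")
  }
  if (!is.null(res$cleavage)) {
    files["cleavage"] <- tsv(res$cleavage, "cleavage_calls.tsv")
    files["profile"] <- tsv(res$profile$counts, "degradome_profile.tsv")
  }
  manifest <- list(
    package = "mirstalk",
    version = as.character(utils::packageVersion("mirstalk")),
    seed = config$seed,
    parameters = list(filter = unclass(config$filter),
                      penalty = unclass(config$penalty),
                      min_stack_count = config$min_stack_count),
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files["manifest"] <- file.path(out, "manifest.json")
  files
}

#' Score pipeline results against a simulation's ground truth
#'
#' @param res result list from [run_pipeline()].
#' @param dataset bundle from [simulate_dataset()].
#' @param de_comparison label of the comparison carrying the planted
#'   effects (default the stem short-term vs control contrast).
#' @return list with `known_recovery`, `novel_recovery`, `decoys_accepted`,
#'   `de_sensitivity`, `de_fdr`, `degradome_accuracy` and supporting detail.
#' @export
compare_to_truth <- function(res, dataset, de_comparison = "SS vs CS") {
  truth <- dataset$truth
  config <- dataset$config

  known <- truth[truth$type == "known", ]
  known_rows <- res$catalog[res$catalog$type == "known", ]
  known_counts <- res$cm$counts[known_rows$mirna_id, , drop = FALSE]
  detected <- rowSums(known_counts) > 0
  seq_of <- setNames(known_rows$sequence, known_rows$mirna_id)
  known_recovery <- mean(known$mature_seq %in%
                           seq_of[names(detected)[detected]])

  novel <- truth[truth$type == "novel", ]
  acc <- res$novel[res$novel$accepted, , drop = FALSE]
  novel_recovery <- mean(novel$mature_seq %in% acc$mature_seq)
  decoys_accepted <- sum(truth$mature_seq[truth$type == "decoy"] %in%
                           acc$mature_seq)

  ## map truth ids -> pipeline ids via the mature sequence
  pid <- setNames(res$catalog$mirna_id, res$catalog$sequence)
  truth_pid <- setNames(unname(pid[truth$mature_seq]), truth$mirna_id)

  de <- res$de[[de_comparison]]
  planted <- config$de_spec[config$de_spec$tissue == "S" &
                              config$de_spec$treatment == "S", ]
  planted_pid <- unname(truth_pid[planted$mirna_id])
  called <- de$mirna_id[de$significant]
  tp <- sum(called %in% planted_pid)
  de_sensitivity <- tp / length(planted_pid)
  de_fdr <- if (length(called)) (length(called) - tp) / length(called) else 0

  degradome_accuracy <- NA_real_
  deg_detail <- NULL
  if (!is.null(res$cleavage)) {
    ts <- dataset$degradome$truth_sites
    ts$pid <- unname(truth_pid[ts$mirna_id])
    cl <- res$cleavage
    ok <- vapply(seq_len(nrow(ts)), function(i) {
      hit <- cl$mirna_id == ts$pid[i] & cl$transcript == ts$transcript[i] &
        cl$cleavage_pos == ts$cleavage_pos[i]
      any(hit & !is.na(cl$category) & cl$category == ts$category[i])
    }, logical(1))
    degradome_accuracy <- mean(ok)
    deg_detail <- cbind(ts, recovered = ok)
  }
  list(known_recovery = known_recovery, novel_recovery = novel_recovery,
       decoys_accepted = decoys_accepted, de_sensitivity = de_sensitivity,
       de_fdr = de_fdr, de_called = called,
       degradome_accuracy = degradome_accuracy, deg_detail = deg_detail)
}

#' Simulate a dataset and run the pipeline on it
#'
#' @param config a [sim_config()].
#' @param workdir directory for simulated files and the report bundle.
#' @return list with `dataset`, `result` and `evaluation`
#'   (from [compare_to_truth()]).
#' @export
run_simulation_study <- function(config = sim_config(),
                                 workdir = tempfile("mirstalk_sim_")) {
  dataset <- simulate_dataset(config, file.path(workdir, "data"))
  pc <- pipeline_config(
    genome = dataset$genome, mature_ref = dataset$mature_ref,
    hairpin_ref = dataset$hairpin_ref,
    samples = dataset$libraries$samples,
    transcripts = dataset$degradome$transcripts,
    degradome = dataset$degradome$degradome_fastq,
    class_refs = dataset$class_refs,
    filter = filter_params(adapter3 = config$adapter3,
                           adapter5 = config$adapter5),
    min_stack_count = config$min_stack_count,
    outdir = file.path(workdir, "run"), seed = config$seed)
  result <- run_pipeline(pc)
  list(dataset = dataset, result = result,
       evaluation = compare_to_truth(result, dataset))
}
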