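## End-to-end driver: QC -> overlap detection/scoring -> size-capped
## single-linkage clustering -> per-cluster local assembly -> global
## master-graph assembly. Stage artifacts are written under the working
## directory and reused on resume when the configuration hash is
## unchanged. Cluster-level parallelism only; merge order is fixed by
## cluster id, so results are independent of the schedule.

#' Pipeline configuration
#'
#' @param reads1 FASTQ path (R1), or a [read_set()] already in memory.
#' @param reads2 optional mate FASTQ path (R2).
#' @param workdir working directory for stage artifacts.
#' @param qc a [qc_params()].
#' @param overlap an [overlap_params()].
#' @param max_cluster_size single-linkage size cap (default 3000 reads).
#' @param min_cluster_size minimum cluster size for local assembly
#'   (default 3).
#' @param local a [local_params()].
#' @param global a [global_params()].
#' @param threads worker processes for cluster-level parallelism.
#' @param seed integer seed (the pipeline itself is deterministic; the
#'   seed is recorded for provenance and used by any randomized stage).
#' @param resume reuse stage artifacts when config and inputs are
#'   unchanged (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reads1, reads2 = NULL, workdir = tempfile("strainasm_"),
                            qc = qc_params(), overlap = overlap_params(),
                            max_cluster_size = 3000L,
                            min_cluster_size = 3L,
                            local = local_params(),
                            global = global_params(),
                            threads = 1L, seed = 1L, resume = TRUE) {
  structure(list(reads1 = reads1, reads2 = reads2, workdir = workdir,
                 qc = qc, overlap = overlap,
                 max_cluster_size = max_cluster_size,
                 min_cluster_size = check_count(min_cluster_size,
                                                "min_cluster_size", 1L),
                 local = local, global = global,
                 threads = check_count(threads, "threads", 1L),
                 seed = check_count(seed, "seed"), resume = resume),
            class = "pipeline_config")
}

config_hash <- function(config) {
  x <- config[setdiff(names(config), c("workdir", "threads", "resume"))]
  if (is.character(x$reads1) && length(x$reads1) == 1L &&
      file.exists(x$reads1))
    x$reads1_size <- file.info(x$reads1)$size
  if (!is.null(x$reads2) && is.character(x$reads2) &&
      file.exists(x$reads2))
    x$reads2_size <- file.info(x$reads2)$size
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp)
  unname(tools::md5sum(tmp))
}

stage_path <- function(config, name) file.path(config$workdir, name)

stage_fresh <- function(config, name, hash) {
  f <- stage_path(config, name)
  h <- stage_path(config, paste0(name, ".hash"))
  config$resume && file.exists(f) && file.exists(h) &&
    identical(readLines(h, warn = FALSE)[1], hash)
}

stage_save <- function(config, name, hash, obj) {
  saveRDS(obj, stage_path(config, name))
  writeLines(hash, stage_path(config, paste0(name, ".hash")))
  obj
}

stage_load <- function(config, name) {
  obj <- tryCatch(readRDS(stage_path(config, name)),
                  error = function(e)
                    stopf("corrupt intermediate '%s': %s", name,
                          conditionMessage(e)))
  obj
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[strainasm] %-10s %s", stage, sprintf(fmt, ...)))
}

#' Run the full assembly pipeline
#'
#' Executes QC, overlap computation, read clustering, local assembly and
#' global assembly in order, writing each stage's artifacts under the
#' configured working directory. With `resume = TRUE` a rerun with an
#' unchanged configuration reuses existing artifacts.
#'
#' @param config a [pipeline_config()].
#' @return a `strainasm_run` list: final `contigs` data.frame,
#'   `provenance`, per-stage `counts`, the assembly FASTA path, and the
#'   evaluated configuration.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  set.seed(config$seed)
  counts <- list()

  ## stage 1: QC ------------------------------------------------------
  if (stage_fresh(config, "qc.rds", hash)) {
    reads <- stage_load(config, "qc.rds")
    log_stage("qc", "resumed: %d reads", nrow(reads))
  } else {
    raw <- if (inherits(config$reads1, "read_set")) config$reads1
           else parse_fastq(config$reads1, config$reads2)
    t0 <- Sys.time()
    reads <- qc_reads(raw, config$qc)
    rep <- attr(reads, "report")
    log_stage("qc", "%d reads in, %d kept, %d bases corrected (%.1fs)",
              rep$n_input, rep$n_kept, rep$n_bases_corrected,
              as.numeric(Sys.time() - t0, units = "secs"))
    stage_save(config, "qc.rds", hash, reads)
  }
  counts$reads <- nrow(reads)

  ## stage 2: overlaps --------------------------------------------------
  if (stage_fresh(config, "overlaps.rds", hash)) {
    scored <- stage_load(config, "overlaps.rds")
    log_stage("overlap", "resumed: %d overlaps", nrow(scored))
  } else {
    t0 <- Sys.time()
    hits <- find_overlaps(setNames(reads$seq, reads$id), config$overlap,
                          keep_cigar = FALSE)
    scored <- filter_overlaps(score_overlaps(hits, config$overlap),
                              config$overlap)
    scored <- scored[scored$type %in% c("ab", "ba", "b_in_a", "a_in_b"), ,
                     drop = FALSE]
    log_stage("overlap", "%d overlaps retained (%.1fs)", nrow(scored),
              as.numeric(Sys.time() - t0, units = "secs"))
    stage_save(config, "overlaps.rds", hash, scored)
  }
  counts$overlaps <- nrow(scored)

  ## stage 3: clustering ------------------------------------------------
  if (stage_fresh(config, "clusters.rds", hash)) {
    clusters <- stage_load(config, "clusters.rds")
    log_stage("cluster", "resumed: %d clusters", length(clusters$clusters))
  } else {
    t0 <- Sys.time()
    dove <- scored[scored$type %in% c("ab", "ba"), , drop = FALSE]
    ordered <- sort_by_score(dove)
    clusters <- single_linkage_cluster(ordered, reads$id,
                                       config$max_cluster_size)
    ## contained reads follow their container's cluster already via the
    ## union (containments were filtered out above; reads without any
    ## dovetail overlap stay singletons)
    log_stage("cluster", "%d clusters, %d singletons (%.1fs)",
              length(clusters$clusters), clusters$n_singletons,
              as.numeric(Sys.time() - t0, units = "secs"))
    stage_save(config, "clusters.rds", hash, clusters)
  }
  counts$clusters <- length(clusters$clusters)

  ## stage 4: local assembly -------------------------------------------
  if (stage_fresh(config, "local.rds", hash)) {
    local_res <- stage_load(config, "local.rds")
    log_stage("local", "resumed: %d contigs", nrow(local_res$contigs))
  } else {
    t0 <- Sys.time()
    sizes <- lengths(clusters$clusters)
    eligible <- names(clusters$clusters)[sizes >= config$min_cluster_size]
    eligible <- eligible[order(as.integer(eligible))]
    worker <- function(cid) {
      members <- clusters$clusters[[cid]]
      sub <- reads[match(members, reads$id), , drop = FALSE]
      assemble_cluster(sub, config$local,
                       contig_prefix = sprintf("cluster%s_ctg", cid))
    }
    res <- if (config$threads > 1L)
      parallel::mclapply(eligible, worker, mc.cores = config$threads,
                         mc.preschedule = TRUE)
    else lapply(eligible, worker)
    for (r in res) if (inherits(r, "try-error")) stop(r)
    local_res <- list(
      contigs = do.call(rbind, lapply(res, `[[`, "contigs")),
      support = do.call(rbind, lapply(res, `[[`, "support")),
      unplaced = unlist(lapply(res, `[[`, "unplaced")))
    if (is.null(local_res$contigs))
      local_res$contigs <- data.frame(id = character(0),
                                      seq = character(0),
                                      length = integer(0),
                                      mean_depth = numeric(0))
    log_stage("local", "%d cluster contigs from %d clusters (%.1fs)",
              nrow(local_res$contigs), length(eligible),
              as.numeric(Sys.time() - t0, units = "secs"))
    stage_save(config, "local.rds", hash, local_res)
  }
  counts$cluster_contigs <- nrow(local_res$contigs)

  ## stage 5: global assembly ------------------------------------------
  if (stage_fresh(config, "global.rds", hash)) {
    assembly <- stage_load(config, "global.rds")
    log_stage("global", "resumed: %d master contigs",
              nrow(assembly$contigs))
  } else {
    t0 <- Sys.time()
    if (nrow(local_res$contigs) == 0L) {
      assembly <- list(contigs = data.frame(id = character(0),
                                            seq = character(0),
                                            length = integer(0),
                                            n_sources = integer(0)),
                       provenance = NULL)
    } else {
      mg <- build_master_graph(local_res$contigs, config$global)
      assembly <- extend_unique_paths(mg, reads, config$global)
    }
    log_stage("global", "%d master contigs (%.1fs)",
              nrow(assembly$contigs),
              as.numeric(Sys.time() - t0, units = "secs"))
    stage_save(config, "global.rds", hash, assembly)
  }
  counts$master_contigs <- nrow(assembly$contigs)

  fa <- write_assembly(assembly, config$workdir)
  structure(list(contigs = assembly$contigs,
                 provenance = assembly$provenance,
                 counts = counts, assembly_fasta = fa,
                 config = config), class = "strainasm_run")
}

#' @export
print.strainasm_run <- function(x, ...) {
  cat("strainasm run\n")
  cat(sprintf("  reads:           %d\n", x$counts$reads))
  cat(sprintf("  overlaps:        %d\n", x$counts$overlaps))
  cat(sprintf("  clusters:        %d\n", x$counts$clusters))
  cat(sprintf("  cluster contigs: %d\n", x$counts$cluster_contigs))
  cat(sprintf("  master contigs:  %d\n", x$counts$master_contigs))
  cat(sprintf("  assembly:        %s\n", x$assembly_fasta))
  invisible(x)
}
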