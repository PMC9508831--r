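## Size-capped single-linkage read clustering. Overlaps are sorted from
## best to worst score (equivalently, ascending distance 1 - D) and merged
## in one pass with a union-find structure; a merge is refused when the
## united cluster would exceed the size cap, which is what makes the
## best-first processing order meaningful. Sorting dominates the cost;
## the union-find pass itself is near-linear.

#' Sort scored overlaps from best to worst
#'
#' Descending by score `D`; ties broken by higher identity, longer
#' overlap, then lexicographic `(id_a, id_b)`. The sort is stable.
#'
#' @param scored a `scored_overlaps` data.frame.
#' @return the rows reordered, same class.
#' @export
sort_by_score <- function(scored) {
  ord <- order(-scored$D, -scored$i, -scored$o, scored$id_a, scored$id_b,
               method = "radix")
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-pass size-capped single-linkage clustering
#'
#' Processes the pre-sorted overlaps from best to worst; for each overlap
#' `(a, b)` the two clusters are united unless they are already one or
#' their combined size would exceed `max_size`. Reads appearing in no
#' retained overlap become singletons. With `max_size = Inf` the result
#' equals the connected components of the filtered overlap graph.
#'
#' @param ordered a `scored_overlaps` data.frame sorted descending by `D`
#'   (as produced by [sort_by_score()]); an increasing score is a hard
#'   error.
#' @param read_ids character vector of all read ids (the clustering
#'   universe, including reads without overlaps).
#' @param max_size cluster size cap in reads (default 3000; `Inf` for
#'   uncapped).
#' @return a `cluster_set`: list with `assignments` (named integer vector,
#'   dense cluster ids from 0 in order of first appearance), `clusters`
#'   (list of member id vectors named by cluster id), `max_size` and
#'   `n_singletons`.
#' @export
single_linkage_cluster <- function(ordered, read_ids, max_size = 3000L) {
  if (nrow(ordered) > 1L && any(diff(ordered$D) > 1e-12))
    stopf("overlaps are not sorted by descending score (row %d increases)",
          which(diff(ordered$D) > 1e-12)[1] + 1L)
  read_ids <- as.character(read_ids)
  if (anyDuplicated(read_ids)) stopf("read ids must be unique")
  ia <- match(ordered$id_a, read_ids)
  ib <- match(ordered$id_b, read_ids)
  if (anyNA(ia) || anyNA(ib))
    stopf("overlap references read id absent from `read_ids`")
  cap <- if (is.finite(max_size)) as.integer(max_size) else -1L
  comp <- cpp_union_find(length(read_ids), ia, ib, cap)
  cl <- comp - 1L  # dense ids from 0, by first appearance
  assignments <- setNames(cl, read_ids)
  clusters <- split(read_ids, cl)
  structure(list(assignments = assignments, clusters = clusters,
                 max_size = max_size,
                 n_singletons = sum(lengths(clusters) == 1L)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf(paste0("cluster_set: %d reads in %d clusters ",
                     "(%d singletons, largest %d, cap %s)\n"),
              length(x$assignments), length(x$clusters), x$n_singletons,
              if (length(sz)) max(sz) else 0L,
              if (is.finite(x$max_size)) x$max_size else "none"))
  invisible(x)
}

#' Write per-cluster read FASTA files and a manifest
#'
#' Clusters with at least `min_cluster_size` reads are written to
#' `cluster_<id>.fasta`; smaller clusters and singletons are routed to an
#' `unclustered.fasta` pool (excluded from local assembly but retained
#' for reporting). A manifest TSV (`cluster_id`, `n_reads`) and a read
#' assignment TSV (`read_id`, `cluster_id`) are written alongside.
#'
#' @param clusters a `cluster_set`.
#' @param reads a [read_set()] containing every assigned read.
#' @param outdir output directory (created if needed).
#' @param min_cluster_size minimum reads for assembly eligibility
#'   (default 3).
#' @return the manifest data.frame, invisibly.
#' @export
emit_cluster_reads <- function(clusters, reads, outdir,
                               min_cluster_size = 3L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  missing <- setdiff(names(clusters$assignments), reads$id)
  if (length(missing))
    stopf("read '%s' assigned to a cluster but absent from the read store",
          missing[1])
  seqs <- setNames(reads$seq, reads$id)
  eligible <- names(clusters$clusters)[lengths(clusters$clusters) >=
                                         min_cluster_size]
  manifest <- data.frame(cluster_id = integer(0), n_reads = integer(0))
  unclustered <- character(0)
  for (cid in names(clusters$clusters)) {
    members <- clusters$clusters[[cid]]
    if (cid %in% eligible) {
      write_fasta(seqs[members],
                  file.path(outdir, sprintf("cluster_%s.fasta", cid)))
      manifest <- rbind(manifest,
                        data.frame(cluster_id = as.integer(cid),
                                   n_reads = length(members)))
    } else {
      unclustered <- c(unclustered, members)
    }
  }
  write_fasta(seqs[unclustered], file.path(outdir, "unclustered.fasta"))
  manifest <- manifest[order(manifest$cluster_id), , drop = FALSE]
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  assign_tab <- data.frame(read_id = names(clusters$assignments),
                           cluster_id = unname(clusters$assignments))
  write.table(assign_tab, file.path(outdir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
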