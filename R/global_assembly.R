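## Global assembly: cluster contigs are collected into a master overlap
## graph (edges: dovetail overlaps > 100 bp at identity >= 0.99),
## transitive edges are removed, branches are identified from read
## support at the contig junctions, and contigs are merged along unique
## (branch-free) paths only, iterating until no further merge occurs.
## Branches are never resolved: extension stops there, which is what
## keeps master contigs free of cross-strain joins.

#' Global assembly parameters
#'
#' @param min_ovlen_gt master-graph edges require an overlap strictly
#'   greater than this many bp (default 100).
#' @param min_identity master-graph edges require at least this overlap
#'   identity (default 0.99, inclusive).
#' @param min_span_reads minimum junction-spanning reads or read pairs
#'   for an edge to count as read-supported (default 3).
#' @param map_identity minimum identity for a read-to-junction alignment
#'   (default 0.98).
#' @param trans_tol_bp,trans_tol_frac layout tolerance when testing a
#'   candidate transitive edge: offsets must agree within
#'   `trans_tol_bp + trans_tol_frac * span` (defaults 3 bp + 2%%);
#'   needed because contig overlaps may contain small discrepancies.
#' @param junction_flank bp of flanking sequence on each side of a
#'   junction used for read mapping (default 350).
#' @param junction_margin bp a spanning alignment must extend past the
#'   overlap region on both sides (default 25).
#' @param support_max_mismatch maximum mismatches for a read block to
#'   count as junction support (default 1). Reads from the correct
#'   continuation align near-perfectly, while reads bridging a
#'   sibling-strain junction carry systematic SNP mismatches; counting
#'   only near-perfect blocks keeps such junctions unsupported.
#' @param max_global_iterations cap on extend/re-detect rounds
#'   (default 10).
#' @param branch_compete_ovlen minimum overlap length (bp) at which a
#'   second outgoing continuation counts as a competing branch
#'   (default 30). Master-graph edges themselves require an overlap
#'   > `min_ovlen_gt`, but a competing continuation overlapping by
#'   less than that still signals an ambiguous junction, and extension
#'   must stop there rather than pick a side.
#' @param drop_contained_identity contained contigs at or above this
#'   identity to their container are treated as fully represented and
#'   dropped from the output (default 0.999).
#' @param seed_k,window,max_occ minimizer settings (see
#'   [overlap_params()]).
#' @return a `global_params` list.
#' @export
global_params <- function(min_ovlen_gt = 100L, min_identity = 0.99,
                          min_span_reads = 3L, map_identity = 0.98,
                          trans_tol_bp = 3L, trans_tol_frac = 0.02,
                          junction_flank = 350L, junction_margin = 25L,
                          support_max_mismatch = 1L,
                          max_global_iterations = 10L,
                          branch_compete_ovlen = 30L,
                          drop_contained_identity = 0.999,
                          seed_k = 15L, window = 5L, max_occ = 1000L) {
  structure(list(
    min_ovlen_gt = check_count(min_ovlen_gt, "min_ovlen_gt"),
    min_identity = check_fraction(min_identity, "min_identity"),
    min_span_reads = check_count(min_span_reads, "min_span_reads"),
    map_identity = check_fraction(map_identity, "map_identity"),
    trans_tol_bp = check_count(trans_tol_bp, "trans_tol_bp"),
    trans_tol_frac = check_fraction(trans_tol_frac, "trans_tol_frac"),
    junction_flank = check_count(junction_flank, "junction_flank", 50L),
    junction_margin = check_count(junction_margin, "junction_margin"),
    support_max_mismatch = check_count(support_max_mismatch,
                                       "support_max_mismatch"),
    max_global_iterations = check_count(max_global_iterations,
                                        "max_global_iterations", 1L),
    branch_compete_ovlen = check_count(branch_compete_ovlen,
                                       "branch_compete_ovlen", 1L),
    drop_contained_identity = check_fraction(drop_contained_identity,
                                             "drop_contained_identity"),
    seed_k = check_count(seed_k, "seed_k", 4L),
    window = check_count(window, "window", 1L),
    max_occ = check_count(max_occ, "max_occ", 1L)
  ), class = "global_params")
}

global_overlap_params <- function(params) {
  overlap_params(min_ovlen = params$min_ovlen_gt + 1L,
                 min_identity = params$min_identity,
                 seed_k = params$seed_k, window = params$window,
                 max_occ = params$max_occ)
}

#' Build the master overlap graph over cluster contigs
#'
#' Vertices are contigs; edges are dovetail overlaps of length strictly
#' greater than `min_ovlen_gt` bp at identity at least `min_identity`.
#' Contained contigs are recorded and set aside from path extension.
#'
#' @param contigs data.frame with `id`, `seq` and optionally
#'   `mean_depth` columns (as produced by [assemble_cluster()]).
#' @param params a [global_params()].
#' @return a `master_graph`: list with `ids`, `seqs`, `depth`, `edges`
#'   (oriented edge table), `contained` (data.frame of containment
#'   records) and `branch_flags`.
#' @export
build_master_graph <- function(contigs, params = global_params()) {
  if (nrow(contigs) < 1L) stopf("at least one contig is required")
  ids <- contigs$id
  seqs <- contigs$seq
  depth <- if ("mean_depth" %in% names(contigs)) contigs$mean_depth
           else rep(1, length(ids))
  hits <- if (length(ids) >= 2L)
    score_overlaps(find_overlaps(setNames(seqs, ids),
                                 global_overlap_params(params),
                                 keep_cigar = FALSE))
  else score_overlaps(empty_hits(FALSE))
  edges <- graph_edges_from_hits(hits[hits$type %in% c("ab", "ba"), ,
                                      drop = FALSE], ids)
  cont <- hits[hits$type %in% c("b_in_a", "a_in_b"), , drop = FALSE]
  contained <- data.frame(
    child = ifelse(cont$type == "b_in_a", cont$id_b, cont$id_a),
    parent = ifelse(cont$type == "b_in_a", cont$id_a, cont$id_b),
    i = cont$i, stringsAsFactors = FALSE)
  g <- list(ids = ids, seqs = seqs, depth = depth, edges = edges,
            contained = contained,
            branch_flags = setNames(rep("clean", length(ids)), ids))
  class(g) <- "master_graph"
  g
}

#' @export
print.master_graph <- function(x, ...) {
  cat(sprintf(paste0("master_graph: %d contigs, %d oriented edges, ",
                     "%d containment records, %d branched\n"),
              length(x$ids), nrow(x$edges), nrow(x$contained),
              sum(x$branch_flags == "branched")))
  invisible(x)
}

#' Remove transitive edges from a master graph
#'
#' An edge `u -> w` is removed when consistent edges `u -> v` and
#' `v -> w` exist whose implied layout agrees with `u -> w` within
#' `trans_tol_bp + trans_tol_frac * span`. Mirror edges are removed
#' together; non-transitive edges are never touched.
#'
#' @param g a `master_graph` (or any graph with an oriented edge table).
#' @param params a [global_params()].
#' @return `g` with reduced `edges`.
#' @export
transitive_reduce <- function(g, params = global_params()) {
  e <- g$edges
  if (nrow(e) < 3L) return(g)
  key <- paste(e$from, e$to)
  shift_of <- setNames(e$shift, key)
  adj <- split(seq_len(nrow(e)), e$from)
  remove <- rep(FALSE, nrow(e))
  for (r in seq_len(nrow(e))) {
    u <- e$from[r]; w <- e$to[r]; s_uw <- e$shift[r]
    tol <- params$trans_tol_bp + params$trans_tol_frac * s_uw
    for (r2 in adj[[as.character(u)]]) {
      v <- e$to[r2]
      if (v == w || r2 == r) next
      s_uv <- e$shift[r2]
      if (s_uv >= s_uw) next  # v must lie between u and w in the layout
      s_vw <- shift_of[paste(v, w)]
      if (is.na(s_vw)) next
      if (abs(s_uv + s_vw - s_uw) <= tol) { remove[r] <- TRUE; break }
    }
  }
  ## remove mirrors together
  mkey <- paste(ov_flip(e$to), ov_flip(e$from))
  remove <- remove | mkey %in% key[remove]
  g$edges <- e[!remove, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

## Build one junction window per oriented edge; returns windows plus the
## in-window coordinates of the overlap region.
junction_windows <- function(g, params) {
  e <- g$edges
  if (nrow(e) == 0L)
    return(list(seq = character(0), u_only = integer(0),
                v_start = integer(0)))
  win <- character(nrow(e))
  u_only <- integer(nrow(e))
  v_start <- integer(nrow(e))
  for (r in seq_len(nrow(e))) {
    uv <- ov_vertex(e$from[r]) + 1L
    vv <- ov_vertex(e$to[r]) + 1L
    us <- if (ov_orient(e$from[r]) == 0L) g$seqs[uv] else revcomp(g$seqs[uv])
    vs <- if (ov_orient(e$to[r]) == 0L) g$seqs[vv] else revcomp(g$seqs[vv])
    lu <- nchar(us)
    o <- lu - e$shift[r]           # overlap length in the layout
    wu <- min(params$junction_flank + o, lu)
    tailu <- substr(us, lu - wu + 1L, lu)
    after <- substr(vs, o + 1L, min(nchar(vs), o + params$junction_flank))
    win[r] <- paste0(tailu, after)
    u_only[r] <- wu - o
    v_start[r] <- wu
  }
  list(seq = win, u_only = u_only, v_start = v_start)
}

#' Identify read-supported edges and branching vertices
#'
#' Reads are mapped to each edge's junction window (the contig overlap
#' plus flanking sequence). An edge is read-supported when at least
#' `min_span_reads` single reads span the whole overlap region (with
#' `junction_margin` bp to spare on both sides) or mate pairs bridge the
#' two contigs consistently. Unsupported edges are pruned, and a vertex
#' with two or more supported out-edges on one side is flagged branched.
#'
#' @param g a `master_graph`.
#' @param reads a [read_set()] used for junction support.
#' @param params a [global_params()].
#' @return `g` with pruned `edges`, per-edge `support` counts and updated
#'   `branch_flags`.
#' @export
detect_branches <- function(g, reads, params = global_params()) {
  e <- g$edges
  if (nrow(e) == 0L) return(g)
  jw <- junction_windows(g, params)
  blocks <- cpp_map_blocks(reads$seq, jw$seq, params$seed_k,
                           params$window, params$max_occ, 2L, 4L)
  support <- integer(nrow(e))
  if (nrow(blocks)) {
    blocks <- blocks[blocks$n_match / blocks$aln_len >=
                       params$map_identity &
                       blocks$aln_len - blocks$n_match <=
                       params$support_max_mismatch, , drop = FALSE]
  }
  if (nrow(blocks)) {
    m <- params$junction_margin
    stems <- sub("/[12]$", "", reads$id)
    for (r in seq_len(nrow(e))) {
      bl <- blocks[blocks$target == r, , drop = FALSE]
      if (nrow(bl) == 0L) next
      ov_s <- jw$u_only[r]
      ov_e <- jw$v_start[r]
      spans <- bl$t_start <= ov_s - m & bl$t_end >= ov_e + m
      n_single <- length(unique(bl$query[spans]))
      ## mate pairs bridging: one mate reaching into the contig-u flank,
      ## its (distinct) mate reaching into the contig-v flank
      left <- bl$t_start <= ov_s - m & !spans
      right <- bl$t_end >= ov_e + m & !spans
      lmap <- unique(data.frame(stem = stems[bl$query[left]],
                                q = bl$query[left]))
      rmap <- unique(data.frame(stem = stems[bl$query[right]],
                                q = bl$query[right]))
      br <- merge(lmap, rmap, by = "stem")
      n_pairs <- length(unique(br$stem[br$q.x != br$q.y]))
      support[r] <- n_single + n_pairs
    }
  }
  keep <- support >= params$min_span_reads
  g$edges <- e[keep, , drop = FALSE]
  g$edges$support <- support[keep]
  rownames(g$edges) <- NULL
  outdeg <- tabulate(g$edges$from + 1L, nbins = 2L * length(g$ids))
  branched <- unique(ov_vertex(which(outdeg >= 2L) - 1L)) + 1L
  g$branch_flags[] <- "clean"
  g$branch_flags[branched] <- "branched"
  g
}

#' Extend contigs along unique paths into master contigs
#'
#' Iterates transitive reduction, branch detection and unambiguous-path
#' merging until a pass makes no merge. Extension never crosses a
#' branched vertex; at merged overlaps, disagreeing columns are resolved
#' toward the deeper-supported contig. Contigs contained in others are
#' excluded from extension and appended to the output unless they are
#' fully represented by their container.
#'
#' @param g a `master_graph` from [build_master_graph()].
#' @param reads a [read_set()] for junction support (NULL skips branch
#'   detection, retaining every edge).
#' @param params a [global_params()].
#' @return list with `contigs` (data.frame `id`, `seq`, `length`,
#'   `n_sources`), `provenance` (data.frame `master_id`, `source_id`,
#'   `order`, `offset`, `orient`, `source_cluster`).
#' @export
extend_unique_paths <- function(g, reads = NULL,
                                params = global_params()) {
  ## set contained contigs aside
  dropped <- unique(g$contained$child[g$contained$i >=
                                        params$drop_contained_identity])
  aside <- setdiff(unique(g$contained$child), dropped)
  active <- !(g$ids %in% unique(g$contained$child))
  cur <- data.frame(id = g$ids[active], seq = g$seqs[active],
                    mean_depth = g$depth[active], stringsAsFactors = FALSE)
  sources <- setNames(lapply(cur$id, function(id)
    data.frame(source_id = id, order = 1L, offset = 0L, orient = 0L,
               stringsAsFactors = FALSE)), cur$id)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (nrow(cur) < 2L || iter > params$max_global_iterations) break
    mg <- build_master_graph(cur, params)
    mg <- transitive_reduce(mg, params)
    if (!is.null(reads)) mg <- detect_branches(mg, reads, params)
    ## competing continuations below the master edge threshold still
    ## make a junction ambiguous: with two distinct out-neighbours at
    ## any overlap length, extension stops instead of picking a side
    comp <- overlap_params(min_ovlen = params$branch_compete_ovlen,
                           min_identity = params$min_identity,
                           seed_k = params$seed_k,
                           window = params$window,
                           max_occ = params$max_occ)
    chits <- find_overlaps(setNames(cur$seq, cur$id), comp,
                           keep_cigar = FALSE)
    chits <- score_overlaps(chits)
    cedges <- graph_edges_from_hits(chits[chits$type %in% c("ab", "ba"), ,
                                          drop = FALSE], mg$ids)
    cdeg <- tabulate(cedges$from + 1L, nbins = 2L * length(mg$ids))
    ambiguous <- cdeg >= 2L
    if (nrow(mg$edges)) {
      keep <- !ambiguous[mg$edges$from + 1L] &
        !ambiguous[ov_flip(mg$edges$to) + 1L]
      mg$edges <- mg$edges[keep, , drop = FALSE]
      mg$branch_flags[unique(ov_vertex(which(ambiguous) - 1L)) + 1L] <-
        "branched"
    }
    ## reciprocal-best by identity, as in the local stage: an extension
    ## crossing a strain boundary carries SNP mismatches and loses to
    ## the exact within-strain alternative wherever one exists
    mg$edges <- prune_mutual_best(mg$edges)
    ## depth-weighted merge of unambiguous paths
    ## encode each contig's mean support depth as a per-base quality so
    ## that consensus ties at merged overlaps resolve toward the deeper
    ## contig
    depth_qual <- mapply(function(q, n) strrep(rawToChar(as.raw(q + 33L)), n),
                         pmin(93, pmax(1, round(cur$mean_depth))),
                         nchar(cur$seq))
    gg <- structure(list(ids = mg$ids, seqs = mg$seqs,
                         quals = depth_qual,
                         support = lapply(seq_along(mg$ids), function(j)
                           data.frame(read_id = mg$ids[j], offset = 0L,
                                      orient = 0L,
                                      len = nchar(mg$seqs[j]),
                                      stringsAsFactors = FALSE)),
                         edges = mg$edges, generation = iter),
                    class = "overlap_graph")
    store <- data.frame(id = cur$id, seq = cur$seq, qual = depth_qual,
                        stringsAsFactors = FALSE)
    mres <- merge_unambiguous_paths(gg, reads = store,
                                    min_read_identity = 0.9)
    if (mres$n_merged == 0L) break
    ## carry provenance and depth through the merge
    new_sources <- list()
    new_depth <- numeric(nrow(mres$vertices))
    for (j in seq_len(nrow(mres$vertices))) {
      nid <- mres$vertices$id[j]
      sup <- mres$support[[nid]]
      src <- do.call(rbind, lapply(seq_len(nrow(sup)), function(k) {
        s0 <- sources[[sup$read_id[k]]]
        if (sup$orient[k] == 1L) {
          lv <- nchar(cur$seq[cur$id == sup$read_id[k]])
          s0$offset <- sup$offset[k] + (lv - (s0$offset +
            vapply(s0$source_id, function(sid)
              nchar(g$seqs[g$ids == sid]), integer(1))))
          s0$orient <- 1L - s0$orient
        } else {
          s0$offset <- s0$offset + sup$offset[k]
        }
        s0
      }))
      src <- src[order(src$offset), , drop = FALSE]
      src$order <- seq_len(nrow(src))
      new_sources[[nid]] <- src
      w <- vapply(sup$read_id, function(rid)
        cur$mean_depth[cur$id == rid] *
          nchar(cur$seq[cur$id == rid]), numeric(1))
      new_depth[j] <- sum(w) / nchar(mres$vertices$seq[j])
    }
    sources <- new_sources
    cur <- data.frame(id = mres$vertices$id, seq = mres$vertices$seq,
                      mean_depth = new_depth, stringsAsFactors = FALSE)
    ## stable final naming happens below; internal sr ids stay unique
  }

  ## append set-aside contained contigs that are not fully represented
  if (length(aside)) {
    idx <- match(aside, g$ids)
    cur <- rbind(cur, data.frame(id = aside, seq = g$seqs[idx],
                                 mean_depth = g$depth[idx],
                                 stringsAsFactors = FALSE))
    for (id in aside)
      sources[[id]] <- data.frame(source_id = id, order = 1L,
                                  offset = 0L, orient = 0L,
                                  stringsAsFactors = FALSE)
  }
  ord <- order(-nchar(cur$seq), cur$id, method = "radix")
  cur <- cur[ord, , drop = FALSE]
  out_ids <- sprintf("master_%d", seq_len(nrow(cur)))
  prov <- do.call(rbind, lapply(seq_len(nrow(cur)), function(j) {
    src <- sources[[cur$id[j]]]
    data.frame(master_id = out_ids[j], source_id = src$source_id,
               order = src$order, offset = src$offset,
               orient = src$orient,
               source_cluster = sub("^(cluster[0-9]+).*", "\\1",
                                    src$source_id),
               stringsAsFactors = FALSE)
  }))
  contigs <- data.frame(id = out_ids, seq = cur$seq,
                        length = nchar(cur$seq),
                        n_sources = vapply(cur$id, function(id)
                          nrow(sources[[id]]), integer(1)),
                        stringsAsFactors = FALSE)
  rownames(contigs) <- NULL
  list(contigs = contigs, provenance = prov)
}

#' Write a final assembly and its report
#'
#' @param assembly list from [extend_unique_paths()] (or any data.frame
#'   of contigs with `id`, `seq`).
#' @param dir output directory; writes `assembly.fasta`, `report.tsv`
#'   (contig, length, n_sources) and `provenance.tsv`.
#' @return the FASTA path, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- if (is.data.frame(assembly)) assembly else assembly$contigs
  n_sources <- if ("n_sources" %in% names(contigs)) contigs$n_sources
               else rep(1L, nrow(contigs))
  hdr <- sprintf("%s len=%d n_sources=%d", contigs$id,
                 nchar(contigs$seq), n_sources)
  fa <- file.path(dir, "assembly.fasta")
  write_fasta(setNames(contigs$seq, gsub("\\s+", "_", hdr)), fa)
  write.table(data.frame(contig = contigs$id, length = nchar(contigs$seq),
                         n_sources = n_sources),
              file.path(dir, "report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.data.frame(assembly) && !is.null(assembly$provenance))
    write.table(assembly$provenance, file.path(dir, "provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fa)
}
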