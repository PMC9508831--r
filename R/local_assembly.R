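## Per-cluster strain-aware assembly via an iterative overlap graph.
##
## Each iteration (i) recomputes dovetail overlaps among the current
## vertices at strict identity, (ii) absorbs contained vertices into their
## best container, (iii) prunes dovetail edges to reciprocal best
## overlaps (the highest-scoring out-edge of u kept only when it is also
## the highest-scoring in-edge of v), (iv) collapses unambiguous paths
## into quality-weighted consensus super-reads, and repeats to fixpoint.
## The strict identity threshold plus best-overlap reciprocity is the
## strain-separation mechanism: an overlap crossing a strain boundary
## carries SNP mismatches, scores below the within-strain alternative,
## and loses the reciprocal-best competition; remaining ambiguities
## surface as branches, which terminate paths instead of being resolved.

#' Local assembly parameters
#'
#' @param local_min_identity minimum overlap identity within a cluster
#'   (default 0.99; strict enough that one mismatch in a ~100 bp short
#'   read overlap breaks the edge).
#' @param local_min_ovlen minimum overlap length in bp (default 30).
#' @param max_iterations iteration cap for the merge loop (default 20).
#' @param min_contig_out minimum emitted contig length in bp (default 300).
#' @param min_read_identity a merged path is rejected when any supporting
#'   read aligns to the consensus below this identity (default 0.9).
#' @param merge_min_ovlen minimum overlap length for an edge to be a
#'   path-extension candidate (default 150 bp). Edges shorter than the
#'   typical inter-SNP gap could join strains through locally identical
#'   windows; requiring most of a read length keeps at least one
#'   discriminating position inside every candidate overlap whenever
#'   SNP gaps are shorter than the read length.
#' @param absorb_min_identity minimum containment identity for absorbing
#'   a contained vertex during the merge iterations (default 0.995).
#'   Stricter than the edge threshold: a containment spanning two or
#'   more strain-distinguishing positions stays unabsorbed rather than
#'   joining the wrong strain early; leftovers are recovered by the
#'   final sweep once deep containers exist on both strains.
#' @param final_absorb_identity after the merge loop, residual shallow
#'   vertices (reads whose own sequencing errors kept them below the
#'   strict threshold) are absorbed into deep consensus contigs at this
#'   relaxed containment identity; the deep majority outvotes their
#'   errors (default 0.97).
#' @param min_depth_deep minimum mean depth for a contig to act as an
#'   absorbing container in the final sweep (default 3).
#' @param end_trim_depth emitted contigs are trimmed to the maximal span
#'   supported by at least this many reads (default 2): a lone read's
#'   overhang is not a consensus and carries that read's raw errors.
#' @param seed_k,window,max_occ minimizer seeding settings (see
#'   [overlap_params()]).
#' @return a `local_params` list.
#' @export
local_params <- function(local_min_identity = 0.99, local_min_ovlen = 30L,
                         max_iterations = 20L, min_contig_out = 300L,
                         min_read_identity = 0.9,
                         merge_min_ovlen = 150L,
                         absorb_min_identity = 0.995,
                         final_absorb_identity = 0.97,
                         min_depth_deep = 3L, end_trim_depth = 2L,
                         seed_k = 15L,
                         window = 5L, max_occ = 500L) {
  structure(list(
    local_min_identity = check_fraction(local_min_identity,
                                        "local_min_identity"),
    local_min_ovlen = check_count(local_min_ovlen, "local_min_ovlen", 1L),
    max_iterations = check_count(max_iterations, "max_iterations", 1L),
    min_contig_out = check_count(min_contig_out, "min_contig_out", 1L),
    min_read_identity = check_fraction(min_read_identity,
                                       "min_read_identity"),
    merge_min_ovlen = check_count(merge_min_ovlen, "merge_min_ovlen", 1L),
    absorb_min_identity = check_fraction(absorb_min_identity,
                                         "absorb_min_identity"),
    final_absorb_identity = check_fraction(final_absorb_identity,
                                           "final_absorb_identity"),
    min_depth_deep = check_count(min_depth_deep, "min_depth_deep", 1L),
    end_trim_depth = check_count(end_trim_depth, "end_trim_depth", 1L),
    seed_k = check_count(seed_k, "seed_k", 4L),
    window = check_count(window, "window", 1L),
    max_occ = check_count(max_occ, "max_occ", 1L)
  ), class = "local_params")
}

local_overlap_params <- function(params) {
  overlap_params(min_ovlen = params$local_min_ovlen,
                 min_identity = params$local_min_identity,
                 seed_k = params$seed_k, window = params$window,
                 max_occ = params$max_occ)
}

## oriented-vertex encoding: state = 2 * vertex_index + orientation
ov_enc <- function(v, o) 2L * v + o
ov_flip <- function(s) bitwXor(s, 1L)
ov_vertex <- function(s) s %/% 2L
ov_orient <- function(s) s %% 2L

## Directed oriented edge table from dovetail hits (both directions per
## hit). `shift` is the start of the oriented `to` vertex in the frame of
## the oriented `from` vertex.
oriented_edges <- function(hits, vidx_a, vidx_b) {
  if (nrow(hits) == 0L)
    return(data.frame(from = integer(0), to = integer(0),
                      shift = integer(0), o = integer(0),
                      i = numeric(0), D = numeric(0)))
  s <- ifelse(hits$strand == "same", 0L, 1L)
  d <- hits$offset
  ab <- hits$type == "ab"
  ba <- hits$type == "ba"
  D <- hits$D
  i <- hits$i
  o <- hits$o
  la <- hits$len_a
  lb <- hits$len_b
  e1 <- data.frame(
    from = ifelse(ab, ov_enc(vidx_a, 0L), ov_enc(vidx_b, s)),
    to = ifelse(ab, ov_enc(vidx_b, s), ov_enc(vidx_a, 0L)),
    shift = ifelse(ab, d, -d),
    o = o, i = i, D = D)
  ## mirror: flip(to) -> flip(from)
  e2 <- data.frame(
    from = ov_flip(e1$to), to = ov_flip(e1$from),
    shift = ifelse(ab, d + lb - la, -d + la - lb),
    o = o, i = i, D = D)
  keep <- ab | ba
  rbind(e1[keep, , drop = FALSE], e2[keep, , drop = FALSE])
}

#' Build the overlap graph of one read cluster
#'
#' Vertices are the cluster sequences; edges are the dovetail overlaps
#' passing the local thresholds, oriented (each overlap contributes a
#' directed edge and its mirror on the reverse-complement side). At most
#' one edge is kept per ordered vertex pair: conflicting orientations are
#' resolved by discarding the lower-scoring edge. Containments are
#' recorded separately.
#'
#' @param seqs named character vector of cluster sequences (>= 3).
#' @param params a [local_params()].
#' @param quals optional named character vector of Phred+33 strings.
#' @return an `overlap_graph`: list with `ids`, `seqs`, `quals`,
#'   `support` (per-vertex read layout), `edges` (oriented edge table),
#'   `containments`, and `generation`.
#' @export
build_cluster_graph <- function(seqs, params = local_params(),
                                quals = NULL) {
  if (length(seqs) < 3L) stopf("a cluster graph needs >= 3 sequences")
  ids <- names(seqs)
  support <- lapply(seq_along(ids), function(j)
    data.frame(read_id = ids[j], offset = 0L, orient = 0L,
               len = nchar(seqs[[j]]), stringsAsFactors = FALSE))
  g <- list(ids = ids, seqs = unname(as.character(seqs)),
            quals = if (is.null(quals)) rep(NA_character_, length(ids))
                    else unname(quals[ids]),
            support = support, generation = 0L)
  hits <- find_overlaps(setNames(g$seqs, ids),
                        local_overlap_params(params), keep_cigar = FALSE)
  hits <- score_overlaps(hits)
  g$edges <- graph_edges_from_hits(hits, ids)
  g$containments <- hits[hits$type %in% c("b_in_a", "a_in_b"), ,
                         drop = FALSE]
  class(g) <- "overlap_graph"
  g
}

graph_edges_from_hits <- function(hits, ids) {
  va <- match(hits$id_a, ids) - 1L
  vb <- match(hits$id_b, ids) - 1L
  e <- oriented_edges(hits, va, vb)
  if (nrow(e) == 0L) return(e)
  ## one edge per ordered oriented pair: keep the best score
  ord <- order(e$from, e$to, -e$D, -e$o, method = "radix")
  e <- e[ord, , drop = FALSE]
  e <- e[!duplicated(e[c("from", "to")]), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d vertices, %d oriented edges (gen %d)\n",
              length(x$ids), nrow(x$edges), x$generation))
  invisible(x)
}

## Reciprocal-best pruning of the oriented edge table. Candidate
## extensions are ranked by identity first, then overlap length: within a
## strain overlaps are (after consensus correction) exact, while an
## overlap crossing a strain boundary carries SNP mismatches, so the
## identity-first ranking is what separates strains.
prune_mutual_best <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  ord <- order(edges$from, -edges$i, -edges$o, edges$to, method = "radix")
  e <- edges[ord, , drop = FALSE]
  best <- e[!duplicated(e$from), , drop = FALSE]
  best_to <- setNames(best$to, best$from)
  keep <- !is.na(best_to[as.character(ov_flip(best$to))]) &
    best_to[as.character(ov_flip(best$to))] == ov_flip(best$from)
  out <- best[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quality-weighted consensus of a read layout
#'
#' Builds a consensus sequence from reads placed on a common coordinate
#' frame: per column, a majority vote weighted by Phred quality; ties are
#' broken toward the base carried at the highest single quality. When any
#' supporting read aligns to the consensus below `min_read_identity` the
#' layout is considered inconsistent and `NULL` is returned.
#'
#' @param support data.frame with `read_id`, `offset`, `orient`
#'   (0 forward / 1 reverse) on a common frame.
#' @param reads a [read_set()] (or data.frame with `id`, `seq`, `qual`)
#'   supplying the sequences and qualities.
#' @param min_read_identity consistency threshold (default 0.9).
#' @return list with `seq`, `depth` (per-base supporting-read count) and
#'   the normalized `support` table, or `NULL` when rejected.
#' @export
consensus_super_read <- function(support, reads, min_read_identity = 0.9) {
  idx <- match(support$read_id, reads$id)
  if (anyNA(idx)) stopf("support references unknown read '%s'",
                        support$read_id[which(is.na(idx))[1]])
  support$offset <- support$offset - min(support$offset)
  res <- cpp_consensus(reads$seq[idx], reads$qual[idx],
                       as.integer(support$offset),
                       as.integer(support$orient))
  for (r in seq_len(nrow(support))) {
    v <- cpp_verify_pair(res$seq, reads$seq[idx[r]], support$orient[r],
                         support$offset[r])
    if (v$o == 0L || v$n_match / v$o < min_read_identity) return(NULL)
  }
  list(seq = res$seq, depth = res$depth, support = support)
}

## transform a support table into the frame of a chain/parent placement:
## the vertex (length len_v) sits at `at` with relative orientation `flip`
shift_support <- function(sup, at, flip, len_v) {
  if (flip == 1L) {
    sup$offset <- at + (len_v - (sup$offset + sup$len))
    sup$orient <- 1L - sup$orient
  } else {
    sup$offset <- at + sup$offset
  }
  sup
}

#' Merge unambiguous paths of an overlap graph into super-reads
#'
#' Maximal paths whose edges connect an unambiguous out-side to an
#' unambiguous in-side (out-degree 1 at the tail, in-degree 1 at the
#' head, on the oriented graph) are collapsed into consensus super-reads;
#' branching vertices terminate paths and isolated vertices pass through
#' as singleton super-reads. A path whose reads are inconsistent with the
#' consensus is rejected and its vertices returned unmerged.
#'
#' @param g an `overlap_graph` (its `edges` decide ambiguity; callers may
#'   prune them first).
#' @param reads read store for consensus (defaults to the graph's own
#'   vertices).
#' @param min_read_identity see [consensus_super_read()].
#' @return list with `vertices` (data.frame `id`, `seq`), `support`
#'   (per-vertex layout tables), `n_merged` (vertices consumed by merges)
#'   and `chains` (the merged vertex paths).
#' @export
merge_unambiguous_paths <- function(g, reads = NULL,
                                    min_read_identity = 0.9) {
  nv <- length(g$ids)
  if (is.null(reads))
    reads <- data.frame(id = g$ids, seq = g$seqs, qual = g$quals,
                        stringsAsFactors = FALSE)
  e <- g$edges
  outdeg <- tabulate(e$from + 1L, nbins = 2L * nv)
  indeg <- tabulate(e$to + 1L, nbins = 2L * nv)
  trav <- e[outdeg[e$from + 1L] == 1L & indeg[e$to + 1L] == 1L, ,
            drop = FALSE]
  nxt <- rep(NA_integer_, 2L * nv)
  shift_of <- rep(NA_integer_, 2L * nv)
  nxt[trav$from + 1L] <- trav$to
  shift_of[trav$from + 1L] <- trav$shift
  has_in <- rep(FALSE, 2L * nv)
  has_in[trav$to + 1L] <- TRUE

  visited <- rep(FALSE, nv)
  chains <- list()
  starts <- which(!is.na(nxt) & !has_in) - 1L
  starts <- starts[order(starts)]
  for (s in starts) {
    if (visited[ov_vertex(s) + 1L]) next
    chain_v <- s
    shifts <- integer(0)
    cur <- s
    while (!is.na(nxt[cur + 1L])) {
      nx <- nxt[cur + 1L]
      if (visited[ov_vertex(nx) + 1L]) break
      shifts <- c(shifts, shift_of[cur + 1L])
      chain_v <- c(chain_v, nx)
      cur <- nx
    }
    visited[ov_vertex(chain_v) + 1L] <- TRUE
    if (length(chain_v) > 1L)
      chains[[length(chains) + 1L]] <- list(states = chain_v,
                                            shifts = shifts)
  }
  ## cycles: any unvisited vertex that still has a traversable out-edge
  repeat {
    rem <- which(!visited)
    rem_states <- c(ov_enc(rem - 1L, 0L), ov_enc(rem - 1L, 1L))
    cyc <- rem_states[!is.na(nxt[rem_states + 1L])]
    if (length(cyc) == 0L) break
    s <- min(cyc)
    chain_v <- s
    shifts <- integer(0)
    cur <- s
    while (!is.na(nxt[cur + 1L])) {
      nx <- nxt[cur + 1L]
      if (ov_vertex(nx) %in% ov_vertex(chain_v)) break
      if (visited[ov_vertex(nx) + 1L]) break
      shifts <- c(shifts, shift_of[cur + 1L])
      chain_v <- c(chain_v, nx)
      cur <- nx
    }
    visited[ov_vertex(chain_v) + 1L] <- TRUE
    if (length(chain_v) > 1L)
      chains[[length(chains) + 1L]] <- list(states = chain_v,
                                            shifts = shifts)
  }

  new_ids <- character(0)
  new_seqs <- character(0)
  new_support <- list()
  merged <- rep(FALSE, nv)
  n_merged <- 0L
  chain_paths <- list()
  for (ch in chains) {
    vs <- ov_vertex(ch$states)
    os <- ov_orient(ch$states)
    at <- cumsum(c(0L, ch$shifts))
    sup <- do.call(rbind, lapply(seq_along(vs), function(j) {
      shift_support(g$support[[vs[j] + 1L]], at[j], os[j],
                    nchar(g$seqs[vs[j] + 1L]))
    }))
    cons <- consensus_super_read(sup, reads, min_read_identity)
    if (is.null(cons)) next  # inconsistent layout: leave unmerged
    merged[vs + 1L] <- TRUE
    n_merged <- n_merged + length(vs)
    nid <- sprintf("sr%d_%d", g$generation + 1L, length(new_ids) + 1L)
    new_ids <- c(new_ids, nid)
    new_seqs <- c(new_seqs, cons$seq)
    new_support[[length(new_support) + 1L]] <- cons$support
    chain_paths[[length(chain_paths) + 1L]] <- g$ids[vs + 1L]
  }
  for (v in which(!merged)) {
    new_ids <- c(new_ids, g$ids[v])
    new_seqs <- c(new_seqs, g$seqs[v])
    new_support[[length(new_support) + 1L]] <- g$support[[v]]
  }
  list(vertices = data.frame(id = new_ids, seq = new_seqs,
                             stringsAsFactors = FALSE),
       support = setNames(new_support, new_ids),
       n_merged = n_merged, chains = chain_paths)
}

## Absorb contained vertices into their best container; returns updated
## support list and the logical vector of absorbed vertices.
absorb_containments <- function(g, hits) {
  nv <- length(g$ids)
  cont <- hits[hits$type %in% c("b_in_a", "a_in_b"), , drop = FALSE]
  absorbed <- rep(FALSE, nv)
  gained <- rep(FALSE, nv)
  if (nrow(cont) == 0L)
    return(list(support = g$support, absorbed = absorbed,
                gained = gained, n = 0L))
  va <- match(cont$id_a, g$ids) - 1L
  vb <- match(cont$id_b, g$ids) - 1L
  s <- ifelse(cont$strand == "same", 0L, 1L)
  d <- cont$offset
  b_in_a <- cont$type == "b_in_a"
  child <- ifelse(b_in_a, vb, va)
  parent <- ifelse(b_in_a, va, vb)
  la <- cont$len_a
  lb <- cont$len_b
  ## placement of the child in the parent frame
  par_off <- ifelse(b_in_a, d, ifelse(s == 0L, -d, lb + d - la))
  flip <- s
  cand <- data.frame(child = child, parent = parent, par_off = par_off,
                     flip = flip, i = cont$i, D = cont$D)
  ## best container per child; for equal-length mutual containments the
  ## smaller vertex index acts as container (drop the reverse direction)
  eq_len <- nchar(g$seqs[cand$child + 1L]) ==
    nchar(g$seqs[cand$parent + 1L])
  cand <- cand[!(eq_len & cand$child < cand$parent), , drop = FALSE]
  cand <- cand[order(cand$child, -cand$i, -cand$D, cand$parent,
                     method = "radix"), , drop = FALSE]
  cand <- cand[!duplicated(cand$child), , drop = FALSE]
  link <- rep(NA_integer_, nv)
  link_off <- rep(0L, nv)
  link_flip <- rep(0L, nv)
  link[cand$child + 1L] <- cand$parent
  link_off[cand$child + 1L] <- cand$par_off
  link_flip[cand$child + 1L] <- cand$flip
  support <- g$support
  n <- 0L
  for (c0 in cand$child) {
    ## resolve the final (un-absorbed) ancestor, transforming the child's
    ## support table stepwise through each containment placement
    v <- c0
    seen <- c0
    sup <- support[[c0 + 1L]]
    ok <- TRUE
    while (!is.na(link[v + 1L])) {
      p <- link[v + 1L]
      if (p %in% seen) { ok <- FALSE; break }
      sup <- shift_support(sup, link_off[v + 1L], link_flip[v + 1L],
                           nchar(g$seqs[v + 1L]))
      seen <- c(seen, p)
      v <- p
    }
    if (!ok || v == c0) next
    support[[v + 1L]] <- rbind(support[[v + 1L]], sup)
    absorbed[c0 + 1L] <- TRUE
    gained[v + 1L] <- TRUE
    n <- n + 1L
  }
  list(support = support, absorbed = absorbed, gained = gained, n = n)
}

#' Assemble one read cluster into strain-aware contigs
#'
#' Iterates overlap-graph construction, containment absorption,
#' reciprocal-best edge pruning, unambiguous-path merging and consensus
#' until no merge occurs or `max_iterations` is reached, then emits the
#' contigs of at least `min_contig_out` bp together with per-contig read
#' support. Clusters of fewer than 3 reads are skipped.
#'
#' @param reads a [read_set()] holding the cluster's reads.
#' @param params a [local_params()].
#' @param contig_prefix prefix for contig ids (default `"ctg"`).
#' @return list with `contigs` (data.frame `id`, `seq`, `length`,
#'   `mean_depth`), `support` (data.frame `contig_id`, `read_id`,
#'   `offset`, `orient`) and `unplaced` (read ids not in any emitted
#'   contig's support).
#' @export
assemble_cluster <- function(reads, params = local_params(),
                             contig_prefix = "ctg") {
  empty <- list(contigs = data.frame(id = character(0), seq = character(0),
                                     length = integer(0),
                                     mean_depth = numeric(0),
                                     stringsAsFactors = FALSE),
                support = data.frame(contig_id = character(0),
                                     read_id = character(0),
                                     offset = integer(0),
                                     orient = integer(0),
                                     stringsAsFactors = FALSE),
                unplaced = reads$id)
  if (nrow(reads) < 3L) return(empty)
  store <- data.frame(id = reads$id, seq = reads$seq, qual = reads$qual,
                      stringsAsFactors = FALSE)
  ids <- reads$id
  seqs <- reads$seq
  support <- setNames(lapply(seq_along(ids), function(j)
    data.frame(read_id = ids[j], offset = 0L, orient = 0L,
               len = nchar(seqs[j]), stringsAsFactors = FALSE)), ids)

  oparams <- local_overlap_params(params)
  for (iter in seq_len(params$max_iterations)) {
    if (length(ids) < 2L) break
    hits <- find_overlaps(setNames(seqs, ids), oparams, keep_cigar = FALSE)
    hits <- score_overlaps(hits)
    g <- structure(list(ids = ids, seqs = seqs,
                        quals = rep(NA_character_, length(ids)),
                        support = unname(support), generation = iter),
                   class = "overlap_graph")
    ab <- absorb_containments(g, hits[hits$i >=
                                        params$absorb_min_identity, ,
                                      drop = FALSE])
    ## refresh consensus of vertices that gained contained reads (their
    ## layout coordinates are unchanged, only the votes deepen)
    for (v in which(ab$gained & !ab$absorbed)) {
      cons <- consensus_super_read(ab$support[[v]], store,
                                   params$min_read_identity)
      if (!is.null(cons)) {
        seqs[v] <- cons$seq
        ab$support[[v]] <- cons$support
      }
    }
    keep_v <- !ab$absorbed
    ids <- ids[keep_v]
    seqs <- seqs[keep_v]
    support <- setNames(ab$support[keep_v], ids)
    ## rebuild edges on surviving vertices
    hits2 <- hits[hits$id_a %in% ids & hits$id_b %in% ids &
                    hits$type %in% c("ab", "ba"), , drop = FALSE]
    g2 <- structure(list(ids = ids, seqs = seqs,
                         quals = rep(NA_character_, length(ids)),
                         support = unname(support), generation = iter),
                    class = "overlap_graph")
    hits2 <- hits2[hits2$o >= params$merge_min_ovlen, , drop = FALSE]
    g2$edges <- prune_mutual_best(graph_edges_from_hits(hits2, ids))
    mg <- merge_unambiguous_paths(g2, reads = store,
                                  min_read_identity =
                                    params$min_read_identity)
    ids <- mg$vertices$id
    seqs <- mg$vertices$seq
    support <- mg$support
    if (mg$n_merged == 0L && ab$n == 0L) break
  }

  ## final sweep: reads whose own errors kept them below the strict
  ## identity threshold linger as shallow vertices; absorb them into deep
  ## consensus contigs at relaxed identity (best container by identity,
  ## so a same-strain container still outranks a cross-strain one)
  depth <- vapply(seq_along(ids), function(v)
    sum(support[[v]]$len) / nchar(seqs[v]), numeric(1))
  deep <- depth >= params$min_depth_deep &
    nchar(seqs) >= params$min_contig_out
  if (any(deep) && any(!deep)) {
    relax <- local_overlap_params(params)
    relax$min_identity <- params$final_absorb_identity
    hits <- score_overlaps(find_overlaps(setNames(seqs, ids), relax,
                                         keep_cigar = FALSE))
    cont <- hits[hits$type %in% c("b_in_a", "a_in_b"), , drop = FALSE]
    child <- ifelse(cont$type == "b_in_a", cont$id_b, cont$id_a)
    parent <- ifelse(cont$type == "b_in_a", cont$id_a, cont$id_b)
    ok <- !deep[match(child, ids)] & deep[match(parent, ids)]
    cont <- cont[ok, , drop = FALSE]
    if (nrow(cont)) {
      g <- structure(list(ids = ids, seqs = seqs,
                          quals = rep(NA_character_, length(ids)),
                          support = unname(support), generation = 99L),
                     class = "overlap_graph")
      ab <- absorb_containments(g, cont)
      for (v in which(ab$gained)) {
        cons <- consensus_super_read(ab$support[[v]], store,
                                     params$min_read_identity)
        if (!is.null(cons)) {
          seqs[v] <- cons$seq
          ab$support[[v]] <- cons$support
        }
      }
      keep_v <- !ab$absorbed
      ids <- ids[keep_v]
      seqs <- seqs[keep_v]
      support <- setNames(ab$support[keep_v], ids)
    }
  }

  ## trim termini to the >= end_trim_depth consensus region
  if (params$end_trim_depth > 1L) {
    for (v in seq_along(ids)) {
      sup <- support[[v]]
      n <- nchar(seqs[v])
      cover <- integer(n + 1L)
      lo <- pmax(sup$offset, 0L) + 1L
      hi <- pmin(sup$offset + sup$len, n)
      for (r in seq_len(nrow(sup))) {
        cover[lo[r]] <- cover[lo[r]] + 1L
        cover[hi[r] + 1L] <- cover[hi[r] + 1L] - 1L
      }
      depth_v <- cumsum(cover[seq_len(n)])
      okpos <- which(depth_v >= params$end_trim_depth)
      if (length(okpos) == 0L) { seqs[v] <- ""; next }
      s0 <- min(okpos); s1 <- max(okpos)
      if (s0 > 1L || s1 < n) {
        seqs[v] <- substr(seqs[v], s0, s1)
        sup$offset <- sup$offset - (s0 - 1L)
        support[[v]] <- sup
      }
    }
  }

  keep <- nchar(seqs) >= params$min_contig_out
  if (!any(keep)) return(empty)
  cids <- sprintf("%s%d", contig_prefix, seq_len(sum(keep)))
  sup_tab <- do.call(rbind, lapply(seq_along(which(keep)), function(j) {
    v <- which(keep)[j]
    s <- support[[v]]
    data.frame(contig_id = cids[j], read_id = s$read_id,
               offset = s$offset, orient = s$orient,
               stringsAsFactors = FALSE)
  }))
  placed <- unique(sup_tab$read_id)
  contigs <- data.frame(
    id = cids, seq = seqs[keep], length = nchar(seqs[keep]),
    mean_depth = vapply(which(keep), function(v)
      sum(support[[v]]$len) / nchar(seqs[v]), numeric(1)),
    stringsAsFactors = FALSE)
  list(contigs = contigs, support = sup_tab,
       unplaced = setdiff(reads$id, placed))
}
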