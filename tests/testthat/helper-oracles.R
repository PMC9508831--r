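## Shared fixtures and independent oracles. The oracles are deliberately
## naive (all-pairs, all-offsets, transitive closure) so they stay
## independent of the package's seeded/engineered code paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

const_qual <- function(n, q = 40L) strrep(rawToChar(as.raw(q + 33L)), n)

make_read_set <- function(seqs, prefix = "r", q = 40L) {
  read_set(sprintf("%s%03d", prefix, seq_along(seqs)), seqs,
           vapply(nchar(seqs), const_qual, character(1), q = q))
}

## uniform random reads from a genome, optional substitution errors
sim_cluster_reads <- function(genome, coverage, read_len = 250L,
                              label = "r", err = 0, qchar = "8") {
  n <- round(coverage * nchar(genome) / read_len)
  starts <- floor(runif(n, 0, nchar(genome) - read_len)) + 1L
  s <- substring(genome, starts, starts + read_len - 1L)
  if (err > 0) {
    s <- vapply(strsplit(s, ""), function(b) {
      flip <- runif(length(b)) < err
      b[flip] <- vapply(b[flip], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
      paste(b, collapse = "")
    }, character(1))
  }
  rs <- read_set(sprintf("%s_%04d", label, seq_len(n)), s,
                 vapply(nchar(s), function(k) strrep(qchar, k),
                        character(1)))
  attr(rs, "starts") <- starts
  rs
}

## brute-force all-pairs, all-offsets, both-strands gapless dovetail scan
brute_overlaps <- function(seqs, min_ov = 30L, min_id = 0.9) {
  ids <- names(seqs)
  res <- list()
  cmp <- function(a, b, d) {
    la <- nchar(a); lb <- nchar(b)
    a0 <- max(0L, d); a1 <- min(la, d + lb)
    if (a1 - a0 < min_ov) return(NULL)
    av <- strsplit(a, "")[[1]][(a0 + 1):a1]
    bv <- strsplit(b, "")[[1]][(a0 - d + 1):(a1 - d)]
    m <- sum(av == bv)
    o <- a1 - a0
    if (m / o < min_id) return(NULL)
    list(o = o, m = m, d = d)
  }
  for (x in seq_along(seqs)) for (y in seq_along(seqs)) {
    if (x >= y) next
    for (strand in c("same", "opposite")) {
      b <- if (strand == "same") seqs[[y]] else revcomp(seqs[[y]])
      la <- nchar(seqs[[x]]); lb <- nchar(b)
      best <- NULL
      for (d in seq(-(lb - min_ov), la - min_ov)) {
        h <- cmp(seqs[[x]], b, d)
        if (!is.null(h) && (is.null(best) || h$m > best$m)) best <- h
      }
      if (!is.null(best))
        res[[length(res) + 1L]] <- data.frame(
          id_a = ids[x], id_b = ids[y], strand = strand,
          o = best$o, n_match = best$m, offset = best$d,
          stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      strand = character(0), o = integer(0),
                      n_match = integer(0), offset = integer(0)))
  do.call(rbind, res)
}

## transitive closure (connected components) over an edge list
brute_components <- function(ids, a, b) {
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (k in seq_along(a)) {
      ca <- comp[a[k]]; cb <- comp[b[k]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

## O(E^2) transitive-reduction oracle on an oriented edge table
brute_transitive_edges <- function(edges, tol_bp = 3, tol_frac = 0.02) {
  removed <- rep(FALSE, nrow(edges))
  for (r in seq_len(nrow(edges))) {
    u <- edges$from[r]; w <- edges$to[r]; s_uw <- edges$shift[r]
    tol <- tol_bp + tol_frac * s_uw
    for (r2 in seq_len(nrow(edges))) {
      if (edges$from[r2] != u) next
      v <- edges$to[r2]
      if (v == w) next
      s_uv <- edges$shift[r2]
      if (s_uv >= s_uw) next
      for (r3 in seq_len(nrow(edges))) {
        if (edges$from[r3] != v || edges$to[r3] != w) next
        if (abs(s_uv + edges$shift[r3] - s_uw) <= tol) removed[r] <- TRUE
      }
    }
  }
  removed
}

brute_n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  total <- sum(lengths)
  best <- 0L
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= total / 2) best <- L
  }
  best
}

## haplotype purity of each contig's supporting reads, by id prefix
support_purity <- function(res, split_chars = 2L) {
  vapply(res$contigs$id, function(cid) {
    sup <- res$support[res$support$contig_id == cid, ]
    lab <- substr(sup$read_id, 1L, split_chars)
    max(table(lab)) / nrow(sup)
  }, numeric(1))
}
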