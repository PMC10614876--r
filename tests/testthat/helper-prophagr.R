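# shared test utilities: temp FASTA writer, random match instances, and
# an independent connected-components oracle for the joining step

options(prophagr.quiet = TRUE)

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

fixture_path <- function(name) test_path("fixtures", name)

# Random small match instances for property tests. Signatures (the
# coordinate tuples) are kept unique so partitions can be compared as
# multisets of sets. Half the time a match is placed "in series" after
# the previous one so that the joinable branch is exercised often.
random_matches <- function(n, qlen = 10000L) {
  targets <- sample(c("gA", "gB"), n, replace = TRUE)
  queries <- sample(c("p1", "p2"), n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rows <- vector("list", n)
  t_cursor <- 1L
  q_prev <- 1L
  for (i in seq_len(n)) {
    len <- sample(200:3000, 1L)
    t_start <- t_cursor + sample(0:2800, 1L)
    t_cursor <- t_start + len
    if (runif(1) < 0.5) {
      q_start <- min(qlen - len, max(1L, q_prev + sample(-80:400, 1L)))
    } else {
      q_start <- sample.int(qlen - len, 1L)
    }
    q_prev <- q_start + len
    rows[[i]] <- match_record(
      queries[i], qlen, targets[i],
      query_start = q_start, query_end = min(qlen, q_start + len - 1L),
      target_start = t_start, target_end = t_start + len - 1L,
      strand = strands[i], evalue = 10^-sample(5:40, 1L),
      score = sample(50:500, 1L)
    )
  }
  do.call(rbind, rows)
}

match_signature <- function(m) {
  paste(m$query_id, m$target_id, m$strand, m$query_start, m$query_end,
        m$target_start, m$target_end, sep = ":")
}

# canonical form of a partition: sorted list of sorted signature vectors
canonical_partition <- function(m, group) {
  parts <- split(match_signature(m), group)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}

# Independent oracle: per (target, query, strand) group, link consecutive
# sorted matches iff joinable, then take graph connected components.
oracle_partition <- function(matches, config) {
  n <- nrow(matches)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  key <- paste(matches$target_id, matches$query_id, matches$strand)
  for (grp in unique(key)) {
    idx <- which(key == grp)
    idx <- idx[order(matches$target_start[idx], matches$target_end[idx],
                     matches$query_start[idx])]
    if (length(idx) > 1L) {
      for (j in 2:length(idx)) {
        if (joinable(matches[idx[j - 1L], ], matches[idx[j], ], config)) {
          g <- igraph::add_edges(g, c(idx[j - 1L], idx[j]))
        }
      }
    }
  }
  membership <- igraph::components(g)$membership
  canonical_partition(matches, membership)
}

empty_annotation_input <- function() {
  match_record("p", 10L, "g", 1, 1, 1, 1)[0L, ]
}

# a pair of matches that satisfies every joining criterion under defaults
joinable_pair <- function() {
  rbind(
    match_record("p", 12000, "g", 1, 4900, 100, 5000, score = 100),
    match_record("p", 12000, "g", 4950, 6950, 7000, 9000, score = 80)
  )
}
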