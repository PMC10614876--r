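# Match filtering, the four joining criteria, greedy chaining, and
# full-length calling

test_that("filter_matches applies the inclusive E-value threshold", {
  cfg <- pipeline_config()
  m <- do.call(rbind, lapply(c(1e-3, 1e-4, 1e-5, 1e-6), function(e) {
    match_record("p", 1000, "g", 1, 500, 1, 500, evalue = e)
  }))
  kept <- filter_matches(m, cfg)
  expect_identical(sort(kept$evalue), c(1e-6, 1e-5))
})

test_that("filter_matches applies the minimum match length on the target", {
  cfg <- pipeline_config(min_match_length = 1000L)
  m <- do.call(rbind, lapply(c(999L, 1000L, 1001L), function(len) {
    match_record("p", 5000, "g", 1, len, 100, 100 + len - 1L)
  }))
  kept <- filter_matches(m, cfg)
  expect_identical(kept$target_end - kept$target_start + 1L, c(1000L, 1001L))
})

test_that("filter_matches preserves order, keeps empty input, is idempotent", {
  cfg <- pipeline_config()
  expect_identical(nrow(filter_matches(empty_annotation_input(), cfg)), 0L)
  set.seed(11)
  m <- random_matches(20)
  once <- filter_matches(m, cfg)
  expect_identical(filter_matches(once, cfg), once)
  expect_identical(match_signature(once),
                   match_signature(m)[m$evalue <= cfg$evalue_max])
})

test_that("joinable accepts a pair meeting all four criteria", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  # genome gap |5000 - 7000| = 2000 <= 0.25 * 12000
  expect_true(joinable(pair[1, ], pair[2, ], cfg))
})

test_that("joinable enforces the genome-gap bound k * n (criterion Ca)", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  far <- pair[2, ]
  far$target_start <- 8100L   # gap 3100 > 3000
  expect_false(joinable(pair[1, ], far, cfg))
  boundary <- pair[2, ]
  boundary$target_start <- 8000L  # gap exactly 3000 = 0.25 * 12000
  expect_true(joinable(pair[1, ], boundary, cfg))
})

test_that("joinable caps query overlap at theta but never penalizes gaps (Cb)", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  over <- pair[2, ]
  over$query_start <- 4850L   # overlap 4900 - 4850 + 1 = 51 > 50
  expect_false(joinable(pair[1, ], over, cfg))
  over$query_start <- 4851L   # overlap exactly 50
  expect_true(joinable(pair[1, ], over, cfg))
  # a huge query gap (deletion in the integrated copy) still joins
  gap <- pair[2, ]
  gap$query_start <- 10000L
  gap$query_end <- 11000L
  expect_true(joinable(pair[1, ], gap, cfg))
})

test_that("joinable requires same query, target, and strand (criterion A)", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  other <- pair[2, ]
  other$query_id <- "different_phage"
  expect_false(joinable(pair[1, ], other, cfg))
  other <- pair[2, ]
  other$target_id <- "other_genome"
  expect_false(joinable(pair[1, ], other, cfg))
  other <- pair[2, ]
  other$strand <- "-"
  expect_false(joinable(pair[1, ], other, cfg))
})

test_that("joinable enforces colinear order on both strands (criterion B)", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  # '+' strand: query going backwards on the genome-forward pair fails
  back <- pair[2, ]
  back$query_start <- 1L
  back$query_end <- 2000L
  expect_false(joinable(pair[1, ], back, cfg))
  # '-' strand: query order must be mirrored
  a <- match_record("p", 12000, "g", 7000, 11900, 100, 5000, strand = "-")
  b <- match_record("p", 12000, "g", 1, 2001, 7000, 9000, strand = "-")
  expect_true(joinable(a, b, cfg))
  bad <- b
  bad$query_start <- 8000L
  bad$query_end <- 12000L
  expect_false(joinable(a, bad, cfg))
})

test_that("joinable rejects pairs given in the wrong genome order", {
  cfg <- pipeline_config()
  pair <- joinable_pair()
  expect_error(joinable(pair[2, ], pair[1, ], cfg), "prev")
})

test_that("query_coverage is the union length of query intervals", {
  one <- match_record("p", 1000, "g", 1, 100, 1, 100)
  expect_identical(query_coverage(one), 100L)
  overlapping <- rbind(one, match_record("p", 1000, "g", 51, 150, 300, 399))
  expect_identical(query_coverage(overlapping), 150L)
  abutting <- rbind(one, match_record("p", 1000, "g", 101, 200, 300, 399))
  expect_identical(query_coverage(abutting), 200L)
})

test_that("full-length boundary at 70% of the query is inclusive", {
  cfg <- pipeline_config()
  expect_true(call_full_length(match_record("p", 1000, "g", 1, 1000, 1, 1000),
                               cfg))
  expect_true(call_full_length(match_record("p", 1000, "g", 1, 700, 1, 700),
                               cfg))
  expect_false(call_full_length(match_record("p", 1000, "g", 1, 699, 1, 699),
                                cfg))
})

test_that("assign_integrations chains the worked examples correctly", {
  cfg <- pipeline_config()
  one <- match_record("p", 1000, "g", 1, 800, 1, 800)
  ann1 <- assign_integrations(one, cfg)
  expect_identical(length(unique(ann1$integration_id)), 1L)

  ann2 <- assign_integrations(joinable_pair(), cfg)
  expect_identical(length(unique(ann2$integration_id)), 1L)
  expect_identical(query_coverage(ann2), 6901L)  # 4900 + 2001, disjoint

  # (m1, m2) joinable, (m2, m3) not (Ca violated) -> chains of size 2 and 1
  three <- rbind(
    joinable_pair(),
    match_record("p", 12000, "g", 7000, 9000, 13000, 15000)
  )
  ann3 <- assign_integrations(three, cfg)
  sizes <- sort(as.integer(table(ann3$integration_id)))
  expect_identical(sizes, c(1L, 2L))

  # interleaved matches to different phages stay separate
  inter <- rbind(
    match_record("pA", 12000, "g", 1, 4900, 100, 5000),
    match_record("pB", 12000, "g", 1, 2000, 5500, 7500),
    match_record("pA", 12000, "g", 4950, 6950, 8000, 10000)
  )
  ann4 <- assign_integrations(inter, cfg)
  expect_identical(length(unique(ann4$integration_id)), 2L)
  pa <- ann4[ann4$query_id == "pA", ]
  expect_identical(length(unique(pa$integration_id)), 1L)
})

test_that("integration ids are deterministic target-ordinal labels", {
  cfg <- pipeline_config()
  three <- rbind(
    joinable_pair(),
    match_record("p", 12000, "g", 7000, 9000, 13000, 15000)
  )
  ann <- assign_integrations(three, cfg)
  expect_identical(sort(unique(ann$integration_id)), c("g_1", "g_2"))
  # first id along the genome is g_1
  expect_identical(ann$integration_id[which.min(ann$target_start)], "g_1")
})

test_that("greedy partition equals the connected-components oracle", {
  cfg <- pipeline_config()
  set.seed(2024)
  for (rep in 1:200) {
    m <- random_matches(sample(1:10, 1L))
    ann <- assign_integrations(m, cfg)
    expect_identical(canonical_partition(ann, ann$integration_id),
                     oracle_partition(m, cfg))
  }
})

test_that("fragments are partitioned: nothing lost, nothing duplicated", {
  cfg <- pipeline_config()
  set.seed(99)
  for (rep in 1:25) {
    m <- filter_matches(random_matches(sample(1:12, 1L)), cfg)
    ann <- assign_integrations(m, cfg)
    expect_identical(sort(match_signature(ann)), sort(match_signature(m)))
  }
})

test_that("every consecutive fragment pair inside an integration is joinable", {
  cfg <- pipeline_config()
  set.seed(7)
  for (rep in 1:25) {
    ann <- assign_integrations(random_matches(sample(2:12, 1L)), cfg)
    for (id in unique(ann$integration_id)) {
      f <- ann[ann$integration_id == id, ]
      f <- f[order(f$target_start, f$target_end, f$query_start), ]
      if (nrow(f) > 1L) {
        for (j in 2:nrow(f)) {
          expect_true(joinable(f[j - 1L, ], f[j, ], cfg))
        }
      }
    }
  }
})

test_that("integration count is monotone in k and theta; full-length in the fraction", {
  set.seed(31)
  n_int <- function(ann) length(unique(ann$integration_id))
  for (rep in 1:20) {
    m <- random_matches(sample(4:12, 1L))
    loose_k <- assign_integrations(m, pipeline_config(gap_fraction_k = 0.4))
    tight_k <- assign_integrations(m, pipeline_config(gap_fraction_k = 0.1))
    expect_lte(n_int(loose_k), n_int(tight_k))
    loose_t <- assign_integrations(
      m, pipeline_config(max_query_overlap_theta = 500L))
    tight_t <- assign_integrations(
      m, pipeline_config(max_query_overlap_theta = 0L))
    expect_lte(n_int(loose_t), n_int(tight_t))
    lo <- assign_integrations(m, pipeline_config(full_length_fraction = 0.5))
    hi <- assign_integrations(m, pipeline_config(full_length_fraction = 0.9))
    # same chains (k, theta unchanged), so flags align row by row
    expect_true(all(hi$full_length <= lo$full_length))
  }
})

test_that("pipeline_config validates its arguments", {
  expect_error(pipeline_config(evalue_max = 0), "evalue_max")
  expect_error(pipeline_config(full_length_fraction = 1.5), "full_length")
  expect_error(pipeline_config(gap_fraction_k = -1), "gap_fraction_k")
  cfg <- pipeline_config()
  expect_identical(cfg$evalue_max, 1e-5)
  expect_identical(cfg$gap_fraction_k, 0.25)
  expect_identical(cfg$max_query_overlap_theta, 50L)
  expect_identical(cfg$full_length_fraction, 0.70)
  expect_identical(cfg$min_match_length, 0L)
})
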