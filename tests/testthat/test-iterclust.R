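test_that("label rendering matches the published grammar", {
  expect_equal(render_label(list(kind = "member", batch_index = 0,
                                 cluster_index = 0, seq_index = 0)),
               "A_0#a_0")
  expect_equal(render_label(list(kind = "member", batch_index = 0,
                                 cluster_index = 11, seq_index = 15)),
               "A_11#a_15")
  expect_equal(render_label(list(kind = "singleton", batch_index = 0,
                                 seq_index = 1)),
               "Sa_1#a_1")
  expect_equal(render_label(list(kind = "member", batch_index = 10,
                                 cluster_index = 9, seq_index = 3)),
               "K_9#k_3")

  lab <- parse_label("A_11#a_15")
  expect_equal(lab$kind, "member")
  expect_equal(lab$batch_index, 0)
  expect_equal(lab$cluster_index, 11L)
  expect_equal(lab$seq_index, 15L)

  lab <- parse_label("Sa_1#a_1")
  expect_equal(lab$kind, "singleton")
  expect_equal(lab$batch_index, 0)
  expect_equal(lab$seq_index, 1L)
})

test_that("labels round-trip for 1000 random labels", {
  set.seed(77)
  for (i in 1:1000) {
    lab <- if (runif(1) < 0.5) {
      list(kind = "member", batch_index = sample(0:60, 1),
           cluster_index = sample(0:5000, 1), seq_index = sample(0:5000, 1))
    } else {
      list(kind = "singleton", batch_index = sample(0:60, 1),
           seq_index = sample(0:5000, 1))
    }
    back <- parse_label(render_label(lab))
    expect_equal(back[order(names(back))],
                 lab[order(names(lab))])
  }
})

test_that("malformed labels are rejected", {
  expect_error(parse_label("A_11"), "malformed")
  expect_error(parse_label("A_11#b_15"), "disagree")
  expect_error(parse_label("Sa_1#a_2"), "malformed")
  expect_error(parse_label("a_11#a_15"), "malformed")
})

test_that("batch letters extend beyond 26 batches", {
  expect_equal(batch_letters(c(0, 25, 26, 27, 701, 702)),
               c("A", "Z", "AA", "AB", "ZZ", "AAA"))
})

test_that("mutually dissimilar sequences make no sub-clusters", {
  set.seed(88)
  recs <- seq_records(sprintf("r%d", 1:6),
                      vapply(rep(80, 6), random_seq, ""))
  res <- cluster_batch(recs)
  expect_equal(length(res$subclusters), 0L)
  expect_equal(res$singletons, 0:5)
})

test_that("planted families become sub-clusters, the rest singletons", {
  set.seed(14)
  fam1 <- make_family(family_spec(n_members = 3, seed_length = 80,
                                  rng_seed = 21), family_index = 1)
  fam2 <- make_family(family_spec(n_members = 3, seed_length = 80,
                                  rng_seed = 22), family_index = 2)
  loner <- seq_records("loner", random_seq(80))
  recs <- rbind(fam1$records, fam2$records, loner)
  # oracle: all-pairs statistics against the threshold
  n <- nrow(recs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- align_stats(recs$residues[i], recs$residues[j])$len_ratio > 0.8
  }
  expect_true(all(adj[1:3, 1:3][upper.tri(diag(3))]))
  expect_true(all(adj[4:6, 4:6][upper.tri(diag(3))]))
  expect_false(any(adj[1:3, 4:7]))
  res <- cluster_batch(recs)
  expect_equal(res$subclusters, list(0:2, 3:5))
  expect_equal(res$singletons, 6L)
})

test_that("sub-clusters and singletons conserve the batch", {
  set.seed(19)
  for (i in 1:20) {
    ds <- make_dataset(n_families = sample(1:3, 1),
                       family = family_spec(n_members = sample(2:4, 1),
                                            seed_length = 50, rng_seed = i),
                       n_decoys = sample(0:3, 1), rng_seed = i + 100)
    recs <- filter_batch(ds$records)$records
    res <- cluster_batch(recs)
    covered <- c(unlist(res$subclusters), res$singletons)
    expect_equal(sort(covered), seq_len(nrow(recs)) - 1L)
  }
})

test_that("the representative is the first sequence of each sub-cluster", {
  res <- batch_result(list(c(1L, 3L, 7L), c(0L, 2L)), c(4L, 5L, 6L),
                      sprintf("s%d", 0:7))
  recs <- seq_records(sprintf("s%d", 0:7), vapply(rep(40, 8), random_seq, ""))
  reps <- representatives(res, recs)
  expect_equal(reps$seq_id, c("s1", "s0"))
  expect_equal(nrow(reps), length(res$subclusters))
})

test_that("the published 4-iteration schedule is expressible and readable", {
  sched <- iteration_schedule(
    list(c("1", "2", "3"), c("4", "5", "6", "7"), c("8", "9", "10", "11")),
    list(c("1-2-3", "4-5-6-7")),
    list(c("1-2-3-4-5-6-7", "8-9-10-11")))
  expect_length(sched$iterations, 3L)

  path <- system.file("extdata", "schedule-11-batches.yaml",
                      package = "homoclust")
  from_yaml <- read_schedule(path)
  expect_equal(from_yaml, sched)
})

test_that("next-iteration batch size equals sub-clusters plus singletons", {
  set.seed(31)
  ds <- make_dataset(n_families = 6,
                     family = family_spec(n_members = 4, seed_length = 60,
                                          rng_seed = 8),
                     n_decoys = 3, rng_seed = 8)
  recs <- filter_batch(ds$records)$records
  batches <- split(recs, rep(1:3, length.out = nrow(recs)))
  batches <- lapply(batches, function(b) { rownames(b) <- NULL; b })
  trace <- run_iterations(batches, dedup = FALSE)
  iter1 <- trace$iterations[[1]]
  expected <- sum(vapply(iter1, function(b)
    length(b$result$subclusters) + length(b$result$singletons), 1L))
  final_in <- length(trace$iterations[[2]][[1]]$ids)
  expect_equal(final_in, expected)
})

test_that("a single batch with the trivial schedule gives a depth-1 trace", {
  set.seed(3)
  fam <- make_family(family_spec(n_members = 3, seed_length = 50,
                                 rng_seed = 5))
  trace <- run_iterations(list(fam$records))
  expect_length(trace$iterations, 1L)
  direct <- cluster_batch(fam$records)
  expect_equal(trace$iterations[[1]][[1]]$result, direct)
})

test_that("schedules consuming unknown batches are rejected", {
  fam <- make_family(family_spec(n_members = 2, seed_length = 40,
                                 rng_seed = 6))
  expect_error(
    run_iterations(list(fam$records),
                   schedule = iteration_schedule(list(c("1", "nope")))),
    "unknown batch")
})

test_that("cross-batch dedup removes duplicates when batches combine", {
  set.seed(47)
  fam <- make_family(family_spec(n_members = 3, seed_length = 60,
                                 sub_rate = 0, indel_rate = 0, rng_seed = 9))
  # identical sequences in two different batches survive per-batch
  # filtering but meet when the batches are combined
  b1 <- fam$records[1, , drop = FALSE]
  b2 <- fam$records[2:3, , drop = FALSE]
  rownames(b1) <- rownames(b2) <- NULL
  trace <- run_iterations(list(b1, b2), dedup = TRUE)
  combined <- trace$iterations[[2]][[1]]
  expect_length(combined$removed, 1L)
  cs <- merge_all(trace)
  # the removed duplicate's lineage still lands in the final partition
  expect_equal(sort(c(unlist(cs$clusters), cs$singletons)),
               sort(fam$records$seq_id))
})

test_that("every next-iteration sequence has exactly one provenance", {
  set.seed(52)
  ds <- make_dataset(n_families = 4,
                     family = family_spec(n_members = 4, seed_length = 60,
                                          rng_seed = 12),
                     n_decoys = 2, rng_seed = 12)
  recs <- filter_batch(ds$records)$records
  batches <- lapply(split(seq_len(nrow(recs)), rep(1:2, length.out = nrow(recs))),
                    function(i) { b <- recs[i, , drop = FALSE]; rownames(b) <- NULL; b })
  trace <- run_iterations(batches)
  for (t in seq_along(trace$iterations)) {
    for (b in trace$iterations[[t]]) {
      expect_setequal(names(b$provenance), b$ids)
      kinds <- vapply(b$provenance, `[[`, "", "kind")
      expect_true(all(kinds %in% c("original", "rep", "singleton")))
    }
  }
})
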