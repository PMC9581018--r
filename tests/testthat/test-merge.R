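test_that("the worked-example trace merges into one seven-member cluster", {
  trace <- example_trace()
  cs <- merge_all(trace)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$clusters[[1]],
               sort(c("b1_s1", "b1_s2", "b2_S1", "b4_S1", "b7_s1",
                      "b8_S1", "b9_S1")))
  expect_equal(sort(cs$singletons),
               sort(c("b3_S1", "b5_S1", "b6_S1", "b10_S1", "b11_S1")))
})

test_that("expanding a representative resolves its whole lineage", {
  trace <- example_trace()
  expect_equal(expand_member(trace, 4, "b1_s1"),
               sort(c("b1_s1", "b1_s2", "b2_S1", "b4_S1", "b7_s1")))
  expect_equal(expand_member(trace, 4, "b8_S1"), sort(c("b8_S1", "b9_S1")))
  # base case: an iteration-1 sequence resolves to itself
  expect_equal(expand_member(trace, 1, "b1_s2"), "b1_s2")
  expect_error(expand_member(trace, 2, "nope"), "unknown")
})

test_that("expansion equals an independent transitive-closure oracle", {
  set.seed(710)
  for (i in 1:6) {
    ds <- make_dataset(n_families = 4,
                       family = family_spec(n_members = 4, seed_length = 60,
                                            rng_seed = i + 40),
                       n_decoys = 2, n_duplicates = 1, rng_seed = i + 40)
    recs <- filter_batch(ds$records)$records
    nb <- 3
    batches <- lapply(split(seq_len(nrow(recs)),
                            rep(1:nb, length.out = nrow(recs))),
                      function(ix) { b <- recs[ix, , drop = FALSE]
                                     rownames(b) <- NULL; b })
    sched <- iteration_schedule(list(c("1", "2")), list(c("1-2", "3")))
    trace <- run_iterations(batches, schedule = sched)
    t_final <- length(trace$iterations)
    fb <- trace$iterations[[t_final]][[trace$final_batch]]
    for (id in fb$ids) {
      expect_equal(expand_member(trace, t_final, id),
                   oracle_expand(trace, t_final, id), info = id)
    }
  }
})

test_that("a depth-1 trace merges to the batch result itself", {
  set.seed(9)
  fam <- make_family(family_spec(n_members = 3, seed_length = 50,
                                 rng_seed = 77))
  loner <- seq_records("loner", random_seq(50))
  recs <- rbind(fam$records, loner)
  trace <- run_iterations(list(recs))
  cs <- merge_all(trace)
  res <- trace$iterations[[1]][[1]]$result
  expect_equal(cs$clusters,
               lapply(res$subclusters, function(m) sort(res$ids[m + 1])))
  expect_equal(sort(cs$singletons), sort(res$ids[res$singletons + 1]))
})

test_that("merged clusters and singletons partition the filtered input", {
  set.seed(920)
  for (i in 1:20) {
    ds <- make_dataset(n_families = sample(2:5, 1),
                       family = family_spec(n_members = sample(2:5, 1),
                                            seed_length = 50,
                                            rng_seed = i),
                       n_decoys = sample(0:3, 1),
                       n_duplicates = sample(0:2, 1), rng_seed = i)
    recs <- filter_batch(ds$records)$records
    nb <- sample(1:3, 1)
    batches <- lapply(split(seq_len(nrow(recs)),
                            rep(1:nb, length.out = nrow(recs))),
                      function(ix) { b <- recs[ix, , drop = FALSE]
                                     rownames(b) <- NULL; b })
    trace <- run_iterations(batches)
    cs <- merge_all(trace)
    all_ids <- c(unlist(cs$clusters), cs$singletons)
    expect_equal(sort(all_ids), sort(recs$seq_id), info = i)
    expect_equal(length(all_ids), nrow(recs))
    expect_true(all(lengths(cs$clusters) >= 2))
  }
})

test_that("iterative clustering equals direct clustering on separable data", {
  set.seed(314)
  for (i in 1:3) {
    ds <- make_dataset(n_families = 5,
                       family = family_spec(n_members = 4, seed_length = 80,
                                            rng_seed = i + 60),
                       n_decoys = 2, rng_seed = i + 60)
    direct <- homoclust(ds$records, batches = 1)
    split2 <- homoclust(ds$records, batches = 2)
    expect_equal(norm_cluster_set(direct$clusters),
                 norm_cluster_set(split2$clusters), info = i)
  }
})

test_that("cluster sets validate and round-trip through JSON lines", {
  expect_error(cluster_set(list("a")), "at least 2")
  expect_error(cluster_set(list(c("a", "b")), "a"), "disjoint")

  cs <- cluster_set(list(c("a", "b"), c("c", "d", "e")), c("f", "g"))
  path <- withr::local_tempfile()
  write_clusters(cs, path)
  back <- read_clusters(path)
  expect_equal(back, cs)
})
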