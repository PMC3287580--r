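test_that("EDRD defaults follow the n/25 rule and its grids", {
  cfg <- kdc_config(76, control = "x")
  expect_equal(cfg$edrd, 3L)
  expect_equal(cfg$cluster_counts, seq(3L, 75L, by = 3L))
  expect_equal(cfg$ranks, seq(3L, 76L, by = 3L))

  # small n degrades to step 1
  cfg2 <- kdc_config(20, control = "x")
  expect_equal(cfg2$edrd, 1L)
})

test_that("a sweep finds planted clades and always realizes c = n", {
  spec <- sim_spec(n_clades = 3, species_per_clade = 4, seq_length = 600,
                   seed = 2)
  ds <- simulate_dataset(spec)
  A <- build_trigram_matrix(ds)
  n <- ncol(A)
  cfg <- kdc_config(n, control = ds$positive_control,
                    cluster_counts = c(3L, n))
  res <- kdc_sweep(A, ds, cfg)
  expect_gt(length(res), 0)

  # c = n (all singletons) is achievable for every swept rank
  cn <- Filter(function(r) r$c == n, res)
  expect_equal(length(cn), length(cfg$ranks[cfg$ranks <= svd_decompose(A)$rank]))
  expect_true(all(vapply(cn, function(r) r$n_singletons == n, logical(1))))

  # some c = 3 result recovers the planted clades exactly
  c3 <- Filter(function(r) r$c == 3, res)
  planted <- planted_partition(spec)
  expect_true(any(vapply(c3, function(r) {
    same_partition(r$partition, planted)
  }, logical(1))))
})

test_that("sweeps are deterministic under the fixed pivot order", {
  spec <- sim_spec(n_clades = 2, species_per_clade = 3, seq_length = 300,
                   seed = 5)
  ds <- simulate_dataset(spec)
  A <- build_trigram_matrix(ds)
  cfg <- kdc_config(ncol(A), control = ds$positive_control)
  r1 <- kdc_sweep(A, ds, cfg)
  r2 <- kdc_sweep(A, ds, cfg)
  expect_identical(
    lapply(r1, function(r) r$partition$clusters),
    lapply(r2, function(r) r$partition$clusters))
})

test_that("recursion drops singleton species and protects the control", {
  spec <- sim_spec(n_clades = 3, species_per_clade = 4, seq_length = 600,
                   n_outliers = 2, seed = 3)
  ds <- simulate_dataset(spec)
  # results lacking isolation: force by restricting counts so that the
  # only results available carry outliers as singletons
  A <- build_trigram_matrix(ds)
  cfg <- kdc_config(ncol(A), control = ds$positive_control)
  res <- kdc_sweep(A, ds, cfg)
  no_iso <- Filter(function(r) !r$control_isolated, res)
  if (length(no_iso) > 0) {
    sel <- kdc_retain(no_iso, cfg)
    expect_true(all(cfg$control %in% sel$retained))
    singles <- unlist(sel$best$partition$clusters[
      lengths(sel$best$partition$clusters) == 1L])
    dropped <- setdiff(singles, cfg$control)
    expect_true(all(!(dropped %in% sel$retained)))
  }
  expect_error(kdc_retain(list(), cfg), "no kdc results")
})

test_that("unrelated outliers never contaminate clade clusters", {
  spec <- sim_spec(n_clades = 3, species_per_clade = 4, seq_length = 800,
                   n_outliers = 2, seed = 4)
  ds <- simulate_dataset(spec)
  res <- kdc_search(ds)
  expect_false(is.null(res$finalize))
  top <- res$finalize$results[[1]]
  expect_true(top$control_isolated)
  # outliers are either shed during recursion or kept apart from every
  # clade species in the winning partition
  out_ids <- grep("^OUT", names(ds$records), value = TRUE)
  for (cl in top$partition$clusters) {
    has_out <- any(cl %in% out_ids)
    has_clade <- any(!(cl %in% out_ids))
    expect_false(has_out && has_clade)
  }
})

test_that("finalize ranks the bundled example sets by median correctly", {
  rk <- example_finalize_ranking()
  expect_equal(rk$config[1], "06clusters"); expect_equal(rk$rank_k[1], 6)
  expect_equal(rk$median[1], 82.00)
  expect_equal(rk$config[2], "06clusters"); expect_equal(rk$rank_k[2], 3)
  expect_equal(rk$median[2], 70.50)
  expect_equal(rk$config[3], "08clusters"); expect_equal(rk$rank_k[3], 9)
  expect_equal(rk$median[3], 52.00)
  # negative-control configurations are excluded
  expect_false(any(rk$rank_k %in% c(12, 30, 36) &
                     rk$config %in% c("08clusters", "10clusters",
                                      "14clusters") &
                     !paste(rk$config, rk$rank_k) %in%
                       c("12clusters 12", "14clusters 60")))
})

test_that("finalize gate and tie-breaks behave as documented", {
  spec <- sim_spec(n_clades = 2, species_per_clade = 3, seq_length = 400,
                   seed = 6)
  ds <- simulate_dataset(spec)
  A <- build_trigram_matrix(ds)
  cfg <- kdc_config(ncol(A), control = ds$positive_control)
  res <- kdc_sweep(A, ds, cfg)
  iso <- Filter(function(r) r$control_isolated, res)
  fin <- kdc_finalize(iso)
  # gate soundness: every ranked partition holds the control exactly
  for (r in fin$results) {
    hit <- vapply(r$partition$clusters, function(cl) {
      setequal(cl, cfg$control)
    }, logical(1))
    expect_true(any(hit))
  }
  meds <- vapply(fin$results, function(r) r$report$median, numeric(1))
  expect_true(all(diff(meds) <= 0))
  # mixing in a non-isolating result is rejected
  bad <- Filter(function(r) !r$control_isolated, res)
  if (length(bad) > 0) expect_error(kdc_finalize(c(iso, bad[1])),
                                    "control_isolated")
  expect_error(kdc_finalize(list()), "no isolating")
  # single candidate is rank 1
  expect_equal(kdc_finalize(iso[1])$results[[1]]$k, iso[[1]]$k)
})

test_that("two full searches give identical ranked output", {
  spec <- sim_spec(n_clades = 3, species_per_clade = 4, seq_length = 500,
                   seed = 8)
  ds <- simulate_dataset(spec)
  r1 <- kdc_search(ds)
  r2 <- kdc_search(ds)
  expect_identical(r1$finalize$table, r2$finalize$table)
})
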