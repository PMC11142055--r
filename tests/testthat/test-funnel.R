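# The funnel tests use the filtered synthetic library against the open
# cavity pocket; the toy scorer is deterministic, so exhaustive scoring is
# a cheap oracle.

filtered_library <- function(n = 120, seed = 7) {
  cached(sprintf("funnel_lib_%d_%d", n, seed), {
    lib <- make_compound_library(n, seed = seed)
    out <- filter_library(lib)
    out[out$passes_filter, , drop = FALSE]
  })
}

test_that("with keep_top_k = N a stage is a pure sort by the scorer", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  sc <- make_scorer("toy", function(cmp, pk) toy_scorer(cmp, pk))
  res <- run_stage(lib, p, funnel_stage(sc, keep_top_k = nrow(lib)))
  expect_equal(nrow(res$survivors), nrow(lib))
  brute <- vapply(seq_len(nrow(lib)), function(i) {
    toy_scorer(lib[i, , drop = FALSE], p)
  }, numeric(1))
  expect_equal(res$survivors$compound_id,
               lib$compound_id[order(brute, lib$compound_id)])
})

test_that("keep_top_k = 1 selects the brute-force minimum", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  sc <- make_scorer("toy", function(cmp, pk) toy_scorer(cmp, pk))
  res <- run_stage(lib, p, funnel_stage(sc, keep_top_k = 1))
  brute <- vapply(seq_len(nrow(lib)), function(i) {
    toy_scorer(lib[i, , drop = FALSE], p)
  }, numeric(1))
  expect_equal(res$survivors$compound_id,
               lib$compound_id[order(brute, lib$compound_id)][1])
})

test_that("two rank-consistent scorers keep the same survivors as one", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  s1 <- make_scorer("toy", function(cmp, pk) toy_scorer(cmp, pk))
  s2 <- make_scorer("toy_affine", function(cmp, pk) 3 * toy_scorer(cmp, pk) + 7,
                    cost_tier = 2)
  single <- run_stage(lib, p, funnel_stage(s1, 10))
  both <- run_stage(lib, p, funnel_stage(list(s1, s2), 10,
                                         aggregation = "mean_rank"))
  expect_equal(both$survivors$compound_id, single$survivors$compound_id)
})

test_that("funnel ranking equals single-pass sorting when nothing is culled", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  s1 <- make_scorer("toy", function(cmp, pk) toy_scorer(cmp, pk))
  n <- nrow(lib)
  rl <- run_funnel(lib, p, list(funnel_stage(s1, n), funnel_stage(s1, n)),
                   final_n = n)
  single <- run_stage(lib, p, funnel_stage(s1, n))
  expect_equal(rl$compound_id, single$survivors$compound_id)
  expect_equal(rl$final_rank, seq_len(n))
})

test_that("monotone-consistent stages preserve the global optimum", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  s1 <- make_scorer("broad", function(cmp, pk) toy_scorer(cmp, pk))
  s2 <- make_scorer("refined", function(cmp, pk) exp(toy_scorer(cmp, pk) / 100),
                    cost_tier = 2)
  rl <- run_funnel(lib, p, list(funnel_stage(s1, 25), funnel_stage(s2, 10)),
                   final_n = 5)
  brute <- vapply(seq_len(nrow(lib)), function(i) {
    toy_scorer(lib[i, , drop = FALSE], p)
  }, numeric(1))
  expect_equal(rl$compound_id[1], lib$compound_id[order(brute, lib$compound_id)][1])
})

test_that("funnel output is invariant to library order and keeps provenance", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  s1 <- make_scorer("toy", function(cmp, pk) toy_scorer(cmp, pk))
  stages <- list(funnel_stage(s1, 30), funnel_stage(s1, 12))
  rl <- run_funnel(lib, p, stages, final_n = 12)
  shuffled <- with_seed_helper(99, lib[sample.int(nrow(lib)), , drop = FALSE])
  rl2 <- run_funnel(shuffled, p, stages, final_n = 12)
  expect_equal(rl2$compound_id, rl$compound_id)
  prov <- attr(rl, "provenance")
  # no compound eliminated earlier reappears later
  expect_true(all(prov$last_stage[prov$status == "ranked"] == length(stages)))
  expect_true(all(rl$compound_id %in% prov$compound_id[prov$status == "ranked"]))
})

test_that("scorer failures drop the compound with a reason, not the run", {
  lib <- filtered_library()
  p <- open_cavity()$pockets[[1]]
  victim <- lib$compound_id[3]
  sc <- make_scorer("flaky", function(cmp, pk) {
    if (cmp$compound_id == victim) stop("engine crashed")
    toy_scorer(cmp, pk)
  })
  res <- run_stage(lib, p, funnel_stage(sc, nrow(lib)))
  expect_equal(nrow(res$survivors), nrow(lib) - 1)
  expect_equal(res$dropped$compound_id, victim)
  expect_match(res$dropped$reason, "engine crashed")
})

test_that("the toy scorer is deterministic with a constructed minimum", {
  p <- open_cavity()$pockets[[1]]
  perfect <- data.frame(compound_id = "OPT", mw = 0.4 * p$volume,
                        hbd = p$polar_residue_count, hba = 0)
  expect_equal(toy_scorer(perfect, p), 0)
  off <- perfect; off$mw <- off$mw + 25
  expect_equal(toy_scorer(off, p), 25)
  off2 <- perfect; off2$mw <- off2$mw + 50
  expect_gt(toy_scorer(off2, p), toy_scorer(off, p))
  expect_identical(toy_scorer(off, p), toy_scorer(off, p))
})
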