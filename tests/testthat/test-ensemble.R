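test_that("hydrogen-bond probabilities hit 0 and 1 at the extremes", {
  nat <- toy_native()
  spec <- default_ensemble_spec(nat, seed = 1, n_frames = 200)
  spec$hbond_pairs$prob <- c(1, 1, 0, 0, 1, 0)
  spec$noise_nm <- 0
  ens <- make_intermediate_ensemble(spec, nat)
  hb <- hbond_map(ens, native = nat)
  p <- spec$hbond_pairs
  for (k in seq_len(nrow(p))) {
    expect_equal(hb$probability[p$resno_i[k], p$resno_j[k]], p$prob[k])
  }
  expect_true(all(diag(hb$probability) == 0))
  expect_true(all(hb$probability >= 0 & hb$probability <= 1))
  # native annotation reflects the reference structure's bonds
  expect_true(hb$native[1, 4])
  expect_false(hb$native[1, 9])
})

test_that("hbond map errors when donor/acceptor roles are missing", {
  nat <- toy_native()
  traj <- noisy_trajectory(nat, n = 3, sd = 0.01)
  expect_error(hbond_map(traj, donors = "N4"), "missing")
})

test_that("hbond probabilities are invariant under frame duplication", {
  nat <- toy_native()
  spec <- default_ensemble_spec(nat, seed = 3, n_frames = 100)
  ens <- make_intermediate_ensemble(spec, nat)
  dup <- g4_trajectory(ens$topology,
                       array(c(ens$coords, ens$coords),
                             c(dim(ens$coords)[1], 3, 200)),
                       array(c(ens$ion_coords, ens$ion_coords),
                             c(dim(ens$ion_coords)[1], 3, 200)),
                       times = 0:199)
  h1 <- hbond_map(ens)
  h2 <- hbond_map(dup)
  expect_equal(h1$probability, h2$probability)
})

test_that("ion binding profile: pinned ion, empty system, planted occupancies", {
  one <- two_point_structure(d = 3, role = "O6")
  one$ions <- matrix(c(0.1, 0, 0), 1, 3)
  tr <- trajectory_from_structures(list(one, one, one))
  ip <- ion_binding_profile(tr)
  expect_equal(unname(ip$probability["1"]), 1)
  expect_equal(ip$mean_bound, 1)
  bare <- two_point_structure(d = 3, role = "O6")
  tr0 <- trajectory_from_structures(list(bare, bare))
  ip0 <- ion_binding_profile(tr0)
  expect_true(all(ip0$probability == 0))
  expect_equal(ip0$mean_bound, 0)
})

test_that("syn/anti classification follows the windows and the fluctuation rule", {
  con_anti <- classify_glycosidic(rep(180, 50))
  expect_equal(con_anti$classification, "anti")
  expect_equal(con_anti$n_transitions, 0L)
  con_syn <- classify_glycosidic(rep(0, 50))
  expect_equal(con_syn$classification, "syn")
  # noiseless telegraph: planted transitions recovered exactly
  st <- rep(c(30, -170, 30, -170, 30), each = 20)
  g <- classify_glycosidic(st, times = seq_along(st) * 0.5)
  expect_equal(g$n_transitions, 4L)
  expect_equal(g$classification, "fluctuating")
  expect_equal(unname(g$mean_dwell_ns["syn"]), 10)   # 20 samples x 0.5 ns
  # 85% occupancy with a single transition still counts as a pure state
  one_jump <- c(rep(-170, 85), rep(30, 15))
  expect_equal(classify_glycosidic(one_jump)$classification, "anti")
  expect_error(classify_glycosidic(1), "length")
})

test_that("pathway graphs collapse runs and count traversals", {
  pg <- build_pathway_graph(list(c("A", "B", "C")))
  expect_equal(pg$edges$count, c(1, 1))
  expect_equal(pg$n_trajectories, 1)
  # repeated labels collapse to a single edge
  pg2 <- build_pathway_graph(list(c("A", "A", "B")))
  expect_equal(nrow(pg2$edges), 1)
  expect_equal(pg2$edges$from, "A")
  # 8-vs-1-vs-1 split
  seqs <- c(replicate(8, c("A", "B", "D"), simplify = FALSE),
            list(c("A", "C", "D")), list(c("A", "D")))
  pg3 <- build_pathway_graph(seqs)
  e <- pg3$edges
  expect_equal(e$count[e$from == "A" & e$to == "B"], 8)
  expect_equal(e$count[e$from == "A" & e$to == "C"], 1)
  expect_equal(e$count[e$from == "A" & e$to == "D"], 1)
  expect_equal(sum(pg3$paths$count), 10)
  expect_error(build_pathway_graph(list(character(0))), "empty")
  dot <- pathway_graph_to_dot(pg3)
  expect_match(dot, "digraph")
  expect_match(dot, "label=\"8\"")
})
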