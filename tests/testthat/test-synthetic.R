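test_that("the toy quadruplex is deterministic and satisfies its invariants", {
  n1 <- make_toy_quadruplex(seed = 1)
  n2 <- make_toy_quadruplex(seed = 1)
  expect_identical(n1, n2)
  expect_equal(nrow(n1$nucleotides), 12)
  expect_equal(nrow(n1$ions), 2)
  ct <- build_native_contacts(n1)
  expect_equal(compute_q(n1, ct), 1)
  expect_equal(compute_drmsd(n1, n1), 0)
  # tetrad-layer O6 ring centers are collinear (on the channel axis)
  for (lay in 1:3) {
    sel <- n1$nucleotides$resno[n1$nucleotides$tetrad == lay]
    ctr <- colMeans(atom_coords(n1, "O6", resno = sel))
    expect_lt(max(abs(ctr[1:2])), 1e-9)
  }
  expect_error(make_toy_quadruplex(geometry = list(rise = -1)), "geometry")
  expect_error(make_toy_quadruplex(n_repeats = 1), "repeats")
})

test_that("planted probability 1 with zero noise gives Q = 1 in every frame", {
  nat <- toy_native()
  spec <- default_ensemble_spec(nat, seed = 2, n_frames = 30)
  spec$hbond_pairs <- spec$hbond_pairs[spec$hbond_pairs$native, ]
  spec$hbond_pairs$prob <- 1
  spec$noise_nm <- 0
  spec$torsion <- NULL
  ens <- make_intermediate_ensemble(spec, nat)
  ct <- build_native_contacts(nat)
  for (f in seq_len(n_frames(ens)))
    expect_equal(compute_q(get_frame(ens, f), ct), 1)
})

test_that("ensemble generation is reproducible and validates constraints", {
  nat <- toy_native()
  spec <- default_ensemble_spec(nat, seed = 5, n_frames = 20)
  e1 <- make_intermediate_ensemble(spec, nat)
  e2 <- make_intermediate_ensemble(spec, nat)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$ion_coords, e2$ion_coords)
  # reusing an acceptor atom in two pairs is rejected, naming the pair
  bad <- spec
  bad$hbond_pairs <- rbind(bad$hbond_pairs, bad$hbond_pairs[1, ])
  bad$hbond_pairs$resno_i[nrow(bad$hbond_pairs)] <- 2
  expect_error(make_intermediate_ensemble(bad, nat), "infeasible")
})

test_that("planted hydrogen-bond and ion statistics are recovered", {
  nat <- toy_native()
  spec <- default_ensemble_spec(nat, seed = 8, n_frames = 1000)
  spec$hbond_pairs$prob[1] <- 0.7
  ens <- make_intermediate_ensemble(spec, nat)
  hb <- hbond_map(ens, native = nat)
  est <- hb$probability[spec$hbond_pairs$resno_i[1],
                        spec$hbond_pairs$resno_j[1]]
  ci <- 2.576 * sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(est - 0.7), ci)
  ip <- ion_binding_profile(ens)
  expect_lt(abs(ip$mean_bound - 1.5), 3 * sqrt(0.25 / 1000) + 0.02)
})

test_that("unfolding sets plant separable stages with true labels", {
  nat <- toy_native()
  u1 <- make_unfolding_set(nat, seed = 4)
  u2 <- make_unfolding_set(nat, seed = 4)
  expect_identical(u1$labels, u2$labels)
  expect_identical(lapply(u1$trajectories, `[[`, "coords"),
                   lapply(u2$trajectories, `[[`, "coords"))
  expect_equal(length(u1$trajectories), 10)
  # stage conformations are far apart, frames within a stage are tight
  t1 <- u1$trajectories[[1]]
  f1 <- get_frame(t1, 1)
  f_mid <- get_frame(t1, 6)
  expect_gt(compute_drmsd(f_mid, f1), 0.45)
  expect_lt(compute_drmsd(get_frame(t1, 2), f1), 0.1)
  expect_error(make_unfolding_set(nat, multiplicities = c(5, 1, 1),
                                  n_trajectories = 10), "sum")
  expect_error(make_unfolding_set(nat, multiplicities = c(8, 1)),
               "match")
  single <- make_unfolding_set(nat, paths = list(c("N", "U")),
                               multiplicities = 1, seed = 2)
  expect_equal(length(single$trajectories), 1)
  expect_equal(unique(single$labels[[1]]), c("N", "U"))
})

test_that("clustering-based stage labels reproduce the planted pathway counts", {
  nat <- toy_native()
  unf <- make_unfolding_set(nat, seed = 6)
  lab <- label_stages_by_clustering(unf$trajectories, threshold = 0.45)
  pg <- build_pathway_graph(lab$label_sequences)
  pg_true <- build_pathway_graph(unf$labels)
  expect_equal(sort(pg$paths$count), sort(pg_true$paths$count))
  expect_equal(sort(pg$edges$count), sort(pg_true$edges$count))
  expect_equal(max(pg$edges$count), 8)
})
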