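test_that("native contacts follow the cutoff and sequence-separation rules", {
  s <- two_point_structure(d = 0.3)
  expect_error(build_native_contacts(s, roles = "O6", cutoff = 0.45),
               NA)
  ct <- build_native_contacts(s, roles = "O6", cutoff = 0.45, min_sep = 1)
  expect_equal(ct$n_total, 1)
  expect_equal(ct$pairs$native_distance, 0.3)
  ct0 <- build_native_contacts(s, roles = "O6", cutoff = 0.2, min_sep = 1)
  expect_equal(ct0$n_total, 0)
  # neighbours |i-j| < 2 are excluded with the default separation
  expect_equal(build_native_contacts(s, roles = "O6",
                                     cutoff = 0.45)$n_total, 0)
})

test_that("contact count equals a brute-force double loop on the toy quadruplex", {
  nat <- toy_native()
  roles <- c("O6", "N7", "N2")
  cutoff <- 0.45
  ct <- build_native_contacts(nat, roles = roles, cutoff = cutoff)
  at <- nat$atoms[nat$atoms$role %in% roles, ]
  n_ref <- 0
  for (i in seq_len(nrow(at) - 1)) for (j in (i + 1):nrow(at)) {
    if (abs(at$resno[i] - at$resno[j]) < 2) next
    d <- sqrt(sum((as.numeric(at[i, c("x", "y", "z")]) -
                     as.numeric(at[j, c("x", "y", "z")]))^2))
    if (d < cutoff) n_ref <- n_ref + 1
  }
  expect_equal(ct$n_total, n_ref)
  expect_true(all(ct$pairs$resno_i < ct$pairs$resno_j))
  expect_true(all(ct$pairs$native_distance > 0))
})

test_that("Q is 1 on the native structure and 0 when stretched 3x", {
  nat <- toy_native()
  ct <- build_native_contacts(nat)
  expect_equal(compute_q(nat, ct, mode = "sharp"), 1.0)
  stretched <- nat
  stretched$atoms[, c("x", "y", "z")] <-
    as.matrix(nat$atoms[, c("x", "y", "z")]) * 3
  expect_equal(compute_q(stretched, ct, mode = "sharp"), 0.0)
  expect_error(compute_q(nat, list(pairs = NULL)), "empty")
})

test_that("sharp Q equals the brute-force formed fraction at intermediate scalings", {
  nat <- toy_native()
  ct <- build_native_contacts(nat)
  lambda <- 1.2
  qs <- numeric(0)
  for (sc in c(1.1, 1.25, 1.4)) {
    s <- nat
    s$atoms[, c("x", "y", "z")] <-
      as.matrix(nat$atoms[, c("x", "y", "z")]) * sc
    # uniform scaling multiplies every distance by sc, so the formed
    # fraction is 1 when sc < lambda and 0 when sc > lambda
    expect_equal(compute_q(s, ct, lambda = lambda),
                 as.numeric(sc < lambda))
    qs <- c(qs, compute_q(s, ct, lambda = lambda))
  }
  expect_true(all(diff(qs) <= 0))  # monotone under scaling away from native
})

test_that("Q is 0.5 when exactly half the contacts are formed", {
  # two-atom nucleotides on a line: contacts i..i+2; move half out of reach
  n <- 10
  base <- g4_structure(
    data.frame(resno = 1:n, resname = "DG"),
    data.frame(resno = 1:n, role = "O6", x = 0.2 * (1:n), y = 0, z = 0))
  ct <- build_native_contacts(base, roles = "O6", cutoff = 0.45)
  expect_equal(ct$n_total, n - 2)   # all |i-j| == 2 pairs at 0.4 nm
  moved <- base
  # displace nucleotides 3 and 7 perpendicular: each breaks its two
  # contacts, (1,3), (3,5), (5,7), (7,9), leaving 4 of 8 formed
  idx <- moved$atoms$resno %in% c(3, 7)
  moved$atoms$y[idx] <- 1.0
  d <- compute_q(moved, ct, mode = "sharp")
  # brute-force count
  p <- ct$pairs
  formed <- 0
  for (k in seq_len(nrow(p))) {
    a <- moved$atoms[moved$atoms$resno == p$resno_i[k], c("x", "y", "z")]
    b <- moved$atoms[moved$atoms$resno == p$resno_j[k], c("x", "y", "z")]
    dd <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
    if (dd < 1.2 * p$native_distance[k]) formed <- formed + 1
  }
  expect_equal(d, formed / ct$n_total)
  expect_equal(d, 0.5)
})

test_that("ion coordination counts (ion, O6) pairs inside r0", {
  nat <- toy_native()
  bare <- nat; bare$ions <- matrix(numeric(0), 0, 3)
  expect_equal(compute_ion_coordination(bare), 0)
  one <- two_point_structure(d = 3, role = "O6")
  one$ions <- matrix(c(0.1, 0, 0), 1, 3)
  expect_equal(compute_ion_coordination(one, r0 = 0.35), 1)
  # random placement vs brute force
  set.seed(3)
  s <- nat
  s$ions <- matrix(runif(9, -0.5, 0.5), 3, 3)
  O <- atom_coords(s, "O6")
  ref <- 0
  for (i in 1:3) for (j in seq_len(nrow(O)))
    if (sqrt(sum((s$ions[i, ] - O[j, ])^2)) < 0.35) ref <- ref + 1
  expect_equal(compute_ion_coordination(s, r0 = 0.35), ref)
})

test_that("smooth switching converges to the sharp indicator", {
  # limit value at r = r0 is n/m
  expect_equal(switching_function(1, 1), 0.6)
  # the pointwise limit holds for distances bounded away from the switching
  # radius, so frames with a pair inside a 5% band around r0 are redrawn
  nat <- toy_native()
  ct <- build_native_contacts(nat, roles = "O6")
  away_from_band <- function(d, r0) all(abs(d / r0 - 1) > 0.05)
  set.seed(11)
  tested <- 0
  draws <- 0
  while (tested < 20 && draws < 2000) {
    draws <- draws + 1
    s <- nat
    s$atoms[, c("x", "y", "z")] <-
      as.matrix(nat$atoms[, c("x", "y", "z")]) +
      rnorm(nrow(nat$atoms) * 3, sd = 0.05)
    s$ions <- matrix(runif(6, -0.4, 0.4), 2, 3)
    dq <- quadfold:::contact_distances(s, ct)
    di <- as.vector(quadfold:::cross_dist(s$ions, atom_coords(s, "O6")))
    if (!away_from_band(dq, 1.2 * ct$pairs$native_distance) ||
        !away_from_band(di, 0.35)) next
    tested <- tested + 1
    sharp_q <- compute_q(s, ct, mode = "sharp", lambda = 1.2)
    smooth_q <- compute_q(s, ct, mode = "smooth", lambda = 1.2,
                          n = 600, m = 1000)
    expect_lt(abs(sharp_q - smooth_q), 0.01)
    sharp_i <- compute_ion_coordination(s, mode = "sharp")
    smooth_i <- compute_ion_coordination(s, mode = "smooth",
                                         n = 600, m = 1000)
    expect_lt(abs(sharp_i - smooth_i), 0.01)
  }
  expect_equal(tested, 20)
})

test_that("the CV vector matches its standalone components", {
  nat <- toy_native()
  ct <- build_native_contacts(nat)
  cv <- evaluate_cv_vector(nat, nat, ct)
  expect_equal(cv$q, 1.0)
  expect_equal(cv$drmsd, 0)
  expect_equal(cv$n_ion, compute_ion_coordination(nat))
  expect_equal(cv$rg, compute_rg(nat))
  set.seed(5)
  s <- nat
  s$atoms[, c("x", "y", "z")] <-
    as.matrix(nat$atoms[, c("x", "y", "z")]) * 1.6
  cv2 <- evaluate_cv_vector(s, nat, ct)
  expect_equal(cv2$q, compute_q(s, ct))
  expect_equal(cv2$drmsd, compute_drmsd(s, nat))
  expect_equal(cv2$rg, compute_rg(s))
  expect_true(cv2$q < cv$q && cv2$drmsd > 0 && cv2$rg > cv$rg)
  expect_true(cv2$q >= 0 && cv2$q <= 1)
})
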