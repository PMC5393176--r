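test_that("circular_diff closed forms", {
  expect_equal(circular_diff(350, 10), 20)
  expect_equal(circular_diff(0, 180), 180)
  expect_equal(circular_diff(123.4, 123.4), 0)
  expect_equal(circular_diff(-170, 170), 20)
  # branch invariance: +/- 360 on either argument changes nothing
  set.seed(1)
  a <- runif(50, -180, 180); b <- runif(50, -180, 180)
  expect_equal(circular_diff(a + 360, b), circular_diff(a, b))
  expect_equal(circular_diff(a, b - 360), circular_diff(a, b))
})

test_that("duplex torsions are defined and close to the generator's canon", {
  fx <- build_duplex("GGCAUCGC", seed = 2)
  tp <- torsions(fx$structure)
  canon <- fx$ground_truth$torsions_used
  ri <- residue_table(fx$structure)
  for (r in seq_len(nrow(tp))) {
    pos <- ri$resno[match(tp$key[r], ri$key)]
    is5p <- pos == 1
    is3p <- pos == 8
    expect_equal(is.na(tp$alpha[r]), is5p, info = tp$key[r])
    expect_equal(is.na(tp$epsilon[r]), is3p, info = tp$key[r])
    expect_equal(is.na(tp$zeta[r]), is3p, info = tp$key[r])
    parent <- ri$parent[match(tp$key[r], ri$key)]
    chi_canon <- if (parent %in% c("A", "G")) canon[["chi_purine"]] else
      canon[["chi_pyrimidine"]]
    for (ang in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")) {
      if (!is.na(tp[[ang]][r])) {
        expect_lt(circular_diff(tp[[ang]][r], canon[[ang]]), 25)
      }
    }
    expect_lt(circular_diff(tp$chi[r], chi_canon), 25)
  }
})

test_that("collinear quadruples give an undefined dihedral", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_true(is.na(rnassess:::dihedral_angle(p)))
})

test_that("MCQ closed forms: identity, constant shift, one-sided penalty", {
  fx <- build_duplex("GACUGC", seed = 8)
  tp <- torsions(fx$structure)
  r0 <- mcq(tp, tp)
  expect_equal(r0$mcq, 0)
  expect_equal(r0$n_penalized, 0)
  shifted <- tp
  for (a in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")) {
    shifted[[a]] <- ifelse(is.na(tp[[a]]), NA, tp[[a]] + 10)
  }
  expect_equal(mcq(shifted, tp)$mcq, 10, tolerance = 1e-9)
  # +360 on stored angles changes nothing
  wrapped <- shifted
  wrapped$gamma <- wrapped$gamma + 360
  expect_equal(mcq(wrapped, tp)$mcq, 10, tolerance = 1e-9)
  # all-undefined model vs defined reference -> 180
  undef <- tp
  for (a in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")) {
    undef[[a]] <- NA_real_
  }
  r180 <- mcq(undef, tp)
  expect_equal(r180$mcq, 180)
  expect_equal(r180$n_penalized, r180$n_compared)
  # both undefined everywhere -> NA sentinel
  expect_true(is.na(mcq(undef, undef)$mcq))
  # symmetry
  noisy <- perturb_noise(fx$structure, 0.3, seed = 3)
  tn <- torsions(noisy)
  expect_equal(mcq(tn, tp)$mcq, mcq(tp, tn)$mcq, tolerance = 1e-12)
})

test_that("torsions are invariant under rigid motion (internal coordinates)", {
  fx <- build_duplex("GGAUCC", seed = 4)
  s <- fx$structure
  set.seed(99)
  s2 <- transform_structure(s, random_rotation(), c(12, -3, 7))
  t1 <- torsions(s); t2 <- torsions(s2)
  for (a in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")) {
    expect_equal(t2[[a]], t1[[a]], tolerance = 1e-9)
  }
  expect_equal(mcq(t2, t1)$mcq, 0, tolerance = 1e-9)
})

test_that("uniform torsion perturbation raises MCQ by the shift", {
  fx <- build_duplex("GGCAUCGC", seed = 13)
  s <- fx$structure
  t0 <- torsions(s)
  prev <- -1
  for (shift in c(5, 15, 45)) {
    ps <- perturb_torsions(s, shift)
    m <- mcq(torsions(ps), t0)
    expect_equal(m$mcq, shift, tolerance = 0.5)
    expect_gt(m$mcq, prev)
    prev <- m$mcq
  }
  # zero shift is the identity
  expect_equal(mcq(torsions(perturb_torsions(s, 0)), t0)$mcq, 0,
               tolerance = 1e-6)
})
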