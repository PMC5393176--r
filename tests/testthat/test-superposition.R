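test_that("kabsch recovers an applied rigid motion exactly", {
  set.seed(42)
  pts <- matrix(rnorm(15, sd = 3), 5, 3)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg z
  tr <- c(5, -2, 1)
  moved <- sweep(pts %*% t(R), 2, tr, "+")
  sp <- kabsch_superpose(pts, moved)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(sp$rotation, R, tolerance = 1e-9)
  expect_equal(sp$translation, tr, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch agrees with the quaternion oracle on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(3:10, 1)
    a <- matrix(rnorm(3 * n, sd = 4), n, 3)
    b <- a %*% t(random_rotation()) + matrix(rnorm(3 * n, sd = 0.6), n, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("reflections are rejected: chiral set vs mirror keeps det +1", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  mirror <- pts %*% diag(c(1, 1, -1))
  sp <- kabsch_superpose(pts, mirror)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)
  # brute force over both sign choices: the reflected fit would be lower
  expect_lt(quaternion_rmsd(pts, mirror), sp$rmsd + 1e-12)
})

test_that("global_rmsd is 0 for identity and pure rigid motion", {
  fx <- build_duplex("GGCAUC", seed = 5)
  s <- fx$structure
  m <- map_residues(s, s)
  expect_equal(global_rmsd(s, s, m), 0, tolerance = 1e-9)
  s2 <- transform_structure(s, random_rotation(), c(3, -8, 2))
  expect_equal(global_rmsd(s2, s, m), 0, tolerance = 1e-9)
  expect_equal(global_rmsd(s, s2, m), 0, tolerance = 1e-9)
})

test_that("global_rmsd equals direct kabsch on the stacked coordinates", {
  fx <- build_duplex("GGCAUCGG", seed = 6)
  s <- fx$structure
  noisy <- perturb_noise(s, 0.4, seed = 11)
  mp <- map_residues(noisy, s)
  pc <- rnassess:::paired_coordinates(noisy, s, mp, "heavy")
  expect_equal(global_rmsd(noisy, s, mp),
               kabsch_superpose(pc$model, pc$ref)$rmsd, tolerance = 1e-12)
  # symmetry
  mp2 <- map_residues(s, noisy)
  expect_equal(global_rmsd(noisy, s, mp), global_rmsd(s, noisy, mp2),
               tolerance = 1e-9)
})

test_that("deformation profile is zero for identity and global rigid motion", {
  fx <- build_duplex("GACUGG", seed = 3)
  s <- fx$structure
  m <- map_residues(s, s)
  dp <- deformation_profile(s, s, m)
  expect_true(all(abs(dp$values[!dp$degenerate, !dp$degenerate]) < 1e-9))
  s2 <- transform_structure(s, random_rotation(), c(-4, 9, 1))
  dp2 <- deformation_profile(s2, s, m)
  expect_true(all(abs(dp2$values[!dp2$degenerate, !dp2$degenerate]) < 1e-9))
})

test_that("hinge fixture: intra-domain DP ~ 0, inter-domain large", {
  fx <- build_duplex("GGCAUCAGGCAUCAGG", seed = 9)
  ref <- subset_residues(fx$structure,
                         residue_table(fx$structure)$key[1:16])  # strand A
  h <- perturb_hinge(ref, res_key("A", 8, ""), 30)
  m <- map_residues(h$structure, ref)
  dp <- deformation_profile(h$structure, ref, m)
  keys <- dp$residue_keys
  i1 <- which(keys %in% h$domain_split$head)
  i2 <- which(keys %in% h$domain_split$tail)
  intra1 <- dp$values[i1, i1]; intra2 <- dp$values[i2, i2]
  inter <- dp$values[i1, i2]
  expect_lt(max(intra1, na.rm = TRUE), 0.1)
  expect_lt(max(intra2, na.rm = TRUE), 0.1)
  expect_gt(mean(inter, na.rm = TRUE), 2)
  # monotone neighborhood: no entry in row i is below the diagonal entry
  for (i in c(i1[1], i2[length(i2)])) {
    expect_true(all(dp$values[i, ] >= dp$values[i, i] - 1e-9))
  }
  # domain aggregation: intra mean < inter mean, min <= mean <= max
  stats <- aggregate_dp(dp, list(head = h$domain_split$head,
                                 tail = h$domain_split$tail))
  intra_mean <- stats$mean[stats$domain_a == stats$domain_b]
  inter_mean <- stats$mean[stats$domain_a != stats$domain_b]
  expect_true(all(intra_mean < inter_mean))
  expect_true(all(stats$min <= stats$mean & stats$mean <= stats$max))
})

test_that("aggregate_dp handles constant matrices and bad domains", {
  fx <- build_duplex("GGCC", seed = 1)
  s <- fx$structure
  m <- map_residues(s, s)
  dp <- deformation_profile(s, s, m)
  dp$values[] <- 1
  doms <- list(d1 = dp$residue_keys[1:4], d2 = dp$residue_keys[5:8])
  st <- aggregate_dp(dp, doms)
  expect_true(all(st$min == 1 & st$max == 1 & st$mean == 1))
  expect_error(aggregate_dp(dp, list(bad = "Z:99")), "not in DP")
})

test_that("deformation index follows the stated conventions", {
  expect_equal(deformation_index(4.0, 0.8), 5.0)
  expect_equal(deformation_index(2.37, 1.0), 2.37)
  expect_true(is.na(deformation_index(3.0, 0.0)))
  expect_true(is.na(deformation_index(3.0, NA)))
  expect_error(deformation_index(-1, 0.5), ">= 0")
})

test_that("RMSD grows monotonically with noise sigma", {
  fx <- build_duplex("GGCAUCGCAUGGCAUCGCAU", seed = 4)
  s <- fx$structure
  m <- map_residues(s, s)
  sigmas <- c(0.1, 0.5, 1.0, 2.0)
  means <- vapply(sigmas, function(sg) {
    mean(vapply(1:5, function(k) {
      global_rmsd(perturb_noise(s, sg, seed = k), s, m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
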