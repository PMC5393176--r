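test_that("base_frame fits planar bases and flags undefined frames", {
  fx <- build_duplex("GGCC", seed = 1)
  res <- rnassess:::residue_atoms(fx$structure, res_key("A", 2, ""))
  fr <- base_frame(res)
  expect_equal(sqrt(sum(fr$normal^2)), 1, tolerance = 1e-9)
  # origin within 3 A of every ring atom
  ring <- select_atoms(res, "base")
  d <- sqrt(rowSums(sweep(rnassess:::coord_matrix(ring), 2, fr$origin)^2))
  expect_true(all(d < 3))
  # SVD oracle: displace one atom off-plane, compare with direct svd fit
  res2 <- res
  i <- which(res2$name == "C8")
  res2$z[i] <- res2$z[i] + 0.5
  fr2 <- base_frame(res2)
  ring2 <- select_atoms(res2, "base")
  xyz <- rnassess:::coord_matrix(ring2)
  v <- svd(sweep(xyz, 2, colMeans(xyz)))$v[, 3]
  expect_equal(abs(sum(fr2$normal * v)), 1, tolerance = 1e-9)
  # backbone-only residue: frame undefined
  bb <- res[res$name %in% c("P", "O5'", "C5'", "C4'", "C3'", "O3'"), ]
  expect_null(base_frame(bb))
})

test_that("fixture duplexes are annotated exactly as constructed", {
  fx <- build_duplex("GGCAUCGC", seed = 3)
  pairs <- detect_base_pairs(fx$structure)
  expect_equal(nrow(pairs), 8)
  expect_true(all(pairs$edge_i == "WC" & pairs$edge_j == "WC"))
  expect_true(all(pairs$orientation == "cis"))
  expect_true(all(pairs$is_canonical))
  got <- sort(paste(pairs$i, pairs$j))
  want <- sort(paste(pmin(fx$ground_truth$wc_pairs$i, fx$ground_truth$wc_pairs$j),
                     pmax(fx$ground_truth$wc_pairs$i, fx$ground_truth$wc_pairs$j)))
  expect_equal(got, want)
})

test_that("separated strands and isolated nucleotides yield no pairs", {
  fx <- build_duplex("GGCAUC", seed = 2)
  s <- fx$structure
  sel <- s$atoms$chain == "B"
  s$atoms$x[sel] <- s$atoms$x[sel] + 20
  expect_equal(nrow(detect_base_pairs(s)), 0)
  single <- subset_residues(fx$structure, res_key("A", 1, ""))
  expect_equal(nrow(detect_base_pairs(single)), 0)
})

test_that("stacking follows the construction: neighbors stack, partners do not", {
  fx <- build_duplex("GGCAUCGC", seed = 3)
  st <- detect_stacking(fx$structure)
  got <- sort(paste(st$i, st$j))
  want <- sort(paste(fx$ground_truth$stack_pairs$i, fx$ground_truth$stack_pairs$j))
  expect_equal(got, want)
  # WC partners are coplanar: vertical separation ~0 fails the window
  expect_false(any(paste(st$i, st$j) %in%
                   paste(fx$ground_truth$wc_pairs$i, fx$ground_truth$wc_pairs$j)))
})

test_that("interaction_sets partitions into wc / nwc / stack", {
  fx <- build_duplex("GGGGCCCC", seed = 1)
  is1 <- interaction_sets(fx$structure)
  expect_equal(nrow(is1$wc), 8)
  expect_equal(nrow(is1$nwc), 0)
  expect_equal(nrow(is1$stack), 14)
  expect_equal(nrow(is1$all), 8)
})

test_that("an engineered G-U wobble lands in the wc set when cis WC/WC", {
  fx <- build_duplex("GGGGCCCC", seed = 1)
  # pair A:3 (G) - B:6 (C): make it G-U
  s <- mutate_base(fx$structure, res_key("B", 6, ""), "U")
  pairs <- detect_base_pairs(s)
  row <- pairs[pairs$i == res_key("A", 3, "") & pairs$j == res_key("B", 6, ""), ]
  expect_equal(nrow(row), 1)
  is1 <- interaction_sets(s)
  in_wc <- any(is1$wc$i == res_key("A", 3, "") & is1$wc$j == res_key("B", 6, ""))
  expect_equal(in_wc,
               row$edge_i == "WC" && row$edge_j == "WC" && row$orientation == "cis")
  # strict flag excludes wobbles from wc
  is2 <- interaction_sets(s, annotation_config(strict_wc = TRUE))
  expect_false(any(is2$wc$i == res_key("A", 3, "") & is2$wc$j == res_key("B", 6, "")))
})

test_that("annotation is invariant to rigid motion", {
  fx <- build_duplex("GAUCGAUC", seed = 5)
  s <- fx$structure
  set.seed(12)
  s2 <- transform_structure(s, random_rotation(), c(30, -12, 4))
  p1 <- detect_base_pairs(s); p2 <- detect_base_pairs(s2)
  expect_equal(p2, p1)
  expect_equal(detect_stacking(s2), detect_stacking(s))
})

test_that("translating one strand away gives non-increasing pair counts", {
  fx <- build_duplex("GGCAUCGC", seed = 6)
  counts <- vapply(seq(0, 10, by = 1), function(dx) {
    s <- fx$structure
    sel <- s$atoms$chain == "B"
    s$atoms$x[sel] <- s$atoms$x[sel] + dx
    nrow(detect_base_pairs(s))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 8)
  expect_equal(counts[length(counts)], 0)
})

test_that("ground truth survives a PDB round-trip", {
  fx <- build_duplex("GACUAGUC", seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, f)
  s2 <- read_structure(f)
  pairs <- detect_base_pairs(s2)
  got <- sort(paste(pairs$i[pairs$is_canonical], pairs$j[pairs$is_canonical]))
  want <- sort(paste(fx$ground_truth$wc_pairs$i, fx$ground_truth$wc_pairs$j))
  expect_equal(got, want)
})
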