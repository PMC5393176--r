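pair_df <- function(...) {
  v <- list(...)
  data.frame(i = vapply(v, `[`, "", 1), j = vapply(v, `[`, "", 2),
             stringsAsFactors = FALSE)
}

test_that("INF analytic cases", {
  a <- pair_df(c("x1", "y1"), c("x2", "y2"))
  expect_equal(inf_score(a, a), 1.0)
  half <- inf_score(pair_df(c("a", "b")), pair_df(c("a", "b"), c("a", "c")))
  # ref {ab}, model {ab, ac}: TP 1, precision 1/2, sensitivity 1 -> sqrt(.5)
  expect_equal(half, sqrt(0.5))
  # half-overlap: ref {a,b} model {a,c} -> 0.5
  r <- pair_df(c("p", "q"), c("p", "r"))
  m <- pair_df(c("p", "q"), c("p", "s"))
  expect_equal(inf_score(r, m), 0.5)
  expect_equal(inf_score(a, pair_df()), 0.0)
  expect_true(is.na(inf_score(pair_df(), pair_df())))
  # unordered: reversed pairs are the same pair
  expect_equal(inf_score(pair_df(c("u", "v")), pair_df(c("v", "u"))), 1.0)
})

test_that("self-assessment yields the perfect panel", {
  fx <- build_duplex("GGCAUCGC", seed = 1)
  a <- assess_model(fx$structure, fx$structure)
  b <- a$best
  expect_equal(b$rmsd, 0, tolerance = 1e-9)
  expect_equal(b$inf_all, 1)
  expect_equal(b$inf_wc, 1)
  expect_equal(b$inf_stack, 1)
  expect_true(is.na(b$inf_nwc))       # nothing non-WC to predict
  expect_equal(b$mcq, 0, tolerance = 1e-9)
  expect_equal(b$di_all, 0, tolerance = 1e-9)
  expect_equal(b$coverage, 1)
  expect_equal(b$clash_score, 0)
})

test_that("best-over-references picks the smaller RMSD and orchestration matches standalone calls", {
  fx <- build_duplex("GGCAUCGCAU", seed = 2)
  ref1 <- fx$structure
  ref2 <- perturb_noise(ref1, 1.0, seed = 9); ref2$id <- "ref2"
  model <- perturb_noise(ref1, 0.2, seed = 5); model$id <- "model"
  a <- assess_model(model, list(ref1, ref2))
  expect_equal(length(a$records), 2)
  expect_equal(a$best$reference_id, ref1$id)
  # standalone recomputation of the best record's metrics
  m <- map_residues(model, ref1)
  expect_equal(a$best$rmsd, global_rmsd(model, ref1, m))
  expect_equal(a$best$mcq, mcq(torsions(model, m$pairs$model_key),
                               torsions(ref1, m$pairs$ref_key))$mcq)
  expect_equal(a$best$clash_score,
               clash_score(rnassess:::nucleotide_only(model))$score)
  if (!is.na(a$best$inf_all) && a$best$inf_all > 0) {
    expect_equal(a$best$di_all, a$best$rmsd / a$best$inf_all)
  }
})

test_that("rank_models: direction, ties, NA sinking", {
  recs <- list(
    list(model_id = "m1", rmsd = 3.2, inf_wc = 0.9, mcq = 12),
    list(model_id = "m2", rmsd = 1.1, inf_wc = 0.9, mcq = NA),
    list(model_id = "m3", rmsd = 2.0, inf_wc = 0.5, mcq = 8))
  r <- rank_models(recs, "rmsd")
  expect_equal(r$model_id, c("m2", "m3", "m1"))
  expect_equal(r$rank, 1:3)
  r2 <- rank_models(recs, "inf_wc")  # descending; tie m1/m2 broken by id
  expect_equal(r2$model_id, c("m1", "m2", "m3"))
  r3 <- rank_models(recs, "mcq")     # NA last
  expect_equal(r3$model_id, c("m3", "m1", "m2"))
  expect_error(rank_models(recs, "nope"), "unknown metric")
  # permutation invariance
  r4 <- rank_models(recs[c(3, 1, 2)], "rmsd")
  expect_equal(r4, r)
})

test_that("radar data: dominant group ranks 1 everywhere; divergent first/best", {
  mk <- function(g, sub, rmsd, extra = 0) {
    list(model_id = paste0(g, "_", sub), group_id = g, submitted_rank = sub,
         rmsd = rmsd, di_all = rmsd * 1.2 + extra, inf_wc = 1 / (1 + rmsd),
         inf_nwc = 0.5 / (1 + rmsd), inf_stack = 0.8 / (1 + rmsd),
         mcq = 10 * rmsd, clash_score = rmsd)
  }
  recs <- list(mk("g1", 1, 1.0), mk("g1", 2, 3.0),
               mk("g2", 1, 5.0), mk("g2", 2, 4.0),
               mk("g3", 1, 9.0), mk("g3", 2, 2.0))
  rd <- radar_data(recs)
  expect_equal(unname(unlist(rd$first["g1", ])), rep(1, 7))
  # g3's best-RMSD model (rank-2 model, rmsd 2) beats its first (rmsd 9)
  expect_lt(rd$best_rmsd["g3", "rmsd"], rd$first["g3", "rmsd"])
  expect_true(all(as.matrix(rd$first) >= 1 & as.matrix(rd$first) <= 3))
  # single group: all ranks 1
  rd1 <- radar_data(recs[1:2])
  expect_equal(unname(unlist(rd1$first["g1", ])), rep(1, 7))
  expect_warning(radar_data(list(mk("g4", NA, 1))), "submitted_rank")
})

test_that("bfactor_profile averages heavy atoms per residue", {
  fx <- build_duplex("GGCC", seed = 1)
  s <- fx$structure
  s$atoms$b <- 30
  bp <- bfactor_profile(s)
  expect_true(all(bp$b_mean == 30))
  # residue with atoms {20, 40} -> 30
  two <- rna_structure(data.frame(
    chain = "A", resno = 1L, icode = "", resname = "G",
    name = c("C1'", "N9"), element = c("C", "N"),
    x = c(0, 1.5), y = 0, z = 0, occ = 1, b = c(20, 40), het = FALSE,
    stringsAsFactors = FALSE), id = "two")
  expect_equal(bfactor_profile(two, keys = "A:1")$b_mean, 30)
  s2 <- transform_structure(s, rnassess:::rot_z(45), c(1, 2, 3))
  expect_equal(bfactor_profile(s2), bfactor_profile(s))
})

test_that("summary table and JSON report carry the documented columns", {
  fx <- build_duplex("GGCAUC", seed = 3)
  model <- perturb_noise(fx$structure, 0.3, seed = 2)
  a <- assess_model(model, fx$structure, group_id = "g1", submitted_rank = 1)
  tab <- summary_table(a)
  expect_equal(names(tab),
               c("model", "group", "submitted_rank", "reference", "RMSD",
                 "DI_all", "INF_all", "INF_wc", "INF_nwc", "INF_stack",
                 "MCQ", "Clash", "coverage"))
  f <- withr::local_tempfile(fileext = ".json")
  write_report(a, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(length(parsed), 1)
  expect_equal(parsed[[1]]$best$rmsd, a$best$rmsd, tolerance = 1e-6)
})

test_that("monotone degradation orders ranks by noise level", {
  fx <- build_duplex("GGCAUCGCAU", seed = 4)
  ref <- fx$structure
  sigmas <- c(0.2, 0.8, 1.6)
  recs <- lapply(seq_along(sigmas), function(k) {
    m <- perturb_noise(ref, sigmas[k], seed = 21)
    m$id <- paste0("m", k)
    assess_model(m, ref)$best
  })
  expect_equal(rank_models(recs, "rmsd")$model_id, c("m1", "m2", "m3"))
})
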