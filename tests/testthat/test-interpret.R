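# The exact identities here (full-window equality, infinite-cutoff
# equality) hold for any parameter values, so an untrained seeded model is
# the right probe: fast and free of training noise.

test_that("neighbor counting matches brute force on constructed geometry", {
  rec <- toy_record("lin", cbind(c(0, 5, 10), c(0, 0, 0), c(0, 0, 0)), b = 1:3)
  nh <- nhat(rec, rcut = 6)
  expect_equal(nh$n_i, c(1, 2, 1))
  expect_equal(nh$n_bar, 4 / 3, tolerance = 1e-12)
  expect_equal(nh$n_hat, 2 / 3, tolerance = 1e-12)

  expect_equal(nhat(rec, rcut = 4)$n_hat, 0)    # below min pairwise distance
  expect_equal(nhat(rec, rcut = 10)$n_hat, 1)   # covers the diameter

  # randomized brute-force oracle
  rec2 <- random_record(n = 25, seed = 14)
  xyz <- as.matrix(rec2$sites[, c("x", "y", "z")])
  for (rc in c(5, 8, 12)) {
    brute <- vapply(1:25, function(i) {
      sum(vapply(setdiff(1:25, i), function(j)
        sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= rc, logical(1)))
    }, numeric(1))
    expect_equal(nhat(rec2, rc)$n_i, brute)
    expect_equal(nhat(rec2, rc)$n_hat, mean(brute) / 24, tolerance = 1e-12)
  }
})

test_that("n_hat is bounded, monotone in rcut, and shrinks under a window", {
  rec <- random_record(n = 30, seed = 15)
  grid <- seq(2, 40, by = 2)
  vals <- vapply(grid, function(rc) nhat(rec, rc)$n_hat, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) >= 0))
  windowed <- vapply(grid, function(rc) nhat(rec, rc, ws = 4)$n_hat, numeric(1))
  expect_true(all(windowed <= vals + 1e-15))
  expect_error(nhat(toy_record("one", cbind(0, 0, 0), b = 1), 5), "at least 2")
})

test_that("a window covering the protein reproduces the full prediction", {
  m <- tiny_model(seed = 41)
  rec <- random_record(n = 18, seed = 16)
  enc <- encode_protein(rec)
  full <- predict_protein(m, enc)
  for (i in c(1, 2, 9, 18)) {
    expect_identical(window_predict(m, enc, i, ws = 17), full[i])
    expect_identical(window_predict(m, enc, i, ws = 40), full[i])
  }
  # ws = 0: prediction from the residue's own features alone
  single <- predict_protein(m, enc$X[5, , drop = FALSE])
  expect_identical(window_predict(m, enc, 5, ws = 0), single)
  expect_error(window_predict(m, enc, 19, ws = 2), "out of range")
})

test_that("window sweeps find the plateau consistently", {
  m <- tiny_model(seed = 42)
  rec <- random_record(n = 20, seed = 17)
  enc <- encode_protein(rec)
  sw <- window_sweep(m, enc, ws_grid = c(0, 2, 4, 8, 19), plateau_tol = 0.02)
  expect_equal(nrow(sw$sweep), 5L)
  # the largest window equals the unwindowed evaluation
  full_pcc <- pearson_cc(predict_protein(m, enc), enc$y)
  expect_equal(sw$sweep$pcc[5], full_pcc, tolerance = 1e-12)
  expect_equal(sw$plateau_pcc, full_pcc, tolerance = 1e-12)
  # degenerate tolerance accepts the smallest grid point
  expect_equal(window_sweep(m, enc, ws_grid = c(0, 2, 4, 8, 19),
                            plateau_tol = Inf)$wsc_estimate, 0)
  expect_error(window_sweep(m, enc, ws_grid = c(4, 2)), "ascending")
})

test_that("an infinite cutoff is bit-identical to the unmasked prediction", {
  m <- tiny_model(seed = 43)
  rec <- random_record(n = 15, seed = 18)
  enc <- encode_protein(rec)
  full <- predict_protein(m, enc)
  for (i in seq_len(15))
    expect_identical(masked_predict_rcut(m, rec, enc, i, Inf), full[i])
  # large finite cutoff covering the diameter also suffices
  diam <- max(dist(as.matrix(rec$sites[, c("x", "y", "z")])))
  expect_identical(masked_predict_rcut(m, rec, enc, 7, diam), full[7])
  expect_error(masked_predict_rcut(m, rec, enc, 1, -1), ">= 0")
})

test_that("a cutoff below the minimum distance leaves only the residue itself", {
  m <- tiny_model(seed = 44)
  rec <- random_record(n = 12, seed = 19)
  enc <- encode_protein(rec)
  lone <- enc$X * 0
  lone[6, ] <- enc$X[6, ]
  expect_identical(masked_predict_rcut(m, rec, enc, 6, 0.5),
                   predict_protein(m, lone)[6])
})

test_that("the deletion convention is offered and differs by design", {
  m <- tiny_model(seed = 45)
  rec <- random_record(n = 12, seed = 20)
  enc <- encode_protein(rec)
  z <- masked_predict_rcut(m, rec, enc, 6, 6, convention = "zero")
  d <- masked_predict_rcut(m, rec, enc, 6, 6, convention = "delete")
  expect_true(is.finite(z) && is.finite(d))
  # with everything in radius both conventions equal the full prediction
  expect_identical(masked_predict_rcut(m, rec, enc, 6, Inf, "delete"),
                   predict_protein(m, enc)[6])
})

test_that("cutoff sweeps converge to the unmasked PCC and count pairs cubically", {
  m <- tiny_model(seed = 46)
  recs <- lapply(1:3, function(s) random_record(n = 15, seed = 25 + s,
                                                id = paste0("rc", s)))
  encs <- encode_dataset(recs)
  diam <- max(vapply(recs, function(r)
    max(dist(as.matrix(r$sites[, c("x", "y", "z")]))), numeric(1)))
  grid <- c(4, 8, 12, ceiling(diam) + 1)
  rs <- rcut_sweep(m, recs, encs, grid)
  expect_equal(rs$sweep$pcc_ratio[4], 1, tolerance = 1e-12)
  expect_true(all(diff(rs$sweep$atoms_considered) >= 0))
  n_tot <- sum(vapply(recs, n_residues, integer(1))^2 -
                 vapply(recs, n_residues, integer(1)))
  expect_equal(rs$sweep$atoms_considered[4], n_tot)  # all ordered pairs

  # pair counts grow like the enclosed volume in the bulk of a globule
  big <- random_record(n = 120, seed = 29)
  rg <- c(4, 6, 8, 10)
  counts <- vapply(rg, function(rc) nhat(big, rc)$n_bar, numeric(1))
  fit <- lm(log(counts) ~ log(rg))
  expect_gt(coef(fit)[2], 1.8)  # near-cubic growth, attenuated by the surface
})

test_that("per-atom marginal contributions difference correctly and telescope", {
  sweep <- list(sweep = data.frame(rcut = c(1, 2, 3),
                                   pcc = c(0.2, 0.6, 0.8),
                                   pcc_ratio = c(0.25, 0.75, 1),
                                   atoms_considered = c(10, 40, 80)),
                pcc_all = 0.8)
  d <- delta_pcc_per_atom(sweep)
  expect_equal(d$ratio, c(0.4 / 30, 0.2 / 40), tolerance = 1e-12)
  expect_equal(d$deuc, c(1.5, 2.5))
  expect_lt(abs(sum(d$delta_pcc) - (0.8 - 0.2)), 1e-12)

  flat <- sweep
  flat$sweep$pcc <- rep(0.5, 3)
  expect_equal(delta_pcc_per_atom(flat)$ratio, c(0, 0))

  gap <- sweep
  gap$sweep$atoms_considered <- c(10, 10, 80)
  dg <- delta_pcc_per_atom(gap)
  expect_equal(nrow(dg), 1L)
  expect_equal(attr(dg, "skipped"), 1.5)

  none <- sweep
  none$sweep$atoms_considered <- c(10, 10, 10)
  expect_error(delta_pcc_per_atom(none), "no grid step")
})

test_that("an affine n_hat curve yields a perfect curve correlation", {
  rec <- random_record(n = 20, seed = 30)
  ws_grid <- c(0, 2, 4, 8, 16)
  nh <- vapply(ws_grid, function(w) nhat(rec, 8, ws = w)$n_hat, numeric(1))
  fake <- list(sweep = data.frame(ws = ws_grid, pcc = 0.1 + 0.5 * nh))
  out <- pccn_vs_rcut(list(fake), list(rec), rcut_grid = 8, ws_grid = ws_grid)
  expect_equal(out$curve$pccn_mean, 1, tolerance = 1e-12)
  expect_equal(out$peak_rcut, 8)
  # a single protein's mean is its own curve correlation
  expect_equal(out$curve$n_proteins, 1L)
})

test_that("group summaries match a brute-force group-by and partition counts", {
  recs <- lapply(1:2, function(s) random_record(n = 20, seed = 34 + s,
                                                id = paste0("g", s)))
  encs <- encode_dataset(recs)
  preds <- lapply(encs, function(e) e$y * 0.5 + 0.1)
  gs <- group_summary(recs, encs, predictions = preds,
                      group_by = "amino_acid")
  expect_equal(sum(gs$count), 40L)
  key <- unlist(lapply(recs, function(r) r$sites$aa_code))
  actual <- unlist(lapply(encs, `[[`, "y"))
  brute_mean <- tapply(actual, key, mean)
  expect_equal(gs$mean_actual, as.vector(brute_mean[gs$group]),
               tolerance = 1e-12)
  brute_sd <- tapply(actual, key, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(gs$sd_actual, as.vector(brute_sd[gs$group]), tolerance = 1e-12)

  ss <- group_summary(recs, encs, predictions = preds, group_by = "ss_class")
  expect_equal(sum(ss$count), 40L)
  expect_true(all(ss$group %in% c("helix", "sheet", "coil")))
})

test_that("constructed group values are recovered exactly", {
  xyz <- bflex:::helix_template(9, 3.8)
  rec <- toy_record("gly_ala", xyz, b = rep(c(30, 10), 5),
                    aa = rep(c("GLY", "ALA"), 5), ss = "coil")
  enc <- encode_protein(rec, mask = feature_mask(TRUE, FALSE, TRUE, TRUE))
  gs <- group_summary(list(rec), list(enc), predictions = list(enc$y),
                      group_by = "amino_acid")
  expect_equal(gs$mean_actual[gs$group == "GLY"], 1, tolerance = 1e-12)
  expect_equal(gs$mean_actual[gs$group == "ALA"], -1, tolerance = 1e-12)
  expect_equal(gs$sd_actual, c(0, 0), tolerance = 1e-12)
  expect_true("TRP" %in% attr(gs, "omitted"))
})
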