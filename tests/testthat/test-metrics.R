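test_that("kabsch recovers constructed rigid motions exactly", {
  set.seed(21)
  x <- matrix(rnorm(30, sd = 4), 10)
  tf <- kabsch(x, x)
  expect_lt(tf$rmsd, 1e-12)
  expect_lt(max(abs(tf$R - diag(3))), 1e-9)
  for (s in 1:4) {
    rig <- random_rigid(s)
    y <- sweep(x %*% rig$R, 2, rig$t, "+")
    tf <- kabsch(x, y)
    expect_lt(tf$rmsd, 1e-9)
    expect_equal(det(tf$R), 1, tolerance = 1e-9)
    expect_lt(max(abs(apply_transform(tf, x) - y)), 1e-9)
  }
})

test_that("kabsch rejects degenerate geometry", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear|coincident")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 4, 3)), "collinear|coincident")
  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3")
})

test_that("kabsch matches a brute-force rotation-grid search", {
  for (s in 5:7) {
    set.seed(s)
    x <- matrix(rnorm(12, sd = 2), 4)
    y <- matrix(rnorm(12, sd = 2), 4)
    opt <- kabsch(x, y)$rmsd
    grid <- grid_rmsd(x, y, step_deg = 15)
    expect_lte(opt, grid + 1e-9)       # the grid can never beat the optimum
    # grid resolution bound: a 15-degree step misrotates a point at radius r
    # by at most 2 sin(7.5 deg) r
    rmax <- sqrt(max(rowSums(sweep(x, 2, colMeans(x))^2)))
    expect_lte(grid - opt, 2 * sin(7.5 * pi / 180) * rmax + 1e-9)
  }
})

test_that("kabsch agrees with an independent superposition implementation", {
  set.seed(33)
  x <- matrix(rnorm(36, sd = 3), 12)
  y <- x + matrix(rnorm(36, sd = 0.8), 12)
  ours <- kabsch(x, y)$rmsd
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(y)),
                           mobile = as.numeric(t(x)),
                           fixed.inds = 1:36, mobile.inds = 1:36)
  theirs <- bio3d::rmsd(as.numeric(t(y)), fitted)
  expect_lt(abs(ours - theirs), 1e-3)  # bio3d rounds to 3 digits
})

test_that("ca_rmsd is zero under congruence and symmetric in its arguments", {
  mod <- make_backbone(synthetic_spec(n_residues = 10, seed = 1))
  expect_equal(as.numeric(ca_rmsd(mod, mod)), 0, tolerance = 1e-12)
  shifted <- mod
  shifted$residues$x <- shifted$residues$x + 1
  shifted$atoms$x <- shifted$atoms$x + 1
  expect_lt(as.numeric(ca_rmsd(shifted, mod)), 1e-9)
  hit <- inject_conformational_error(mod, c(5, 5), 3, seed = 2)
  expect_equal(as.numeric(ca_rmsd(hit, mod)), as.numeric(ca_rmsd(mod, hit)),
               tolerance = 1e-9)
  # matches a direct Kabsch on all pairs
  expect_equal(as.numeric(ca_rmsd(hit, mod)),
               kabsch(ca_matrix(hit), ca_matrix(mod))$rmsd,
               tolerance = 1e-12)
  expect_equal(attr(ca_rmsd(hit, mod), "n_pairs"), 10L)
})

test_that("GDT-HA is 1 for identical structures and invariant to rigid motion", {
  mod <- make_backbone(synthetic_spec(n_residues = 10, seed = 3))
  g <- gdt_ha(mod, mod)
  expect_equal(as.numeric(g), 1)
  expect_equal(unname(attr(g, "per_threshold")), rep(1, 4))
  rig <- random_rigid(9)
  rot <- mod
  xyz <- sweep(as.matrix(rot$residues[, c("x", "y", "z")]) %*% rig$R, 2,
               rig$t, "+")
  rot$residues[, c("x", "y", "z")] <- xyz
  rot$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(as.numeric(gdt_ha(rot, mod)), 1)
})

test_that("two of ten Calphas displaced 10 A give GDT-HA 0.8 exactly", {
  mod <- make_backbone(synthetic_spec(n_residues = 10, seed = 4))
  disp <- inject_conformational_error(mod, c(4, 5), 10, seed = 5)
  g <- gdt_ha(disp, mod)
  expect_equal(unname(attr(g, "per_threshold")), rep(0.8, 4))
  expect_equal(as.numeric(g), 0.8)
})

test_that("per-threshold fractions are monotone and beat the global fit", {
  mod <- make_backbone(synthetic_spec(n_residues = 12, seed = 5))
  disp <- inject_conformational_error(mod, c(3, 6), 5, seed = 6)
  g <- gdt_fractions(disp, mod)
  expect_true(all(diff(g$per_threshold) >= 0))
  expect_true(all(g$per_threshold >= 0) && all(g$per_threshold <= 1))
  # the seed search can only improve on the single global superposition
  tf <- kabsch(ca_matrix(disp), ca_matrix(mod))
  d <- sqrt(rowSums((apply_transform(tf, ca_matrix(disp)) -
                       ca_matrix(mod))^2))
  global_frac <- vapply(c(0.5, 1, 2, 4), function(t) mean(d <= t), numeric(1))
  expect_true(all(g$per_threshold >= global_frac - 1e-12))
})

test_that("seed-and-extend equals exhaustive seeding on small structures", {
  cases <- list(
    list(n = 8, geom = "helix", region = c(3, 4), disp = 10),
    list(n = 10, geom = "extended", region = c(6, 8), disp = 12),
    list(n = 12, geom = "mixed", region = c(5, 9), disp = 10))
  for (cs in cases) {
    mod <- make_backbone(synthetic_spec(n_residues = cs$n,
                                        geometry = cs$geom, seed = cs$n))
    disp <- inject_conformational_error(mod, cs$region, cs$disp,
                                        seed = cs$n + 1)
    fast <- gdt_fractions(disp, mod)
    full <- gdt_fractions(disp, mod, seed_lengths = "exhaustive")
    expect_equal(fast$per_threshold, full$per_threshold, tolerance = 1e-12)
  }
})

test_that("the misalignment detector finds exactly the planted segment", {
  mod <- make_backbone(synthetic_spec(n_residues = 40, seed = 7))
  expect_equal(nrow(detect_misaligned(mod, mod)), 0)
  shifted <- inject_trace_shift(mod, c(11, 20), 4)  # about one helix turn
  segs <- detect_misaligned(shifted, mod)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, "11")
  expect_equal(segs$end, "20")
  expect_equal(segs$length, 10L)
  # exhaustive per-residue oracle: exactly the region is inconsistent
  tf <- kabsch(ca_matrix(shifted), ca_matrix(mod))
  x <- apply_transform(tf, ca_matrix(shifted))
  bad <- vapply(1:40, function(i) {
    d_own <- sqrt(sum((x[i, ] - ca_matrix(mod)[i, ])^2))
    d_all <- sqrt(rowSums(sweep(ca_matrix(mod), 2, x[i, ])^2))
    j <- which.min(d_all)
    d_own > 2 && d_all[j] <= 5 && j != i
  }, logical(1))
  expect_identical(which(bad), 11:20)
})

test_that("a single isolated outlier never forms a segment", {
  mod <- make_backbone(synthetic_spec(n_residues = 40, seed = 8))
  one <- inject_conformational_error(mod, c(25, 25), 3, seed = 9)
  expect_equal(nrow(detect_misaligned(one, mod)), 0)
  # three in a row is still below the minimum run of four
  three <- inject_trace_shift(mod, c(11, 13), 4)
  expect_equal(nrow(detect_misaligned(three, mod)), 0)
})

test_that("misalignment detection ignores chain labels", {
  mod <- make_backbone(synthetic_spec(n_residues = 30, seed = 10))
  shifted <- inject_trace_shift(mod, c(10, 15), 4)
  a <- detect_misaligned(shifted, mod)
  shifted$chain_id <- "Z"
  b <- detect_misaligned(shifted, mod)
  expect_identical(a, b)
})

test_that("evaluate_model assembles a coherent report", {
  mod <- make_backbone(synthetic_spec(n_residues = 20, seed = 11))
  disp <- inject_conformational_error(mod, c(8, 12), 9, seed = 12)
  rep <- evaluate_model(disp, mod)
  expect_s3_class(rep, "quality_report")
  expect_equal(rep$gdt_ha, mean(unname(rep$per_threshold)))
  expect_equal(rep$n_pairs, 20L)
  expect_equal(rep$coverage, 1)
})
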