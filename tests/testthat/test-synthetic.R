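test_that("backbone geometries have the stated Calpha spacings", {
  hel <- make_backbone(synthetic_spec(n_residues = 10, geometry = "helix",
                                      seed = 1))
  d <- sqrt(rowSums(diff(ca_matrix(hel))^2))
  expect_lt(max(d) - min(d), 1e-9)  # ideal helix: all spacings identical
  ext <- make_backbone(synthetic_spec(n_residues = 10, geometry = "extended",
                                      seed = 1))
  d <- sqrt(rowSums(diff(ca_matrix(ext))^2))
  expect_equal(unname(d), rep(3.8, 9), tolerance = 1e-9)
  expect_error(make_backbone(synthetic_spec(n_residues = 10,
                                            geometry = "coil", seed = 1)),
               "geometry")
})

test_that("generators are pure functions of the seed", {
  s <- synthetic_spec(n_residues = 12, seed = 99)
  m1 <- make_backbone(s)
  m2 <- make_backbone(s)
  expect_identical(m1$residues, m2$residues)
  v1 <- make_probability_volume(m1, s)
  v2 <- make_probability_volume(m2, s)
  expect_identical(v1$channels, v2$channels)
  other <- make_backbone(synthetic_spec(n_residues = 12, seed = 100))
  expect_false(identical(m1$residues$aa, other$residues$aa))
})

test_that("a peak of 1/20 degenerates to a uniform volume and zero scores", {
  spec <- synthetic_spec(n_residues = 10, peak_prob = 1 / 20, seed = 2)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  rng <- range(vapply(vol$channels, range, numeric(2)))
  expect_equal(rng, c(0.05, 0.05), tolerance = 1e-12)
  track <- daq_score(mod, vol)
  expect_lt(max(abs(track$entries$windowed)), 1e-12)
})

test_that("every voxel distribution sums to one", {
  spec <- synthetic_spec(n_residues = 15, seed = 3)
  vol <- make_probability_volume(make_backbone(spec), spec)
  set.seed(4)
  idx <- cbind(sample(vol$dims[1], 1000, TRUE),
               sample(vol$dims[2], 1000, TRUE),
               sample(vol$dims[3], 1000, TRUE))
  s <- Reduce(`+`, lapply(vol$channels, function(ch) ch[idx]))
  expect_lt(max(abs(s - 1)), 1e-9)
})

test_that("without noise the true type dominates its own channel at its Calpha", {
  spec <- synthetic_spec(n_residues = 12, noise = 0, seed = 5)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  ca <- ca_matrix(mod)
  for (i in seq_len(12)) {
    p_all <- vapply(AA_TYPES, function(a) {
      as.numeric(probability_at(vol, ca[i, , drop = FALSE], a))
    }, numeric(1))
    expect_equal(names(which.max(p_all)), mod$residues$aa[i])
    # direct lookup comparison: own type beats every other type at the Calpha
    expect_true(all(p_all[mod$residues$aa[i]] >= p_all))
  }
})

test_that("Dirichlet-style noise perturbs but preserves normalization", {
  spec <- synthetic_spec(n_residues = 10, noise = 0.05, seed = 6)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  clean <- make_probability_volume(mod, synthetic_spec(n_residues = 10,
                                                       noise = 0, seed = 6))
  expect_false(identical(vol$channels$A, clean$channels$A))
  s <- Reduce(`+`, vol$channels)
  expect_lt(max(abs(s - 1)), 1e-9)
})

test_that("register shifts move types, not coordinates", {
  mod <- make_backbone(synthetic_spec(n_residues = 30, seed = 7))
  expect_identical(inject_register_shift(mod, c(11, 20), 0), mod)
  sh <- inject_register_shift(mod, c(11, 20), 2)
  expect_identical(ca_matrix(sh), ca_matrix(mod))  # coordinates bit-identical
  expect_identical(sh$residues$aa[11], mod$residues$aa[13])
  expect_identical(sh$residues$aa[20], mod$residues$aa[22])
  expect_identical(sh$residues$aa[c(1:10, 21:30)],
                   mod$residues$aa[c(1:10, 21:30)])
  expect_error(inject_register_shift(mod, c(25, 30), 3), "chain end")
  expect_error(inject_register_shift(mod, c(28, 35), 1), "outside")
})

test_that("a shifted model scores lower inside the planted region", {
  spec <- synthetic_spec(n_residues = 60, seed = 8)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  sh <- inject_register_shift(mod, c(25, 34), 3)
  track <- daq_score(sh, vol, window = 19)
  w <- track$entries$windowed
  inside <- track$entries$number %in% 25:34
  expect_gt(mean(w[!inside]) - mean(w[inside]), 0)
})

test_that("conformational errors displace coordinates but keep types", {
  mod <- make_backbone(synthetic_spec(n_residues = 10, seed = 9))
  expect_identical(inject_conformational_error(mod, c(4, 5), 0), mod)
  disp <- inject_conformational_error(mod, c(4, 5), 10, seed = 10)
  expect_identical(disp$residues$aa, mod$residues$aa)
  moved <- sqrt(rowSums((ca_matrix(disp) - ca_matrix(mod))^2))
  expect_true(all(moved[4:5] > 8))
  expect_true(all(moved[-(4:5)] == 0))
  # links to the plant-and-count metric fixture
  expect_equal(as.numeric(gdt_ha(disp, mod)), 0.8)
})

test_that("a displaced run is caught by the misalignment detector", {
  mod <- make_backbone(synthetic_spec(n_residues = 30, seed = 11))
  tr <- inject_trace_shift(mod, c(12, 17), 4)
  segs <- detect_misaligned(tr, mod)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$length, 6L)
})
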