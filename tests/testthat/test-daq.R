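test_that("interpolation is exact on voxel centres and uniform interiors", {
  mod <- make_backbone(synthetic_spec(n_residues = 8, seed = 1))
  vol <- uniform_volume(mod)
  vol$channels$A[4, 5, 6] <- 0.07
  centre <- vol$origin + c(3, 4, 5) * vol$spacing
  expect_equal(as.numeric(probability_at(vol, centre, "A")), 0.07)
  interior <- vol$origin + c(2.37, 3.91, 4.2)
  expect_equal(as.numeric(probability_at(vol, interior, "C")), 0.05)
})

test_that("midpoint of an axis-aligned edge interpolates the corner mean", {
  channels <- lapply(AA_TYPES, function(a) array(0.05, dim = c(3, 3, 3)))
  names(channels) <- AA_TYPES
  channels$A[, , ] <- 0.3
  channels$A[1, 1, 1] <- 0.2
  channels$A[2, 1, 1] <- 0.4
  vol <- probability_volume(c(0, 0, 0), 1, channels)
  # eight-corner weighted sum: only the two x-corners carry weight 0.5 each
  expect_equal(as.numeric(probability_at(vol, c(0.5, 0, 0), "A")), 0.3)
})

test_that("out-of-grid lookups return the floor and are tallied", {
  mod <- make_backbone(synthetic_spec(n_residues = 8, seed = 1))
  vol <- uniform_volume(mod)
  v <- probability_at(vol, rbind(c(1e4, 0, 0), vol$origin + 1), "A",
                      floor = 1e-6)
  expect_equal(as.numeric(v), c(1e-6, 0.05))
  expect_equal(attr(v, "n_floored"), 1)
})

test_that("a uniform volume scores zero everywhere", {
  mod <- make_backbone(synthetic_spec(n_residues = 30, seed = 2))
  vol <- uniform_volume(mod)
  track <- daq_score(mod, vol, window = 19)
  expect_lt(max(abs(track$entries$raw)), 1e-12)
  expect_lt(max(abs(track$entries$windowed)), 1e-12)
  expect_equal(total_daq(track), 0, tolerance = 1e-12)
})

test_that("the two-position log-ratio matches hand arithmetic", {
  # type-A probabilities 0.4 and 0.2 at the two scored positions:
  # raw_1 = ln(0.4 / 0.3), raw_2 = ln(0.2 / 0.3)
  probs <- matrix((1 - 0.4) / 19, 2, 20, dimnames = list(NULL, AA_TYPES))
  probs[1, ] <- (1 - 0.4) / 19
  probs[2, ] <- (1 - 0.2) / 19
  probs[1, "A"] <- 0.4
  probs[2, "A"] <- 0.2
  vol <- probability_table(c("1", "2"), probs)
  mod <- protein_model("A", number = 1:2, aa = c("A", "A"),
                       ca = rbind(c(0, 0, 0), c(3.8, 0, 0)))
  track <- raw_daq_aa(mod, vol)
  expect_equal(track$entries$raw[1], log(0.4 / 0.3), tolerance = 1e-12)
  expect_equal(track$entries$raw[2], log(0.2 / 0.3), tolerance = 1e-12)
})

test_that("the score is positive iff the probability exceeds the type mean", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    aa <- sample(AA_TYPES, n, replace = TRUE)
    probs <- matrix(stats::runif(n * 20), n, 20,
                    dimnames = list(NULL, AA_TYPES))
    probs <- probs / rowSums(probs)
    vol <- probability_table(as.character(1:n), probs)
    mod <- protein_model("A", number = 1:n, aa = aa,
                         ca = cbind(3.8 * (1:n), 0, 0))
    track <- raw_daq_aa(mod, vol)
    own <- probs[cbind(1:n, match(aa, AA_TYPES))]
    expect_identical(track$entries$raw > 0,
                     unname(own > colMeans(probs)[aa]))
  }
})

test_that("raising a residue's own-type probability never lowers its score", {
  keys <- as.character(1:6)
  aa <- rep("L", 6)
  v1 <- table_volume(keys, aa, own_prob = 0.3)
  mod <- protein_model("A", number = 1:6, aa = aa, ca = cbind(1:6, 0, 0))
  r1 <- raw_daq_aa(mod, v1)$entries$raw[3]
  v2 <- v1
  v2$probs[3, "L"] <- 0.5  # hold all other lookups fixed
  r2 <- raw_daq_aa(mod, v2)$entries$raw[3]
  expect_gt(r2, r1)
})

test_that("scaling one channel globally cancels in the log-ratio", {
  spec <- synthetic_spec(n_residues = 20, seed = 4)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  base <- raw_daq_aa(mod, vol)$entries
  for (const in c(0.2, 7)) {
    v2 <- vol
    v2$channels$W <- v2$channels$W * const
    scaled <- raw_daq_aa(mod, v2)$entries
    w_res <- base$aa == "W"
    if (any(w_res)) {
      expect_lt(max(abs(scaled$raw[w_res] - base$raw[w_res])), 1e-9)
    }
  }
})

test_that("smoothing averages within the window and shrinks at edges", {
  mk_track <- function(raw, number = seq_along(raw)) {
    mod <- protein_model("A", number = number,
                         aa = rep("A", length(raw)),
                         ca = cbind(number, 0, 0))
    tr <- raw_daq_aa(mod, table_volume(as.character(number),
                                       rep("A", length(raw)), 0.3))
    tr$entries$raw <- raw
    tr
  }
  # constant raw stays constant
  tr <- smooth_track(mk_track(rep(1.7, 30)), 19)
  expect_equal(tr$entries$windowed, rep(1.7, 30))
  # window 1 is the identity
  raw <- stats::rnorm(15)
  expect_equal(smooth_track(mk_track(raw), 1)$entries$windowed, raw)
  # linear ramp: interior windowed value equals the centre value
  ramp <- as.numeric(1:50)
  sm <- smooth_track(mk_track(ramp), 19)
  expect_equal(sm$entries$windowed[10:41], ramp[10:41])
  # brute-force mean oracle at the shrunken edge
  expect_equal(sm$entries$windowed[2], mean(ramp[1:11]))
  # even windows are rejected
  expect_error(smooth_track(mk_track(raw), 4), "odd")
})

test_that("numbering gaps truncate the smoothing window", {
  number <- c(1:10, 31:40)  # chain break between 10 and 31
  raw <- c(rep(1, 10), rep(-1, 10))
  mod <- protein_model("A", number = number, aa = rep("A", 20),
                       ca = cbind(number, 0, 0))
  tr <- raw_daq_aa(mod, table_volume(as.character(number), rep("A", 20), 0.3))
  tr$entries$raw <- raw
  sm <- smooth_track(tr, 9)
  # windows never mix the two segments
  expect_equal(sm$entries$windowed[1:10], rep(1, 10))
  expect_equal(sm$entries$windowed[11:20], rep(-1, 10))
})

test_that("flagging and totals follow the windowed scores", {
  mod <- protein_model("A", number = 1:5, aa = rep("A", 5),
                       ca = cbind(1:5, 0, 0))
  tr <- raw_daq_aa(mod, table_volume(as.character(1:5), rep("A", 5), 0.3))
  tr$entries$windowed <- c(0.2, 0.2, -0.6, 0.2, -0.4)
  expect_identical(flag_low_confidence(tr, -0.5), "3")
  expect_identical(flag_low_confidence(tr, -0.7), character(0))
  expect_equal(total_daq(tr), sum(tr$entries$windowed))
  # additivity across a junction at window 1
  a <- tr$entries$windowed[1:2]
  b <- tr$entries$windowed[3:5]
  expect_equal(total_daq(tr), sum(a) + sum(b))
})

test_that("a frame mismatch beyond half the residues is a hard error", {
  spec <- synthetic_spec(n_residues = 10, seed = 9)
  mod <- make_backbone(spec)
  vol <- make_probability_volume(mod, spec)
  far <- mod
  shiftv <- c(500, 0, 0)
  far$residues[, c("x", "y", "z")] <-
    sweep(as.matrix(far$residues[, c("x", "y", "z")]), 2, shiftv, "+")
  far$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(far$atoms[, c("x", "y", "z")]), 2, shiftv, "+")
  expect_error(raw_daq_aa(far, vol), "coordinate frame")
})
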