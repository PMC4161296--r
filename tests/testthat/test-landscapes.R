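test_that("peak landscapes evaluate fitness and membership correctly", {
  sp <- seq_space(4, 4)
  bp <- broad_peak(sp, "AAAA", w = 1, advantage = 2)
  expect_true(is_target(bp, "AAAA"))
  expect_true(is_target(bp, "AAAC"))
  expect_false(is_target(bp, "AACC"))
  expect_equal(fitness_of(bp, c("AAAA", "AACC")), c(2, 1))
  mp <- multi_peak(sp, c("AAAA", "TTTT"), w = 1)
  expect_true(all(is_target(mp, c("AAAT", "TTTA"))))
  # membership agrees with min over per-center distances, brute force
  seqs <- all_sequences(sp)
  dmin <- pmin(hamming_distance(seqs, rep("AAAA", 256)),
               hamming_distance(seqs, rep("TTTT", 256)))
  expect_equal(is_target(mp, seqs), dmin <= 1)
  ml <- multiplicative_peak(sp, "AAAA", sigma = 0.5, w = 1)
  expect_equal(fitness_of(ml, "AAAA"), 1.5^4)
  expect_equal(fitness_of(ml, "CCCC"), 1)
  flat <- multiplicative_peak(sp, "AAAA", sigma = 0, w = 1)
  expect_true(all(fitness_of(flat, seqs) == 1))
})

test_that("rough-Mount-Fuji generator: cone, reproducibility, maxima density", {
  sp <- seq_space(4, 4)
  set.seed(1)
  cone <- generate_rugged(sp, "ACGT", theta = 1, noise_sd = 0)
  expect_equal(find_local_maxima(cone), "ACGT")
  set.seed(3)
  a <- generate_rugged(sp, "AAAA", theta = 0.5, noise_sd = 1)
  set.seed(3)
  b <- generate_rugged(sp, "AAAA", theta = 0.5, noise_sd = 1)
  expect_identical(a$fitness, b$fitness)
  # pure noise field: a sequence beats its 3L neighbors with prob 1/(3L+1)
  L <- 3
  sp3 <- seq_space(L, 4)
  set.seed(7)
  frac <- mean(vapply(1:40, function(i) {
    land <- generate_rugged(sp3, "AAA", theta = 0, noise_sd = 1)
    length(find_local_maxima(land)) / nrow(land)
  }, numeric(1)))
  p <- 1 / (3 * L + 1)
  se <- sqrt(p * (1 - p) / (40 * 4^L))  # conservative (maxima are dependent)
  expect_lt(abs(frac - p), 6 * se)
})

test_that("local maxima and greedy basins on the exhaustively-checked toy", {
  land <- toy_land_2x2()
  expect_setequal(find_local_maxima(land), c("00", "11"))
  # constant landscape: no strict maxima
  sp <- attr(land, "space")
  flat <- tabulated_landscape(sp, rep(1, 4))
  expect_length(find_local_maxima(flat), 0)
  # greedy from 01: neighbors are 11 (fitness 3) and 00 (fitness 5) -> 00
  expect_equal(greedy_basin(land, "01"), "00")
  expect_equal(greedy_basin(land, "00"), "00")
  basins <- greedy_basins(land)
  expect_equal(nrow(basins), 4)
  expect_true(all(basins$basin %in% c("00", "11")))
  # basins partition: every sequence assigned to exactly one maximum
  expect_equal(sort(basins$sequence), sort(all_sequences(sp)))
})

test_that("basin partition and path termination hold on random landscapes", {
  sp <- seq_space(5, 2)
  set.seed(21)
  for (i in 1:5) {
    land <- generate_rugged(sp, all_sequences(sp)[1], theta = 0.3, noise_sd = 1)
    basins <- greedy_basins(land)
    maxima <- find_local_maxima(land)
    expect_setequal(unique(basins$basin), maxima)
    # the vectorized map agrees with the single-path tracer
    idx <- sample.int(nrow(land), 6)
    for (j in idx) {
      expect_equal(greedy_basin(land, land$sequence[j]), basins$basin[j])
    }
  }
})

test_that("threshold binarization matches the worked example and flags empties", {
  land <- toy_land_2x2()
  ap <- approximate_threshold(land, f_star = 3)
  expect_setequal(ap$target, c("00", "11"))
  expect_true(all(ap$landscape$fitness[match(ap$target, ap$landscape$sequence)] > 1))
  expect_true(all(ap$landscape$fitness[!ap$landscape$sequence %in% ap$target] == 1))
  # f* below the minimum: everything is a target
  expect_length(approximate_threshold(land, 0.5)$target, 4)
  expect_error(approximate_threshold(land, 99), "empty target")
})

test_that("plateau approximation lifts sub-threshold ranges to f_max", {
  land <- toy_land_2x2()
  ap <- approximate_plateau(land, f_star = 5)
  expect_setequal(ap$target, c("00", "01", "10"))
  expect_equal(ap$f_max, 3)
  non <- setdiff(ap$landscape$sequence, ap$target)
  expect_equal(ap$landscape$fitness[match(non, ap$landscape$sequence)], 3)
  # target fitness untouched
  expect_equal(ap$landscape$fitness[match("00", ap$landscape$sequence)], 5)
  # single-basin cone with f* = max: whole space is a target
  sp <- seq_space(3, 4)
  set.seed(2)
  cone <- generate_rugged(sp, "AAA", theta = 1, noise_sd = 0)
  full <- approximate_plateau(cone, max(cone$fitness))
  expect_length(full$target, nrow(cone))
})

test_that("threshold targets are a subset of plateau targets (leniency)", {
  sp <- seq_space(4, 4)
  set.seed(31)
  for (i in 1:5) {
    land <- generate_rugged(sp, "ACGT", theta = 0.4, noise_sd = 1)
    f_star <- stats::quantile(land$fitness, 0.95)
    thr <- approximate_threshold(land, f_star)
    plt <- approximate_plateau(land, f_star)
    expect_true(all(thr$target %in% plt$target))
  }
})

test_that("tabulated landscapes round-trip through the text format", {
  sp <- seq_space(3, 2)
  set.seed(4)
  land <- generate_rugged(sp, all_sequences(sp)[1], theta = 0.2, noise_sd = 0.7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(land, path)
  back <- read_landscape(path)
  expect_equal(back$sequence, land$sequence)
  expect_equal(back$fitness, land$fitness)
  expect_equal(attr(back, "space")$alphabet, sp$alphabet)
})

test_that("enumeration guard refuses oversized spaces", {
  expect_error(all_sequences(seq_space(11, 4)), "too large")
})
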