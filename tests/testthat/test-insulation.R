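# direct-summation oracle for the insulation pipeline, written independently
# of the package's summed-area-table implementation
oracle_insulation <- function(m, w = 20) {
  n <- nrow(m)
  raw <- vapply(seq_len(n - w), function(j) sum(m[j:(j + w - 1), j:(j + w - 1)]),
                numeric(1))
  log2(raw / mean(raw))
}

oracle_delta <- function(ins, d = 10) {
  vapply(seq.int(d, length(ins) - d), function(j)
    mean(ins[(j + 1):(j + d)]) - mean(ins[(j - d + 1):j]), numeric(1))
}

test_that("insulation vector matches the direct-summation oracle", {
  for (seed in 1:5) {
    m <- sym_map(60, seed)
    expect_equal(insulation_vector(m), oracle_insulation(m), tolerance = 1e-12)
  }
})

test_that("insulation is zero for constant maps and scale invariant", {
  expect_equal(insulation_vector(matrix(3, 60, 60)), rep(0, 40))
  m <- sym_map(60, 17)
  expect_equal(insulation_vector(m), insulation_vector(7 * m),
               tolerance = 1e-12)
})

test_that("two separated blocks give the insulation minimum at the junction", {
  m <- matrix(0.01, 80, 80)
  m[1:40, 1:40] <- 1; m[41:80, 41:80] <- 1
  iv <- insulation_vector(m)
  # insulation positions map to bins 10 .. 69 (0-based); junction at bin 39.5
  expect_equal(which.min(iv) + 10 - 1, 40, tolerance = 1) # 1-based bin 40/41
  expect_equal(iv, oracle_insulation(m), tolerance = 1e-12)
})

test_that("delta vector obeys the printed length formula", {
  p <- insulation_params()
  expect_length(delta_vector(insulation_vector(sym_map(40, 1), p), p), 1)
  for (n in c(41, 55, 64, 100, 257)) {
    m <- sym_map(n, n)
    expect_length(delta_vector(insulation_vector(m, p), p), n - 20 - 19)
  }
  expect_error(insulation_vector(sym_map(39, 2), p), "shorter")
  expect_error(delta_vector(rep(1, 19), p), "shorter")
})

test_that("delta of constant and linear insulation has closed form", {
  p <- insulation_params()
  expect_equal(delta_vector(rep(2.5, 30), p), rep(0, 11))
  # linearly increasing scores: every downstream/upstream mean differs by s*d
  s <- 0.3
  lin <- s * (1:40)
  expect_equal(delta_vector(lin, p), rep(s * 10, 21), tolerance = 1e-12)
  expect_equal(delta_vector(lin, p), oracle_delta(lin), tolerance = 1e-12)
})

test_that("boundary calling finds negative-to-positive crossings", {
  p <- insulation_params()
  expect_identical(nrow(call_boundaries(c(0.2, 0.5, 1), p)), 0L)

  # exhaustive-scan oracle over a crafted delta vector with two valleys
  delta <- c(0.4, -0.1, -0.6, -0.2, 0.3, 0.5, 0.1, -0.4, -0.05, 0.25, 0.3)
  b <- call_boundaries(delta, p)
  crossings <- which(delta[-length(delta)] < 0 & delta[-1] >= 0)
  expect_identical(nrow(b), length(crossings))
  # first valley: crossing between indices 4 and 5 (interp 0.4 -> bin 4);
  # amplitude = right max 0.5 - left min (-0.6) = 1.1
  expect_identical(b$bin[1], 3L) # 0-based
  expect_equal(b$strength[1], 0.5 - (-0.6))
  # threshold filters weak boundaries
  weak <- c(0.05, -0.04, 0.05)
  expect_identical(nrow(call_boundaries(weak, p)), 0L)
  expect_identical(nrow(call_boundaries(weak, insulation_params(
    strength_threshold = 0.01))), 1L)
})

test_that("planted TAD junctions are recovered within two bins", {
  junctions <- list(c(60), c(45, 90), c(40, 80, 120))
  sizes <- c(120, 140, 160)
  for (k in seq_along(junctions)) {
    n <- sizes[k]
    cuts <- c(0, junctions[[k]], n)
    tads <- lapply(seq_len(length(cuts) - 1), function(i)
      c(cuts[i], cuts[i + 1], 4))
    cm <- generate_hic(toy_hic_spec(n, tads = tads, noise = FALSE))
    b <- tad_boundaries(cm$matrix)
    expect_identical(nrow(b), length(junctions[[k]]))
    expect_true(all(abs(b$bin - junctions[[k]]) <= 2))
    expect_true(all(b$strength > 0.1))
  }
})

test_that("differentiable delta equals the plain pipeline on random maps", {
  p <- insulation_params()
  worst <- 0
  for (seed in 1:25) {
    m <- sym_map(60, seed, lo = 0.05, hi = 2)
    d1 <- delta_vector(insulation_vector(m, p), p)
    d2 <- differentiable_delta(m, p)
    worst <- max(worst, max(abs(d1 - d2)))
  }
  expect_lt(worst, 1e-5)
})

test_that("differentiable delta is flat on constant maps and gradient-exact", {
  m <- matrix(0.7, 50, 50)
  expect_equal(differentiable_delta(m), rep(0, 11), tolerance = 1e-7)
  g0 <- vehicle:::.diff_delta_bw(m, 2 * differentiable_delta(m))
  expect_equal(max(abs(g0)), 0, tolerance = 1e-7) # gradient of sum(delta^2)

  # central-difference check on a 40x40 map
  m <- sym_map(40, 23, lo = 0.1)
  gd <- stats::rnorm(length(differentiable_delta(m)))
  ga <- vehicle:::.diff_delta_bw(m, gd)
  eps <- 1e-6
  set.seed(1)
  for (ii in sample(length(m), 6)) {
    mp <- m; mp[ii] <- mp[ii] + eps
    mn <- m; mn[ii] <- mn[ii] - eps
    fd <- (sum(gd * differentiable_delta(mp)) -
             sum(gd * differentiable_delta(mn))) / (2 * eps)
    expect_equal(ga[ii], fd, tolerance = 1e-3)
  }

  # all-zero window sums are guarded, no NaN
  expect_true(all(is.finite(differentiable_delta(matrix(0, 45, 45)))))
})

test_that("insulation loss is a mean absolute delta difference", {
  e <- sym_map(60, 31); t2 <- sym_map(60, 32)
  expect_equal(insulation_loss(e, e), 0)
  expect_equal(insulation_loss(matrix(0.2, 60, 60), matrix(0.9, 60, 60)), 0,
               tolerance = 1e-7)
  de <- differentiable_delta(e); dt <- differentiable_delta(t2)
  expect_equal(insulation_loss(e, t2), mean(abs(de - dt)))
  expect_error(insulation_loss(e, sym_map(50, 1)), "mismatch")
})

test_that("delta_l2 is a symmetric Euclidean distance on delta vectors", {
  a <- sym_map(70, 41); b <- sym_map(70, 42)
  expect_equal(delta_l2(a, a), 0)
  expect_equal(delta_l2(a, b), delta_l2(b, a))
  da <- oracle_delta(oracle_insulation(a)); db <- oracle_delta(oracle_insulation(b))
  expect_equal(delta_l2(a, b), sqrt(sum((da - db)^2)), tolerance = 1e-10)
  expect_error(delta_l2(a, sym_map(60, 1)), "mismatch")
})

test_that("boundaries export as 0-based half-open BED records", {
  cm <- generate_hic(toy_hic_spec(120, tads = list(c(0, 60, 4), c(60, 120, 4)),
                                  noise = FALSE))
  b <- tad_boundaries(cm$matrix)
  f <- tempfile(fileext = ".bed")
  write_boundaries_bed(b, f, chrom = "chrS", resolution = 10000)
  bed <- utils::read.table(f, sep = "\t")
  expect_identical(nrow(bed), nrow(b))
  expect_equal(bed$V2, b$bin * 10000)
  expect_equal(bed$V3, (b$bin + 1) * 10000)
  expect_equal(bed$V5, b$strength)
  unlink(f)
})
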