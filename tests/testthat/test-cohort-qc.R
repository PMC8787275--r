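# Framewise displacement, the exclusion threshold, and the iterative
# motion-matching algorithm.

# Build a cohort table from per-subject condition-mean FD values: each
# subject gets 4 identical runs per condition at the given level.
fd_cohort <- function(rest, movie, ids = seq_along(rest)) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    tibble::tibble(
      subject_id = ids[i],
      condition = rep(c("rest", "movie"), each = 4),
      run = rep(1:4, 2),
      mean_fd = rep(c(rest[i], movie[i]), each = 4)
    )
  }))
}

test_that("FD follows the Power convention with a 50 mm radius", {
  p0 <- matrix(0, 10, 6)
  tr0 <- framewise_displacement(p0)
  expect_identical(tr0$fd, rep(0, 9))
  expect_identical(tr0$mean_fd, 0)

  p1 <- matrix(0, 10, 6)
  p1[5:10, 1] <- 1  # single 1 mm x-translation step at transition 4->5
  expect_equal(framewise_displacement(p1)$fd, c(0, 0, 0, 1, 0, 0, 0, 0, 0))

  p2 <- matrix(0, 10, 6)
  p2[5:10, 5] <- 0.02  # single 0.02 rad rotation step: 50 * 0.02 = 1 mm
  expect_equal(framewise_displacement(p2)$fd[4], 1.0)
  # radius is configurable
  expect_equal(framewise_displacement(p2, radius = 100)$fd[4], 2.0)

  p3 <- matrix(0, 3, 6)
  p3[2, ] <- c(0.1, -0.2, 0.3, 0.001, -0.002, 0.003)
  expect_equal(
    framewise_displacement(p3)$fd[1],
    0.6 + 50 * 0.006
  )
  p3[1, 1] <- NA
  expect_error(framewise_displacement(p3), "finite")
})

test_that("motion TSV reader handles headers and degree rotations", {
  tab <- data.frame(
    trans_x = c(0, 1), trans_y = 0, trans_z = 0,
    rot_x = c(0, 90), rot_y = 0, rot_z = 0
  )
  f1 <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  m1 <- read_motion_tsv(f1, degrees = TRUE)
  expect_equal(unname(m1[2, "rot_x"]), pi / 2)
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f2, sep = "\t", row.names = FALSE, quote = FALSE,
    col.names = FALSE
  )
  m2 <- read_motion_tsv(f2)
  expect_equal(unname(m2[2, 1]), 1)
})

test_that("exclusion uses a strict threshold, flags missing runs, idempotent", {
  co <- fd_cohort(
    rest = c(0.10, 0.16, 0.12),
    movie = c(0.15, 0.10, 0.11)
  )
  # subject 1 peaks exactly at 0.15: not excluded (strict inequality)
  out <- apply_exclusion(co, threshold = 0.15)
  inc <- unique(out[, c("subject_id", "included", "exclusion_reason")])
  expect_identical(inc$included, c(TRUE, FALSE, TRUE))
  expect_match(inc$exclusion_reason[2], "mean_fd")
  # idempotent
  expect_identical(apply_exclusion(out, 0.15)$included, out$included)
  # missing runs flagged, not dropped
  co2 <- rbind(co, tibble::tibble(
    subject_id = 4, condition = "rest", run = 1, mean_fd = 0.05
  ))
  out2 <- apply_exclusion(co2, 0.15)
  expect_identical(
    unique(out2$exclusion_reason[out2$subject_id == 4]), "missing_runs"
  )
})

test_that("seeded high-motion subjects are exactly the excluded set", {
  set.seed(14)
  n <- 100
  rest <- runif(n, 0.05, 0.14)
  movie <- runif(n, 0.05, 0.14)
  bad <- sample(n, 30)
  rest[bad] <- runif(30, 0.151, 0.30)
  out <- apply_exclusion(fd_cohort(rest, movie), 0.15)
  excl <- unique(out$subject_id[!out$included])
  expect_setequal(excl, bad)
})

test_that("motion matching removes max-rest-FD subjects until p >= alpha", {
  # already matched: zero removals
  set.seed(3)
  base <- runif(40, 0.08, 0.12)
  co0 <- apply_exclusion(fd_cohort(base, base + rnorm(40, 0, 0.001)), 0.15)
  out0 <- motion_match(co0)
  expect_identical(attr(out0, "match_log"), character(0))

  # 40 matched subjects plus 10 with inflated rest FD
  rest_inf <- runif(10, 0.130, 0.145)
  rest <- c(base, rest_inf)
  movie <- c(base + rnorm(40, 0, 0.002), rest_inf - 0.02)
  co <- apply_exclusion(fd_cohort(rest, movie), 0.15)
  out <- motion_match(co)
  removed <- attr(out, "match_log")
  expect_gt(length(removed), 0)
  expect_gte(attr(out, "final_p"), 0.05)

  # brute-force replication of the removal order
  wide <- data.frame(id = 1:50, rest = rest, movie = movie)
  expected <- character(0)
  repeat {
    p <- t.test(wide$movie, wide$rest, paired = TRUE)$p.value
    if (p >= 0.05) break
    w <- order(-wide$rest, wide$id)[1]
    expected <- c(expected, as.character(wide$id[w]))
    wide <- wide[-w, ]
  }
  expect_identical(removed, expected)
  # removals come from the inflated group first
  expect_true(all(as.integer(removed[seq_len(min(5, length(removed)))]) > 40))
  # deterministic
  expect_identical(attr(motion_match(co), "match_log"), removed)

  # the rest-minus-movie gap shrinks monotonically along the removal path
  gaps <- numeric(0)
  wide2 <- data.frame(id = 1:50, rest = rest, movie = movie)
  gaps <- mean(wide2$rest - wide2$movie)
  for (r in removed) {
    wide2 <- wide2[wide2$id != as.integer(r), ]
    gaps <- c(gaps, mean(wide2$rest - wide2$movie))
  }
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("motion matching errors when the cohort is exhausted", {
  co <- apply_exclusion(
    fd_cohort(rest = c(0.14, 0.14, 0.14), movie = c(0.05, 0.06, 0.055)),
    0.15
  )
  expect_error(motion_match(co), "exhausted|degenerate")
})

test_that("constant FD traces are rejected by the fractal step", {
  p <- matrix(0, 900, 6)
  p[, 1] <- as.numeric(0:899)  # exactly constant 1 mm steps
  tr <- framewise_displacement(p)
  expect_error(fd_hurst(tr), "constant")
})
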