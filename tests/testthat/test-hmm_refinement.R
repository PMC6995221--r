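test_that("transition matrix follows the Haldane map function", {
  p <- hmm_parameters()
  expect_equal(transition_matrix(0, p),
               diag(2), ignore_attr = TRUE)
  expect_equal(transition_matrix(1e12, p)["I", "D"], 0.5, tolerance = 1e-12)
  t500 <- transition_matrix(5e5, p)["I", "D"]
  expect_equal(t500, 0.004975083, tolerance = 1e-6)
  m <- transition_matrix(123456, p)
  expect_equal(rowSums(m), c(I = 1, D = 1))
  expect_true(m["I", "D"] >= 0 && m["I", "D"] < 0.5)
})

test_that("emission model is symmetric with uninformative missing", {
  p <- hmm_parameters(epsilon = 0.10)
  expect_equal(emission_prob("i", "I", p), 0.9)
  expect_equal(emission_prob("d", "D", p), 0.9)
  expect_equal(emission_prob("d", "I", p), 0.1)
  expect_equal(emission_prob("i", "D", p), 0.1)
  expect_equal(emission_prob(NA, "I", p), 1)
  expect_equal(emission_prob(NA, "D", p), 1)
  for (s in c("I", "D")) {
    expect_equal(emission_prob("i", s, p) + emission_prob("d", s, p), 1)
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(hmm_parameters(epsilon = 0))
  expect_error(hmm_parameters(epsilon = 0.6))
  expect_error(hmm_parameters(recomb_rate_per_bp = 0))
  expect_error(hmm_parameters(decode_mode = "magic"))
})

test_that("a concordant track decodes to all-I and isolated artifacts are absorbed", {
  p <- hmm_parameters()
  tr <- make_track(seq(1e6, by = 1e4, length.out = 50), rep("i", 50))
  expect_equal(unique(viterbi_decode(tr, p)), "I")
  tr2 <- make_track(seq(1e6, by = 1e4, length.out = 7),
                    c("i", "i", "i", "d", "i", "i", "i"))
  path <- viterbi_decode(tr2, p)
  expect_equal(path, rep("I", 7))
  # cross-check against exhaustive enumeration
  o <- oracle_hmm(tr2$obs, tr2$pos, p$epsilon, p$recomb_rate_per_bp)
  expect_true(any(apply(o$argmax, 1, function(a) all(a == path))))
})

test_that("viterbi and posteriors match exhaustive enumeration on random short tracks", {
  set.seed(2024)
  p <- hmm_parameters()
  for (rep in 1:60) {
    tr <- random_track()
    eps <- stats::runif(1, 0.05, 0.45)
    pr <- hmm_parameters(epsilon = eps,
                         recomb_rate_per_bp = 10^stats::runif(1, -9, -6))
    path <- viterbi_decode(tr, pr)
    o <- oracle_hmm(tr$obs, tr$pos, pr$epsilon, pr$recomb_rate_per_bp)
    expect_true(any(apply(o$argmax, 1, function(a) all(a == path))),
                info = paste("rep", rep))
    post <- forward_backward(tr, pr)
    expect_equal(post$posterior_I, o$post_I, tolerance = 1e-9,
                 info = paste("rep", rep))
  }
})

test_that("posteriors are exact in closed-form cases and normalized", {
  p <- hmm_parameters(epsilon = 0.10)
  one <- make_track(1e6, "i")
  post <- forward_backward(one, p)
  expect_equal(post$posterior_I, 0.9, tolerance = 1e-12)
  long <- make_track(seq(1e6, by = 1e4, length.out = 30), rep("i", 30))
  pl <- forward_backward(long, p)
  expect_true(all(pl$posterior_I[5:25] > 0.99))
  expect_true(all(abs(pl$posterior_I + pl$posterior_D - 1) < 1e-9))
})

test_that("empty tracks are rejected", {
  empty <- make_track(numeric(0), character(0))
  expect_error(viterbi_decode(empty, hmm_parameters()), "empty")
  expect_error(forward_backward(empty, hmm_parameters()), "empty")
})

test_that("increasing epsilon never increases the number of decoded switches", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 200
    tr <- make_track(sort(sample.int(5e7, n)),
                     sample(c("i", "d"), n, replace = TRUE,
                            prob = c(0.7, 0.3)))
    switches <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.3, 0.4), function(eps) {
      s <- viterbi_decode(tr, hmm_parameters(epsilon = eps))
      sum(s[-1] != s[-n])
    }, numeric(1))
    expect_true(all(diff(switches) <= 0), info = paste("rep", rep))
  }
})

test_that("near-zero epsilon reproduces the raw observations", {
  set.seed(3)
  n <- 120
  obs <- rep(c("i", "d"), each = 60)  # one consistent switch
  obs[sample.int(n, 10)] <- NA
  tr <- make_track(sort(sample.int(9e7, n)), obs)
  s <- viterbi_decode(tr, hmm_parameters(epsilon = 1e-6))
  known <- !is.na(tr$obs)
  expect_identical(tolower(s[known]), tr$obs[known])
})

test_that("segment_blocks run-length encodes states with breakpoints between sites", {
  p <- hmm_parameters()
  tr <- make_track((1:8) * 1e6, c(rep("i", 4), rep("d", 4)))
  seg <- segment_blocks(decode_track(tr, p), p)
  expect_equal(nrow(seg$blocks), 2)
  expect_equal(seg$blocks$state, c("I", "D"))
  expect_equal(seg$blocks$start_pos, c(1e6, 5e6))
  expect_equal(seg$blocks$end_pos, c(4e6, 8e6))
  expect_equal(seg$blocks$n_sites, c(4L, 4L))
  expect_equal(nrow(seg$breakpoints), 1)
  expect_equal(seg$breakpoints$left_pos, 4e6)
  expect_equal(seg$breakpoints$right_pos, 5e6)
  # blocks tile without overlap; adjacent states differ
  expect_true(all(seg$blocks$start_pos[-1] > seg$blocks$end_pos[-2]))
})

test_that("short weak blocks are merged into their flanks", {
  # weak smoothing so the raw 2-site D run survives decoding
  p <- hmm_parameters(epsilon = 0.45, recomb_rate_per_bp = 1e-6)
  pos <- c(seq(1e6, by = 1e5, length.out = 10),
           10.01e6 + c(0, 2e4),                       # 2-site, 20 kb D run
           seq(11e6, by = 1e5, length.out = 10))
  obs <- c(rep("i", 10), "d", "d", rep("i", 10))
  seq_df <- decode_track(make_track(pos, obs), p)
  expect_equal(sum(seq_df$state == "D"), 2)  # decoder kept the D run
  seg <- segment_blocks(seq_df, p)
  expect_equal(nrow(seg$blocks), 1)
  expect_equal(seg$blocks$state, "I")
  expect_equal(nrow(seg$breakpoints), 0)
  expect_true(all(seg$sites$state == "I"))
})

test_that("decode_track honours both decoding modes and they agree on clean data", {
  tr <- make_track(seq(1e6, by = 5e4, length.out = 40),
                   rep(c("i", "d"), each = 20))
  v <- decode_track(tr, hmm_parameters(decode_mode = "viterbi"))
  g <- decode_track(tr, hmm_parameters(decode_mode = "posterior"))
  expect_equal(v$state, g$state)
  expect_equal(v$state, rep(c("I", "D"), each = 20))
})
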