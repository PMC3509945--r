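test_that("enumeration: worked L=2 example, peak start, additive L=4", {
  ls <- additive_l2()
  ens <- enumerate_monotone_paths(ls, "00")
  expect_length(ens, 1)
  expect_identical(ens[[1]]$peak, "11")
  expect_identical(ens[[1]]$paths,
                   list(c("00", "01", "11"), c("00", "10", "11")))
  expect_equal(ens[[1]]$probabilities, c(0.5, 0.5))

  from_peak <- enumerate_monotone_paths(ls, "11")
  expect_length(from_peak, 1)
  expect_identical(from_peak[[1]]$paths, list("11"))
  expect_equal(from_peak[[1]]$probabilities, 1)

  l4 <- additive_from_effects(c(0.05, 0.1, 0.15, 0.2))
  e4 <- enumerate_monotone_paths(l4, "0000")
  expect_length(e4, 1)
  expect_length(e4[[1]]$paths, factorial(4))
  expect_equal(e4[[1]]$probabilities, rep(1 / 24, 24))
})

test_that("enumeration respects end filter, cap, and missing start", {
  ls <- two_peak_l2()
  to_global <- enumerate_monotone_paths(ls, "01", end = "00")
  expect_length(to_global, 1)
  expect_identical(to_global[[1]]$paths, list(c("01", "00")))
  # the local peak 11 has no monotone route to the global peak 00
  expect_length(enumerate_monotone_paths(ls, "11", end = "00"), 0)

  l4 <- additive_from_effects(rep(0.1, 4))
  expect_error(enumerate_monotone_paths(l4, "0000", max_paths = 10),
               "cap of 10.*0000")
  expect_error(enumerate_monotone_paths(ls, "22"), "not present")
})

test_that("sswm_path_probability: hand values and contract violations", {
  ls <- additive_l2()
  expect_equal(sswm_path_probability(ls, c("00", "01", "11")), 0.5)
  expect_equal(sswm_path_probability(ls, c("00", "10", "11")), 0.5)
  expect_equal(sswm_path_probability(ls, "11"), 1)

  l4 <- additive_from_effects(c(0.05, 0.1, 0.15, 0.2))
  expect_equal(sswm_path_probability(l4, c("0000", "1000", "1100", "1110", "1111")),
               1 / 24)

  expect_error(sswm_path_probability(ls, c("11", "00")), "not monotone")
  expect_error(sswm_path_probability(ls, c("01", "00")), "not monotone")  # downhill
})

test_that("DP counting matches enumeration, closed forms, and exact bignum", {
  ls <- additive_l2()
  expect_equal(c(count_monotone_paths(ls, "11")),
               c("00" = 2, "01" = 1, "10" = 1, "11" = 1))

  l5 <- additive_from_effects(seq(0.02, 0.1, length.out = 5))
  cnt <- count_monotone_paths(l5, "11111")
  expect_equal(unname(cnt["00000"]), factorial(5))  # 120, oracle: enumeration
  expect_length(enumerate_monotone_paths(l5, "00000")[[1]]$paths, 120)

  tp <- two_peak_l2()
  expect_equal(unname(count_monotone_paths(tp, "00")["11"]), 0)  # other peak
  expect_error(count_monotone_paths(ls, "00"), "not a peak")
})

test_that("exact integer accumulation survives past 2^53 (frozen oracles)", {
  # internal bignum helpers: factorials by repeated addition-free checks
  big_from_num <- function(x) {
    v <- numeric(0)
    while (x > 0) { v <- c(v, x %% 1e15); x <- x %/% 1e15 }
    if (length(v) == 0) 0 else v
  }
  # 20! and 25! computed with an independent arbitrary-precision oracle
  fact_chr <- c("2432902008176640000", "15511210043330985984000000")
  acc <- big_from_num(1)
  for (n in 2:25) {
    # multiply by n via n-fold addition (the DP only ever adds)
    s <- acc
    for (i in seq_len(n - 1)) s <- fitpaths:::.big_add(s, acc)
    acc <- s
    if (n == 20) expect_identical(fitpaths:::.big_to_chr(acc), fact_chr[1])
  }
  expect_identical(fitpaths:::.big_to_chr(acc), fact_chr[2])
})

test_that("reach probabilities: hand DP, simulation oracle, conservation", {
  ls <- additive_l2()
  expect_equal(unname(reach_probability(ls, "11")), rep(1, 4))

  # 01 and 10 each have TWO fitter neighbors (00 and 11), so the walk reaches
  # the global peak with probability 1/2 -- verified by an independent
  # 20,000-walk simulation (phat = 0.505)
  tp <- two_peak_l2()
  rho <- reach_probability(tp, "00")
  expect_equal(rho, c("00" = 1, "01" = 0.5, "10" = 0.5, "11" = 0))
  sim <- simulate_walks(tp, "01", 4000, seed = 1)
  expect_lt(abs(mean(sim$ends == "00") - 0.5), 3 * sqrt(0.25 / 4000))

  # conservation over peaks, random landscapes
  for (seed in 1:5) {
    rl <- random_landscape(5, seed = 500 + seed, hole_frac = 0.2)
    pks <- find_peaks(rl)$genotype
    tot <- Reduce(`+`, lapply(pks, function(p) reach_probability(rl, p)))
    expect_equal(unname(tot), rep(1, length(rl$genotypes)), tolerance = 1e-12)
  }
})

test_that("peak accessibility: additive = 1, two-peak = 3/4, ties warn", {
  l3 <- additive_from_effects(c(0.1, 0.2, 0.3))
  acc <- peak_accessibility(l3)
  expect_equal(acc$existence_accessibility, 1)
  expect_equal(acc$mean_reach_probability, 1)
  expect_identical(acc$n_peaks, 1L)

  tp <- two_peak_l2()
  acc2 <- peak_accessibility(tp)
  expect_identical(acc2$global_peak, "00")
  expect_equal(acc2$existence_accessibility, 3 / 4)  # 11 cannot reach 00
  expect_equal(acc2$mean_reach_probability, (1 + 0.5 + 0.5 + 0) / 4)

  tie <- fitness_landscape(c("00", "01", "10", "11"), c(1, 0.5, 0.5, 1))
  expect_warning(at <- peak_accessibility(tie), "tie")
  expect_length(at, 2)

  # house-of-cards typically strictly between 0 and 1
  hoc <- generate_uncorrelated(6, seed = 8)
  a <- peak_accessibility(hoc)
  expect_gt(a$existence_accessibility, 0)
  expect_lt(a$existence_accessibility, 1)
})

test_that("enumeration agrees with the igraph oracle on random landscapes", {
  skip_if_not_installed("igraph")
  for (seed in 1:6) {
    L <- sample(3:5, 1)
    rl <- random_landscape(L, seed = 700 + seed, hole_frac = runif(1, 0, 0.4))
    for (start in rl$genotypes[seq(1, length(rl$genotypes), by = 3)]) {
      mine <- enumerate_monotone_paths(rl, start)
      mine_paths <- sort(vapply(unlist(lapply(mine, `[[`, "paths"),
                                       recursive = FALSE),
                                paste, character(1), collapse = ","))
      oracle <- sort(vapply(igraph_monotone_paths(rl, start),
                            paste, character(1), collapse = ","))
      expect_identical(mine_paths, oracle)
      # DP count agrees too, per terminal peak
      for (ens in mine) {
        cnt <- count_monotone_paths(rl, ens$peak)
        expect_equal(unname(cnt[start]), length(ens$paths))
      }
    }
  }
})

test_that("probability conservation and termination on random landscapes", {
  for (seed in 1:10) {
    L <- sample(3:6, 1)
    rl <- random_landscape(L, seed = 900 + seed, hole_frac = runif(1, 0, 0.3))
    for (start in rl$genotypes) {
      ens <- enumerate_monotone_paths(rl, start)
      probs <- unlist(lapply(ens, `[[`, "probabilities"))
      expect_equal(sum(probs), 1, tolerance = 1e-9)
      for (e in ens) {
        expect_identical(fitter_neighbors(rl, e$peak), character(0))
        for (p in e$paths) expect_identical(p[length(p)], e$peak)
      }
    }
  }
})

test_that("sampled walks are seeded, terminate at peaks, and match analytics", {
  ls <- additive_l2()
  w1 <- sample_sswm_walk(ls, "00", seed = 4)
  expect_identical(w1, sample_sswm_walk(ls, "00", seed = 4))
  expect_identical(w1[1], "00")
  expect_identical(w1[length(w1)], "11")
  expect_identical(sample_sswm_walk(ls, "11", seed = 1), "11")  # peak start

  # 2e4 walks: each L=2 path frequency 0.5 within 3 sigma
  set.seed(77)
  n <- 2e4
  first_step <- vapply(seq_len(n), function(i)
    sample_sswm_walk(ls, "00")[2], character(1))
  phat <- mean(first_step == "01")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})
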