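toy_layout <- function(n_bins, bw = 200)
  genome_layout("chr1", n_bins * bw, bw)

toy_tracks <- function(obs, genotype = NULL) {
  n_samples <- 1
  if (is.list(obs)) n_samples <- length(obs)
  if (is.null(genotype)) genotype <- rep("WT", n_samples)
  B <- if (is.list(obs)) nrow(obs[[1]]) else nrow(obs)
  samples <- data.frame(sample_id = paste0("s", seq_len(n_samples)),
                        genotype = genotype)
  binarized_tracks(obs, samples, hmm_marks, toy_layout(B))
}

test_that("binarize thresholds the Poisson upper tail at lambda = track mean", {
  B <- 2000
  set.seed(1)
  counts <- matrix(rpois(B * 5, 1), B, 5)
  counts[1, 1] <- 10  # P(X >= 10 | lambda ~ 1) ~ 1.1e-7 < 1e-4
  samples <- data.frame(sample_id = "s1", genotype = "WT")
  tr <- binarize(counts, samples, hmm_marks, toy_layout(B))
  expect_equal(unname(tr$obs[1, 1]), 1L)
  # x = 0 -> P(X >= 0) = 1 -> never flagged
  expect_true(all(tr$obs[counts == 0] == 0L))
  # uniform counts equal to lambda -> no enrichment anywhere
  flat <- matrix(3L, B, 5)
  tr2 <- binarize(flat, samples, hmm_marks, toy_layout(B))
  expect_true(all(tr2$obs == 0L))
  # all-zero track warns
  zero <- matrix(0L, B, 1)
  expect_warning(binarize(zero, samples, "H3K4me1", toy_layout(B)),
                 "all-zero")
})

test_that("K = 1 fit is the closed-form independent-Bernoulli model", {
  set.seed(2)
  obs <- matrix(rbinom(500 * 5, 1, 0.3), 500, 5)
  m <- fit_hmm(toy_tracks(obs), K = 1)
  expect_equal(as.numeric(m$phi), colMeans(obs), tolerance = 1e-9)
  ll <- sum(obs %*% log(t(m$phi)) + (1 - obs) %*% log(t(1 - m$phi)))
  expect_equal(m$loglik, ll, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and recovers a planted K=2 model", {
  phi_true <- rbind(c(0.9, 0.9, 0.1, 0.1, 0.9),
                    c(0.1, 0.1, 0.9, 0.9, 0.1))
  colnames(phi_true) <- hmm_marks
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  true <- epicmml:::new_state_model(unname(phi_true), A, c(0.5, 0.5),
                                    NA, hmm_marks)
  sim <- simulate_hmm_tracks(true, n_samples = 2, n_bins = 25000, seed = 3)
  fit <- fit_hmm(sim$tracks, K = 2, n_restarts = 2, seed = 3)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-6 * abs(trace[-length(trace)])))
  maes <- vapply(all_perms(1:2), function(p)
    mean(abs(fit$phi[p, ] - phi_true)), numeric(1))
  expect_lt(min(maes), 0.05)
})

test_that("viterbi decoding equals exhaustive path enumeration (T <= 10, K <= 3)", {
  for (seed in 1:12) {
    set.seed(seed)
    K <- sample(2:3, 1)
    Tn <- sample(4:10, 1)
    phi <- matrix(runif(K * 5, 0.1, 0.9), K, 5)
    A <- matrix(runif(K * K, 0.1, 1), K); A <- A / rowSums(A)
    pi <- rep(1 / K, K)
    model <- epicmml:::new_state_model(phi, A, pi, NA, hmm_marks)
    obs <- matrix(rbinom(Tn * 5, 1, 0.5), Tn, 5)
    lay <- genome_layout("chr1", Tn * 200, 200)
    tr <- binarized_tracks(obs, data.frame(sample_id = "s1",
                                           genotype = "WT"),
                           hmm_marks, lay)
    got <- decode(model, tr, method = "viterbi")$states[1, ]
    want <- brute_viterbi(obs, phi, A, pi)$path
    expect_equal(as.integer(got), want)
  }
})

test_that("decoding edge cases: K = 1 and the noiseless limit", {
  obs <- matrix(rbinom(50 * 5, 1, 0.5), 50, 5)
  m1 <- fit_hmm(toy_tracks(obs), K = 1)
  expect_true(all(decode(m1, toy_tracks(obs))$states == 1L))
  # deterministic emissions: decoded states equal generating states
  phi <- rbind(c(0.999, 0.999, 0.001, 0.001, 0.999),
               c(0.001, 0.001, 0.999, 0.999, 0.001))
  A <- matrix(0.5, 2, 2); pi <- c(0.5, 0.5)
  model <- epicmml:::new_state_model(phi, A, pi, NA, hmm_marks)
  states <- rep(c(1L, 2L), each = 25)
  obs2 <- round(phi[states, ])
  tr <- toy_tracks(obs2)
  for (meth in c("viterbi", "posterior"))
    expect_equal(as.integer(decode(model, tr, meth)$states[1, ]), states)
})

test_that("state labelling heuristics are pure and permutation-stable", {
  phi <- default_true_model()$phi
  labs <- label_states(phi)
  expect_setequal(labs, c("poised_promoter", "repressed",
                          "inactive_enhancer", "accessible",
                          "active_promoter", "active_enhancer",
                          "quiescent"))
  perm <- c(3, 1, 7, 2, 5, 4, 6)
  expect_equal(label_states(phi[perm, ]), labs[perm])
})

test_that("genotype_contrast is zero under identical genotypes and conserves mass", {
  set.seed(5)
  B <- 400
  obs1 <- matrix(rbinom(B * 5, 1, 0.3), B, 5)
  tr <- toy_tracks(list(obs1, obs1), genotype = c("WT", "MT"))
  model <- fit_hmm(tr, K = 2, n_restarts = 1, seed = 5)
  map <- decode(model, tr)
  genes <- gene_models(c("g1", "g2"), "chr1", c("+", "-"),
                       c(20000, 50000), c(30000, 60000))
  ct <- genotype_contrast(map, genes)
  expect_true(all(abs(ct$delta) < 1e-12))
  expect_true(all(ct$transition_matrix[upper.tri(ct$transition_matrix)] == 0))
  expect_true(all(ct$transition_matrix[lower.tri(ct$transition_matrix)] == 0))
  # per-position conservation: rows sum to zero at machine precision
  expect_true(all(abs(rowSums(ct$delta)) < 1e-9))
})

test_that("promoter occupancy counts bins correctly and buckets by extent", {
  # hand-built map: 20 promoter bins, 8 in state 2 -> 40 %, bucket (25-50]
  lay <- toy_layout(100)
  states <- matrix(1L, 2, 100)
  genes <- gene_models("g1", "chr1", "+", 10000, 14000)  # tss 10000, bins 41..60
  states[, 41:48] <- 2L
  map <- structure(list(states = states, posterior = NULL,
                        freq = NULL,
                        samples = data.frame(sample_id = c("a", "b"),
                                             genotype = c("WT", "MT")),
                        layout = lay, K = 2,
                        labels = c("quiescent", "active_promoter")),
                   class = "state_map")
  occ <- promoter_occupancy(map, genes)
  expect_equal(as.numeric(occ$MT$occ["g1", ]), c(0.6, 0.4))
  expect_equal(as.character(occ$MT$bucket["g1", 2]), "(25-50]")
  expect_equal(sum(occ$WT$occ["g1", ]), 1)
  # full occupancy -> bucket (75-100]
  states[, 41:60] <- 2L
  map$states <- states
  occ2 <- promoter_occupancy(map, genes)
  expect_equal(as.character(occ2$MT$bucket["g1", 2]), "(75-100]")
  expect_equal(as.numeric(occ2$MT$occ["g1", 2]), 1)
})

test_that("model JSON round trip preserves the fit", {
  m <- default_true_model()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_state_model(m, tmp)
  m2 <- read_state_model(tmp)
  expect_equal(m2$phi, m$phi, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$A, m$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$labels, m$labels)
})
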