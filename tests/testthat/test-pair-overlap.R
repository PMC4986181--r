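test_that("action pairs classify by sign agreement; unsigned is an error", {
  expect_equal(classify_action_pair(1L, 1L), "coherent")
  expect_equal(classify_action_pair(-1L, -1L), "coherent")
  expect_equal(classify_action_pair(1L, -1L), "incoherent")
  expect_equal(classify_action_pair(-1L, 1L), "incoherent")
  expect_error(classify_action_pair(0L, 1L), "unsigned")
})

test_that("pair enumeration matches the brute-force oracle on random networks", {
  set.seed(101)
  for (k in 1:25) {
    net <- random_test_network(sample(3:25, 1), sample(2:15, 1),
                               sample(5:40, 1), unsigned_prob = 0.15)
    got <- enumerate_shared_pairs(net)
    want <- oracle_shared_pairs(net)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
      next
    }
    cols <- c("drug_i", "drug_j", "c_pp", "c_mm", "c_pm",
              "p_pp", "p_mm", "p_pm", "t_i", "t_j", "p_i", "p_j")
    expect_equal(as.data.frame(got)[, cols], want[, cols],
                 ignore_attr = TRUE)
  }
})

test_that("overlap counts conserve the (pair, shared target) incidences", {
  set.seed(202)
  for (k in 1:10) {
    net <- random_test_network(15, 8, 40)
    ov <- enumerate_shared_pairs(net)
    e <- net$edges
    per_target <- table(e$target)
    direct <- sum(choose(per_target, 2))
    expect_equal(sum(ov$c_ij), direct)
    expect_equal(ov$c_ij, ov$c_pp + ov$c_mm + ov$c_pm)
    expect_equal(ov$s_ij, ov$c_ij - ov$p_ij)
    expect_true(all(ov$p_ij <= ov$c_ij))
    expect_true(all(ov$s_i >= 0 & ov$s_j >= 0))
  }
})

test_that("worked-example overlap: shared on/off-target pair", {
  ov <- enumerate_shared_pairs(generate_fixture("modafinil_pair"))
  expect_equal(nrow(ov), 1)
  expect_equal(ov$c_ij, 2)
  expect_equal(ov$c_mm, 1)   # the shared pharmacological target
  expect_equal(ov$c_pm, 1)   # the opposite-sign off-target
  expect_equal(ov$p_ij, 1)
  expect_equal(ov$s_ij, 1)
})

test_that("pharmacological splits require the flag on both drugs", {
  net <- signed_dtn(data.frame(
    drug = c("d1", "d2"), target = c("t1", "t1"),
    sign = c(1L, 1L), pharmacological = c(TRUE, FALSE)
  ))
  ov <- enumerate_shared_pairs(net)
  expect_equal(ov$c_pp, 1)
  expect_equal(ov$p_pp, 0)  # pharmacological for one drug only
  expect_equal(ov$s_pp, 0)  # ...and an off-target action for one only
  expect_equal(ov$s_ij, 1)
})

test_that("pair sign histograms bin pairs by per-pattern counts", {
  ov <- data.frame(drug_i = "a", drug_j = "b", c_pp = 2L, c_mm = 0L,
                   c_pm = 0L, c_ij = 2L)
  h <- pair_sign_histograms(ov)
  expect_equal(h$n_pairs[h$pattern == "any" & h$n_common_targets == 2], 1)
  expect_equal(h$n_pairs[h$pattern == "++" & h$n_common_targets == 2], 1)
  expect_false("--" %in% h$pattern)

  ov2 <- data.frame(drug_i = "a", drug_j = "b", c_pp = 1L, c_mm = 0L,
                    c_pm = 1L, c_ij = 2L)
  h2 <- pair_sign_histograms(ov2)
  expect_equal(h2$n_common_targets[h2$pattern == "any"], 2)
  expect_equal(h2$n_common_targets[h2$pattern == "++"], 1)
  expect_equal(h2$n_common_targets[h2$pattern == "+-"], 1)
  expect_equal(attr(h2, "totals")[["any"]], 1)

  h0 <- pair_sign_histograms(ov2[0, ])
  expect_equal(nrow(h0), 0)
})

test_that("coherence probability follows the action totals", {
  ov <- data.frame(drug_i = "a", drug_j = "b", c_pp = 1L, c_mm = 0L,
                   c_pm = 1L, c_ij = 2L)
  expect_equal(coherence_probability(ov)$rho, 0.5)

  ov_all <- data.frame(drug_i = c("a", "c"), drug_j = c("b", "d"),
                       c_pp = c(3L, 2L), c_mm = c(1L, 0L),
                       c_pm = c(0L, 0L), c_ij = c(4L, 2L))
  expect_equal(coherence_probability(ov_all)$rho, 1)

  expect_error(coherence_probability(ov[0, ]), "no drug pairs")
})

test_that("published action totals give rho = 0.779 and both quantities differ", {
  # 37439 coherent actions over 48033 total; 20017 of 25461 pairs coherent
  ov <- data.frame(drug_i = sprintf("a%05d", 1:25461),
                   drug_j = sprintf("b%05d", 1:25461),
                   c_pp = c(rep(1L, 20017), rep(0L, 5444)),
                   c_mm = c(rep(0L, 20017), rep(0L, 5444)))
  ov$c_pp[1] <- 37439L - 20016L  # pile the remaining coherent actions
  ov$c_pm <- c(rep(0L, 20017), rep(1L, 5444))
  ov$c_pm[20018] <- 10594L - 5443L
  ov$c_ij <- ov$c_pp + ov$c_mm + ov$c_pm
  cs <- coherence_probability(ov)
  expect_equal(cs$total_coherent, 37439)
  expect_equal(cs$total_incoherent, 10594)
  expect_equal(round(cs$rho, 3), 0.779)
  expect_equal(cs$n_pairs_coherent_ge1, 20017)
  expect_false(isTRUE(all.equal(cs$rho, cs$pair_coherent_fraction)))
})

test_that("binomial enrichment matches exact tail enumeration up to c_ij = 12", {
  rho <- 0.779
  cases <- expand.grid(n = 1:12, xi = 0:12)
  cases <- cases[cases$xi <= cases$n, ]
  ov <- data.frame(drug_i = sprintf("a%03d", seq_len(nrow(cases))),
                   drug_j = sprintf("b%03d", seq_len(nrow(cases))),
                   c_pp = cases$xi, c_mm = 0L, c_pm = cases$n - cases$xi,
                   c_ij = cases$n)
  enr <- binomial_enrichment(ov, rho)
  for (k in seq_len(nrow(cases))) {
    expect_equal(enr$p_coherent[k],
                 oracle_upper_tail(cases$xi[k], cases$n[k], rho),
                 tolerance = 1e-12)
    expect_equal(enr$p_incoherent[k],
                 oracle_upper_tail(cases$n[k] - cases$xi[k], cases$n[k],
                                   1 - rho),
                 tolerance = 1e-12)
  }
})

test_that("enrichment calls reproduce hand-computable cases", {
  ov <- data.frame(drug_i = c("a", "c", "e"), drug_j = c("b", "d", "f"),
                   c_pp = c(5L, 1L, 0L), c_mm = 0L, c_pm = c(0L, 0L, 3L),
                   c_ij = c(5L, 1L, 3L))
  enr <- binomial_enrichment(ov[1, ], rho = 0.5)
  expect_equal(enr$p_coherent, 0.03125)     # 1/2^5, all-coherent
  expect_equal(enr$call, "coherent-enriched")

  enr2 <- binomial_enrichment(ov[2, ], rho = 0.779)
  expect_equal(enr2$p_coherent, 0.779)      # single Bernoulli trial
  expect_equal(enr2$call, "none")

  enr3 <- binomial_enrichment(ov[3, ], rho = 0.779)
  expect_equal(enr3$p_incoherent, (1 - 0.779)^3, tolerance = 1e-12)
  expect_equal(enr3$call, "incoherent-enriched")
})

test_that("p_coherent is non-increasing in xi at fixed c_ij and rho", {
  for (rho in c(0.3, 0.5, 0.779)) {
    ov <- data.frame(drug_i = sprintf("a%02d", 0:10),
                     drug_j = sprintf("b%02d", 0:10),
                     c_pp = 0:10, c_mm = 0L, c_pm = 10:0, c_ij = 10L)
    p <- binomial_enrichment(ov, rho)$p_coherent
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("rho outside (0,1) is rejected", {
  ov <- data.frame(drug_i = "a", drug_j = "b", c_pp = 1L, c_mm = 0L,
                   c_pm = 0L, c_ij = 1L)
  expect_error(binomial_enrichment(ov, 0), "inside")
  expect_error(binomial_enrichment(ov, 1), "inside")
})

test_that("printed-orientation mode reproduces the published algebra", {
  ov <- data.frame(drug_i = "a", drug_j = "b", c_pp = 3L, c_mm = 1L,
                   c_pm = 2L, c_ij = 6L)
  rho <- 0.7
  enr <- binomial_enrichment(ov, rho, mode = "printed")
  # p = 1 - sum_{l=0}^{xi} C(n,l) (1-rho)^l rho^(n-l)
  manual <- 1 - sum(vapply(0:4, function(l) {
    choose(6, l) * (1 - rho)^l * rho^(6 - l)
  }, 0))
  expect_equal(enr$p_coherent, manual, tolerance = 1e-12)
  # and differs from the standard upper-tail orientation
  std <- binomial_enrichment(ov, rho)
  expect_false(isTRUE(all.equal(enr$p_coherent, std$p_coherent)))
})

test_that("BH adjustment only makes calls more conservative", {
  set.seed(77)
  net <- random_test_network(20, 10, 60)
  ov <- enumerate_shared_pairs(net)
  rho <- coherence_probability(ov)$rho
  expect_true(rho > 0 && rho < 1)
  raw <- binomial_enrichment(ov, rho)
  bh <- binomial_enrichment(ov, rho, adjust = "BH")
  expect_true(all(bh$call == "none" | bh$call == raw$call))
  expect_lte(sum(bh$call != "none"), sum(raw$call != "none"))
})

test_that("coherence histogram cells agree with per-pair calls", {
  set.seed(55)
  net <- random_test_network(20, 10, 60)
  ov <- enumerate_shared_pairs(net)
  rho <- coherence_probability(ov)$rho
  h <- coherence_histogram(ov, rho)
  expect_equal(sum(h$n_pairs), nrow(ov))
  enr <- binomial_enrichment(ov, rho)
  for (k in seq_len(nrow(h))) {
    calls <- enr$call[enr$xi == h$n_coherent[k] &
                        enr$n_incoherent == h$n_incoherent[k]]
    expect_equal(unique(sub("-enriched", "", calls)), h$flag[k])
  }
  # single-pair cell
  one <- data.frame(drug_i = "a", drug_j = "b", c_pp = 3L, c_mm = 0L,
                    c_pm = 0L, c_ij = 3L)
  h1 <- coherence_histogram(one, 0.5)
  expect_equal(h1$n_coherent, 3)
  expect_equal(h1$n_incoherent, 0)
  expect_equal(h1$n_pairs, 1)
})
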