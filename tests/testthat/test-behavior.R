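make_schedule <- function(is_target, is_pseudo = rep(FALSE, length(is_target))) {
  n <- length(is_target)
  onset1 <- (seq_len(n) - 1) * 2.4
  structure(list(trials = data.frame(
    pair_index = seq_len(n),
    letter1 = ifelse(is_target, "A", "B"),
    letter2 = ifelse(is_target | is_pseudo, "K", "C"),
    onset1 = onset1, onset2 = onset1 + 1.2,
    is_target = is_target, is_pseudo = is_pseudo,
    stringsAsFactors = FALSE),
    phases = NULL, distractors = NULL, spec = NULL),
    class = "cpt_schedule")
}

test_that("omission rate counts missed targets out of all targets", {
  s <- make_schedule(rep(TRUE, 10))
  # respond to 8 of 10 targets at 400 ms
  resp <- data.frame(time = s$trials$onset2[1:8] + 0.4)
  sc <- score_cpt(s, resp)
  expect_equal(sc$omission_rate, 20)
  expect_equal(sc$n_hits, 8)
  # hit and omission percentages are complementary
  expect_equal(sc$omission_rate + 100 * sc$n_hits / 10, 100)
})

test_that("RTV equals sample SD over mean of hit reaction times", {
  s <- make_schedule(c(TRUE, TRUE, TRUE, FALSE))
  resp <- data.frame(time = s$trials$onset2[1:3] + c(0.3, 0.4, 0.5))
  sc <- score_cpt(s, resp)
  expect_equal(sc$rtv, 0.25, tolerance = 1e-9)  # sd {300,400,500} = 100
  expect_equal(sc$commission_rate, 0)
})

test_that("RTV is invariant under scaling all reaction times", {
  s <- make_schedule(rep(TRUE, 6))
  rts <- c(0.3, 0.35, 0.42, 0.5, 0.61, 0.28)
  sc1 <- score_cpt(s, data.frame(time = s$trials$onset2 + rts))
  sc2 <- score_cpt(s, data.frame(time = s$trials$onset2 + 2 * rts),
                   window = c(150, 2400))
  expect_equal(sc1$rtv, sc2$rtv, tolerance = 1e-9)
})

test_that("commission pools pseudo and plain non-targets with subtype detail", {
  s <- make_schedule(rep(FALSE, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  # press on 2 of 4 pseudo and 1 of 6 other non-targets
  resp <- data.frame(time = s$trials$onset2[c(1, 2, 5)] + 0.4)
  # add two targets so RTV is defined
  s2 <- make_schedule(c(rep(FALSE, 10), TRUE, TRUE),
                      c(rep(TRUE, 4), rep(FALSE, 8)))
  resp2 <- data.frame(time = s2$trials$onset2[c(1, 2, 5, 11, 12)] + 0.4)
  sc <- score_cpt(s2, resp2)
  expect_equal(sc$commission_rate, 100 * 3 / 10)
  expect_equal(sc$commission_rate_pseudo, 50)
  expect_equal(sc$commission_rate_other, 100 * 1 / 6)
})

test_that("responses outside the window or before onset do not count", {
  s <- make_schedule(c(TRUE, TRUE, TRUE))
  resp <- data.frame(time = c(s$trials$onset2[1] + 0.05,   # too early
                              s$trials$onset2[2] + 0.4,
                              s$trials$onset2[3] + 0.6))
  sc <- score_cpt(s, resp)
  expect_equal(sc$omission_rate, 100 / 3, tolerance = 1e-9)
})

test_that("perfect responders score zero errors; rare hits abort RTV", {
  spec <- micro_cpt_spec()
  s <- generate_cpt_block(spec, 3)
  p <- subject_profile(p_hit = 1, p_fa_pseudo = 0, p_fa_other = 0)
  sc <- score_cpt(s, generate_responses(s, p, rng_seed = 1))
  expect_equal(sc$omission_rate, 0)
  expect_equal(sc$commission_rate, 0)
  one <- make_schedule(c(TRUE, TRUE))
  expect_error(score_cpt(one, data.frame(time = one$trials$onset2[1] + 0.4)),
               "fewer than 2")
})

test_that("rating summaries are plain cell means with range validation", {
  r <- data.frame(scale = "inattention", block = "pre", value = c(3, 3))
  expect_equal(summarize_ratings(r)$mean_value, 3)
  r2 <- data.frame(scale = "impulsivity", block = "post", value = c(-3, 3))
  expect_equal(summarize_ratings(r2)$mean_value, 0)
  # hand-summed toy table over 4 subjects x 2 blocks
  toy <- expand.grid(subject = 1:4, block = c("pre", "post"),
                     scale = "hyperactivity", stringsAsFactors = FALSE)
  toy$value <- c(1, 2, 0, 1, -1, 0, 1, 0)
  out <- summarize_ratings(toy)
  expect_equal(out$mean_value[out$block == "pre"], 1)
  expect_equal(out$mean_value[out$block == "post"], 0)
  bad <- data.frame(scale = "inattention", block = "pre", value = 5)
  expect_error(summarize_ratings(bad), "-3")
})
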