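test_that("schedule counts, timing and phase structure are exact for any seed", {
  spec <- cpt_block_spec()
  for (seed in c(1, 17, 202, 4040)) {
    s <- generate_cpt_block(spec, seed)
    expect_equal(nrow(s$trials), 450)
    expect_equal(sum(s$trials$is_target), 135)
    expect_equal(sum(s$trials$is_pseudo), 158)
    expect_equal(sum(!s$trials$is_target & !s$trials$is_pseudo), 157)
    expect_false(is.unsorted(s$trials$onset1, strictly = TRUE))
    expect_true(all(s$trials$onset2 > s$trials$onset1))
    expect_equal(cpt_block_duration(spec), 1080)
    expect_equal(sort(s$phases$kind), c(rep("DP", 3), rep("NDP", 3)))
    expect_equal(nrow(s$distractors), 54)
    expect_equal(as.integer(table(s$distractors$modality)[
      c("audiovisual", "auditory", "visual")]), c(18L, 18L, 18L))
  }
})

test_that("target and lure structure is clean in the letter stream", {
  # exhaustive per schedule: targets are exactly (A,K), pseudo-targets have
  # a K second letter not preceded by A, and no A->K arises across pairs
  for (seed in 1:100) {
    s <- generate_cpt_block(cpt_block_spec(), seed)
    tr <- s$trials
    expect_true(all(tr$letter1[tr$is_target] == "A"))
    expect_true(all(tr$letter2[tr$is_target] == "K"))
    expect_true(all(tr$letter1[tr$is_pseudo] != "A"))
    expect_true(all(tr$letter2[tr$is_pseudo] == "K"))
    other <- !tr$is_target & !tr$is_pseudo
    expect_false(any(tr$letter2[other] == "K"))
    expect_false(any(tr$letter1[other] == "A" & tr$letter2[other] == "K"))
    n <- nrow(tr)
    expect_false(any(tr$letter2[-n] == "A" & tr$letter1[-1] == "K"))
  }
})

test_that("empty target set leaves no K preceded by non-A anywhere", {
  spec <- cpt_block_spec(n_targets = 0, n_pseudo = 0)
  s <- generate_cpt_block(spec, 5)
  stream <- as.vector(rbind(s$trials$letter1, s$trials$letter2))
  expect_false(any(stream == "K"))
  expect_false(any(stream[-length(stream)] == "A" & stream[-1] == "K"))
})

test_that("distractor events lie inside DP windows without overlap", {
  for (seed in c(3, 33)) {
    s <- generate_cpt_block(cpt_block_spec(), seed)
    dp <- s$phases[s$phases$kind == "DP", ]
    for (i in seq_len(nrow(s$distractors))) {
      on <- s$distractors$onset[i]
      off <- on + s$distractors$duration[i]
      expect_true(any(on >= dp$start & off <= dp$end))
    }
    ord <- order(s$distractors$onset)
    on <- s$distractors$onset[ord]
    off <- on + s$distractors$duration[ord]
    expect_true(all(diff(on) >= s$spec$distractor_duration - 1e-9))
    expect_true(all(off[-length(off)] <= on[-1] + 1e-9))
  }
})

test_that("infeasible block specifications are refused", {
  expect_error(cpt_block_spec(n_targets = 300, n_pseudo = 300),
               "infeasible")
  expect_error(cpt_block_spec(phase_length = 100), "tile")
  expect_error(cpt_block_spec(distractor_duration = 11,
                              n_distractors = 54), "overlap")
  expect_error(cpt_block_spec(distractor_modality_counts =
                                c(visual = 10, auditory = 10,
                                  audiovisual = 10)), "sum")
})

test_that("schedules are a deterministic function of (spec, seed)", {
  a <- generate_cpt_block(cpt_block_spec(), 99)
  b <- generate_cpt_block(cpt_block_spec(), 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$distractors, b$distractors)
  c <- generate_cpt_block(cpt_block_spec(), 100)
  expect_false(identical(a$trials$letter1, c$trials$letter1))
})

test_that("deterministic responder presses once per target and nowhere else", {
  s <- generate_cpt_block(cpt_block_spec(), 11)
  p <- subject_profile(p_hit = 1, p_fa_pseudo = 0, p_fa_other = 0)
  resp <- generate_responses(s, p, rng_seed = 2)
  expect_equal(nrow(resp), 135)
  # every keypress sits shortly after a target second-letter onset
  tgt <- s$trials$onset2[s$trials$is_target]
  idx <- findInterval(resp$time, sort(tgt))
  expect_true(all(idx >= 1))
})

test_that("hit fraction matches the binomial expectation", {
  s <- generate_cpt_block(cpt_block_spec(), 21)
  p <- subject_profile(p_hit = 0.8, p_fa_pseudo = 0, p_fa_other = 0)
  n_total <- 0; n_hit <- 0
  for (seed in 1:75) {  # 75 x 135 targets > 10^4 Bernoulli draws
    resp <- generate_responses(s, p, rng_seed = seed)
    n_hit <- n_hit + nrow(resp)
    n_total <- n_total + 135
  }
  sd3 <- 3 * sqrt(0.8 * 0.2 / n_total)
  expect_lt(abs(n_hit / n_total - 0.8), sd3)
})

test_that("degenerate RT spread propagates to zero RTV", {
  s <- generate_cpt_block(cpt_block_spec(), 31)
  p <- subject_profile(p_hit = 1, p_fa_pseudo = 0, p_fa_other = 0,
                       rt_sigma = 0)
  resp <- generate_responses(s, p, rng_seed = 3)
  sc <- score_cpt(s, resp)
  expect_equal(sc$rtv, 0)
  expect_equal(sc$omission_rate, 0)
})
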