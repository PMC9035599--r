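test_that("binarization produces a symmetric game matching joint_P", {
  probs <- fig6_probs()
  game <- binarize_game(probs, tau = 3, alpha_low = 0.25, alpha_high = 0.75)
  expect_true(game$symmetric)
  expect_equal(game$payoff_row["low", "high"],
               joint_P(0.25, 0.75, probs, tau = 3))
  expect_equal(game$payoff_row["high", "low"],
               joint_P(0.75, 0.25, probs, tau = 3))
  expect_equal(game$payoff_col, t(game$payoff_row))

  # near-degenerate binarization: all four cells converge
  eps <- 1e-9
  g2 <- binarize_game(probs, tau = 3, alpha_low = 0.5 - eps,
                      alpha_high = 0.5 + eps)
  expect_lt(diff(range(g2$payoff_row)), 1e-8)

  expect_error(binarize_game(probs, tau = 3, alpha_low = 0.8,
                             alpha_high = 0.2), "alpha_low")
})

test_that("pure Nash enumeration: dominant-strategy and indifferent games", {
  # canonical Prisoner's Dilemma: defect dominates
  pd <- two_by_two_game(matrix(c(3, 5, 0, 1), 2, 2),
                        labels = c("cooperate", "defect"))
  ne <- pure_nash(pd)
  expect_equal(nrow(ne), 1L)
  expect_equal(ne$row, "defect")
  expect_equal(ne$col, "defect")
  expect_true(ne$strict)

  # total indifference: every profile is a weak equilibrium
  flat <- two_by_two_game(matrix(1, 2, 2))
  ne_flat <- pure_nash(flat)
  expect_equal(nrow(ne_flat), 4L)
  expect_false(any(ne_flat$strict))
})

test_that("the binarized encounter game has the two diagonal equilibria", {
  for (bin in list(c(0, 1), c(0.25, 0.75))) {
    game <- binarize_game(fig6_probs(), tau = 3, alpha_low = bin[1],
                          alpha_high = bin[2])
    ne <- pure_nash(game)
    expect_equal(nrow(ne), 2L)
    expect_setequal(paste(ne$row, ne$col), c("low low", "high high"))
    expect_true(all(ne$strict))
  }
})

test_that("pure_nash agrees with brute-force enumeration on random games", {
  withr::with_seed(505, {
    for (i in 1:200) {
      bm <- random_bimatrix()
      game <- two_by_two_game(bm$R, bm$C, labels = c("s1", "s2"))
      got <- pure_nash(game)
      want <- nash_brute_force(bm$R, bm$C)
      got_keys <- sort(paste(match(got$row, game$labels),
                             match(got$col, game$labels)))
      want_keys <- sort(paste(want$i, want$j))
      expect_identical(got_keys, want_keys)
      if (nrow(got) > 0) {
        ord <- order(match(got$row, game$labels), match(got$col, game$labels))
        ordw <- order(want$i, want$j)
        expect_identical(got$strict[ord], as.logical(want$strict[ordw]))
      }
    }
  })
})

test_that("equilibria of symmetric games come in mirrored pairs", {
  withr::with_seed(606, {
    for (i in 1:50) {
      R <- matrix(rnorm(4), 2, 2)
      game <- two_by_two_game(R)
      ne <- pure_nash(game)
      for (k in seq_len(nrow(ne))) {
        expect_true(any(ne$row == ne$col[k] & ne$col == ne$row[k]))
      }
    }
  })
})

test_that("ordinal ranks reproduce the canonical pattern and are invariant", {
  game <- binarize_game(fig6_probs(), tau = 3)
  r <- ordinal_ranks(game)
  expect_false(r$ties)
  expect_equal(r$row["low", "low"], 1)
  expect_equal(r$row["low", "high"], 2)
  expect_equal(r$row["high", "low"], 0)
  expect_equal(r$row["high", "high"], 3)

  # invariance under strictly increasing transforms
  trans <- two_by_two_game(exp(5 * game$payoff_row))
  expect_equal(ordinal_ranks(trans)$row, r$row)

  flat <- two_by_two_game(matrix(2, 2, 2))
  rf <- ordinal_ranks(flat)
  expect_true(rf$ties)
  expect_true(all(rf$row == 1.5))
})

test_that("classification: assurance, PD, dominance-solvable, ties", {
  expect_equal(classify_game(binarize_game(fig6_probs(), tau = 3)),
               "assurance")
  expect_equal(classify_game(binarize_game(fig6_probs(), tau = 3,
                                           alpha_low = 0, alpha_high = 1)),
               "assurance")

  pd <- two_by_two_game(matrix(c(3, 5, 0, 1), 2, 2))
  expect_equal(classify_game(pd), "prisoners_dilemma")

  # below the threshold the diagonal-coordination structure collapses
  low_w <- binarize_game(reduced_probs(0.04, 0.1, 2.0), tau = 3,
                         alpha_low = 0, alpha_high = 1)
  ne <- pure_nash(low_w)
  expect_equal(nrow(ne), 1L)
  expect_false(classify_game(low_w) == "assurance")

  # classification invariant under monotone transforms
  game <- binarize_game(fig6_probs(), tau = 3)
  expect_equal(classify_game(two_by_two_game(game$payoff_row^3)),
               "assurance")

  expect_warning(cls <- classify_game(two_by_two_game(matrix(1, 2, 2))),
                 "Tied")
  expect_equal(cls, "other")
})

test_that("assurance holds across binarization choices at the canonical set", {
  for (lo in c(0.05, 0.15, 0.25)) {
    for (hi in c(0.75, 0.85, 0.95)) {
      game <- binarize_game(fig6_probs(), tau = 3, alpha_low = lo,
                            alpha_high = hi)
      expect_equal(classify_game(game), "assurance")
    }
  }
})

test_that("tidy and glance summarise a game", {
  game <- binarize_game(fig6_probs(), tau = 3)
  td <- tidy(game)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$nash), 2L)
  expect_setequal(td$rank_row, 0:3)

  gl <- glance(game)
  expect_equal(gl$classification, "assurance")
  expect_equal(gl$n_pure_nash, 2L)
  expect_equal(gl$n_strict_nash, 2L)
  expect_true(gl$symmetric)
})
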