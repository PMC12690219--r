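out_row <- function(strategy, cost, qaly) {
  tibble::tibble(strategy = strategy, mean_cost = cost, mean_qaly = qaly)
}

# Independent frontier oracle: a strategy is on the frontier exactly when it
# attains the maximum net monetary benefit for some willingness-to-pay on a
# dense scan (plus the cheapest strategy at WTP 0). Shares no code with
# frontier().
frontier_oracle_members <- function(tab) {
  wtps <- c(0, exp(seq(log(1), log(1e8), length.out = 4000)))
  members <- character(0)
  for (w in wtps) {
    nmb <- tab$mean_qaly * w - tab$mean_cost
    members <- union(members, tab$strategy[which.max(nmb)])
  }
  cheap <- tab$strategy[order(tab$mean_cost, -tab$mean_qaly)][1]
  union(members, cheap)
}

test_that("icer computes the documented ratio and flags dominance", {
  a <- out_row("a", 1000, 10)
  b <- out_row("b", 1000 + 895.09, 10 + 0.0096)
  r <- icer(a, b)
  expect_equal(r$icer, 895.09 / 0.0096, tolerance = 1e-12)
  expect_equal(round(r$icer, 1), 93238.5)
  expect_gt(r$icer, 38223)

  expect_equal(icer(a, out_row("c", 1000, 10.5))$icer, 0)
  dom <- icer(a, out_row("d", 990, 10.1))
  expect_identical(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
  und <- icer(a, out_row("e", 1200, 10))
  expect_true(und$undefined)
})

test_that("the frontier keeps collinear points and removes strict and extended dominance", {
  tri <- dplyr::bind_rows(out_row("a", 0, 1.0), out_row("b", 100, 1.1),
                          out_row("c", 50, 1.05))
  fr <- frontier(tri)
  expect_true(all(fr$on_frontier))
  expect_equal(fr$icer[fr$strategy == "c"], 1000)
  expect_equal(fr$icer[fr$strategy == "b"], 1000)

  tab <- dplyr::bind_rows(out_row("a", 0, 1.0), out_row("worse", 120, 0.9),
                          out_row("b", 100, 1.1))
  fr2 <- frontier(tab)
  expect_identical(fr2$dominance[fr2$strategy == "worse"], "strict")

  # textbook extended dominance: middle strategy's ICER from the previous
  # member exceeds the next member's
  ext <- dplyr::bind_rows(out_row("a", 0, 1.0), out_row("b", 600, 1.01),
                          out_row("c", 800, 1.05))
  fr3 <- frontier(ext)
  expect_identical(fr3$dominance[fr3$strategy == "b"], "extended")
  expect_true(all(fr3$on_frontier[fr3$strategy %in% c("a", "c")]))
})

test_that("the frontier matches a brute-force dominance oracle on 200 random instances", {
  set.seed(4242)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    tab <- out_row(paste0("s", seq_len(k)),
                   round(runif(k, 0, 5000), 2),
                   round(runif(k, 8, 12), 4))
    fr <- frontier(tab)
    expect_setequal(fr$strategy[fr$on_frontier],
                    frontier_oracle_members(tab))
    ic <- fr$icer[fr$on_frontier]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) >= -1e-9))
  }
})

test_that("net-monetary-benefit ranking agrees with the frontier + WTP rule", {
  set.seed(99)
  for (rep in 1:50) {
    k <- sample(3:6, 1)
    tab <- out_row(paste0("s", seq_len(k)), runif(k, 0, 5000),
                   runif(k, 8, 12))
    wtp <- runif(1, 0, 60000)
    best_nmb <- net_monetary_benefit(tab, wtp)$strategy[1]
    choice <- frontier_choice(frontier(tab), wtp)
    expect_identical(choice, best_nmb)
  }
})

test_that("degenerate PSA distributions give a step-function CEAC that picks the cheapest at WTP 0", {
  p <- unclass(default_params())
  p$psa <- lapply(p$psa, function(e) { e$dist <- "point"; e })
  p <- osteo_params(p)
  st <- builtin_strategies()[c(1, 2, 6), ]
  res <- psa(p, st, n_outer = 3, n_inner = 400, seed = 2,
             wtp_grid = c(0, 20000, 38223, 80000))
  expect_true(all(res$ceac$probability %in% c(0, 1)))
  sums <- dplyr::summarise(dplyr::group_by(res$ceac, wtp),
                           s = sum(probability))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  at0 <- res$ceac[res$ceac$wtp == 0 & res$ceac$probability == 1, ]
  cheapest <- res$draws$strategy[which.min(res$draws$cost[res$draws$draw == 1])]
  expect_identical(at0$strategy, cheapest)
})

test_that("tornado bars are sorted, include the discount rate, and widen with the range", {
  p <- default_params()
  ranges <- tibble::tibble(
    parameter = c("costs$dxa (fixed)", "hip disutility narrow",
                  "discount_rate"),
    path = list(c("costs", "dxa"),
                c("utilities", "fracture_multiplier_first", "hip"),
                "discount_rate"),
    low = c(26.2, 0.65, 0),
    high = c(26.2, 0.75, 0.08))
  st <- builtin_strategies()
  tor <- tornado(p, st[1, ], st[2, ], ranges = ranges, n = 1500, seed = 5,
                 horizon = 15)
  expect_identical(nrow(tor), 3L)
  expect_true(all(diff(tor$spread) <= 0))
  fixed <- tor[tor$parameter == "costs$dxa (fixed)", ]
  expect_equal(fixed$spread, 0)
  expect_true("discount_rate" %in% tor$parameter)

  wide <- ranges
  wide$low[2] <- 0.45
  wide$high[2] <- 0.95
  tor2 <- tornado(p, st[1, ], st[2, ], ranges = wide, n = 1500, seed = 5,
                  horizon = 15)
  expect_gte(tor2$spread[tor2$parameter == "hip disutility narrow"],
             tor$spread[tor$parameter == "hip disutility narrow"])
})
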