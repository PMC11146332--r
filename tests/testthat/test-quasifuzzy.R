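test_that("partition fitting uses the observed data space with a midpoint peak", {
  s <- weather_series(data.frame(date = as.Date("2005-01-01") + 0:2,
                                 tmin = c(10, 20, 30), tmax = c(30, 35, 40)),
                      terai_site())
  p <- fit_partition(s, "tmin")
  expect_equal(c(p$l, p$m, p$h), c(10, 20, 30))
  p2 <- fuzzy_partition("ws", 0, 2, 4)
  expect_equal(c(p2$l, p2$m, p2$h), c(0, 2, 4))
  const <- weather_series(data.frame(date = as.Date("2005-01-01") + 0:2,
                                     tmin = c(5, 5, 5), tmax = c(9, 9, 9)),
                          terai_site())
  expect_error(fit_partition(const, "tmin"), "constant")

  # brute-force min/max scan oracle on a synthetic training split
  big <- generate_synthetic_weather(400, terai_site(), seed = 5)
  tr <- chronological_split(big, 0.7)$train
  for (v in c("tmin", "tmax", "ws", "rh", "sr")) {
    pv <- fit_partition(tr, v)
    lo <- Inf; hi <- -Inf
    for (x in tr[[v]]) { lo <- min(lo, x); hi <- max(hi, x) }
    expect_equal(c(pv$l, pv$m, pv$h), c(lo, (lo + hi) / 2, hi))
  }
})

test_that("membership vertices, midpoints and clamping are exact", {
  p <- fuzzy_partition("tmin", 10, 20, 30)
  expect_equal(membership_degrees(10, p)[1, ], c(low = 1, medium = 0, high = 0))
  expect_equal(membership_degrees(20, p)[1, ], c(low = 0, medium = 1, high = 0))
  expect_equal(membership_degrees(30, p)[1, ], c(low = 0, medium = 0, high = 1))
  expect_equal(membership_degrees(15, p)[1, ],
               c(low = 0.5, medium = 0.5, high = 0))
  expect_equal(membership_degrees(35, p)[1, ], c(low = 0, medium = 0, high = 1))
  expect_equal(membership_degrees(5, p)[1, ], c(low = 1, medium = 0, high = 0))
})

test_that("memberships form a partition of unity over random inputs", {
  set.seed(77)
  for (i in 1:40) {
    brk <- sort(runif(3, -50, 150))
    if (any(diff(brk) == 0)) next
    p <- fuzzy_partition("rh", brk[1], brk[2], brk[3])
    x <- runif(300, brk[1] - 30, brk[3] + 30)  # includes clamped regions
    mu <- membership_degrees(x, p)
    expect_true(all(mu >= 0 & mu <= 1))
    expect_lt(max(abs(rowSums(mu) - 1)), 1e-9)
  }
})

test_that("the combination catalogue is the base pair plus all subsets of the rest", {
  combos <- standard_combinations()
  expect_length(combos, 8)
  expect_true(all(vapply(combos, function(v) {
    all(c("tmin", "tmax") %in% v)
  }, logical(1))))
  # brute-force subset enumeration oracle
  opt <- c("ws", "rh", "sr")
  expected <- lapply(0:7, function(bits) {
    extra <- opt[bitwAnd(bits, c(1L, 2L, 4L)) > 0]
    c("tmin", "tmax", extra)
  })
  key <- function(v) paste(sort(v), collapse = "|")
  expect_setequal(vapply(combos, key, character(1)),
                  vapply(expected, key, character(1)))
  expect_identical(unname(rule_group_sizes()),
                   c(9L, 27L, 27L, 27L, 81L, 81L, 81L, 243L))
  expect_equal(sum(rule_group_sizes()), 576)
})

test_that("rule enumeration is the full lexicographic Cartesian product", {
  g1 <- enumerate_rule_group("C1")
  expect_equal(g1$size, 9)
  expect_equal(unname(g1$rules[1, ]), c(1, 1))      # all-low first
  expect_equal(unname(g1$rules[9, ]), c(3, 3))      # all-high last
  # lexicographic: first variable most significant
  expect_equal(unname(g1$rules[2, ]), c(1, 2))
  expect_equal(unname(g1$rules[4, ]), c(2, 1))
  expect_equal(enumerate_rule_group("C8")$size, 243)
  expect_false(anyDuplicated(apply(enumerate_rule_group("C5")$rules, 1,
                                   paste, collapse = "")) > 0)
  # stable across re-enumeration
  expect_identical(enumerate_rule_group("C6"), enumerate_rule_group("C6"))
  lab <- rule_labels(g1)
  expect_identical(lab[1, ], c(tmin = "low", tmax = "low"))
  expect_identical(lab[6, ], c(tmin = "medium", tmax = "high"))
})

test_that("product t-norm firing matches exhaustive hand multiplication", {
  parts <- list(tmin = fuzzy_partition("tmin", 10, 20, 30),
                tmax = fuzzy_partition("tmax", 20, 30, 40))
  g <- enumerate_rule_group("C1")
  # tmin = 15 -> (0.5, 0.5, 0); tmax = 27.5 -> (0.25, 0.75, 0)
  rec <- data.frame(tmin = 15, tmax = 27.5)
  fired <- fire_rule_group(rec, g, parts)
  mu1 <- c(0.5, 0.5, 0); mu2 <- c(0.25, 0.75, 0)
  manual <- as.numeric(t(outer(mu1, mu2)))  # lexicographic order
  expect_equal(as.numeric(fired), manual)
  expect_true(all(fired >= 0 & fired <= 1))

  # a variable with degree zero for a label annihilates those rules
  expect_true(all(fired[1, g$rules[, "tmax"] == 3] == 0))
  expect_true(all(fired[1, g$rules[, "tmin"] == 3] == 0))

  # record at every medium peak: the all-medium rule fires one-hot
  rec_m <- data.frame(tmin = 20, tmax = 30)
  fired_m <- fire_rule_group(rec_m, g, parts)
  expect_equal(as.numeric(fired_m), as.numeric(g$rules[, 1] == 2 &
                                               g$rules[, 2] == 2))
  expect_error(fire_rule_group(data.frame(tmin = 15), g, parts), "tmax")
})

test_that("normalisation is proportionate and guards all-zero firing", {
  expect_equal(as.numeric(normalize_firings(c(1, 1, 2))),
               c(0.25, 0.25, 0.5))
  expect_equal(as.numeric(normalize_firings(rep(0.3, 10))), rep(0.1, 10))
  expect_error(normalize_firings(c(0, 0, 0)), "all-zero")
})

test_that("interim vectors equal fire-then-normalise and sum to 1", {
  s <- generate_synthetic_weather(200, terai_site(), seed = 13)
  parts <- fit_partitions(s)
  for (id in c("C1", "C5", "C8")) {
    g <- enumerate_rule_group(id)
    iv <- interim_vectors(s, id, parts)
    expect_equal(dim(iv), c(200L, g$size))
    expect_lt(max(abs(rowSums(iv) - 1)), 1e-9)
    expect_equal(iv, normalize_firings(fire_rule_group(s, g, parts)))
  }
  # with symmetric partitions, firing already sums to 1 (product of
  # partitions of unity), so normalisation is the identity
  fired <- fire_rule_group(s, enumerate_rule_group("C8"), parts)
  expect_lt(max(abs(rowSums(fired) - 1)), 1e-9)
})

test_that("out-of-range records never produce all-zero firing", {
  parts <- list(tmin = fuzzy_partition("tmin", 10, 20, 30),
                tmax = fuzzy_partition("tmax", 20, 30, 40))
  rec <- data.frame(tmin = c(-5, 100), tmax = c(10, 200))  # far outside
  iv <- interim_vectors(rec, "C1", parts)
  expect_lt(max(abs(rowSums(iv) - 1)), 1e-9)
  # fully clamped records one-hot on the extreme corner rules
  expect_equal(unname(iv[1, 1]), 1)        # all-low corner
  expect_equal(unname(iv[2, ncol(iv)]), 1) # all-high corner
})
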