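mk_scale <- function(...) {
  v <- c(...)
  structure(list(name = "test", by_residue = v), class = "reference_scale")
}

mk_exposure_tab <- function(resno, resid, ratio, abs_area) {
  data.frame(resno = resno, insert = rep("", length(resno)), resid = resid,
             abs_area = abs_area, ratio = ratio,
             klass = classify_exposure(ratio), stringsAsFactors = FALSE)
}

test_that("exposure ratio is an uncapped percentage of the reference area", {
  sc <- mk_scale(LYS = 174.2)
  expect_equal(exposure_ratio(174.2, "LYS", sc), 100)
  expect_equal(exposure_ratio(0, "LYS", sc), 0)
  expect_equal(exposure_ratio(87.1, "LYS", sc), 50)
  expect_gt(exposure_ratio(250, "LYS", sc), 100)
  expect_error(exposure_ratio(10, "XYZ", sc), "XYZ")
})

test_that("classification uses strict thresholds and partitions [0, Inf)", {
  expect_equal(classify_exposure(75.7), "exposed")
  expect_equal(classify_exposure(0), "buried")
  expect_equal(classify_exposure(c(50, 20)),
               c("intermediate", "intermediate"))
  grid <- seq(0, 150, by = 0.5)
  k <- classify_exposure(grid)
  expect_true(all(k %in% c("exposed", "buried", "intermediate")))
  expect_true(all(k[grid < 20] == "buried"))
  expect_true(all(k[grid > 50] == "exposed"))
  expect_true(all(k[grid >= 20 & grid <= 50] == "intermediate"))
  expect_error(exposure_thresholds(20, 50), "buried_max < exposed_min")
})

test_that("becomes_exposed applies the dual criterion to published-style records", {
  a <- mk_exposure_tab(c(526, 536, 529), c("LYS", "SER", "VAL"),
                       c(34.2, 17.4, 0), c(61.17, 39.67, 2.21))
  b <- mk_exposure_tab(c(526, 536, 529), c("LYS", "SER", "VAL"),
                       c(74.0, 54.4, 75.7), c(129.01, 39.81, 96.76))
  d <- becomes_exposed(pair_states(a, b))
  k526 <- d[d$resno == 526, ]
  expect_true(k526$becomes_exposed_ratio)
  expect_true(k526$becomes_exposed_abs)
  expect_true(k526$consensus)
  # ratio criterion fires for S536 but the absolute area barely moves
  s536 <- d[d$resno == 536, ]
  expect_true(s536$becomes_exposed_ratio)
  expect_false(s536$becomes_exposed_abs)
  expect_false(s536$consensus)
  expect_true(d[d$resno == 529, "consensus"])
  expect_equal(d$consensus, d$becomes_exposed_ratio & d$becomes_exposed_abs)
})

test_that("identical states yield no flags; state swap cannot double-flag", {
  a <- mk_exposure_tab(1:6, "LYS", c(10, 34, 60, 80, 49, 51),
                       c(5, 60, 100, 140, 80, 90))
  expect_false(any(becomes_exposed(pair_states(a, a))$consensus))
  for (seed in 1:10) {
    b <- epiunmask:::with_seed(seed, mk_exposure_tab(
      1:6, "LYS", stats::runif(6, 0, 120), stats::runif(6, 0, 200)))
    fwd <- becomes_exposed(pair_states(a, b))
    rev <- becomes_exposed(pair_states(b, a))
    expect_false(any(fwd$becomes_exposed_ratio & rev$becomes_exposed_ratio))
    expect_false(any(fwd$consensus & rev$consensus))
  }
})

test_that("state pairing matches by number+name, reports the rest, honours offsets", {
  a <- mk_exposure_tab(1:4, c("LYS", "VAL", "SER", "GLY"),
                       rep(10, 4), rep(20, 4))
  expect_equal(nrow(pair_states(a, a)$pairs), 4L)

  b <- a
  b$resno[2] <- 99
  p <- pair_states(a, b)
  expect_equal(nrow(p$pairs), 3L)
  expect_equal(p$unpaired_A, 2L)
  expect_equal(p$unpaired_B, 99L)

  b2 <- a
  b2$resid[3] <- "TRP"
  p2 <- pair_states(a, b2)
  expect_equal(p2$mismatched, 3L)
  expect_equal(nrow(p2$pairs), 3L)

  b3 <- a
  b3$resno <- b3$resno + 7
  expect_equal(nrow(pair_states(a, b3, offset = 7)$pairs), 4L)
  expect_error(pair_states(a, b3, offset = 100), "no residues")
})

test_that("domain summary counts exposed and becomes-exposed residues per interval", {
  dm <- data.frame(domain = c("III", "IV"), start = c(328, 533),
                   end = c(532, 667))
  empty <- mk_exposure_tab(integer(0), character(0), numeric(0), numeric(0))
  z <- domain_summary(empty, dm)
  expect_true(all(z$n_exposed == 0))

  one <- mk_exposure_tab(400, "LYS", 80, 150)
  s1 <- domain_summary(one, dm)
  expect_equal(s1$n_exposed[s1$domain == "III"], 1L)
  expect_equal(s1$n_exposed[s1$domain == "IV"], 0L)

  out <- mk_exposure_tab(c(400, 600, 900), "LYS", c(80, 80, 80),
                         rep(150, 3))
  s2 <- domain_summary(out, dm)
  expect_equal(s2$n_exposed[s2$domain == "unassigned"], 1L)
})

test_that("planted differential counts match the plant allocation by domain", {
  ps <- make_paired_structures(n_residues = 40, planted = c(5, 9, 30),
                               seed = 2)
  rep <- run_exposure_pipeline(
    ps$state_a, ps$state_b,
    domain_map = data.frame(domain = c("D1", "D2"), start = c(1, 21),
                            end = c(20, 40)))
  ds <- rep$domains
  expect_equal(ds$n_becomes_exposed[ds$domain == "D1"], 2L)
  expect_equal(ds$n_becomes_exposed[ds$domain == "D2"], 1L)
})

test_that("fragment overlap inference recovers the printed binding intervals", {
  fs <- vip3aa_fragment_set()
  reg <- infer_binding_regions(fs)
  expect_equal(reg$start, c(400, 502))
  expect_equal(reg$end, c(500, 550))
  expect_setequal(reg$support, c("F6+F7", "F7+F8"))
})

test_that("region inference is order-invariant and handles degenerate input", {
  fs <- vip3aa_fragment_set()
  shuffled <- fragment_set(fs$name[c(4, 1, 6, 3, 2, 5)],
                           fs$start[c(4, 1, 6, 3, 2, 5)],
                           fs$end[c(4, 1, 6, 3, 2, 5)],
                           fs$binds[c(4, 1, 6, 3, 2, 5)])
  expect_equal(infer_binding_regions(shuffled), infer_binding_regions(fs))

  apart <- fragment_set(c("X", "Y"), c(1, 500), c(100, 600), c(TRUE, TRUE))
  expect_equal(nrow(infer_binding_regions(apart)), 0L)
  none <- fragment_set("X", 1, 100, FALSE)
  expect_warning(r0 <- infer_binding_regions(none), "no binding fragments")
  expect_equal(nrow(r0), 0L)
  expect_error(fragment_set(c("A", "A"), c(1, 2), c(5, 6), c(TRUE, TRUE)),
               "unique")
  expect_error(fragment_set("A", 5, 5, TRUE), "start must be <")
})
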