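test_that("cumulative disparity matches hand values and a prefix-sum oracle", {
  r <- replicon("t", "GGCC", topology = "linear")
  cv <- cumulative_disparity(r, "GC", stride = 1)
  expect_equal(cv$value, c(1, 2, 1, 0))
  expect_equal(cumulative_disparity(replicon("a", strrep("A", 10),
                                             topology = "linear"),
                                    "GC", stride = 1)$value, rep(0, 10))
  # oracle: explicit per-base loop on a 50 kb synthetic sequence
  s <- random_dna(50000, gc = 0.6, seed = 9)
  rr <- replicon("s", s)
  cv2 <- cumulative_disparity(rr, "GC", stride = 1)
  ch <- strsplit(s, "")[[1]]
  ora <- cumsum((ch == "G") - (ch == "C"))
  expect_equal(cv2$value, ora)
  # final value equals the total base-count difference
  cnt <- table(factor(ch, levels = c("A", "C", "G", "T")))
  expect_equal(cv2$value[length(cv2$value)], unname(cnt["G"] - cnt["C"]))
})

test_that("component sum rules hold exactly on any input", {
  s <- random_dna(20000, gc = 0.55, seed = 4)
  r <- replicon("s", s)
  get <- function(comp) cumulative_disparity(r, comp, stride = 1)$value
  expect_equal(get("RY") + get("MK"), 2 * get("AT"))
  expect_equal(get("RY") - get("MK"), 2 * get("GC"))
  # weak-minus-strong at n is n minus twice the cumulative G+C count
  ch <- strsplit(s, "")[[1]]
  expect_equal(get("WS"), seq_along(ch) - 2 * cumsum(ch %in% c("G", "C")))
})

test_that("reverse complement negates and reverses the disparity curve", {
  s <- random_dna(5000, gc = 0.6, seed = 12)
  for (comp in c("GC", "AT")) {
    v <- cumulative_disparity(replicon("f", s), comp, stride = 1)$value
    vr <- cumulative_disparity(replicon("r", oracle_revcomp(s)), comp,
                               stride = 1)$value
    total <- v[length(v)]
    # value of the reverse complement at n equals -(total - value at L-n)
    expect_equal(vr, -(total - c(rev(v)[-1], 0)))
  }
})

test_that("rotation recomputes the curve and moves the extremum accordingly", {
  g <- fixture("skew_genome", function() {
    generate_genome(synth_spec(401, list(
      synth_replicon_spec("sk", 2e5, gc = 0.6, n_cds = 20,
                          ori = list(pos = 6e4, g = 0.03)))))
  })
  r <- g$replicons$sk
  cv <- cumulative_disparity(r, "GC")
  expect_equal(rotate_to_origin(cv, 0)$value, cv$value)
  expect_equal(rotate_to_origin(cv, r$length)$value, cv$value)
  expect_error(rotate_to_origin(cv, -1), "origin")
  ori_true <- g$manifest$start[g$manifest$type == "ori"]
  est <- locate_skew_extremum(cv)
  expect_lt(abs(est - ori_true), 0.05 * r$length)
  # after rotating to the origin the minimum sits at x ~ 0 (mod L)
  rot <- rotate_to_origin(cv, ori_true)
  est_rot <- locate_skew_extremum(rot)
  d <- min(est_rot, r$length - est_rot)
  expect_lt(d, 0.05 * r$length)
})

test_that("extremum detection honors ties, ends and the constant-curve error", {
  expect_error(locate_skew_extremum(
    cumulative_disparity(replicon("n", strrep("AT", 50), topology = "linear"),
                         "GC", stride = 1)), "constant")
  # monotone curve: extremum at an end
  gmono <- cumulative_disparity(replicon("g", strrep("G", 100),
                                         topology = "linear"),
                                "GC", stride = 1)
  expect_equal(locate_skew_extremum(gmono, "max"), 100)
  expect_equal(locate_skew_extremum(gmono, "min"), 1)
  # tie broken by the smallest coordinate
  vshape <- cumulative_disparity(replicon("v", "CGCG", topology = "linear"),
                                 "GC", stride = 1)
  expect_equal(locate_skew_extremum(vshape), 1)
})

test_that("windowed GC skew agrees with the cumulative-difference quotient", {
  expect_equal(windowed_gc_skew(replicon("g", "GGGG", topology = "linear"),
                                window = 4, stride = 4)$value, 1)
  expect_equal(windowed_gc_skew(replicon("c", "CCCC", topology = "linear"),
                                window = 4, stride = 4)$value, -1)
  expect_true(is.na(windowed_gc_skew(replicon("a", "ATAT",
                                              topology = "linear"),
                                     window = 4, stride = 4)$value))
  s <- random_dna(30000, gc = 0.6, seed = 3)
  r <- replicon("s", s, topology = "linear")
  tr <- windowed_gc_skew(r, window = 2000, stride = 2000)
  cv <- cumulative_disparity(r, "GC", stride = 1)$value
  ch <- strsplit(s, "")[[1]]
  gpc <- cumsum(ch %in% c("G", "C"))
  for (i in seq_len(nrow(tr))) {
    num <- cv[tr$end[i]] - if (tr$start[i] == 0) 0 else cv[tr$start[i]]
    den <- gpc[tr$end[i]] - if (tr$start[i] == 0) 0 else gpc[tr$start[i]]
    expect_equal(tr$value[i], num / den, tolerance = 1e-12)
  }
})
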