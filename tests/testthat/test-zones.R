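make_status <- function(end_insp, end_exp) {
  structure(list(end_insp = end_insp, end_exp = end_exp,
                 tidal = end_insp - end_exp),
            class = "status_images")
}

test_that("status_images averages marked frames and forms the tidal image", {
  # all frames identical -> zero tidal image
  fs <- frame_sequence(array(2, c(4, 2, 2)), 40, "t", 0)
  m <- eitzones:::new_breath_marks(c(2, 4), c(1, 3))
  st <- status_images(fs, m)
  expect_true(all(st$tidal == 0))

  # inspiratory frame = expiratory frame + c -> tidal = c everywhere
  frames <- array(1, c(2, 3, 3)); frames[1, , ] <- 1 + 0.7
  fs <- frame_sequence(frames, 40, "t", 0)
  st <- status_images(fs, eitzones:::new_breath_marks(1L, 2L))
  expect_true(all(abs(st$tidal - 0.7) < 1e-12))

  # 5 random insp + 5 random exp frames vs loop-based per-pixel oracle
  fs <- random_seq(10, 3, 3, seed = 21)
  insp <- c(2L, 4L, 6L, 8L, 10L); exp_ <- c(1L, 3L, 5L, 7L, 9L)
  st <- status_images(fs, eitzones:::new_breath_marks(insp, exp_))
  for (r in 1:3) for (c in 1:3) {
    mi <- mean(sapply(insp, function(t) fs$frames[t, r, c]))
    me <- mean(sapply(exp_, function(t) fs$frames[t, r, c]))
    expect_equal(st$end_insp[r, c], mi)
    expect_equal(st$end_exp[r, c], me)
    expect_equal(st$tidal[r, c], mi - me)
  }
  # definitional identity (up to floating rounding): tidal + end_exp == end_insp
  expect_equal(st$tidal + st$end_exp, st$end_insp, tolerance = 1e-14)

  expect_error(status_images(fs, eitzones:::new_breath_marks(11L, 1L)),
               "out of range")
})

test_that("lung_mask uses strict inequality relative to the image maximum", {
  img <- matrix(c(25, 25.0001, 100, 0), 2, 2)
  m <- lung_mask(img, 0.25)
  expect_false(m[1, 1])   # exactly at threshold: excluded
  expect_true(m[2, 1])    # just above: included
  expect_true(m[1, 2])

  # uniform positive image: every pixel equals the max, so all included
  expect_true(all(lung_mask(matrix(5, 3, 3), 0.25)))

  # hand-enumerated 3x3 case: threshold 0.25 * 10 = 2.5 selects {3,4,10,5}
  img <- matrix(c(0, 1, 2, 3, 4, 10, 0, 0, 5), 3, 3, byrow = TRUE)
  m <- lung_mask(img, 0.25)
  expect_equal(sort(img[m]), c(3, 4, 5, 10))

  expect_error(lung_mask(matrix(-1, 2, 2), 0.25), "no positive signal")
  expect_error(lung_mask(matrix(0, 2, 2), 0.25), "no positive signal")
})

test_that("lung_mask is invariant under positive rescaling", {
  set.seed(31)
  img <- matrix(rnorm(64, 1), 8, 8)
  m <- lung_mask(img, 0.2)
  for (k in c(0.001, 3, 1e6)) expect_equal(lung_mask(k * img, 0.2), m)
})

test_that("classify_step derives categories by set difference", {
  # identical lung regions -> no overinflated, no cyclic
  ee <- matrix(c(4, 4, 0, 0), 2, 2)
  st <- make_status(end_insp = ee + ee, end_exp = ee)
  z <- classify_step(st, thresholds(0.25, 0.20))
  expect_equal(z$lung_ee, z$lung_tidal)
  expect_false(any(z$overinflated))
  expect_false(any(z$cyclic))

  # degenerate tidal image (all zero) propagates the lung_mask error
  st <- make_status(end_insp = matrix(1, 2, 2), end_exp = matrix(1, 2, 2))
  expect_error(classify_step(st), "no positive signal")

  # toy masks lung_ee = {A, B}, lung_tidal = {B, C}
  end_exp <- matrix(0, 1, 4); end_exp[1, 1:2] <- 10       # A = px1, B = px2
  tidal <- matrix(0, 1, 4); tidal[1, 2:3] <- 10           # B = px2, C = px3
  st <- make_status(end_insp = end_exp + tidal, end_exp = end_exp)
  z <- classify_step(st)
  expect_equal(which(z$overinflated), 1L)  # A
  expect_equal(which(z$cyclic), 3L)        # C
})

test_that("recruited_mask is the set difference against the reference", {
  cur <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_false(any(recruited_mask(cur, cur)))
  none <- matrix(FALSE, 2, 2)
  expect_equal(recruited_mask(cur, none), cur)
  ref <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)  # {B}
  expect_equal(which(recruited_mask(cur, ref)), c(1L, 3L))  # {A, C}
  expect_error(recruited_mask(cur, matrix(FALSE, 3, 2)), "share one shape")
})

test_that("zone set-algebra invariants hold on random images", {
  set.seed(77)
  for (i in 1:25) {
    end_exp <- matrix(runif(64), 8, 8)
    tidal <- matrix(runif(64, -0.2, 1), 8, 8)
    st <- make_status(end_insp = end_exp + tidal, end_exp = end_exp)
    z <- classify_step(st)
    ref <- matrix(runif(64) > 0.5, 8, 8)
    rec <- recruited_mask(z$lung_ee, ref)
    expect_false(any(z$overinflated & z$cyclic))
    expect_true(all(z$overinflated <= z$lung_ee))
    expect_true(all(z$cyclic <= z$lung_tidal))
    expect_true(all(rec <= z$lung_ee))
    expect_equal(z$n_negative_tidal, sum(st$tidal < 0))
  }
})

test_that("raising ee_frac never grows lung_ee or overinflated regions", {
  set.seed(13)
  end_exp <- matrix(runif(256), 16, 16)
  tidal <- matrix(runif(256), 16, 16)
  st <- make_status(end_insp = end_exp + tidal, end_exp = end_exp)
  ref <- matrix(runif(256) > 0.6, 16, 16)
  fracs <- c(0.15, 0.25, 0.35, 0.5)
  sizes <- t(sapply(fracs, function(f) {
    z <- classify_step(st, thresholds(ee_frac = f, tidal_frac = 0.20))
    c(ee = sum(z$lung_ee), ovr = sum(z$overinflated),
      rec = sum(recruited_mask(z$lung_ee, ref)))
  }))
  expect_true(all(diff(sizes[, "ee"]) <= 0))
  expect_true(all(diff(sizes[, "ovr"]) <= 0))
  expect_true(all(diff(sizes[, "rec"]) <= 0))
})

test_that("classification commutes with a consistent pixel permutation", {
  set.seed(41)
  end_exp <- matrix(runif(36), 6, 6)
  tidal <- matrix(runif(36), 6, 6)
  perm <- sample(36)
  permute <- function(m) matrix(as.vector(m)[perm], 6, 6)
  z1 <- classify_step(make_status(end_exp + tidal, end_exp))
  z2 <- classify_step(make_status(permute(end_exp) + permute(tidal),
                                  permute(end_exp)))
  expect_equal(z2$overinflated, permute(z1$overinflated))
  expect_equal(z2$cyclic, permute(z1$cyclic))
})
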