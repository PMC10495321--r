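test_that("colour features of a flat gray leaf match hand arithmetic", {
  img <- generate_fixture("flat", size = c(4, 4), value = 0.5)
  f <- color_features(img, matrix(TRUE, 4, 4))
  expect_equal(unname(f[c("R", "G", "B")]), rep(0.5, 3))
  expect_equal(f[["G/R"]], 1); expect_equal(f[["G-R"]], 0)
  expect_equal(f[["(B-G-R)/(B+G)"]], -0.5)
  expect_equal(unname(f[c("r", "g", "b")]), rep(1 / 3, 3))
  expect_equal(unname(f[c("gr", "gb", "br")]), rep(0, 3))
  expect_equal(f[["S"]], 0); expect_equal(f[["V"]], 0.5); expect_equal(f[["H"]], 0)
  # CIELAB lightness of sRGB 0.5 gray via the grDevices conversion oracle
  L_oracle <- unname(grDevices::convertColor(matrix(0.5, 1, 3), "sRGB", "Lab")[1, 1])
  expect_equal(f[["Lab_L"]], L_oracle)
  expect_equal(f[["Lab_L"]], 53.389, tolerance = 1e-4)
})

test_that("a pure green leaf hits the HSV/chromatic corners with capped ratios", {
  px <- array(0, c(4, 4, 3)); px[, , 2] <- 1
  f <- color_features(rgb_image(px), matrix(TRUE, 4, 4))
  expect_equal(unname(f[c("r", "g", "b")]), c(0, 1, 0))
  expect_equal(f[["H"]], 120 / 360)
  expect_equal(f[["S"]], 1); expect_equal(f[["V"]], 1)
  expect_equal(f[["G/R"]], 1e6)   # eps-guarded
})

test_that("two-tone leaf features are the means of the halves", {
  px <- array(0, c(4, 4, 3))
  for (ch in 1:3) {
    px[, 1:2, ch] <- c(0.2, 0.6, 0.2)[ch]
    px[, 3:4, ch] <- c(0.4, 0.8, 0.4)[ch]
  }
  f <- color_features(rgb_image(px), matrix(TRUE, 4, 4))
  expect_equal(unname(f[c("R", "G", "B")]), c(0.3, 0.7, 0.3))
  expect_equal(f[["G-R"]], 0.4)
})

test_that("features depend only on masked pixels", {
  leaf <- disk_leaf_image(size = 32)
  f1 <- c(color_features(leaf$image, leaf$mask),
          texture_features(leaf$image, leaf$mask, levels = 8))
  px <- leaf$image$pixels
  px[, , 1][!leaf$mask] <- runif(sum(!leaf$mask))    # scribble on background
  f2 <- c(color_features(rgb_image(px), leaf$mask),
          texture_features(rgb_image(px), leaf$mask, levels = 8))
  expect_identical(f1, f2)
})

test_that("normalised chromatic coordinates close to one and antisymmetry", {
  set.seed(8)
  for (i in 1:20) {
    px <- array(runif(4 * 4 * 3, 0.05, 0.95), c(4, 4, 3))
    f <- color_features(rgb_image(px), matrix(TRUE, 4, 4))
    expect_equal(f[["r"]] + f[["g"]] + f[["b"]], 1, tolerance = 1e-9)
    expect_equal(f[["gr"]], -(f[["r"]] - f[["g"]]), tolerance = 1e-12)
  }
})

test_that("gray quantisation bins the foreground range as specified", {
  cb <- generate_fixture("checkerboard", size = c(4, 4), levels = c(0, 1))
  q <- quantize_gray(cb, matrix(TRUE, 4, 4), levels = 2)
  expect_equal(q$index[1:2, 1:2], matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_false(q$degenerate)

  flat <- generate_fixture("flat", size = c(4, 4), value = 0.3)
  qf <- quantize_gray(flat, matrix(TRUE, 4, 4), levels = 8)
  expect_true(qf$degenerate)
  expect_true(all(qf$index == 0L))

  # 64-column linear luminance ramp maps column c to level c
  ramp <- matrix(seq(0.1, 0.9, length.out = 64), 16, 64, byrow = TRUE)
  qr <- quantize_gray(rgb_image(ramp), matrix(TRUE, 16, 64), levels = 64)
  expect_equal(qr$index[1, ], 0:63)
})

test_that("tiny GLCMs match the hand-enumerated pair counts", {
  idx <- matrix(c(0L, 1L, 0L, 1L), 2, 2)       # [[0,0],[1,1]] by rows
  gray <- list(index = idx, valid = matrix(TRUE, 2, 2), levels = 2L,
               degenerate = FALSE)
  g0 <- glcm(gray, angle = 0)
  expect_equal(g0$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  g90 <- glcm(gray, angle = 90)
  expect_equal(g90$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  flat <- list(index = matrix(0L, 3, 3), valid = matrix(TRUE, 3, 3),
               levels = 2L, degenerate = TRUE)
  expect_equal(glcm(flat, angle = 45)$p[1, 1], 1)
})

test_that("glcm statistics match hand evaluation on two-cell matrices", {
  mk <- function(p) structure(list(p = p, levels = nrow(p), distance = 1L,
                                   angle = 0), class = "glcm_matrix")
  s1 <- glcm_stats(mk(matrix(c(1, 0, 0, 0), 2, 2)))
  expect_equal(unname(s1[c("ASM", "IDM", "CON", "ENT")]), c(1, 1, 0, 0))
  expect_true(is.na(s1[["COR"]]))

  s2 <- glcm_stats(mk(diag(c(0.5, 0.5))))
  expect_equal(unname(s2), c(0.5, 1, 0, log(2), 1))

  s3 <- glcm_stats(mk(matrix(c(0, 0.5, 0.5, 0), 2, 2)))
  expect_equal(unname(s3), c(0.5, 0.5, 1, log(2), -1))
})

test_that("GLCM and statistics agree with the brute-force oracle", {
  set.seed(99)
  for (case in 1:100) {
    H <- sample(3:8, 1); W <- sample(3:8, 1); L <- sample(2:5, 1)
    idx <- matrix(sample(0:(L - 1), H * W, replace = TRUE), H, W)
    valid <- matrix(runif(H * W) > 0.2, H, W)
    gray <- list(index = ifelse(valid, idx, NA_integer_), valid = valid,
                 levels = L, degenerate = FALSE)
    for (ang in c(0, 45, 90, 135)) {
      Po <- tryCatch(oracle_glcm(idx, valid, L, angle = ang), error = function(e) NULL)
      if (is.null(Po) || any(!is.finite(Po))) {
        expect_error(glcm(gray, angle = ang), "no valid")
        next
      }
      g <- glcm(gray, angle = ang)
      expect_lt(max(abs(g$p - Po)), 1e-12)
      so <- oracle_glcm_stats(Po)
      si <- glcm_stats(g)
      expect_equal(unname(si[1:4]), unname(so[1:4]), tolerance = 1e-12)
      expect_equal(si[["COR"]], so[["COR"]], tolerance = 1e-10)
    }
  }
})

test_that("entropy is zero exactly when energy saturates", {
  set.seed(12)
  for (i in 1:20) {
    L <- sample(2:6, 1)
    p <- matrix(rexp(L * L), L, L); p <- (p + t(p)); p <- p / sum(p)
    g <- structure(list(p = p, levels = L, distance = 1L, angle = 0),
                   class = "glcm_matrix")
    s <- glcm_stats(g)
    expect_true((s[["ENT"]] == 0) == (s[["ASM"]] == 1))
  }
  one <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), levels = 2L,
                        distance = 1L, angle = 0), class = "glcm_matrix")
  s <- glcm_stats(one)
  expect_identical(s[["ENT"]], 0); expect_identical(s[["ASM"]], 1)
})

test_that("direction-averaged texture features are 90-degree rotation invariant", {
  leaf <- disk_leaf_image(size = 32)
  px <- leaf$image$pixels
  set.seed(4)
  px[, , 1][leaf$mask] <- runif(sum(leaf$mask), 0.2, 0.7)
  img <- rgb_image(px)
  rot <- rgb_image(array(apply(px, 3, function(m) t(m[nrow(m):1, ])),
                         dim = dim(px)))
  rot_mask <- t(leaf$mask[nrow(leaf$mask):1, ])
  a <- texture_features(img, leaf$mask, levels = 8)
  b <- texture_features(rot, rot_mask, levels = 8)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("flat leaves give the degenerate texture signature", {
  tf <- texture_features(generate_fixture("flat", c(8, 8), value = 0.5),
                         matrix(TRUE, 8, 8))
  expect_equal(unname(tf[c("ASM", "IDM", "CON", "ENT")]), c(1, 1, 0, 0))
  expect_true(is.na(tf[["COR"]]))
})

test_that("feature tables have the fixed shape, order and determinism", {
  ds <- generate_dataset(generator_config(n_samples = 3, image_size = c(48, 48),
                                          seed = 6))
  imgs <- lapply(ds, `[[`, "image")
  masks <- lapply(ds, `[[`, "true_mask")
  tab <- extract_features(imgs, masks, levels = 16)
  expect_equal(dim(tab), c(3, 29))
  expect_identical(names(tab), feature_names())
  expect_false(anyNA(tab[, setdiff(names(tab), "COR")]))

  dup <- extract_features(imgs[c(1, 1)], masks[c(1, 1)], levels = 16)
  expect_identical(unname(unlist(dup[1, ])), unname(unlist(dup[2, ])))

  bad <- matrix(FALSE, 48, 48)
  expect_error(extract_features(imgs[1], list(bad), sample_ids = "leaf_A"),
               "leaf_A")
})
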